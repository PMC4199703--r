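#' Distortion-scan parameters
#'
#' @param loess_span LOESS span: fraction of markers in each local
#'   neighbourhood (default 0.3).
#' @param curve_threshold smoothed -log10(p) level the curve must exceed
#'   (default 3, i.e. the p = 0.001 line on the -log10 scale).
#' @param min_consecutive minimum run of qualifying markers (default 3).
#' @param p_cut per-marker p-value each member must beat (default 0.001).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(loess_span = 0.3, curve_threshold = 3.0,
                        min_consecutive = 3L, p_cut = 0.001) {
  stopifnot(loess_span > 0, loess_span <= 1, min_consecutive >= 1,
            p_cut > 0, p_cut < 1, curve_threshold >= 0)
  structure(list(loess_span = loess_span,
                 curve_threshold = curve_threshold,
                 min_consecutive = as.integer(min_consecutive),
                 p_cut = p_cut), class = "scan_config")
}

#' LOESS smoothing of -log10(p) along a linkage group
#'
#' Degree-1 local regression with tricube weights over the span-fraction
#' nearest neighbours, evaluated at each marker position, single pass (no
#' robustness iterations). With fewer than three points the input is
#' returned unchanged with a warning. Very small spans are widened to keep
#' at least three points in every local fit.
#'
#' @param positions sorted marker positions (cM).
#' @param values values to smooth (e.g. -log10 p).
#' @param span LOESS span.
#' @return Numeric vector of smoothed values at `positions`.
#' @export
loess_smooth <- function(positions, values, span = 0.3) {
  stopifnot(length(positions) == length(values))
  n <- length(values)
  if (n < 3) {
    warning("fewer than 3 points; returning input unchanged")
    return(values)
  }
  if (is.unsorted(positions)) stop("positions must be sorted")
  span_used <- max(span, min(1, 3.5 / n))
  # tiny neighbourhoods on short groups trigger harmless pseudoinverse
  # chatter from the underlying fitter
  suppressWarnings({
    fit <- stats::loess(values ~ positions, span = span_used, degree = 1,
                        family = "gaussian", surface = "direct",
                        control = stats::loess.control(iterations = 1))
    out <- unname(stats::predict(fit, data.frame(positions = positions)))
  })
  out
}

#' Call distortion regions along one linkage group
#'
#' A region is a maximal run of consecutive markers where the smoothed
#' curve exceeds `curve_threshold`, the marker p-value is below `p_cut`,
#' and the skew direction is constant, with run length at least
#' `min_consecutive`. Region bounds are the first and last member
#' positions.
#'
#' @param positions sorted marker positions (cM).
#' @param p marker p-values.
#' @param direction marker skew directions (`"excess_presence"` /
#'   `"excess_absence"`).
#' @param smoothed smoothed -log10(p) values aligned with the markers.
#' @param config a [scan_config()].
#' @param markers optional marker ids.
#' @return data.frame with one row per region: `start_cM`, `end_cM`,
#'   `direction`, `peak` (max smoothed value in the run), `n_markers`,
#'   `markers` (comma-joined ids).
#' @export
call_regions <- function(positions, p, direction, smoothed,
                         config = scan_config(), markers = NULL) {
  n <- length(positions)
  stopifnot(length(p) == n, length(direction) == n, length(smoothed) == n)
  if (is.null(markers)) markers <- as.character(seq_len(n))
  qual <- !is.na(p) & !is.na(smoothed) &
    smoothed > config$curve_threshold & p < config$p_cut
  sgn <- ifelse(direction == "excess_presence", 1L, -1L)
  key <- ifelse(qual, sgn, 0L)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= config$min_consecutive
  if (!any(keep))
    return(data.frame(start_cM = numeric(0), end_cM = numeric(0),
                      direction = character(0), peak = numeric(0),
                      n_markers = integer(0), markers = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(which(keep), function(i) {
    idx <- starts[i]:ends[i]
    data.frame(start_cM = positions[idx[1L]],
               end_cM = positions[idx[length(idx)]],
               direction = if (r$values[i] > 0) "excess_presence" else
                 "excess_absence",
               peak = max(smoothed[idx]),
               n_markers = length(idx),
               markers = paste(markers[idx], collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Scan a genetic map for segregation-distortion regions
#'
#' Joins per-marker distortion statistics onto map positions, smooths
#' -log10(p) along each linkage group with LOESS, and calls regions with
#' the three-consecutive-marker rule.
#'
#' @param map a `genetic_map`, or a data.frame with columns
#'   `linkage_group`, `marker`, `position_cM`.
#' @param sda an [sda_screen()] table (columns `marker`, `p`, `neglog10p`,
#'   `direction`).
#' @param config a [scan_config()].
#' @return Object of class `distortion_scan`: list with `points` (tidy
#'   per-marker table: `linkage_group`, `marker`, `position_cM`,
#'   `neglog10p`, `direction`, `smoothed`, `in_region`) and `regions`
#'   (per-region table with `linkage_group` prepended).
#' @export
scan_distortion <- function(map, sda, config = scan_config()) {
  tab <- if (inherits(map, "genetic_map")) map$table else map
  stopifnot(all(c("linkage_group", "marker", "position_cM") %in% names(tab)))
  i <- match(tab$marker, sda$marker)
  if (anyNA(i)) stop("marker id(s) in map missing from the SDA table")
  pts <- data.frame(linkage_group = tab$linkage_group,
                    marker = tab$marker,
                    position_cM = tab$position_cM,
                    p = sda$p[i],
                    neglog10p = sda$neglog10p[i],
                    direction = sda$direction[i],
                    stringsAsFactors = FALSE)
  pts$smoothed <- NA_real_
  pts$in_region <- FALSE
  regions <- NULL
  for (g in unique(pts$linkage_group)) {
    sel <- which(pts$linkage_group == g)
    sel <- sel[order(pts$position_cM[sel])]
    d <- pts[sel, ]
    sm <- if (nrow(d) >= 3)
      loess_smooth(d$position_cM, d$neglog10p, config$loess_span)
    else d$neglog10p
    pts$smoothed[sel] <- sm
    if (nrow(d) < config$min_consecutive) next
    reg <- call_regions(d$position_cM, d$p, d$direction, sm, config,
                        markers = d$marker)
    if (nrow(reg)) {
      member <- unlist(strsplit(reg$markers, ","), use.names = FALSE)
      pts$in_region[pts$marker %in% member] <- TRUE
      regions <- rbind(regions,
                       cbind(linkage_group = g, reg,
                             stringsAsFactors = FALSE))
    }
  }
  if (is.null(regions))
    regions <- data.frame(linkage_group = integer(0), start_cM = numeric(0),
                          end_cM = numeric(0), direction = character(0),
                          peak = numeric(0), n_markers = integer(0),
                          markers = character(0), stringsAsFactors = FALSE)
  structure(list(points = pts, regions = regions, config = config),
            class = "distortion_scan")
}

#' @export
print.distortion_scan <- function(x, ...) {
  cat(sprintf("distortion scan: %d markers on %d linkage groups, %d region(s)\n",
              nrow(x$points), length(unique(x$points$linkage_group)),
              nrow(x$regions)))
  if (nrow(x$regions)) {
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf("  LG %s: %.1f-%.1f cM, %s, peak %.2f, %d markers\n",
                  as.character(x$regions$linkage_group[i]),
                  x$regions$start_cM[i], x$regions$end_cM[i],
                  x$regions$direction[i], x$regions$peak[i],
                  x$regions$n_markers[i]))
  }
  invisible(x)
}

#' @export
plot.distortion_scan <- function(x, linkage_group = NULL, ...) {
  pts <- x$points
  if (!is.null(linkage_group))
    pts <- pts[pts$linkage_group %in% linkage_group, ]
  if (!nrow(pts)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  pts <- pts[order(pts$linkage_group, pts$position_cM), ]
  graphics::plot(pts$position_cM, pts$neglog10p,
                 col = ifelse(pts$in_region, "red", "grey40"),
                 pch = 16, xlab = "position (cM)",
                 ylab = expression(-log[10](p)), ...)
  for (g in unique(pts$linkage_group)) {
    d <- pts[pts$linkage_group == g, ]
    graphics::lines(d$position_cM, d$smoothed, col = "blue")
  }
  graphics::abline(h = x$config$curve_threshold, lty = 2)
  invisible(x)
}
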