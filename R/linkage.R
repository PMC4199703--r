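#' Map-construction parameters
#'
#' @param group_lod minimum pairwise LOD for two markers to join one
#'   linkage group (default 14).
#' @param order_min_lod minimum pairwise LOD for a pair to inform marker
#'   ordering (default 1.0).
#' @param max_rf maximum recombination fraction for a pair to inform
#'   ordering (default 0.35).
#' @return An object of class `map_config`. Distances always use the
#'   Kosambi mapping function.
#' @export
map_config <- function(group_lod = 14, order_min_lod = 1.0, max_rf = 0.35) {
  stopifnot(group_lod > 0, order_min_lod >= 0, max_rf > 0, max_rf < 0.5)
  structure(list(group_lod = group_lod, order_min_lod = order_min_lod,
                 max_rf = max_rf, mapping_function = "kosambi"),
            class = "map_config")
}

#' Kosambi mapping function and its inverse
#'
#' `kosambi_cm()` maps a recombination fraction `r` in `[0, 0.5)` to a map
#' distance `d = 25 ln((1 + 2r) / (1 - 2r))` centimorgans;
#' `kosambi_inverse()` maps a distance back to
#' `r = (e^{d/25} - 1) / (2 (e^{d/25} + 1))`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return Numeric vector of distances (cM) or fractions.
#' @examples
#' kosambi_cm(0.10)              # ~10.14 cM
#' kosambi_inverse(kosambi_cm(0.25))
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0)) stop("d must be >= 0")
  e <- exp(d / 25)
  (e - 1) / (2 * (e + 1))
}

#' Pairwise recombination fractions and LOD scores
#'
#' For every pair of presence/absence marker vectors, over
#' pairwise-complete progeny: `R` is the number of state mismatches,
#' `rf = min(R/n, 0.5)`, and the base-10 LOD of linkage versus
#' independence, evaluated at the estimate, is
#' `R log10(rf) + (n - R) log10(1 - rf) + n log10 2` (with `0 log 0 = 0`).
#' Mismatch fractions above 0.5 (repulsion-like pairs) are capped at
#' `rf = 0.5` with `lod = 0`; pairs with no shared typed progeny are `NA`.
#'
#' @param presence markers x progeny matrix of 0/1/`NA`.
#' @return List of class `pairwise_linkage` with symmetric matrices `rf`,
#'   `lod` and `n` (informative progeny).
#' @export
pairwise_linkage <- function(presence) {
  stopifnot(is.matrix(presence), nrow(presence) >= 1)
  A <- (presence == 1); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  B <- (presence == 0); B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
  n <- tcrossprod(A + B)
  R <- tcrossprod(A, B) + tcrossprod(B, A)
  frac <- R / n                       # NaN where n = 0
  t1 <- R * log10(frac); t1[R == 0] <- 0
  t2 <- (n - R) * log10(1 - frac); t2[R == n] <- 0
  lod <- t1 + t2 + n * log10(2)
  rf <- pmin(frac, 0.5)
  cap <- !is.nan(frac) & frac > 0.5
  rf[cap] <- 0.5
  lod[cap] <- 0
  rf[n == 0] <- NA_real_
  lod[n == 0] <- NA_real_
  diag(rf) <- 0
  diag(lod) <- NA_real_
  dimnames(rf) <- dimnames(lod) <- dimnames(n) <-
    list(rownames(presence), rownames(presence))
  structure(list(rf = rf, lod = lod, n = n), class = "pairwise_linkage")
}

#' Group markers by LOD threshold
#'
#' Linkage groups are the connected components of the graph whose edges
#' join marker pairs with LOD at or above `group_lod` (single-linkage
#' transitive closure). Singletons are reported as unplaced.
#'
#' @param linkage a [pairwise_linkage()] object.
#' @param group_lod grouping threshold.
#' @return List with `groups` (list of marker-id vectors, largest first)
#'   and `unplaced` (singleton marker ids).
#' @export
group_markers <- function(linkage, group_lod = 14) {
  lod <- linkage$lod
  m <- nrow(lod)
  if (m == 0) return(list(groups = list(), unplaced = character(0)))
  adj <- !is.na(lod) & lod >= group_lod
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  ids <- rownames(lod)
  parts <- split(ids, comp)
  sizes <- lengths(parts)
  singles <- unlist(parts[sizes == 1L], use.names = FALSE)
  groups <- parts[sizes > 1L]
  first_id <- vapply(groups, function(g) sort(g)[1L], "")
  groups <- groups[order(-lengths(groups), first_id)]
  names(groups) <- NULL
  list(groups = lapply(groups, sort),
       unplaced = sort(as.character(singles %||% character(0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SARF cost matrix: rf where the pair qualifies for ordering, else the
# maximum penalty 0.5
.order_cost <- function(markers, linkage, config) {
  rf <- linkage$rf[markers, markers, drop = FALSE]
  lod <- linkage$lod[markers, markers, drop = FALSE]
  q <- !is.na(rf) & !is.na(lod) &
    lod >= config$order_min_lod & rf <= config$max_rf
  D <- matrix(0.5, length(markers), length(markers),
              dimnames = dimnames(rf))
  D[q] <- rf[q]
  diag(D) <- 0
  diag(q) <- FALSE
  list(D = D, qualifying = q)
}

.sarf <- function(ord, D) sum(D[cbind(ord[-length(ord)], ord[-1L])])

#' Order the markers of one linkage group
#'
#' Deterministic seriation minimising the sum of adjacent recombination
#' fractions (SARF): the two farthest linked markers (largest qualifying
#' rf) seed the order; remaining markers are inserted nearest-first at the
#' position of least SARF increase; a 2-opt segment-reversal pass then
#' polishes to a local optimum. Only pairs with LOD at least
#' `order_min_lod` and rf at most `max_rf` inform the objective;
#' non-qualifying pairs cost the maximum 0.5. Orientation is normalised so
#' the first marker id sorts before the last.
#'
#' @param markers marker ids of the group (length >= 2).
#' @param linkage a [pairwise_linkage()] object covering them.
#' @param config a [map_config()].
#' @return Character vector: the ordered marker ids.
#' @export
order_group <- function(markers, linkage, config = map_config()) {
  stopifnot(length(markers) >= 2)
  markers <- sort(markers)            # canonical input order
  if (length(markers) == 2) return(markers)
  oc <- .order_cost(markers, linkage, config)
  D <- oc$D
  if (!any(oc$qualifying)) {
    warning("no qualifying pairs; ordering by marker id")
    return(markers)
  }
  # farthest qualifying pair seeds the order (row-major tie-break)
  Q <- ifelse(oc$qualifying, D, -1)
  seedi <- which(Q == max(Q), arr.ind = TRUE)
  seedi <- seedi[order(seedi[, 1L], seedi[, 2L]), , drop = FALSE][1L, ]
  ord <- markers[sort(seedi)]
  placed <- markers %in% ord
  while (!all(placed)) {
    un <- markers[!placed]
    dmin <- vapply(un, function(u) min(D[u, ord]), 0)
    u <- un[order(dmin, un)][1L]
    k <- length(ord)
    # SARF increase for insertion at each of the k + 1 slots
    inc <- numeric(k + 1L)
    inc[1L] <- D[u, ord[1L]]
    inc[k + 1L] <- D[ord[k], u]
    if (k > 1L) for (s in 2L:k)
      inc[s] <- D[ord[s - 1L], u] + D[u, ord[s]] - D[ord[s - 1L], ord[s]]
    s <- which.min(inc)
    ord <- append(ord, u, after = s - 1L)
    placed[markers == u] <- TRUE
  }
  # 2-opt polish: reverse any segment that strictly lowers SARF
  k <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        left <- if (i > 1L) D[ord[i - 1L], ord[i]] else 0
        right <- if (j < k) D[ord[j], ord[j + 1L]] else 0
        nleft <- if (i > 1L) D[ord[i - 1L], ord[j]] else 0
        nright <- if (j < k) D[ord[i], ord[j + 1L]] else 0
        if (nleft + nright < left + right - 1e-12) {
          ord[i:j] <- ord[j:i]
          improved <- TRUE
        }
      }
    }
  }
  if (ord[1L] > ord[k]) ord <- rev(ord)
  ord
}

#' Cumulative Kosambi positions along an ordered group
#'
#' The first marker sits at 0 cM; each next marker adds the Kosambi
#' distance of the adjacent recombination fraction. An undefined adjacent
#' rf (no shared typed progeny) falls back to the nearest typed pair
#' spanning the gap, its Kosambi length split evenly across the spanned
#' gaps. Adjacent fractions at the 0.5 cap are truncated to 0.49 to keep
#' distances finite.
#'
#' @param ordered ordered marker ids.
#' @param linkage a [pairwise_linkage()] object.
#' @return Numeric vector of cM positions, named by marker.
#' @export
map_positions <- function(ordered, linkage) {
  k <- length(ordered)
  if (k == 1L) return(stats::setNames(0, ordered))
  rf_adj <- linkage$rf[cbind(ordered[-k], ordered[-1L])]
  gap <- numeric(k - 1L)
  for (i in seq_len(k - 1L)) {
    r <- rf_adj[i]
    if (!is.na(r)) {
      gap[i] <- kosambi_cm(min(r, 0.49))
    } else {
      # nearest typed pair spanning this gap
      found <- FALSE
      if (k >= 3L) for (w in 2L:(k - 1L)) {
        for (a in max(1L, i - w + 1L):i) {
          b <- a + w
          if (b > k) next
          r2 <- linkage$rf[ordered[a], ordered[b]]
          if (!is.na(r2)) {
            gap[i] <- kosambi_cm(min(r2, 0.49)) / w
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) {
        warning("no typed pair spans a gap; zero distance used")
        gap[i] <- 0
      }
    }
  }
  stats::setNames(cumsum(c(0, gap)), ordered)
}

#' Build a pseudo-testcross linkage map from a presence matrix
#'
#' Runs [pairwise_linkage()], [group_markers()], [order_group()] and
#' [map_positions()] for one parent's SDA presence/absence matrix.
#'
#' @param presence markers x progeny matrix of 0/1/`NA`.
#' @param config a [map_config()].
#' @param parent label stored with the map (e.g. `"mother"`).
#' @return Object of class `genetic_map`: list with `table` (data.frame
#'   `parent`, `linkage_group`, `marker`, `position_cM`), `groups`,
#'   `unplaced`, `config` and `linkage`.
#' @export
build_linkage_map <- function(presence, config = map_config(),
                              parent = "unknown") {
  if (nrow(presence) == 0)
    return(structure(list(table = data.frame(parent = character(0),
                                             linkage_group = integer(0),
                                             marker = character(0),
                                             position_cM = numeric(0)),
                          groups = list(), unplaced = character(0),
                          config = config, linkage = NULL),
                     class = "genetic_map"))
  pl <- pairwise_linkage(presence)
  grp <- group_markers(pl, config$group_lod)
  tabs <- vector("list", length(grp$groups))
  for (g in seq_along(grp$groups)) {
    ord <- order_group(grp$groups[[g]], pl, config)
    pos <- map_positions(ord, pl)
    tabs[[g]] <- data.frame(parent = parent, linkage_group = g,
                            marker = ord, position_cM = unname(pos),
                            stringsAsFactors = FALSE)
  }
  table <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(parent = character(0), linkage_group = integer(0),
               marker = character(0), position_cM = numeric(0))
  structure(list(table = table, groups = grp$groups,
                 unplaced = grp$unplaced, config = config, linkage = pl),
            class = "genetic_map")
}

#' Name homologs A-D within each chromosome
#'
#' Given an assignment of linkage groups to chromosomes (e.g. from
#' [assign_chromosomes()]), homologs within a chromosome are lettered A-D
#' by descending marker count, ties broken by smallest marker id. More
#' than four groups on one chromosome are flagged and lettered onward
#' (E, F, ...).
#'
#' @param map a `genetic_map`.
#' @param group_chrom named vector mapping linkage-group id (as character)
#'   to chromosome label.
#' @return The `genetic_map` with `chrom` and `homolog` columns added to
#'   its table and a combined `lg_name` (e.g. `"4B"`).
#' @export
name_homologs <- function(map, group_chrom) {
  stopifnot(inherits(map, "genetic_map"))
  tab <- map$table
  tab$chrom <- unname(group_chrom[as.character(tab$linkage_group)])
  tab$homolog <- NA_character_
  for (cc in unique(stats::na.omit(tab$chrom))) {
    gs <- unique(tab$linkage_group[!is.na(tab$chrom) & tab$chrom == cc])
    cnt <- vapply(gs, function(g) sum(tab$linkage_group == g), 0L)
    fid <- vapply(gs, function(g) min(tab$marker[tab$linkage_group == g]), "")
    gs <- gs[order(-cnt, fid)]
    if (length(gs) > 4L)
      warning(sprintf("chromosome %s has %d groups; lettering beyond D",
                      cc, length(gs)))
    for (i in seq_along(gs))
      tab$homolog[tab$linkage_group == gs[i]] <- LETTERS[i]
  }
  tab$lg_name <- ifelse(is.na(tab$chrom), NA_character_,
                        paste0(tab$chrom, tab$homolog))
  map$table <- tab
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  tab <- x$table
  cat(sprintf("genetic map: %d markers in %d linkage groups (%d unplaced)\n",
              nrow(tab), length(x$groups), length(x$unplaced)))
  if (nrow(tab)) {
    len <- tapply(tab$position_cM, tab$linkage_group, max)
    cat(sprintf("  total length: %.1f cM; group sizes %d-%d markers\n",
                sum(len), min(table(tab$linkage_group)),
                max(table(tab$linkage_group))))
  }
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) {
  tab <- object$table
  if (!nrow(tab))
    return(data.frame(linkage_group = integer(0), n_markers = integer(0),
                      length_cM = numeric(0)))
  out <- do.call(rbind, lapply(split(tab, tab$linkage_group), function(d) {
    data.frame(linkage_group = d$linkage_group[1],
               lg_name = if ("lg_name" %in% names(d)) d$lg_name[1] else NA,
               n_markers = nrow(d), length_cM = max(d$position_cM))
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.genetic_map <- function(x, ...) {
  tab <- x$table
  if (!nrow(tab)) {
    warning("empty map")
    return(invisible(x))
  }
  gs <- sort(unique(tab$linkage_group))
  graphics::plot(NA, xlim = c(0.5, length(gs) + 0.5),
                 ylim = c(max(tab$position_cM), 0),
                 xlab = "linkage group", ylab = "position (cM)",
                 xaxt = "n", ...)
  graphics::axis(1, at = seq_along(gs), labels = gs)
  for (i in seq_along(gs)) {
    d <- tab[tab$linkage_group == gs[i], ]
    graphics::segments(i, 0, i, max(d$position_cM))
    graphics::segments(i - 0.2, d$position_cM, i + 0.2, d$position_cM)
  }
  invisible(x)
}
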