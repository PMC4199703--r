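#' Synteny-comparison parameters
#'
#' @param evalue_cutoff maximum e-value (strict) for a hit to qualify;
#'   the default 1e-5 is the permissive screen, 1e-20 the stringent
#'   alternative.
#' @param min_votes minimum number of hit-bearing mapped markers required
#'   before a linkage group is assigned to a chromosome.
#' @return An object of class `synteny_config`.
#' @export
synteny_config <- function(evalue_cutoff = 1e-5, min_votes = 3L) {
  stopifnot(evalue_cutoff > 0, min_votes >= 1)
  structure(list(evalue_cutoff = evalue_cutoff,
                 min_votes = as.integer(min_votes)),
            class = "synteny_config")
}

#' Keep the single best qualifying hit per marker
#'
#' Among hits with e-value strictly below the cutoff, the best hit is the
#' one with the highest bitscore; ties are broken by lowest e-value, then
#' lowest subject position. Markers with no qualifying hit are dropped.
#'
#' @param hits data.frame as from [read_blast_table()] (columns `marker`,
#'   `subject`, `subject_pos`, `evalue`, `bitscore`).
#' @param config a [synteny_config()].
#' @return data.frame with at most one row per marker.
#' @export
filter_best_hits <- function(hits, config = synteny_config()) {
  stopifnot(all(c("marker", "subject", "subject_pos", "evalue",
                  "bitscore") %in% names(hits)))
  h <- hits[hits$evalue < config$evalue_cutoff, , drop = FALSE]
  if (!nrow(h)) return(h)
  h <- h[order(h$marker, -h$bitscore, h$evalue, h$subject_pos), ,
         drop = FALSE]
  h <- h[!duplicated(h$marker), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Assign linkage groups to reference chromosomes by majority vote
#'
#' Each mapped marker with a best hit votes for its subject chromosome;
#' a linkage group is assigned to the chromosome with the most votes. The
#' assignment is flagged ambiguous when the top chromosome ties with
#' another or draws less than half the votes; groups with fewer than
#' `min_votes` voting markers stay unassigned.
#'
#' @param map a `genetic_map` or its table.
#' @param best_hits a [filter_best_hits()] table.
#' @param config a [synteny_config()].
#' @return data.frame with one row per linkage group: `linkage_group`,
#'   `chrom`, `n_votes`, `vote_fraction`, `status`
#'   (`"assigned"` / `"ambiguous"` / `"unassigned"`).
#' @export
assign_chromosomes <- function(map, best_hits, config = synteny_config()) {
  tab <- if (inherits(map, "genetic_map")) map$table else map
  i <- match(tab$marker, best_hits$marker)
  tab$subject <- best_hits$subject[i]
  out <- do.call(rbind, lapply(split(tab, tab$linkage_group), function(d) {
    v <- table(d$subject[!is.na(d$subject)])
    n <- sum(v)
    if (n < config$min_votes)
      return(data.frame(linkage_group = d$linkage_group[1],
                        chrom = NA_character_, n_votes = n,
                        vote_fraction = NA_real_, status = "unassigned",
                        stringsAsFactors = FALSE))
    top <- max(v)
    winners <- names(v)[v == top]
    frac <- top / n
    amb <- length(winners) > 1L || frac < 0.5
    data.frame(linkage_group = d$linkage_group[1],
               chrom = sort(winners)[1L], n_votes = n,
               vote_fraction = frac,
               status = if (amb) "ambiguous" else "assigned",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dotplot table and per-group collinearity
#'
#' Joins each mapped marker's genetic position with its best-hit physical
#' position. The restricted table keeps only markers hitting their group's
#' assigned chromosome; the Spearman rank correlation between cM and bp is
#' reported per group, with `|rho|` as the collinearity score (the sign is
#' arbitrary because linkage-group orientation is arbitrary).
#'
#' @param map a `genetic_map` or its table.
#' @param best_hits a [filter_best_hits()] table.
#' @param assignments an [assign_chromosomes()] table.
#' @return List with `table` (restricted tidy table: `linkage_group`,
#'   `marker`, `position_cM`, `chrom`, `subject_pos`), `full_table`
#'   (unrestricted, for cross-chromosome dot patterns) and `collinearity`
#'   (per group: `linkage_group`, `chrom`, `n`, `rho`, `abs_rho`).
#' @export
dotplot_table <- function(map, best_hits, assignments) {
  tab <- if (inherits(map, "genetic_map")) map$table else map
  i <- match(tab$marker, best_hits$marker)
  full <- data.frame(linkage_group = tab$linkage_group,
                     marker = tab$marker,
                     position_cM = tab$position_cM,
                     chrom = best_hits$subject[i],
                     subject_pos = best_hits$subject_pos[i],
                     stringsAsFactors = FALSE)
  full <- full[!is.na(full$chrom), , drop = FALSE]
  asg <- stats::setNames(assignments$chrom,
                         as.character(assignments$linkage_group))
  keep <- !is.na(asg[as.character(full$linkage_group)]) &
    full$chrom == asg[as.character(full$linkage_group)]
  restricted <- full[keep, , drop = FALSE]
  coll <- do.call(rbind, lapply(split(restricted,
                                      restricted$linkage_group),
                                function(d) {
    rho <- if (nrow(d) >= 3)
      suppressWarnings(stats::cor(d$position_cM, d$subject_pos,
                                  method = "spearman"))
    else NA_real_
    data.frame(linkage_group = d$linkage_group[1], chrom = d$chrom[1],
               n = nrow(d), rho = rho, abs_rho = abs(rho),
               stringsAsFactors = FALSE)
  }))
  if (is.null(coll))
    coll <- data.frame(linkage_group = integer(0), chrom = character(0),
                       n = integer(0), rho = numeric(0),
                       abs_rho = numeric(0))
  rownames(coll) <- rownames(restricted) <- NULL
  list(table = restricted, full_table = full, collinearity = coll)
}

#' Fabricate a truth-linked BLAST hit table for a simulated map
#'
#' Gives each marker a strong hit at its true chromosome with physical
#' position proportional to its true cM position (plus Gaussian jitter),
#' except that a `noise_frac` fraction of markers instead receive a weaker
#' random hit (uniform chromosome and position, e-value between the
#' stringent and permissive cutoffs) emulating unreliable alignments that
#' a stringent e-value screen removes.
#'
#' @param truth_map data.frame with columns `marker`, `chrom`, `pos_cM`
#'   (e.g. the `map` element of a truth set).
#' @param bp_per_cM physical-to-genetic scale (default 5e5 bp/cM).
#' @param noise_frac fraction of markers with a noise hit.
#' @param n_chromosomes number of reference chromosomes.
#' @param jitter_cM standard deviation of positional jitter for true hits.
#' @return data.frame in the layout of [read_blast_table()] output.
#' @export
simulate_hit_table <- function(truth_map, bp_per_cM = 5e5,
                               noise_frac = 0.05, n_chromosomes = 8,
                               jitter_cM = 0.2) {
  n <- nrow(truth_map)
  noisy <- stats::runif(n) < noise_frac
  max_bp <- (max(truth_map$pos_cM) + 1) * bp_per_cM
  chrom <- paste0("chr", truth_map$chrom)
  pos <- pmax(1, (truth_map$pos_cM +
                    stats::rnorm(n, 0, jitter_cM)) * bp_per_cM)
  evalue <- 10^-stats::runif(n, 25, 60)
  bitscore <- stats::runif(n, 110, 130)
  chrom[noisy] <- paste0("chr", sample.int(n_chromosomes, sum(noisy),
                                           replace = TRUE))
  pos[noisy] <- stats::runif(sum(noisy), 1, max_bp)
  evalue[noisy] <- 10^-stats::runif(sum(noisy), 5.1, 19.9)
  bitscore[noisy] <- stats::runif(sum(noisy), 50, 70)
  data.frame(marker = truth_map$marker, subject = chrom,
             subject_pos = round(pos), evalue = evalue,
             bitscore = round(bitscore, 1), stringsAsFactors = FALSE)
}
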