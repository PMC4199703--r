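#' Binomial read-depth genotype likelihood for a tetraploid SNP
#'
#' For a biallelic SNP with total depth `n` in an autotetraploid
#' individual, the A-allele read count follows a binomial distribution
#' whose success probability depends on the dosage class: `1 - alpha`,
#' `3/4`, `1/2`, `1/4` and `alpha` for AAAA, AAAB, AABB, ABBB and BBBB
#' respectively, where `alpha` is the symmetric sequencing error rate.
#' Only the two homozygote classes involve `alpha`; the heterozygote
#' classes use the exact allele fractions.
#'
#' @param x_a A-allele read count (vectorised).
#' @param n total read count.
#' @param g dosage class: one of `"AAAA"`, `"AAAB"`, `"AABB"`, `"ABBB"`,
#'   `"BBBB"`.
#' @param alpha sequencing error rate in `[0, 0.5)`.
#' @return `P(X_A = x_a | G = g; n, alpha)`.
#' @examples
#' genotype_likelihood(11, 11, "AAAB")   # (3/4)^11, just under 0.05
#' genotype_likelihood(3, 6, "AABB")     # choose(6,3)/2^6 = 0.3125
#' @export
genotype_likelihood <- function(x_a, n, g, alpha = 0.005) {
  if (alpha < 0 || alpha >= 0.5) stop("alpha must be in [0, 0.5)")
  g <- match.arg(g, c("AAAA", "AAAB", "AABB", "ABBB", "BBBB"))
  stopifnot(all(x_a >= 0), all(x_a <= n))
  p <- switch(g,
              AAAA = 1 - alpha,
              AAAB = 3 / 4,
              AABB = 1 / 2,
              ABBB = 1 / 4,
              BBBB = alpha)
  stats::dbinom(x_a, n, p)
}

#' Minimum depth for calling a homozygote
#'
#' The smallest total depth `N` at which the probability that a triplex
#' heterozygote (AAAB) yields only A reads, `(3/4)^N`, falls below
#' `p_threshold`. At the conventional threshold 0.05 this gives 11 reads,
#' the minimum depth for calling a homozygote when a single allele is
#' observed.
#'
#' @param p_threshold miscall probability bound in (0, 1).
#' @return Integer depth.
#' @examples
#' min_homozygote_depth(0.05)  # 11
#' @export
min_homozygote_depth <- function(p_threshold = 0.05) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  n <- 1L
  while ((3 / 4)^n >= p_threshold) n <- n + 1L
  n
}

#' Calling-rule parameters
#'
#' @param alpha sequencing error rate (used by likelihood reporting, not
#'   by the deterministic rules).
#' @param min_hom_depth minimum total depth to call a homozygote when only
#'   one allele is observed (default 11, from [min_homozygote_depth()] at
#'   0.05).
#' @param min_het_reads minimum reads per allele to call a heterozygote.
#' @param min_het_maf minor-allele read fraction that must be exceeded
#'   (strictly) to call a heterozygote.
#' @return An object of class `call_model`.
#' @export
call_model <- function(alpha = 0.005, min_hom_depth = 11L,
                       min_het_reads = 2L, min_het_maf = 0.10) {
  stopifnot(alpha >= 0, alpha < 0.5, min_hom_depth >= 1,
            min_het_reads >= 1, min_het_maf >= 0, min_het_maf < 0.5)
  structure(list(alpha = alpha, min_hom_depth = as.integer(min_hom_depth),
                 min_het_reads = as.integer(min_het_reads),
                 min_het_maf = min_het_maf), class = "call_model")
}

#' Call a tetraploid genotype from allele depths
#'
#' Deterministic rules: if only one allele is observed, a homozygote
#' (`"AA"` or `"BB"`) is called when total depth is at least
#' `min_hom_depth`, otherwise missing (`NA`); if both alleles are
#' observed, a heterozygote (`"AB"`, dosage classes not distinguished) is
#' called when both alleles have at least `min_het_reads` reads and the
#' minor-allele fraction strictly exceeds `min_het_maf`, otherwise
#' missing; zero depth is missing.
#'
#' @param x_a,x_b allele read counts (vectorised).
#' @param model a [call_model()].
#' @return Character vector of `"AA"`, `"AB"`, `"BB"` or `NA`.
#' @examples
#' call_genotype(c(11, 10, 20, 20, 0), c(0, 0, 3, 2, 0))
#' # "AA" NA "AB" NA NA
#' @export
call_genotype <- function(x_a, x_b, model = call_model()) {
  stopifnot(inherits(model, "call_model"), all(x_a >= 0), all(x_b >= 0))
  n <- x_a + x_b
  out <- rep(NA_character_, length(n))
  only_a <- x_a > 0 & x_b == 0
  only_b <- x_b > 0 & x_a == 0
  out[only_a & n >= model$min_hom_depth] <- "AA"
  out[only_b & n >= model$min_hom_depth] <- "BB"
  both <- x_a > 0 & x_b > 0
  mn <- pmin(x_a, x_b)
  out[both & mn >= model$min_het_reads & mn / n > model$min_het_maf] <- "AB"
  out
}

#' Call a genotype matrix from a read-count matrix
#'
#' Applies [call_genotype()] elementwise and records the per-marker
#' missingness fraction as attribute `"missingness"`.
#'
#' @param reads a `read_counts` object.
#' @param model a [call_model()].
#' @return Character matrix (markers x individuals) of `"AA"`, `"AB"`,
#'   `"BB"`, `NA`, class `genotype_calls`.
#' @export
call_matrix <- function(reads, model = call_model()) {
  stopifnot(inherits(reads, "read_counts"))
  if (!identical(dim(reads$xA), dim(reads$xB)))
    stop("xA and xB dimensions differ")
  calls <- call_genotype(as.vector(reads$xA), as.vector(reads$xB), model)
  dim(calls) <- dim(reads$xA)
  dimnames(calls) <- dimnames(reads$xA)
  structure(calls, missingness = rowMeans(is.na(calls)),
            class = c("genotype_calls", class(calls)))
}

#' Pool parent replicate libraries before calling
#'
#' Sums the allele depths of each parent's replicate columns into a single
#' column, leaving all other columns untouched. Parents are called from
#' the pooled depths.
#'
#' @param reads a `read_counts` object.
#' @param replicate_map named list mapping each merged column name to the
#'   replicate column names it pools; defaults to the map recorded by
#'   [simulate_reads()].
#' @return A `read_counts` object with one column per parent.
#' @export
merge_parent_replicates <- function(reads,
                                    replicate_map = reads$replicate_map) {
  stopifnot(inherits(reads, "read_counts"))
  if (!length(replicate_map)) return(reads)
  all_reps <- unlist(replicate_map, use.names = FALSE)
  missing_cols <- setdiff(all_reps, colnames(reads$xA))
  if (length(missing_cols))
    stop("unknown replicate column(s): ", paste(missing_cols, collapse = ", "))
  keep <- setdiff(colnames(reads$xA), all_reps)
  pool <- function(m) {
    merged <- do.call(cbind, lapply(replicate_map, function(cols)
      rowSums(m[, cols, drop = FALSE])))
    colnames(merged) <- names(replicate_map)
    cbind(m[, keep, drop = FALSE], merged)
  }
  structure(list(xA = pool(reads$xA), xB = pool(reads$xB),
                 replicate_map = list()), class = "read_counts")
}

#' Filter markers by missingness and tabulate missingness tiers
#'
#' Retains markers whose missing-call fraction among the given columns is
#' at most `cutoff`, and reports, for cutoffs 10%..90% ("NA10".."NA90")
#' plus "All", the number of markers at or below each tier and their mean
#' missingness — the structure of a missing-data tier table.
#'
#' @param calls a `genotype_calls` matrix.
#' @param cutoff retention cutoff in (0, 1].
#' @param progeny column names over which missingness is computed
#'   (default: all columns).
#' @return List with `calls` (filtered matrix), `missingness` (per-marker
#'   fractions, all markers) and `tiers` (the tier report data.frame).
#' @export
filter_by_missingness <- function(calls, cutoff = 0.5, progeny = NULL) {
  stopifnot(cutoff > 0, cutoff <= 1)
  sub <- if (is.null(progeny)) calls else calls[, progeny, drop = FALSE]
  miss <- rowMeans(is.na(sub))
  tiers <- data.frame(
    tier = c(sprintf("NA%d", seq(10, 90, 10)), "All"),
    max_missing = c(seq(0.1, 0.9, 0.1), 1),
    stringsAsFactors = FALSE)
  tiers$n_markers <- vapply(tiers$max_missing,
                            function(cc) sum(miss <= cc), 0L)
  tiers$mean_missing_pct <- vapply(tiers$max_missing, function(cc)
    if (any(miss <= cc)) round(100 * mean(miss[miss <= cc]), 1) else NA_real_,
    0)
  kept <- calls[miss <= cutoff, , drop = FALSE]
  attr(kept, "missingness") <- miss[miss <= cutoff]
  list(calls = kept, missingness = miss, tiers = tiers)
}
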