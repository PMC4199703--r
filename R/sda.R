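#' Single-dose-allele screen parameters
#'
#' @param max_ratio presence:absence ratio below which (strictly) a marker
#'   is accepted as a single-dose allele; the default 2 separates simplex
#'   (expected 1:1) from duplex (expected 5:1) segregation, the
#'   equal-evidence point being about 2.24:1 (see
#'   [equal_evidence_ratio()]).
#' @param max_missing missing-call fraction among progeny that must not be
#'   reached (strictly).
#' @param distortion_alpha nominal significance level used when reporting
#'   distorted markers.
#' @return An object of class `sda_config`.
#' @export
sda_config <- function(max_ratio = 2.0, max_missing = 0.5,
                       distortion_alpha = 0.001) {
  stopifnot(max_ratio > 1, max_missing > 0, max_missing <= 1,
            distortion_alpha > 0, distortion_alpha < 1)
  structure(list(max_ratio = max_ratio, max_missing = max_missing,
                 distortion_alpha = distortion_alpha),
            class = "sda_config")
}

#' Classify the parental configuration of a marker
#'
#' A marker is informative for the pseudo-testcross when it is
#' heterozygous in exactly one parent: `maternal_only` (AB x AA or
#' AB x BB) or `paternal_only` (the mirror image). Markers heterozygous in
#' both parents are `both` (excluded by design), homozygous in both are
#' `neither`, and any missing parent call makes the marker `unusable`.
#'
#' @param maternal_call,paternal_call parent genotype calls (`"AA"`,
#'   `"AB"`, `"BB"` or `NA`), typically from replicate-pooled depths;
#'   vectorised.
#' @return Character vector of configurations.
#' @export
classify_parental_configuration <- function(maternal_call, paternal_call) {
  hom <- c("AA", "BB")
  out <- rep("neither", length(maternal_call))
  m_het <- !is.na(maternal_call) & maternal_call == "AB"
  p_het <- !is.na(paternal_call) & paternal_call == "AB"
  m_hom <- !is.na(maternal_call) & maternal_call %in% hom
  p_hom <- !is.na(paternal_call) & paternal_call %in% hom
  out[m_het & p_hom] <- "maternal_only"
  out[p_het & m_hom] <- "paternal_only"
  out[m_het & p_het] <- "both"
  out[is.na(maternal_call) | is.na(paternal_call)] <- "unusable"
  out
}

#' Presence/absence segregation counts for a single-parent marker
#'
#' For a marker segregating from one parent, progeny calls carrying the
#' segregating allele (heterozygotes, or homozygotes of that allele) count
#' as "presence"; homozygotes of the common allele count as "absence";
#' missing calls are excluded.
#'
#' @param progeny_calls character vector of progeny calls.
#' @param common_allele the allele carried homozygously by the
#'   non-segregating parent (`"A"` or `"B"`); the segregating allele is
#'   the other one.
#' @return List with `n_present`, `n_absent`, `n_missing`, `ratio`.
#' @export
segregation_counts <- function(progeny_calls, common_allele = c("B", "A")) {
  common_allele <- match.arg(common_allele)
  n_missing <- sum(is.na(progeny_calls))
  typed <- progeny_calls[!is.na(progeny_calls)]
  if (!length(typed)) stop("zero typed progeny")
  absent_call <- paste0(common_allele, common_allele)
  n_absent <- sum(typed == absent_call)
  n_present <- length(typed) - n_absent
  list(n_present = n_present, n_absent = n_absent, n_missing = n_missing,
       ratio = n_present / n_absent)
}

#' Single-dose acceptance rule
#'
#' A marker passes when its presence:absence ratio is strictly below
#' `max_ratio` and its missing fraction among progeny strictly below
#' `max_missing`. A marker with no absence calls has infinite ratio and
#' fails.
#'
#' @param n_present,n_absent,n_missing segregation counts.
#' @param n_progeny total progeny.
#' @param config an [sda_config()].
#' @return Logical.
#' @export
is_sda <- function(n_present, n_absent, n_missing, n_progeny,
                   config = sda_config()) {
  ratio <- n_present / n_absent
  !is.nan(ratio) & ratio < config$max_ratio &
    n_missing / n_progeny < config$max_missing
}

#' Segregation ratio at which simplex and duplex are equally supported
#'
#' Solves for the presence fraction `x` at which the one-degree-of-freedom
#' chi-square goodness-of-fit statistic of observed proportions
#' `(x, 1 - x)` against the simplex expectation equals the statistic
#' against the duplex expectation, and returns `x / (1 - x)`. The
#' statistic equality is scale-free, so the result does not depend on
#' sample size. With the default expectations (1:1 and 5:1) the ratio is
#' `sqrt(5)`, approximately 2.24:1.
#'
#' @param expected_simplex,expected_duplex length-2 probability vectors
#'   (presence, absence) for the two competing hypotheses.
#' @return The equal-evidence presence:absence ratio. Identical
#'   hypotheses return 1 by convention.
#' @export
equal_evidence_ratio <- function(expected_simplex = c(1 / 2, 1 / 2),
                                 expected_duplex = c(5 / 6, 1 / 6)) {
  stopifnot(length(expected_simplex) == 2, length(expected_duplex) == 2,
            all(expected_simplex > 0), all(expected_duplex > 0),
            abs(sum(expected_simplex) - 1) < 1e-8,
            abs(sum(expected_duplex) - 1) < 1e-8)
  if (isTRUE(all.equal(expected_simplex, expected_duplex))) return(1.0)
  chi2 <- function(x, e) (x - e[1])^2 / e[1] + ((1 - x) - e[2])^2 / e[2]
  f <- function(x) chi2(x, expected_simplex) - chi2(x, expected_duplex)
  lo <- min(expected_simplex[1], expected_duplex[1])
  hi <- max(expected_simplex[1], expected_duplex[1])
  x <- stats::uniroot(f, c(lo + 1e-9, hi - 1e-9), tol = 1e-12)$root
  x / (1 - x)
}

#' Chi-square test of 1:1 segregation
#'
#' One-degree-of-freedom goodness of fit of the presence/absence counts
#' against 1:1, without continuity correction:
#' `chi2 = (n_present - n_absent)^2 / (n_present + n_absent)`.
#'
#' @param n_present,n_absent typed progeny counts (vectorised).
#' @return List with `chi2`, `p`, `neglog10p` and `direction`
#'   (`"excess_presence"` or `"excess_absence"`; ties count as
#'   excess_presence with chi2 = 0, p = 1).
#' @export
distortion_test <- function(n_present, n_absent) {
  n <- n_present + n_absent
  if (any(n == 0)) stop("zero typed progeny")
  chi2 <- (n_present - n_absent)^2 / n
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, neglog10p = -log10(p),
       direction = ifelse(n_present >= n_absent,
                          "excess_presence", "excess_absence"))
}

#' Screen a genotype matrix for single-dose-allele markers
#'
#' Classifies each marker's parental configuration from the (pooled)
#' parent calls, computes presence/absence segregation counts over the
#' progeny for single-parent markers, applies the SDA rule and the 1:1
#' distortion test.
#'
#' @param calls a `genotype_calls` matrix containing the progeny columns
#'   and one column per parent.
#' @param mother,father the parent column names.
#' @param config an [sda_config()].
#' @return data.frame of class `sda_table` with one row per marker:
#'   `marker`, `parent`, `configuration`, `n_present`, `n_absent`,
#'   `n_missing`, `ratio`, `chi2`, `p`, `neglog10p`, `direction`,
#'   `is_sda`.
#' @export
sda_screen <- function(calls, mother = "mother", father = "father",
                       config = sda_config()) {
  stopifnot(all(c(mother, father) %in% colnames(calls)))
  prog <- setdiff(colnames(calls), c(mother, father))
  n_progeny <- length(prog)
  gm <- calls[, mother]
  gf <- calls[, father]
  conf <- classify_parental_configuration(gm, gf)
  pc <- calls[, prog, drop = FALSE]
  out <- data.frame(marker = rownames(calls), parent = NA_character_,
                    configuration = conf,
                    n_present = NA_integer_, n_absent = NA_integer_,
                    n_missing = NA_integer_, ratio = NA_real_,
                    chi2 = NA_real_, p = NA_real_, neglog10p = NA_real_,
                    direction = NA_character_, is_sda = FALSE,
                    stringsAsFactors = FALSE)
  single <- conf %in% c("maternal_only", "paternal_only")
  if (any(single)) {
    out$parent[single] <- ifelse(conf[single] == "maternal_only",
                                 "mother", "father")
    hom_call <- ifelse(conf[single] == "maternal_only",
                       gf[single], gm[single])
    common <- substr(hom_call, 1, 1)          # "AA" -> "A", "BB" -> "B"
    sub <- pc[single, , drop = FALSE]
    absent_call <- paste0(common, common)
    n_missing <- rowSums(is.na(sub))
    n_absent <- rowSums(sub == absent_call, na.rm = TRUE)
    n_present <- (n_progeny - n_missing) - n_absent
    out$n_present[single] <- n_present
    out$n_absent[single] <- n_absent
    out$n_missing[single] <- n_missing
    out$ratio[single] <- n_present / n_absent
    typed <- n_present + n_absent
    has <- typed > 0
    idx <- which(single)[has]
    dt <- distortion_test(n_present[has], n_absent[has])
    out$chi2[idx] <- dt$chi2
    out$p[idx] <- dt$p
    out$neglog10p[idx] <- dt$neglog10p
    out$direction[idx] <- dt$direction
    out$is_sda[idx] <- is_sda(n_present[has], n_absent[has],
                              n_missing[has], n_progeny, config)
  }
  attr(out, "n_progeny") <- n_progeny
  class(out) <- c("sda_table", "data.frame")
  out
}

#' Presence/absence matrix of one parent's SDA markers
#'
#' Converts progeny genotype calls at a parent's SDA markers into the
#' binary presence matrix used for pseudo-testcross linkage analysis:
#' 1 when the progeny carries the segregating allele, 0 when homozygous
#' for the common allele, `NA` when missing.
#'
#' @param calls a `genotype_calls` matrix.
#' @param sda an [sda_screen()] table.
#' @param parent `"mother"` or `"father"`.
#' @param mother,father parent column names in `calls`.
#' @return Integer matrix (SDA markers x progeny) of 0/1/`NA`.
#' @export
presence_matrix <- function(calls, sda, parent = c("mother", "father"),
                            mother = "mother", father = "father") {
  parent <- match.arg(parent)
  keep <- sda$is_sda & !is.na(sda$parent) & sda$parent == parent
  mk <- sda$marker[keep]
  if (!length(mk)) return(matrix(NA_integer_, 0, 0))
  prog <- setdiff(colnames(calls), c(mother, father))
  hom_parent <- if (parent == "mother") father else mother
  common <- substr(calls[mk, hom_parent], 1, 1)
  sub <- calls[mk, prog, drop = FALSE]
  # the common allele varies by row, so compare row blocks per allele
  pres <- matrix(NA_integer_, length(mk), length(prog),
                 dimnames = list(mk, prog))
  for (a in unique(common)) {
    rows <- which(common == a)
    pres[rows, ] <- (sub[rows, , drop = FALSE] != paste0(a, a)) * 1L
  }
  pres
}
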