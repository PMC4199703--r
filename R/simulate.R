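#' Simulation configuration for a tetrasomic GBS mapping population
#'
#' Defines the study conditions emulated by the generator: an F1 population
#' of `n_progeny` individuals from a cross of two autotetraploid parents,
#' with maternal- and paternal-simplex markers laid out along each homolog
#' plus duplex "decoy" markers, GBS-like negative-binomial read depths and
#' a symmetric sequencing error rate.
#'
#' @param n_progeny number of surviving F1 progeny (default 384).
#' @param n_chromosomes number of chromosomes (default 8).
#' @param markers_per_homolog simplex markers per homolog per parent.
#' @param chrom_length_cM genetic length of each chromosome in centimorgans;
#'   recycled to `n_chromosomes`.
#' @param duplex_per_chromosome duplex decoy markers per chromosome (allele
#'   on two homologs of one parent; parents alternate).
#' @param depth_mean expected total reads per marker per individual.
#' @param depth_dispersion negative-binomial size parameter; small values
#'   give the heavy-tailed, zero-inflated depth typical of GBS.
#' @param alpha sequencing error rate in `[0, 0.5)`.
#' @param viability_loci `NULL`, or a data.frame with columns `marker` and
#'   `survival`: conceived progeny carrying the marker's segregating allele
#'   (dosage >= 1) survive with the given probability; dead conceptions are
#'   redrawn until `n_progeny` survive.
#' @param parent_replicates named integer vector `c(mother=, father=)`
#'   giving the number of replicate GBS libraries per parent.
#' @param double_reduction probability, per chromosome per gamete, that the
#'   two transmitted products are sister copies of a single bivalent product
#'   (coarse double-reduction hook; default 0, random chromosome
#'   segregation).
#' @param seed RNG seed used by [simulate_cross()]; `NULL` leaves the RNG
#'   state untouched.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cross()], [make_parents()], [meiosis()]
#' @export
sim_config <- function(n_progeny = 384L,
                       n_chromosomes = 8L,
                       markers_per_homolog = 25L,
                       chrom_length_cM = 70,
                       duplex_per_chromosome = 5L,
                       depth_mean = 4,
                       depth_dispersion = 0.7,
                       alpha = 0.005,
                       viability_loci = NULL,
                       parent_replicates = c(mother = 5L, father = 7L),
                       double_reduction = 0,
                       seed = NULL) {
  stopifnot(n_progeny >= 1, n_chromosomes >= 1,
            markers_per_homolog >= 0, duplex_per_chromosome >= 0,
            depth_mean > 0, depth_dispersion > 0,
            alpha >= 0, alpha < 0.5,
            double_reduction >= 0, double_reduction < 1,
            all(chrom_length_cM > 0))
  if (markers_per_homolog == 0 && duplex_per_chromosome == 0)
    stop("configuration places zero markers on the genome")
  if (!is.null(viability_loci)) {
    stopifnot(is.data.frame(viability_loci),
              all(c("marker", "survival") %in% names(viability_loci)),
              all(viability_loci$survival >= 0),
              all(viability_loci$survival <= 1))
  }
  stopifnot(length(parent_replicates) == 2,
            all(c("mother", "father") %in% names(parent_replicates)),
            all(parent_replicates >= 1))
  chrom_length_cM <- rep_len(chrom_length_cM, n_chromosomes)
  structure(list(n_progeny = as.integer(n_progeny),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_homolog = as.integer(markers_per_homolog),
                 chrom_length_cM = chrom_length_cM,
                 duplex_per_chromosome = as.integer(duplex_per_chromosome),
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 alpha = alpha,
                 viability_loci = viability_loci,
                 parent_replicates = parent_replicates,
                 double_reduction = double_reduction,
                 seed = seed),
            class = "sim_config")
}

#' Construct the two simulated parents
#'
#' Each parent carries four homologs per chromosome. Every homolog of every
#' parent receives `markers_per_homolog` simplex markers (allele A on that
#' single homolog, absent from the other parent) at evenly spaced
#' positions; duplex decoys carry allele A on two homologs of one parent.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `sim_parents` with elements `mother`, `father`
#'   (each a list of per-chromosome 4 x markers 0/1 haplotype matrices
#'   with a `pos_cM` attribute) and `markers`, a data.frame describing
#'   every marker (`marker`, `chrom`, `pos_cM`, `parent`, `type`,
#'   `homolog`).
#' @export
make_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$markers_per_homolog
  nd <- config$duplex_per_chromosome
  hap_m <- vector("list", config$n_chromosomes)
  hap_f <- vector("list", config$n_chromosomes)
  marker_tabs <- vector("list", config$n_chromosomes)
  for (cc in seq_len(config$n_chromosomes)) {
    L <- config$chrom_length_cM[cc]
    tab <- NULL
    if (m > 0) {
      pos <- if (m == 1) L / 2 else seq(0, L, length.out = m)
      for (par in c("mat", "pat")) {
        for (h in 1:4) {
          tab <- rbind(tab, data.frame(
            marker = sprintf("%s_c%d%s_%03d", par, cc, LETTERS[h], seq_len(m)),
            chrom = cc, pos_cM = pos,
            parent = if (par == "mat") "mother" else "father",
            type = "simplex", homolog = LETTERS[h],
            stringsAsFactors = FALSE))
        }
      }
    }
    if (nd > 0) {
      # offset duplex positions off the simplex grid so no homolog carries
      # two markers at one spot
      dpos <- pmin((seq_len(nd) - 0.382) / nd * L + 0.1, L - 0.05)
      dpar <- if (cc %% 2 == 1) "mother" else "father"
      tab <- rbind(tab, data.frame(
        marker = sprintf("dup_c%d_%03d", cc, seq_len(nd)),
        chrom = cc, pos_cM = dpos, parent = dpar,
        type = "duplex", homolog = NA_character_,
        stringsAsFactors = FALSE))
    }
    tab <- tab[order(tab$pos_cM, tab$marker), , drop = FALSE]
    if (anyDuplicated(tab$marker))
      stop("duplicate marker ids generated")
    nm <- nrow(tab)
    Hm <- matrix(0L, 4, nm, dimnames = list(NULL, tab$marker))
    Hf <- matrix(0L, 4, nm, dimnames = list(NULL, tab$marker))
    simp <- tab$type == "simplex"
    for (i in which(simp)) {
      h <- match(tab$homolog[i], LETTERS[1:4])
      if (tab$parent[i] == "mother") Hm[h, i] <- 1L else Hf[h, i] <- 1L
    }
    for (i in which(tab$type == "duplex")) {
      hh <- sample.int(4, 2)
      if (tab$parent[i] == "mother") Hm[hh, i] <- 1L else Hf[hh, i] <- 1L
    }
    # per-homolog positions must be strictly increasing (no double hits)
    for (H in list(Hm, Hf)) for (h in 1:4) {
      p <- tab$pos_cM[H[h, ] == 1L]
      if (anyDuplicated(p)) stop("duplicate positions on one homolog")
    }
    attr(Hm, "pos_cM") <- tab$pos_cM; attr(Hm, "length_cM") <- L
    attr(Hf, "pos_cM") <- tab$pos_cM; attr(Hf, "length_cM") <- L
    hap_m[[cc]] <- Hm; hap_f[[cc]] <- Hf
    marker_tabs[[cc]] <- tab
  }
  markers <- do.call(rbind, marker_tabs)
  rownames(markers) <- NULL
  structure(list(
    mother = structure(list(name = "mother", haplotypes = hap_m),
                       class = "sim_parent"),
    father = structure(list(name = "father", haplotypes = hap_f),
                       class = "sim_parent"),
    markers = markers,
    config = config), class = "sim_parents")
}

# one meiotic product from a bivalent: Poisson crossovers at 1 / 100 cM,
# alternating strands (Haldane, no interference)
.bivalent_product <- function(hap, pos, hpair, L) {
  n_co <- stats::rpois(1L, L / 100)
  k <- if (n_co > 0) findInterval(pos, sort(stats::runif(n_co, 0, L))) else
    integer(length(pos))
  start <- sample.int(2L, 1L)
  origin <- hpair[1L + (start + k) %% 2L]
  list(allele = hap[cbind(origin, seq_along(pos))], origin = origin)
}

.pairings <- list(rbind(c(1L, 2L), c(3L, 4L)),
                  rbind(c(1L, 3L), c(2L, 4L)),
                  rbind(c(1L, 4L), c(2L, 3L)))

#' Simulate one tetrasomic meiosis
#'
#' The four homologs of each chromosome are paired uniformly at random into
#' two bivalents (three equally likely pairings). Within each bivalent,
#' crossovers follow a Poisson process at one event per 100 cM with no
#' interference, and one recombinant product per bivalent enters the
#' gamete. With `double_reduction = 0` (the default) this is random
#' chromosome segregation with no double reduction.
#'
#' @param parent a `sim_parent` (element of [make_parents()] output).
#' @param double_reduction per-chromosome probability that both transmitted
#'   products are copies of a single bivalent product.
#' @return A list with one element per chromosome, each a list with
#'   `allele` (2 x markers 0/1 matrix) and `origin` (2 x markers matrix of
#'   parental homolog indices 1-4).
#' @export
meiosis <- function(parent, double_reduction = 0) {
  stopifnot(inherits(parent, "sim_parent"))
  lapply(parent$haplotypes, function(hap) {
    pos <- attr(hap, "pos_cM")
    L <- attr(hap, "length_cM")
    prs <- .pairings[[sample.int(3L, 1L)]]
    p1 <- .bivalent_product(hap, pos, prs[1L, ], L)
    p2 <- .bivalent_product(hap, pos, prs[2L, ], L)
    if (double_reduction > 0 && stats::runif(1) < double_reduction) {
      keep <- if (sample.int(2L, 1L) == 1L) p1 else p2
      p1 <- keep; p2 <- keep
    }
    al <- rbind(p1$allele, p2$allele)
    colnames(al) <- colnames(hap)
    list(allele = al, origin = rbind(p1$origin, p2$origin))
  })
}

# gamete dosage vector over all markers, in marker-table order
.gamete_dosage <- function(gam) {
  unlist(lapply(gam, function(g) g$allele[1L, ] + g$allele[2L, ]),
         use.names = FALSE)
}

#' Exact gamete dosage distribution under random chromosome segregation
#'
#' Enumerates the three equally likely bivalent pairings of a tetraploid
#' parent carrying `parent_dosage` copies of allele A at a locus, each
#' bivalent transmitting either homolog with probability 1/2, and returns
#' the exact distribution of gamete dosage (0, 1 or 2 copies of A). For a
#' duplex parent this gives (1/6, 2/3, 1/6), hence 5:1 presence:absence in
#' progeny of a cross to a nulliplex parent; for a simplex parent, 1:1.
#'
#' @param parent_dosage number of homologs (0-4) carrying allele A.
#' @return Named numeric vector of probabilities for gamete dosage 0, 1, 2.
#' @export
gamete_dosage_probs <- function(parent_dosage) {
  stopifnot(parent_dosage %in% 0:4)
  alleles <- c(rep(1L, parent_dosage), rep(0L, 4L - parent_dosage))
  probs <- c("0" = 0, "1" = 0, "2" = 0)
  for (prs in .pairings) {
    for (c1 in 1:2) for (c2 in 1:2) {
      d <- alleles[prs[1L, c1]] + alleles[prs[2L, c2]]
      probs[as.character(d)] <- probs[as.character(d)] + 1 / 12
    }
  }
  probs
}

#' Generate the F1 progeny truth set
#'
#' Each progeny is the union of one maternal and one paternal gamete. If
#' `viability_loci` are configured, each conceived progeny carrying a
#' selected allele survives with the locus's survival probability and is
#' otherwise redrawn, until `n_progeny` survive.
#'
#' @param parents a [make_parents()] object.
#' @param config the [sim_config()] used.
#' @return An object of class `truth_set`: list with `dosage`,
#'   `maternal_dosage`, `paternal_dosage` (markers x progeny integer
#'   matrices), `map` (the true marker table with chromosome, homolog and
#'   cM position) and `n_conceived` (total conceptions drawn).
#' @export
make_progeny <- function(parents, config) {
  stopifnot(inherits(parents, "sim_parents"), inherits(config, "sim_config"))
  mk <- parents$markers
  M <- nrow(mk)
  n <- config$n_progeny
  vl <- config$viability_loci
  vl_idx <- if (is.null(vl)) integer(0) else match(vl$marker, mk$marker)
  if (anyNA(vl_idx)) stop("viability locus marker not found")
  dm <- matrix(0L, M, n)
  dp <- matrix(0L, M, n)
  n_conceived <- 0L
  for (i in seq_len(n)) {
    repeat {
      n_conceived <- n_conceived + 1L
      gm <- .gamete_dosage(meiosis(parents$mother, config$double_reduction))
      gf <- .gamete_dosage(meiosis(parents$father, config$double_reduction))
      if (length(vl_idx)) {
        d <- gm[vl_idx] + gf[vl_idx]
        surv <- prod(vl$survival[d >= 1L])
        if (stats::runif(1) > surv) next
      }
      break
    }
    dm[, i] <- gm; dp[, i] <- gf
  }
  ids <- sprintf("F1_%03d", seq_len(n))
  dimnames(dm) <- dimnames(dp) <- list(mk$marker, ids)
  structure(list(dosage = dm + dp,
                 maternal_dosage = dm,
                 paternal_dosage = dp,
                 map = mk,
                 n_conceived = n_conceived,
                 config = config), class = "truth_set")
}

#' Simulate GBS allele read depths from a truth set
#'
#' Total depth per marker per individual is negative-binomial
#' (`mu = depth_mean`, `size = depth_dispersion`; zero allowed); the
#' A-allele count is binomial with success probability
#' `p = (d/4)(1 - alpha) + (1 - d/4) alpha` for true dosage `d`. Parent
#' replicate columns are drawn independently from the parental dosages.
#'
#' @param truth a [make_progeny()] truth set.
#' @param config the [sim_config()] used.
#' @param parents the [make_parents()] object (needed for parental
#'   dosages; if `NULL`, parent replicate columns are omitted).
#' @return An object of class `read_counts`: list with integer matrices
#'   `xA` and `xB` (markers x individuals) and attribute-like element
#'   `replicate_map`, a named list giving the replicate columns of each
#'   parent.
#' @export
simulate_reads <- function(truth, config, parents = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  dos <- truth$dosage
  if (!is.null(parents)) {
    pd <- function(p) unlist(lapply(p$haplotypes, colSums), use.names = FALSE)
    dmo <- pd(parents$mother); dfa <- pd(parents$father)
    nr <- config$parent_replicates
    rep_cols <- c(sprintf("mother_rep%d", seq_len(nr[["mother"]])),
                  sprintf("father_rep%d", seq_len(nr[["father"]])))
    pmat <- cbind(matrix(dmo, nrow(dos), nr[["mother"]]),
                  matrix(dfa, nrow(dos), nr[["father"]]))
    colnames(pmat) <- rep_cols
    dos <- cbind(dos, pmat)
    replicate_map <- list(
      mother = sprintf("mother_rep%d", seq_len(nr[["mother"]])),
      father = sprintf("father_rep%d", seq_len(nr[["father"]])))
  } else {
    replicate_map <- list()
  }
  nc <- length(dos)
  N <- stats::rnbinom(nc, size = config$depth_dispersion,
                      mu = config$depth_mean)
  p <- (dos / 4) * (1 - config$alpha) + (1 - dos / 4) * config$alpha
  xA <- stats::rbinom(nc, N, as.vector(p))
  xB <- N - xA
  dim(xA) <- dim(xB) <- dim(dos)
  dimnames(xA) <- dimnames(xB) <- dimnames(dos)
  structure(list(xA = xA, xB = xB, replicate_map = replicate_map),
            class = "read_counts")
}

#' Run the full generator under one seed
#'
#' Seeds the RNG (if `config$seed` is set), then builds parents, progeny
#' and read counts. Identical configuration and seed give byte-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return A list of class `tetra_sim` with `parents`, `truth`, `reads`
#'   and `config`.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  parents <- make_parents(config)
  truth <- make_progeny(parents, config)
  reads <- simulate_reads(truth, config, parents)
  structure(list(parents = parents, truth = truth, reads = reads,
                 config = config), class = "tetra_sim")
}

#' @export
print.tetra_sim <- function(x, ...) {
  mk <- x$parents$markers
  cat(sprintf("tetrasomic F1 simulation: %d progeny, %d chromosomes, %d markers\n",
              x$config$n_progeny, x$config$n_chromosomes, nrow(mk)))
  cat(sprintf("  simplex: %d  duplex: %d  depth_mean: %g  alpha: %g\n",
              sum(mk$type == "simplex"), sum(mk$type == "duplex"),
              x$config$depth_mean, x$config$alpha))
  invisible(x)
}
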