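# shared fixtures: all simulated in code, no stored data

# simulate and call in one step
sim_and_call <- function(cfg) {
  sim <- simulate_cross(cfg)
  calls <- call_matrix(merge_parent_replicates(sim$reads))
  list(sim = sim, calls = calls)
}

# true homolog label ("<chrom><homolog>") for each marker id
truth_labels <- function(truth_map, markers) {
  i <- match(markers, truth_map$marker)
  stats::setNames(paste0(truth_map$chrom[i], truth_map$homolog[i]), markers)
}

# presence matrix built from calls but with the parental configuration taken
# from the simulator's truth (every simplex marker of `parent`, common allele
# B by construction) — isolates downstream steps from parent-call dropout
true_config_presence <- function(sim, calls, parent) {
  truth <- sim$truth$map
  mk <- truth$marker[truth$parent == parent & truth$type == "simplex"]
  prog <- grep("^F1_", colnames(calls), value = TRUE)
  sub <- calls[mk, prog, drop = FALSE]
  (sub != "BB") * 1L
}

# does a grouping reproduce the true homolog partition exactly?
partition_matches <- function(grp, labels) {
  if (length(grp$unplaced)) return(FALSE)
  glab <- lapply(grp$groups, function(g) unique(labels[g]))
  all(lengths(glab) == 1L) && !anyDuplicated(unlist(glab))
}

# hand-built pairwise_linkage object from an rf matrix (lod defaults high so
# every pair qualifies)
fake_linkage <- function(rf, lod = NULL, n = 100) {
  if (is.null(lod)) {
    lod <- matrix(50, nrow(rf), ncol(rf), dimnames = dimnames(rf))
    diag(lod) <- NA
  }
  nm <- matrix(n, nrow(rf), ncol(rf), dimnames = dimnames(rf))
  structure(list(rf = rf, lod = lod, n = nm), class = "pairwise_linkage")
}
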