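test_that("Kosambi function matches closed forms and round-trips", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.10), 25 * log(1.2 / 0.8), tolerance = 1e-12)
  expect_equal(round(kosambi_cm(0.10), 2), 10.14)
  expect_equal(round(kosambi_cm(0.25), 2), 27.47)
  expect_error(kosambi_cm(0.5), "0.5")
  expect_error(kosambi_cm(-0.1))
  expect_equal(kosambi_inverse(0), 0)
  expect_equal(kosambi_inverse(10.14), 0.10, tolerance = 1e-3)
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(kosambi_inverse(kosambi_cm(r)), r, tolerance = 1e-10)
  expect_equal(kosambi_inverse(1e4), 0.5, tolerance = 1e-6)
})

test_that("pairwise rf and LOD match the closed forms", {
  v <- rep(c(1, 0), 50)
  m <- rbind(a = v, b = v)
  pl <- pairwise_linkage(m)
  expect_equal(pl$rf["a", "b"], 0)
  expect_equal(pl$lod["a", "b"], 100 * log10(2), tolerance = 1e-10)
  # 10 mismatches in 100
  w <- v; w[1:10] <- 1 - w[1:10]
  pl2 <- pairwise_linkage(rbind(a = v, b = w))
  expect_equal(pl2$rf["a", "b"], 0.1)
  expect_equal(pl2$lod["a", "b"],
               10 * log10(0.1) + 90 * log10(0.9) + 100 * log10(2),
               tolerance = 1e-10)
  expect_equal(round(pl2$lod["a", "b"], 2), 15.98)
  # independent vectors: rf near 0.5, lod near 0
  set.seed(41)
  pl3 <- pairwise_linkage(rbind(a = rbinom(400, 1, 0.5),
                                b = rbinom(400, 1, 0.5)))
  expect_gt(pl3$rf["a", "b"], 0.4)
  expect_lt(pl3$lod["a", "b"], 1)
  # repulsion-like mismatch fractions are capped
  pl4 <- pairwise_linkage(rbind(a = v, b = 1 - v))
  expect_equal(pl4$rf["a", "b"], 0.5)
  expect_equal(pl4$lod["a", "b"], 0)
  # zero overlap
  pl5 <- pairwise_linkage(rbind(a = c(1, 0, NA, NA), b = c(NA, NA, 1, 0)))
  expect_true(is.na(pl5$rf["a", "b"]))
})

test_that("rf estimator is consistent for coupled pairs at n = 384", {
  set.seed(42)
  cfg <- sim_config(n_progeny = 10, n_chromosomes = 1,
                    markers_per_homolog = 15, chrom_length_cM = 70,
                    duplex_per_chromosome = 0)
  p <- make_parents(cfg)
  # markers at 0, 5, 10, 20 cM on maternal homolog A
  mk <- sprintf("mat_c1A_%03d", c(1, 2, 3, 5))
  reps <- 20
  est <- matrix(NA_real_, reps, 3)
  for (rr in seq_len(reps)) {
    G <- matrix(0L, 384, 4)
    for (i in 1:384) {
      g <- meiosis(p$mother)[[1]]
      G[i, ] <- g$allele[1, mk] + g$allele[2, mk]
    }
    # progeny presence from a cross to a nulliplex parent equals the
    # maternal gamete state; rf estimate = mismatch fraction
    for (j in 2:4) est[rr, j - 1] <- mean(G[, 1] != G[, j])
  }
  d <- c(5, 10, 20)
  r_true <- (1 - exp(-2 * d / 100)) / 2
  se <- sqrt(r_true * (1 - r_true) / (384 * reps))
  expect_true(all(abs(colMeans(est) - r_true) < 3 * se))
})

test_that("grouping separates homologs and leaves weak pairs apart", {
  # constructed: 43% mismatch over 384 progeny is below LOD 14
  set.seed(43)
  a <- rbinom(384, 1, 0.5)
  b <- a; flip <- sample(384, 165); b[flip] <- 1 - b[flip]
  pl <- pairwise_linkage(rbind(m1 = a, m2 = b))
  expect_lt(pl$lod["m1", "m2"], 14)
  grp <- group_markers(pl, 14)
  expect_length(grp$groups, 0)
  expect_identical(grp$unplaced, c("m1", "m2"))
  # a tight chain forms one group
  c2 <- a; f2 <- sample(384, 10); c2[f2] <- 1 - c2[f2]
  d2 <- c2; f3 <- sample(384, 10); d2[f3] <- 1 - d2[f3]
  grp2 <- group_markers(pairwise_linkage(rbind(m1 = a, m2 = c2, m3 = d2)), 14)
  expect_length(grp2$groups, 1)
  expect_identical(grp2$groups[[1]], c("m1", "m2", "m3"))
  # empty input
  expect_length(group_markers(pairwise_linkage(matrix(1, 1, 4,
    dimnames = list("x", NULL))), 14)$groups, 0)
})

test_that("ordering recovers additive toy maps and is permutation-invariant", {
  rf <- matrix(0.5, 3, 3, dimnames = list(c("m1", "m2", "m3"),
                                          c("m1", "m2", "m3")))
  rf["m1", "m2"] <- rf["m2", "m1"] <- 0.05
  rf["m2", "m3"] <- rf["m3", "m2"] <- 0.05
  rf["m1", "m3"] <- rf["m3", "m1"] <- 0.10
  diag(rf) <- 0
  pl <- fake_linkage(rf)
  expect_identical(order_group(c("m1", "m2", "m3"), pl), c("m1", "m2", "m3"))
  expect_identical(order_group(c("m3", "m1", "m2"), pl), c("m1", "m2", "m3"))
  expect_identical(order_group(c("m2", "m3"), pl), c("m2", "m3"))
  # no qualifying pairs: identity order with warning
  rf_bad <- matrix(0.5, 3, 3, dimnames = dimnames(rf)); diag(rf_bad) <- 0
  expect_warning(got <- order_group(c("m3", "m2", "m1"),
                                    fake_linkage(rf_bad)), "qualifying")
  expect_identical(got, c("m1", "m2", "m3"))
})

test_that("simulated homolog order is recovered at 3 cM spacing", {
  set.seed(44)
  cfg <- sim_config(n_progeny = 384, n_chromosomes = 1,
                    markers_per_homolog = 25, chrom_length_cM = 72,
                    duplex_per_chromosome = 0)
  p <- make_parents(cfg)
  mkA <- sprintf("mat_c1A_%03d", 1:25)
  G <- matrix(0L, 25, 384, dimnames = list(mkA, NULL))
  for (i in 1:384) {
    g <- meiosis(p$mother)[[1]]
    G[, i] <- (g$allele[1, mkA] + g$allele[2, mkA])
  }
  pl <- pairwise_linkage(G)
  ord <- order_group(mkA, pl, map_config())
  rho <- stats::cor(match(ord, mkA), 1:25, method = "spearman")
  expect_gte(abs(rho), 0.95)
  # permutation invariance of the canonical output
  expect_identical(order_group(sample(mkA), pl, map_config()), ord)
  # positions accumulate Kosambi distances; length near the truth
  pos <- map_positions(ord, pl)
  expect_equal(unname(pos[1]), 0)
  expect_true(all(diff(pos) >= 0))
  expect_gt(max(pos), 72 * 0.85)
  expect_lt(max(pos), 72 * 1.3)
})

test_that("positions follow the Kosambi accumulation rule", {
  rf <- matrix(0.5, 3, 3, dimnames = list(c("m1", "m2", "m3"),
                                          c("m1", "m2", "m3")))
  rf["m1", "m2"] <- rf["m2", "m1"] <- 0.10
  rf["m2", "m3"] <- rf["m3", "m2"] <- 0.10
  diag(rf) <- 0
  pos <- map_positions(c("m1", "m2", "m3"), fake_linkage(rf))
  expect_equal(unname(pos), c(0, 10.14, 20.28), tolerance = 1e-3)
  expect_equal(unname(map_positions("m1", fake_linkage(rf))), 0)
  # missing adjacent rf falls back to a spanning pair
  rf2 <- rf
  rf2["m2", "m3"] <- rf2["m3", "m2"] <- NA
  rf2["m1", "m3"] <- rf2["m3", "m1"] <- 0.18
  pos2 <- map_positions(c("m1", "m2", "m3"), fake_linkage(rf2))
  expect_equal(unname(pos2[2]), 10.14, tolerance = 1e-2)
  expect_gt(unname(pos2[3]), unname(pos2[2]))
})

test_that("homolog letters follow descending marker counts", {
  tab <- data.frame(
    parent = "mother",
    linkage_group = rep(1:4, times = c(69, 61, 48, 41)),
    marker = sprintf("mk%03d", 1:219),
    position_cM = 0)
  gm <- structure(list(table = tab, groups = list(), unplaced = character(0),
                       config = map_config(), linkage = NULL),
                  class = "genetic_map")
  named <- name_homologs(gm, c("1" = "1", "2" = "1", "3" = "1", "4" = "1"))
  cnt <- table(named$table$homolog)
  expect_equal(unname(cnt[c("A", "B", "C", "D")]), c(69, 61, 48, 41),
               ignore_attr = TRUE)
  expect_identical(unique(named$table$homolog[named$table$linkage_group == 1]),
                   "A")
  # ties break by smallest marker id; three groups letter A-C
  tab2 <- data.frame(parent = "m", linkage_group = rep(c(2, 1, 3), each = 5),
                     marker = sprintf("mk%02d", c(6:10, 1:5, 11:15)),
                     position_cM = 0)
  gm2 <- structure(list(table = tab2, groups = list(),
                        unplaced = character(0), config = map_config(),
                        linkage = NULL), class = "genetic_map")
  named2 <- name_homologs(gm2, c("1" = "5", "2" = "5", "3" = "5"))
  expect_identical(named2$table$homolog[named2$table$linkage_group == 1][1], "A")
  expect_identical(named2$table$homolog[named2$table$linkage_group == 2][1], "B")
  expect_false("D" %in% named2$table$homolog)
  # more than four groups warns and letters onward
  tab3 <- data.frame(parent = "m", linkage_group = rep(1:5, each = 2),
                     marker = sprintf("mk%02d", 1:10), position_cM = 0)
  gm3 <- structure(list(table = tab3, groups = list(),
                        unplaced = character(0), config = map_config(),
                        linkage = NULL), class = "genetic_map")
  expect_warning(named3 <- name_homologs(gm3,
    stats::setNames(rep("2", 5), as.character(1:5))), "beyond D")
  expect_true("E" %in% named3$table$homolog)
})

test_that("grouping recovers the 32 homologs when enough markers enter", {
  # >= 20 markers per homolog entering the grouping step (true parental
  # configurations), calls at depth 30 with alpha 0.005
  n_ok <- 0
  reps <- 8
  for (rr in seq_len(reps)) {
    cfg <- sim_config(n_progeny = 384, n_chromosomes = 8,
                      markers_per_homolog = 25, depth_mean = 30,
                      duplex_per_chromosome = 0, alpha = 0.005,
                      seed = 500 + rr)
    sc <- sim_and_call(cfg)
    pres <- true_config_presence(sc$sim, sc$calls, "mother")
    grp <- group_markers(pairwise_linkage(pres), 14)
    labels <- truth_labels(sc$sim$truth$map, rownames(pres))
    if (length(grp$groups) == 32 && partition_matches(grp, labels))
      n_ok <- n_ok + 1
  }
  expect_gte(n_ok, reps - 1)
})

test_that("full map building yields sane per-homolog maps", {
  cfg <- sim_config(n_progeny = 384, n_chromosomes = 2,
                    markers_per_homolog = 25, depth_mean = 30,
                    duplex_per_chromosome = 0, alpha = 0.005, seed = 51)
  sc <- sim_and_call(cfg)
  pres <- true_config_presence(sc$sim, sc$calls, "mother")
  gm <- build_linkage_map(pres, map_config(), parent = "mother")
  expect_s3_class(gm, "genetic_map")
  expect_length(gm$groups, 8)
  sm <- summary(gm)
  # true homolog length 70 cM: estimates bracketed by [40, 100]
  expect_true(all(sm$length_cM >= 40 & sm$length_cM <= 100))
  expect_true(all(sm$n_markers >= 15))
  expect_output(print(gm), "genetic map")
})
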