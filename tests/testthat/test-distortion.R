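test_that("the smoother reproduces constants and straight lines", {
  x <- sort(runif(30, 0, 100))
  expect_equal(loess_smooth(x, rep(2.5, 30)), rep(2.5, 30), tolerance = 1e-8)
  y <- 1 + 0.05 * x
  sm <- loess_smooth(x, y)
  interior <- 4:27
  expect_equal(sm[interior], y[interior], tolerance = 1e-6)
  expect_warning(out <- loess_smooth(c(1, 2), c(3, 4)), "fewer than 3")
  expect_identical(out, c(3, 4))
})

test_that("smoothing a noisy step stays within the input range on the interior", {
  set.seed(61)
  x <- seq(0, 99, by = 1)
  y <- ifelse(x < 50, 0, 5) + rnorm(100, 0, 0.3)
  sm <- loess_smooth(x, y, span = 0.3)
  interior <- 10:90
  eps <- 1e-6
  expect_true(all(sm[interior] >= min(y) - eps))
  expect_true(all(sm[interior] <= max(y) + eps))
})

test_that("region calling needs three consecutive same-direction markers", {
  cfgs <- scan_config()
  pos <- seq(0, 45, by = 5)
  # null: no regions
  expect_identical(nrow(call_regions(pos, rep(0.5, 10),
                                     rep("excess_presence", 10),
                                     rep(0.3, 10), cfgs)), 0L)
  # five strong markers, same direction, curve above threshold
  p <- c(rep(0.5, 3), rep(1e-6, 5), rep(0.5, 2))
  sm <- c(rep(1, 3), rep(6, 5), rep(1, 2))
  dir <- rep("excess_absence", 10)
  reg <- call_regions(pos, p, dir, sm, cfgs,
                      markers = sprintf("m%02d", 1:10))
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$start_cM, 15)
  expect_equal(reg$end_cM, 35)
  expect_identical(reg$direction, "excess_absence")
  expect_identical(reg$n_markers, 5L)
  # two qualifying markers only: below the minimum run
  p2 <- c(rep(0.5, 4), 1e-6, 1e-6, rep(0.5, 4))
  sm2 <- c(rep(1, 4), 6, 6, rep(1, 4))
  expect_identical(nrow(call_regions(pos, p2, dir, sm2, cfgs)), 0L)
  # a direction flip splits a run
  dir3 <- c(rep("excess_absence", 5), rep("excess_presence", 5))
  p3 <- rep(1e-6, 10); sm3 <- rep(6, 10)
  reg3 <- call_regions(pos, p3, dir3, sm3, cfgs)
  expect_identical(nrow(reg3), 2L)
  expect_identical(reg3$direction, c("excess_absence", "excess_presence"))
})

test_that("scan joins maps with statistics and enforces shared markers", {
  map_tab <- data.frame(linkage_group = "1A",
                        marker = c("a", "b", "c"),
                        position_cM = c(0, 5, 10))
  sda <- data.frame(marker = c("a", "b", "c"),
                    p = c(0.5, 0.5, 0.5), neglog10p = rep(0.3, 3),
                    direction = rep("excess_presence", 3))
  ds <- scan_distortion(map_tab, sda)
  expect_s3_class(ds, "distortion_scan")
  expect_identical(nrow(ds$regions), 0L)
  expect_identical(nrow(ds$points), 3L)
  # single-marker group: no regions, no smoothing crash
  one <- data.frame(linkage_group = "2A", marker = "z", position_cM = 0)
  sda_z <- data.frame(marker = "z", p = 1e-9, neglog10p = 9,
                      direction = "excess_absence")
  expect_identical(nrow(scan_distortion(one, sda_z)$regions), 0L)
  # unmatched marker ids error
  expect_error(scan_distortion(map_tab, sda_z), "missing from")
})

test_that("every reported region member is distorted in the region direction", {
  set.seed(62)
  # constructed scan with a genuine region plus scattered noise
  pos <- seq(0, 120, by = 4)
  n <- length(pos)
  p <- runif(n, 0.2, 1)
  dir <- sample(c("excess_presence", "excess_absence"), n, replace = TRUE)
  p[10:14] <- 1e-8
  dir[10:14] <- "excess_absence"
  nl <- -log10(p)
  sm <- loess_smooth(pos, nl, 0.3)
  cfgs <- scan_config()
  reg <- call_regions(pos, p, dir, sm, cfgs, markers = as.character(1:n))
  expect_gte(nrow(reg), 1)
  for (i in seq_len(nrow(reg))) {
    idx <- as.integer(strsplit(reg$markers[i], ",")[[1]])
    expect_true(all(p[idx] < cfgs$p_cut))
    expect_true(all(dir[idx] == reg$direction[i]))
  }
})

test_that("regions survive deletion of markers outside them", {
  set.seed(63)
  pos <- seq(0, 120, by = 4)
  n <- length(pos)
  p <- runif(n, 0.3, 1)
  dir <- rep("excess_presence", n)
  p[12:16] <- 1e-8
  dir[12:16] <- "excess_absence"
  scan1 <- scan_distortion(
    data.frame(linkage_group = "1A", marker = as.character(1:n),
               position_cM = pos),
    data.frame(marker = as.character(1:n), p = p, neglog10p = -log10(p),
               direction = dir))
  expect_identical(nrow(scan1$regions), 1L)
  keep <- c(8:20, 25, 28)     # region plus a few outside markers
  scan2 <- scan_distortion(
    data.frame(linkage_group = "1A", marker = as.character(keep),
               position_cM = pos[keep]),
    data.frame(marker = as.character(keep), p = p[keep],
               neglog10p = -log10(p[keep]), direction = dir[keep]))
  expect_identical(nrow(scan2$regions), 1L)
  expect_identical(scan2$regions$direction, "excess_absence")
})

test_that("a viability locus is recovered on error-free simulated data", {
  # alpha = 0 isolates the scan from caller-induced dropout bias
  detected <- 0
  for (rr in 1:3) {
    vl <- data.frame(marker = "mat_c2B_013", survival = 0.5)
    cfg <- sim_config(n_progeny = 384, n_chromosomes = 4,
                      markers_per_homolog = 25, depth_mean = 60, alpha = 0,
                      duplex_per_chromosome = 0, viability_loci = vl,
                      seed = 600 + rr)
    sc <- sim_and_call(cfg)
    sda <- sda_screen(sc$calls)
    truth <- sc$sim$truth$map
    keep <- sda$is_sda & !is.na(sda$parent) & sda$parent == "mother"
    mk <- sda$marker[keep]
    ti <- match(mk, truth$marker)
    map_tab <- data.frame(
      linkage_group = paste0(truth$chrom[ti], truth$homolog[ti]),
      marker = mk, position_cM = truth$pos_cM[ti])
    ds <- scan_distortion(map_tab, sda)
    reg <- ds$regions[ds$regions$linkage_group == "2B", , drop = FALSE]
    locus_pos <- truth$pos_cM[truth$marker == "mat_c2B_013"]
    if (nrow(reg) == 1 && reg$start_cM <= locus_pos &&
        reg$end_cM >= locus_pos && reg$direction == "excess_absence")
      detected <- detected + 1
  }
  expect_gte(detected, 2)
})

test_that("stronger selection gives a stronger smoothed peak (matched seeds)", {
  peak_at <- function(surv, seed) {
    vl <- data.frame(marker = "mat_c1A_008", survival = surv)
    cfg <- sim_config(n_progeny = 384, n_chromosomes = 2,
                      markers_per_homolog = 15, depth_mean = 60, alpha = 0,
                      duplex_per_chromosome = 0, viability_loci = vl,
                      seed = seed)
    sc <- sim_and_call(cfg)
    sda <- sda_screen(sc$calls)
    truth <- sc$sim$truth$map
    keep <- sda$is_sda & !is.na(sda$parent) & sda$parent == "mother"
    mk <- sda$marker[keep]
    ti <- match(mk, truth$marker)
    map_tab <- data.frame(
      linkage_group = paste0(truth$chrom[ti], truth$homolog[ti]),
      marker = mk, position_cM = truth$pos_cM[ti])
    ds <- scan_distortion(map_tab, sda)
    max(ds$points$smoothed[ds$points$linkage_group == "1A"], na.rm = TRUE)
  }
  for (seed in c(71, 72, 73)) {
    expect_gte(peak_at(0.3, seed), peak_at(0.8, seed) - 0.5)
  }
})
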