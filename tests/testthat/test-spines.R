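test_that("group summary averages per slice first", {
  one <- data.frame(slice_id = "s1", condition = "C",
                    lw_ratio = c(2, 4))
  s <- summarizeSpines(one)
  expect_equal(s$mean_lw, 3)
  expect_equal(s$sem_lw, 0)
  expect_true(s$sem_flag)
  ## identical slices give SEM 0
  k <- data.frame(slice_id = rep(c("s1", "s2", "s3"), each = 4),
                  condition = "C", lw_ratio = rep(c(1, 2, 3, 4), 3))
  sk <- summarizeSpines(k)
  expect_equal(sk$sem_lw, 0)
  ## random populations match the two-stage aggregation oracle
  set.seed(4)
  df <- data.frame(slice_id = sample(sprintf("s%d", 1:6), 200, TRUE),
                   condition = "C", lw_ratio = rlnorm(200, 0.8, 0.5))
  got <- summarizeSpines(df)
  want <- oracleTwoStage(df$lw_ratio, df$slice_id)
  expect_equal(got$mean_lw, unname(want["mean"]), tolerance = 1e-12)
  expect_equal(got$sem_lw, unname(want["sem"]), tolerance = 1e-12)
  expect_error(summarizeSpines(df[0, ]), "empty")
})

test_that("shape statistics are scale-free", {
  cfg <- spineSimConfig(nSpines = 500, seed = 14L)
  rec <- simulateSpines(cfg)
  k <- 3.1
  rec2 <- rec
  rec2$length_um <- rec$length_um * k
  rec2$width_um <- rec$width_um * k
  rec2$lw_ratio <- rec2$length_um / rec2$width_um
  expect_equal(summarizeSpines(rec2)$mean_lw, summarizeSpines(rec)$mean_lw,
               tolerance = 1e-12)
  expect_equal(rec2$lw_ratio, rec$lw_ratio, tolerance = 1e-12)
})

test_that("binned subpopulations are proportions that sum to one", {
  set.seed(6)
  a <- rlnorm(400, 1, 0.5); b <- rlnorm(350, 0.7, 0.5)
  bins <- binDistribution(a, b)
  expect_equal(sum(bins$prop_a), 1, tolerance = 1e-12)
  expect_equal(sum(bins$prop_b), 1, tolerance = 1e-12)
  expect_identical(binDistribution(a, a)$significant & TRUE,
                   rep(FALSE, nrow(bins)))
  expect_error(binDistribution(a, numeric(0)), "non-empty")
  expect_error(binDistribution(a, b, binEdges = c(1, 1)), "degenerate")
})

test_that("a maturation shift enriches the low-ratio bins", {
  cs <- simulateSpines(spineConfigForMeanRatio(
    spineSimConfig(nSpines = 3000, seed = 51L), 2.87))
  ltp <- simulateSpines(spineConfigForMeanRatio(
    spineSimConfig(nSpines = 3000, seed = 52L), 1.84))
  bins <- binDistribution(cs$lw_ratio, ltp$lw_ratio)
  low <- bins$bin_hi <= 1.5
  expect_true(all(bins$prop_b[low] >= bins$prop_a[low]))
  expect_true(any(bins$significant))
})

test_that("KS statistic equals the brute-force ECDF maximum", {
  expect_equal(ksCompare(1:10, 1:10)$D, 0)
  expect_equal(ksCompare(1:10, 11:20)$D, 1)
  set.seed(9)
  for (i in 1:25) {
    a <- rnorm(sample(3:50, 1)); b <- rnorm(sample(3:50, 1), sd = 2)
    expect_equal(ksCompare(a, b)$D, oracleKsD(a, b), tolerance = 1e-12)
  }
  ## p-value agrees with the reference implementation asymptotically
  set.seed(10)
  a <- rnorm(120); b <- rnorm(150, 0.3)
  got <- ksCompare(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 0.15)
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(11)
  a <- rlnorm(40); b <- rlnorm(60, 0.4)
  d0 <- ksCompare(a, b)$D
  expect_equal(ksCompare(log(a), log(b))$D, d0, tolerance = 1e-12)
  expect_equal(ksCompare(a^3, b^3)$D, d0, tolerance = 1e-12)
})

test_that("spine density is count over length, averaged across dendrites", {
  expect_equal(spineDensity(10, 10)$mean, 1)
  expect_equal(spineDensity(0, 25)$mean, 0)
  expect_error(spineDensity(3, 0), "> 0")
  ## generator recovery: 50 dendrites at 1.13 per um
  cfg <- spineSimConfig(nSpines = round(1.13 * 40 * 50), density = 1.13,
                        dendriteLength = 40, nSlices = 10, seed = 61L)
  rec <- simulateSpines(cfg)
  counts <- as.vector(table(factor(rec$dendrite_id,
                                   levels = sprintf("dend%03d", 1:50))))
  d <- spineDensity(counts, rep(40, 50))
  expect_equal(d$mean, 1.13, tolerance = 0.05 * 1.13)
})
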