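smallConfig <- function(...) {
  ephysSimConfig(baselineMinutes = 2, postMinutes = 3, ioRepeats = 2, ...)
}

test_that("input-output curve recovers the generator gain (noise-free)", {
  set <- simulateExperiment(smallConfig(noiseSd = 0))
  io <- buildIOCurve(set, "io_pre")
  cfg <- groundTruth(set)$config
  g <- abs(io$slope_mV_per_ms) / max(abs(io$slope_mV_per_ms))
  expect_equal(g, cfg@ioGain / max(cfg@ioGain), tolerance = 0.02)
  expect_true(all(io$slope_sem == 0))  # duplicated sweeps per intensity
  expect_error(buildIOCurve(set, "baseline"), "2 distinct")
})

test_that("all-zero traces give a zero curve with detection flags", {
  mk <- function(int) fieldTrace(rep(0, 600), stimTimes = 0.01)
  sw <- lapply(rep(c(50, 100), each = 2), mk)
  info <- data.frame(sweep_id = sprintf("s%d", 1:4), epoch = "io_pre",
                     time_s = (0:3) * 10,
                     intensity_uA = rep(c(50, 100), each = 2),
                     train_index = NA_real_, scale_truth = NA_real_)
  set <- new("SweepSet", sweeps = sw, info = info)
  io <- buildIOCurve(set)
  expect_true(all(io$slope_mV_per_ms == 0))
  expect_true(all(io$n_flagged == io$n))
  expect_error(selectBasalIntensity(io), "flat")
})

test_that("basal intensity selection follows the 30-40% convention", {
  io <- data.frame(intensity_uA = seq(0, 300, by = 50),
                   slope_mV_per_ms = -seq(0, 1, length.out = 7))
  expect_equal(selectBasalIntensity(io, 0.35, interpolate = TRUE), 105)
  expect_equal(selectBasalIntensity(io, 1.0), 300)
  ## random monotone curves against a dense grid-scan oracle
  set.seed(5)
  for (i in 1:20) {
    s <- cumsum(runif(8))
    io <- data.frame(intensity_uA = sort(sample(10:300, 8)),
                     slope_mV_per_ms = -s)
    fr <- runif(1, 0.2, 0.9)
    got <- selectBasalIntensity(io, fr, interpolate = TRUE)
    grid <- seq(min(io$intensity_uA), max(io$intensity_uA), length.out = 20001)
    dense <- approx(io$intensity_uA, s, xout = grid)$y
    want <- grid[which(dense >= fr * max(s) - 1e-12)[1]]
    expect_equal(got, want, tolerance = 0.05)
  }
})

test_that("paired-pulse ratio is recovered across facilitation regimes", {
  mkPpf <- function(fac) {
    cfg <- ephysSimConfig(noiseSd = 0, stimTimes = c(0.01, 0.06),
                          sweepDuration = 0.12, facilitationFactor = fac)
    simulateSweep(cfg)
  }
  expect_equal(computePPF(mkPpf(1.0))$ppf_index, 1.0, tolerance = 0.005)
  expect_equal(computePPF(mkPpf(1.58))$ppf_index, 1.58, tolerance = 0.005)
  expect_equal(computePPF(mkPpf(0.5))$ppf_index, 0.5, tolerance = 0.005)
  flat <- fieldTrace(rep(0, 1200), stimTimes = c(0.01, 0.06))
  expect_error(computePPF(flat), "not detectable")
  expect_error(computePPF(fieldTrace(rep(0, 600), stimTimes = 0.01)),
               "two stimuli")
})

test_that("baseline bins of a normalized time course average exactly 100%", {
  set <- simulateExperiment(smallConfig(noiseSd = 0.02, seed = 3L))
  tc <- normalizeTimecourse(set, plateauTimes = 3)
  base <- tc$bins$percent[tc$bins$bin_min <= 0]
  expect_equal(mean(base), 100, tolerance = 1e-9)
  tc2 <- normalizeTimecourse(set, plateauTimes = 3, averageTraces = FALSE)
  expect_equal(mean(tc2$bins$percent[tc2$bins$bin_min <= 0]), 100,
               tolerance = 1e-9)
})

test_that("a no-plasticity experiment stays at 100% within noise", {
  set <- simulateExperiment(smallConfig(noiseSd = 0.0177, seed = 8L,
                                        ptpPercent = 100,
                                        ltpPlateauPercent = 100))
  tc <- normalizeTimecourse(set, plateauTimes = 3)
  expect_true(all(abs(tc$bins$percent - 100) < 10))
})

test_that("envelope area of an exact rectangle is -amplitude x duration", {
  fs <- 10000
  pre <- 0.01
  n <- fs * 1.5
  t <- (seq_len(n) - 1) / fs
  stims <- pre + (0:99) / 100
  mk <- function() {
    v <- numeric(n)
    v[t >= pre & t <= pre + 1] <- -1
    fieldTrace(v, samplingRate = fs, stimTimes = stims)
  }
  tm <- analyzeHfsTrains(list(mk(), mk(), mk(), mk()), baselineMean = 0)
  expect_equal(tm$per_train$envelope_mVms, rep(-1000, 4), tolerance = 1e-9)
  expect_equal(tm$summed_envelope_mVms, sum(tm$per_train$envelope_mVms),
               tolerance = 1e-12)
  expect_error(analyzeHfsTrains(list(mk(), mk()), 0), "four")
})

test_that("afterpositivity amplitude and train scaling are recovered", {
  cfg <- smallConfig(noiseSd = 0, afpAmplitude = 0.19,
                     afpTrainScaling = c(1, 1.35, 1.55, 1.61))
  set <- simulateExperiment(cfg)
  hfs <- which(sweepInfo(set)$epoch == "hfs")
  tm <- analyzeHfsTrains(sweeps(set)[hfs], baselineMean = 0)
  expect_equal(tm$per_train$afp_mV[1], 0.19, tolerance = 1e-3)
  expect_equal(tm$per_train$relative_afp, c(1, 1.35, 1.55, 1.61),
               tolerance = 1e-3)
  expect_false(any(tm$per_train$afp_clipped))
})

test_that("post-induction input-output curve shifts by the late scale", {
  set <- simulateExperiment(smallConfig(noiseSd = 0, seed = 2L))
  pre <- buildIOCurve(set, "io_pre")
  post <- buildIOCurve(set, "io_post")
  k <- groundTruth(set)$late_scale
  expect_equal(post$slope_mV_per_ms, k * pre$slope_mV_per_ms,
               tolerance = 0.01)
})

test_that("LTP-PPF correlation matches the covariance formula", {
  x <- c(160, 150, 140, 130)
  y <- c(0.85, 0.9, 0.95, 1.0)
  r <- correlateLtpPpf(x, y)
  expect_equal(r$r, -1, tolerance = 1e-12)
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10)
  got <- correlateLtpPpf(x, y)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, want, tolerance = 1e-12)
  expect_error(correlateLtpPpf(rep(1, 5), rnorm(5)), "variance")
  expect_error(correlateLtpPpf(1:2, 1:2), "3 paired")
})
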