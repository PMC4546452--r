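test_that("sweep amplitude passes through and scales linearly", {
  cfg <- ephysSimConfig(noiseSd = 0, fepspPeakAmplitude = -1,
                        ioIntensity = c(0, 300), ioGain = c(1, 1))
  tr <- simulateSweep(cfg, stimIntensity = 300, potentiationScale = 1)
  t <- traceTimes(tr)
  win <- t >= 0.013 & t <= 0.04
  expect_equal(min(voltages(tr)[win]), -1, tolerance = 1e-3)
  tr2 <- simulateSweep(cfg, stimIntensity = 300, potentiationScale = 2)
  expect_equal(min(voltages(tr2)[win]), -2, tolerance = 1e-3)
  ## pure linearity of the fEPSP component (past the fiber volley)
  win2 <- t >= 0.017 & t <= 0.04
  expect_equal(voltages(tr2)[win2], 2 * voltages(tr)[win2], tolerance = 1e-12)
})

test_that("paired stimuli carry the facilitation factor as ground truth", {
  cfg <- ephysSimConfig(noiseSd = 0, stimTimes = c(0.01, 0.06),
                        sweepDuration = 0.12, facilitationFactor = 1.58)
  tr <- simulateSweep(cfg)
  sc <- traceMetadata(tr)$fepsp_scale_mv
  expect_equal(sc[2] / sc[1], 1.58, tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- ephysSimConfig(noiseSd = 0.02, seed = 11L)
  expect_identical(voltages(simulateSweep(cfg)), voltages(simulateSweep(cfg)))
  sp <- spineSimConfig(nSpines = 50, seed = 11L)
  expect_identical(simulateSpines(sp), simulateSpines(sp))
  fc <- fishSimConfig(backgroundSd = 3, cellNoiseSd = 5, seed = 11L)
  expect_identical(simulateFishField(fc), simulateFishField(fc))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(ephysSimConfig(fepspRiseTau = NA_real_), "fepspRiseTau")
  expect_error(ephysSimConfig(noiseSd = -1), "noiseSd")
  expect_error(ephysSimConfig(fepspRiseTau = 20, fepspDecayTau = 10),
               "fepspDecayTau")
  expect_error(ephysSimConfig(ioGain = rev(seq(0, 1, length.out = 12))),
               "non-decreasing")
  expect_error(ephysSimConfig(afpTrainScaling = c(1, 1.3, 1.5)),
               "4 entries")
  expect_error(ephysSimConfig(afpTrainScaling = c(1.2, 1.3, 1.5, 1.6)),
               "equal 1")
  expect_error(spineSimConfig(lwCorrelation = 2), "lwCorrelation")
  expect_error(fishSimConfig(backgroundMean = -5), "means")
})

test_that("stimulus intensity outside the gain-curve domain is rejected", {
  cfg <- ephysSimConfig(noiseSd = 0)
  expect_error(simulateSweep(cfg, stimIntensity = 500), "domain")
})

test_that("experiment ground truth follows the configured plasticity", {
  cfg <- ephysSimConfig(noiseSd = 0, ptpPercent = 206.1,
                        ltpPlateauPercent = 160.2, ptpDecayTau = 10)
  expect_equal(potentiationScaleAt(cfg, 0), 2.061, tolerance = 1e-12)
  expect_equal(potentiationScaleAt(cfg, 1e6), 1.602, tolerance = 1e-9)
  null <- ephysSimConfig(noiseSd = 0, ptpPercent = 100,
                         ltpPlateauPercent = 100, baselineMinutes = 2,
                         postMinutes = 3, ioRepeats = 1)
  set <- simulateExperiment(null)
  post <- sweepInfo(set)$scale_truth[sweepInfo(set)$epoch == "post"]
  expect_true(all(abs(post - 1) < 1e-12))
})

test_that("afterpositivity ground truth scales across trains", {
  cfg <- ephysSimConfig(noiseSd = 0, baselineMinutes = 2, postMinutes = 2,
                        ioRepeats = 1,
                        afpTrainScaling = c(1, 1.35, 1.55, 1.61))
  set <- simulateExperiment(cfg)
  hfs <- which(sweepInfo(set)$epoch == "hfs")
  afp <- vapply(sweeps(set)[hfs],
                function(tr) traceMetadata(tr)$afp_mv, numeric(1))
  expect_equal(afp / afp[1], c(1, 1.35, 1.55, 1.61), tolerance = 1e-12)
})

test_that("overlapping stimulus schedules are rejected", {
  cfg <- ephysSimConfig(noiseSd = 0, pacingHz = 20, baselineMinutes = 0.02,
                        postMinutes = 0.02, ioRepeats = 1)
  expect_error(simulateExperiment(cfg), "overlap")
})

test_that("spine generator honours degenerate and empty configurations", {
  degen <- spineSimConfig(nSpines = 20, lengthLogmean = log(2),
                          lengthLogsd = 0, widthLogmean = log(1),
                          widthLogsd = 0, lwCorrelation = 0)
  rec <- simulateSpines(degen)
  expect_equal(rec$lw_ratio, rep(2, 20), tolerance = 1e-12)
  expect_identical(nrow(simulateSpines(spineSimConfig(nSpines = 0))), 0L)
})

test_that("moment-calibrated spine generator hits the target mean ratio", {
  cfg <- spineConfigForMeanRatio(
    spineSimConfig(nSpines = 10000, seed = 21L), 2.87)
  rec <- simulateSpines(cfg)
  expect_true(all(rec$length_um > 0) && all(rec$width_um > 0))
  expect_equal(mean(rec$lw_ratio), 2.87, tolerance = 0.02)
})

test_that("fish generator reproduces fold changes exactly without noise", {
  fc <- matrix(1, 2, 2, dimnames = list(c("C", "LTP"),
                                        c("astrocyte", "neuron")))
  fc["LTP", "astrocyte"] <- 7.94
  cfg <- fishSimConfig(nCells = c(astrocyte = 40, neuron = 30),
                       conditions = c("C", "LTP"), foldChange = fc,
                       backgroundSd = 0, cellNoiseSd = 0)
  cells <- simulateFishField(cfg)
  corr <- correctBackground(cells)
  a <- corr$corrected[corr$condition == "LTP" & corr$cell_type == "astrocyte"]
  c0 <- corr$corrected[corr$condition == "C" & corr$cell_type == "astrocyte"]
  expect_equal(unique(a / mean(c0)), 7.94, tolerance = 1e-12)
  ## fold 1 everywhere, no noise: all cells identical to control mean
  cfg1 <- fishSimConfig(nCells = c(astrocyte = 10), conditions = c("C", "CS"),
                        foldChange = matrix(1, 2, 1,
                          dimnames = list(c("C", "CS"), "astrocyte")),
                        backgroundSd = 0, cellNoiseSd = 0)
  cells1 <- simulateFishField(cfg1)
  expect_true(length(unique(cells1$roi_mean)) == 1)
})

test_that("pure-background fields normalize to ~100% at large n", {
  cfg <- fishSimConfig(nCells = c(astrocyte = 10000),
                       conditions = c("C", "CS"),
                       foldChange = matrix(1, 2, 1,
                         dimnames = list(c("C", "CS"), "astrocyte")),
                       controlSignalMean = 0, backgroundSd = 10,
                       cellNoiseSd = 0, seed = 31L)
  res <- percentOfControl(simulateFishField(cfg))
  cs <- res$summary$percent[res$summary$condition == "CS"]
  expect_lt(abs(cs - 100), 5)
})
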