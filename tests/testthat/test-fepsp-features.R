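flatTrace <- function(level = 0, fs = 10000, dur = 0.06, stim = 0.01)
  fieldTrace(rep(level, fs * dur), samplingRate = fs, stimTimes = stim)

test_that("baseline is the plain average of the pre-stimulus window", {
  expect_equal(as.numeric(measureBaseline(flatTrace(0), 0.01)), 0)
  expect_equal(as.numeric(measureBaseline(flatTrace(0.3), 0.01)), 0.3)
  ## linear drift: compare against direct averaging of the same samples
  fs <- 10000
  v <- seq(0, 1, length.out = fs * 0.06)
  tr <- fieldTrace(v, samplingRate = fs, stimTimes = 0.01)
  t <- traceTimes(tr)
  sel <- t >= 0.01 - 5e-3 - 1e-12 & t <= 0.01 - 0.5e-3 + 1e-12
  expect_equal(as.numeric(measureBaseline(tr, 0.01)), mean(v[sel]),
               tolerance = 1e-12)
  expect_error(measureBaseline(tr, 0.0002), "pre-stimulus")
})

test_that("fiber volley amplitude is recovered and flat traces are flagged", {
  cfg <- ephysSimConfig(noiseSd = 0, fvAmplitude = 0.2,
                        ioIntensity = c(0, 300), ioGain = c(1, 1))
  tr <- simulateSweep(cfg, 300)
  fv <- measureFiberVolley(tr, 0.01)
  expect_true(fv$detected)
  expect_equal(fv$amplitude, 0.2, tolerance = 2e-3)
  f0 <- measureFiberVolley(flatTrace(), 0.01)
  expect_false(f0$detected)
  expect_identical(f0$amplitude, 0)
  expect_error(measureFiberVolley(flatTrace(dur = 0.012), 0.01), "exceeds")
})

test_that("fiber volley recovery sweep matches generator truth within 2%", {
  set.seed(42)
  for (i in 1:100) {
    cfg <- ephysSimConfig(
      noiseSd = 0, fvAmplitude = runif(1, 0.05, 0.5),
      fvLatency = runif(1, 1.3, 2.5), fvWidth = runif(1, 0.2, 0.4),
      fepspPeakAmplitude = -runif(1, 0.3, 1.5),
      ioIntensity = c(0, 300), ioGain = c(1, 1))
    tr <- simulateSweep(cfg, 300)
    fv <- measureFiberVolley(tr, 0.01)
    expect_equal(fv$amplitude, cfg@fvAmplitude, tolerance = 0.02)
  }
})

test_that("a linear ramp yields its exact slope", {
  fs <- 10000
  n <- fs * 0.06
  t <- (seq_len(n) - 1) / fs
  v <- numeric(n)
  ramp <- t >= 0.015 & t < 0.016
  v[ramp] <- -(t[ramp] - 0.015) * 1000      # -1 mV/ms
  v[t >= 0.016] <- -1
  tr <- fieldTrace(v, samplingRate = fs, stimTimes = 0.01)
  sl <- measureFepspSlope(tr, 0.01)
  expect_equal(sl$slope, -1, tolerance = 0.02)
  expect_equal(sl$amplitude, -1, tolerance = 0.02)
})

test_that("slope scales linearly with amplitude at fixed kinetics", {
  cfg <- ephysSimConfig(noiseSd = 0, ioIntensity = c(0, 300),
                        ioGain = c(1, 1))
  s1 <- measureFepspSlope(simulateSweep(cfg, 300, 1), 0.01)$slope
  s2 <- measureFepspSlope(simulateSweep(cfg, 300, 2), 0.01)$slope
  expect_equal(s2 / s1, 2, tolerance = 1e-6)
})

test_that("slope matches a 10x-oversampled derivative oracle (noise-free)", {
  set.seed(7)
  for (i in 1:25) {
    amp <- runif(1, 0.3, 1.5)
    rise <- runif(1, 1.5, 4); decay <- runif(1, 10, 30)
    cfg <- ephysSimConfig(noiseSd = 0, fepspPeakAmplitude = -amp,
                          fepspRiseTau = rise, fepspDecayTau = decay,
                          ioIntensity = c(0, 300), ioGain = c(1, 1))
    sl <- measureFepspSlope(simulateSweep(cfg, 300), 0.01)$slope
    expect_equal(sl, oracleSlope(amp, rise, decay), tolerance = 0.01)
  }
})

test_that("features are scale-equivariant and shift-invariant", {
  cfg <- ephysSimConfig(noiseSd = 0)
  tr <- simulateSweep(cfg)
  base <- measureFepspSlope(tr, 0.01)
  k <- 3.7
  trk <- fieldTrace(voltages(tr) * k, samplingRate = samplingRate(tr),
                    stimTimes = 0.01)
  sk <- measureFepspSlope(trk, 0.01)
  expect_equal(sk$slope, k * base$slope, tolerance = 1e-6)
  expect_equal(sk$amplitude, k * base$amplitude, tolerance = 1e-6)
  expect_equal(sk$slopeWindow, base$slopeWindow, tolerance = 1e-9)
  ## shift stimulus and waveform together by 20 ms
  fs <- samplingRate(tr)
  shift <- 0.02
  vs <- c(rep(0, fs * shift), voltages(tr))
  trs <- fieldTrace(vs, samplingRate = fs, stimTimes = 0.01 + shift)
  ss <- measureFepspSlope(trs, 0.01 + shift)
  expect_equal(ss$slope, base$slope, tolerance = 1e-9)
  expect_equal(ss$amplitude, base$amplitude, tolerance = 1e-9)
  expect_equal(ss$slopeWindow - shift, base$slopeWindow, tolerance = 1e-9)
})

test_that("median slope error stays below 5% at 5% noise", {
  cfg <- ephysSimConfig(noiseSd = 0, ioIntensity = c(0, 300),
                        ioGain = c(1, 1))
  tr0 <- simulateSweep(cfg, 300)
  v0 <- voltages(tr0)
  truth <- oracleSlope(1, cfg@fepspRiseTau, cfg@fepspDecayTau)
  set.seed(99)
  errs <- vapply(1:200, function(i) {
    tr <- fieldTrace(v0 + rnorm(length(v0), 0, 0.05),
                     samplingRate = samplingRate(tr0), stimTimes = 0.01)
    abs(measureFepspSlope(tr, 0.01)$slope / truth - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("degenerate inputs are flagged", {
  expect_identical(measureFepspSlope(flatTrace(), 0.01)$flag, "no_response")
  ## a span too narrow for derivative estimation falls back to a secant
  cfg <- ephysSimConfig(noiseSd = 0)
  tr <- simulateSweep(cfg)
  sl <- measureFepspSlope(tr, 0.01, spanFractions = c(0.49, 0.51))
  expect_identical(sl$flag, "secant")
  expect_true(is.finite(sl$slope) && sl$slope < 0)
})
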