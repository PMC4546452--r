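#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a FieldTrace
#'
#' @param voltage numeric vector of samples in mV
#' @param samplingRate Hz
#' @param t0 sweep start time in seconds
#' @param stimTimes stimulus times in seconds (same clock as `t0`)
#' @param metadata named list of annotations
#' @return a [FieldTrace-class]
#' @export
fieldTrace <- function(voltage, samplingRate = 10000, t0 = 0,
                       stimTimes = numeric(0), metadata = list()) {
  new("FieldTrace", voltage = as.numeric(voltage),
      samplingRate = samplingRate, t0 = t0,
      stimTimes = as.numeric(stimTimes), metadata = metadata)
}

#' Configure the synthetic field-potential generator
#'
#' Defaults emulate Schaffer-collateral/CA1 recordings: 10 kHz sampling,
#' paired-pulse facilitation 1.58 at a 50 ms interstimulus interval, tetanic
#' induction by 4 trains of 100 Hz for 1 s separated by 10 s, post-tetanic
#' potentiation of 206.1% of baseline decaying with a 10-min time constant to
#' a 160.2% plateau, an afterpositivity of 0.19 mV peaking 70 ms after each
#' train and scaling by 1 / 1.35 / 1.55 / 1.61 across the four trains, 0.1 Hz
#' pacing during baseline and follow-up epochs, and a saturating input-output
#' gain curve over 25-300 µA with basal stimulation at 30-40% of the maximal
#' response.
#'
#' @param samplingRate Hz (default 10000)
#' @param sweepDuration s, single-stimulus sweep length
#' @param stimTimes s, stimulus offsets within a sweep
#' @param artifactAmplitude,artifactWidth stimulus artifact (mV, ms)
#' @param fvAmplitude,fvLatency,fvWidth fiber volley (mV, ms, ms)
#' @param fepspPeakAmplitude mV (negative) at maximal stimulation
#' @param fepspRiseTau,fepspDecayTau,fepspLatency fEPSP kinetics (ms)
#' @param facilitationFactor paired-pulse scale ratio (2nd/1st)
#' @param isi ms, paired-pulse interstimulus interval
#' @param ppfRepeats number of paired-pulse sweeps (averaged at analysis time)
#' @param ioIntensity,ioGain input-output gain curve (µA, scale in [0,1])
#' @param basalFraction fraction of max response for basal intensity
#' @param ptpPercent,ltpPlateauPercent,ptpDecayTau plasticity time course
#'   (% of baseline, % of baseline, min)
#' @param afpAmplitude,afpPeakLatency,afpTrainScaling afterpositivity
#' @param hfsDepressionTau ms, within-train response rundown
#' @param nTrains,trainHz,trainDuration,interTrainInterval HFS protocol
#' @param pacingHz,baselineMinutes,postMinutes paced epochs
#' @param ioRepeats sweeps per intensity in input-output series
#' @param noiseSd mV, additive Gaussian noise
#' @param seed integer RNG seed
#' @return an [EphysSimConfig-class]
#' @export
ephysSimConfig <- function(samplingRate = 10000,
                           sweepDuration = 0.06,
                           stimTimes = 0.01,
                           artifactAmplitude = 1.0, artifactWidth = 0.5,
                           fvAmplitude = 0.2, fvLatency = 2, fvWidth = 0.3,
                           fepspPeakAmplitude = -1.0,
                           fepspRiseTau = 2.5, fepspDecayTau = 15,
                           fepspLatency = 5,
                           facilitationFactor = 1.58, isi = 50, ppfRepeats = 5,
                           ioIntensity = seq(25, 300, by = 25),
                           ioGain = NULL,
                           basalFraction = 0.35,
                           ptpPercent = 206.1, ltpPlateauPercent = 160.2,
                           ptpDecayTau = 10,
                           afpAmplitude = 0.19, afpPeakLatency = 70,
                           afpTrainScaling = c(1, 1.35, 1.55, 1.61),
                           hfsDepressionTau = 50,
                           nTrains = 4, trainHz = 100, trainDuration = 1,
                           interTrainInterval = 10,
                           pacingHz = 0.1, baselineMinutes = 10,
                           postMinutes = 90,
                           ioRepeats = 3,
                           noiseSd = 0, seed = 1L) {
  if (is.null(ioGain)) {
    g <- (1 - exp(-ioIntensity / 130))
    ioGain <- g / max(g)
  }
  new("EphysSimConfig",
      samplingRate = samplingRate, sweepDuration = sweepDuration,
      stimTimes = stimTimes,
      artifactAmplitude = artifactAmplitude, artifactWidth = artifactWidth,
      fvAmplitude = fvAmplitude, fvLatency = fvLatency, fvWidth = fvWidth,
      fepspPeakAmplitude = fepspPeakAmplitude,
      fepspRiseTau = fepspRiseTau, fepspDecayTau = fepspDecayTau,
      fepspLatency = fepspLatency,
      facilitationFactor = facilitationFactor, isi = isi,
      ppfRepeats = ppfRepeats,
      ioIntensity = as.numeric(ioIntensity), ioGain = as.numeric(ioGain),
      basalFraction = basalFraction,
      ptpPercent = ptpPercent, ltpPlateauPercent = ltpPlateauPercent,
      ptpDecayTau = ptpDecayTau,
      afpAmplitude = afpAmplitude, afpPeakLatency = afpPeakLatency,
      afpTrainScaling = as.numeric(afpTrainScaling),
      hfsDepressionTau = hfsDepressionTau,
      nTrains = nTrains, trainHz = trainHz, trainDuration = trainDuration,
      interTrainInterval = interTrainInterval,
      pacingHz = pacingHz, baselineMinutes = baselineMinutes,
      postMinutes = postMinutes, ioRepeats = ioRepeats,
      noiseSd = noiseSd, seed = as.integer(seed))
}

## --- waveform kernels (times in seconds within a sweep) ------------------

## smooth-onset fEPSP kernel, peak-normalized to -1 at its extremum
.fepspKernel <- function(t, riseTau, decayTau) {
  x <- pmax(t, 0)
  v <- -(1 - exp(-x / riseTau))^2 * exp(-x / decayTau)
  v[t <= 0] <- 0
  v / abs(.fepspKernelPeak(riseTau, decayTau))
}

## peak value (negative) and peak time of the unnormalized kernel
.fepspKernelPeak <- function(riseTau, decayTau) {
  xstar <- riseTau / (2 * decayTau + riseTau)
  tstar <- riseTau * log(1 / xstar)
  -(1 - xstar)^2 * exp(-tstar / decayTau)
}

.fvKernel <- function(t, latency, width) {
  -exp(-(t - latency)^2 / (2 * width^2))
}

## biphasic artifact: one full sine period over the artifact width
.artifactKernel <- function(t, width) {
  v <- sin(2 * pi * t / width)
  v[t < 0 | t >= width] <- 0
  v
}

## alpha-shaped afterpositivity, peak 1 at t = peakLatency
.afpKernel <- function(t, peakLatency) {
  x <- pmax(t, 0)
  v <- (x / peakLatency) * exp(1 - x / peakLatency)
  v[t <= 0] <- 0
  v
}

## interpolated input-output gain at an arbitrary intensity
.ioGainAt <- function(config, intensity) {
  rng <- range(config@ioIntensity)
  if (any(intensity < rng[1] - 1e-9) || any(intensity > rng[2] + 1e-9))
    stop(sprintf(
      "stim intensity %.4g uA outside the io_gain_curve domain [%g, %g]",
      intensity[1], rng[1], rng[2]))
  stats::approx(config@ioIntensity, config@ioGain, xout = intensity,
                rule = 2)$y
}

## basal intensity from the configured gain curve (smallest grid intensity
## whose gain reaches basalFraction of the maximum)
.basalIntensity <- function(config) {
  thr <- config@basalFraction * max(config@ioGain)
  config@ioIntensity[which(config@ioGain >= thr - 1e-12)[1]]
}

## deterministic sweep synthesis; stimOffsets in s relative to sweep start,
## fepspScaleMv / fvScaleMv / afpScaleMv are per-stimulus peak amplitudes (mV)
.sweepVoltage <- function(config, nSamples, stimOffsets, fepspScaleMv,
                          fvScaleMv, afpScaleMv = NULL) {
  fs <- config@samplingRate
  t <- (seq_len(nSamples) - 1) / fs
  v <- numeric(nSamples)
  rise <- config@fepspRiseTau / 1000
  decay <- config@fepspDecayTau / 1000
  lat <- config@fepspLatency / 1000
  fvlat <- config@fvLatency / 1000
  fvw <- config@fvWidth / 1000
  aw <- config@artifactWidth / 1000
  afplat <- config@afpPeakLatency / 1000
  for (j in seq_along(stimOffsets)) {
    st <- stimOffsets[j]
    ## restrict kernel evaluation to samples at/after the stimulus
    i0 <- max(1L, as.integer(floor(st * fs)) + 1L)
    idx <- i0:nSamples
    rel <- t[idx] - st
    v[idx] <- v[idx] +
      config@artifactAmplitude * .artifactKernel(rel, aw) +
      fvScaleMv[j] * .fvKernel(rel, fvlat, fvw) +
      fepspScaleMv[j] * .fepspKernel(rel - lat, rise, decay)
    if (!is.null(afpScaleMv) && afpScaleMv[j] != 0)
      v[idx] <- v[idx] + afpScaleMv[j] * .afpKernel(rel, afplat)
  }
  v
}

#' Simulate a single evoked sweep
#'
#' Synthesizes one sweep containing, for every stimulus in
#' `stimTimes(config)`: a brief biphasic artifact, a negative fiber-volley
#' deflection and a negative-going fEPSP whose amplitude is
#' `io gain(stimIntensity) * potentiationScale` times the configured peak
#' amplitude. Successive stimuli within the sweep are scaled by the
#' paired-pulse facilitation factor. Additive Gaussian noise of sd
#' `noiseSd` is applied; the RNG is seeded from `config@seed`, so an
#' identical seed and configuration yields a bit-identical sweep.
#'
#' Ground-truth component amplitudes are stored in the trace metadata
#' (`fepsp_scale_mv`, `fv_scale_mv`).
#'
#' @param config an [EphysSimConfig-class]
#' @param stimIntensity µA, within the configured input-output domain
#' @param potentiationScale dimensionless response scale (> 0)
#' @param t0 sweep start time on the experiment clock (s)
#' @return a [FieldTrace-class]
#' @export
simulateSweep <- function(config, stimIntensity = NULL,
                          potentiationScale = 1, t0 = 0) {
  validObject(config)
  set.seed(config@seed)
  if (is.null(stimIntensity)) stimIntensity <- .basalIntensity(config)
  .simulateSweepCore(config, stimIntensity, potentiationScale, t0)
}

## core used by simulateSweep and simulateExperiment; does not touch the seed
.simulateSweepCore <- function(config, stimIntensity, potentiationScale, t0,
                               stimOffsets = config@stimTimes) {
  if (!is.finite(potentiationScale) || potentiationScale <= 0)
    stop("potentiationScale must be a positive finite number")
  gain <- .ioGainAt(config, stimIntensity)
  n <- as.integer(round(config@sweepDuration * config@samplingRate))
  k <- seq_along(stimOffsets)
  fepspScale <- abs(config@fepspPeakAmplitude) * gain * potentiationScale *
    config@facilitationFactor^(k - 1)
  fvScale <- config@fvAmplitude * gain
  v <- .sweepVoltage(config, n, stimOffsets, fepspScale,
                     rep(fvScale, length(k)))
  if (config@noiseSd > 0)
    v <- v + stats::rnorm(n, 0, config@noiseSd)
  fieldTrace(v, samplingRate = config@samplingRate, t0 = t0,
             stimTimes = t0 + stimOffsets,
             metadata = list(
               stim_intensity_uA = stimIntensity,
               potentiation_scale = potentiationScale,
               fepsp_scale_mv = fepspScale,
               fv_scale_mv = rep(fvScale, length(k)),
               noise_sd = config@noiseSd))
}

## one HFS train trace: pulses at trainHz for trainDuration, within-train
## exponential rundown, constant fiber volleys, afterpositivity after the
## last pulse
.simulateTrainCore <- function(config, trainIndex, t0, basalIntensity) {
  gain <- .ioGainAt(config, basalIntensity)
  fs <- config@samplingRate
  pre <- 0.01
  post <- 0.3
  nPulse <- as.integer(round(config@trainDuration * config@trainHz))
  offs <- pre + (seq_len(nPulse) - 1) / config@trainHz
  dur <- pre + config@trainDuration + post
  n <- as.integer(round(dur * fs))
  dep <- exp(-(seq_len(nPulse) - 1) * 1000 / config@trainHz /
               config@hfsDepressionTau)
  fepspScale <- abs(config@fepspPeakAmplitude) * gain * dep
  fvScale <- rep(config@fvAmplitude * gain, nPulse)
  afpScale <- c(rep(0, nPulse - 1),
                config@afpAmplitude * config@afpTrainScaling[trainIndex])
  v <- .sweepVoltage(config, n, offs, fepspScale, fvScale, afpScale)
  if (config@noiseSd > 0)
    v <- v + stats::rnorm(n, 0, config@noiseSd)
  fieldTrace(v, samplingRate = fs, t0 = t0, stimTimes = t0 + offs,
             metadata = list(
               train_index = trainIndex,
               stim_intensity_uA = basalIntensity,
               fepsp_scale_mv = fepspScale,
               fv_scale_mv = fvScale,
               afp_mv = config@afpAmplitude *
                 config@afpTrainScaling[trainIndex],
               noise_sd = config@noiseSd))
}

#' Ground-truth potentiation scale of the post-induction epoch
#'
#' `plateau + (ptp - plateau) * exp(-t / ptpDecayTau)`, expressed as a
#' fraction of baseline (baseline = 1), with `t` in minutes after the end of
#' the last train.
#'
#' @param config an [EphysSimConfig-class]
#' @param tMin minutes after the end of the last HFS train
#' @return numeric vector of potentiation scales
#' @export
potentiationScaleAt <- function(config, tMin) {
  plateau <- config@ltpPlateauPercent / 100
  ptp <- config@ptpPercent / 100
  plateau + (ptp - plateau) * exp(-tMin / config@ptpDecayTau)
}

#' Simulate a full slice plasticity experiment
#'
#' Emits, in protocol order: an input-output series over the configured
#' intensity grid, a paced baseline epoch at the basal intensity (30-40% of
#' the maximal response by default), one paired-pulse sweep at the configured
#' interstimulus interval, the HFS trains (with within-train rundown and a
#' train-scaled afterpositivity), a paced post-induction epoch whose
#' ground-truth potentiation follows
#' `plateau + (ptp - plateau) * exp(-t / ptpDecayTau)`, and a repeat
#' input-output series scaled by the late potentiation. Sweep start times are
#' expressed relative to the start of the first train (time 0); paced epochs
#' are represented by sweep timestamps rather than continuous recordings.
#'
#' @param config an [EphysSimConfig-class]
#' @return a [SweepSet-class] with ground truth attached
#' @export
simulateExperiment <- function(config) {
  validObject(config)
  set.seed(config@seed)
  basal <- .basalIntensity(config)
  pace <- 1 / config@pacingHz
  sweepsL <- list()
  info <- list()
  addSweep <- function(trace, epoch, intensity, trainIndex = NA_real_,
                       scale = NA_real_) {
    sweepsL[[length(sweepsL) + 1L]] <<- trace
    info[[length(info) + 1L]] <<- data.frame(
      sweep_id = sprintf("sw%04d", length(info) + 1L), epoch = epoch,
      time_s = trace@t0, intensity_uA = intensity,
      train_index = trainIndex, scale_truth = scale,
      stringsAsFactors = FALSE)
  }

  ## 1. input-output series, before any conditioning
  tClock <- -(config@baselineMinutes * 60 +
                (length(config@ioIntensity) * config@ioRepeats +
                   max(1, round(config@ppfRepeats)) + 1) * pace)
  for (i in config@ioIntensity) {
    for (r in seq_len(config@ioRepeats)) {
      addSweep(.simulateSweepCore(config, i, 1, tClock), "io_pre", i,
               scale = 1)
      tClock <- tClock + pace
    }
  }

  ## 2. paired-pulse sweep at the basal intensity
  ppfOffsets <- c(config@stimTimes[1], config@stimTimes[1] + config@isi / 1000)
  ppfDur <- max(config@sweepDuration,
                ppfOffsets[2] + 0.04)
  ppfConfig <- config
  ppfConfig@sweepDuration <- ppfDur
  for (r in seq_len(max(1, round(config@ppfRepeats)))) {
    addSweep(.simulateSweepCore(ppfConfig, basal, 1, tClock,
                                stimOffsets = ppfOffsets),
             "ppf", basal, scale = 1)
    tClock <- tClock + pace
  }

  ## 3. paced baseline epoch
  tClock <- -config@baselineMinutes * 60
  while (tClock <= -pace / 2) {
    addSweep(.simulateSweepCore(config, basal, 1, tClock), "baseline",
             basal, scale = 1)
    tClock <- tClock + pace
  }

  ## 4. HFS trains; train k starts at (k-1)*(duration + intertrain interval)
  trainStarts <- (seq_len(config@nTrains) - 1) *
    (config@trainDuration + config@interTrainInterval)
  for (k in seq_len(config@nTrains))
    addSweep(.simulateTrainCore(config, k, trainStarts[k] - 0.01, basal),
             "hfs", basal, trainIndex = k, scale = NA_real_)
  hfsEnd <- trainStarts[config@nTrains] + config@trainDuration

  ## 5. paced post-induction epoch
  tClock <- hfsEnd + 5
  tEnd <- config@postMinutes * 60
  while (tClock <= tEnd) {
    sc <- potentiationScaleAt(config, (tClock - hfsEnd) / 60)
    addSweep(.simulateSweepCore(config, basal, sc, tClock), "post", basal,
             scale = sc)
    tClock <- tClock + pace
  }

  ## 6. repeat input-output series, scaled by the late potentiation
  lateScale <- potentiationScaleAt(config, (tEnd - hfsEnd) / 60)
  for (i in config@ioIntensity) {
    for (r in seq_len(config@ioRepeats)) {
      addSweep(.simulateSweepCore(config, i, lateScale, tClock), "io_post",
               i, scale = lateScale)
      tClock <- tClock + pace
    }
  }

  info <- do.call(rbind, info)
  ## overlapping stimulus schedules are a protocol error
  starts <- info$time_s
  ends <- starts + vapply(sweepsL, traceDuration, numeric(1))
  ord <- order(starts)
  if (any(starts[ord][-1] < ends[ord][-length(ord)] - 1e-9))
    stop("overlapping stimulus schedule: sweeps overlap in time; ",
         "increase pacing interval or shorten sweeps")

  new("SweepSet", sweeps = sweepsL, info = info,
      groundTruth = list(
        basal_intensity_uA = basal,
        basal_gain = .ioGainAt(config, basal),
        ptp_percent = config@ptpPercent,
        ltp_plateau_percent = config@ltpPlateauPercent,
        ptp_decay_tau_min = config@ptpDecayTau,
        facilitation_factor = config@facilitationFactor,
        afp_train_scaling = config@afpTrainScaling,
        afp_amplitude_mv = config@afpAmplitude,
        late_scale = lateScale,
        hfs_end_s = hfsEnd,
        io_intensity = config@ioIntensity,
        io_gain = config@ioGain,
        config = config))
}

#' Closed-form depolarizing-envelope area of one simulated HFS train
#'
#' Analytic integral (trapezoid-free) of the noise-free train waveform over
#' `[first stimulus, first stimulus + trainDuration]`, in mV*ms: the sum of
#' truncated fEPSP kernel integrals with within-train rundown, the fiber
#' volley Gaussian masses, and the tail of the afterpositivity that falls
#' inside the window (the biphasic artifact integrates to zero). Used to
#' calibrate train amplitudes to a target envelope area independently of the
#' measurement path.
#'
#' @param config an [EphysSimConfig-class]
#' @param trainIndex which train (affects only the afterpositivity scale)
#' @param stimIntensity µA; defaults to the basal intensity
#' @return envelope area in mV*ms (negative for depolarizing envelopes)
#' @export
trainEnvelopeAreaTheory <- function(config, trainIndex = 1,
                                    stimIntensity = NULL) {
  if (is.null(stimIntensity)) stimIntensity <- .basalIntensity(config)
  gain <- .ioGainAt(config, stimIntensity)
  Tms <- config@trainDuration * 1000
  nPulse <- as.integer(round(config@trainDuration * config@trainHz))
  gap <- 1000 / config@trainHz
  tk <- (seq_len(nPulse) - 1) * gap
  dep <- exp(-tk / config@hfsDepressionTau)
  tr <- config@fepspRiseTau; td <- config@fepspDecayTau
  pk <- abs(.fepspKernelPeak(tr, td))
  ## integral of the unnormalized kernel over [0, u]
  kint <- function(u) {
    u <- pmax(u, 0)
    i1 <- td * (1 - exp(-u / td))
    t2 <- 1 / (1 / tr + 1 / td)
    i2 <- t2 * (1 - exp(-u / t2))
    t3 <- 1 / (2 / tr + 1 / td)
    i3 <- t3 * (1 - exp(-u / t3))
    i1 - 2 * i2 + i3
  }
  upto <- Tms - tk - config@fepspLatency
  fepspArea <- -abs(config@fepspPeakAmplitude) * gain *
    sum(dep * kint(upto)) / pk
  ## fiber volley Gaussian mass inside the window
  fvMass <- config@fvWidth * sqrt(2 * pi) *
    (stats::pnorm((Tms - tk - config@fvLatency) / config@fvWidth) -
       stats::pnorm((-tk - config@fvLatency) / config@fvWidth))
  fvArea <- -config@fvAmplitude * gain * sum(fvMass)
  ## afterpositivity tail inside the window (starts at the last pulse)
  uAfp <- Tms - tk[nPulse]
  tau <- config@afpPeakLatency
  afpArea <- config@afpAmplitude * config@afpTrainScaling[trainIndex] *
    exp(1) * tau * (1 - exp(-uAfp / tau) * (1 + uAfp / tau))
  fepspArea + fvArea + afpArea
}

#' Calibrate the train response amplitude to a target envelope area
#'
#' Scales `fepspPeakAmplitude` so that the closed-form first-train envelope
#' area ([trainEnvelopeAreaTheory]) equals `targetArea`. The fiber-volley and
#' afterpositivity contributions do not scale with the fEPSP amplitude and
#' are accounted for analytically.
#'
#' @param config an [EphysSimConfig-class]
#' @param targetArea mV*ms (negative for depolarizing envelopes)
#' @return the config with an adjusted `fepspPeakAmplitude`
#' @export
calibrateTrainEnvelope <- function(config, targetArea) {
  zero <- config
  zero@fepspPeakAmplitude <- -1e-12  # isolate FV + AFP contributions
  base <- trainEnvelopeAreaTheory(zero, 1)
  perUnit <- (trainEnvelopeAreaTheory(config, 1) - base) /
    abs(config@fepspPeakAmplitude)  # area per unit amplitude magnitude, < 0
  ampMag <- (targetArea - base) / perUnit
  if (!is.finite(ampMag) || ampMag <= 0)
    stop("targetArea cannot be reached with a negative-going fEPSP")
  config@fepspPeakAmplitude <- -ampMag
  config
}
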