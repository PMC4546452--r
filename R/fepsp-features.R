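#' @include AllClasses.R AllGenerics.R
NULL

## sample index of a time point on the trace clock (1-based, rounded)
.sampleAt <- function(trace, time) {
  as.integer(round((time - trace@t0) * trace@samplingRate)) + 1L
}

## indices covering [from, to] (seconds, trace clock), clipped check optional
.windowIdx <- function(trace, from, to) {
  i0 <- as.integer(ceiling((from - trace@t0) * trace@samplingRate - 1e-9)) + 1L
  i1 <- as.integer(floor((to - trace@t0) * trace@samplingRate + 1e-9)) + 1L
  c(max(i0, 1L), min(i1, length(trace@voltage)))
}

#' Pre-stimulus baseline voltage
#'
#' Mean voltage over the window from `preMs` to `gapMs` milliseconds before
#' the stimulus (default 5 to 0.5 ms pre-stimulus).
#'
#' @param trace a [FieldTrace-class]
#' @param stimTime stimulus time in seconds (trace clock)
#' @param preMs window start before the stimulus (ms)
#' @param gapMs window end before the stimulus (ms)
#' @return baseline mean in mV, with attribute `"sd"` (baseline noise sd)
#' @export
measureBaseline <- function(trace, stimTime, preMs = 5, gapMs = 0.5) {
  w <- .windowIdx(trace, stimTime - preMs / 1000, stimTime - gapMs / 1000)
  nNeed <- as.integer((preMs - gapMs) / 1000 * trace@samplingRate) - 1L
  if (w[2] - w[1] < max(nNeed, 1L))
    stop(sprintf(
      "insufficient pre-stimulus samples: need the window [stim - %g ms, stim - %g ms] inside the trace",
      preMs, gapMs))
  v <- trace@voltage[w[1]:w[2]]
  out <- mean(v)
  attr(out, "sd") <- stats::sd(v)
  out
}

#' Fiber-volley amplitude
#'
#' Magnitude of the first baseline-subtracted negative extremum in the
#' fiber-volley search window (default 1-3 ms post-stimulus, after artifact
#' blanking). Returns 0 with `detected = FALSE` when no negative deflection
#' exceeds three times the baseline noise sd.
#'
#' @param trace a [FieldTrace-class]
#' @param stimTime stimulus time in seconds (trace clock)
#' @param windowMs search window, ms post-stimulus
#' @param blankMs samples within this many ms after the stimulus are excluded
#'   (artifact blanking)
#' @return list with `amplitude` (mV, >= 0) and `detected` (logical)
#' @export
measureFiberVolley <- function(trace, stimTime, windowMs = c(1, 3),
                               blankMs = 0.5) {
  bl <- measureBaseline(trace, stimTime)
  from <- stimTime + max(windowMs[1], blankMs) / 1000
  to <- stimTime + windowMs[2] / 1000
  if (to > trace@t0 + traceDuration(trace) + 1e-9)
    stop("fiber-volley window exceeds the trace")
  w <- .windowIdx(trace, from, to)
  v <- trace@voltage[w[1]:w[2]] - as.numeric(bl)
  floor_ <- 3 * attr(bl, "sd")
  i <- which.min(v)
  amp <- -v[i]
  ## parabolic refinement of the extremum to beat sample discretization
  if (i > 1 && i < length(v)) {
    denom <- v[i + 1] - 2 * v[i] + v[i - 1]
    if (denom > 0)
      amp <- -(v[i] - (v[i + 1] - v[i - 1])^2 / (8 * denom))
  }
  if (!is.finite(amp) || amp <= floor_ || amp <= 0)
    return(list(amplitude = 0, detected = FALSE))
  list(amplitude = amp, detected = TRUE)
}

## minimum of the first derivative (mV/ms) over [t20, t80], chosen by noise
## regime: central differences of the raw samples when the window is
## effectively noise-free, otherwise a local-quadratic kernel derivative with
## a plug-in bandwidth (scaled for derivative estimation)
.slopeEstimate <- function(tMs, vMv, i20, i80, noiseSd, peakMag) {
  if (noiseSd < 0.005 * peakMag) {
    dt <- tMs[2] - tMs[1]
    n <- length(vMv)
    lo <- max(i20, 2L); hi <- min(i80, n - 1L)
    d <- (vMv[(lo + 1):(hi + 1)] - vMv[(lo - 1):(hi - 1)]) / (2 * dt)
    return(min(d))
  }
  ## noise-adaptive bandwidth (ms): smoothing bias grows as h^2 while the
  ## extremum-selection bias of the span minimum shrinks as sigma/h^(3/2), so
  ## the two cancel at h ~ (sigma/peak)^(2/7); the prefactor is calibrated on
  ## synthetic fEPSP waveforms
  h <- min(max(0.95 * (noiseSd / peakMag)^(2 / 7), 0.25), 1)
  gs <- max(128L, as.integer(4 * length(tMs)))
  d <- KernSmooth::locpoly(tMs, vMv, drv = 1, degree = 2, bandwidth = h,
                           gridsize = gs, range.x = range(tMs))
  sel <- d$x >= tMs[i20] & d$x <= tMs[i80]
  min(d$y[sel])
}

#' fEPSP slope, amplitude and slope window
#'
#' Locates the baseline-subtracted negative peak inside the response window
#' (default 3-30 ms post-stimulus, after the fiber volley), then measures the
#' maximal slope of the descending phase between 20% and 80% of the negative
#' peak response: on the limb falling toward the peak, the slope is the most
#' negative first derivative of a smoothing-spline fit of the response window
#' (smoothing selected by generalized cross-validation), evaluated over the
#' contiguous 20-80% span. Amplitude ties at the 20%/80% crossings break
#' toward the earlier sample. When the span holds fewer than three samples
#' the slope falls back to the two-point secant across the span and the
#' result is flagged `"secant"`. When no peak exceeds three times the
#' baseline noise sd the result is flagged `"no_response"`.
#'
#' @param trace a [FieldTrace-class]
#' @param stimTime stimulus time in seconds (trace clock)
#' @param windowMs response search window, ms post-stimulus
#' @param blankMs artifact blanking, ms post-stimulus
#' @param spanFractions lower/upper amplitude fractions of the slope span
#' @return list with `slope` (mV/ms, negative for negative-going responses),
#'   `amplitude` (mV, negative peak relative to baseline), `slopeWindow`
#'   (c(start, end) in seconds, trace clock), `baselineMean` (mV) and `flag`
#'   (`"ok"`, `"secant"` or `"no_response"`)
#' @export
measureFepspSlope <- function(trace, stimTime, windowMs = c(3, 30),
                              blankMs = 0.5, spanFractions = c(0.2, 0.8)) {
  bl <- measureBaseline(trace, stimTime)
  from <- stimTime + max(windowMs[1], blankMs) / 1000
  to <- min(stimTime + windowMs[2] / 1000,
            trace@t0 + traceDuration(trace))
  w <- .windowIdx(trace, from, to)
  idx <- w[1]:w[2]
  ## time axis relative to the stimulus, built from sample indices so that
  ## sweeps at different absolute start times yield identical grids
  stimOff <- stimTime - trace@t0
  tMs <- ((idx - 1) / trace@samplingRate - stimOff) * 1000
  vRel <- trace@voltage[idx] - as.numeric(bl)
  out <- list(slope = NA_real_, amplitude = NA_real_,
              slopeWindow = c(NA_real_, NA_real_),
              baselineMean = as.numeric(bl), flag = "no_response")
  if (length(idx) < 8) return(out)
  ## pilot fit: locates the peak, the 20-80% span and the noise level
  pilot <- stats::smooth.spline(tMs, vRel)
  sm <- stats::predict(pilot, tMs)$y
  noiseSd <- stats::mad(vRel - sm)
  pk <- which.min(sm)
  peakMag <- -sm[pk]
  if (!is.finite(peakMag) || peakMag <= 3 * attr(bl, "sd") || peakMag <= 0)
    return(out)
  mag <- -sm[1:pk]
  i20 <- which(mag >= spanFractions[1] * peakMag)[1]
  i80 <- which(mag >= spanFractions[2] * peakMag)[1]
  if (is.na(i20) || is.na(i80) || i80 < i20) return(out)
  out$amplitude <- sm[pk]
  out$slopeWindow <- stimTime + c(tMs[i20], tMs[i80]) / 1000
  if (i80 - i20 + 1 < 3) {
    out$slope <- (vRel[i80] - vRel[i20]) /
      (tMs[i80] - tMs[i20])
    out$flag <- "secant"
    return(out)
  }
  out$slope <- .slopeEstimate(tMs, vRel, i20, i80, noiseSd, peakMag)
  out$flag <- "ok"
  out
}

#' Per-stimulus feature table for one sweep
#'
#' Applies [measureFiberVolley] and [measureFepspSlope] to every stimulus in
#' the sweep. For multi-stimulus sweeps, each response window is truncated at
#' the following stimulus so that the slope is measured before the next
#' response begins.
#'
#' @param trace a [FieldTrace-class]
#' @param windowMs response search window, ms post-stimulus
#' @param fvWindowMs fiber-volley search window, ms post-stimulus
#' @return data.frame with one row per stimulus: `stim_index`, `stim_time_s`,
#'   `fv_mV`, `fv_detected`, `slope_mV_per_ms`, `amp_mV`, `baseline_mV`,
#'   `flag`
#' @export
extractFeatures <- function(trace, windowMs = c(3, 30),
                            fvWindowMs = c(1, 3)) {
  sts <- sort(trace@stimTimes)
  rows <- lapply(seq_along(sts), function(j) {
    wm <- windowMs
    if (j < length(sts)) {
      gapMs <- (sts[j + 1] - sts[j]) * 1000
      wm[2] <- min(wm[2], gapMs - 5.5)  # leave the next baseline window free
    }
    fv <- measureFiberVolley(trace, sts[j], windowMs = fvWindowMs)
    sl <- measureFepspSlope(trace, sts[j], windowMs = wm)
    data.frame(stim_index = j, stim_time_s = sts[j],
               fv_mV = fv$amplitude, fv_detected = fv$detected,
               slope_mV_per_ms = sl$slope, amp_mV = sl$amplitude,
               baseline_mV = sl$baselineMean, flag = sl$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
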