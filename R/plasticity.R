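#' @include AllClasses.R AllGenerics.R fepsp-features.R
NULL

.sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  stats::sd(x) / sqrt(length(x))
}

## slope/fv features for a subset of sweeps; memoized per call site
.sweepFeatures <- function(set, which) {
  rows <- lapply(which, function(i) {
    tr <- set@sweeps[[i]]
    ft <- extractFeatures(tr)
    ft$sweep <- i
    ft
  })
  do.call(rbind, rows)
}

#' Input-output curve from the sweeps of one experiment
#'
#' Groups sweeps by stimulus intensity, extracts fiber-volley amplitude and
#' fEPSP slope per sweep and returns the per-intensity mean and SEM, ordered
#' by increasing intensity. Sweeps without a detectable response contribute a
#' zero slope and are counted in `n_flagged`.
#'
#' @param set a [SweepSet-class]
#' @param epoch which input-output epoch to use (`"io_pre"` or `"io_post"`);
#'   for sweep sets not built by [simulateExperiment], any epoch label whose
#'   sweeps cover at least two intensities works
#' @return data.frame: `intensity_uA`, `fv_mV`, `fv_sem`, `slope_mV_per_ms`,
#'   `slope_sem`, `n`, `n_flagged`
#' @export
buildIOCurve <- function(set, epoch = "io_pre") {
  idx <- which(set@info$epoch == epoch)
  if (!length(idx))
    stop(sprintf("no sweeps with epoch '%s'", epoch))
  ints <- set@info$intensity_uA[idx]
  if (length(unique(ints)) < 2)
    stop("input-output curve needs >= 2 distinct intensities; ",
         "use computePPF() or normalizeTimecourse() for single-intensity data")
  ft <- .sweepFeatures(set, idx)
  ft$intensity <- ints[match(ft$sweep, idx)]
  ft$slope_mV_per_ms[!is.finite(ft$slope_mV_per_ms)] <- 0
  sp <- split(ft, ft$intensity)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    intensity_uA = g$intensity[1],
    fv_mV = mean(g$fv_mV), fv_sem = .sem(g$fv_mV),
    slope_mV_per_ms = mean(g$slope_mV_per_ms),
    slope_sem = .sem(g$slope_mV_per_ms),
    n = nrow(g), n_flagged = sum(g$flag != "ok"))))
  out <- out[order(out$intensity_uA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Basal stimulation intensity from an input-output curve
#'
#' Returns the stimulus intensity at which the mean fEPSP slope magnitude
#' reaches `fraction` of its maximum (default 0.35, the midpoint of the
#' conventional 30-40% range used for basal stimulation). With
#' `interpolate = TRUE` the crossing is found by linear interpolation between
#' grid points; otherwise the smallest tabulated intensity whose slope
#' magnitude reaches the threshold is returned.
#'
#' @param io data.frame from [buildIOCurve]
#' @param fraction target fraction of the maximal response, in (0, 1]
#' @param interpolate interpolate linearly between grid points?
#' @return stimulus intensity in µA
#' @export
selectBasalIntensity <- function(io, fraction = 0.35, interpolate = FALSE) {
  s <- abs(io$slope_mV_per_ms)
  if (max(s) <= 0) stop("flat input-output curve: no responses detected")
  thr <- fraction * max(s)
  i <- which(s >= thr - 1e-12)[1]
  if (!interpolate || i == 1) return(io$intensity_uA[i])
  x0 <- io$intensity_uA[i - 1]; x1 <- io$intensity_uA[i]
  y0 <- s[i - 1]; y1 <- s[i]
  if (y1 == y0) return(x1)
  x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
}

#' Average sweeps sample-wise
#'
#' Averages sweeps that share sampling rate, length and in-sweep stimulus
#' layout (e.g. the repeats of a paired-pulse measurement) into one trace;
#' averaging before feature extraction suppresses noise ahead of the slope
#' extremum.
#'
#' @param traces list of [FieldTrace-class] objects
#' @return a [FieldTrace-class] with the time base of the first sweep
#' @export
averageSweeps <- function(traces) {
  if (!length(traces)) stop("no sweeps to average")
  n <- length(traces[[1]]@voltage)
  fs <- traces[[1]]@samplingRate
  offs <- traces[[1]]@stimTimes - traces[[1]]@t0
  for (tr in traces) {
    if (length(tr@voltage) != n || tr@samplingRate != fs ||
        max(abs((tr@stimTimes - tr@t0) - offs)) > 1e-9)
      stop("sweeps must share length, sampling rate and stimulus layout")
  }
  v <- rowMeans(vapply(traces, function(tr) tr@voltage, numeric(n)))
  fieldTrace(v, samplingRate = fs, t0 = traces[[1]]@t0,
             stimTimes = traces[[1]]@stimTimes,
             metadata = list(n_averaged = length(traces)))
}

## Fit an exponential decay to the tail of the first response over
## [stim2 - tailMs, stim2 - gapMs] and return its extrapolation at arbitrary
## times; falls back to a constant (the window mean) when the segment is not
## a clean monotone decay. Removing the tail both recenters the second
## response's baseline and cancels the residual tail slope that otherwise
## biases the paired-pulse ratio low.
.tailModel <- function(trace, stim2, tailMs = 12, gapMs = 0.5) {
  w <- .windowIdx(trace, stim2 - tailMs / 1000, stim2 - gapMs / 1000)
  idx <- w[1]:w[2]
  tMs <- ((idx - 1) / trace@samplingRate - (stim2 - trace@t0)) * 1000
  v <- trace@voltage[idx]
  const <- mean(v)
  ## two-segment estimator: noise-robust exponential from the segment means
  half <- length(v) %/% 2
  m1 <- mean(v[seq_len(half)])
  m2 <- mean(v[(half + 1):length(v)])
  t1 <- mean(tMs[seq_len(half)])
  t2 <- mean(tMs[(half + 1):length(v)])
  if (m1 < 0 && m2 < 0 && m1 < m2) {
    tau <- (t2 - t1) / log(m1 / m2)
    if (is.finite(tau) && tau > 1 && tau < 1000) {
      a <- -m1 * exp(t1 / tau)  # magnitude extrapolated to the stimulus
      return(function(tt) -a * exp(-((tt - stim2) * 1000) / tau))
    }
  }
  function(tt) rep(const, length(tt))
}

#' Paired-pulse facilitation from a two-stimulus sweep
#'
#' Measures the fEPSP slope of both responses ([measureFepspSlope]) and
#' returns their ratio (second/first). The first response window is truncated
#' before the second stimulus; the second response is measured after
#' subtracting an exponential fit of the first response's decaying tail
#' (estimated over the 12 ms preceding the second stimulus), which otherwise
#' biases the ratio low at short interstimulus intervals.
#'
#' @param trace a [FieldTrace-class] with exactly two stimuli
#' @param windowMs response search window, ms post-stimulus
#' @return list: `slope1`, `slope2` (mV/ms), `ppf_index` (slope2/slope1),
#'   `isi_ms`
#' @export
computePPF <- function(trace, windowMs = c(3, 30)) {
  if (length(trace@stimTimes) != 2)
    stop("paired-pulse facilitation needs a sweep with exactly two stimuli")
  sts <- sort(trace@stimTimes)
  wm1 <- windowMs
  wm1[2] <- min(wm1[2], (sts[2] - sts[1]) * 1000 - 5.5)
  r1 <- measureFepspSlope(trace, sts[1], windowMs = wm1)
  if (r1$flag == "no_response" || !is.finite(r1$slope) || r1$slope == 0)
    stop("first response not detectable: paired-pulse ratio undefined")
  tail <- .tailModel(trace, sts[2])
  detr <- trace
  tt <- traceTimes(trace)
  sel <- tt >= sts[2] - 0.012  # only at/after the fitted tail segment
  detr@voltage[sel] <- trace@voltage[sel] - tail(tt[sel])
  r2 <- measureFepspSlope(detr, sts[2], windowMs = windowMs)
  if (!is.finite(r2$slope) || sign(r1$slope) != sign(r2$slope))
    stop("responses have opposite slope signs: paired-pulse ratio undefined")
  list(slope1 = r1$slope, slope2 = r2$slope,
       ppf_index = r2$slope / r1$slope,
       isi_ms = (sts[2] - sts[1]) * 1000)
}

#' Baseline-normalized LTP time course
#'
#' Expresses the fEPSP slope of every paced sweep as percent of the mean
#' baseline slope and bins the result into `binMinutes` bins relative to
#' tetanization (time 0 = start of the first train). The normalization
#' divides by the mean of the baseline *bin* means, so the baseline bins
#' average exactly 100% by construction. The per-bin estimate is the mean of
#' the per-sweep slopes (whose SEM is reported); `averageTraces = TRUE`
#' instead measures the slope of the sample-wise averaged sweep of each bin.
#'
#' Post-tetanic potentiation (PTP) is the first post-induction bin; the late
#' plateau at time `t` is the mean normalized slope over the last
#' `plateauSpan` minutes up to `t`.
#'
#' @param set a [SweepSet-class] containing `baseline` and `post` epochs
#' @param hfsTime tetanization time on the experiment clock (s)
#' @param binMinutes bin width in minutes
#' @param plateauTimes minutes post-induction at which to read the plateau
#' @param plateauSpan minutes averaged for each plateau read-out
#' @param averageTraces average sweeps within a bin before measuring?
#' @return list with `bins` (data.frame: `bin_min` right bin edge in minutes,
#'   `percent`, `sem`, `n`), `ptp_percent`, `plateau_percent` (named by
#'   read-out time), `baseline_slope` (mV/ms) and `n_baseline`
#' @export
normalizeTimecourse <- function(set, hfsTime = 0, binMinutes = 1,
                                plateauTimes = 90, plateauSpan = 5,
                                averageTraces = FALSE) {
  idx <- which(set@info$epoch %in% c("baseline", "post"))
  if (sum(set@info$epoch == "baseline") < 10)
    stop("need >= 10 baseline sweeps to normalize a time course")
  tMin <- (set@info$time_s[idx] - hfsTime) / 60
  bin <- ceiling(tMin / binMinutes - 1e-9)
  perSweep <- vapply(idx, function(i) {
    measureFepspSlope(set@sweeps[[i]], set@sweeps[[i]]@stimTimes[1])$slope
  }, numeric(1))
  binIds <- sort(unique(bin))
  binSlope <- numeric(length(binIds))
  binSem <- numeric(length(binIds))
  binN <- integer(length(binIds))
  for (k in seq_along(binIds)) {
    sel <- which(bin == binIds[k])
    binN[k] <- length(sel)
    binSem[k] <- .sem(perSweep[sel])
    if (averageTraces && length(sel) > 1) {
      lens <- vapply(sel, function(j) length(set@sweeps[[idx[j]]]@voltage),
                     integer(1))
      if (length(unique(lens)) == 1) {
        tr0 <- set@sweeps[[idx[sel[1]]]]
        vAvg <- rowMeans(vapply(sel, function(j)
          set@sweeps[[idx[j]]]@voltage, numeric(lens[1])))
        avg <- fieldTrace(vAvg, samplingRate = tr0@samplingRate,
                          t0 = tr0@t0, stimTimes = tr0@stimTimes)
        binSlope[k] <- measureFepspSlope(avg, avg@stimTimes[1])$slope
      } else binSlope[k] <- mean(perSweep[sel], na.rm = TRUE)
    } else {
      binSlope[k] <- mean(perSweep[sel], na.rm = TRUE)
    }
  }
  isBase <- binIds <= 0
  if (!any(isBase)) stop("no baseline bins found before hfsTime")
  denom <- mean(binSlope[isBase])
  if (!is.finite(denom) || abs(denom) < 1e-12)
    stop("baseline mean slope not distinguishable from 0; cannot normalize")
  percent <- binSlope / denom * 100
  semPct <- binSem / abs(denom) * 100
  bins <- data.frame(bin_min = binIds * binMinutes, percent = percent,
                     sem = semPct, n = binN)
  firstPost <- which(binIds > 0)[1]
  ## per-sweep normalized values for plateau read-outs
  sweepPct <- perSweep / denom * 100
  plateau <- vapply(plateauTimes, function(tt) {
    sel <- tMin > tt - plateauSpan & tMin <= tt
    if (!any(sel)) return(NA_real_)
    mean(sweepPct[sel], na.rm = TRUE)
  }, numeric(1))
  names(plateau) <- sprintf("%g", plateauTimes)
  list(bins = bins,
       ptp_percent = if (is.na(firstPost)) NA_real_ else percent[firstPost],
       plateau_percent = plateau,
       baseline_slope = denom,
       n_baseline = sum(set@info$epoch == "baseline"))
}

## trapezoid integral over a sample window, x in ms
.trapz <- function(y, dtMs) {
  if (length(y) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2) * dtMs
}

#' Envelope area and afterpositivity of the HFS trains
#'
#' For each train trace: the depolarizing envelope area is the trapezoidal
#' integral of the voltage relative to 0 mV over
#' `[first stimulus, first stimulus + trainSeconds]` (negative for
#' depolarizing envelopes); the afterpositivity (AFP) amplitude is the
#' maximal positive voltage, relative to the pre-tetanus baseline mean, in a
#' 50-100 ms window after the last train stimulus, read from a
#' moving-average-smoothed trace (default 10 ms) so that the slow positive
#' deflection is not confounded by sample noise. Relative AFP amplitudes are
#' normalized to the first train.
#'
#' Setting `envelopeFromBaseline = TRUE` integrates relative to
#' `baselineMean` instead of 0 mV, for recordings with a DC offset.
#'
#' @param trainTraces list of [FieldTrace-class], one per train, each
#'   covering its train plus at least 200 ms after the last stimulus
#' @param baselineMean mV, pre-tetanus baseline (AFP reference)
#' @param trainSeconds integration window from the first stimulus (s)
#' @param afpWindowMs AFP search window after the last stimulus (ms)
#' @param afpSmoothMs moving-average width for the AFP read-out (ms)
#' @param envelopeFromBaseline integrate from `baselineMean` instead of 0 mV
#' @return list with `per_train` (data.frame: `train`, `envelope_mVms`,
#'   `afp_mV`, `relative_afp`, `afp_clipped`) and `summed_envelope_mVms`
#' @export
analyzeHfsTrains <- function(trainTraces, baselineMean = 0,
                             trainSeconds = 1, afpWindowMs = c(50, 100),
                             afpSmoothMs = 10,
                             envelopeFromBaseline = FALSE) {
  if (length(trainTraces) < 4)
    stop("expected the four traces of the HFS protocol")
  ref <- if (envelopeFromBaseline) baselineMean else 0
  rows <- lapply(seq_along(trainTraces), function(k) {
    tr <- trainTraces[[k]]
    dtMs <- 1000 / tr@samplingRate
    sts <- sort(tr@stimTimes)
    w <- .windowIdx(tr, sts[1], sts[1] + trainSeconds)
    env <- .trapz(tr@voltage[w[1]:w[2]] - ref, dtMs)
    last <- sts[length(sts)]
    wa <- .windowIdx(tr, last + afpWindowMs[1] / 1000,
                     last + afpWindowMs[2] / 1000)
    clipped <- (last + afpWindowMs[2] / 1000) >
      (tr@t0 + traceDuration(tr) + 1e-9)
    nSm <- max(1L, as.integer(round(afpSmoothMs / dtMs)))
    if (nSm %% 2 == 0) nSm <- nSm + 1L
    vs <- stats::filter(tr@voltage, rep(1 / nSm, nSm), sides = 2)
    seg <- vs[wa[1]:wa[2]]
    seg <- seg[is.finite(seg)]
    afp <- max(seg) - baselineMean
    data.frame(train = k, envelope_mVms = env, afp_mV = afp,
               afp_clipped = clipped)
  })
  per <- do.call(rbind, rows)
  per$relative_afp <- per$afp_mV / per$afp_mV[1]
  per <- per[, c("train", "envelope_mVms", "afp_mV", "relative_afp",
                 "afp_clipped")]
  list(per_train = per,
       summed_envelope_mVms = sum(per$envelope_mVms))
}

#' Correlation between late LTP magnitude and paired-pulse change
#'
#' Pearson correlation (two-sided) between per-slice late-LTP magnitudes and
#' per-slice relative paired-pulse ratio changes.
#'
#' @param latePercent numeric vector of late LTP magnitudes (% of baseline)
#' @param ppfChange numeric vector of relative PPF changes (post/pre)
#' @return list with `r`, `p`, `n`
#' @export
correlateLtpPpf <- function(latePercent, ppfChange) {
  if (length(latePercent) != length(ppfChange))
    stop("inputs must be paired")
  ok <- is.finite(latePercent) & is.finite(ppfChange)
  if (sum(ok) < 3) stop("need >= 3 paired observations")
  x <- latePercent[ok]; y <- ppfChange[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
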