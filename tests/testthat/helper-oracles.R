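## Independent oracles used across tests. These re-derive the generator's
## waveform analytically and never call the measurement code under test.

## analytic fEPSP kernel (smooth onset, peak-normalized to -1), evaluated at
## arbitrary times; taus in ms, t in ms relative to response onset
oracleFepsp <- function(tMs, ampMv, riseTau, decayTau) {
  xstar <- riseTau / (2 * decayTau + riseTau)
  tstar <- riseTau * log(1 / xstar)
  pk <- (1 - xstar)^2 * exp(-tstar / decayTau)
  shape <- ifelse(tMs <= 0, 0,
                  (1 - exp(-tMs / riseTau))^2 * exp(-tMs / decayTau) / pk)
  -ampMv * shape  # ampMv is the (positive) peak magnitude; output negative
}

## dense-grid maximal descending slope within the 20-80% span (mV/ms),
## oversampled by `over` relative to `fsHz`
oracleSlope <- function(ampMv, riseTau, decayTau, fsHz = 10000, over = 10,
                        windowMs = c(3, 30), latencyMs = 5) {
  dt <- 1000 / (fsHz * over)
  t <- seq(windowMs[1], windowMs[2], by = dt)
  v <- oracleFepsp(t - latencyMs, ampMv, riseTau, decayTau)
  pk <- which.min(v)
  mag <- -v[1:pk]
  pkmag <- mag[pk]
  i20 <- which(mag >= 0.2 * pkmag)[1]
  i80 <- which(mag >= 0.8 * pkmag)[1]
  d <- diff(v) / dt
  min(d[i20:max(i20, i80 - 1)])
}

## brute-force two-sample KS statistic: exhaustive maximum over all observed
## points of the absolute ECDF difference
oracleKsD <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x)
    abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

## brute-force trapezoid on a fine analytic grid of one simulated train
oracleTrainEnvelope <- function(config, trainIndex, intensity, over = 10) {
  fs <- config@samplingRate * over
  pre <- 0.01
  nPulse <- round(config@trainDuration * config@trainHz)
  offs <- pre + (seq_len(nPulse) - 1) / config@trainHz
  dur <- pre + config@trainDuration + 0.3
  t <- seq(0, dur - 1/fs, by = 1/fs)
  gain <- approx(config@ioIntensity, config@ioGain, xout = intensity,
                 rule = 2)$y
  dep <- exp(-(seq_len(nPulse) - 1) * 1000 / config@trainHz /
               config@hfsDepressionTau)
  v <- numeric(length(t))
  for (k in seq_len(nPulse)) {
    rel <- (t - offs[k]) * 1000
    v <- v + oracleFepsp(rel - config@fepspLatency,
                         abs(config@fepspPeakAmplitude) * gain * dep[k],
                         config@fepspRiseTau, config@fepspDecayTau)
    v <- v - config@fvAmplitude * gain *
      exp(-(rel - config@fvLatency)^2 / (2 * config@fvWidth^2))
    art <- sin(2 * pi * rel / config@artifactWidth)
    art[rel < 0 | rel >= config@artifactWidth] <- 0
    v <- v + config@artifactAmplitude * art
  }
  relA <- (t - offs[nPulse]) * 1000
  afp <- (relA / config@afpPeakLatency) * exp(1 - relA / config@afpPeakLatency)
  afp[relA <= 0] <- 0
  v <- v + config@afpAmplitude * config@afpTrainScaling[trainIndex] * afp
  w <- t >= offs[1] & t <= offs[1] + config@trainDuration
  y <- v[w]
  sum((y[-1] + y[-length(y)]) / 2) * (1000 / fs)
}

## two-stage aggregation oracle: per-slice means, then across-slice mean/SEM
oracleTwoStage <- function(values, slices) {
  m <- tapply(values, slices, mean)
  c(mean = mean(m), sem = sd(m) / sqrt(length(m)))
}
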