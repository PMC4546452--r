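#' @import methods
NULL

#' FieldTrace: one uniformly sampled extracellular voltage sweep
#'
#' A single field-potential sweep: voltage samples (mV) at a fixed sampling
#' rate, a start time on the experiment clock, and the stimulus times that
#' fall inside the sweep. `metadata` carries free-form annotations, including
#' generator ground truth for synthetic sweeps.
#'
#' Time conventions used throughout the package: seconds inside traces and
#' for stimulus times, minutes for LTP time courses, milliseconds for
#' latencies and analysis windows.
#'
#' @slot samplingRate sampling rate in Hz
#' @slot voltage numeric vector of voltage samples in mV
#' @slot t0 sweep start time in seconds (experiment clock)
#' @slot stimTimes stimulus times in seconds, on the same clock as `t0`
#' @slot metadata named list of annotations
#' @export
setClass("FieldTrace",
  representation(
    samplingRate = "numeric",
    voltage = "numeric",
    t0 = "numeric",
    stimTimes = "numeric",
    metadata = "list"
  ),
  prototype(samplingRate = 10000, voltage = numeric(0), t0 = 0,
            stimTimes = numeric(0), metadata = list())
)

setValidity("FieldTrace", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive finite number")
  if (anyNA(object@voltage) || any(!is.finite(object@voltage)))
    msg <- c(msg, "voltage samples must all be finite")
  if (length(object@t0) != 1 || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  dur <- length(object@voltage) / object@samplingRate
  if (length(object@stimTimes) &&
      (any(object@stimTimes < object@t0 - 1e-9) ||
       any(object@stimTimes > object@t0 + dur + 1e-9)))
    msg <- c(msg, "stimTimes must lie within [t0, t0 + duration]")
  if (length(msg)) msg else TRUE
})

#' SweepSet: an ordered collection of sweeps from one slice experiment
#'
#' Holds the sweeps of a full stimulation protocol (input-output series,
#' paced baseline, paired-pulse sweep, high-frequency trains, post-induction
#' epoch, repeat input-output series) together with per-sweep annotations and
#' the generator ground truth when the set is synthetic.
#'
#' @slot sweeps list of [FieldTrace-class] objects
#' @slot info data.frame with one row per sweep: `sweep_id`, `epoch`,
#'   `time_s` (sweep start relative to the first HFS train), `intensity_uA`,
#'   `train_index`, `scale_truth` (ground-truth potentiation scale, NA for
#'   real data)
#' @slot groundTruth named list of generator parameters (empty for real data)
#' @export
setClass("SweepSet",
  representation(
    sweeps = "list",
    info = "data.frame",
    groundTruth = "list"
  ),
  prototype(sweeps = list(), info = data.frame(), groundTruth = list())
)

setValidity("SweepSet", function(object) {
  msg <- character(0)
  if (length(object@sweeps) != nrow(object@info))
    msg <- c(msg, "info must have one row per sweep")
  if (length(object@sweeps) &&
      !all(vapply(object@sweeps, is, logical(1), class2 = "FieldTrace")))
    msg <- c(msg, "all sweeps must be FieldTrace objects")
  need <- c("sweep_id", "epoch", "time_s", "intensity_uA")
  if (nrow(object@info) && !all(need %in% names(object@info)))
    msg <- c(msg, paste("info must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' EphysSimConfig: parameters of the synthetic field-potential generator
#'
#' Waveform, plasticity and protocol parameters for simulated slice
#' experiments. Amplitudes are in mV, latencies and kinetic time constants in
#' ms, `ptpDecayTau` in minutes, sweep-level times in seconds.
#'
#' @slot samplingRate Hz
#' @slot sweepDuration s, duration of single-stimulus sweeps
#' @slot stimTimes s, stimulus offsets within a sweep
#' @slot artifactAmplitude mV, biphasic stimulus-artifact amplitude
#' @slot artifactWidth ms, artifact duration
#' @slot fvAmplitude mV, fiber-volley magnitude (negative deflection)
#' @slot fvLatency ms, fiber-volley latency after the stimulus
#' @slot fvWidth ms, Gaussian width (sd) of the fiber volley
#' @slot fepspPeakAmplitude mV, fEPSP peak (negative) at maximal stimulation
#' @slot fepspRiseTau ms
#' @slot fepspDecayTau ms (must exceed the rise tau)
#' @slot fepspLatency ms, fEPSP onset after the stimulus
#' @slot facilitationFactor ratio of 2nd/1st response scale for paired pulses
#' @slot isi ms, paired-pulse interstimulus interval
#' @slot ioIntensity µA, stimulus grid of the input-output curve
#' @slot ioGain response scale in [0, 1] for each `ioIntensity` entry,
#'   non-decreasing (saturating)
#' @slot basalFraction target fraction of the maximal response used to pick
#'   the basal stimulation intensity
#' @slot ptpPercent % of baseline immediately after the tetanus
#' @slot ltpPlateauPercent % of baseline at late time points
#' @slot ptpDecayTau min, decay of the post-tetanic transient
#' @slot afpAmplitude mV, afterpositivity peak after the first train
#' @slot afpPeakLatency ms after the last train stimulus
#' @slot afpTrainScaling length-4 scaling of the afterpositivity across
#'   trains; the first entry must be 1
#' @slot hfsDepressionTau ms, within-train rundown of per-pulse responses
#' @slot nTrains number of HFS trains
#' @slot trainHz within-train stimulation frequency
#' @slot trainDuration s, duration of each train
#' @slot interTrainInterval s, gap between consecutive trains
#' @slot ppfRepeats paired-pulse sweeps recorded per experiment
#' @slot pacingHz baseline/post-induction pacing frequency
#' @slot baselineMinutes min, paced baseline epoch
#' @slot postMinutes min, paced post-induction epoch
#' @slot ioRepeats sweeps per intensity in the input-output series
#' @slot noiseSd mV, additive Gaussian noise
#' @slot seed integer RNG seed
#' @export
setClass("EphysSimConfig",
  representation(
    samplingRate = "numeric", sweepDuration = "numeric",
    stimTimes = "numeric",
    artifactAmplitude = "numeric", artifactWidth = "numeric",
    fvAmplitude = "numeric", fvLatency = "numeric", fvWidth = "numeric",
    fepspPeakAmplitude = "numeric", fepspRiseTau = "numeric",
    fepspDecayTau = "numeric", fepspLatency = "numeric",
    facilitationFactor = "numeric", isi = "numeric",
    ppfRepeats = "numeric",
    ioIntensity = "numeric", ioGain = "numeric", basalFraction = "numeric",
    ptpPercent = "numeric", ltpPlateauPercent = "numeric",
    ptpDecayTau = "numeric",
    afpAmplitude = "numeric", afpPeakLatency = "numeric",
    afpTrainScaling = "numeric", hfsDepressionTau = "numeric",
    nTrains = "numeric", trainHz = "numeric", trainDuration = "numeric",
    interTrainInterval = "numeric", pacingHz = "numeric",
    baselineMinutes = "numeric", postMinutes = "numeric",
    ioRepeats = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("EphysSimConfig", function(object) {
  msg <- character(0)
  num1 <- function(x, nm, positive = FALSE, nonneg = FALSE) {
    if (length(x) != 1 || !is.finite(x))
      return(sprintf("%s must be a single finite number", nm))
    if (positive && x <= 0) return(sprintf("%s must be > 0", nm))
    if (nonneg && x < 0) return(sprintf("%s must be >= 0", nm))
    NULL
  }
  msg <- c(msg,
    num1(object@samplingRate, "samplingRate", positive = TRUE),
    num1(object@sweepDuration, "sweepDuration", positive = TRUE),
    num1(object@fvLatency, "fvLatency", nonneg = TRUE),
    num1(object@fvWidth, "fvWidth", positive = TRUE),
    num1(object@fepspRiseTau, "fepspRiseTau", positive = TRUE),
    num1(object@fepspDecayTau, "fepspDecayTau", positive = TRUE),
    num1(object@fepspLatency, "fepspLatency", nonneg = TRUE),
    num1(object@artifactWidth, "artifactWidth", positive = TRUE),
    num1(object@facilitationFactor, "facilitationFactor", positive = TRUE),
    num1(object@isi, "isi", positive = TRUE),
    num1(object@ptpDecayTau, "ptpDecayTau", positive = TRUE),
    num1(object@hfsDepressionTau, "hfsDepressionTau", positive = TRUE),
    num1(object@afpPeakLatency, "afpPeakLatency", nonneg = TRUE),
    num1(object@noiseSd, "noiseSd", nonneg = TRUE))
  if (any(!is.finite(object@stimTimes)) || any(object@stimTimes < 0))
    msg <- c(msg, "stimTimes must be finite and >= 0")
  if (all(is.finite(c(object@fepspDecayTau, object@fepspRiseTau))) &&
      object@fepspDecayTau <= object@fepspRiseTau)
    msg <- c(msg, "fepspDecayTau must exceed fepspRiseTau")
  if (length(object@ioIntensity) != length(object@ioGain))
    msg <- c(msg, "ioIntensity and ioGain must have equal length")
  if (any(!is.finite(object@ioIntensity)) || any(!is.finite(object@ioGain)))
    msg <- c(msg, "ioIntensity and ioGain must be finite")
  if (is.unsorted(object@ioIntensity, strictly = TRUE))
    msg <- c(msg, "ioIntensity must be strictly increasing")
  if (is.unsorted(object@ioGain))
    msg <- c(msg, "ioGain must be non-decreasing in stimulus intensity")
  if (any(object@ioGain < 0) || any(object@ioGain > 1))
    msg <- c(msg, "ioGain must lie in [0, 1]")
  if (length(object@afpTrainScaling) != object@nTrains)
    msg <- c(msg, sprintf("afpTrainScaling must have exactly %d entries",
                          as.integer(object@nTrains)))
  if (length(object@afpTrainScaling) &&
      abs(object@afpTrainScaling[1] - 1) > 1e-12)
    msg <- c(msg, "afpTrainScaling[1] must equal 1.0")
  if (object@basalFraction <= 0 || object@basalFraction > 1)
    msg <- c(msg, "basalFraction must lie in (0, 1]")
  msg <- msg[!vapply(msg, is.null, logical(1))]
  if (length(msg)) unlist(msg) else TRUE
})

#' SpineSimConfig: parameters of the synthetic spine-population generator
#'
#' Spine lengths and head widths are drawn from a correlated bivariate
#' lognormal distribution; spines are distributed over dendritic segments so
#' that the configured linear density is reproduced on average.
#'
#' @slot nSpines number of spines to generate
#' @slot lengthLogmean,lengthLogsd log-µm moments of the spine length
#' @slot widthLogmean,widthLogsd log-µm moments of the spine head width
#' @slot lwCorrelation correlation of log-length and log-width, in [-1, 1]
#' @slot dendriteLength µm, length of each dendritic segment
#' @slot density spines per µm of dendrite
#' @slot nSlices number of slices the dendrites are spread over
#' @slot conditionLabel condition label attached to every record
#' @slot seed integer RNG seed
#' @export
setClass("SpineSimConfig",
  representation(
    nSpines = "numeric",
    lengthLogmean = "numeric", lengthLogsd = "numeric",
    widthLogmean = "numeric", widthLogsd = "numeric",
    lwCorrelation = "numeric",
    dendriteLength = "numeric", density = "numeric",
    nSlices = "numeric", conditionLabel = "character",
    seed = "integer"
  )
)

setValidity("SpineSimConfig", function(object) {
  msg <- character(0)
  if (object@nSpines < 0) msg <- c(msg, "nSpines must be >= 0")
  if (object@lengthLogsd < 0 || object@widthLogsd < 0)
    msg <- c(msg, "log-sds must be >= 0")
  if (abs(object@lwCorrelation) > 1)
    msg <- c(msg, "lwCorrelation must lie in [-1, 1]")
  if (object@density < 0) msg <- c(msg, "density must be >= 0")
  if (object@dendriteLength <= 0)
    msg <- c(msg, "dendriteLength must be > 0")
  if (object@nSlices < 1) msg <- c(msg, "nSlices must be >= 1")
  fin <- c(object@lengthLogmean, object@lengthLogsd, object@widthLogmean,
           object@widthLogsd, object@lwCorrelation, object@dendriteLength,
           object@density)
  if (any(!is.finite(fin))) msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' FishSimConfig: parameters of the synthetic cell-fluorescence generator
#'
#' Per-cell ROI intensities are background plus a condition- and
#' cell-type-specific fold change of the control signal, plus cell-level
#' noise. The recorded `background` column carries the per-slice background
#' estimate (the mean), while the realized background fluctuates around it.
#'
#' @slot nCells named numeric vector: cells per cell type (per condition)
#' @slot conditions condition labels; must include the control
#' @slot controlCondition label of the unstimulated control
#' @slot foldChange matrix (conditions x cell types) of fold changes over the
#'   control signal; the control row must be 1
#' @slot backgroundMean,backgroundSd a.u., background fluorescence
#' @slot controlSignalMean a.u., background-corrected control signal
#' @slot cellNoiseSd a.u., per-cell noise
#' @slot nSlices slices per condition
#' @slot seed integer RNG seed
#' @export
setClass("FishSimConfig",
  representation(
    nCells = "numeric", conditions = "character",
    controlCondition = "character", foldChange = "matrix",
    backgroundMean = "numeric", backgroundSd = "numeric",
    controlSignalMean = "numeric", cellNoiseSd = "numeric",
    nSlices = "numeric", seed = "integer"
  )
)

setValidity("FishSimConfig", function(object) {
  msg <- character(0)
  if (is.null(names(object@nCells)) || any(object@nCells < 0))
    msg <- c(msg, "nCells must be a named vector of non-negative counts")
  if (!object@controlCondition %in% object@conditions)
    msg <- c(msg, "conditions must include the control condition")
  fc <- object@foldChange
  if (!all(rownames(fc) == object@conditions) ||
      !all(colnames(fc) == names(object@nCells)))
    msg <- c(msg, "foldChange must be a conditions x cell-types matrix")
  if (any(!is.finite(fc)) || any(fc <= 0))
    msg <- c(msg, "fold_change entries must be finite and > 0")
  if (object@controlCondition %in% rownames(fc) &&
      any(abs(fc[object@controlCondition, ] - 1) > 1e-12))
    msg <- c(msg, "control condition must have fold_change 1.0")
  if (object@backgroundMean < 0 || object@controlSignalMean < 0)
    msg <- c(msg, "means must be >= 0")
  if (object@backgroundSd < 0 || object@cellNoiseSd < 0)
    msg <- c(msg, "sds must be >= 0")
  if (length(msg)) msg else TRUE
})
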