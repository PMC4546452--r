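#' @include AllClasses.R
NULL

#' Accessors for FieldTrace and SweepSet objects
#'
#' Slot access for the data containers. `traceTimes()` returns the sample
#' time axis of a sweep, `traceDuration()` its length in seconds.
#'
#' @param object a [FieldTrace-class] or [SweepSet-class]
#' @return the corresponding slot (or derived vector)
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname trace-accessors
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))
#' @rdname trace-accessors
#' @export
setGeneric("stimTimes", function(object) standardGeneric("stimTimes"))
#' @rdname trace-accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname trace-accessors
#' @export
setGeneric("traceDuration", function(object) standardGeneric("traceDuration"))
#' @rdname trace-accessors
#' @export
setGeneric("traceStart", function(object) standardGeneric("traceStart"))
#' @rdname trace-accessors
#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))
#' @rdname trace-accessors
#' @export
setGeneric("sweeps", function(object) standardGeneric("sweeps"))
#' @rdname trace-accessors
#' @export
setGeneric("sweepInfo", function(object) standardGeneric("sweepInfo"))
#' @rdname trace-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname trace-accessors
setMethod("samplingRate", "FieldTrace", function(object) object@samplingRate)
#' @rdname trace-accessors
setMethod("voltages", "FieldTrace", function(object) object@voltage)
#' @rdname trace-accessors
setMethod("stimTimes", "FieldTrace", function(object) object@stimTimes)
#' @rdname trace-accessors
setMethod("traceStart", "FieldTrace", function(object) object@t0)
#' @rdname trace-accessors
setMethod("traceDuration", "FieldTrace",
          function(object) length(object@voltage) / object@samplingRate)
#' @rdname trace-accessors
setMethod("traceTimes", "FieldTrace", function(object)
  object@t0 + (seq_along(object@voltage) - 1) / object@samplingRate)
#' @rdname trace-accessors
setMethod("traceMetadata", "FieldTrace", function(object) object@metadata)
#' @rdname trace-accessors
setMethod("sweeps", "SweepSet", function(object) object@sweeps)
#' @rdname trace-accessors
setMethod("sweepInfo", "SweepSet", function(object) object@info)
#' @rdname trace-accessors
setMethod("groundTruth", "SweepSet", function(object) object@groundTruth)

setMethod("show", "FieldTrace", function(object) {
  cat(sprintf(
    "FieldTrace: %d samples at %g kHz (%.4g s), t0 = %.4g s, %d stimulus(es)\n",
    length(object@voltage), object@samplingRate / 1000,
    traceDuration(object), object@t0, length(object@stimTimes)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "SweepSet", function(object) {
  cat(sprintf("SweepSet: %d sweeps\n", length(object@sweeps)))
  if (nrow(object@info)) {
    tab <- table(object@info$epoch)
    cat("  epochs:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  if (length(object@groundTruth))
    cat("  ground truth attached\n")
})

setMethod("show", "EphysSimConfig", function(object) {
  cat(sprintf(
    paste0("EphysSimConfig: %g kHz, fEPSP %.3g mV (rise %.3g / decay %.3g ms),",
           " PTP %.4g%%, plateau %.4g%%, noise sd %.3g mV, seed %d\n"),
    object@samplingRate / 1000, object@fepspPeakAmplitude,
    object@fepspRiseTau, object@fepspDecayTau, object@ptpPercent,
    object@ltpPlateauPercent, object@noiseSd, object@seed))
})

setMethod("show", "SpineSimConfig", function(object) {
  cat(sprintf(
    "SpineSimConfig: %d spines, condition '%s', density %.3g / um, seed %d\n",
    as.integer(object@nSpines), object@conditionLabel, object@density,
    object@seed))
})

setMethod("show", "FishSimConfig", function(object) {
  cat(sprintf(
    "FishSimConfig: cell types %s; conditions %s; control '%s'; seed %d\n",
    paste(names(object@nCells), collapse = "/"),
    paste(object@conditions, collapse = "/"),
    object@controlCondition, object@seed))
})
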