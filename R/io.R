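#' @include AllClasses.R AllGenerics.R
NULL

.TRACE_FMT <- "%.6f"

#' Write a sweep to a delimited text file
#'
#' Two tab-separated columns (`time_s`, `voltage_mV`, both printed with six
#' decimals) preceded by `#`-prefixed header lines carrying
#' `sampling_rate_hz`, `sweep_t0_s`, `stim_times_s` (comma-separated),
#' `stim_intensity_uA`, `condition` and `sweep_id`. Reading a written file
#' and writing it again reproduces the bytes exactly (values round-trip at
#' the printed precision).
#'
#' @param trace a [FieldTrace-class]
#' @param path output file
#' @param sweepId,condition,stimIntensity header fields; defaults are taken
#'   from the trace metadata when present
#' @return `path`, invisibly
#' @export
writeFieldTrace <- function(trace, path, sweepId = NULL, condition = NULL,
                            stimIntensity = NULL) {
  md <- trace@metadata
  if (is.null(sweepId)) sweepId <- md$sweep_id %||% "sweep"
  if (is.null(condition)) condition <- md$condition %||% "unknown"
  if (is.null(stimIntensity))
    stimIntensity <- md$stim_intensity_uA %||% NA_real_
  hdr <- c(
    sprintf("# sampling_rate_hz: %s", sprintf(.TRACE_FMT, trace@samplingRate)),
    sprintf("# sweep_t0_s: %s", sprintf(.TRACE_FMT, trace@t0)),
    sprintf("# stim_times_s: %s",
            paste(sprintf(.TRACE_FMT, trace@stimTimes), collapse = ",")),
    sprintf("# stim_intensity_uA: %s", sprintf(.TRACE_FMT, stimIntensity)),
    sprintf("# condition: %s", condition),
    sprintf("# sweep_id: %s", sweepId),
    "time_s\tvoltage_mV")
  tt <- sprintf(.TRACE_FMT, traceTimes(trace))
  vv <- sprintf(.TRACE_FMT, trace@voltage)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(tt, vv, sep = "\t")), con, sep = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sweep from a delimited text file
#'
#' Counterpart of [writeFieldTrace].
#'
#' @param path trace file
#' @return a [FieldTrace-class]; header fields are stored in the metadata
#' @export
readFieldTrace <- function(path) {
  lines <- readLines(path)
  hsel <- grepl("^#", lines)
  hdr <- lines[hsel]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!hsel]
  body <- body[-1]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  voltage <- as.numeric(vapply(parts, `[`, character(1), 2))
  fs <- as.numeric(kv$sampling_rate_hz)
  t0 <- as.numeric(kv$sweep_t0_s)
  stims <- if (nzchar(kv$stim_times_s %||% ""))
    as.numeric(strsplit(kv$stim_times_s, ",", fixed = TRUE)[[1]])
  else numeric(0)
  fieldTrace(voltage, samplingRate = fs, t0 = t0, stimTimes = stims,
             metadata = list(
               sweep_id = kv$sweep_id %||% "sweep",
               condition = kv$condition %||% "unknown",
               stim_intensity_uA = as.numeric(kv$stim_intensity_uA %||% NA)))
}

#' Write a sweep set as trace files plus a manifest
#'
#' One trace file per sweep and a `manifest.yaml` listing, per sweep: file,
#' epoch, start time, intensity, train index and ground-truth scale; scalar
#' ground-truth parameters of the generator are stored under `ground_truth`.
#'
#' @param set a [SweepSet-class]
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
writeSweepSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- set@info
  files <- sprintf("%s.txt", info$sweep_id)
  for (i in seq_along(set@sweeps))
    writeFieldTrace(set@sweeps[[i]], file.path(dir, files[i]),
                    sweepId = info$sweep_id[i], condition = info$epoch[i],
                    stimIntensity = info$intensity_uA[i])
  gt <- set@groundTruth
  gt <- gt[vapply(gt, function(x) is.numeric(x) || is.character(x),
                  logical(1))]
  manifest <- list(
    sweeps = lapply(seq_len(nrow(info)), function(i) list(
      file = files[i], sweep_id = info$sweep_id[i],
      epoch = info$epoch[i], time_s = info$time_s[i],
      intensity_uA = info$intensity_uA[i],
      train_index = if (is.na(info$train_index[i])) NULL
                    else info$train_index[i],
      scale_truth = if (is.na(info$scale_truth[i])) NULL
                    else info$scale_truth[i])),
    ground_truth = gt)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a sweep set written by [writeSweepSet]
#'
#' @param dir directory containing `manifest.yaml` and the trace files
#' @return a [SweepSet-class]
#' @export
readSweepSet <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sw <- manifest$sweeps
  traces <- lapply(sw, function(s) readFieldTrace(file.path(dir, s$file)))
  info <- do.call(rbind, lapply(sw, function(s) data.frame(
    sweep_id = s$sweep_id, epoch = s$epoch, time_s = s$time_s,
    intensity_uA = s$intensity_uA,
    train_index = s$train_index %||% NA_real_,
    scale_truth = s$scale_truth %||% NA_real_,
    stringsAsFactors = FALSE)))
  new("SweepSet", sweeps = traces, info = info,
      groundTruth = manifest$ground_truth %||% list())
}

#' Read/write spine and cell-fluorescence tables
#'
#' Plain CSV with fixed column names: spine tables need `slice_id`,
#' `dendrite_id`, `condition`, `length_um`, `width_um` (`lw_ratio` is
#' recomputed on read); cell tables need `cell_id`, `slice_id`, `cell_type`,
#' `condition`, `roi_mean`, `background`.
#'
#' @param x data.frame to write
#' @param path CSV file
#' @return the data.frame (readers) or `path` invisibly (writers)
#' @name table-io
NULL

#' @rdname table-io
#' @export
readSpineTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_id", "dendrite_id", "condition", "length_um", "width_um")
  if (!all(need %in% names(df)))
    stop("spine table must contain columns: ", paste(need, collapse = ", "))
  if (any(df$length_um <= 0) || any(df$width_um <= 0))
    stop("spine lengths and widths must be > 0")
  df$lw_ratio <- df$length_um / df$width_um
  df
}

#' @rdname table-io
#' @export
writeSpineTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
readCellTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "slice_id", "cell_type", "condition", "roi_mean",
            "background")
  if (!all(need %in% names(df)))
    stop("cell table must contain columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname table-io
#' @export
writeCellTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
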