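#' @include AllClasses.R AllGenerics.R
NULL

#' Configure the synthetic cell-fluorescence generator
#'
#' Emulates the quantification of FISH images: per-cell ROI mean intensities
#' for neurons and astrocytes under stimulation conditions, each the sum of a
#' slice background, a condition x cell-type fold change of the control
#' signal, and per-cell noise. The `background` column of the generated table
#' carries the per-slice background estimate (its mean), while the realized
#' background fluctuates around it with sd `backgroundSd`.
#'
#' @param nCells named vector: cells per cell type and condition
#' @param conditions condition labels (must include `controlCondition`)
#' @param controlCondition unstimulated control label
#' @param foldChange conditions x cell-types matrix of fold changes; control
#'   row must be 1
#' @param backgroundMean,backgroundSd background fluorescence (a.u.)
#' @param controlSignalMean background-corrected control signal (a.u.)
#' @param cellNoiseSd per-cell noise (a.u.)
#' @param nSlices slices per condition
#' @param seed integer RNG seed
#' @return a [FishSimConfig-class]
#' @export
fishSimConfig <- function(nCells = c(astrocyte = 500, neuron = 250),
                          conditions = c("C", "CS", "LTP", "LTP BAY"),
                          controlCondition = "C",
                          foldChange = NULL,
                          backgroundMean = 50, backgroundSd = 0,
                          controlSignalMean = 100, cellNoiseSd = 0,
                          nSlices = 4, seed = 1L) {
  if (is.null(foldChange)) {
    foldChange <- matrix(1, nrow = length(conditions),
                         ncol = length(nCells),
                         dimnames = list(conditions, names(nCells)))
  }
  new("FishSimConfig", nCells = nCells, conditions = conditions,
      controlCondition = controlCondition, foldChange = foldChange,
      backgroundMean = backgroundMean, backgroundSd = backgroundSd,
      controlSignalMean = controlSignalMean, cellNoiseSd = cellNoiseSd,
      nSlices = nSlices, seed = as.integer(seed))
}

#' Simulate a field of cell fluorescence measurements
#'
#' @param config a [FishSimConfig-class]
#' @return data.frame of cell records: `cell_id`, `slice_id`, `cell_type`,
#'   `condition`, `roi_mean`, `background`
#' @export
simulateFishField <- function(config) {
  validObject(config)
  set.seed(config@seed)
  rows <- list()
  for (cond in config@conditions) {
    for (ct in names(config@nCells)) {
      n <- as.integer(config@nCells[[ct]])
      if (n == 0) next
      slice <- rep_len(seq_len(as.integer(config@nSlices)), n)
      bg <- stats::rnorm(n, config@backgroundMean, config@backgroundSd)
      signal <- config@foldChange[cond, ct] * config@controlSignalMean
      roi <- bg + signal + stats::rnorm(n, 0, config@cellNoiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("%s_%s_%04d", gsub(" ", "", cond), ct, seq_len(n)),
        slice_id = sprintf("%s_sl%d", gsub(" ", "", cond), slice),
        cell_type = ct, condition = cond,
        roi_mean = pmax(roi, 0), background = config@backgroundMean,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Background-correct cell fluorescence
#'
#' Subtracts the recorded background from each ROI mean, clipping negative
#' corrected values at 0; the number of clipped cells is reported as an
#' attribute.
#'
#' @param cells cell record data.frame with `roi_mean` and `background`
#' @return the data.frame with a `corrected` column; attribute
#'   `"n_clipped"` counts cells whose corrected value was clipped to 0
#' @export
correctBackground <- function(cells) {
  if (is.null(cells$roi_mean) || is.null(cells$background))
    stop("cells need 'roi_mean' and 'background' columns")
  raw <- cells$roi_mean - cells$background
  cells$corrected <- pmax(raw, 0)
  attr(cells, "n_clipped") <- sum(raw < 0)
  cells
}

#' Percent-of-control expression summary
#'
#' For each cell type, the mean background-corrected fluorescence of the
#' control condition defines 100%; every cell's corrected fluorescence is
#' expressed as a percentage of that mean and summarized per (condition,
#' cell type) as mean +/- SEM over cells (`perCell = TRUE`, the default,
#' where n counts cells) or over slice means (`perCell = FALSE`).
#'
#' @param cells cell record data.frame (a `corrected` column is added with
#'   [correctBackground] if missing)
#' @param controlCondition label of the control condition
#' @param perCell summarize over cells (TRUE) or slice means (FALSE)
#' @return list with `summary` (data.frame: `condition`, `cell_type`,
#'   `percent`, `sem`, `n`), `per_cell` (input with a `percent` column) and
#'   `control_condition`
#' @export
percentOfControl <- function(cells, controlCondition = "C",
                             perCell = TRUE) {
  if (is.null(cells$corrected)) cells <- correctBackground(cells)
  out <- list()
  cells$percent <- NA_real_
  for (ct in unique(cells$cell_type)) {
    sel <- cells$cell_type == ct
    ctrl <- cells$corrected[sel & cells$condition == controlCondition]
    if (!length(ctrl))
      stop(sprintf("no control ('%s') cells for cell type '%s'",
                   controlCondition, ct))
    m <- mean(ctrl)
    if (m <= 0)
      stop(sprintf("control mean for cell type '%s' is not positive", ct))
    cells$percent[sel] <- cells$corrected[sel] / m * 100
  }
  sp <- split(cells, list(cells$condition, cells$cell_type), drop = TRUE)
  summ <- do.call(rbind, lapply(sp, function(g) {
    if (perCell) {
      vals <- g$percent
    } else {
      vals <- as.numeric(tapply(g$percent, g$slice_id, mean))
    }
    data.frame(condition = g$condition[1], cell_type = g$cell_type[1],
               percent = mean(vals), sem = .sem(vals),
               n = length(vals), stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$cell_type, summ$condition), ]
  rownames(summ) <- NULL
  list(summary = summ, per_cell = cells,
       control_condition = controlCondition)
}
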