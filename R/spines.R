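#' @include AllClasses.R AllGenerics.R
NULL

#' Configure the synthetic spine-population generator
#'
#' Lengths and head widths are correlated lognormals, so the length-to-width
#' ratio is itself lognormal with log-mean `lengthLogmean - widthLogmean` and
#' log-variance `lengthLogsd^2 + widthLogsd^2 -
#' 2 * lwCorrelation * lengthLogsd * widthLogsd`. Use
#' [spineConfigForMeanRatio] to place the mean ratio of a condition by the
#' lognormal moment formula.
#'
#' @param nSpines number of spines
#' @param lengthLogmean,lengthLogsd log-µm moments of spine length
#' @param widthLogmean,widthLogsd log-µm moments of head width
#' @param lwCorrelation correlation of log-length and log-width
#' @param dendriteLength µm per dendritic segment
#' @param density spines per µm
#' @param nSlices slices the dendrites are spread over
#' @param conditionLabel condition label for the records
#' @param seed integer RNG seed
#' @return a [SpineSimConfig-class]
#' @export
spineSimConfig <- function(nSpines = 300,
                           lengthLogmean = log(1.3), lengthLogsd = 0.5,
                           widthLogmean = log(0.45), widthLogsd = 0.5,
                           lwCorrelation = 0.103,
                           dendriteLength = 40, density = 1.13,
                           nSlices = 7, conditionLabel = "C",
                           seed = 1L) {
  new("SpineSimConfig", nSpines = nSpines,
      lengthLogmean = lengthLogmean, lengthLogsd = lengthLogsd,
      widthLogmean = widthLogmean, widthLogsd = widthLogsd,
      lwCorrelation = lwCorrelation, dendriteLength = dendriteLength,
      density = density, nSlices = nSlices,
      conditionLabel = conditionLabel, seed = as.integer(seed))
}

#' Place the generator's mean length-to-width ratio
#'
#' Adjusts `lengthLogmean` so that the expected length-to-width ratio equals
#' `meanRatio`: for a lognormal ratio, `E[L/W] = exp(dmu + s2/2)` with
#' `dmu = lengthLogmean - widthLogmean` and `s2` the log-variance of the
#' ratio, so `lengthLogmean = widthLogmean + log(meanRatio) - s2/2`.
#'
#' @param config a [SpineSimConfig-class]
#' @param meanRatio target mean length-to-width ratio
#' @return the config with an adjusted `lengthLogmean`
#' @export
spineConfigForMeanRatio <- function(config, meanRatio) {
  s2 <- config@lengthLogsd^2 + config@widthLogsd^2 -
    2 * config@lwCorrelation * config@lengthLogsd * config@widthLogsd
  config@lengthLogmean <- config@widthLogmean + log(meanRatio) - s2 / 2
  config
}

#' Simulate a spine population
#'
#' Draws `nSpines` correlated lognormal (length, width) pairs and distributes
#' them over dendritic segments sized so that the configured linear density
#' is reproduced on average; dendrites are assigned round-robin to slices.
#'
#' @param config a [SpineSimConfig-class]
#' @return data.frame of spine records: `slice_id`, `dendrite_id`,
#'   `condition`, `length_um`, `width_um`, `lw_ratio`
#' @export
simulateSpines <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- as.integer(config@nSpines)
  if (n == 0)
    return(data.frame(slice_id = character(0), dendrite_id = character(0),
                      condition = character(0), length_um = numeric(0),
                      width_um = numeric(0), lw_ratio = numeric(0)))
  z1 <- stats::rnorm(n)
  z2 <- config@lwCorrelation * z1 +
    sqrt(1 - config@lwCorrelation^2) * stats::rnorm(n)
  len <- exp(config@lengthLogmean + config@lengthLogsd * z1)
  wid <- exp(config@widthLogmean + config@widthLogsd * z2)
  nDend <- max(1L, as.integer(round(n / (config@density *
                                           config@dendriteLength))))
  dend <- sample.int(nDend, n, replace = TRUE)
  slice <- ((dend - 1L) %% as.integer(config@nSlices)) + 1L
  data.frame(
    slice_id = sprintf("slice%02d", slice),
    dendrite_id = sprintf("dend%03d", dend),
    condition = config@conditionLabel,
    length_um = len, width_um = wid, lw_ratio = len / wid,
    stringsAsFactors = FALSE)
}

#' Group summary of the spine shape parameter
#'
#' Mean and SEM of the length-to-width ratio for one condition. With
#' `perSlice = TRUE` (default, matching the convention that n counts slices)
#' the ratio is first averaged within each slice and the group mean and SEM
#' are taken across slice means; with `perSlice = FALSE` spines are pooled.
#'
#' @param records spine record data.frame (needs `slice_id`, `lw_ratio`, and
#'   optionally `condition`)
#' @param perSlice average within slices first?
#' @return data.frame: `condition`, `n_slices`, `n_spines`, `mean_lw`,
#'   `sem_lw`, `sem_flag` (TRUE when the SEM is undefined, i.e. one unit)
#' @export
summarizeSpines <- function(records, perSlice = TRUE) {
  if (!nrow(records)) stop("empty spine group")
  if (is.null(records$condition)) records$condition <- "all"
  sp <- split(records, records$condition)
  out <- lapply(sp, function(g) {
    if (perSlice) {
      m <- tapply(g$lw_ratio, g$slice_id, mean)
      m <- m[!is.na(m)]
    } else m <- g$lw_ratio
    data.frame(condition = g$condition[1],
               n_slices = length(unique(g$slice_id)),
               n_spines = nrow(g),
               mean_lw = mean(m),
               sem_lw = .sem(m),
               sem_flag = length(m) < 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Binned subpopulation comparison of two spine groups
#'
#' Bins the length-to-width ratios of both groups on shared edges (default
#' 0.5-wide bins on [0, 6) plus an overflow bin), returns the per-bin
#' relative frequencies and compares the groups per bin with a two-proportion
#' z-test, Holm-Sidak corrected across the tested bins. Bins with fewer than
#' `minCount` pooled spines are not tested (their p-values are NA).
#'
#' @param groupA,groupB numeric vectors of length-to-width ratios
#' @param binEdges increasing break points; values beyond the last edge go to
#'   an overflow bin
#' @param alpha family-wise significance level for the `significant` flag
#' @param minCount minimal pooled count for a bin to be tested
#' @return data.frame: `bin_lo`, `bin_hi`, `prop_a`, `prop_b`, `count_a`,
#'   `count_b`, `p`, `p_adj`, `significant`
#' @export
binDistribution <- function(groupA, groupB, binEdges = seq(0, 6, by = 0.5),
                            alpha = 0.05, minCount = 5) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  if (length(binEdges) < 2 || is.unsorted(binEdges, strictly = TRUE))
    stop("degenerate bin edges")
  edges <- c(binEdges, Inf)
  ca <- as.vector(table(cut(groupA, edges, right = FALSE)))
  cb <- as.vector(table(cut(groupB, edges, right = FALSE)))
  na <- length(groupA); nb <- length(groupB)
  pa <- ca / na; pb <- cb / nb
  pool <- (ca + cb) / (na + nb)
  se <- sqrt(pool * (1 - pool) * (1 / na + 1 / nb))
  z <- (pa - pb) / se
  p <- 2 * stats::pnorm(-abs(z))
  p[ca + cb < minCount | se == 0] <- NA_real_
  padj <- rep(NA_real_, length(p))
  tested <- which(!is.na(p))
  if (length(tested)) padj[tested] <- holmSidak(p[tested])
  data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    prop_a = pa, prop_b = pb, count_a = ca, count_b = cb,
    p = p, p_adj = padj,
    significant = !is.na(padj) & padj <= alpha)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The statistic D is the maximal vertical distance between the empirical
#' cumulative distributions of the two samples; the two-sided p-value uses
#' the asymptotic Kolmogorov distribution with the usual small-sample
#' effective-size correction.
#'
#' @param groupA,groupB numeric vectors (each of size >= 1)
#' @return list with `D`, `p`, `n_a`, `n_b`
#' @export
ksCompare <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  na <- length(groupA); nb <- length(groupB)
  pts <- sort(unique(c(groupA, groupB)))
  fa <- vapply(pts, function(x) sum(groupA <= x), numeric(1)) / na
  fb <- vapply(pts, function(x) sum(groupB <= x), numeric(1)) / nb
  D <- max(abs(fa - fb))
  neff <- na * nb / (na + nb)
  lambda <- (sqrt(neff) + 0.12 + 0.11 / sqrt(neff)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(max(p, 0), 1), n_a = na, n_b = nb)
}

#' Spine density per dendrite and group
#'
#' @param counts spines per dendrite
#' @param lengths µm per dendrite (all > 0)
#' @return list: `per_dendrite` (per-µm densities), `mean`, `sem`
#' @export
spineDensity <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("counts and lengths must be paired")
  if (any(lengths <= 0)) stop("dendrite lengths must be > 0")
  d <- counts / lengths
  list(per_dendrite = d, mean = mean(d), sem = .sem(d))
}
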