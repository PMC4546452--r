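#' @include AllClasses.R
NULL

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak procedure: order the m p-values ascending, adjust the i-th
#' as `1 - (1 - p_i)^(m - i + 1)`, enforce monotonicity with a running
#' maximum, and restore the input order. Adjusted values are never smaller
#' than the raw ones and are monotone in them.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values in the input order
#' @export
holmSidak <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Significance stars
#'
#' `*` for p <= 0.05, `**` for p <= 0.01, `***` for p <= 0.005.
#'
#' @param p numeric vector of p-values
#' @return character vector of star codes
#' @export
significanceStars <- function(p) {
  vapply(p, function(x) {
    if (!is.finite(x)) return("")
    if (x <= 0.005) return("***")
    if (x <= 0.01) return("**")
    if (x <= 0.05) return("*")
    ""
  }, character(1))
}

#' Group comparisons: t-test, one-way and two-way ANOVA
#'
#' `design = "ttest"` runs an unpaired two-sample t-test (equal variances);
#' `"anova_oneway"` a one-way ANOVA with Holm-Sidak-adjusted pairwise
#' post-hoc t-tests; `"anova_twoway"` a two-way ANOVA (`value ~ group *
#' level`, e.g. treatment group x stimulus intensity for input-output
#' comparisons) whose reported statistic is the group main effect.
#'
#' @param values numeric response vector
#' @param group factor-like group labels
#' @param design one of `"ttest"`, `"anova_oneway"`, `"anova_twoway"`
#' @param level second factor for the two-way design
#' @return list: `test`, `statistic`, `df`, `p`, `n` (per-group counts),
#'   `direction` (sign of first-vs-last group mean difference), and for
#'   ANOVAs `posthoc` (data.frame with raw and Holm-Sidak-adjusted pairwise
#'   p-values), plus `table` (the full ANOVA table) for the two-way design
#' @export
compareGroups <- function(values, group,
                          design = c("ttest", "anova_oneway",
                                     "anova_twoway"),
                          level = NULL) {
  design <- match.arg(design)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2))
    stop("each group needs n >= 2")
  ns <- as.vector(table(group))
  names(ns) <- levels(group)
  gm <- tapply(values, group, mean)
  direction <- sign(gm[1] - gm[length(gm)])
  if (design == "ttest") {
    if (nlevels(group) != 2) stop("ttest design needs exactly 2 groups")
    sds <- tapply(values, group, stats::sd)
    if (all(sds == 0)) {
      if (gm[1] == gm[2])
        return(list(test = "ttest", statistic = 0,
                    df = length(values) - 2, p = 1, n = ns, direction = 0))
      stop("zero within-group variance: t-test undefined")
    }
    tt <- stats::t.test(values ~ group, var.equal = TRUE)
    return(list(test = "ttest", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value, n = ns,
                direction = unname(direction)))
  }
  if (design == "anova_oneway") {
    fit <- stats::aov(values ~ group)
    tab <- summary(fit)[[1]]
    lev <- levels(group)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    praw <- vapply(pairs, function(pr) {
      sel <- group %in% pr
      stats::t.test(values[sel] ~ droplevels(group[sel]),
                    var.equal = TRUE)$p.value
    }, numeric(1))
    posthoc <- data.frame(
      comparison = vapply(pairs, paste, character(1), collapse = " vs "),
      p = praw, p_adj = holmSidak(praw), stringsAsFactors = FALSE)
    return(list(test = "anova_oneway",
                statistic = tab[1, "F value"],
                df = c(tab[1, "Df"], tab[2, "Df"]),
                p = tab[1, "Pr(>F)"], n = ns,
                direction = unname(direction), posthoc = posthoc))
  }
  ## two-way: group x level
  if (is.null(level)) stop("anova_twoway needs a 'level' factor")
  level <- factor(level)
  if (any(table(group, level) < 1))
    stop("anova_twoway needs a complete group x level layout")
  fit <- stats::aov(values ~ group * level)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  ig <- which(rn == "group")
  ir <- which(rn == "Residuals")
  list(test = "anova_twoway",
       statistic = tab[ig, "F value"],
       df = c(tab[ig, "Df"], tab[ir, "Df"]),
       p = tab[ig, "Pr(>F)"], n = ns,
       direction = unname(direction),
       table = tab)
}

.fmtNum <- function(x, digits = 4) {
  ifelse(is.finite(x), trimws(formatC(x, digits = digits, format = "g")), "NA")
}

#' Deterministic text report of analysis outputs
#'
#' Renders means +/- SEM tables and comparison summaries for whichever
#' analyses are supplied; identical inputs yield byte-identical output.
#' Sections: `timecourse` (from [normalizeTimecourse]), `ppf` (from
#' [computePPF]), `trains` (from [analyzeHfsTrains]), `io` (from
#' [buildIOCurve]), `spines` (from [summarizeSpines]), `spine_bins` (from
#' [binDistribution]), `ks` (from [ksCompare]), `fish` (from
#' [percentOfControl]), `comparisons` (list of [compareGroups] results,
#' named). Empty/absent sections are omitted.
#'
#' @param sections named list of analysis outputs (see Details)
#' @param file optional path; when given, the lines are also written there
#' @return character vector of report lines (invisibly when `file` is given)
#' @export
reportTables <- function(sections, file = NULL) {
  if (!length(sections)) stop("at least one analysis output is required")
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  if (!is.null(sections$timecourse)) {
    tc <- sections$timecourse
    add("== LTP time course (%% of baseline) ==")
    add("PTP: %s%%", .fmtNum(tc$ptp_percent))
    for (nm in names(tc$plateau_percent))
      add("plateau at %s min: %s%%", nm, .fmtNum(tc$plateau_percent[[nm]]))
    add("baseline slope: %s mV/ms (n = %d sweeps)",
        .fmtNum(tc$baseline_slope), tc$n_baseline)
  }
  if (!is.null(sections$ppf)) {
    p <- sections$ppf
    add("== Paired-pulse facilitation ==")
    add("PPF index (slope2/slope1): %s at ISI %s ms",
        .fmtNum(p$ppf_index), .fmtNum(p$isi_ms))
  }
  if (!is.null(sections$trains)) {
    tr <- sections$trains
    add("== HFS trains ==")
    for (i in seq_len(nrow(tr$per_train)))
      add("train %d: envelope %s mV*ms, AFP %s mV (relative %s)",
          tr$per_train$train[i], .fmtNum(tr$per_train$envelope_mVms[i]),
          .fmtNum(tr$per_train$afp_mV[i]),
          .fmtNum(tr$per_train$relative_afp[i]))
    add("summed envelope: %s mV*ms", .fmtNum(tr$summed_envelope_mVms))
  }
  if (!is.null(sections$io)) {
    io <- sections$io
    add("== Input-output curve ==")
    for (i in seq_len(nrow(io)))
      add("%s uA: slope %s +/- %s mV/ms, FV %s mV [n = %d]",
          .fmtNum(io$intensity_uA[i]), .fmtNum(io$slope_mV_per_ms[i]),
          .fmtNum(io$slope_sem[i]), .fmtNum(io$fv_mV[i]), io$n[i])
  }
  if (!is.null(sections$spines)) {
    sg <- sections$spines
    add("== Spine length-to-width ratio ==")
    for (i in seq_len(nrow(sg)))
      add("%s: %s +/- %s (n = %d slices, %d spines)",
          sg$condition[i], .fmtNum(sg$mean_lw[i]), .fmtNum(sg$sem_lw[i]),
          sg$n_slices[i], sg$n_spines[i])
  }
  if (!is.null(sections$spine_bins)) {
    b <- sections$spine_bins
    add("== Spine shape subpopulations ==")
    for (i in seq_len(nrow(b)))
      add("[%s, %s): %s vs %s %s", .fmtNum(b$bin_lo[i]),
          .fmtNum(b$bin_hi[i]), .fmtNum(b$prop_a[i]), .fmtNum(b$prop_b[i]),
          ifelse(isTRUE(b$significant[i]), "(*)", ""))
  }
  if (!is.null(sections$ks)) {
    k <- sections$ks
    add("== Kolmogorov-Smirnov ==")
    add("D = %s, p = %s (n = %d vs %d)", .fmtNum(k$D), .fmtNum(k$p),
        k$n_a, k$n_b)
  }
  if (!is.null(sections$fish)) {
    f <- sections$fish
    add("== Expression, %% of control ('%s') ==", f$control_condition)
    s <- f$summary
    for (i in seq_len(nrow(s)))
      add("%s / %s: %s%% +/- %s (n = %d)", s$cell_type[i], s$condition[i],
          .fmtNum(s$percent[i]), .fmtNum(s$sem[i]), s$n[i])
  }
  if (!is.null(sections$comparisons)) {
    add("== Statistical comparisons ==")
    cmp <- sections$comparisons
    for (nm in sort(names(cmp))) {
      r <- cmp[[nm]]
      add("%s: %s statistic = %s, df = %s, p = %s %s", nm, r$test,
          .fmtNum(r$statistic), paste(.fmtNum(r$df), collapse = ","),
          .fmtNum(r$p), significanceStars(r$p))
    }
  }
  if (!is.null(file)) {
    writeLines(ln, file)
    return(invisible(ln))
  }
  ln
}
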