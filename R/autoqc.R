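#' Automated QC flagging and cutoff calibration
#'
#' Metric values are z-scored against a reference population, compared to
#' per-metric cutoff ranges (one- or two-sided), and counted: a scan is
#' flagged bad when at least `bad_threshold` metrics (default 3) are out of
#' range. Cutoffs are calibrated against expert labels by sweeping z-score
#' cutoffs from -5 to 5 in steps of 0.05 and choosing the value maximising
#' (sensitivity + specificity) / 2 under stratified threefold
#' cross-validation.
#'
#' @name autoqc
NULL

#' Reference distribution for one metric
#'
#' @param mean,sd reference population mean and SD (SD > 0).
#' @param directionality `"lower_is_worse"`, `"higher_is_worse"` or
#'   `"two_sided"`.
#' @param metric,profile identifying keys.
#' @return object of class `qc_reference`.
#' @export
metric_reference <- function(mean, sd, directionality = c("lower_is_worse",
                                                          "higher_is_worse",
                                                          "two_sided"),
                             metric = NA_character_,
                             profile = NA_character_) {
  directionality <- match.arg(directionality)
  if (!is.finite(sd) || sd <= 0) stop("reference SD must be positive")
  structure(list(mean = mean, sd = sd, directionality = directionality,
                 metric = metric, profile = profile),
            class = "qc_reference")
}

#' Cutoff range for one metric
#'
#' @param lower,upper interval bounds (either may be `NA` for one-sided
#'   ranges; at least one must be present and lower < upper when both are).
#' @param scale `"z"` (bounds are z-scores, the default) or `"raw"`.
#' @return object of class `qc_cutoff`.
#' @export
cutoff_range <- function(lower = NA_real_, upper = NA_real_,
                         scale = c("z", "raw")) {
  scale <- match.arg(scale)
  if (is.na(lower) && is.na(upper))
    stop("cutoff range needs at least one bound")
  if (!is.na(lower) && !is.na(upper) && lower >= upper)
    stop("cutoff lower bound must be below the upper bound")
  structure(list(lower = lower, upper = upper, scale = scale),
            class = "qc_cutoff")
}

#' Z-score a metric value against its reference
#'
#' @param value observed metric value.
#' @param reference a [metric_reference()].
#' @return `(value - mean) / sd`.
#' @export
zscore <- function(value, reference) {
  (value - reference$mean) / reference$sd
}

#' Flag one metric as good or bad
#'
#' Bad iff the value falls outside the closed interval `[lower, upper]`
#' (one-sided when only one bound is present); boundary values are good.
#' `NA` values are flagged `"unavailable"` and never counted as bad.
#'
#' @param value observed metric value (raw scale).
#' @param cutoff a [cutoff_range()].
#' @param reference a [metric_reference()]; required for z-scale cutoffs.
#' @return `"good"`, `"bad"` or `"unavailable"`.
#' @export
flag_metric <- function(value, cutoff, reference = NULL) {
  if (is.na(value)) return("unavailable")
  x <- value
  if (cutoff$scale == "z") {
    if (is.null(reference))
      stop("z-scale cutoffs need a metric reference")
    x <- zscore(value, reference)
  }
  bad <- (!is.na(cutoff$lower) && x < cutoff$lower) ||
         (!is.na(cutoff$upper) && x > cutoff$upper)
  if (bad) "bad" else "good"
}

#' Scan-level verdict from per-metric flags
#'
#' The scan is bad when the number of bad metrics reaches
#' `bad_threshold` (n_bad >= threshold; set `strict = TRUE` for the
#' strictly-greater reading). Unavailable metrics are never counted.
#'
#' @param flags character vector of `"good"`/`"bad"`/`"unavailable"`,
#'   usually named by metric.
#' @param bad_threshold count of bad metrics that makes the scan bad
#'   (default 3).
#' @param strict require strictly more than `bad_threshold` bad metrics.
#' @return object of class `qc_decision`: `verdict` (good/bad/
#'   undetermined), `n_bad`, `flags`, `threshold`, `rationale`.
#' @export
decide_case <- function(flags, bad_threshold = 3L, strict = FALSE) {
  flags <- unlist(flags)
  if (!length(flags) || all(flags == "unavailable")) {
    return(structure(list(verdict = "undetermined", n_bad = 0L,
                          flags = flags, threshold = bad_threshold,
                          rationale = "all metrics unavailable"),
                     class = "qc_decision"))
  }
  bad <- names(flags)[flags == "bad"]
  if (is.null(bad)) bad <- character(sum(flags == "bad"))
  n_bad <- sum(flags == "bad")
  is_bad <- if (strict) n_bad > bad_threshold else n_bad >= bad_threshold
  structure(list(
    verdict = if (is_bad) "bad" else "good",
    n_bad = n_bad, flags = flags, threshold = bad_threshold,
    rationale = if (n_bad)
      paste0("bad metrics: ", paste(bad, collapse = ", "))
    else "no metrics out of range"),
    class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  cat("<qc_decision> verdict:", x$verdict, "(", x$n_bad,
      "bad, threshold", x$threshold, ")\n")
  invisible(x)
}

# sensitivity/specificity of a one- or two-sided z cutoff
sweep_confusion <- function(z, labels_bad, cutoff, directionality) {
  pred_bad <- switch(directionality,
                     lower_is_worse = z < cutoff,
                     higher_is_worse = z > cutoff,
                     two_sided = abs(z) > cutoff)
  sens <- if (any(labels_bad)) mean(pred_bad[labels_bad]) else NA_real_
  spec <- if (any(!labels_bad)) mean(!pred_bad[!labels_bad]) else NA_real_
  c(sens = sens, spec = spec)
}

# stratified fold ids (1..k) with a locally seeded shuffle
stratified_folds <- function(labels_bad, k, seed) {
  fold <- integer(length(labels_bad))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels_bad == cls)
      if (length(idx))
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Calibrate a per-metric cutoff by cross-validated ROC search
#'
#' Values are z-standardised against the pooled sample; one-sided (or
#' two-sided) cutoffs are swept from z = -5 to z = 5 in steps of 0.05 in
#' the metric's bad direction. Under stratified threefold cross-validation
#' the cutoff maximising (sensitivity + specificity) / 2 on the training
#' folds is applied to the held-out fold; ties are broken toward the less
#' aggressive cutoff (fewer bad calls). The AUC is the trapezoidal area
#' under the full-sample ROC traced by the sweep.
#'
#' @param values numeric metric values, one per scan.
#' @param labels logical (`TRUE` = bad) or character (`"bad"`/`"good"`).
#' @param directionality sweep direction; see [metric_reference()].
#' @param n_folds folds (default 3).
#' @param z_grid sweep grid (default `seq(-5, 5, 0.05)`; two-sided sweeps
#'   use its non-negative part).
#' @param seed fold-assignment seed.
#' @return object of class `qc_roc`: `auc`, `cutoff_z`, `cutoff_raw`,
#'   `sensitivity`, `specificity`, `accuracy` (cross-validated means),
#'   `folds`, `sweep` (full-sample sens/spec per grid point), `reference`
#'   (pooled mean/sd used for z-scoring).
#' @export
calibrate_cutoffs <- function(values, labels,
                              directionality = c("lower_is_worse",
                                                 "higher_is_worse",
                                                 "two_sided"),
                              n_folds = 3L, z_grid = seq(-5, 5, by = 0.05),
                              seed = 42L) {
  directionality <- match.arg(directionality)
  if (is.character(labels)) labels <- labels == "bad"
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to calibrate a cutoff")
  if (length(values) < 30L)
    warning("calibrating on fewer than 30 scans is unreliable")
  mu <- mean(values); sigma <- stats::sd(values)
  if (!is.finite(sigma) || sigma == 0)
    stop("constant metric values; cutoff undefined")
  z <- (values - mu) / sigma
  grid <- if (directionality == "two_sided") z_grid[z_grid >= 0] else z_grid
  # full-sample sweep (for AUC and reporting)
  sweep_tab <- t(vapply(grid, function(cu)
    sweep_confusion(z, labels, cu, directionality), numeric(2)))
  fpr <- 1 - sweep_tab[, "spec"]
  tpr <- sweep_tab[, "sens"]
  o <- order(fpr, tpr)
  fx <- c(0, fpr[o], 1); fy <- c(0, tpr[o], 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  # tie-break: the less aggressive cutoff makes fewer bad calls
  pick <- function(obj) {
    best <- which(obj == max(obj, na.rm = TRUE))
    if (directionality == "lower_is_worse") best[1]       # smallest cutoff
    else best[length(best)]                                # largest cutoff
  }
  folds <- stratified_folds(labels, n_folds, seed)
  perf <- matrix(NA_real_, n_folds, 3,
                 dimnames = list(NULL, c("sens", "spec", "cutoff")))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    obj <- vapply(grid, function(cu) {
      cs <- sweep_confusion(z[tr], labels[tr], cu, directionality)
      (cs["sens"] + cs["spec"]) / 2
    }, numeric(1))
    cu <- grid[pick(obj)]
    cs <- sweep_confusion(z[!tr], labels[!tr], cu, directionality)
    perf[f, ] <- c(cs["sens"], cs["spec"], cu)
  }
  obj_full <- (sweep_tab[, "sens"] + sweep_tab[, "spec"]) / 2
  best_z <- grid[pick(obj_full)]
  structure(list(
    auc = auc,
    cutoff_z = best_z,
    cutoff_raw = mu + best_z * sigma,
    sensitivity = mean(perf[, "sens"], na.rm = TRUE),
    specificity = mean(perf[, "spec"], na.rm = TRUE),
    accuracy = mean((perf[, "sens"] + perf[, "spec"]) / 2, na.rm = TRUE),
    folds = folds, fold_cutoffs = perf[, "cutoff"],
    sweep = data.frame(cutoff = grid, sens = sweep_tab[, "sens"],
                       spec = sweep_tab[, "spec"]),
    directionality = directionality,
    reference = c(mean = mu, sd = sigma)),
    class = "qc_roc")
}

#' @export
print.qc_roc <- function(x, ...) {
  cat(sprintf(
    "<qc_roc> AUC %.3f, cutoff z = %.2f, CV sens %.2f / spec %.2f\n",
    x$auc, x$cutoff_z, x$sensitivity, x$specificity))
  invisible(x)
}

#' Area-normalised histogram density
#'
#' Histogram on a shared bin grid whose heights are divided by the total
#' area, giving an empirical probability density (integrates to 1).
#'
#' @param values numeric sample (non-empty).
#' @param n_bins bin count.
#' @param shared_range length-2 range covered by the bins; values outside
#'   are clamped into the end bins so densities stay comparable.
#' @return object of class `qc_histogram_density`: `breaks`, `density`.
#' @export
histogram_density <- function(values, n_bins, shared_range) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty input")
  if (length(shared_range) != 2L || shared_range[1] >= shared_range[2])
    stop("`shared_range` must be an increasing length-2 range")
  breaks <- seq(shared_range[1], shared_range[2], length.out = n_bins + 1L)
  values <- pmin(pmax(values, shared_range[1]), shared_range[2])
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     n_bins)
  bw <- diff(breaks)[1]
  structure(list(breaks = breaks,
                 density = counts / (sum(counts) * bw)),
            class = "qc_histogram_density")
}

#' Dice overlap between two histogram densities
#'
#' `sum_i min(h1_i, h2_i) * binwidth`; for unit-area densities this equals
#' the familiar `2|A^B| / (|A| + |B|)` overlap and lies in [0, 1] — 1 iff
#' the histograms are identical on the shared grid.
#'
#' @param h1,h2 [histogram_density()] objects on identical bin grids.
#' @return scalar in [0, 1].
#' @export
dice_overlap <- function(h1, h2) {
  if (!isTRUE(all.equal(h1$breaks, h2$breaks)))
    stop("histograms are not on the same bin grid")
  bw <- diff(h1$breaks)[1]
  sum(pmin(h1$density, h2$density)) * bw
}

#' Pearson correlation matrix across metrics
#'
#' @param values data.frame or matrix, one column per metric, one row per
#'   scan; pairwise-complete observations.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
metric_correlation_matrix <- function(values) {
  m <- stats::cor(as.matrix(values), use = "pairwise.complete.obs")
  diag(m) <- 1
  m
}

#' Study-level summary of QC results
#'
#' @param metrics data.frame with one row per scan: metric columns plus an
#'   optional `verdict` column and grouping columns.
#' @param group_by character vector of grouping column names (empty for a
#'   single overall group).
#' @return data.frame, one row per group: `n`, per-metric mean/SD columns,
#'   and verdict counts when a `verdict` column is present.
#' @export
study_summary <- function(metrics, group_by = character(0)) {
  stopifnot(is.data.frame(metrics))
  metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                               logical(1))], group_by)
  key <- if (length(group_by))
    interaction(metrics[group_by], drop = TRUE, sep = "|")
  else factor(rep("all", nrow(metrics)))
  rows <- lapply(levels(key), function(g) {
    sub <- metrics[key == g, , drop = FALSE]
    out <- data.frame(group = g, n = nrow(sub))
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- mean(sub[[mc]], na.rm = TRUE)
      out[[paste0(mc, "_sd")]] <- stats::sd(sub[[mc]], na.rm = TRUE)
    }
    if ("verdict" %in% names(sub)) {
      out$n_good <- sum(sub$verdict == "good")
      out$n_bad <- sum(sub$verdict == "bad")
    }
    out
  })
  do.call(rbind, rows)
}
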