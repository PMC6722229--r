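#' QC reports: canonical JSON schema and CSV export
#'
#' A report carries one scan's identity, its scalar metric block (value +
#' availability flag + directionality per metric), named vector blocks,
#' the scan-level verdict and provenance. JSON is the canonical format;
#' CSV export writes a scalar table plus one tidy table per vector.
#'
#' @name cli_reporting
NULL

QC_SCHEMA_VERSION <- 1L

#' Assemble a QC report
#'
#' @param scan_id scan identifier (usually the input filename).
#' @param profile modality/profile string (t1, t2, flair, ct, phantom,
#'   fmri, dti).
#' @param metrics named list; each element a list with `value`, `flag`,
#'   `directionality`.
#' @param vectors named list of numeric vectors or data.frames.
#' @param verdict a `qc_decision`, or the string `"undetermined"` when no
#'   cutoffs were applied.
#' @param seed seed used by any stochastic step.
#' @param timestamp ISO timestamp; defaults to now. Excluded from
#'   determinism comparisons.
#' @return object of class `qc_report`.
#' @export
qc_report <- function(scan_id, profile, metrics, vectors = list(),
                      verdict = "undetermined", seed = NA_integer_,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  rep <- structure(list(
    schema_version = QC_SCHEMA_VERSION,
    scan_id = scan_id, profile = profile,
    metrics = metrics, vectors = vectors,
    verdict = if (inherits(verdict, "qc_decision"))
      list(verdict = verdict$verdict, n_bad = verdict$n_bad,
           threshold = verdict$threshold,
           flags = as.list(verdict$flags),
           rationale = verdict$rationale)
    else list(verdict = verdict),
    provenance = list(tool = "scanqc",
                      version = as.character(
                        utils::packageVersion("scanqc")),
                      seed = seed, timestamp = timestamp)),
    class = "qc_report")
  validate_report(rep)
  rep
}

#' Validate a QC report against the schema
#'
#' @param report a `qc_report` (or plain list from JSON).
#' @return the report, invisibly; errors on schema violations.
#' @export
validate_report <- function(report) {
  required <- c("schema_version", "scan_id", "profile", "metrics",
                "verdict", "provenance")
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop("invalid QC report: missing block(s) ",
         paste(missing, collapse = ", "))
  for (nm in names(report$metrics)) {
    m <- report$metrics[[nm]]
    if (!all(c("value", "flag") %in% names(m)))
      stop("invalid metric entry '", nm, "': needs value and flag")
  }
  if (anyDuplicated(names(report$metrics)))
    stop("invalid QC report: duplicated metric names")
  invisible(report)
}

#' Write a QC report
#'
#' @param report a `qc_report`.
#' @param path output path. For `format = "csv"` this is a prefix:
#'   `<path>_scalars.csv` plus `<path>_<vector>.csv` tidy tables.
#' @param format `"json"` (canonical) or `"csv"`.
#' @return the written file path(s), invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  validate_report(report)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null",
                         pretty = TRUE)
    return(invisible(path))
  }
  prefix <- sub("\\.csv$", "", path)
  scal <- do.call(rbind, lapply(names(report$metrics), function(nm) {
    m <- report$metrics[[nm]]
    data.frame(metric = nm,
               value = if (is.null(m$value) || is.na(m$value)) NA_real_
                       else as.numeric(m$value),
               flag = m$flag,
               directionality = m$directionality %||% NA_character_)
  }))
  files <- paste0(prefix, "_scalars.csv")
  utils::write.csv(scal, files, row.names = FALSE)
  for (nm in names(report$vectors)) {
    v <- report$vectors[[nm]]
    tab <- if (is.data.frame(v)) v
           else data.frame(index = seq_along(v), value = as.numeric(v))
    f <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a QC report back from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return a `qc_report`.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  validate_report(rep)
  class(rep) <- "qc_report"
  rep
}

metric_entry <- function(value, flag, directionality = NULL) {
  list(value = if (is.null(value) || !is.finite(value)) NA else value,
       flag = flag, directionality = directionality)
}

# structural metrics object -> report
structural_to_report <- function(sm, scan_id, seed = NA_integer_) {
  metrics <- list()
  for (nm in names(sm$scalars))
    metrics[[nm]] <- metric_entry(sm$scalars[[nm]], sm$flags[[nm]],
                                  sm$directionality[[nm]])
  if (!is.null(sm$fwhm)) {
    metrics$fwhm <- metric_entry(sm$fwhm$magnitude, sm$flags[["fwhm"]],
                                 sm$directionality[["fwhm"]])
    metrics$resolvable_elements <-
      metric_entry(sm$fwhm$resolvable_elements, sm$flags[["fwhm"]], NULL)
  } else {
    metrics$fwhm <- metric_entry(NA, "undefined", "higher_is_worse")
  }
  metrics$com <- metric_entry(sm$com$magnitude, sm$flags[["com"]],
                              sm$directionality[["com"]])
  vectors <- list(msi = sm$msi)
  if (!is.null(sm$odd_even_difference))
    metrics$odd_even_difference <-
      metric_entry(sm$odd_even_difference, "ok", NULL)
  if (!is.null(sm$fwhm))
    vectors$fwhm_per_axis <- as.numeric(sm$fwhm$fwhm)
  vectors$com_offset <- as.numeric(sm$com$offset_mm)
  qc_report(scan_id, sm$profile, metrics, vectors, seed = seed)
}

functional_to_report <- function(fm, scan_id, seed = NA_integer_) {
  metrics <- list()
  for (nm in names(fm$scalars)) {
    val <- fm$scalars[[nm]]
    metrics[[nm]] <- metric_entry(val,
                                  if (is.finite(val)) "ok" else "undefined",
                                  fm$directionality[[nm]])
  }
  if (!is.null(fm$sfnr))
    metrics$median_sfnr <- metric_entry(fm$sfnr$median_sfnr, "ok",
                                        "lower_is_worse")
  vectors <- list(dvars = fm$dvars$dvars, velocity = fm$velocity)
  if (!is.null(fm$fd)) vectors$fd <- fm$fd$fd
  if (!is.null(fm$outliers)) vectors$outlier_fraction <- fm$outliers$fraction
  if (!is.null(fm$spectrum)) {
    metrics$spectrum_mean <- metric_entry(fm$spectrum$spectrum_mean,
                                          "ok", NULL)
    metrics$spectrum_max <- metric_entry(fm$spectrum$spectrum_max,
                                         "ok", NULL)
  }
  if (!is.null(fm$per_frame)) {
    vectors$volume_mean <- fm$per_frame$volume_mean
    vectors$slice_variation <- fm$per_frame$slice_variation
  }
  qc_report(scan_id, "fmri", metrics, vectors, seed = seed)
}

diffusion_to_report <- function(dm, scan_id, seed = NA_integer_) {
  pg <- dm$per_gradient
  metrics <- list(
    mean_gradient_snr = metric_entry(mean(pg$snr, na.rm = TRUE), "ok",
                                     "lower_is_worse"),
    max_com_displacement = metric_entry(
      max(abs(pg$com_displacement), na.rm = TRUE), "ok",
      "higher_is_worse"))
  vectors <- list(msi = pg$msi, snr = pg$snr,
                  com_displacement = as.data.frame(pg$com_displacement))
  qc_report(scan_id, "dti", metrics, vectors, seed = seed)
}
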