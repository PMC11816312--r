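# Delimited-text readers and writers. Every writer has a matching reader
# and writing is canonical (fixed number formatting, tab separation, LF line
# endings), so write -> read -> write is byte-stable.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, "")
  out
}

write_table_c14n <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) fmt_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

read_table_c14n <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  comments <- sub("^# ?", "", lines[!keep])
  df <- utils::read.table(text = paste(lines[keep], collapse = "\n"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  attr(df, "comments") <- comments
  df
}

parse_kv_comments <- function(comments) {
  kv <- strsplit(comments[grepl("=", comments, fixed = TRUE)], "=", fixed = TRUE)
  stats::setNames(
    vapply(kv, function(p) trimws(paste(p[-1], collapse = "=")), ""),
    vapply(kv, function(p) trimws(p[1]), ""))
}

#' Read and write exposure-event tables
#'
#' Tab-separated text with columns `route`, `magnitude`, `unit`,
#' `t_start_days`, `t_end_days`; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_exposure_events()` returns an `exposure_events` table.
#' @export
read_exposure_events <- function(path) {
  df <- read_table_c14n(path)
  req <- c("route", "magnitude", "unit", "t_start_days", "t_end_days")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("events file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    if (!df$route[i] %in% ROUTES || !is.finite(df$magnitude[i]) ||
        df$magnitude[i] < 0 || df$t_end_days[i] < df$t_start_days[i]) {
      stop("malformed event in ", path, " at data row ", i)
    }
  }
  exposure_events(df$route, df$magnitude, df$t_start_days, df$t_end_days,
                  unit = df$unit)
}

#' @rdname read_exposure_events
#' @param events An `exposure_events` table.
#' @export
write_exposure_events <- function(events, path) {
  events <- as_exposure_events(events)
  write_table_c14n(as.data.frame(events)[, c("route", "magnitude", "unit",
                                             "t_start_days", "t_end_days")],
                   path)
}

#' Read and write exposure profiles
#'
#' Tab-separated `t_days` / `level` pairs (segment start times), with the
#' unit and TU flag stored in `# key = value` header comments. Dense-grid
#' profiles are stored point-wise with `representation = dense`.
#'
#' @param path File path.
#' @return `read_profile()` returns an [exposure_profile()].
#' @export
read_profile <- function(path) {
  df <- read_table_c14n(path)
  kv <- parse_kv_comments(attr(df, "comments"))
  unit <- if (!is.na(kv["unit"])) kv[["unit"]] else "TU"
  tu <- identical(kv[["is_toxic_units"]], "true")
  if (identical(kv[["representation"]], "dense")) {
    exposure_profile(0, 0, unit = unit, is_toxic_units = tu,
                     dense = list(t = df$t_days, c = df$level))
  } else {
    exposure_profile(df$t_days, df$level, unit = unit, is_toxic_units = tu)
  }
}

#' @rdname read_profile
#' @param profile An [exposure_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "exposure_profile"))
  dense <- !is.null(profile$dense)
  df <- if (dense) {
    data.frame(t_days = profile$dense$t, level = profile$dense$c)
  } else {
    data.frame(t_days = profile$breakpoints, level = profile$levels)
  }
  write_table_c14n(df, path, comments = c(
    paste0("unit = ", profile$unit),
    paste0("is_toxic_units = ", if (profile$is_toxic_units) "true" else "false"),
    paste0("representation = ", if (dense) "dense" else "piecewise")))
}

#' Read and write survival data tables
#'
#' Tab-separated text with columns `study_id`, `treatment`, `replicate`,
#' `time_days`, `n_alive`, `n_initial`.
#'
#' @param path File path.
#' @return `read_survival_data()` returns a `data.frame` suitable for
#'   [survival_dataset()].
#' @export
read_survival_data <- function(path) {
  df <- read_table_c14n(path)
  req <- c("treatment", "replicate", "time_days", "n_alive", "n_initial")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("survival file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$treatment <- as.character(df$treatment)
  df$replicate <- as.character(df$replicate)
  df
}

#' @rdname read_survival_data
#' @param data A survival data `data.frame` (or a [survival_dataset()], in
#'   which case its `data` slot is written).
#' @export
write_survival_data <- function(data, path) {
  if (inherits(data, "survival_dataset")) data <- data$data
  if (!"study_id" %in% names(data)) data <- cbind(study_id = "study1", data)
  write_table_c14n(data[, c("study_id", "treatment", "replicate",
                            "time_days", "n_alive", "n_initial")], path)
}

#' Read and write dose-response fits
#'
#' Small `key = value` text records holding `lc50`, `slope`, `timepoint`
#' and `endpoint_label`.
#'
#' @param path File path.
#' @return `read_dose_response()` returns a `dose_response_fit`.
#' @export
read_dose_response <- function(path) {
  kv <- parse_kv_comments(sub("^", "", readLines(path)))
  structure(list(lc50 = as.numeric(kv[["lc50"]]),
                 slope = as.numeric(kv[["slope"]]),
                 timepoint = as.numeric(kv[["timepoint"]]),
                 endpoint_label = kv[["endpoint_label"]],
                 objective = if (!is.na(kv["objective"])) kv[["objective"]]
                             else NA_character_),
            class = "dose_response_fit")
}

#' @rdname read_dose_response
#' @param fit A `dose_response_fit`.
#' @export
write_dose_response <- function(fit, path) {
  stopifnot(inherits(fit, "dose_response_fit"))
  lines <- c(paste0("lc50 = ", fmt_num(fit$lc50)),
             paste0("slope = ", fmt_num(fit$slope)),
             paste0("timepoint = ", fmt_num(fit$timepoint)),
             paste0("endpoint_label = ", fit$endpoint_label),
             paste0("objective = ", fit$objective))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a calibration result bundle
#'
#' Serializes a [calibrate()] result into `summary.json` (parameter
#' summaries, diagnostics, settings) and `samples.tsv` (pooled posterior
#' draws on the natural scale) inside `dir`.
#'
#' @param result A `calibration_result`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_calibration_result <- function(result, dir) {
  stopifnot(inherits(result, "calibration_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    model = result$model,
    mechanism = result$mechanism,
    parameters = result$summary,
    diagnostics = list(
      rhat = as.list(result$diagnostics$rhat),
      ess = as.list(result$diagnostics$ess),
      accept_rate = result$diagnostics$accept_rate,
      divergences = result$diagnostics$divergences,
      flagged = result$diagnostics$flagged),
    settings = result$settings[c("preset", "n_chains", "n_tune", "n_draw",
                                 "target_accept", "seed", "n_steps")])
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_table_c14n(as.data.frame(result$samples),
                   file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Write a metrics report as JSON
#'
#' @param report A [metrics_report()].
#' @param path Output file.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(ppc_pass_fraction = report$ppc_pass_fraction,
         nrmse = report$nrmse,
         sppe_per_replicate = as.list(report$sppe_per_replicate),
         sppe_min = report$sppe_min, sppe_max = report$sppe_max),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
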