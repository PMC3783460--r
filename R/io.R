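# CSV readers/writers and the end-to-end pipeline:
# (fit or load parameters) -> reconstruct the drive -> dieting-effect
# report. Months are 0-based from the record start; dietary intervals are
# half-open [start, end).

read_numeric_column <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) | is.na(x))
  if (length(bad)) {
    stop_domain("non-numeric value in column '", col, "' of ", path,
                " at data row ", bad[1], " ('", x[bad[1]], "')")
  }
  v
}

#' Read a monthly weight series from CSV
#'
#' Expects a header `month,weight_lb`; months must be strictly increasing
#' and weights positive. Malformed cells are reported with their row
#' number.
#'
#' @param path CSV file path.
#' @return A validated tibble with columns `month`, `weight_lb`.
#' @export
read_weight_series <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!all(c("month", "weight_lb") %in% names(raw))) {
    stop_domain("weight CSV must have columns 'month' and 'weight_lb' (",
                path, ")")
  }
  out <- tibble::tibble(
    month = read_numeric_column(raw$month, "month", path),
    weight_lb = read_numeric_column(raw$weight_lb, "weight_lb", path)
  )
  dup <- which(duplicated(out$month))
  if (length(dup)) {
    stop_domain("duplicated month ", out$month[dup[1]], " in ", path)
  }
  if (is.unsorted(out$month, strictly = TRUE)) {
    stop_domain("months must be strictly increasing in ", path)
  }
  validate_weight_series(out)
}

#' Read a diet schedule from CSV
#'
#' Expects a header `start_month,end_month`; periods are half-open
#' `[start, end)`, must be sorted and non-overlapping. A file with a
#' header and no rows is a valid empty schedule.
#'
#' @param path CSV file path.
#' @return A validated tibble with columns `start_month`, `end_month`.
#' @export
read_schedule <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!all(c("start_month", "end_month") %in% names(raw))) {
    stop_domain("schedule CSV must have columns 'start_month' and ",
                "'end_month' (", path, ")")
  }
  out <- tibble::tibble(
    start_month = read_numeric_column(raw$start_month, "start_month", path),
    end_month = read_numeric_column(raw$end_month, "end_month", path)
  )
  out <- out[order(out$start_month), , drop = FALSE]
  validate_schedule(out)
  out
}

#' Write pipeline tables to CSV
#'
#' Plain-CSV writers for the package's tabular outputs (weight series,
#' diet schedules, drive series, cross-correlation curves). Full double
#' precision is kept so files round-trip through their readers.
#'
#' @param data The tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_series <- function(data, path) {
  validate_weight_series(data)
  readr::write_csv(data[, c("month", "weight_lb")], path)
  invisible(path)
}

#' @rdname write_weight_series
#' @export
write_schedule <- function(data, path) {
  validate_schedule(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_weight_series
#' @export
write_drive_series <- function(data, path) {
  validate_drive_series(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages of the analysis in order: estimate the model
#' parameters from the weight record (or use supplied ones), reconstruct
#' the monthly drive, and quantify the dieting effect. Deterministic for
#' a given `seed`.
#'
#' @param weights Weight series: a data frame (`month`, `weight_lb`) or a
#'   CSV path.
#' @param schedule Diet schedule: a data frame (`start_month`,
#'   `end_month`) or a CSV path.
#' @param params Optional [model_params()] (or a parameter-file path for
#'   [read_params()]); when `NULL` the parameters are fitted.
#' @param transition_month Optional transition month; when given the
#'   piecewise fit ([fit_piecewise()]) is used.
#' @param fix_delta Optional fixed body-fat fraction for the fit.
#' @param n_starts,seed Multi-start settings passed to the fit.
#' @param shifts Shifts for the cross-correlation.
#' @param days_per_month Days per month.
#' @param out_dir Optional directory; when given, writes
#'   `drive.csv`, `xcorr.csv`, `fitted.csv`, `params.txt`,
#'   `report.json` (if jsonlite is available), `summary.txt` and a
#'   provenance record `run_config.txt`.
#' @return A list of class `pipeline_result` with `fit` (or `NULL` when
#'   parameters were supplied), `params`, `drive`, `report`
#'   (a [diet_effect_report()]).
#' @export
run_pipeline <- function(weights, schedule, params = NULL,
                         transition_month = NULL, fix_delta = NULL,
                         n_starts = 32, seed = 1, shifts = -12:12,
                         days_per_month = DAYS_PER_MONTH, out_dir = NULL) {
  if (is.character(weights)) weights <- read_weight_series(weights)
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  if (is.character(params)) params <- read_params(params)
  validate_weight_series(weights)
  validate_schedule(schedule)

  fit <- NULL
  if (is.null(params)) {
    fit <- if (is.null(transition_month)) {
      fit_weight_model(weights, n_starts = n_starts, seed = seed,
                       fix_delta = fix_delta,
                       days_per_month = days_per_month)
    } else {
      fit_piecewise(weights, transition_month, n_starts = n_starts,
                    seed = seed, fix_delta = fix_delta,
                    days_per_month = days_per_month)
    }
    params <- fit$params
  }
  drive <- reconstruct_drive(weights, params,
                             days_per_month = days_per_month)
  report <- diet_effect_report(drive, schedule, params = params,
                               shifts = shifts)
  result <- structure(list(fit = fit, params = params, drive = drive,
                           report = report),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, weights, seed,
                                               out_dir)
  result
}

write_pipeline_result <- function(result, weights, seed, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_drive_series(result$drive, fp("drive.csv"))
  readr::write_csv(result$report$xcorr, fp("xcorr.csv"))
  write_params(result$params, fp("params.txt"))
  if (!is.null(result$fit)) {
    readr::write_csv(result$fit$fitted, fp("fitted.csv"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    g <- glance(result$report)
    jsonlite::write_json(as.list(g), fp("report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summary_lines <- utils::capture.output(print(result$report))
  writeLines(summary_lines, fp("summary.txt"))
  writeLines(c(
    paste0("package: weightdrive ",
           as.character(utils::packageVersion("weightdrive"))),
    paste0("seed: ", seed),
    paste0("n_obs: ", nrow(weights)),
    paste0("n_periods: ", nrow(result$report$schedule))
  ), fp("run_config.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$fit)) print(x$fit) else print(x$params)
  print(x$report)
  invisible(x)
}
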