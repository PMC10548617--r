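#' Call-log vocabulary
#'
#' Valid values for the `category` and `response` columns of a call log.
#'
#' @format Character vectors.
#' @name call_log_vocabulary
NULL

#' @rdname call_log_vocabulary
#' @export
call_categories <- c("substance_use", "mental_health", "referral", "other")

#' @rdname call_log_vocabulary
#' @export
response_types <- c("none", "ems", "community")

call_log_columns <- c("timestamp", "period", "category", "overdose",
                      "caller_id", "response", "false_positive_ems",
                      "non_overdose_emergency")

#' Validate a call log
#'
#' Checks that a data frame has the call-log schema and that every record is
#' internally consistent: `category` and `response` take known values, a
#' dispatched response (`response != "none"`) is justified by an overdose, a
#' false-positive EMS call-out or a non-overdose emergency, and a
#' false-positive flag implies an EMS response. Violations are reported with
#' the offending row numbers.
#'
#' A call log has one row per call with columns `timestamp` (date-time),
#' `period` (label), `category` (one of `r paste(call_categories, collapse = ", ")`),
#' `overdose` (logical), `caller_id` (character; `NA` = unknown caller),
#' `response` (one of `r paste(response_types, collapse = ", ")`),
#' `false_positive_ems` and `non_overdose_emergency` (logical).
#'
#' @param calls A data frame of call records.
#' @return The validated log as a tibble (invisibly usable in a pipe).
#' @export
validate_call_log <- function(calls) {
  missing <- setdiff(call_log_columns, names(calls))
  if (length(missing)) {
    abort(paste0("Call log is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vomscba_schema_error")
  }
  calls <- as_tibble(calls)[call_log_columns]
  bad_line <- function(which) paste(utils::head(which, 5), collapse = ", ")

  bad <- which(!calls$category %in% call_categories)
  if (length(bad)) {
    abort(paste0("Unknown call category '", calls$category[bad[1]],
                 "' at row(s): ", bad_line(bad)),
          class = "vomscba_parse_error")
  }
  bad <- which(!calls$response %in% response_types)
  if (length(bad)) {
    abort(paste0("Unknown response type '", calls$response[bad[1]],
                 "' at row(s): ", bad_line(bad)),
          class = "vomscba_parse_error")
  }
  for (col in c("overdose", "false_positive_ems", "non_overdose_emergency")) {
    if (!is.logical(calls[[col]]) || anyNA(calls[[col]])) {
      abort(paste0("Column `", col, "` must be logical with no missing values"),
            class = "vomscba_schema_error")
    }
  }
  bad <- which(calls$response != "none" &
                 !(calls$overdose | calls$false_positive_ems |
                     calls$non_overdose_emergency))
  if (length(bad)) {
    abort(paste0("Dispatched response without an overdose, false positive, ",
                 "or non-overdose emergency at row(s): ", bad_line(bad)),
          class = "vomscba_parse_error")
  }
  bad <- which(calls$false_positive_ems & calls$response != "ems")
  if (length(bad)) {
    abort(paste0("false_positive_ems implies an EMS response; violated at row(s): ",
                 bad_line(bad)),
          class = "vomscba_parse_error")
  }
  calls
}

#' Read and write call logs
#'
#' Call logs are comma-separated UTF-8 files with a header row, ISO-8601
#' timestamps, and an empty `caller_id` field for unknown callers. Reading
#' validates every record ([validate_call_log()]); malformed rows are
#' reported with their row numbers.
#'
#' @param path Path to a call-log CSV file.
#' @return `read_call_log()` returns a validated tibble of call records;
#'   `write_call_log()` returns `path` invisibly.
#' @export
read_call_log <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Call log not found: ", path), class = "vomscba_io_error")
  }
  calls <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      period = readr::col_character(),
      category = readr::col_character(),
      overdose = readr::col_logical(),
      caller_id = readr::col_character(),
      response = readr::col_character(),
      false_positive_ems = readr::col_logical(),
      non_overdose_emergency = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_call_log(calls)
}

#' @param calls A validated call-log data frame.
#' @rdname read_call_log
#' @export
write_call_log <- function(calls, path) {
  calls <- validate_call_log(calls)
  readr::write_csv(calls, path, na = "")
  invisible(path)
}

#' Tally a call log into per-period service counts
#'
#' Reduces a call log to the per-period counts the cost and benefit models
#' consume: call totals by category, overdose totals, overdoses among unique
#' identified callers (each `caller_id` counted once per period) and among
#' unknown callers, EMS overdose call-outs (`t_ems`), false-positive EMS
#' call-outs (`t_fc`), community-based responses (`t_cr`), the
#' hospital-pathway count (`t_od`, equal to `t_ems`: every EMS-attended
#' overdose enters the ambulance/ED/admission pathway), and EMS call-outs
#' for non-overdose emergencies (excluded from overdose medical costing).
#'
#' @param calls A call-log data frame (validated with [validate_call_log()]).
#' @param periods Optional character vector of period labels defining the
#'   rows (and their order) of the tally; every record's period must be
#'   listed. Defaults to the periods present in the log, in order of first
#'   appearance. Periods with no records tally to zero.
#' @return A tibble with one row per period and the count columns described
#'   above.
#' @examples
#' tally_calls(nors_fixture())
#' @export
tally_calls <- function(calls, periods = NULL) {
  calls <- validate_call_log(calls)
  periods <- periods %||% unique(calls$period)
  extra <- setdiff(unique(calls$period), periods)
  if (length(extra)) {
    abort(paste0("Call log contains period(s) not listed: ",
                 paste(extra, collapse = ", ")),
          class = "vomscba_invalid_parameter")
  }
  calls$period <- factor(calls$period, levels = periods)
  out <- calls |>
    dplyr::group_by(period = .data$period, .drop = FALSE) |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      n_substance_calls = sum(.data$category == "substance_use"),
      n_mh_calls = sum(.data$category == "mental_health"),
      n_referrals = sum(.data$category == "referral"),
      n_overdoses_total = sum(.data$overdose),
      n_overdoses_unique = dplyr::n_distinct(
        .data$caller_id[.data$overdose & !is.na(.data$caller_id)]),
      n_overdoses_unknown = sum(.data$overdose & is.na(.data$caller_id)),
      t_ems = sum(.data$overdose & .data$response == "ems"),
      t_fc = sum(.data$false_positive_ems),
      t_cr = sum(.data$overdose & .data$response == "community"),
      n_ems_non_od = sum(.data$non_overdose_emergency &
                           .data$response == "ems" & !.data$overdose),
      .groups = "drop"
    ) |>
    dplyr::mutate(t_od = .data$t_ems, .after = "t_cr") |>
    dplyr::mutate(period = as.character(.data$period))
  out
}
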