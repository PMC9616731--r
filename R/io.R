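# CSV / JSON dialects. All readers are schema-checked (missing columns are
# named errors); extra columns pass through untouched. Doubles survive a
# write -> read round trip exactly (readr writes shortest round-trippable
# representations). Times are timezone-naive local study time, serialized
# as ISO-8601 and re-read as UTC.

#' Check a data frame for required columns
#' @param df data frame.
#' @param required character vector of required column names.
#' @param what label used in the error message.
#' @return `df`, invisibly.
#' @export
check_columns <- function(df, required, what = "table") {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

read_checked_csv <- function(path, required, what, col_types = NULL) {
  df <- as.data.frame(readr::read_csv(path, col_types = col_types,
                                      progress = FALSE,
                                      show_col_types = FALSE))
  check_columns(df, required, what)
  df
}

fmt_time <- function(x) strftime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
parse_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC")

#' Read / write the visit-log dialect
#'
#' Columns: `bee_id`, `colony_id` (optional), `bout_index`, `bout_type`,
#' `visit_index`, `arm_id`, `timestamp_s`.
#'
#' @param path file path.
#' @return `read_visits_csv()`: a data frame; writers return `path`
#'   invisibly.
#' @export
read_visits_csv <- function(path) {
  read_checked_csv(path, c("bee_id", "bout_index", "arm_id"), "visit log",
                   col_types = readr::cols(bee_id = "c"))
}

#' @rdname read_visits_csv
#' @param visits visit-log data frame.
#' @export
write_visits_csv <- function(visits, path) {
  readr::write_csv(visits, path, progress = FALSE)
  invisible(path)
}

#' Read / write the scored-bee dialect
#'
#' Columns: `bee_id`, `ram_score`, `ram_score_log1p`, `n_bouts`.
#' @param path file path.
#' @export
read_scores_csv <- function(path) {
  read_checked_csv(path, c("bee_id", "ram_score", "ram_score_log1p"),
                   "scores", col_types = readr::cols(bee_id = "c"))
}

#' @rdname read_scores_csv
#' @param scores scored-bee data frame from [ram_scores()].
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}

#' Read / write RFID event logs
#'
#' Columns: `tag_id`, `timestamp` (ISO-8601), `direction` (`out`/`in`).
#' @param path file path.
#' @export
read_rfid_csv <- function(path) {
  df <- read_checked_csv(path, c("tag_id", "timestamp", "direction"),
                         "rfid log",
                         col_types = readr::cols(tag_id = "c",
                                                 timestamp = "c"))
  df$timestamp <- parse_time(df$timestamp)
  df
}

#' @rdname read_rfid_csv
#' @param rfid RFID event data frame.
#' @export
write_rfid_csv <- function(rfid, path) {
  rfid$timestamp <- fmt_time(rfid$timestamp)
  readr::write_csv(rfid, path, progress = FALSE)
  invisible(path)
}

#' Read / write weigh-event logs
#'
#' Columns: `tag_id`, `timestamp`, `direction`, `mass_mg`,
#' `pollen_oneleg_mg`.
#' @param path file path.
#' @export
read_weighs_csv <- function(path) {
  df <- read_checked_csv(path,
                         c("tag_id", "timestamp", "direction", "mass_mg"),
                         "weigh log",
                         col_types = readr::cols(tag_id = "c",
                                                 timestamp = "c"))
  df$timestamp <- parse_time(df$timestamp)
  df
}

#' @rdname read_weighs_csv
#' @param weighs weigh-event data frame.
#' @export
write_weighs_csv <- function(weighs, path) {
  weighs$timestamp <- fmt_time(weighs$timestamp)
  readr::write_csv(weighs, path, progress = FALSE)
  invisible(path)
}

#' Read / write daily weather records
#'
#' Columns: `date`, `temp_C`, `humidity_pct`, `wind_ms` (daily means of
#' hourly station records).
#' @param path file path.
#' @export
read_weather_csv <- function(path) {
  df <- read_checked_csv(path, c("date", "temp_C", "humidity_pct",
                                 "wind_ms"), "weather",
                         col_types = readr::cols(date = "D"))
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_weather_csv
#' @param weather daily weather data frame.
#' @export
write_weather_csv <- function(weather, path) {
  readr::write_csv(weather, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-bee career tables
#'
#' Columns: `bee_id`, `colony_id`, `size_mm`, `age_at_release_days`,
#' `release_date`, `end_date`, `tested`.
#' @param path file path.
#' @export
read_bees_csv <- function(path) {
  df <- read_checked_csv(path, c("bee_id", "colony_id", "size_mm"),
                         "bee table",
                         col_types = readr::cols(bee_id = "c",
                                                 colony_id = "c"))
  for (col in c("release_date", "end_date"))
    if (col %in% names(df)) df[[col]] <- as.Date(df[[col]])
  df
}

#' @rdname read_bees_csv
#' @param bees bee table.
#' @export
write_bees_csv <- function(bees, path) {
  readr::write_csv(bees, path, progress = FALSE)
  invisible(path)
}

#' Read / write trip tables
#'
#' The full per-trip record emitted by the trip stage.
#' @param path file path.
#' @export
read_trips_csv <- function(path) {
  df <- read_checked_csv(path, c("bee_id", "t_out", "t_in", "duration_min"),
                         "trips",
                         col_types = readr::cols(bee_id = "c", t_out = "c",
                                                 t_in = "c"))
  df$t_out <- parse_time(df$t_out)
  df$t_in <- parse_time(df$t_in)
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

#' @rdname read_trips_csv
#' @param trips trip table.
#' @export
write_trips_csv <- function(trips, path) {
  trips$t_out <- fmt_time(trips$t_out)
  trips$t_in <- fmt_time(trips$t_in)
  readr::write_csv(trips, path, progress = FALSE)
  invisible(path)
}

#' Serialize a transition matrix to JSON
#'
#' @param tm a `transition_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix_json <- function(tm, path) {
  jsonlite::write_json(
    list(bee_id = tm$bee_id, n_arms = tm$n_arms,
         P = as.vector(t(tm$P)), counts = as.vector(t(tm$counts)),
         start_dist = tm$start_dist),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transition_matrix_json
#' @export
read_transition_matrix_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- x$n_arms
  new_transition_matrix(x$bee_id, k,
                        matrix(x$P, k, k, byrow = TRUE),
                        matrix(x$counts, k, k, byrow = TRUE),
                        x$start_dist)
}
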