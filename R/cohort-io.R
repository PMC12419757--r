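# On-disk cohort layout: three CSV files (profiles, sessions, surveys) plus
# a JSONL event file. All timestamps ISO-8601 UTC.

iso_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")

#' Write a cohort to a directory
#'
#' Writes `profiles.csv`, `sessions.csv`, `surveys.csv` and `events.jsonl`
#' (one JSON object per event line). A header comment line carrying the seed
#' and config hash can be prepended via `stamp`.
#'
#' @param cohort An `mh_cohort`.
#' @param dir Output directory (created if needed).
#' @param stamp Optional single comment line (without the leading `#`)
#'   written at the top of each CSV.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, stamp = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- cohort$sessions
  sessions$session_start <- iso_ts(sessions$session_start)
  sessions$session_end <- iso_ts(sessions$session_end)
  write_csv_stamped(cohort$profiles, file.path(dir, "profiles.csv"), stamp)
  write_csv_stamped(sessions, file.path(dir, "sessions.csv"), stamp)
  write_csv_stamped(cohort$surveys, file.path(dir, "surveys.csv"), stamp)

  ev <- cohort$events
  con <- file(file.path(dir, "events.jsonl"), open = "wb")
  on.exit(close(con))
  if (nrow(ev)) {
    lines <- vapply(seq_len(nrow(ev)), function(i) {
      jsonlite::toJSON(list(participant_id = ev$participant_id[i],
                            session_id = ev$session_id[i],
                            timestamp = iso_ts(ev$timestamp[i]),
                            kind = ev$kind[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(dir)
}

write_csv_stamped <- function(x, path, stamp = NULL) {
  if (!is.null(stamp)) {
    writeLines(paste0("# ", stamp), path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

read_csv_stamped <- function(path, ...) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read a cohort from a directory
#'
#' Reads the layout written by [write_cohort()] and re-validates it.
#'
#' @param dir Directory holding `profiles.csv`, `sessions.csv`,
#'   `surveys.csv` and optionally `events.jsonl`.
#' @param window_days Observation window length.
#' @return An `mh_cohort`.
#' @export
read_cohort <- function(dir, window_days = 28L) {
  profiles <- read_csv_stamped(file.path(dir, "profiles.csv"))
  profiles$enrollment_date <- as.Date(profiles$enrollment_date)
  sessions <- read_csv_stamped(file.path(dir, "sessions.csv"))
  if (nrow(sessions)) {
    sessions$session_start <- parse_ts(sessions$session_start)
    sessions$session_end <- parse_ts(sessions$session_end)
  }
  surveys <- read_csv_stamped(file.path(dir, "surveys.csv"))
  ev_path <- file.path(dir, "events.jsonl")
  events <- NULL
  if (file.exists(ev_path)) {
    lines <- readLines(ev_path)
    if (length(lines)) {
      parsed <- jsonlite::stream_in(textConnection(lines), verbose = FALSE)
      events <- tibble::tibble(
        participant_id = parsed$participant_id,
        session_id = parsed$session_id,
        timestamp = parse_ts(parsed$timestamp),
        kind = parsed$kind
      )
    }
  }
  validate_log(profiles, sessions, surveys, events, window_days)
}
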