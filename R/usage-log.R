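# Usage-log data model: cohort container, structural validation, and the
# per-participant log metrics (engagement time, visit gaps, daily active
# users, mileage).

new_mh_cohort <- function(profiles, sessions, events, surveys, window_days,
                          truth = NULL, flagged = character()) {
  structure(
    list(profiles = profiles, sessions = sessions, events = events,
         surveys = surveys, window_days = as.integer(window_days),
         truth = truth, flagged = flagged),
    class = "mh_cohort"
  )
}

#' @export
print.mh_cohort <- function(x, ...) {
  cat("<mh_cohort>\n")
  cat(sprintf("  %d participants, %d sessions, %d events, %d surveys (%d-day window)\n",
              nrow(x$profiles), nrow(x$sessions), nrow(x$events),
              nrow(x$surveys), x$window_days))
  if (length(x$flagged)) {
    cat(sprintf("  %d participant(s) lack a post survey and are excluded from scoring\n",
                length(x$flagged)))
  }
  invisible(x)
}

validation_error <- function(where, msg) {
  stop(sprintf("log validation failed [%s]: %s", where, msg), call. = FALSE)
}

#' Validate session-structured usage logs into an analyzable cohort
#'
#' Checks the structural invariants a downstream scoring run relies on:
#' sessions and events must reference known participants, sessions must have
#' non-negative durations and at least one page view, all timestamps must lie
#' inside each participant's observation window
#' `[enrollment, enrollment + window_days)`, surveys must be one per
#' participant with 20 items in 1-5 whose sum equals the recorded total.
#' Participants without a post survey are not an error: they are flagged and
#' excluded from index scoring, mirroring the usual handling of survey
#' non-completers in this design.
#'
#' @param profiles Tibble with `participant_id`, `enrollment_date` and the
#'   eight characteristics of [characteristic_levels()].
#' @param sessions Tibble with `participant_id`, `session_id`,
#'   `session_start`, `session_end` (POSIXct) and `page_views`.
#' @param surveys Tibble with `participant_id`, `item_01`..`item_20`, `total`.
#' @param events Optional tibble with `participant_id`, `session_id`,
#'   `timestamp`, `kind`. Defaults to an empty event log.
#' @param window_days Observation window length in days.
#'
#' @return An `mh_cohort`: the validated tables plus the window length and
#'   the flagged (survey-less) participant ids.
#' @export
validate_log <- function(profiles, sessions, surveys, events = NULL,
                         window_days = 28L) {
  profiles <- tibble::as_tibble(profiles)
  sessions <- tibble::as_tibble(sessions)
  surveys <- tibble::as_tibble(surveys)
  events <- if (is.null(events)) empty_events() else tibble::as_tibble(events)

  if (anyDuplicated(profiles$participant_id)) {
    validation_error("profiles",
                     paste("duplicated participant_id:",
                           profiles$participant_id[duplicated(profiles$participant_id)][1]))
  }
  levels <- characteristic_levels()
  for (ch in names(levels)) {
    bad <- !profiles[[ch]] %in% levels[[ch]]
    if (any(bad)) {
      validation_error(sprintf("profiles row %d", which(bad)[1]),
                       sprintf("unknown %s category '%s'", ch,
                               profiles[[ch]][which(bad)[1]]))
    }
  }

  ids <- profiles$participant_id
  check_known <- function(tbl, name) {
    bad <- !tbl$participant_id %in% ids
    if (any(bad)) {
      validation_error(sprintf("%s row %d", name, which(bad)[1]),
                       sprintf("unknown participant '%s'",
                               tbl$participant_id[which(bad)[1]]))
    }
  }
  check_known(sessions, "sessions")
  check_known(surveys, "surveys")
  check_known(events, "events")

  if (nrow(sessions)) {
    neg <- sessions$session_end < sessions$session_start
    if (any(neg)) {
      validation_error(sprintf("sessions row %d (%s)", which(neg)[1],
                               sessions$participant_id[which(neg)[1]]),
                       "session_end precedes session_start")
    }
    if (any(sessions$page_views < 1)) {
      i <- which(sessions$page_views < 1)[1]
      validation_error(sprintf("sessions row %d (%s)", i,
                               sessions$participant_id[i]),
                       "an opened session records at least one page view")
    }
    enroll <- profiles$enrollment_date[match(sessions$participant_id, ids)]
    w0 <- as.POSIXct(enroll, tz = "UTC")
    w1 <- w0 + window_days * 86400
    out <- sessions$session_start < w0 | sessions$session_end > w1
    if (any(out)) {
      i <- which(out)[1]
      validation_error(sprintf("sessions row %d (%s)", i,
                               sessions$participant_id[i]),
                       "timestamps outside the participant's observation window")
    }
  }
  if (nrow(events)) {
    bad <- !events$kind %in% event_kinds()
    if (any(bad)) {
      validation_error(sprintf("events row %d", which(bad)[1]),
                       sprintf("unknown event kind '%s'",
                               events$kind[which(bad)[1]]))
    }
    enroll <- profiles$enrollment_date[match(events$participant_id, ids)]
    w0 <- as.POSIXct(enroll, tz = "UTC")
    out <- events$timestamp < w0 | events$timestamp >= w0 + window_days * 86400
    if (any(out)) {
      i <- which(out)[1]
      validation_error(sprintf("events row %d (%s)", i,
                               events$participant_id[i]),
                       "timestamp outside the participant's observation window")
    }
  }

  if (anyDuplicated(surveys$participant_id)) {
    validation_error("surveys", "a participant has more than one survey")
  }
  if (nrow(surveys)) {
    item_cols <- sprintf("item_%02d", 1:20)
    missing_cols <- setdiff(item_cols, names(surveys))
    if (length(missing_cols)) {
      validation_error("surveys", paste("missing item columns:",
                                        paste(missing_cols, collapse = ", ")))
    }
    items <- as.matrix(surveys[item_cols])
    if (any(items < 1 | items > 5 | items != round(items))) {
      validation_error("surveys", "items must be integers in 1..5")
    }
    mismatch <- rowSums(items) != surveys$total
    if (any(mismatch)) {
      validation_error(sprintf("surveys row %d (%s)", which(mismatch)[1],
                               surveys$participant_id[which(mismatch)[1]]),
                       "total does not equal the sum of the 20 items")
    }
  }

  flagged <- setdiff(ids, surveys$participant_id)
  new_mh_cohort(profiles, sessions, events, surveys, window_days,
                flagged = flagged)
}

empty_events <- function() {
  tibble::tibble(participant_id = character(), session_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 kind = character())
}

# Clip one participant's sessions to [enrollment, enrollment + window) and
# drop sessions entirely outside it. Keeps one row per surviving session.
clip_sessions <- function(sessions, enrollment, window_days) {
  w0 <- as.POSIXct(as.Date(enrollment), tz = "UTC")
  w1 <- w0 + window_days * 86400
  keep <- sessions$session_start < w1 & sessions$session_end > w0
  out <- sessions[keep, , drop = FALSE]
  out$session_start <- pmax(out$session_start, w0)
  out$session_end <- pmin(out$session_end, w1)
  out
}

#' Cumulative engagement time for one participant
#'
#' Total minutes of app use across a participant's sessions within the
#' observation window. Sessions straddling a window boundary are truncated at
#' the boundary, and overlapping sessions are merged before summation so no
#' moment of use is counted twice.
#'
#' @param sessions Tibble of one participant's sessions (`session_start`,
#'   `session_end`).
#' @param enrollment Enrollment date anchoring the window.
#' @param window_days Window length in days.
#' @return Non-negative minutes; 0 when there are no sessions.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   session_start = as.POSIXct("2024-04-01 10:00", tz = "UTC") + c(0, 3600),
#'   session_end   = as.POSIXct("2024-04-01 10:00", tz = "UTC") + c(600, 4632)
#' )
#' engagement_time(s, as.Date("2024-04-01"))  # 10 + 17.2 minutes
engagement_time <- function(sessions, enrollment, window_days = 28L) {
  if (is.null(sessions) || nrow(sessions) == 0) return(0)
  s <- clip_sessions(sessions, enrollment, window_days)
  if (nrow(s) == 0) return(0)
  total_interval_minutes(as.numeric(s$session_start), as.numeric(s$session_end))
}

# Union length of [start, end) intervals, in minutes.
total_interval_minutes <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_start <- start[1]; cur_end <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_end) {
      total <- total + (cur_end - cur_start)
      cur_start <- start[i]; cur_end <- end[i]
    } else {
      cur_end <- max(cur_end, end[i])
    }
  }
  (total + (cur_end - cur_start)) / 60
}

#' Day gaps between a participant's visits
#'
#' Collapses sessions to distinct calendar visit days relative to enrollment
#' (a session is attributed to the day it starts) and returns the consecutive
#' differences. These gaps are the input to the recency subindex. A
#' participant with a single visit day returns an empty vector.
#'
#' The `"intersession"` method instead differences raw session start times in
#' (possibly fractional) days, for sensitivity analyses of the distinct-day
#' convention.
#'
#' @param sessions Tibble of one participant's sessions.
#' @param enrollment Enrollment date.
#' @param method `"distinct_days"` (default) or `"intersession"`.
#' @return Numeric vector of positive gaps (integers for the default method).
#' @export
visit_gaps <- function(sessions, enrollment,
                       method = c("distinct_days", "intersession")) {
  method <- match.arg(method)
  if (is.null(sessions) || nrow(sessions) == 0) {
    stop("visit_gaps() is undefined for a participant with no sessions",
         call. = FALSE)
  }
  if (method == "distinct_days") {
    days <- sort(unique(visit_day(sessions$session_start, enrollment)))
    diff(days)
  } else {
    t <- sort(as.numeric(sessions$session_start)) / 86400
    diff(t)
  }
}

visit_day <- function(timestamps, enrollment) {
  w0 <- as.POSIXct(as.Date(enrollment), tz = "UTC")
  as.integer(floor((as.numeric(timestamps) - as.numeric(w0)) / 86400))
}

#' Daily-active-user curve
#'
#' For each day `d` in `[0, window_days)` of a participant's personal
#' timeline (days since enrollment), counts how many participants had at
#' least one session on their own day `d`. Day 0 is therefore the number of
#' participants who used the app on their first day of access.
#'
#' @param sessions Session tibble for the whole cohort.
#' @param profiles Profile tibble (supplies each enrollment date).
#' @param window_days Window length in days.
#' @return Tibble with `day` (0-based) and `active_users`.
#' @export
daily_active_users <- function(sessions, profiles, window_days = 28L) {
  counts <- integer(window_days)
  if (nrow(sessions)) {
    enroll <- profiles$enrollment_date[match(sessions$participant_id,
                                             profiles$participant_id)]
    day <- visit_day(sessions$session_start, as.Date("1970-01-01")) -
      as.integer(enroll - as.Date("1970-01-01"))
    keep <- day >= 0 & day < window_days
    pairs <- unique(data.frame(id = sessions$participant_id[keep],
                               day = day[keep]))
    tab <- table(factor(pairs$day, levels = 0:(window_days - 1)))
    counts <- as.integer(tab)
  }
  tibble::tibble(day = 0:(window_days - 1), active_users = counts)
}

#' In-app reward points ("mileage") for one participant
#'
#' Applies the app's reward tariff to a participant's interaction events:
#' 100 points each for a medication record, mood record, sexual-health
#' record, content rating, or comment; 1000 points per private Q&A post;
#' 2000 points per public Q&A post.
#'
#' @param events Tibble of one participant's events (needs `kind`).
#' @return Non-negative integer point total.
#' @export
#' @examples
#' mileage_total(tibble::tibble(kind = c("medication_record", "public_question")))
mileage_total <- function(events) {
  if (is.null(events) || nrow(events) == 0) return(0L)
  tariff <- c(comment = 100L, public_question = 2000L,
              private_question = 1000L, rating = 100L,
              medication_record = 100L, mood_record = 100L,
              sexual_health_record = 100L)
  unknown <- setdiff(unique(events$kind), names(tariff))
  if (length(unknown)) {
    stop("unknown event kind: ", unknown[1], call. = FALSE)
  }
  sum(tariff[events$kind])
}

#' Sessionize a raw event stream by inactivity gaps
#'
#' Fallback for logs delivered as bare event streams rather than session
#' records: consecutive events of a participant separated by no more than
#' `gap_minutes` of inactivity are grouped into one session. Each derived
#' session spans its first to last event and counts one page view per event.
#' The reference analysis assumes upstream session records and does not use
#' this.
#'
#' @param events Event tibble (`participant_id`, `timestamp`, `kind`).
#' @param gap_minutes Inactivity threshold in minutes (default 30).
#' @return Session tibble in the package layout.
#' @export
sessionize_events <- function(events, gap_minutes = 30) {
  if (nrow(events) == 0) {
    return(tibble::tibble(participant_id = character(), session_id = character(),
                          session_start = as.POSIXct(character(), tz = "UTC"),
                          session_end = as.POSIXct(character(), tz = "UTC"),
                          page_views = integer()))
  }
  events <- dplyr::arrange(events, .data$participant_id, .data$timestamp)
  events <- dplyr::group_by(events, .data$participant_id)
  events <- dplyr::mutate(
    events,
    new_session = c(TRUE, diff(as.numeric(.data$timestamp)) > gap_minutes * 60),
    session_no = cumsum(.data$new_session)
  )
  out <- dplyr::summarise(
    dplyr::group_by(events, .data$participant_id, .data$session_no),
    session_start = min(.data$timestamp),
    session_end = max(.data$timestamp),
    page_views = dplyr::n(),
    .groups = "drop"
  )
  out$session_id <- sprintf("%s-S%03d", out$participant_id, out$session_no)
  out[c("participant_id", "session_id", "session_start", "session_end",
        "page_views")]
}
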