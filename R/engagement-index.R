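# The five engagement subindices and the composite index. Each subindex is
# normalized to a 0-100 percentage; the composite is their arithmetic mean.

#' Click-depth subindex
#'
#' Percentage of a participant's sessions with at least `threshold` page
#' views. Filtering at a page-view threshold (default 4) keeps only sessions
#' deep enough to represent a completed in-app activity — e.g. home screen >
#' medication input > date selection > completion is a 4-page sequence —
#' and screens out reflexive open-and-close visits.
#'
#' @param page_views Integer vector of per-session page-view counts for one
#'   participant (one entry per session).
#' @param threshold Minimum page views for a session to qualify (default 4).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' click_depth_index(c(4, 5, 3, 9))  # 75
click_depth_index <- function(page_views, threshold = 4L) {
  if (length(page_views) == 0) {
    stop("click_depth_index() is undefined for a participant with no sessions",
         call. = FALSE)
  }
  if (threshold < 1) stop("threshold must be a positive integer", call. = FALSE)
  100 * mean(page_views >= threshold)
}

#' Loyalty subindex
#'
#' `100 * (1 - 1 / n_sessions)`: one-time visitors score 0 and frequent
#' returners approach 100, so the subindex orders participants by return
#' visits on a bounded scale.
#'
#' @param n_sessions Positive integer session count(s); vectorized.
#' @return Percentage(s) in \[0, 100).
#' @export
#' @examples
#' loyalty_index(c(1, 28, 47))
loyalty_index <- function(n_sessions) {
  if (length(n_sessions) == 0 || any(n_sessions < 1)) {
    stop("loyalty_index() requires at least one session", call. = FALSE)
  }
  100 * (1 - 1 / n_sessions)
}

#' Recency subindex
#'
#' Reciprocal of the mean number of days between visits, as a percentage:
#' daily users (mean gap 1) score 100, and the score falls as visits grow
#' sparser. Mean gaps below one day (several same-day visits) are capped at
#' 100 to stay on the 0-100 scale. A participant with a single visit day has
#' no gaps; such participants receive the floor score `100 / window_days`,
#' the reciprocal-gap value of the least recent pattern the window can hold.
#'
#' @param gaps Numeric vector of day gaps from [visit_gaps()]; may be empty.
#' @param window_days Window length, used only for the single-visit floor.
#' @return Percentage in \(0, 100\].
#' @export
#' @examples
#' recency_index(c(1, 1, 1))  # 100
#' recency_index(c(2, 2))     # 50
recency_index <- function(gaps, window_days = 28L) {
  if (length(gaps) == 0) return(100 / window_days)
  if (any(gaps < 0)) stop("visit gaps must be non-negative", call. = FALSE)
  100 * min(1, 1 / mean(gaps))  # mean gap < 1 day capped at 100
}

#' Feedback subindex
#'
#' The post-intervention usability-survey total (a 20-item, 5-point Likert
#' instrument, totals 20-100) expressed against its 100-point maximum, so the
#' subindex equals the total score as a percentage.
#'
#' @param total Survey total(s) in \[20, 100\]; vectorized.
#' @return Percentage(s) in \[20, 100\].
#' @export
feedback_index <- function(total) {
  if (any(total < 20 | total > 100)) {
    stop("survey totals must lie in [20, 100]", call. = FALSE)
  }
  100 * total / 100
}

#' Cohort maxima for the interaction subindex
#'
#' The interaction subindex norms each participant's counts by the cohort
#' maximum of that count, so the maxima must be computed once over the same
#' analyzable set that is being scored.
#'
#' @param counts Tibble with one row per participant and the count columns
#'   to be normed (e.g. `comments`, `questions`, `ratings`).
#' @return Named numeric vector of per-column maxima.
#' @export
interaction_maxima <- function(counts) {
  cols <- setdiff(names(counts), "participant_id")
  vapply(counts[cols], function(x) as.numeric(max(x)), numeric(1))
}

#' Interaction subindex
#'
#' Mean of a participant's count-to-cohort-maximum ratios across the active
#' interaction categories (comments, questions, ratings), as a percentage.
#' A category whose cohort maximum is 0 (nobody used it) contributes a ratio
#' of 0 for everyone rather than an undefined division.
#'
#' @param counts Named numeric vector of one participant's counts.
#' @param maxima Named numeric vector of cohort maxima covering the same
#'   names, from [interaction_maxima()].
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' interaction_index(c(comments = 2, questions = 1, ratings = 0),
#'                   c(comments = 4, questions = 2, ratings = 5))
interaction_index <- function(counts, maxima) {
  if (!all(names(counts) %in% names(maxima))) {
    stop("maxima must cover every count category", call. = FALSE)
  }
  maxima <- maxima[names(counts)]
  if (any(counts > maxima)) {
    stop("a participant count exceeds its cohort maximum; ",
         "maxima must be computed over the scored set", call. = FALSE)
  }
  ratios <- ifelse(maxima > 0, counts / maxima, 0)
  100 * mean(ratios)
}

#' Composite engagement index
#'
#' Arithmetic mean of the five normalized subindices (click depth, loyalty,
#' recency, feedback, interaction), each on 0-100, giving a composite on
#' 0-100 meant to rank participants.
#'
#' @param subindices Numeric vector (or single-row data frame) of the five
#'   subindex percentages.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' engagement_index(c(84.2, 96.4, 62.5, 5.3, 84.0))
engagement_index <- function(subindices) {
  x <- as.numeric(unlist(subindices))
  if (length(x) != 5) {
    stop("the engagement index averages exactly five subindices", call. = FALSE)
  }
  if (any(is.na(x)) || any(x < 0 | x > 100)) {
    stop("subindices must lie in [0, 100]", call. = FALSE)
  }
  mean(x)
}

#' Score a cohort: subindices, composite index, time, mileage
#'
#' Computes one engagement summary per analyzable participant — those with a
#' post survey and at least one session inside their observation window.
#' Survey non-completers are excluded (not imputed) and listed in the
#' `excluded` attribute; the interaction maxima are computed once over the
#' analyzable set.
#'
#' @param cohort An `mh_cohort` from [validate_log()] or [generate_cohort()].
#' @param threshold Click-depth page-view threshold (default 4).
#' @param pool_questions If `TRUE` (default) public and private questions are
#'   pooled into one "questions" count for the interaction subindex; if
#'   `FALSE` they are normed separately (four ratios instead of three).
#' @param recency_method Passed to [visit_gaps()].
#' @return Tibble with one row per analyzable participant: the five
#'   subindices, `engagement_index`, `engagement_time_min`, `n_sessions`,
#'   `mileage`. Attribute `excluded` lists participants left out and why.
#' @export
score_cohort <- function(cohort, threshold = 4L, pool_questions = TRUE,
                         recency_method = c("distinct_days", "intersession")) {
  stopifnot(inherits(cohort, "mh_cohort"))
  recency_method <- match.arg(recency_method)
  w <- cohort$window_days
  profiles <- cohort$profiles

  surveyed <- profiles$participant_id %in% cohort$surveys$participant_id
  with_sessions <- profiles$participant_id %in% cohort$sessions$participant_id
  analyzable <- profiles$participant_id[surveyed & with_sessions]
  excluded <- tibble::tibble(
    participant_id = profiles$participant_id[!(surveyed & with_sessions)],
    reason = ifelse(!surveyed[!(surveyed & with_sessions)],
                    "no post survey", "no sessions")
  )
  if (length(analyzable) == 0) {
    stop("no analyzable participants: scoring needs at least one participant ",
         "with both a post survey and a session; check that surveys were ",
         "collected and joined to the log", call. = FALSE)
  }

  enroll <- profiles$enrollment_date[match(analyzable, profiles$participant_id)]
  sess <- cohort$sessions
  sess_idx <- split(seq_len(nrow(sess)),
                    factor(sess$participant_id, levels = analyzable))
  start_all <- as.numeric(sess$session_start)
  end_all <- as.numeric(sess$session_end)
  pages_all <- sess$page_views
  enroll_num <- as.numeric(as.POSIXct(enroll, tz = "UTC"))
  ev <- cohort$events[cohort$events$participant_id %in% analyzable, ,
                      drop = FALSE]

  # Interaction counts per participant over the window
  count_kind <- function(kinds) {
    tab <- table(factor(ev$participant_id[ev$kind %in% kinds],
                        levels = analyzable))
    as.numeric(tab)
  }
  counts <- tibble::tibble(
    participant_id = analyzable,
    comments = count_kind("comment"),
    ratings = count_kind("rating")
  )
  if (pool_questions) {
    counts$questions <- count_kind(c("public_question", "private_question"))
    count_cols <- c("comments", "questions", "ratings")
  } else {
    counts$public_questions <- count_kind("public_question")
    counts$private_questions <- count_kind("private_question")
    count_cols <- c("comments", "public_questions", "private_questions",
                    "ratings")
  }
  maxima <- interaction_maxima(counts[c("participant_id", count_cols)])

  n_p <- length(analyzable)
  click <- loyal <- recency <- time_min <- numeric(n_p)
  n_sessions <- integer(n_p)
  for (j in seq_len(n_p)) {
    # clip to [enrollment, enrollment + window) on plain numerics
    ii <- sess_idx[[j]]
    w0 <- enroll_num[j]; w1 <- w0 + w * 86400
    keep <- start_all[ii] < w1 & end_all[ii] > w0
    st <- pmax(start_all[ii][keep], w0)
    en <- pmin(end_all[ii][keep], w1)
    pg <- pages_all[ii][keep]
    n_sessions[j] <- length(st)
    click[j] <- click_depth_index(pg, threshold)
    loyal[j] <- loyalty_index(length(st))
    gaps <- if (recency_method == "distinct_days") {
      diff(sort(unique(floor((st - w0) / 86400))))
    } else {
      diff(sort(st)) / 86400
    }
    recency[j] <- recency_index(gaps, w)
    time_min[j] <- total_interval_minutes(st, en)
  }
  tariff <- c(comment = 100, public_question = 2000, private_question = 1000,
              rating = 100, medication_record = 100, mood_record = 100,
              sexual_health_record = 100)
  mileage <- as.integer(vapply(
    split(tariff[ev$kind], factor(ev$participant_id, levels = analyzable)),
    sum, numeric(1)))
  feedback <- feedback_index(
    cohort$surveys$total[match(analyzable, cohort$surveys$participant_id)]
  )
  interact <- vapply(seq_len(n_p), function(j) {
    interaction_index(
      stats::setNames(as.numeric(unlist(counts[j, count_cols])), count_cols),
      maxima
    )
  }, numeric(1))

  out <- tibble::tibble(
    participant_id = analyzable,
    click_depth = click,
    loyalty = loyal,
    recency = recency,
    feedback = feedback,
    interaction = interact,
    engagement_index = (click + loyal + recency + feedback + interact) / 5,
    engagement_time_min = time_min,
    n_sessions = n_sessions,
    mileage = mileage
  )
  attr(out, "excluded") <- excluded
  attr(out, "interaction_maxima") <- maxima
  attr(out, "threshold") <- threshold
  out
}
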