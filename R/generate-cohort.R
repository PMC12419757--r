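# Seeded synthetic usage-log generator. One RNG stream per participant,
# derived from (seed, participant index), so editing or extending a cohort
# never perturbs the draws of unrelated participants.

derive_stream_seed <- function(seed, i) {
  # Lehmer-style mix kept inside the 32-bit integer range.
  as.integer((as.double(seed) %% 2147483647 * 48271 + i * 16807) %% 2147483647)
}

#' Generate a synthetic mHealth usage cohort
#'
#' Simulates a cohort with the structure the engagement analysis assumes:
#' a participant-characteristics table drawn from configured category
#' marginals, staggered enrollment dates, per-participant session logs over a
#' fixed observation window, typed interaction events placed inside sessions,
#' and a 20-item post-intervention usability survey (5-point Likert items,
#' totals 20-100).
#'
#' The usage model: each participant draws a latent daily login propensity
#' from a beta distribution (shifted additively by `selfhelp_effect` for
#' self-help group participants); each window day is a login day with that
#' probability; a login day yields one session plus a Poisson number of
#' extras; sessions get negative-binomial page counts (support >= 1) and
#' log-normal durations; interaction-event counts are negative-binomial with
#' means proportional to the participant's propensity, which couples index
#' and time the way engaged users couple them in real logs. Holding the
#' propensity fixed across the window overdisperses session counts, giving
#' the wide session-count spread and the right-skewed engagement-time /
#' left-skewed engagement-index shape the generator is calibrated to.
#'
#' @param config An `mh_cohort_config`, see [cohort_config()].
#' @param seed Optional override of `config$seed`.
#' @return An `mh_cohort` whose `truth` field records each participant's
#'   latent login propensity and satisfaction.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 20, seed = 42))
#' cohort
generate_cohort <- function(config = default_cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "mh_cohort_config"))
  validate_cohort_config(config)
  if (!is.null(seed)) config$seed <- seed

  n <- config$n_participants
  w <- config$window_days
  levels <- characteristic_levels()
  sp <- config$session_propensity
  shape1 <- sp$mean * sp$concentration
  shape2 <- (1 - sp$mean) * sp$concentration
  ss <- config$survey_score
  kinds <- event_kinds()
  rates <- config$interaction_rates[kinds]

  ids <- sprintf("P%04d", seq_len(n))
  prof_rows <- vector("list", n)
  sess_rows <- vector("list", n)
  ev_rows <- vector("list", n)
  surv_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(derive_stream_seed(config$seed, i))
    pid <- ids[i]

    chars <- lapply(names(levels), function(ch) {
      p <- config$characteristic_marginals[[ch]][levels[[ch]]]
      sample(levels[[ch]], 1, prob = p)
    })
    names(chars) <- names(levels)
    enrollment <- config$study_start +
      (sample.int(config$enrollment_span_days, 1) - 1L)

    p_raw <- stats::rbeta(1, shape1, shape2)
    shift <- if (chars$self_help == "yes") config$selfhelp_effect else 0
    propensity <- min(max(p_raw + shift, 0.005), 0.995)

    login_days <- which(stats::runif(w) < propensity) - 1L
    sessions_per_day <- 1L + stats::rpois(length(login_days), sp$extra_sessions)
    n_sess <- sum(sessions_per_day)

    w0 <- as.POSIXct(enrollment, tz = "UTC")
    if (n_sess > 0) {
      day <- rep(login_days, sessions_per_day)
      start_frac <- stats::runif(n_sess, min = 7 / 24, max = 23 / 24)
      start <- w0 + (day + start_frac) * 86400
      usd <- config$session_duration$user_sdlog
      dur_scale <- stats::rlnorm(1, -usd^2 / 2, usd)
      dur_min <- dur_scale * stats::rlnorm(n_sess,
                                           config$session_duration$meanlog,
                                           config$session_duration$sdlog)
      end <- pmin(start + dur_min * 60, w0 + w * 86400 - 1)
      pages <- 1L + stats::rnbinom(n_sess, size = config$pages_per_session$size,
                                   mu = config$pages_per_session$mu)
      o <- order(start)
      sess_rows[[i]] <- list(
        participant_id = rep(pid, n_sess),
        session_id = sprintf("%s-S%03d", pid, seq_len(n_sess)),
        session_start = as.numeric(start[o]),
        session_end = as.numeric(end[o]),
        page_views = pages[o]
      )
      start <- start[o]; end <- end[o]

      mu_i <- rates * propensity / sp$mean
      ev_counts <- stats::rnbinom(length(kinds),
                                  size = config$interaction_dispersion,
                                  mu = mu_i)
      n_ev <- sum(ev_counts)
      if (n_ev > 0) {
        ev_kind <- rep(kinds, ev_counts)
        host <- sample.int(n_sess, n_ev, replace = TRUE)
        ts <- as.numeric(start[host]) +
          stats::runif(n_ev) * pmax(as.numeric(end[host]) -
                                      as.numeric(start[host]), 1)
        ts <- pmin(ts, as.numeric(end[host]))
        ev_rows[[i]] <- list(
          participant_id = rep(pid, n_ev),
          session_id = sprintf("%s-S%03d", pid, host),
          timestamp = ts,
          kind = ev_kind
        )
      }
    }

    satisfaction <- stats::rbeta(1, ss$mean * ss$concentration,
                                 (1 - ss$mean) * ss$concentration)
    if (stats::runif(1) >= ss$dropout) {
      items <- 1L + stats::rbinom(20, 4, satisfaction)
      surv_rows[[i]] <- c(list(participant_id = pid),
                          stats::setNames(as.list(items),
                                          sprintf("item_%02d", 1:20)),
                          list(total = sum(items)))
    }

    prof_rows[[i]] <- c(list(participant_id = pid,
                             enrollment_date = as.integer(enrollment)),
                        chars)
    truth_rows[[i]] <- list(participant_id = pid, propensity = propensity,
                            satisfaction = satisfaction)
  }

  profiles <- bind_row_lists(prof_rows)
  profiles$enrollment_date <- as.Date(profiles$enrollment_date,
                                      origin = "1970-01-01")
  sessions <- bind_row_lists(sess_rows)
  if (nrow(sessions)) {
    sessions$session_start <- as.POSIXct(sessions$session_start, tz = "UTC",
                                         origin = "1970-01-01")
    sessions$session_end <- as.POSIXct(sessions$session_end, tz = "UTC",
                                       origin = "1970-01-01")
  } else {
    sessions <- tibble::tibble(participant_id = character(),
                               session_id = character(),
                               session_start = as.POSIXct(character(), tz = "UTC"),
                               session_end = as.POSIXct(character(), tz = "UTC"),
                               page_views = integer())
  }
  events <- bind_row_lists(ev_rows)
  if (nrow(events)) {
    events$timestamp <- as.POSIXct(events$timestamp, tz = "UTC",
                                   origin = "1970-01-01")
  } else {
    events <- empty_events()
  }
  surveys <- bind_row_lists(surv_rows)
  if (nrow(surveys)) {
    names(surveys) <- c("participant_id", sprintf("item_%02d", 1:20), "total")
  } else {
    surveys <- tibble::as_tibble(
      c(list(participant_id = character()),
        stats::setNames(rep(list(integer()), 20), sprintf("item_%02d", 1:20)),
        list(total = integer()))
    )
  }
  truth <- bind_row_lists(truth_rows)

  cohort <- validate_log(profiles, sessions, surveys, events, w)
  cohort$truth <- truth
  cohort
}

# Bind a list of per-participant row-lists (each a named list of equal-length
# vectors, or a single-row record) into one tibble.
bind_row_lists <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(tibble::tibble())
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cl) {
    unlist(lapply(rows, `[[`, cl), use.names = FALSE)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}
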