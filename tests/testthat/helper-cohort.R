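# Fixtures are built in code: small generated cohorts plus hand-constructed
# profile/session/survey tables for the validation edge cases.

tiny_cohort <- function(n = 12, seed = 1, ...) {
  generate_cohort(cohort_config(n_participants = n, seed = seed, ...))
}

a_date <- as.Date("2024-04-01")

make_profiles <- function(ids, enrollment = a_date, self_help = "no") {
  tibble::tibble(
    participant_id = ids,
    enrollment_date = rep(enrollment, length.out = length(ids)),
    age_group = "30-39", marital_status = "no_spouse",
    living_status = "alone", education = ">=college",
    employment = "employed", economic_status = "middle",
    care_stage = "familiarization_to_sustaining",
    self_help = rep(self_help, length.out = length(ids))
  )
}

# Sessions for one participant: day offsets (fractional days since the given
# enrollment), durations in minutes, page views.
make_sessions <- function(id, day, dur_min = 5, pages = 5,
                          enrollment = a_date) {
  w0 <- as.POSIXct(enrollment, tz = "UTC")
  start <- w0 + day * 86400
  tibble::tibble(
    participant_id = id,
    session_id = sprintf("%s-S%03d", id, seq_along(day)),
    session_start = start,
    session_end = start + rep(dur_min, length.out = length(day)) * 60,
    page_views = as.integer(rep(pages, length.out = length(day)))
  )
}

make_survey <- function(id, items = rep(4L, 20)) {
  stopifnot(length(items) == 20)
  out <- c(list(participant_id = id),
           stats::setNames(as.list(as.integer(items)),
                           sprintf("item_%02d", 1:20)),
           list(total = sum(items)))
  tibble::as_tibble(out)
}

make_events <- function(id, kinds, day = 0.5, enrollment = a_date) {
  w0 <- as.POSIXct(enrollment, tz = "UTC")
  tibble::tibble(
    participant_id = id,
    session_id = sprintf("%s-S001", id),
    timestamp = w0 + rep(day, length.out = length(kinds)) * 86400,
    kind = kinds
  )
}

# Self-help Mann-Whitney p-value on the engagement index of one simulated
# cohort: the replicate unit of the calibration/power simulations.
selfhelp_pvalue <- function(seed, effect, n = 261) {
  cohort <- generate_cohort(
    cohort_config(n_participants = n, seed = seed, selfhelp_effect = effect)
  )
  scores <- score_cohort(cohort)
  sh <- cohort$profiles$self_help[match(scores$participant_id,
                                        cohort$profiles$participant_id)]
  mann_whitney(scores$engagement_index[sh == "yes"],
               scores$engagement_index[sh == "no"])$p_value
}
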