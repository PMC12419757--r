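test_that("click depth is the percentage of sessions at or above the threshold", {
  expect_equal(click_depth_index(c(4, 6, 9, 12)), 100)
  expect_equal(click_depth_index(c(4, 5, 3, 9)), 75)
  # a 4-page task flow (home > input > date > completion) qualifies
  expect_equal(click_depth_index(4), 100)
  expect_error(click_depth_index(integer(0)), "no sessions")
})

test_that("click depth agrees with a brute-force per-session filter and count", {
  set.seed(31)
  for (rep in 1:20) {
    pages <- 1 + rnbinom(sample(1:40, 1), size = 2, mu = 8)
    thr <- sample(2:6, 1)
    brute <- 100 * sum(vapply(pages, function(p) p >= thr, logical(1))) /
      length(pages)
    expect_equal(click_depth_index(pages, thr), brute)
  }
})

test_that("click depth weakly increases when a session crosses the threshold", {
  pages <- c(3, 5, 2, 8)
  bumped <- c(4, 5, 2, 8)
  expect_gt(click_depth_index(bumped), click_depth_index(pages))
})

test_that("loyalty is 0 for one-time visitors and strictly increases with sessions", {
  expect_equal(loyalty_index(1), 0)
  expect_gt(loyalty_index(15), loyalty_index(3))
  counts <- 1:60
  expect_true(all(diff(loyalty_index(counts)) > 0))
  expect_true(all(loyalty_index(counts) >= 0 & loyalty_index(counts) < 100))
  expect_error(loyalty_index(0), "at least one session")
})

test_that("recency is the reciprocal mean gap, capped at 100, with the single-visit floor", {
  expect_equal(recency_index(c(1, 1, 1)), 100)
  expect_equal(recency_index(c(2, 2)), 50)
  expect_equal(recency_index(c(0.2, 0.3)), 100)          # same-day cap
  expect_equal(recency_index(numeric(0), 28), 100 / 28)  # single visit day
  # strictly decreasing in the mean gap above the cap
  means <- seq(1, 14, by = 0.5)
  vals <- vapply(means, function(m) recency_index(c(m, m)), numeric(1))
  expect_true(all(diff(vals) < 0))
  # a recent, regular visitor outranks a sparse one
  expect_gt(recency_index(rep(1, 27)), recency_index(rep(7, 3)))
})

test_that("feedback equals the survey total on the percent scale", {
  expect_equal(feedback_index(100), 100)
  expect_equal(feedback_index(20), 20)
  expect_equal(feedback_index(84), 84)
  expect_error(feedback_index(12), "20, 100")
})

test_that("interaction averages count-to-maximum ratios with zero-usage categories scoring 0", {
  mx <- c(comments = 4, questions = 2, ratings = 5)
  expect_equal(interaction_index(c(comments = 4, questions = 2, ratings = 5),
                                 mx), 100)
  expect_equal(interaction_index(c(comments = 0, questions = 0, ratings = 0),
                                 mx), 0)
  expect_equal(interaction_index(c(comments = 2, questions = 1, ratings = 0),
                                 mx), 100 * (0.5 + 0.5 + 0) / 3)
  # nobody rated anything: that category contributes 0 for everyone
  mx0 <- c(comments = 4, questions = 2, ratings = 0)
  expect_equal(interaction_index(c(comments = 4, questions = 2, ratings = 0),
                                 mx0), 100 * 2 / 3)
  expect_error(interaction_index(c(comments = 9, questions = 0, ratings = 0),
                                 mx), "exceeds")
})

test_that("the composite index is the mean of exactly five bounded subindices", {
  expect_equal(engagement_index(rep(100, 5)), 100)
  expect_equal(engagement_index(rep(0, 5)), 0)
  expect_equal(engagement_index(c(84.2, 96.4, 62.5, 5.3, 84.0)), 66.48)
  expect_error(engagement_index(c(50, 50, 50, 50, 120)), "0, 100")
  expect_error(engagement_index(c(50, 50)), "five")
})

test_that("all subindices and the composite stay in [0, 100] on randomized cohorts", {
  for (seed in c(101, 202, 303)) {
    cohort <- generate_cohort(cohort_config(
      n_participants = 60, seed = seed,
      selfhelp_effect = c(0, 0.15, 0.4)[(seed %% 3) + 1]
    ))
    scores <- score_cohort(cohort)
    for (col in c("click_depth", "loyalty", "recency", "feedback",
                  "interaction", "engagement_index")) {
      expect_true(all(scores[[col]] >= 0 & scores[[col]] <= 100),
                  label = sprintf("%s in [0,100] (seed %d)", col, seed))
    }
    expect_equal(scores$engagement_index,
                 rowMeans(scores[c("click_depth", "loyalty", "recency",
                                   "feedback", "interaction")]),
                 ignore_attr = TRUE)
    expect_true(all(scores$engagement_time_min >= 0))
  }
})

test_that("interaction subindices are invariant to rescaling a category's counts", {
  cohort <- tiny_cohort(n = 25, seed = 8)
  base <- score_cohort(cohort)
  # triple every comment by replicating comment events
  comments <- cohort$events[cohort$events$kind == "comment", ]
  cohort$events <- dplyr::bind_rows(cohort$events, comments, comments)
  tripled <- score_cohort(cohort)
  expect_equal(tripled$interaction, base$interaction)
  expect_equal(tripled$engagement_index, base$engagement_index)
})

test_that("scoring is invariant to participant order", {
  cohort <- tiny_cohort(n = 20, seed = 14)
  base <- score_cohort(cohort)
  set.seed(1)
  cohort$profiles <- cohort$profiles[sample(nrow(cohort$profiles)), ]
  cohort$sessions <- cohort$sessions[sample(nrow(cohort$sessions)), ]
  cohort$events <- cohort$events[sample(nrow(cohort$events)), ]
  permuted <- score_cohort(cohort)
  expect_equal(dplyr::arrange(permuted, participant_id),
               dplyr::arrange(base, participant_id),
               ignore_attr = TRUE)
})

test_that("a degenerate one-analyzable-participant cohort scores sensibly", {
  prof <- make_profiles("A")
  sess <- make_sessions("A", day = 0.5, dur_min = 3, pages = 2)
  surv <- make_survey("A", items = rep(3L, 20))
  ev <- make_events("A", c("comment", "rating"))
  cohort <- validate_log(prof, sess, surv, ev)
  s <- score_cohort(cohort)
  expect_equal(nrow(s), 1)
  expect_equal(s$loyalty, 0)                 # one-time visitor
  expect_equal(s$click_depth, 0)             # 2 pages < threshold 4
  expect_equal(s$recency, 100 / 28)          # single visit day
  expect_equal(s$feedback, 60)               # total 60 of 100
  expect_equal(s$interaction, 100 * 2 / 3)   # holds both nonzero maxima
  expect_equal(s$mileage, 200L)
})

test_that("participants without surveys or sessions are excluded and tracked", {
  prof <- make_profiles(c("A", "B", "C"))
  sess <- dplyr::bind_rows(make_sessions("A", day = c(0.5, 2.5)),
                           make_sessions("B", day = 1.5))
  surv <- dplyr::bind_rows(make_survey("A"), make_survey("C"))
  cohort <- validate_log(prof, sess, surv)
  s <- score_cohort(cohort)
  expect_equal(s$participant_id, "A")
  excl <- attr(s, "excluded")
  expect_setequal(excl$participant_id, c("B", "C"))
  expect_equal(excl$reason[excl$participant_id == "B"], "no post survey")
  expect_equal(excl$reason[excl$participant_id == "C"], "no sessions")
})

test_that("pooling vs splitting questions is a scoring switch", {
  cohort <- tiny_cohort(n = 25, seed = 8)
  pooled <- score_cohort(cohort, pool_questions = TRUE)
  split <- score_cohort(cohort, pool_questions = FALSE)
  expect_length(attr(pooled, "interaction_maxima"), 3)
  expect_length(attr(split, "interaction_maxima"), 4)
  expect_true(all(split$interaction >= 0 & split$interaction <= 100))
})
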