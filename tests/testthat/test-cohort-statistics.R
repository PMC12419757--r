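test_that("distribution diagnostics flag normal samples as normal", {
  set.seed(12)
  flags <- vapply(1:100, function(i) {
    diagnose_distribution(rnorm(1000), "x")$normality_flag
  }, logical(1))
  expect_gte(mean(flags), 0.95)
})

test_that("heavy right-skewed samples fail the joint normality criterion", {
  set.seed(13)
  d <- diagnose_distribution(exp(rnorm(500)), "t")
  expect_gt(d$skewness, 1)
  expect_false(d$normality_flag)
  expect_lt(d$ks_p, 0.05)
})

test_that("skewness negates exactly under reflection and degenerate input errors", {
  set.seed(14)
  x <- rexp(60)
  a <- diagnose_distribution(x)$skewness
  b <- diagnose_distribution(2 * mean(x) - x)$skewness
  expect_equal(a, -b)
  expect_error(diagnose_distribution(rep(3, 50)), "degenerate")
  expect_error(diagnose_distribution(rnorm(5)), "at least 8")
})

test_that("median and quartiles use linear interpolation with both IQR renderings", {
  m <- median_iqr(c(1, 2, 3))
  expect_equal(m$median, 2)
  expect_equal(median_iqr(rep(7, 9))$iqr_width, 0)
  x <- c(2, 4, 4, 5, 9, 11, 13)
  m <- median_iqr(x)
  expect_equal(m$median, unname(quantile(x, 0.5)))
  expect_equal(m$iqr_width, unname(diff(quantile(x, c(0.25, 0.75)))))
})

test_that("Mann-Whitney U equals the exhaustive cross-pair count on small groups", {
  brute_u <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  set.seed(15)
  for (rep in 1:30) {
    a <- sample(1:6, sample(2:8, 1), replace = TRUE)  # tie-heavy
    b <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(mann_whitney(a, b)$u, brute_u(a, b))
  }
})

test_that("Mann-Whitney p-values match the reference normal-approximation test", {
  set.seed(16)
  for (rep in 1:20) {
    a <- round(rnorm(sample(10:40, 1)), 1)
    b <- round(rnorm(sample(10:40, 1), mean = runif(1, 0, 1)), 1)
    mine <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$u, unname(ref$statistic))
  }
})

test_that("Mann-Whitney handles exchangeable, separated, and invalid inputs", {
  same <- mann_whitney(c(1, 2, 2, 5), c(5, 2, 1, 2))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  apart <- mann_whitney(rnorm(30) + 100, rnorm(30))
  expect_lt(apart$p_value, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney U is invariant under strictly monotone transforms", {
  set.seed(17)
  a <- rnorm(15); b <- rnorm(20)
  f <- function(x) exp(3 * x) + 1
  expect_equal(mann_whitney(a, b)$u, mann_whitney(f(a), f(b))$u)
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula on a small instance", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6, 7))
  n <- 7
  rbar <- c(mean(c(1, 2)), mean(c(3, 4)), mean(c(5, 6, 7)))
  h_hand <- 12 / (n * (n + 1)) *
    sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
  kw <- kruskal_wallis(groups)
  expect_equal(kw$h, h_hand)
  expect_equal(kw$df, 2)
})

test_that("Kruskal-Wallis is zero on identical groups and invariant to relabeling", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(g)$h, 0)
  groups <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  expect_equal(kruskal_wallis(groups)$h, kruskal_wallis(rev(groups))$h)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "at least 3")
  expect_error(kruskal_wallis(list(1:3, numeric(0), 4:6)), "nonempty")
})

test_that("Kruskal-Wallis holds its nominal size under a uniform null", {
  set.seed(18)
  reject <- vapply(1:500, function(i) {
    g <- split(runif(60), rep(1:4, each = 15))
    kruskal_wallis(g)$p_value < 0.05
  }, logical(1))
  se3 <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(reject) - 0.05), se3)
})

test_that("Spearman rho is exact under monotone association and matches the rank oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_assoc(x, exp(x))$rho, 1)
  expect_equal(spearman_assoc(x, -x)$rho, -1)
  set.seed(19)
  for (rep in 1:15) {
    a <- sample(1:5, 25, replace = TRUE)  # heavy ties
    b <- a + sample(1:5, 25, replace = TRUE)
    oracle <- cor(rank(a), rank(b))  # product-moment on mid-ranks
    expect_equal(spearman_assoc(a, b)$rho, oracle, tolerance = 1e-12)
  }
  expect_error(spearman_assoc(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_assoc(1:2, 2:1), "n >= 3")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(20)
  x <- rnorm(40); y <- x + rnorm(40)
  expect_equal(spearman_assoc(exp(x), y^3 - 100)$rho,
               spearman_assoc(x, y)$rho)
})

test_that("characteristic comparisons pick the right test and partition the cohort", {
  cohort <- generate_cohort(cohort_config(n_participants = 120, seed = 23))
  scores <- score_cohort(cohort)
  comp <- compare_by_characteristics(scores, cohort$profiles)
  expect_s3_class(comp, "mh_comparison")
  expect_equal(sort(unique(comp$tests$characteristic)),
               sort(names(characteristic_levels())))
  expect_equal(nrow(comp$tests), 8 * 2)
  binary <- comp$tests[comp$tests$characteristic == "self_help", ]
  expect_true(all(binary$statistic_label == "U/z"))
  multi <- comp$tests[comp$tests$characteristic == "age_group", ]
  expect_true(all(multi$statistic_label == "H"))
  g <- comp$groups[comp$groups$characteristic == "self_help" &
                     comp$groups$measure == "engagement_index", ]
  expect_equal(sum(g$n), nrow(scores))
  expect_true(all(comp$tests$p_value >= 0 & comp$tests$p_value <= 1))
})

test_that("empty categories are dropped with a warning", {
  cohort <- tiny_cohort(n = 30, seed = 4)
  cohort$profiles$economic_status <- rep(c("low", "middle"), 15)
  scores <- score_cohort(cohort)
  expect_warning(
    comp <- compare_by_characteristics(scores, cohort$profiles,
                                       measures = "engagement_index",
                                       characteristics = "economic_status"),
    "empty categor"
  )
  expect_equal(comp$tests$statistic_label, "U/z")  # 3-level fell back to 2
})

test_that("an injected self-help effect surfaces as that characteristic's p-value", {
  set.seed(24)
  hits <- vapply(1:20, function(r) {
    cohort <- generate_cohort(
      cohort_config(n_participants = 261, seed = 7000 + r,
                    selfhelp_effect = 0.3)
    )
    scores <- score_cohort(cohort)
    comp <- compare_by_characteristics(scores, cohort$profiles,
                                       measures = "engagement_index")
    t <- comp$tests
    t$p_value[t$characteristic == "self_help"] == min(t$p_value)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("optional p adjustment is available but off by default", {
  cohort <- tiny_cohort(n = 40, seed = 6)
  scores <- score_cohort(cohort)
  none <- compare_by_characteristics(scores, cohort$profiles)
  expect_equal(none$p_adjust_method, "none")
  expect_equal(none$tests$p_adjusted, none$tests$p_value)
  holm <- compare_by_characteristics(scores, cohort$profiles,
                                     p_adjust = "holm")
  expect_true(all(holm$tests$p_adjusted >= holm$tests$p_value))
})
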