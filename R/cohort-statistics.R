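# Nonparametric cohort statistics: distribution diagnostics, median/IQR
# summaries, Mann-Whitney U (tie-corrected normal approximation reporting U
# and z), Kruskal-Wallis, Spearman rank correlation, and the per-
# characteristic comparison table.

#' Distribution diagnostics for a continuous engagement measure
#'
#' One-sample Kolmogorov-Smirnov test against a normal with the sample mean
#' and SD, plus the bias-corrected sample skewness. The normality flag is the
#' joint criterion used to choose between parametric and nonparametric
#' comparisons: it is `FALSE` when the KS p-value falls below `alpha` or
#' |skewness| exceeds 1.
#'
#' @param values Numeric vector, n >= 8, not constant.
#' @param variable Label carried into the output.
#' @param alpha Significance level for the KS test (default 0.05).
#' @return Tibble row: `variable`, `n`, `ks_statistic`, `ks_p`, `skewness`,
#'   `normality_flag`.
#' @export
diagnose_distribution <- function(values, variable = "value", alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 8) {
    stop("diagnose_distribution() needs at least 8 observations", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("degenerate distribution: '", variable, "' is constant", call. = FALSE)
  }
  # ties are expected in engagement data; the KS p-value is still the usual
  # screening statistic, so silence the ties warning
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
  )
  skew <- e1071::skewness(values, type = 2)
  tibble::tibble(
    variable = variable,
    n = length(values),
    ks_statistic = unname(ks$statistic),
    ks_p = ks$p.value,
    skewness = skew,
    normality_flag = ks$p.value >= alpha && abs(skew) <= 1
  )
}

#' Median and interquartile range
#'
#' Quartiles by the linear-interpolation convention (R type 7), so the median
#' of an odd-sized sample is an observed value and monotone transforms
#' commute with the median. Reports both the quartile bounds and the IQR
#' width, matching the two ways engagement tables print "median (IQR)".
#'
#' @param values Numeric vector, n >= 1.
#' @return Tibble row: `n`, `median`, `q1`, `q3`, `iqr_width`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("median_iqr() needs data", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 iqr_width = q[3] - q[1])
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Two-sided two-group comparison reporting the U statistic for `group_a`
#' (the number of cross-pairs where `a > b`, counting ties as 1/2), the z
#' value from the normal approximation with tie-corrected variance and a
#' continuity correction of 1/2, and the two-sided p-value. This is the
#' U/z/p triple that engagement comparison tables print.
#'
#' @param group_a,group_b Numeric vectors, both nonempty.
#' @return Tibble row: `n_a`, `n_b`, `u`, `z`, `p_value`.
#' @export
#' @examples
#' mann_whitney(c(1, 5, 7), c(2, 3, 9))
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("mann_whitney() needs two nonempty groups", call. = FALSE)
  }
  n_a <- length(group_a); n_b <- length(group_b); n <- n_a + n_b
  r <- rank(c(group_a, group_b))  # mid-ranks for ties
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 == 0) {
    z <- 0; p <- 1  # all observations identical
  } else {
    cc <- sign(u - mu) * 0.5
    z <- (u - mu - cc) / sqrt(sigma2)
    if (u == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  tibble::tibble(n_a = n_a, n_b = n_b, u = u, z = z, p_value = p)
}

#' Kruskal-Wallis test
#'
#' Multi-group (k >= 3) rank comparison: the tie-corrected H statistic with a
#' chi-squared reference on k - 1 degrees of freedom, as implemented in
#' [stats::kruskal.test()].
#'
#' @param groups List of >= 3 nonempty numeric vectors.
#' @return Tibble row: `k`, `n`, `h`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stop("kruskal_wallis() needs at least 3 groups; use mann_whitney() for 2",
         call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("kruskal_wallis() groups must all be nonempty", call. = FALSE)
  }
  n <- sum(lengths(groups))
  if (n < 5) stop("kruskal_wallis() needs total n >= 5", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  tibble::tibble(k = length(groups), n = n, h = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value)
}

#' Spearman rank correlation
#'
#' Product-moment correlation of mid-ranks (average ranks for ties) with a
#' two-sided p-value from the t approximation, via
#' [stats::cor.test()] with `method = "spearman", exact = FALSE`.
#'
#' @param x,y Paired numeric vectors, n >= 3, neither constant.
#' @return Tibble row: `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("spearman_assoc() needs n >= 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: one variable is constant", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Compare engagement measures across participant characteristics
#'
#' For each characteristic, splits the scored cohort into its categories and
#' compares each engagement measure across them: Mann-Whitney U for binary
#' characteristics, Kruskal-Wallis for three or more categories. Categories
#' with no participants are dropped with a warning. No multiple-testing
#' adjustment is applied by default (each characteristic is reported as its
#' own unadjusted test, as such engagement tables are conventionally
#' printed); set `p_adjust` to `"holm"` or `"BH"` to adjust within each
#' measure.
#'
#' @param summaries Scored cohort from [score_cohort()].
#' @param profiles Profile tibble supplying the characteristics.
#' @param measures Columns of `summaries` to compare.
#' @param characteristics Characteristics to use (default all eight).
#' @param p_adjust Method for [stats::p.adjust()] (default `"none"`).
#' @return Object of class `mh_comparison`: a list with `groups` (one row per
#'   characteristic x measure x category: n, median, quartiles) and `tests`
#'   (one row per characteristic x measure: `statistic_label` "U/z" or "H",
#'   the statistics, `p_value`, and `p_adjust_method`).
#' @export
compare_by_characteristics <- function(summaries, profiles,
                                       measures = c("engagement_index",
                                                    "engagement_time_min"),
                                       characteristics = names(characteristic_levels()),
                                       p_adjust = "none") {
  data <- dplyr::inner_join(summaries, profiles, by = "participant_id")
  levels_all <- characteristic_levels()
  group_rows <- list()
  test_rows <- list()

  for (m in measures) {
    for (ch in characteristics) {
      lv <- levels_all[[ch]]
      present <- lv[lv %in% data[[ch]]]
      dropped <- setdiff(lv, present)
      if (length(dropped)) {
        warning(sprintf("characteristic '%s': empty categor%s %s dropped",
                        ch, if (length(dropped) > 1) "ies" else "y",
                        paste(dropped, collapse = ", ")), call. = FALSE)
      }
      values <- lapply(present, function(g) data[[m]][data[[ch]] == g])
      for (i in seq_along(present)) {
        mi <- median_iqr(values[[i]])
        group_rows[[length(group_rows) + 1]] <- tibble::tibble(
          characteristic = ch, measure = m, category = present[i],
          n = mi$n, median = mi$median, q1 = mi$q1, q3 = mi$q3,
          iqr_width = mi$iqr_width
        )
      }
      if (length(present) < 2) next
      if (length(present) == 2) {
        mw <- mann_whitney(values[[1]], values[[2]])
        test_rows[[length(test_rows) + 1]] <- tibble::tibble(
          characteristic = ch, measure = m, statistic_label = "U/z",
          u = mw$u, z = mw$z, h = NA_real_, df = NA_real_,
          p_value = mw$p_value
        )
      } else {
        kw <- kruskal_wallis(values)
        test_rows[[length(test_rows) + 1]] <- tibble::tibble(
          characteristic = ch, measure = m, statistic_label = "H",
          u = NA_real_, z = NA_real_, h = kw$h, df = kw$df,
          p_value = kw$p_value
        )
      }
    }
  }
  tests <- dplyr::bind_rows(test_rows)
  if (nrow(tests)) {
    tests <- dplyr::group_by(tests, .data$measure)
    tests <- dplyr::mutate(tests,
                           p_adjusted = stats::p.adjust(.data$p_value,
                                                        method = p_adjust))
    tests <- dplyr::ungroup(tests)
  }
  structure(
    list(groups = dplyr::bind_rows(group_rows), tests = tests,
         p_adjust_method = p_adjust),
    class = "mh_comparison"
  )
}

#' @export
print.mh_comparison <- function(x, ...) {
  cat("<mh_comparison>\n")
  cat(sprintf("  %d tests over %d group rows (p adjustment: %s)\n",
              nrow(x$tests), nrow(x$groups), x$p_adjust_method))
  print(x$tests, n = Inf)
  invisible(x)
}
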