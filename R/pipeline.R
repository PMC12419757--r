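# End-to-end pipeline: simulate -> validate -> score -> analyze -> report,
# with CSV as the interchange format so each stage is independently testable
# and re-runnable from disk.

#' Run the engagement-evaluation pipeline
#'
#' Stages:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort and write the cohort files}
#'   \item{score}{read the cohort, validate it, write the per-participant
#'     engagement summary CSV}
#'   \item{analyze}{write the daily-active-user curve, distribution
#'     diagnostics, index-time Spearman correlation, and the per-
#'     characteristic comparison tables}
#'   \item{report}{render the comparison as a Markdown table}
#'   \item{all}{all of the above in order}
#' }
#' Every output file starts with a comment header recording the seed and a
#' hash of the configuration, so a run can be re-identified and reproduced;
#' with a fixed seed, repeated runs produce byte-identical files.
#'
#' @param subcommand One of `"all"`, `"simulate"`, `"score"`, `"analyze"`,
#'   `"report"`.
#' @param config An `mh_cohort_config` (used by `simulate`; its
#'   `window_days` applies throughout).
#' @param out_dir Directory for all artifacts.
#' @param seed Optional seed override for the simulation stage.
#' @param threshold Click-depth page-view threshold.
#' @param alpha Significance level used in diagnostics.
#' @param report_style `"width"` renders median (IQR width); `"bounds"`
#'   renders median (q1-q3).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "score", "analyze",
                                        "report"),
                         config = default_cohort_config(),
                         out_dir = "mhengage-run",
                         seed = NULL,
                         threshold = 4L,
                         alpha = 0.05,
                         report_style = c("width", "bounds")) {
  subcommand <- match.arg(subcommand)
  report_style <- match.arg(report_style)
  if (!is.null(seed)) config$seed <- seed
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("mhengage seed=%d config=%s", as.integer(config$seed),
                   rlang::hash(unclass(config)))
  results <- list()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  if (subcommand %in% c("all", "simulate")) {
    results$cohort <- stage("simulate", {
      cohort <- generate_cohort(config)
      write_cohort(cohort, out_dir, stamp)
      cohort
    })
  }

  if (subcommand %in% c("all", "score")) {
    results$summaries <- stage("score", {
      cohort <- results$cohort %||% read_cohort(out_dir, config$window_days)
      results$cohort <- cohort
      summaries <- score_cohort(cohort, threshold = threshold)
      write_csv_stamped(summaries, file.path(out_dir, "engagement_summary.csv"),
                        stamp)
      excl <- attr(summaries, "excluded")
      if (nrow(excl)) {
        write_csv_stamped(excl, file.path(out_dir, "excluded.csv"), stamp)
      }
      summaries
    })
  }

  if (subcommand %in% c("all", "analyze")) {
    results <- stage("analyze", {
      cohort <- results$cohort %||% read_cohort(out_dir, config$window_days)
      summaries <- results$summaries %||%
        read_csv_stamped(file.path(out_dir, "engagement_summary.csv"))
      dau <- daily_active_users(cohort$sessions, cohort$profiles,
                                cohort$window_days)
      write_csv_stamped(dau, file.path(out_dir, "daily_active_users.csv"),
                        stamp)
      diagnostics <- dplyr::bind_rows(
        diagnose_distribution(summaries$engagement_index, "engagement_index",
                              alpha),
        diagnose_distribution(summaries$engagement_time_min,
                              "engagement_time_min", alpha)
      )
      write_csv_stamped(diagnostics,
                        file.path(out_dir, "distribution_diagnostics.csv"),
                        stamp)
      correlation <- spearman_assoc(summaries$engagement_index,
                                    summaries$engagement_time_min)
      write_csv_stamped(correlation, file.path(out_dir, "correlation.csv"),
                        stamp)
      comparison <- compare_by_characteristics(summaries, cohort$profiles)
      write_csv_stamped(comparison$groups,
                        file.path(out_dir, "comparison_groups.csv"), stamp)
      write_csv_stamped(comparison$tests,
                        file.path(out_dir, "comparison_tests.csv"), stamp)
      c(results, list(dau = dau, diagnostics = diagnostics,
                      correlation = correlation, comparison = comparison))
    })
  }

  if (subcommand %in% c("all", "report")) {
    results$report <- stage("report", {
      comparison <- results$comparison %||% list(
        groups = read_csv_stamped(file.path(out_dir, "comparison_groups.csv")),
        tests = read_csv_stamped(file.path(out_dir, "comparison_tests.csv"))
      )
      lines <- render_comparison_markdown(comparison, style = report_style,
                                          stamp = stamp)
      writeLines(lines, file.path(out_dir, "comparison_report.md"))
      lines
    })
  }

  invisible(results)
}

#' Render a characteristics comparison as a Markdown table
#'
#' One row per category with its n, "median (IQR)" per measure, and the test
#' statistic and p-value on the characteristic's header row — the layout
#' engagement studies print. `style = "width"` shows the IQR as the single
#' width `q3 - q1`; `"bounds"` shows `q1-q3`.
#'
#' @param comparison An `mh_comparison` (or a list with `groups`/`tests`).
#' @param style `"width"` or `"bounds"`.
#' @param stamp Optional provenance line placed in a comment at the top.
#' @return Character vector of Markdown lines.
#' @export
render_comparison_markdown <- function(comparison,
                                       style = c("width", "bounds"),
                                       stamp = NULL) {
  style <- match.arg(style)
  groups <- comparison$groups
  tests <- comparison$tests
  measures <- unique(groups$measure)
  fmt_iqr <- function(median, q1, q3) {
    if (style == "width") sprintf("%.1f (%.1f)", median, q3 - q1)
    else sprintf("%.1f (%.1f-%.1f)", median, q1, q3)
  }
  fmt_stat <- function(row) {
    if (!nrow(row)) return("")
    if (row$statistic_label == "U/z") sprintf("%.1f/%.2f", row$u, row$z)
    else sprintf("%.2f", row$h)
  }
  lines <- character()
  if (!is.null(stamp)) lines <- c(lines, paste0("<!-- ", stamp, " -->"), "")
  header <- c("Variable", "n (%)")
  for (m in measures) header <- c(header, paste(m, c("median (IQR)", "stat", "p")))
  lines <- c(lines,
             paste0("| ", paste(header, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"))
  total_n <- sum(groups$n[groups$characteristic == groups$characteristic[1] &
                            groups$measure == measures[1]])
  for (ch in unique(groups$characteristic)) {
    row <- c(sprintf("**%s**", ch), "")
    for (m in measures) {
      t <- tests[tests$characteristic == ch & tests$measure == m, ]
      row <- c(row, "", fmt_stat(t),
               if (nrow(t)) sprintf("%.3f", t$p_value) else "")
    }
    lines <- c(lines, paste0("| ", paste(row, collapse = " | "), " |"))
    g1 <- groups[groups$characteristic == ch & groups$measure == measures[1], ]
    for (cat in g1$category) {
      gr <- g1[g1$category == cat, ]
      row <- c(cat, sprintf("%d (%.1f)", gr$n, 100 * gr$n / total_n))
      for (m in measures) {
        gm <- groups[groups$characteristic == ch & groups$measure == m &
                       groups$category == cat, ]
        row <- c(row, fmt_iqr(gm$median, gm$q1, gm$q3), "", "")
      }
      lines <- c(lines, paste0("| ", paste(row, collapse = " | "), " |"))
    }
  }
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
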