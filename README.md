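# mhengage

Engagement evaluation for mobile-health (mHealth) app usage logs.

mHealth trials — for example app-based self-management support for people
living with HIV — need to quantify *how engaged* participants were, because
engagement conditions effectiveness. `mhengage` implements a composite
**engagement index**: five subindices of session-structured usage logs and a
post-intervention usability survey, each normalized to 0–100 and averaged,

| subindex | formula (per participant) |
|---|---|
| click depth | % of sessions with ≥ 4 page views |
| loyalty | 100 · (1 − 1/n_sessions) |
| recency | 100 · min(1, 1 / mean days between visit days) |
| feedback | usability-survey total (20 items, 1–5) out of 100 |
| interaction | mean of comment/question/rating counts over cohort maxima, ×100 |

together with **engagement time** (cumulative minutes of use in the 28-day
window, with boundary truncation and overlap merging), daily-active-user
curves, and in-app reward ("mileage") accounting. An analysis layer supplies
the nonparametric statistics these studies report: Kolmogorov–Smirnov +
skewness distribution diagnostics, Mann–Whitney U with the tie-corrected
U/z/p triple, Kruskal–Wallis, Spearman rank correlation, and a
per-characteristic comparison table. A seeded synthetic cohort generator
emulates the data structure (overdispersed session counts, right-skewed
engagement time, left-skewed engagement index) so the whole pipeline is
testable without any data deposit.

## Worked example

Simulate a 261-participant cohort with a strong self-help-group engagement
shift, score it, and compare:

```r
library(mhengage)

cohort <- generate_cohort(cohort_config(seed = 7, selfhelp_effect = 0.2))
scores <- score_cohort(cohort)
scores
#> # A tibble: 255 × 10
#>   participant_id click_depth loyalty recency feedback interaction ...
#> 1 P0001                 74      98      96.3       70      21.2
#> 2 P0002                 95.2    95.2    37.5       47      17.4
#> ...
```

255 of 261 participants are analyzable (the rest never opened the app; they
are listed in `attr(scores, "excluded")`). Each row carries the five
subindices, their mean (`engagement_index`), `engagement_time_min`,
`n_sessions` and `mileage`. Comparing the index across self-help group
participation:

```r
comp <- compare_by_characteristics(scores, cohort$profiles)
comp$groups[comp$groups$characteristic == "self_help" &
            comp$groups$measure == "engagement_index", ]
#>   characteristic measure          category     n median    q1    q3 iqr_width
#> 1 self_help      engagement_index yes         74   71.4  64.2  75.1      10.9
#> 2 self_help      engagement_index no         181   66.9  59.5  71.9      12.4
comp$tests[comp$tests$characteristic == "self_help" &
           comp$tests$measure == "engagement_index", c("statistic_label", "u", "z", "p_value")]
#>   statistic_label     u     z  p_value
#> 1 U/z              8771  3.88 0.000105
```

The self-help group's median index (71.4) exceeds the non-participants'
(66.9), and the Mann–Whitney U/z test flags the injected shift. The index
and engagement time correlate positively but imperfectly
(`spearman_assoc(scores$engagement_index, scores$engagement_time_min)`
gives ρ = 0.214, p = 0.0006 here) — they capture distinct aspects of engagement and are
meant to be read together.

The whole chain (simulate → validate → score → analyze → report, with CSV
artifacts and a Markdown comparison table) runs as:

```r
run_pipeline("all", config = default_cohort_config(seed = 7), out_dir = "run")
```

or from the shell via `Rscript inst/cli/mhengage-pipeline.R all --seed 7
--out-dir run`. See the vignette
(`vignettes/engagement-evaluation.Rmd`) for the model, the generator's
calibration, and the conventions chosen where the index formulas are
under-determined.

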