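# toxconcord

Concordance analysis of short-term versus long-term repeat-dose toxicity
studies.

In a nonclinical safety package, long-term (chronic, ≥ 26 week) studies are
run late, cost the most animals, and — the 3Rs question this package serves —
may add little beyond what the short-term (≤ 6 w) and mid-term (6–20 w)
studies already showed. `toxconcord` is for preclinical toxicologists and
safety data scientists who have study-level finding data and want to
quantify, per finding category and species group, how well the early
studies predict the chronic ones.

The package harmonizes findings into high-level categories via controlled
terminology, summarizes per-compound overall adversity, classifies NOAEL
progression between phases, and treats the short/mid-phase observation of
each finding as a diagnostic test for the long phase. Counting molecules
gives a 2×2 table per high-level finding *f* and species group —

|                    | seen long-term | not seen long-term |
|--------------------|----------------|--------------------|
| **seen short/mid** | TP             | FP                 |
| **not seen**       | FN             | TN                 |

— from which it computes sensitivity `Se = TP/(TP+FN)`, specificity
`Sp = TN/(FP+TN)`, the positive likelihood ratio

```
+LR  = Se / (1 − Sp)            (> 5: early finding strongly predicts late finding)
iLR− = Sp / (1 − Se)            (> 5: early absence strongly predicts late absence)
```

Fisher's exact test per table (one-sided positive-association by default;
two-sided available), the evidential bins (>10 large, 5–10 moderate, 2–5
small, 1–2 rarely important), and the miss-prediction frequencies
`%FP = 100·FP/N`, `%FN = 100·FN/N`. Infinite ratios from zero cells are
reported as `Inf`, not continuity-corrected. A seeded synthetic-cohort
generator with the same schema (and closed-form expected likelihood ratios)
makes the whole pipeline testable without proprietary data.

See `vignettes/concordance-methods.Rmd` for the model, its assumptions and
the design decisions.

## Worked example

```r
library(toxconcord)

ds <- read_dataset(toxconcord_example("example_studies.txt"),
                   toxconcord_example("example_findings.txt"))
ds
#> <tox_dataset>
#>   molecules: 2 (1 small, 1 large)
#>   studies:   7 (4 short/mid, 3 long)
#>   findings:  9

tm <- load_terminology(toxconcord_example("finding_terms_synthetic.csv"),
                       toxconcord_example("organ_systems_synthetic.csv"))
ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))

overall_adversity(ds)
#> # A tibble: 2 × 5
#>   molecule_id modality adverse_short_mid adverse_long concordant
#> 1 MOL-B       large    no                no           TRUE
#> 2 MOL-A       small    yes               yes          TRUE
```

MOL-A's adverse liver and neurological findings appear in both phases
(concordant "yes"); MOL-B never shows an adverse finding (concordant "no").
`noael_comparison(ds)` reports, per molecule and species group, the lowest
identified per-day NOAEL of each phase and its change class — for MOL-A in
rodents 15 → 15 mg/kg/day, i.e. `same`.

The contingency statistics work directly on cell counts. Taking the
non-rodent liver table (7, 5, 1, 29) from the packaged reference rows:

```r
r <- subset(reference_contingency_rows(),
            finding == "liver" & species_group == "non_rodent")
format_lr(plus_lr(r$tp, r$fp, r$fn, r$tn))            #> "5.95"
format_lr(inv_neg_lr(r$tp, r$fp, r$fn, r$tn))         #> "6.82"
format_p(fisher_exact_p(r$tp, r$fp, r$fn, r$tn))      #> "0"
```

A `+LR` of 5.95 means a liver finding in a short/mid study raises the odds
of a chronic-study liver finding about six-fold; the p-value below 0.005
displays as "0". On a simulated cohort the full analysis runs end-to-end:

```r
sim <- simulate_dataset(sim_spec(seed = 1))
sim$findings <- aggregate_high_level(apply_terminology(sim$findings, tm))
res <- concordance_analysis(build_presence_matrix(sim, scope = "all"))
format_concordance_table(res)
#> # A tibble: 22 × 9
#>   finding          TP    FP    FN    TN plus_lr inv_neg_lr p_value species_group
#> 1 eye_conjunct…     4     0     1    35 Inf     5          0       non_rodent
#> 2 nervous_syst…     3     0     1    36 Inf     4          0       non_rodent
#> 3 neurological…    10     2     1    27 13.18   10.24      0       non_rodent
#> 4 body_weight_…    15     2     0    23 12.5    Inf        0       non_rodent
#> ...
```

Only rows significant at `alpha = 0.05` are kept, matching the reporting
convention of published concordance tables; `run_pipeline(run_config(...))`
writes all result tables, FP/FN frequency figures and run metadata to an
output directory in one call.

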