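# The synthetic-cohort generator: schema closure, determinism, and agreement
# between analytic and sampled likelihood ratios.

test_that("simulated cohorts are reproducible and schema-closed", {
  tm <- fixture_map()
  spec <- sim_spec(n_small = 6, n_large = 4, seed = 99)
  a <- simulate_dataset(spec, map = tm)
  b <- simulate_dataset(spec, map = tm)
  expect_equal(a$studies, b$studies)
  expect_equal(a$findings, b$findings)
  expect_equal(a$ground_truth, b$ground_truth)

  # write/read round trip re-validates every row with zero diagnostics
  dir <- withr::local_tempdir()
  paths <- write_dataset(a, dir)
  back <- read_dataset(paths[1], paths[2])
  expect_equal(nrow(diagnostics(back)), 0)
  expect_equal(nrow(back$studies), nrow(a$studies))
  expect_equal(nrow(back$findings), nrow(a$findings))
  # every molecule satisfies the inclusion rule by construction
  expect_silent(toxconcord:::check_inclusion(back, strict = TRUE))
  # NOAELs sit on the per-day dose ladder
  noaels <- a$studies$noael_dose_per_day
  expect_true(all(is.na(noaels) | noaels %in% sim_spec()$dose_ladder))
})

test_that("degenerate specs are rejected", {
  expect_error(sim_spec(finding_probs = tibble::tibble(
    label = "liver", p11 = 0.5, p10 = 0.5, p01 = 0.2, p00 = 0
  )), "sum to 1")
  expect_error(sim_spec(n_small = 0, n_large = 0), "molecules")
  expect_error(sim_spec(dose_ladder = c(10, 5)), "increasing")
  expect_error(expected_lr(sim_spec(), "no_such_finding"), "no_such_finding")
})

test_that("zero off-diagonal probabilities force infinite ratios", {
  probs <- tibble::tibble(label = "liver", p11 = 0.3, p10 = 0,
                          p01 = 0, p00 = 0.7)
  spec <- sim_spec(n_small = 20, n_large = 0, finding_probs = probs,
                   seed = 12)
  exp <- expected_lr(spec, "liver")
  expect_equal(exp$plus_lr, Inf)
  expect_equal(exp$inv_neg_lr, Inf)
  tm <- fixture_map()
  ds <- simulate_dataset(spec, map = tm)
  ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))
  res <- concordance_analysis(build_presence_matrix(ds, scope = "all"))
  expect_true(all(res$FP == 0))
  expect_true(all(res$FN == 0))
  liv <- res[res$finding == "liver", ]
  expect_true(all(liv$plus_lr == Inf | is.nan(liv$plus_lr)))
})

test_that("analytic LR limits: perfect concordance and independence", {
  probs <- tibble::tibble(label = "x", p11 = 0.5, p10 = 0, p01 = 0, p00 = 0.5)
  spec <- sim_spec(finding_probs = probs)
  expect_equal(expected_lr(spec, "x"),
               list(plus_lr = Inf, inv_neg_lr = Inf))
  probs <- tibble::tibble(label = "x", p11 = 0.25, p10 = 0.25,
                          p01 = 0.25, p00 = 0.25)
  spec <- sim_spec(finding_probs = probs)
  expect_equal(expected_lr(spec, "x"), list(plus_lr = 1, inv_neg_lr = 1))
})

test_that("analytic LR formula matches a large direct Monte-Carlo draw", {
  p <- c(p11 = 0.2, p10 = 0.05, p01 = 0.05, p00 = 0.7)
  spec <- sim_spec(finding_probs = tibble::tibble(
    label = "x", p11 = p[1], p10 = p[2], p01 = p[3], p00 = p[4]
  ))
  exp <- expected_lr(spec, "x")
  # closed form cross-checked against 1e6 categorical draws
  set.seed(123)
  draw <- sample.int(4, 1e6, replace = TRUE, prob = p)
  tp <- sum(draw == 1); fp <- sum(draw == 2)
  fn <- sum(draw == 3); tn <- sum(draw == 4)
  expect_equal(exp$plus_lr, plus_lr(tp, fp, fn, tn), tolerance = 0.02)
  expect_equal(exp$inv_neg_lr, inv_neg_lr(tp, fp, fn, tn), tolerance = 0.02)
  # and the exact closed form
  expect_equal(exp$plus_lr, (0.2 / 0.25) / (0.05 / 0.75))
  expect_equal(exp$inv_neg_lr, (0.7 / 0.75) / (0.05 / 0.25))
})

test_that("independent presence gives null Fisher tests and LR near 1", {
  # p11 = pS * pL etc: no association between phases
  pS <- 0.4; pL <- 0.35
  probs <- tibble::tibble(
    label = "git_clinical_signs",
    p11 = pS * pL, p10 = pS * (1 - pL),
    p01 = (1 - pS) * pL, p00 = (1 - pS) * (1 - pL)
  )
  tm <- fixture_map()
  pvals <- numeric(200)
  cells <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (r in 1:200) {
    spec <- sim_spec(n_small = 30, n_large = 0, finding_probs = probs,
                     seed = 1000 + r)
    ds <- simulate_dataset(spec, map = tm)
    ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))
    res <- concordance_analysis(build_presence_matrix(ds, scope = "all"))
    # pool both species groups of the replicate
    cells <- cells + c(TP = sum(res$TP), FP = sum(res$FP),
                       FN = sum(res$FN), TN = sum(res$TN))
    pvals[r] <- fisher_exact_p(sum(res$TP), sum(res$FP), sum(res$FN),
                               sum(res$TN))
  }
  # one-sided exact p-values under the null are stochastically >= uniform
  expect_lte(mean(pvals < 0.05), 0.10)
  expect_gte(mean(pvals), 0.40)
  # pooled over 200 replicates the empirical LR approaches 1
  expect_equal(plus_lr(cells[["TP"]], cells[["FP"]], cells[["FN"]],
                       cells[["TN"]]), 1, tolerance = 0.1)
  expect_equal(inv_neg_lr(cells[["TP"]], cells[["FP"]], cells[["FN"]],
                          cells[["TN"]]), 1, tolerance = 0.1)
})
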