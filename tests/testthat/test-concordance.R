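# Contingency cells, likelihood ratios, Fisher test, frequencies, bins.

test_that("contingency cells follow the presence definitions", {
  # 3 molecules: both phases, short-only, neither
  pm <- structure(
    tibble::tibble(
      molecule_id = c("M1", "M2", "M3"),
      species_group = "rodent",
      label = "liver",
      present_short_mid = c(TRUE, TRUE, FALSE),
      present_long = c(TRUE, FALSE, FALSE)
    ),
    scope = "all", labels = "liver",
    universe = tibble::tibble(species_group = "rodent",
                              molecule_id = c("M1", "M2", "M3")),
    class = c("presence_matrix", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(build_contingency(pm, "liver", "rodent"),
               c(TP = 1L, FP = 1L, FN = 0L, TN = 1L))
  expect_error(build_contingency(pm, "kidney", "rodent"), "kidney")
})

test_that("contingency builder equals brute-force counting on random data", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    pm <- structure(
      tidyr::crossing(
        tibble::tibble(molecule_id = sprintf("M%02d", 1:n)),
        species_group = c("rodent", "non_rodent"),
        label = c("liver", "gi_tract")
      ),
      scope = "all", labels = c("liver", "gi_tract"),
      class = c("presence_matrix", "tbl_df", "tbl", "data.frame")
    )
    pm$present_short_mid <- runif(nrow(pm)) < 0.4
    pm$present_long <- runif(nrow(pm)) < 0.4
    for (g in c("rodent", "non_rodent")) {
      for (lab in c("liver", "gi_tract")) {
        expect_equal(build_contingency(pm, lab, g),
                     oracle_contingency(pm, lab, g))
      }
    }
  }
})

test_that("likelihood ratios reproduce hand-checked tables and edge cases", {
  expect_equal(plus_lr(6, 3, 2, 31), 8.5)
  expect_equal(plus_lr(4, 1, 2, 23), 16)
  expect_equal(plus_lr(2, 0, 3, 37), Inf)      # zero false positives
  expect_equal(round(inv_neg_lr(2, 0, 3, 37), 2), 1.67)
  expect_equal(round(inv_neg_lr(7, 5, 1, 29), 2), 6.82)
  expect_equal(inv_neg_lr(2, 1, 0, 39), Inf)   # zero false negatives
  # undefined when a margin is empty
  expect_true(is.nan(plus_lr(0, 0, 0, 10)))
  expect_true(is.nan(plus_lr(0, 3, 0, 10)))    # sensitivity margin empty
  expect_true(is.nan(inv_neg_lr(3, 0, 2, 0)))  # specificity margin empty
  expect_error(plus_lr(-1, 0, 0, 1), "non-negative")
})

test_that("ratio definition matches the count formula and its reciprocal", {
  set.seed(11)
  for (i in 1:200) {
    cells <- as.integer(sample(0:12, 4, replace = TRUE))
    tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
    lr <- plus_lr(tp, fp, fn, tn)
    alt <- (tp * (fp + tn)) / (fp * (tp + fn))
    if (is.finite(lr)) expect_equal(lr, alt, tolerance = 1e-12)
    # the inverse negative LR is the reciprocal of the plain negative LR
    # (FN*(FP+TN)) / (TN*(TP+FN))
    ilr <- inv_neg_lr(tp, fp, fn, tn)
    neg <- (fn * (fp + tn)) / (tn * (tp + fn))
    if (is.finite(ilr) && ilr > 0) expect_equal(ilr * neg, 1, tolerance = 1e-12)
  }
})

test_that("plus_lr never decreases as TP grows at fixed FP, FN, TN", {
  for (fp in c(1, 3)) {
    for (fn in c(0, 2)) {
      vals <- plus_lr(0:15, fp, fn, 20)
      vals <- vals[!is.nan(vals)]  # tp = fn = 0 leaves the ratio undefined
      expect_true(all(diff(vals) >= 0))
    }
  }
})

test_that("Fisher p matches the enumeration oracle and its symmetries", {
  # perfectly balanced table: no association two-sided; one-sided upper
  # tail still carries the P(TP >= 1) = 5/6 mass
  expect_equal(fisher_exact_p(1, 1, 1, 1, alternative = "two.sided"), 1)
  expect_equal(fisher_exact_p(1, 1, 1, 1), 5 / 6, tolerance = 1e-9)
  # frozen oracle values for the hand-checked tables
  expect_equal(oracle_fisher(6, 3, 2, 31), 0.000393, tolerance = 1e-2)
  expect_lt(fisher_exact_p(6, 3, 2, 31, alternative = "two.sided"), 0.01)
  expect_equal(fisher_exact_p(3, 5, 1, 33, alternative = "two.sided"),
               oracle_fisher(3, 5, 1, 33), tolerance = 1e-9)
  expect_lt(fisher_exact_p(3, 5, 1, 33, alternative = "two.sided"), 0.05)
  set.seed(21)
  for (i in 1:50) {
    cells <- sample(0:8, 4, replace = TRUE)
    for (alt in c("two.sided", "greater")) {
      p <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4],
                          alternative = alt)
      expect_gte(p, 0)
      expect_lte(p, 1)
      expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4],
                                    alternative = alt),
                   tolerance = 1e-9)
      # simultaneous swap of rows and columns preserves the association
      expect_equal(p, fisher_exact_p(cells[4], cells[3], cells[2], cells[1],
                                     alternative = alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("FP/FN frequencies and their display truncation", {
  expect_equal(pct_fp(2, 2, 1, 25), 100 * 2 / 30)
  expect_equal(format_pct(pct_fp(2, 2, 1, 25)), "6.6")  # not rounded to 6.7
  expect_equal(format_pct(pct_fn(2, 2, 1, 25)), "3.3")
  expect_equal(format_pct(100 * 1 / 42), "2.3")          # 2.38 truncates
  expect_equal(pct_fp(0, 0, 0, 10), 0)
  expect_equal(pct_fn(0, 0, 0, 10), 0)
  expect_true(is.nan(pct_fp(0, 0, 0, 0)))
  # the three frequencies always account for the whole universe
  set.seed(13)
  for (i in 1:100) {
    cells <- sample(0:20, 4, replace = TRUE)
    if (sum(cells) == 0) next
    total <- 100 * (cells[1] + cells[4]) / sum(cells)
    expect_equal(pct_fp(cells[1], cells[2], cells[3], cells[4]) +
                   pct_fn(cells[1], cells[2], cells[3], cells[4]) + total,
                 100, tolerance = 1e-9)
  }
})

test_that("interpretation bins partition the likelihood-ratio scale", {
  expect_equal(
    interpret_lr(c(Inf, 26, 8.5, 5, 2.87, 2, 1.5, 1, 0.4)),
    c("large", "large", "moderate", "moderate", "small", "small",
      "rarely_important", "none", "none")
  )
  expect_true(is.na(interpret_lr(NaN)))
  # every positive value lands in exactly one bin
  vals <- c(10^seq(-2, 3, length.out = 101), Inf)
  expect_false(anyNA(interpret_lr(vals)))
})

test_that("display formatting rounds half-up and flags tiny p as 0", {
  expect_equal(format_lr(c(5.952, 6.8235, 3.90625, 3.647)),
               c("5.95", "6.82", "3.91", "3.65"))
  expect_equal(format_lr(Inf), "Inf")
  expect_equal(format_p(c(0.0176, 0.0004, 0.0355)), c("0.02", "0", "0.04"))
})

test_that("a perfectly concordant finding is infinite on both ratios", {
  # 40 molecules, one finding present in both phases for 5, absent for 35
  pm <- structure(
    tibble::tibble(
      molecule_id = sprintf("M%02d", 1:40),
      species_group = "non_rodent",
      label = "nervous_system",
      present_short_mid = c(rep(TRUE, 5), rep(FALSE, 35)),
      present_long = c(rep(TRUE, 5), rep(FALSE, 35))
    ),
    scope = "adverse", labels = "nervous_system",
    universe = tibble::tibble(species_group = "non_rodent",
                              molecule_id = sprintf("M%02d", 1:40)),
    class = c("presence_matrix", "tbl_df", "tbl", "data.frame")
  )
  res <- concordance_analysis(pm)
  expect_equal(res$TP, 5)
  expect_equal(res$TN, 35)
  expect_equal(res$plus_lr, Inf)
  expect_equal(res$inv_neg_lr, Inf)
  expect_true(res$significant)
  expect_equal(res$fisher_p, oracle_fisher(5, 0, 0, 35, "greater"),
               tolerance = 1e-9)
  expect_equal(res$interpretation_plus, "large")
  # alpha = 0 admits nothing
  expect_equal(nrow(significant_rows(concordance_analysis(pm, alpha = 0))), 0)
})

test_that("analysis rows cover every label x group with cells summing right", {
  tm <- fixture_map()
  ds <- simulate_dataset(sim_spec(n_small = 12, n_large = 8, seed = 29),
                         map = tm)
  ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))
  pm <- build_presence_matrix(ds, scope = "all")
  res <- concordance_analysis(pm)
  u <- attr(pm, "universe")
  for (g in unique(u$species_group)) {
    rows <- res[res$species_group == g, ]
    expect_equal(nrow(rows), length(attr(pm, "labels")))
    expect_true(all(rows$TP + rows$FP + rows$FN + rows$TN ==
                      sum(u$species_group == g)))
  }
  expect_equal(res$significant, res$fisher_p < 0.05)
  expect_equal(res$high_plus_lr,
               !is.na(res$plus_lr) & res$plus_lr > 5)
})
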