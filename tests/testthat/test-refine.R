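# Duration classes, species groups, dose normalization, high-level labels
# and the presence matrix.

test_that("duration classification is total with exact boundaries", {
  expect_equal(classify_duration(4), "short")
  expect_equal(classify_duration(13), "mid")
  expect_equal(classify_duration(26), "long")
  expect_equal(classify_duration(22), "unclassified")
  # boundaries: 6 is still short, 20 falls into the undefined gap, 26 is long
  expect_equal(
    classify_duration(c(6, 6.01, 19.99, 20, 25.9, 26)),
    c("short", "mid", "mid", "unclassified", "unclassified", "long")
  )
  expect_error(classify_duration(0), "positive")
  expect_error(classify_duration(-3), "positive")
  # piecewise-constant and total on a grid over (0, 40]
  grid <- seq(0.1, 40, by = 0.1)
  cls <- classify_duration(grid)
  expect_true(all(cls %in% c("short", "mid", "long", "unclassified")))
  expect_true(all(diff(match(cls, c("short", "mid", "unclassified", "long"))) >= 0))
})

test_that("species grouping is case- and whitespace-insensitive", {
  expect_equal(group_species("rat"), "rodent")
  expect_equal(group_species("cynomolgus monkey"), "non_rodent")
  expect_equal(group_species("Rat "), "rodent")
  expect_equal(
    group_species(c("Mouse", "DOG", "minipig", "marmoset")),
    c("rodent", "non_rodent", "non_rodent", "non_rodent")
  )
  expect_error(group_species("ferret"), "known species")
  expect_error(group_species(""), "non-empty")
  # configurable synonym list
  syn <- rbind(default_species_synonyms(),
               data.frame(species = "goettingen minipig",
                          species_group = "non_rodent"))
  expect_equal(group_species("Goettingen Minipig", synonyms = syn), "non_rodent")
})

test_that("dose normalization multiplies by administrations per day", {
  expect_equal(normalize_dose(10, 1), 10)
  expect_equal(normalize_dose(10, 2), 20)
  expect_equal(normalize_dose(10, 0.5), 5)   # every-other-day dosing
  expect_error(normalize_dose(-1, 1), ">= 0")
  expect_error(normalize_dose(10, 0), "> 0")
})

test_that("every finding gets exactly one high-level label", {
  tm <- fixture_map()
  ds <- simulate_dataset(sim_spec(n_small = 6, n_large = 4, seed = 3), map = tm)
  out <- aggregate_high_level(apply_terminology(ds$findings, tm))
  expect_false(anyNA(out$high_level))
  # partition: post-mortem rows carry organ-system labels, body-weight rows
  # the merged label, clinical rows their own category
  pm <- out$category %in% postmortem_categories()
  bw <- out$category %in% bodyweight_categories()
  expect_true(all(out$high_level[pm] %in% unique(tm$organ_map$target_organ_system)))
  expect_true(all(out$high_level[bw] == "body_weight_changes"))
  expect_equal(out$high_level[!pm & !bw], out$category[!pm & !bw])
  # clinical records keep an empty organ system
  expect_true(all(is.na(out$target_organ_system[!pm])))
})

test_that("high-level label examples: organ system, body weight, clinical", {
  tm <- fixture_map()
  f <- tibble::tibble(
    study_id = "S1",
    category = c("organ_weights", "body_weight_gain",
                 "neurological_clinical_signs"),
    raw_term = c("decrease", "decrease", "tremors"),
    organ = c("liver", NA, NA),
    adverse = FALSE, onset_dose_per_day = NA_real_,
    severity = NA_character_, reversibility = NA_character_,
    notes = NA_character_
  )
  out <- aggregate_high_level(apply_terminology(f, tm))
  expect_equal(out$high_level,
               c("liver", "body_weight_changes", "neurological_clinical_signs"))
  # a post-mortem record with an unknown organ cannot be aggregated
  f$organ[1] <- "flux capacitor"
  expect_error(aggregate_high_level(apply_terminology(f, tm)),
               "flux capacitor")
})

test_that("presence matrix follows scope and phase definitions", {
  # one molecule, rodent: adverse liver finding in the 4-w study only,
  # non-adverse liver finding in the 26-w study
  ds <- make_ds(
    data.frame(molecule_id = "M1", species = "rat",
               duration_weeks = c(4, 26)),
    data.frame(study = c(1L, 2L), category = "microscopic",
               raw_term = "necrosis", organ = "liver",
               adverse = c(TRUE, FALSE))
  )
  tm <- fixture_map()
  ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))
  adverse <- build_presence_matrix(ds, scope = "adverse")
  liv <- adverse[adverse$label == "liver", ]
  expect_true(liv$present_short_mid)
  expect_false(liv$present_long)
  all_sc <- build_presence_matrix(ds, scope = "all")
  liv <- all_sc[all_sc$label == "liver", ]
  expect_true(liv$present_short_mid && liv$present_long)
})

test_that("molecules missing a phase are excluded from the group universe", {
  # M1 complete in rodents; M2 has no rodent long-term study but is complete
  # in non-rodents; a 22-w study counts for neither phase
  ds <- make_ds(
    data.frame(
      molecule_id = c("M1", "M1", "M2", "M2", "M2", "M2"),
      species = c("rat", "rat", "rat", "dog", "dog", "dog"),
      duration_weeks = c(4, 26, 4, 4, 22, 26)
    ),
    data.frame(study = 5L, category = "git_clinical_signs",
               raw_term = "emesis", organ = NA, adverse = TRUE)
  )
  tm <- fixture_map()
  ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))
  pm <- suppressMessages(build_presence_matrix(ds, scope = "all"))
  u <- attr(pm, "universe")
  expect_equal(u$molecule_id[u$species_group == "rodent"], "M1")
  expect_equal(u$molecule_id[u$species_group == "non_rodent"], "M2")
  # the 22-w study is outside both phases: its finding counts nowhere
  git <- pm[pm$label == "git_clinical_signs" & pm$molecule_id == "M2", ]
  expect_false(any(git$present_short_mid))
})

test_that("presence matrix equals sampled truth and brute-force recount", {
  tm <- fixture_map()
  spec <- sim_spec(n_small = 8, n_large = 6, seed = 17)
  ds <- simulate_dataset(spec, map = tm)
  ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))
  pm <- build_presence_matrix(ds, scope = "all")

  # ground truth: the generator's sampled presence indicators
  truth <- ds$ground_truth$presence
  key <- function(d) paste(d$molecule_id, d$species_group, d$label)
  idx <- match(key(pm), key(truth))
  expect_false(anyNA(idx))
  expect_equal(pm$present_short_mid, truth$present_short_mid[idx])
  expect_equal(pm$present_long, truth$present_long[idx])

  # independent brute-force double loop over all finding records
  st <- ds$studies
  for (scope in c("all", "adverse", "non_adverse")) {
    pms <- build_presence_matrix(ds, scope = scope)
    bf <- oracle_presence(st, ds$findings, attr(pms, "universe"),
                          attr(pms, "labels"), scope)
    idx <- match(key(pms), key(bf))
    expect_equal(pms$present_short_mid, bf$present_short_mid[idx])
    expect_equal(pms$present_long, bf$present_long[idx])
  }
})

test_that("presence is monotone in scope", {
  tm <- fixture_map()
  ds <- simulate_dataset(sim_spec(n_small = 10, n_large = 5, seed = 23),
                         map = tm)
  ds$findings <- aggregate_high_level(apply_terminology(ds$findings, tm))
  all_sc <- build_presence_matrix(ds, scope = "all")
  for (scope in c("adverse", "non_adverse")) {
    sub <- build_presence_matrix(ds, scope = scope)
    expect_equal(nrow(sub), nrow(all_sc))
    expect_true(all(all_sc$present_short_mid[sub$present_short_mid]))
    expect_true(all(all_sc$present_long[sub$present_long]))
  }
})
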