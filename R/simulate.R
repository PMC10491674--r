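# Seeded synthetic-cohort generator. Emulates the schema and statistical
# structure the analysis assumes: molecules x species groups x studies x
# findings, with per-finding joint presence probabilities across the two
# phases, an adverse fraction, and a NOAEL dose ladder.

#' Default per-finding joint presence probabilities
#'
#' One row per high-level finding label with the joint probability, per
#' molecule and species group, of the finding being present in
#' (short/mid, long) phases: `p11` both, `p10` short/mid only, `p01` long
#' only, `p00` neither. The defaults are chosen to resemble a repeat-dose
#' toxicity cohort in which post-mortem liver, lymphoid and body-weight
#' findings are common and mostly concordant between phases, while rarer
#' systems (eye, nervous) have low prevalence.
#'
#' @return A tibble with columns `label`, `p11`, `p10`, `p01`, `p00`.
#' @export
default_finding_probs <- function() {
  tibble::tribble(
    ~label,                        ~p11, ~p10, ~p01, ~p00,
    "liver",                        0.17, 0.12, 0.02, 0.69,
    "lymphoid_tissues",             0.19, 0.17, 0.05, 0.59,
    "endocrine_system",             0.20, 0.10, 0.03, 0.67,
    "gi_tract",                     0.17, 0.07, 0.13, 0.63,
    "urinary_system",               0.07, 0.10, 0.05, 0.78,
    "reproductive_system",          0.13, 0.03, 0.07, 0.77,
    "nervous_system",               0.05, 0.02, 0.02, 0.91,
    "eye_conjunctiva",              0.05, 0.00, 0.07, 0.88,
    "cutaneous",                    0.10, 0.05, 0.07, 0.78,
    "body_weight_changes",          0.33, 0.17, 0.00, 0.50,
    "neurological_clinical_signs",  0.14, 0.07, 0.05, 0.74,
    "git_clinical_signs",           0.24, 0.07, 0.05, 0.64,
    "cardiovascular",               0.07, 0.12, 0.02, 0.79,
    "other_clinical_signs",         0.17, 0.10, 0.19, 0.54
  )
}

#' Specification for a synthetic toxicity-study cohort
#'
#' Defines the cohort the generator draws: molecule counts per modality
#' (default 25 small and 18 large, the size of a typical concordance cohort),
#' which species groups each molecule is tested in, study durations per
#' phase, per-finding joint presence probabilities, the adverse fraction
#' among materialized findings, and the NOAEL dose ladder with phase-shift
#' probabilities.
#'
#' @param n_small,n_large Number of small/large molecules.
#' @param p_group Probability a molecule is tested in each species group, per
#'   modality: list with elements `small` and `large`, each
#'   `c(rodent = , non_rodent = )`. Molecules drawing no group are assigned
#'   their modality's most likely group.
#' @param p_mid_study Probability a molecule x group has a mid-term study in
#'   addition to the short-term one.
#' @param finding_probs Tibble as [default_finding_probs()]; rows must sum
#'   to 1.
#' @param adverse_fraction Probability a materialized finding is adverse.
#' @param dose_ladder Increasing per-day dose levels; NOAELs take these
#'   values.
#' @param dose_units Dose unit string carried on every study.
#' @param p_noael_shift Probabilities `c(decrease = , same = , increase = )`
#'   of the long-phase NOAEL moving down/staying/moving up one ladder step.
#' @param p_noael_missing Probability a phase fails to establish a NOAEL.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list with class `"sim_spec"`.
#' @export
sim_spec <- function(n_small = 25,
                     n_large = 18,
                     p_group = list(
                       small = c(rodent = 0.96, non_rodent = 0.90),
                       large = c(rodent = 0.33, non_rodent = 0.94)
                     ),
                     p_mid_study = 0.5,
                     finding_probs = default_finding_probs(),
                     adverse_fraction = 0.3,
                     dose_ladder = c(5, 15, 50, 150),
                     dose_units = "mg/kg/day",
                     p_noael_shift = c(decrease = 0.25, same = 0.55, increase = 0.20),
                     p_noael_missing = 0.1,
                     seed = 1L) {
  pr <- finding_probs[, c("p11", "p10", "p01", "p00")]
  if (any(pr < 0) || any(pr > 1)) {
    stop("finding probabilities must be in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(pr) - 1) > 1e-8)) {
    stop("p11 + p10 + p01 + p00 must sum to 1 for every finding",
         call. = FALSE)
  }
  if (n_small + n_large < 1) stop("cohort must contain molecules", call. = FALSE)
  if (is.unsorted(dose_ladder, strictly = TRUE) || any(dose_ladder <= 0)) {
    stop("dose_ladder must be strictly increasing and positive", call. = FALSE)
  }
  structure(
    list(
      n_small = n_small, n_large = n_large, p_group = p_group,
      p_mid_study = p_mid_study, finding_probs = finding_probs,
      adverse_fraction = adverse_fraction, dose_ladder = dose_ladder,
      dose_units = dose_units, p_noael_shift = p_noael_shift,
      p_noael_missing = p_noael_missing, seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec> ", x$n_small, " small + ", x$n_large, " large molecules, ",
      nrow(x$finding_probs), " finding labels, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Analytic likelihood ratios implied by a simulation spec
#'
#' Closed form from the joint presence probabilities of one finding:
#' `plus_lr = [p11/(p11+p01)] / [p10/(p10+p00)]` and
#' `inv_neg_lr = [p00/(p10+p00)] / [p01/(p11+p01)]`. Zero denominators give
#' infinite or undefined values under the same conventions as [plus_lr()].
#'
#' @param spec A [sim_spec()].
#' @param finding A finding label present in `spec$finding_probs`.
#' @return List with `plus_lr` and `inv_neg_lr`.
#' @export
#' @examples
#' expected_lr(sim_spec(), "liver")
expected_lr <- function(spec, finding) {
  stopifnot(inherits(spec, "sim_spec"))
  row <- spec$finding_probs[spec$finding_probs$label == finding, ]
  if (nrow(row) != 1) {
    stop("unknown finding label: '", finding, "'", call. = FALSE)
  }
  sens <- unname(row$p11 / (row$p11 + row$p01))
  fpr <- unname(row$p10 / (row$p10 + row$p00))
  spc <- unname(row$p00 / (row$p10 + row$p00))
  fnr <- unname(row$p01 / (row$p11 + row$p01))
  list(plus_lr = sens / fpr, inv_neg_lr = spc / fnr)
}

#' Simulate a synthetic toxicity-study dataset
#'
#' Draws a full cohort from a [sim_spec()]: studies (with species, durations,
#' dose ladder and NOAELs) and finding records whose raw terms are sampled
#' from the packaged synthetic terminology fixtures, so the terminology and
#' aggregation steps are exercised end-to-end. The result passes
#' [read_dataset()] validation (schema closure; see [write_dataset()] for the
#' round trip) and carries the sampled ground truth.
#'
#' @param spec A [sim_spec()].
#' @param map Terminology map used to materialize raw terms and organs;
#'   defaults to the packaged synthetic fixtures.
#' @return A `tox_dataset` with an extra `ground_truth` element: `presence`
#'   (molecule x group x label presence indicators actually sampled),
#'   `noael` (per molecule x group phase NOAELs), and `seed`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_spec(seed = 42))
#' ds
simulate_dataset <- function(spec = sim_spec(), map = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(map)) {
    map <- load_terminology(
      toxconcord_example("finding_terms_synthetic.csv"),
      toxconcord_example("organ_systems_synthetic.csv")
    )
  }
  set.seed(spec$seed)

  mols <- tibble::tibble(
    molecule_id = c(
      sprintf("SM-%04d", seq_len(spec$n_small)),
      sprintf("LM-%04d", seq_len(spec$n_large))
    ),
    modality = c(rep("small", spec$n_small), rep("large", spec$n_large))
  )
  areas <- c(
    "neurosciences", "oncology", "immunology", "cardiovascular & metabolism",
    "infectious diseases", "ophthalmology"
  )
  mols$therapeutic_area <- sample(areas, nrow(mols), replace = TRUE)

  # species-group membership; a molecule drawing no group gets the most
  # likely one for its modality, so every molecule is tested somewhere
  p_rod <- vapply(mols$modality, function(m) spec$p_group[[m]][["rodent"]],
                  numeric(1))
  p_non <- vapply(mols$modality, function(m) spec$p_group[[m]][["non_rodent"]],
                  numeric(1))
  in_rod <- stats::runif(nrow(mols)) < p_rod
  in_non <- stats::runif(nrow(mols)) < p_non
  none <- !in_rod & !in_non
  in_rod[none] <- p_rod[none] >= p_non[none]
  in_non[none] <- !in_rod[none]

  cells <- dplyr::bind_rows(
    dplyr::mutate(mols[in_rod, ], species_group = "rodent"),
    dplyr::mutate(mols[in_non, ], species_group = "non_rodent")
  ) |>
    dplyr::arrange(.data$molecule_id, .data$species_group)
  nc <- nrow(cells)

  u <- stats::runif(nc)
  cells$species <- ifelse(
    cells$species_group == "rodent",
    ifelse(u < 0.9, "rat", "mouse"),
    ifelse(cells$modality == "large",
           ifelse(u < 0.9, "cynomolgus monkey", "dog"),
           ifelse(u < 0.6, "cynomolgus monkey",
                  ifelse(u < 0.95, "dog", "minipig")))
  )
  cells$d_short <- sample(c(2, 4), nc, replace = TRUE, prob = c(0.3, 0.7))
  cells$has_mid <- stats::runif(nc) < spec$p_mid_study
  cells$d_long <- sample(c(26, 39), nc, replace = TRUE, prob = c(0.7, 0.3))

  k <- length(spec$dose_ladder)
  sm_idx <- sample.int(k, nc, replace = TRUE)
  shift <- sample(c(-1L, 0L, 1L), nc, replace = TRUE,
                  prob = spec$p_noael_shift)
  long_idx <- pmin(pmax(sm_idx + shift, 1L), k)
  cells$noael_short_mid <- ifelse(stats::runif(nc) < spec$p_noael_missing,
                                  NA_real_, spec$dose_ladder[sm_idx])
  cells$noael_long <- ifelse(stats::runif(nc) < spec$p_noael_missing,
                             NA_real_, spec$dose_ladder[long_idx])

  phase_rows <- function(dur, noael, which_cells) {
    cc <- cells[which_cells, ]
    tibble::tibble(
      molecule_id = cc$molecule_id, modality = cc$modality,
      species = cc$species, species_group = cc$species_group,
      duration_weeks = dur[which_cells],
      therapeutic_area = cc$therapeutic_area,
      noael_dose_per_day = noael[which_cells]
    )
  }
  st <- dplyr::bind_rows(
    phase_rows(cells$d_short, cells$noael_short_mid, rep(TRUE, nc)),
    phase_rows(rep(13, nc), cells$noael_short_mid, cells$has_mid),
    phase_rows(cells$d_long, cells$noael_long, rep(TRUE, nc))
  )
  ns <- nrow(st)
  st$study_id <- sprintf("ST-%05d", seq_len(ns))
  st$route <- ifelse(st$modality == "large", "intravenous", "oral gavage")
  split_dose <- stats::runif(ns) < 0.1
  st$administrations_per_day <- ifelse(split_dose, 2, 1)
  st$dose_levels <- lapply(st$administrations_per_day,
                           function(a) spec$dose_ladder / a)
  st$dose_per_day_levels <- rep(list(spec$dose_ladder), ns)
  st$duration_class <- classify_duration(st$duration_weeks)
  st$dose_units <- spec$dose_units
  studies <- st[, c(
    "study_id", "molecule_id", "modality", "species", "species_group",
    "duration_weeks", "duration_class", "therapeutic_area", "route",
    "dose_levels", "administrations_per_day", "dose_per_day_levels",
    "noael_dose_per_day", "dose_units"
  )]
  studies$phase <- study_phase(studies)

  presence <- sample_presence(spec, studies)
  findings <- materialize_findings(spec, studies, presence, map)

  ds <- new_tox_dataset(
    studies[, setdiff(names(studies), "phase")],
    findings,
    provenance = list(
      source = "simulate_dataset", seed = spec$seed,
      n_study_rows = nrow(studies), n_finding_rows = nrow(findings),
      diagnostics = new_diag()
    )
  )
  ds$ground_truth <- list(
    presence = presence,
    noael = cells[, c("molecule_id", "species_group", "noael_short_mid",
                      "noael_long")],
    seed = spec$seed
  )
  ds
}

# joint presence indicators per molecule x group x label
sample_presence <- function(spec, studies) {
  cells <- dplyr::distinct(studies, .data$molecule_id, .data$species_group)
  grid <- tidyr::crossing(cells, label = spec$finding_probs$label)
  pr <- as.matrix(spec$finding_probs[
    match(grid$label, spec$finding_probs$label),
    c("p11", "p10", "p01", "p00")
  ])
  # inverse-CDF draw of the joint cell, vectorized over the grid
  u <- stats::runif(nrow(grid))
  cum <- pr %*% upper.tri(diag(4), diag = TRUE)
  draw <- 1L + rowSums(u > cum)  # in 1..4: 11, 10, 01, 00
  grid$present_short_mid <- draw %in% c(1L, 2L)
  grid$present_long <- draw %in% c(1L, 3L)
  grid
}

# turn presence indicators into finding records attached to concrete studies
materialize_findings <- function(spec, studies, presence, map) {
  om <- map$organ_map
  systems <- split(om$organ, om$target_organ_system)
  terms_by_cat <- split(map$term_map$raw_term, map$term_map$category)

  known <- c(names(systems), BODY_WEIGHT_LABEL, clinical_categories())
  bad <- setdiff(unique(presence$label), known)
  if (length(bad) > 0) {
    stop("finding label(s) not materializable from the terminology map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  hits <- dplyr::bind_rows(
    dplyr::mutate(presence[presence$present_short_mid, ], phase = "short_mid"),
    dplyr::mutate(presence[presence$present_long, ], phase = "long")
  )
  n <- nrow(hits)
  if (n == 0) {
    return(tibble::tibble(
      study_id = character(), category = character(), raw_term = character(),
      organ = character(), adverse = logical(),
      onset_dose_per_day = numeric(), severity = character(),
      reversibility = character(), notes = character()
    ))
  }

  # random study of the right molecule/group/phase for each finding
  skey <- paste(studies$molecule_id, studies$species_group, studies$phase)
  lookup <- split(studies$study_id, skey)
  hkey <- paste(hits$molecule_id, hits$species_group, hits$phase)
  hits$study_id <- vapply(hkey, function(k) {
    cand <- lookup[[k]]
    cand[sample.int(length(cand), 1)]
  }, character(1), USE.NAMES = FALSE)

  is_system <- hits$label %in% names(systems)
  is_bw <- hits$label == BODY_WEIGHT_LABEL
  category <- hits$label
  category[is_system] <- sample(postmortem_categories(), sum(is_system),
                                replace = TRUE)
  category[is_bw] <- sample(bodyweight_categories(), sum(is_bw),
                            replace = TRUE)

  organ <- rep(NA_character_, n)
  for (lab in unique(hits$label[is_system])) {
    idx <- which(is_system & hits$label == lab)
    organ[idx] <- sample(systems[[lab]], length(idx), replace = TRUE)
  }
  term <- character(n)
  for (cat_i in unique(category)) {
    idx <- which(category == cat_i)
    term[idx] <- sample(terms_by_cat[[cat_i]], length(idx), replace = TRUE)
  }
  # perturb capitalization sometimes: exercises case-insensitive lookup
  flip <- stats::runif(n) < 0.3
  term[flip] <- paste0(toupper(substr(term[flip], 1, 1)),
                       substr(term[flip], 2, nchar(term[flip])))

  tibble::tibble(
    study_id = hits$study_id,
    category = category,
    raw_term = term,
    organ = organ,
    adverse = stats::runif(n) < spec$adverse_fraction,
    onset_dose_per_day = sample(spec$dose_ladder, n, replace = TRUE),
    severity = sample(c("minimal", "mild", "moderate", NA_character_), n,
                      replace = TRUE),
    reversibility = sample(c("reversible", "not reversible", NA_character_),
                           n, replace = TRUE),
    notes = NA_character_
  )
}
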