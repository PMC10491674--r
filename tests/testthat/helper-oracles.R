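# Independent oracles used to cross-check the package's statistics. These
# deliberately share no code with the implementation.

# Exact Fisher p by direct enumeration of the hypergeometric distribution at
# fixed margins. Two-sided: sum of point probabilities not exceeding the
# observed one (with a relative tie tolerance); greater: upper tail of the
# TP cell.
oracle_fisher <- function(tp, fp, fn, tn, alternative = "two.sided") {
  r1 <- tp + fp
  c1 <- tp + fn
  n <- tp + fp + fn + tn
  if (n == 0) return(1)
  x <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(x, c1, n - c1, r1)
  obs <- stats::dhyper(tp, c1, n - c1, r1)
  if (alternative == "greater") {
    sum(probs[x >= tp])
  } else {
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
}

# Brute-force contingency cells from a presence matrix by looping molecules.
oracle_contingency <- function(pm, label, group) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pm))) {
    if (pm$label[i] != label || pm$species_group[i] != group) next
    s <- pm$present_short_mid[i]
    l <- pm$present_long[i]
    if (s && l) tp <- tp + 1L
    else if (s && !l) fp <- fp + 1L
    else if (!s && l) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Brute-force presence from raw records: for every universe molecule x group
# x label x phase, scan all finding records for a hit in a study of that
# molecule/group/phase matching the scope.
oracle_presence <- function(studies, findings, universe, labels, scope) {
  phase <- ifelse(studies$duration_class %in% c("short", "mid"), "short_mid",
                  ifelse(studies$duration_class == "long", "long", NA))
  out <- list()
  for (r in seq_len(nrow(universe))) {
    mol <- universe$molecule_id[r]
    grp <- universe$species_group[r]
    for (lab in labels) {
      hit <- c(short_mid = FALSE, long = FALSE)
      for (i in seq_len(nrow(findings))) {
        f <- findings[i, ]
        if (f$high_level != lab) next
        if (scope == "adverse" && !f$adverse) next
        if (scope == "non_adverse" && f$adverse) next
        j <- which(studies$study_id == f$study_id)
        if (studies$molecule_id[j] != mol || studies$species_group[j] != grp) next
        if (is.na(phase[j])) next
        hit[[phase[j]]] <- TRUE
      }
      out[[length(out) + 1]] <- data.frame(
        molecule_id = mol, species_group = grp, label = lab,
        present_short_mid = hit[["short_mid"]], present_long = hit[["long"]]
      )
    }
  }
  do.call(rbind, out)
}

fixture_map <- function() {
  load_terminology(
    toxconcord_example("finding_terms_synthetic.csv"),
    toxconcord_example("organ_systems_synthetic.csv")
  )
}

reference_rows <- function() reference_contingency_rows()

# delta-method standard error of log(LR+) / log(iLR-) at expected counts;
# used to decide, a priori, which labels a Monte-Carlo recovery check has
# the power to test at a 10% relative-error bound
loglr_se <- function(p11, p10, p01, p00, n, which = c("plus", "inv_neg")) {
  which <- match.arg(which)
  tp <- n * p11; fp <- n * p10; fn <- n * p01; tn <- n * p00
  v <- if (which == "plus") {
    1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)
  } else {
    1 / tn - 1 / (fp + tn) + 1 / fn - 1 / (tp + fn)
  }
  sqrt(v)
}

# Build a minimal in-memory dataset from compact study/finding descriptions.
# studies: data.frame with molecule_id, species, duration_weeks (+ optional
# modality, noael); findings: study index, category, raw_term, organ, adverse.
make_ds <- function(studies, findings = NULL) {
  n <- nrow(studies)
  st <- tibble::tibble(
    study_id = sprintf("S%02d", seq_len(n)),
    molecule_id = studies$molecule_id,
    modality = studies$modality %||% rep("small", n),
    species = studies$species,
    species_group = group_species(studies$species),
    duration_weeks = studies$duration_weeks,
    duration_class = classify_duration(studies$duration_weeks),
    therapeutic_area = NA_character_,
    route = NA_character_,
    dose_levels = rep(list(numeric(0)), n),
    administrations_per_day = rep(1, n),
    dose_per_day_levels = rep(list(numeric(0)), n),
    noael_dose_per_day = studies$noael %||% rep(NA_real_, n),
    dose_units = studies$dose_units %||% rep("mg/kg/day", n)
  )
  if (is.null(findings)) {
    fd <- tibble::tibble(
      study_id = character(), category = character(), raw_term = character(),
      organ = character(), adverse = logical(),
      onset_dose_per_day = numeric(), severity = character(),
      reversibility = character(), notes = character()
    )
  } else {
    m <- nrow(findings)
    fd <- tibble::tibble(
      study_id = st$study_id[findings$study],
      category = findings$category,
      raw_term = findings$raw_term,
      organ = findings$organ %||% rep(NA_character_, m),
      adverse = findings$adverse,
      onset_dose_per_day = rep(NA_real_, m),
      severity = rep(NA_character_, m),
      reversibility = rep(NA_character_, m),
      notes = rep(NA_character_, m)
    )
  }
  toxconcord:::new_tox_dataset(st, fd, provenance = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
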