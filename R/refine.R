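# Data refinement: duration classes, species groups, per-day doses,
# controlled terminology, high-level finding labels and presence matrices.

#' Classify a study duration into short / mid / long
#'
#' Repeat-dose studies of at most 6 weeks are short-term, more than 6 and less
#' than 20 weeks mid-term, and at least 26 weeks long-term. Durations of 20 to
#' under 26 weeks fall outside all three definitions and are returned as
#' `"unclassified"`; such studies take part in neither analysis phase.
#'
#' @param duration_weeks Positive numeric vector of study durations in weeks.
#' @return Character vector: `"short"`, `"mid"`, `"long"` or `"unclassified"`.
#' @export
#' @examples
#' classify_duration(c(4, 13, 26, 22))
classify_duration <- function(duration_weeks) {
  if (any(is.na(duration_weeks)) || any(duration_weeks <= 0)) {
    stop("duration_weeks must be positive", call. = FALSE)
  }
  dplyr::case_when(
    duration_weeks <= 6 ~ "short",
    duration_weeks < 20 ~ "mid",
    duration_weeks >= 26 ~ "long",
    TRUE ~ "unclassified"
  )
}

#' Default species synonym table
#'
#' Maps the common in-vivo test species to the rodent / non-rodent grouping:
#' rat and mouse are rodents; cynomolgus monkey, dog, minipig and marmoset are
#' non-rodents. Matching in [group_species()] is case-insensitive after
#' whitespace normalization.
#'
#' @return A tibble with columns `species` and `species_group`.
#' @export
default_species_synonyms <- function() {
  tibble::tribble(
    ~species,            ~species_group,
    "rat",               "rodent",
    "mouse",             "rodent",
    "cynomolgus monkey", "non_rodent",
    "cynomolgus",        "non_rodent",
    "monkey",            "non_rodent",
    "dog",               "non_rodent",
    "beagle dog",        "non_rodent",
    "minipig",           "non_rodent",
    "marmoset",          "non_rodent"
  )
}

#' Group a species into rodent / non-rodent
#'
#' @param species Character vector of species names.
#' @param synonyms Synonym table as in [default_species_synonyms()].
#' @return Character vector of `"rodent"` / `"non_rodent"`.
#' @export
#' @examples
#' group_species(c("rat", "Cynomolgus Monkey", "dog"))
group_species <- function(species, synonyms = default_species_synonyms()) {
  if (any(is.na(species)) || any(trimws(species) == "")) {
    stop("species must be non-empty", call. = FALSE)
  }
  idx <- match(norm_key(species), norm_key(synonyms$species))
  if (anyNA(idx)) {
    stop(
      "unknown species: ",
      paste(unique(species[is.na(idx)]), collapse = ", "),
      "; known species: ",
      paste(synonyms$species, collapse = ", "),
      call. = FALSE
    )
  }
  synonyms$species_group[idx]
}

#' Normalize a dose to a per-day amount
#'
#' Dosing intervals differ between studies (once daily, twice daily, every
#' other day, ...); doses are therefore expressed per day before comparison:
#' `dose_per_day = dose_amount * administrations_per_day`, with e.g.
#' `administrations_per_day = 0.5` for every-other-day dosing. No conversion
#' across dose units is attempted.
#'
#' @param dose_amount Non-negative dose per administration.
#' @param administrations_per_day Positive administrations per day.
#' @return Dose per day, in the same units as `dose_amount`.
#' @export
#' @examples
#' normalize_dose(10, 2)    # twice daily -> 20/day
#' normalize_dose(10, 0.5)  # every other day -> 5/day
normalize_dose <- function(dose_amount, administrations_per_day) {
  if (any(dose_amount < 0, na.rm = TRUE)) {
    stop("dose_amount must be >= 0", call. = FALSE)
  }
  if (any(administrations_per_day <= 0, na.rm = TRUE)) {
    stop("administrations_per_day must be > 0", call. = FALSE)
  }
  dose_amount * administrations_per_day
}

# Analysis phase of each study: short and mid pool into the "test" phase.
# pooling = "short_mid" (default), "short_only" or "mid_only".
study_phase <- function(studies, pooling = "short_mid") {
  dc <- studies$duration_class
  test <- switch(pooling,
    short_mid = dc %in% c("short", "mid"),
    short_only = dc == "short",
    mid_only = dc == "mid",
    stop("unknown phase pooling: ", pooling, call. = FALSE)
  )
  dplyr::case_when(
    test ~ "short_mid",
    dc == "long" ~ "long",
    TRUE ~ NA_character_
  )
}

#' Apply controlled terminology to finding records
#'
#' Fills `controlled_term` for every finding via the per-category term map,
#' and `target_organ_system` for the post-mortem categories (macroscopic,
#' microscopic, organ weights) via the organ map. Lookup is case-insensitive
#' and whitespace-normalized. Terms absent from the map either raise an error
#' (`unmapped_policy = "error"`) or keep the raw term as controlled term
#' (`"keep_raw"`, the default); unmapped terms and organs are reported in the
#' `"unmapped"` attribute of the result either way.
#'
#' @param findings Findings tibble of a `tox_dataset`.
#' @param map A [load_terminology()] map.
#' @param unmapped_policy `"keep_raw"` or `"error"`.
#' @return The findings with `controlled_term` and `target_organ_system`
#'   columns; unmapped report in `attr(, "unmapped")`.
#' @export
apply_terminology <- function(findings, map,
                              unmapped_policy = c("keep_raw", "error")) {
  unmapped_policy <- match.arg(unmapped_policy)
  stopifnot(inherits(map, "terminology_map"))

  key <- paste(norm_key(findings$category), norm_key(findings$raw_term), sep = "\r")
  idx <- match(key, map$term_map$key)
  controlled <- map$term_map$controlled_term[idx]

  pm <- findings$category %in% postmortem_categories()
  oidx <- match(norm_key(findings$organ), map$organ_map$key)
  system <- ifelse(pm, map$organ_map$target_organ_system[oidx], NA_character_)

  unmapped_terms <- dplyr::distinct(
    findings[is.na(idx), c("category", "raw_term")]
  )
  unmapped_organs <- unique(findings$organ[pm & is.na(oidx)])

  if (unmapped_policy == "error") {
    if (nrow(unmapped_terms) > 0) {
      stop(
        "unmapped finding term(s): ",
        paste(paste0(unmapped_terms$category, ": '", unmapped_terms$raw_term, "'"),
              collapse = "; "),
        call. = FALSE
      )
    }
    if (length(unmapped_organs) > 0) {
      stop("unmapped organ(s): ", paste(unmapped_organs, collapse = ", "),
           call. = FALSE)
    }
  }

  out <- findings
  out$controlled_term <- ifelse(is.na(controlled), findings$raw_term, controlled)
  out$target_organ_system <- system
  attr(out, "unmapped") <- list(terms = unmapped_terms, organs = unmapped_organs)
  out
}

#' Aggregate findings into the six high-level categories
#'
#' Each finding receives exactly one high-level label: the four clinical
#' categories (neurological, gastro-intestinal, cardiovascular, other clinical
#' signs) map to themselves; absolute body weight and body weight gain merge
#' into `"body_weight_changes"`; the three post-mortem categories are labelled
#' with the target organ system of the affected organ.
#'
#' @param findings Findings after [apply_terminology()] (post-mortem records
#'   must have `target_organ_system` filled; a post-mortem record with an
#'   unresolved organ is an error).
#' @return The findings with a `high_level` column.
#' @export
aggregate_high_level <- function(findings) {
  if (!"target_organ_system" %in% names(findings)) {
    stop("apply_terminology() must be run before aggregate_high_level()",
         call. = FALSE)
  }
  pm <- findings$category %in% postmortem_categories()
  bad <- pm & is.na(findings$target_organ_system)
  if (any(bad)) {
    stop(
      "post-mortem finding(s) with unresolved target organ system, organ(s): ",
      paste(unique(findings$organ[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- findings
  out$high_level <- dplyr::case_when(
    pm ~ findings$target_organ_system,
    findings$category %in% bodyweight_categories() ~ BODY_WEIGHT_LABEL,
    TRUE ~ findings$category
  )
  out
}

#' Build the molecule-level presence matrix
#'
#' For every molecule, species group and high-level finding label, records
#' whether at least one matching finding occurred in at least one study of the
#' short/mid phase and of the long phase. The molecule universe of a species
#' group contains only molecules with at least one study in *both* phases in
#' that group; other molecules are excluded from that group (with a message).
#' `scope` restricts the findings considered: `"adverse"` keeps findings the
#' study toxicologist called adverse, `"non_adverse"` the rest, `"all"` both.
#'
#' @param dataset A `tox_dataset` whose findings already carry `high_level`
#'   labels (see [aggregate_high_level()]); if the column is absent but a
#'   `map` is given, terminology and aggregation are applied first.
#' @param scope `"all"`, `"adverse"` or `"non_adverse"`.
#' @param map Optional [load_terminology()] map used when `high_level` is
#'   missing.
#' @param pooling Phase pooling for the test phase: `"short_mid"` (default;
#'   short and mid studies pooled), `"short_only"` or `"mid_only"`.
#' @return A `presence_matrix`: tibble with columns `molecule_id`,
#'   `species_group`, `label`, `present_short_mid`, `present_long`, one row
#'   per universe molecule x label; attributes `scope`, `universe` (tibble of
#'   `species_group`, `molecule_id`, `modality`) and `labels`.
#' @export
build_presence_matrix <- function(dataset,
                                  scope = c("all", "adverse", "non_adverse"),
                                  map = NULL,
                                  pooling = "short_mid") {
  scope <- match.arg(scope)
  stopifnot(inherits(dataset, "tox_dataset"))
  findings <- dataset$findings
  if (!"high_level" %in% names(findings)) {
    if (is.null(map)) {
      stop("findings lack 'high_level' labels; run aggregate_high_level() ",
           "or pass a terminology map", call. = FALSE)
    }
    findings <- aggregate_high_level(apply_terminology(findings, map))
  }

  studies <- dataset$studies
  studies$phase <- study_phase(studies, pooling = pooling)
  uncls <- is.na(studies$phase)
  if (any(uncls)) {
    message(
      sum(uncls), " study/studies outside the analysis phases ",
      "(duration class 'unclassified' or excluded by pooling): ",
      paste(studies$study_id[uncls], collapse = ", ")
    )
  }

  # universe: molecules with >=1 study in both phases, per species group
  universe <- studies[!is.na(studies$phase), ] |>
    dplyr::distinct(.data$molecule_id, .data$modality, .data$species_group,
                    .data$phase) |>
    dplyr::count(.data$molecule_id, .data$modality, .data$species_group) |>
    dplyr::filter(.data$n == 2L) |>
    dplyr::select("species_group", "molecule_id", "modality")
  dropped <- studies[!is.na(studies$phase), ] |>
    dplyr::distinct(.data$molecule_id, .data$species_group) |>
    dplyr::anti_join(universe, by = c("molecule_id", "species_group"))
  if (nrow(dropped) > 0) {
    message(
      "excluded from the analysis universe (missing a phase in that species ",
      "group): ",
      paste(paste0(dropped$molecule_id, "/", dropped$species_group),
            collapse = ", ")
    )
  }

  # label universe: all high-level labels in the refined findings (any scope),
  # so the TN cell is counted over the same label set for every scope
  labels <- sort(unique(findings$high_level))

  scoped <- switch(scope,
    all = findings,
    adverse = findings[findings$adverse, ],
    non_adverse = findings[!findings$adverse, ]
  )

  hits <- scoped |>
    dplyr::inner_join(
      studies[, c("study_id", "molecule_id", "species_group", "phase")],
      by = "study_id"
    ) |>
    dplyr::filter(!is.na(.data$phase)) |>
    dplyr::semi_join(universe, by = c("molecule_id", "species_group")) |>
    dplyr::distinct(.data$molecule_id, .data$species_group, .data$phase,
                    label = .data$high_level)

  grid <- tidyr::crossing(universe[, c("species_group", "molecule_id")],
                          label = labels)
  present <- function(ph) {
    h <- hits[hits$phase == ph, ]
    paste(grid$molecule_id, grid$species_group, grid$label, sep = "\r") %in%
      paste(h$molecule_id, h$species_group, h$label, sep = "\r")
  }
  out <- tibble::tibble(
    molecule_id = grid$molecule_id,
    species_group = grid$species_group,
    label = grid$label,
    present_short_mid = present("short_mid"),
    present_long = present("long")
  )
  structure(
    out,
    scope = scope,
    universe = universe,
    labels = labels,
    class = c("presence_matrix", class(out))
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  u <- attr(x, "universe")
  cat("<presence_matrix> scope=", attr(x, "scope"), "\n", sep = "")
  for (g in unique(u$species_group)) {
    cat("  ", g, ": ", sum(u$species_group == g), " molecules\n", sep = "")
  }
  cat("  labels: ", length(attr(x, "labels")), "\n", sep = "")
  NextMethod()
}
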