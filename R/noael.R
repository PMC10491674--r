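# NOAEL progression from short/mid-term to long-term studies.

#' Minimum identified NOAEL of a study phase
#'
#' Studies of one molecule, species group and phase are pooled and the lowest
#' identified per-day NOAEL is taken; if no study of the phase established a
#' NOAEL the result is not identified (`NA`). Dose units must agree across the
#' studies: no conversion between units is attempted.
#'
#' @param noael_per_day Numeric vector of per-day NOAELs, `NA` = not
#'   identified.
#' @param dose_units Optional character vector of dose units, checked for
#'   consistency.
#' @return The minimum identified NOAEL, or `NA` if none was identified.
#' @export
#' @examples
#' min_phase_noael(c(30, 10, NA))  # 10
#' min_phase_noael(c(NA, NA))      # not identified
min_phase_noael <- function(noael_per_day, dose_units = NULL) {
  if (!is.null(dose_units)) {
    u <- unique(dose_units[!is.na(dose_units)])
    if (length(u) > 1) {
      stop("mixed dose units (", paste(u, collapse = ", "),
           "); no unit conversion is attempted", call. = FALSE)
    }
  }
  v <- noael_per_day[!is.na(noael_per_day)]
  if (length(v) == 0) return(NA_real_)
  min(v)
}

#' Classify the NOAEL change from short/mid to long-term
#'
#' Compares the per-day NOAELs of the two phases: `"same"` when they agree to
#' within `tolerance * short_mid` (tolerance 0, i.e. exact comparison of the
#' raw values, by default), `"decrease"`/`"increase"` otherwise, and
#' `"indeterminate"` when either phase has no identified NOAEL.
#'
#' @param short_mid,long Per-day NOAELs (vectors recycle; `NA` = not
#'   identified).
#' @param tolerance Relative tolerance for calling the values the same.
#' @return Character vector of change classes.
#' @export
#' @examples
#' noael_change(c(10, 100, 30), c(10, 30, NA))
noael_change <- function(short_mid, long, tolerance = 0) {
  if (any(short_mid < 0, na.rm = TRUE) || any(long < 0, na.rm = TRUE)) {
    stop("NOAEL values must be non-negative", call. = FALSE)
  }
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  dplyr::case_when(
    is.na(short_mid) | is.na(long) ~ "indeterminate",
    abs(long - short_mid) <= tolerance * short_mid ~ "same",
    long < short_mid ~ "decrease",
    TRUE ~ "increase"
  )
}

#' Per-molecule NOAEL comparison between phases
#'
#' For every molecule and species group with studies in both phases, takes
#' the lowest identified per-day NOAEL of the short/mid studies and of the
#' long-term studies and classifies the change.
#'
#' @param dataset A `tox_dataset`.
#' @param tolerance Relative tolerance, see [noael_change()].
#' @param pooling Phase pooling (default `"short_mid"`).
#' @return A tibble: `molecule_id`, `modality`, `species_group`,
#'   `noael_short_mid_per_day`, `noael_long_per_day`, `change`.
#' @export
noael_comparison <- function(dataset, tolerance = 0, pooling = "short_mid") {
  stopifnot(inherits(dataset, "tox_dataset"))
  st <- dataset$studies
  st$phase <- study_phase(st, pooling = pooling)
  st <- st[!is.na(st$phase), ]

  u <- unique(st$dose_units[!is.na(st$dose_units)])
  if (length(u) > 1) {
    stop("mixed dose units across studies (", paste(u, collapse = ", "),
         "); no unit conversion is attempted", call. = FALSE)
  }

  phase_min <- st |>
    dplyr::group_by(.data$molecule_id, .data$modality, .data$species_group,
                    .data$phase) |>
    dplyr::summarise(
      noael = min_phase_noael(.data$noael_dose_per_day),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "noael")
  for (col in c("short_mid", "long")) {
    if (!col %in% names(phase_min)) phase_min[[col]] <- NA_real_
  }
  # only molecule x group cells with studies in both phases are comparable
  both <- st |>
    dplyr::distinct(.data$molecule_id, .data$species_group, .data$phase) |>
    dplyr::count(.data$molecule_id, .data$species_group) |>
    dplyr::filter(.data$n == 2L)
  phase_min <- dplyr::semi_join(phase_min, both,
                                by = c("molecule_id", "species_group"))

  tibble::tibble(
    molecule_id = phase_min$molecule_id,
    modality = phase_min$modality,
    species_group = phase_min$species_group,
    noael_short_mid_per_day = phase_min$short_mid,
    noael_long_per_day = phase_min$long,
    change = noael_change(phase_min$short_mid, phase_min$long,
                          tolerance = tolerance)
  ) |>
    dplyr::arrange(.data$modality, .data$species_group, .data$molecule_id)
}

#' Summarize NOAEL changes per modality and species group
#'
#' Counts, per modality x species group, the molecules whose NOAEL stayed the
#' same, increased or decreased from the short/mid to the long phase (`n` =
#' molecules with an identified NOAEL in both phases, i.e. a determinate
#' change). The attribution of a decrease to progression of adverse effects
#' versus lower doses tested is expert judgement read from the study reports;
#' it is consumed here as a curated annotation table, not computed. An
#' optional `expert_change` annotation column overrides the computed change
#' class (logged as a message).
#'
#' @param comparisons Output of [noael_comparison()].
#' @param annotations Optional tibble with `molecule_id`, `species_group` and
#'   any of: `decrease_reason` (`"progression"`, `"lower_doses_tested"`,
#'   `"unknown"`), `expert_change` (overriding change class). Annotations for
#'   unknown molecules are an error.
#' @return A tibble per modality x species group: `n`, `same`, `increase`,
#'   `decrease`, `prog_decrease` (decreases attributed to progression),
#'   `prog_over_decrease`, `prog_over_n` (the progression fractions; `NA`
#'   when no annotations are given).
#' @export
noael_change_summary <- function(comparisons, annotations = NULL) {
  comp <- comparisons
  have_reasons <- FALSE
  if (!is.null(annotations)) {
    key <- paste(comp$molecule_id, comp$species_group)
    akey <- paste(annotations$molecule_id, annotations$species_group)
    unknown <- setdiff(akey, key)
    if (length(unknown) > 0) {
      stop("annotation(s) reference unknown molecule/species-group: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    idx <- match(key, akey)
    if ("expert_change" %in% names(annotations)) {
      ov <- annotations$expert_change[idx]
      replace <- !is.na(ov) & ov != comp$change
      if (any(replace)) {
        message(
          "expert override of computed NOAEL change for: ",
          paste(paste0(comp$molecule_id[replace], "/",
                       comp$species_group[replace], " (",
                       comp$change[replace], " -> ", ov[replace], ")"),
                collapse = ", ")
        )
        comp$change[replace] <- ov[replace]
      }
    }
    if ("decrease_reason" %in% names(annotations)) {
      have_reasons <- TRUE
      comp$decrease_reason <- ifelse(comp$change == "decrease",
                                     annotations$decrease_reason[idx],
                                     NA_character_)
    }
  }
  if (!have_reasons) comp$decrease_reason <- NA_character_

  det <- comp[comp$change != "indeterminate", ]
  det |>
    dplyr::group_by(.data$modality, .data$species_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      same = sum(.data$change == "same"),
      increase = sum(.data$change == "increase"),
      decrease = sum(.data$change == "decrease"),
      prog_decrease = if (have_reasons) {
        sum(.data$decrease_reason == "progression", na.rm = TRUE)
      } else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prog_over_decrease = .data$prog_decrease / .data$decrease,
      prog_over_n = .data$prog_decrease / .data$n
    )
}
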