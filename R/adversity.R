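# Overall adversity per molecule and its short/mid vs long concordance.

#' Overall adversity per molecule and phase
#'
#' A molecule is labelled adverse in a phase (`"yes"`) if at least one of its
#' findings in at least one study of that phase was recorded as adverse by the
#' study toxicologist, `"no"` otherwise. Rodent and non-rodent studies are
#' pooled: the flag is per compound, not per species group. Molecules lacking
#' one of the phases are dropped with a warning.
#'
#' @param dataset A `tox_dataset`.
#' @param pooling Phase pooling passed to the phase assignment (default
#'   `"short_mid"`).
#' @return A tibble with one row per molecule: `molecule_id`, `modality`,
#'   `adverse_short_mid`, `adverse_long` (each `"yes"`/`"no"`) and
#'   `concordant`.
#' @export
overall_adversity <- function(dataset, pooling = "short_mid") {
  stopifnot(inherits(dataset, "tox_dataset"))
  studies <- dataset$studies
  studies$phase <- study_phase(studies, pooling = pooling)

  mols <- dplyr::distinct(studies, .data$molecule_id, .data$modality)
  both <- studies[!is.na(studies$phase), ] |>
    dplyr::distinct(.data$molecule_id, .data$phase) |>
    dplyr::count(.data$molecule_id) |>
    dplyr::filter(.data$n == 2L)
  missing <- setdiff(mols$molecule_id, both$molecule_id)
  if (length(missing) > 0) {
    warning(
      "molecule(s) without both phases dropped from the adversity summary: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
    mols <- mols[mols$molecule_id %in% both$molecule_id, ]
  }

  adv <- dataset$findings[dataset$findings$adverse, ] |>
    dplyr::inner_join(studies[, c("study_id", "molecule_id", "phase")],
                      by = "study_id") |>
    dplyr::filter(!is.na(.data$phase)) |>
    dplyr::distinct(.data$molecule_id, .data$phase)

  yes_no <- function(ph) {
    ifelse(mols$molecule_id %in% adv$molecule_id[adv$phase == ph], "yes", "no")
  }
  out <- tibble::tibble(
    molecule_id = mols$molecule_id,
    modality = mols$modality,
    adverse_short_mid = yes_no("short_mid"),
    adverse_long = yes_no("long")
  )
  out$concordant <- out$adverse_short_mid == out$adverse_long
  dplyr::arrange(out, .data$modality, .data$molecule_id)
}

#' 2x2 adversity concordance counts
#'
#' Cross-tabulates the per-molecule overall adversity of the short/mid phase
#' against the long phase, optionally for one modality.
#'
#' @param rows Output of [overall_adversity()].
#' @param modality `NULL` (all molecules), `"small"` or `"large"`.
#' @return A tibble with columns `adverse_short_mid`, `adverse_long`, `n`
#'   covering all four yes/no combinations; `sum(n)` equals the number of
#'   molecules considered.
#' @export
adversity_concordance_counts <- function(rows, modality = NULL) {
  if (!is.null(modality)) {
    modality <- match.arg(modality, c("small", "large"))
    rows <- rows[rows$modality == modality, ]
  }
  grid <- tidyr::crossing(
    adverse_short_mid = c("no", "yes"),
    adverse_long = c("no", "yes")
  )
  counts <- rows |>
    dplyr::count(.data$adverse_short_mid, .data$adverse_long)
  dplyr::left_join(grid, counts,
                   by = c("adverse_short_mid", "adverse_long")) |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}
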