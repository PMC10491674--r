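# Packaged reference contingency rows used to validate the likelihood-ratio,
# Fisher-test and frequency computations against published values.

#' Reference 2x2 concordance tables
#'
#' The statistically significant contingency rows reported for a cohort of 43
#' molecules (rodent and non-rodent studies; adverse and non-adverse finding
#' scopes), shipped as a plain-text fixture. Each row carries the published
#' cell counts (`tp`, `fp`, `fn`, `tn`), the likelihood ratios as printed
#' (`plus_lr_printed`, `inv_neg_lr_printed`; `Inf` for infinite) and the
#' p-value as printed (`p_printed`, with values below 0.005 printed as 0).
#' The counts are inputs to the package's own statistics; the printed columns
#' exist only to check agreement.
#'
#' @return A tibble with one row per published significant finding x species
#'   group x scope.
#' @export
#' @examples
#' rows <- reference_contingency_rows()
#' with(rows[1, ], plus_lr(tp, fp, fn, tn))
reference_contingency_rows <- function() {
  readr::read_csv(
    toxconcord_example("reference_contingency_rows.csv"),
    col_types = readr::cols(
      finding = readr::col_character(),
      species_group = readr::col_character(),
      scope = readr::col_character(),
      tp = readr::col_integer(), fp = readr::col_integer(),
      fn = readr::col_integer(), tn = readr::col_integer(),
      plus_lr_printed = readr::col_double(),
      inv_neg_lr_printed = readr::col_double(),
      p_printed = readr::col_double()
    ),
    progress = FALSE
  )
}
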