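# Display conventions for result tables. Internal computation is always full
# precision; these helpers only affect how values are printed/serialized.

# round half away from zero at `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Display formatting for likelihood ratios, percentages and p-values
#'
#' `format_lr()` rounds half-up to two decimals and prints infinities as
#' `"Inf"`. `format_pct()` truncates toward zero at one decimal (so 2/30 of
#' the universe displays as `6.6`\%, not `6.7`). `format_p()` rounds to two
#' decimals and displays values below 0.005 as `"0"`.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
#' @examples
#' format_lr(c(5.952, 6.8235, Inf))
#' format_pct(100 * c(2, 1) / 30)
#' format_p(c(0.0176, 0.0004))
format_lr <- function(x) {
  ifelse(is.nan(x), "NaN",
         ifelse(is.infinite(x), "Inf",
                trimws(formatC(round_half_up(x, 2), format = "fg", digits = 15))))
}

#' @rdname format_lr
#' @export
format_pct <- function(x) {
  ifelse(is.nan(x), "NaN",
         trimws(formatC(trunc(x * 10) / 10, format = "fg", digits = 15)))
}

#' @rdname format_lr
#' @export
format_p <- function(x) {
  ifelse(x < 0.005, "0",
         trimws(formatC(round_half_up(x, 2), format = "fg", digits = 15)))
}

#' Format a concordance analysis like a published result table
#'
#' Renders the significant rows of a [concordance_analysis()] with the
#' display conventions of the field's summary tables: columns `finding`,
#' `TP`, `FP`, `FN`, `TN`, `plus_lr`, `inv_neg_lr`, `p_value`,
#' `species_group`, likelihood ratios rounded half-up to two decimals
#' (infinite as `"Inf"`), p-values below 0.005 shown as `"0"`.
#'
#' @param results Output of [concordance_analysis()].
#' @param significant_only Keep only significant rows (default `TRUE`).
#' @return A tibble of character/integer display columns.
#' @export
format_concordance_table <- function(results, significant_only = TRUE) {
  if (significant_only) results <- significant_rows(results)
  tibble::tibble(
    finding = results$finding,
    TP = results$TP, FP = results$FP, FN = results$FN, TN = results$TN,
    plus_lr = format_lr(results$plus_lr),
    inv_neg_lr = format_lr(results$inv_neg_lr),
    p_value = format_p(results$fisher_p),
    species_group = results$species_group
  )
}
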