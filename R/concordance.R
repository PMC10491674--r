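# 2x2 contingency tables per high-level finding, likelihood ratios, Fisher's
# exact test, interpretation bins and false-positive/negative frequencies.
#
# Cell semantics (counted over molecules, not studies):
#   TP finding in both phases; FP short/mid only; FN long only; TN neither.

#' Build a 2x2 contingency table for one finding and species group
#'
#' Counts molecules of the species group's analysis universe by presence of
#' the high-level finding in the short/mid phase versus the long phase.
#'
#' @param matrix A [build_presence_matrix()] result.
#' @param finding_label High-level finding label.
#' @param species_group `"rodent"` or `"non_rodent"`.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
build_contingency <- function(matrix, finding_label, species_group) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!finding_label %in% attr(matrix, "labels")) {
    stop("unknown finding label: '", finding_label, "'", call. = FALSE)
  }
  m <- matrix[matrix$label == finding_label &
                matrix$species_group == species_group, ]
  c(
    TP = sum(m$present_short_mid & m$present_long),
    FP = sum(m$present_short_mid & !m$present_long),
    FN = sum(!m$present_short_mid & m$present_long),
    TN = sum(!m$present_short_mid & !m$present_long)
  )
}

#' Likelihood ratios of a 2x2 concordance table
#'
#' The short/mid-phase observation is treated as a diagnostic test for the
#' long-phase observation. The positive likelihood ratio is
#' `sensitivity / (1 - specificity)` = `TP*(FP+TN) / (FP*(TP+FN))`; the
#' inverse negative likelihood ratio is `specificity / (1 - sensitivity)` =
#' `TN*(TP+FN) / (FN*(FP+TN))`. A zero false-positive cell with non-zero
#' sensitivity makes `plus_lr` infinite (`Inf`, reported as such rather than
#' continuity-corrected); likewise zero false negatives for `inv_neg_lr`.
#' An empty margin (no molecule with, or none without, the finding in the
#' long phase) leaves the ratio undefined (`NaN`).
#'
#' @param tp,fp,fn,tn Non-negative cell counts (vectors recycle).
#' @return Numeric: the ratio, `Inf`, or `NaN` when undefined.
#' @export
#' @examples
#' plus_lr(6, 3, 2, 31)     # 8.5
#' plus_lr(2, 0, 3, 37)     # Inf
#' inv_neg_lr(7, 5, 1, 29)  # 6.82...
plus_lr <- function(tp, fp, fn, tn) {
  check_cells(tp, fp, fn, tn)
  sens <- tp / (tp + fn)
  one_minus_spec <- fp / (fp + tn)
  out <- sens / one_minus_spec
  # 0/0 (defined margins, sens = 0 = 1-spec) is NaN already; empty margins too
  out
}

#' @rdname plus_lr
#' @export
inv_neg_lr <- function(tp, fp, fn, tn) {
  check_cells(tp, fp, fn, tn)
  spec <- tn / (fp + tn)
  one_minus_sens <- fn / (tp + fn)
  spec / one_minus_sens
}

check_cells <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0, na.rm = TRUE)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  invisible(NULL)
}

#' Sensitivity and specificity of a 2x2 concordance table
#'
#' @inheritParams plus_lr
#' @return Proportion in `[0, 1]`, `NaN` when the margin is empty.
#' @export
sensitivity <- function(tp, fp, fn, tn) {
  check_cells(tp, fp, fn, tn)
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(tp, fp, fn, tn) {
  check_cells(tp, fp, fn, tn)
  tn / (fp + tn)
}

#' Fisher's exact test p-value for a 2x2 concordance table
#'
#' Exact hypergeometric test of association between short/mid-phase and
#' long-phase presence. The default alternative `"greater"` tests positive
#' association (concordance), which is the convention under which the
#' package's reference tables reproduce; `"two.sided"` is the conventional
#' sum of all tables, at fixed margins, whose point probability does not
#' exceed the observed one.
#'
#' @inheritParams plus_lr
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact_p(1, 1, 1, 1)  # 1: perfectly balanced
#' fisher_exact_p(6, 3, 2, 31)
fisher_exact_p <- function(tp, fp, fn, tn,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_cells(tp, fp, fn, tn)
  n <- length(tp)
  fp <- rep_len(fp, n); fn <- rep_len(fn, n); tn <- rep_len(tn, n)
  vapply(seq_len(n), function(i) {
    m <- matrix(c(tp[i], fp[i], fn[i], tn[i]), nrow = 2, byrow = TRUE)
    stats::fisher.test(m, alternative = alternative)$p.value
  }, numeric(1))
}

#' False-positive and false-negative frequencies
#'
#' Percentage of the molecule universe that the short/mid phase mis-predicts:
#' `pct_fp = 100 * FP / (TP+FP+FN+TN)` (finding seen short/mid only),
#' `pct_fn = 100 * FN / (TP+FP+FN+TN)` (finding missed by the short/mid
#' phase). Full precision is returned; the display convention truncates
#' toward zero at one decimal (see [format_pct()]).
#'
#' @inheritParams plus_lr
#' @return Percentage in `[0, 100]`; `NaN` for an all-zero table.
#' @export
#' @examples
#' pct_fp(2, 2, 1, 25)  # 6.666...; displays as 6.6
pct_fp <- function(tp, fp, fn, tn) {
  check_cells(tp, fp, fn, tn)
  100 * fp / (tp + fp + fn + tn)
}

#' @rdname pct_fp
#' @export
pct_fn <- function(tp, fp, fn, tn) {
  check_cells(tp, fp, fn, tn)
  100 * fn / (tp + fp + fn + tn)
}

#' Interpretation bin of a likelihood ratio
#'
#' Standard evidential reading of diagnostic likelihood ratios: above 10
#' (including infinite) a large and often conclusive shift in probability,
#' 5-10 moderate, 2-5 small but sometimes important, 1-2 small and rarely
#' important, at or below 1 none. Interval endpoints resolve upward (5 is
#' `"moderate"`, 10 is `"moderate"`, 2 is `"small"`).
#'
#' @param value Positive likelihood ratio(s); `Inf` allowed, `NaN`/`NA`
#'   propagate.
#' @return Character vector of `"large"`, `"moderate"`, `"small"`,
#'   `"rarely_important"`, `"none"`.
#' @export
#' @examples
#' interpret_lr(c(8.5, Inf, 2.87, 1.5, 0.9))
interpret_lr <- function(value) {
  dplyr::case_when(
    is.na(value) ~ NA_character_,
    value > 10 ~ "large",
    value >= 5 ~ "moderate",
    value >= 2 ~ "small",
    value > 1 ~ "rarely_important",
    TRUE ~ "none"
  )
}

#' Full concordance analysis of a presence matrix
#'
#' Builds the 2x2 contingency table for every high-level finding label and
#' species group, and computes sensitivity, specificity, both likelihood
#' ratios, the Fisher exact p-value, the false-positive/negative frequencies
#' and the interpretation bins. Rows with `fisher_p < alpha` are flagged
#' significant; published-table style output keeps only those (see
#' [significant_rows()] and [format_concordance_table()]).
#'
#' @param matrix A [build_presence_matrix()] result.
#' @param alpha Significance level for the Fisher test (default 0.05).
#' @param lr_cutoff Cut-off above which a likelihood ratio is called high
#'   (default 5).
#' @param alternative Sidedness of the Fisher test, see [fisher_exact_p()].
#' @return A tibble with one row per finding label x species group:
#'   `finding`, `species_group`, `scope`, `TP`, `FP`, `FN`, `TN`,
#'   `sensitivity`, `specificity`, `plus_lr`, `inv_neg_lr`, `fisher_p`,
#'   `significant`, `pct_fp`, `pct_fn`, `interpretation_plus`,
#'   `interpretation_inv_neg`, `high_plus_lr`, `high_inv_neg_lr`.
#' @export
concordance_analysis <- function(matrix, alpha = 0.05, lr_cutoff = 5,
                                 alternative = c("greater", "two.sided")) {
  stopifnot(inherits(matrix, "presence_matrix"))
  alternative <- match.arg(alternative)
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must be in [0, 1]", call. = FALSE)

  cells <- matrix |>
    dplyr::group_by(finding = .data$label, .data$species_group) |>
    dplyr::summarise(
      TP = sum(.data$present_short_mid & .data$present_long),
      FP = sum(.data$present_short_mid & !.data$present_long),
      FN = sum(!.data$present_short_mid & .data$present_long),
      TN = sum(!.data$present_short_mid & !.data$present_long),
      .groups = "drop"
    )
  res <- cells |>
    dplyr::mutate(
      scope = attr(matrix, "scope"),
      sensitivity = sensitivity(.data$TP, .data$FP, .data$FN, .data$TN),
      specificity = specificity(.data$TP, .data$FP, .data$FN, .data$TN),
      plus_lr = plus_lr(.data$TP, .data$FP, .data$FN, .data$TN),
      inv_neg_lr = inv_neg_lr(.data$TP, .data$FP, .data$FN, .data$TN),
      fisher_p = fisher_exact_p(.data$TP, .data$FP, .data$FN, .data$TN,
                                alternative = alternative),
      significant = .data$fisher_p < alpha,
      pct_fp = pct_fp(.data$TP, .data$FP, .data$FN, .data$TN),
      pct_fn = pct_fn(.data$TP, .data$FP, .data$FN, .data$TN),
      interpretation_plus = interpret_lr(.data$plus_lr),
      interpretation_inv_neg = interpret_lr(.data$inv_neg_lr),
      high_plus_lr = !is.na(.data$plus_lr) & .data$plus_lr > lr_cutoff,
      high_inv_neg_lr = !is.na(.data$inv_neg_lr) & .data$inv_neg_lr > lr_cutoff
    ) |>
    dplyr::relocate("scope", .after = "species_group") |>
    dplyr::arrange(.data$species_group, dplyr::desc(.data$plus_lr))
  res
}

#' Keep only the statistically significant concordance rows
#'
#' @param results Output of [concordance_analysis()].
#' @return The significant rows, following the convention of reporting only
#'   findings whose contingency table reaches significance.
#' @export
significant_rows <- function(results) {
  results[results$significant, ]
}
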