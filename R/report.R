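# Pipeline orchestration: configuration, dataset overview counts/plots and
# the end-to-end run that writes result CSVs, figures and run metadata.

#' Configuration of a full pipeline run
#'
#' @param study_path,finding_path Input dataset paths (tab-delimited); omit
#'   both to run on a simulated cohort.
#' @param term_path,organ_path Terminology map paths; default to the packaged
#'   synthetic fixtures.
#' @param scopes Finding scopes to analyze (any of `"all"`, `"adverse"`,
#'   `"non_adverse"`).
#' @param alpha Fisher significance level, in (0, 1); default 0.05.
#' @param lr_cutoff High-likelihood-ratio cut-off, > 1; default 5.
#' @param noael_tolerance Relative tolerance of [noael_change()]; default 0.
#' @param pooling Phase pooling mode (see [build_presence_matrix()]).
#' @param alternative Fisher sidedness (see [fisher_exact_p()]).
#' @param out_dir Output directory for CSVs, plots and metadata.
#' @param seed Seed used when simulating (no input paths given).
#' @param strict_inclusion Enforce the inclusion rule as an error.
#' @return A list with class `"run_config"`.
#' @export
run_config <- function(study_path = NULL, finding_path = NULL,
                       term_path = toxconcord_example("finding_terms_synthetic.csv"),
                       organ_path = toxconcord_example("organ_systems_synthetic.csv"),
                       scopes = c("all", "adverse", "non_adverse"),
                       alpha = 0.05, lr_cutoff = 5, noael_tolerance = 0,
                       pooling = "short_mid",
                       alternative = "greater",
                       out_dir = NULL, seed = 1L,
                       strict_inclusion = FALSE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (lr_cutoff <= 1) stop("lr_cutoff must be > 1", call. = FALSE)
  scopes <- match.arg(scopes, several.ok = TRUE)
  structure(
    list(
      study_path = study_path, finding_path = finding_path,
      term_path = term_path, organ_path = organ_path, scopes = scopes,
      alpha = alpha, lr_cutoff = lr_cutoff,
      noael_tolerance = noael_tolerance, pooling = pooling,
      alternative = alternative, out_dir = out_dir, seed = as.integer(seed),
      strict_inclusion = strict_inclusion
    ),
    class = "run_config"
  )
}

#' Overview counts and plots of a dataset
#'
#' Tabulates therapeutic areas (molecules per area and modality), studies per
#' duration class and modality, compounds per species and species group, and
#' finding records per category and species group, with a bar chart for each.
#'
#' @param dataset A `tox_dataset`.
#' @return A list with `counts` (named list of tibbles) and `plots` (named
#'   list of ggplot objects).
#' @export
dataset_overview <- function(dataset) {
  stopifnot(inherits(dataset, "tox_dataset"))
  st <- dataset$studies

  mols <- dplyr::distinct(st, .data$molecule_id, .data$modality,
                          .data$therapeutic_area)
  areas <- mols |>
    dplyr::count(.data$therapeutic_area, .data$modality, name = "n_molecules")
  durations <- st |>
    dplyr::count(.data$duration_class, .data$modality, name = "n_studies")
  species <- st |>
    dplyr::distinct(.data$molecule_id, .data$species, .data$species_group,
                    .data$modality) |>
    dplyr::count(.data$species_group, .data$species, .data$modality,
                 name = "n_compounds")
  fcat <- dataset$findings |>
    dplyr::inner_join(st[, c("study_id", "species_group")], by = "study_id") |>
    dplyr::count(.data$species_group, .data$category, name = "n_findings")

  bar <- function(df, x, y, fill, title) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                     fill = .data[[fill]])) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_text(ggplot2::aes(label = .data[[y]]),
                         position = ggplot2::position_dodge(width = 0.9),
                         vjust = -0.3, size = 3) +
      ggplot2::labs(title = title, x = NULL, y = y) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  }

  list(
    counts = list(
      therapeutic_areas = areas,
      studies_per_duration = durations,
      compounds_per_species = species,
      findings_per_category = fcat
    ),
    plots = list(
      therapeutic_areas = bar(areas, "therapeutic_area", "n_molecules",
                              "modality", "Molecules per therapeutic area"),
      studies_per_duration = bar(durations, "duration_class", "n_studies",
                                 "modality", "Studies per duration class"),
      compounds_per_species = bar(species, "species", "n_compounds",
                                  "species_group", "Compounds per species"),
      findings_per_category = bar(fcat, "category", "n_findings",
                                  "species_group",
                                  "Finding records per category")
    )
  )
}

#' Bar chart of false-positive / false-negative frequencies
#'
#' One panel per species group; only statistically significant rows are
#' shown, following the reporting convention of the concordance tables.
#'
#' @param results Output of [concordance_analysis()].
#' @return A ggplot object.
#' @export
plot_fp_fn <- function(results) {
  df <- significant_rows(results) |>
    tidyr::pivot_longer(c("pct_fp", "pct_fn"), names_to = "measure",
                        values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$finding, y = .data$pct,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~species_group, scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "% of molecule universe",
      title = paste0("False positive / false negative frequencies (scope = ",
                     df$scope[1], ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Run the full concordance pipeline
#'
#' Reads (or simulates) the dataset, applies terminology and high-level
#' aggregation, computes overall adversity and its 2x2 concordance, the
#' per-molecule NOAEL comparison and change summary, and the contingency /
#' likelihood-ratio analysis for every requested scope. When `out_dir` is
#' set, writes one CSV per result table, the overview counts, the FP/FN
#' figures (PNG) and a JSON run-metadata file.
#'
#' @param config A [run_config()].
#' @param dataset Optionally, an already-loaded `tox_dataset` (overrides the
#'   config paths).
#' @param noael_annotations Optional annotation table passed to
#'   [noael_change_summary()].
#' @return Invisibly, a list: `dataset`, `overview`, `adversity`,
#'   `adversity_counts`, `noael`, `noael_summary`, `concordance` (one tibble
#'   per scope), `written` (paths, when `out_dir` was set).
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         noael_annotations = NULL) {
  stopifnot(inherits(config, "run_config"))
  map <- load_terminology(config$term_path, config$organ_path)

  if (is.null(dataset)) {
    if (is.null(config$study_path)) {
      dataset <- simulate_dataset(sim_spec(seed = config$seed), map = map)
    } else {
      dataset <- read_dataset(
        config$study_path, config$finding_path,
        config = schema_config(strict_inclusion = config$strict_inclusion)
      )
    }
  }

  refined <- dataset
  refined$findings <- aggregate_high_level(
    apply_terminology(dataset$findings, map)
  )

  adversity <- overall_adversity(refined, pooling = config$pooling)
  adversity_counts <- dplyr::bind_rows(
    small = adversity_concordance_counts(adversity, "small"),
    large = adversity_concordance_counts(adversity, "large"),
    .id = "modality"
  )
  noael <- noael_comparison(refined, tolerance = config$noael_tolerance,
                            pooling = config$pooling)
  noael_summary <- noael_change_summary(noael, annotations = noael_annotations)

  concordance <- lapply(
    setNames(config$scopes, config$scopes),
    function(sc) {
      pm <- build_presence_matrix(refined, scope = sc,
                                  pooling = config$pooling)
      concordance_analysis(pm, alpha = config$alpha,
                           lr_cutoff = config$lr_cutoff,
                           alternative = config$alternative)
    }
  )
  overview <- dataset_overview(refined)

  written <- NULL
  if (!is.null(config$out_dir)) {
    tables <- c(
      list(
        adversity = adversity,
        adversity_counts = adversity_counts,
        noael_comparison = noael,
        noael_summary = noael_summary
      ),
      setNames(
        lapply(concordance, format_concordance_table),
        paste0("concordance_", names(concordance))
      ),
      setNames(
        lapply(concordance, identity),
        paste0("concordance_full_", names(concordance))
      ),
      overview$counts
    )
    written <- write_results(
      tables, config$out_dir,
      meta = list(
        study_path = config$study_path %||% "simulated",
        finding_path = config$finding_path %||% "simulated",
        term_path = config$term_path, organ_path = config$organ_path,
        scopes = config$scopes, alpha = config$alpha,
        lr_cutoff = config$lr_cutoff,
        noael_tolerance = config$noael_tolerance,
        pooling = config$pooling, alternative = config$alternative,
        seed = config$seed
      )
    )
    for (sc in names(concordance)) {
      if (nrow(significant_rows(concordance[[sc]])) > 0) {
        ggplot2::ggsave(
          file.path(config$out_dir, paste0("fp_fn_", sc, ".png")),
          plot_fp_fn(concordance[[sc]]),
          width = 9, height = 4.5, dpi = 150
        )
      }
    }
    for (nm in names(overview$plots)) {
      ggplot2::ggsave(
        file.path(config$out_dir, paste0("overview_", nm, ".png")),
        overview$plots[[nm]], width = 7, height = 4.5, dpi = 150
      )
    }
  }

  invisible(list(
    dataset = refined, overview = overview,
    adversity = adversity, adversity_counts = adversity_counts,
    noael = noael, noael_summary = noael_summary,
    concordance = concordance, written = written
  ))
}
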