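# Reading, validation and writing of the tab-delimited study/finding dataset
# and the controlled-terminology maps.

#' Schema configuration for reading study datasets
#'
#' Controls how the tab-delimited study and finding tables are parsed and
#' validated.
#'
#' @param missing_tokens Strings treated as a missing cell (besides a truly
#'   empty cell).
#' @param not_identified_tokens Strings in the NOAEL column meaning that no
#'   NOAEL was established in the study.
#' @param dose_sep Separator between dose levels in the `dose_levels` column.
#' @param strict_inclusion If `TRUE`, a molecule lacking either a short/mid or
#'   a long-term study is an error; if `FALSE` (default) a warning, so partial
#'   datasets and fixtures still load.
#' @return A list with class `"schema_config"`.
#' @export
schema_config <- function(missing_tokens = c("", "NA"),
                          not_identified_tokens = c("not identified", "not_identified", "NI"),
                          dose_sep = ";",
                          strict_inclusion = FALSE) {
  structure(
    list(
      missing_tokens = missing_tokens,
      not_identified_tokens = not_identified_tokens,
      dose_sep = dose_sep,
      strict_inclusion = strict_inclusion
    ),
    class = "schema_config"
  )
}

STUDY_REQUIRED <- c(
  "study_id", "molecule_id", "modality", "species",
  "duration_weeks", "noael_dose_per_day"
)
STUDY_OPTIONAL <- c(
  "therapeutic_area", "route", "dose_levels",
  "administrations_per_day", "dose_units"
)
FINDING_REQUIRED <- c("study_id", "category", "raw_term", "adverse")
FINDING_OPTIONAL <- c(
  "organ", "onset_dose_per_day", "severity", "reversibility", "notes"
)

is_missing_cell <- function(x, config) {
  is.na(x) | trimws(x) %in% config$missing_tokens
}

read_delim_chr <- function(path, delim) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
}

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(
      "missing required column(s) in ", what, " table: ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
}

parse_num <- function(x) {
  suppressWarnings(as.numeric(x))
}

new_diag <- function() {
  tibble::tibble(
    table = character(), line = integer(), id = character(),
    field = character(), message = character()
  )
}

add_diag <- function(diag, table, line, id, field, message) {
  dplyr::bind_rows(diag, tibble::tibble(
    table = table, line = as.integer(line), id = as.character(id),
    field = field, message = message
  ))
}

#' Read and validate a study/finding dataset
#'
#' Reads the tab-delimited study table and finding table, validates every row,
#' derives the species group, duration class and per-day dose levels, and
#' returns a `tox_dataset`. Rows with missing mandatory fields, unparseable
#' numbers or invalid enumerations are rejected and reported in row-indexed
#' diagnostics (`diagnostics(x)`); a finding referencing an unknown study is an
#' error. Each molecule is expected to have at least one short- or mid-term
#' study and at least one long-term study; violations warn (or error under
#' `strict_inclusion`).
#'
#' The study table must have columns `study_id`, `molecule_id`, `modality`
#' (`small`/`large`), `species`, `duration_weeks` and `noael_dose_per_day`
#' (a number, or `"not identified"`); optional columns are `therapeutic_area`,
#' `route`, `dose_levels` (per-administration amounts separated by `;`),
#' `administrations_per_day` and `dose_units`. The finding table must have
#' `study_id`, `category` (one of [finding_categories()]), `raw_term` and
#' `adverse` (`yes`/`no`); optional columns are `organ` (required for the
#' post-mortem categories, and only for them), `onset_dose_per_day`,
#' `severity`, `reversibility` and `notes`.
#'
#' @param study_path Path to the tab-delimited study table.
#' @param finding_path Path to the tab-delimited finding table.
#' @param config A [schema_config()].
#' @param species_synonyms Passed to [group_species()].
#' @return A `tox_dataset`: a list with tibbles `studies` and `findings` and a
#'   `provenance` list (paths, row counts, diagnostics).
#' @seealso [write_dataset()], [diagnostics()]
#' @export
#' @examples
#' ds <- read_dataset(
#'   toxconcord_example("example_studies.txt"),
#'   toxconcord_example("example_findings.txt")
#' )
#' ds
read_dataset <- function(study_path, finding_path,
                         config = schema_config(),
                         species_synonyms = default_species_synonyms()) {
  raw_studies <- read_delim_chr(study_path, "\t")
  raw_findings <- read_delim_chr(finding_path, "\t")
  check_columns(raw_studies, STUDY_REQUIRED, "study")
  check_columns(raw_findings, FINDING_REQUIRED, "finding")

  diag <- new_diag()
  keep <- rep(TRUE, nrow(raw_studies))
  # header occupies line 1 of the file
  lines <- seq_len(nrow(raw_studies)) + 1L

  reject <- function(i, tab, id, field, msg) {
    diag <<- add_diag(diag, tab, lines[i], id, field, msg)
    keep[i] <<- FALSE
  }

  for (f in STUDY_OPTIONAL) {
    if (!f %in% names(raw_studies)) raw_studies[[f]] <- NA_character_
  }

  for (i in seq_len(nrow(raw_studies))) {
    row <- raw_studies[i, ]
    for (f in c("study_id", "molecule_id", "modality", "species", "duration_weeks")) {
      if (is_missing_cell(row[[f]], config)) {
        reject(i, "studies", row$study_id, f, paste0("mandatory field '", f, "' is missing"))
        break
      }
    }
    if (!keep[i]) next
    if (!tolower(row$modality) %in% c("small", "large")) {
      reject(i, "studies", row$study_id, "modality",
             paste0("modality must be 'small' or 'large', got '", row$modality, "'"))
      next
    }
    dw <- parse_num(row$duration_weeks)
    if (is.na(dw)) {
      reject(i, "studies", row$study_id, "duration_weeks",
             paste0("unparseable number '", row$duration_weeks, "'"))
      next
    }
    if (dw <= 0) {
      reject(i, "studies", row$study_id, "duration_weeks", "duration_weeks must be > 0")
      next
    }
  }

  # duplicate study ids: the later occurrence is rejected
  ids <- raw_studies$study_id
  dup <- duplicated(ids) & keep
  for (i in which(dup)) {
    diag <- add_diag(diag, "studies", lines[i], ids[i], "study_id",
                     paste0("duplicate study_id '", ids[i], "'"))
    keep[i] <- FALSE
  }

  st <- raw_studies[keep, ]
  lines_kept <- lines[keep]

  noael <- rep(NA_real_, nrow(st))
  noael_ok <- rep(TRUE, nrow(st))
  for (i in seq_len(nrow(st))) {
    cell <- st$noael_dose_per_day[i]
    if (is_missing_cell(cell, config) ||
        tolower(trimws(cell)) %in% tolower(config$not_identified_tokens)) {
      next
    }
    v <- parse_num(cell)
    if (is.na(v)) {
      diag <- add_diag(diag, "studies", lines_kept[i], st$study_id[i],
                       "noael_dose_per_day",
                       paste0("unparseable number '", cell, "'"))
      noael_ok[i] <- FALSE
    } else {
      noael[i] <- v
    }
  }
  st <- st[noael_ok, ]
  noael <- noael[noael_ok]

  apd <- parse_num(ifelse(is_missing_cell(st$administrations_per_day, config),
                          "1", st$administrations_per_day))
  apd[is.na(apd)] <- 1
  dose_levels <- lapply(seq_len(nrow(st)), function(i) {
    cell <- st$dose_levels[i]
    if (is_missing_cell(cell, config)) return(numeric(0))
    sort(parse_num(trimws(strsplit(cell, config$dose_sep, fixed = TRUE)[[1]])))
  })

  studies <- tibble::tibble(
    study_id = st$study_id,
    molecule_id = st$molecule_id,
    modality = tolower(st$modality),
    species = st$species,
    species_group = group_species(st$species, synonyms = species_synonyms),
    duration_weeks = parse_num(st$duration_weeks),
    duration_class = classify_duration(parse_num(st$duration_weeks)),
    therapeutic_area = ifelse(is_missing_cell(st$therapeutic_area, config),
                              NA_character_, st$therapeutic_area),
    route = ifelse(is_missing_cell(st$route, config), NA_character_, st$route),
    dose_levels = dose_levels,
    administrations_per_day = apd,
    dose_per_day_levels = mapply(function(d, a) normalize_dose(d, a),
                                 dose_levels, apd, SIMPLIFY = FALSE),
    noael_dose_per_day = noael,
    dose_units = ifelse(is_missing_cell(st$dose_units, config),
                        NA_character_, st$dose_units)
  )

  # NOAEL must be one of the per-day dose levels when both are given
  mismatch <- vapply(seq_len(nrow(studies)), function(i) {
    lev <- studies$dose_per_day_levels[[i]]
    nv <- studies$noael_dose_per_day[i]
    length(lev) > 0 && !is.na(nv) &&
      !any(abs(lev - nv) <= 1e-8 * pmax(1, abs(nv)))
  }, logical(1))
  if (any(mismatch)) {
    warning(
      "NOAEL not among the per-day-normalized dose levels for study/studies: ",
      paste(studies$study_id[mismatch], collapse = ", "),
      call. = FALSE
    )
  }

  findings <- validate_findings(raw_findings, studies, config, diag)
  diag <- attr(findings, "diag")
  attr(findings, "diag") <- NULL

  ds <- new_tox_dataset(
    studies, findings,
    provenance = list(
      study_path = study_path,
      finding_path = finding_path,
      n_study_rows = nrow(raw_studies),
      n_finding_rows = nrow(raw_findings),
      diagnostics = diag
    )
  )
  check_inclusion(ds, strict = config$strict_inclusion)
  ds
}

validate_findings <- function(raw, studies, config, diag) {
  for (f in FINDING_OPTIONAL) {
    if (!f %in% names(raw)) raw[[f]] <- NA_character_
  }
  keep <- rep(TRUE, nrow(raw))
  lines <- seq_len(nrow(raw)) + 1L
  adverse <- rep(NA, nrow(raw))
  onset <- rep(NA_real_, nrow(raw))

  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    bad <- FALSE
    for (f in c("study_id", "category", "raw_term", "adverse")) {
      if (is_missing_cell(row[[f]], config)) {
        diag <- add_diag(diag, "findings", lines[i], row$study_id, f,
                         paste0("mandatory field '", f, "' is missing"))
        bad <- TRUE
        break
      }
    }
    if (bad) { keep[i] <- FALSE; next }
    cat_i <- tolower(trimws(row$category))
    if (!cat_i %in% finding_categories()) {
      diag <- add_diag(diag, "findings", lines[i], row$study_id, "category",
                       paste0("unknown category '", row$category, "'"))
      keep[i] <- FALSE; next
    }
    adv <- tolower(trimws(row$adverse))
    if (adv %in% c("yes", "true", "1")) {
      adverse[i] <- TRUE
    } else if (adv %in% c("no", "false", "0")) {
      adverse[i] <- FALSE
    } else {
      diag <- add_diag(diag, "findings", lines[i], row$study_id, "adverse",
                       paste0("adverse must be yes/no, got '", row$adverse, "'"))
      keep[i] <- FALSE; next
    }
    organ_missing <- is_missing_cell(row$organ, config)
    if (cat_i %in% postmortem_categories() && organ_missing) {
      diag <- add_diag(diag, "findings", lines[i], row$study_id, "organ",
                       paste0("organ is required for category '", cat_i, "'"))
      keep[i] <- FALSE; next
    }
    if (!cat_i %in% postmortem_categories() && !organ_missing) {
      diag <- add_diag(diag, "findings", lines[i], row$study_id, "organ",
                       paste0("organ must be empty for category '", cat_i, "'"))
      keep[i] <- FALSE; next
    }
    if (!is_missing_cell(row$onset_dose_per_day, config)) {
      v <- parse_num(row$onset_dose_per_day)
      if (is.na(v)) {
        diag <- add_diag(diag, "findings", lines[i], row$study_id,
                         "onset_dose_per_day",
                         paste0("unparseable number '", row$onset_dose_per_day, "'"))
        keep[i] <- FALSE; next
      }
      onset[i] <- v
    }
  }

  fd <- raw[keep, ]
  unknown <- setdiff(unique(fd$study_id), studies$study_id)
  if (length(unknown) > 0) {
    stop(
      "finding(s) reference unknown study_id: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  opt_chr <- function(x) ifelse(is_missing_cell(x, config), NA_character_, x)
  findings <- tibble::tibble(
    study_id = fd$study_id,
    category = tolower(trimws(fd$category)),
    raw_term = fd$raw_term,
    organ = opt_chr(fd$organ),
    adverse = adverse[keep],
    onset_dose_per_day = onset[keep],
    severity = opt_chr(fd$severity),
    reversibility = opt_chr(fd$reversibility),
    notes = opt_chr(fd$notes)
  )
  attr(findings, "diag") <- diag
  findings
}

new_tox_dataset <- function(studies, findings, provenance = list()) {
  structure(
    list(studies = studies, findings = findings, provenance = provenance),
    class = "tox_dataset"
  )
}

#' Row-level diagnostics from reading a dataset
#'
#' @param x A `tox_dataset`.
#' @return A tibble with one row per rejected input row: `table`, `line`
#'   (line number in the source file), `id`, `field`, `message`.
#' @export
diagnostics <- function(x) {
  stopifnot(inherits(x, "tox_dataset"))
  x$provenance$diagnostics %||% new_diag()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tox_dataset <- function(x, ...) {
  ph <- table(factor(study_phase(x$studies), levels = c("short_mid", "long")))
  cat("<tox_dataset>\n")
  cat("  molecules: ", length(unique(x$studies$molecule_id)),
      " (", sum(tapply(x$studies$modality, x$studies$molecule_id, function(m) m[1]) == "small"),
      " small, ",
      sum(tapply(x$studies$modality, x$studies$molecule_id, function(m) m[1]) == "large"),
      " large)\n", sep = "")
  cat("  studies:   ", nrow(x$studies),
      " (", ph[["short_mid"]], " short/mid, ", ph[["long"]], " long)\n", sep = "")
  cat("  findings:  ", nrow(x$findings), "\n", sep = "")
  nd <- nrow(diagnostics(x))
  if (nd > 0) cat("  rejected input rows: ", nd, " (see diagnostics())\n", sep = "")
  invisible(x)
}

# Inclusion rule: each molecule needs >=1 short/mid and >=1 long study.
check_inclusion <- function(ds, strict = FALSE) {
  ph <- study_phase(ds$studies)
  by_mol <- split(ph, ds$studies$molecule_id)
  bad <- names(by_mol)[!vapply(
    by_mol,
    function(p) any(p == "short_mid", na.rm = TRUE) && any(p == "long", na.rm = TRUE),
    logical(1)
  )]
  if (length(bad) > 0) {
    msg <- paste0(
      "molecule(s) without both a short/mid and a long-term study: ",
      paste(bad, collapse = ", ")
    )
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(bad)
}

#' Load the controlled-terminology maps
#'
#' Reads the finding-term map (columns `category`, `raw_term`,
#' `controlled_term`) and the organ map (columns `organ`,
#' `target_organ_system`) from CSV files. Keys are matched case-insensitively
#' after whitespace normalization. Identical duplicate rows are silently
#' de-duplicated; a key mapping to two different values is an error listing
#' both rows.
#'
#' @param term_path CSV path for the per-category finding-term map.
#' @param organ_path CSV path for the organ/tissue to target-organ-system map.
#' @return A `terminology_map` with elements `term_map` and `organ_map`.
#' @export
#' @examples
#' tm <- load_terminology(
#'   toxconcord_example("finding_terms_synthetic.csv"),
#'   toxconcord_example("organ_systems_synthetic.csv")
#' )
#' tm
load_terminology <- function(term_path, organ_path) {
  tm <- read_delim_chr(term_path, ",")
  om <- read_delim_chr(organ_path, ",")
  check_columns(tm, c("category", "raw_term", "controlled_term"), "term map")
  check_columns(om, c("organ", "target_organ_system"), "organ map")

  term_map <- tibble::tibble(
    category = norm_key(tm$category),
    raw_term = tm$raw_term,
    controlled_term = tm$controlled_term,
    key = paste(norm_key(tm$category), norm_key(tm$raw_term), sep = "\r")
  )
  term_map <- dplyr::distinct(term_map, .data$key, .data$controlled_term,
                              .keep_all = TRUE)
  dup <- term_map$key[duplicated(term_map$key)]
  if (length(dup) > 0) {
    rows <- term_map[term_map$key %in% dup, c("category", "raw_term", "controlled_term")]
    stop(
      "conflicting terminology mapping(s):\n",
      paste(utils::capture.output(print(as.data.frame(rows))), collapse = "\n"),
      call. = FALSE
    )
  }

  organ_map <- tibble::tibble(
    organ = om$organ,
    target_organ_system = om$target_organ_system,
    key = norm_key(om$organ)
  )
  organ_map <- dplyr::distinct(organ_map, .data$key, .data$target_organ_system,
                               .keep_all = TRUE)
  dup <- organ_map$key[duplicated(organ_map$key)]
  if (length(dup) > 0) {
    rows <- organ_map[organ_map$key %in% dup, c("organ", "target_organ_system")]
    stop(
      "conflicting organ mapping(s):\n",
      paste(utils::capture.output(print(as.data.frame(rows))), collapse = "\n"),
      call. = FALSE
    )
  }

  structure(list(term_map = term_map, organ_map = organ_map),
            class = "terminology_map")
}

norm_key <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' @export
print.terminology_map <- function(x, ...) {
  cat("<terminology_map>\n")
  cat("  finding terms: ", nrow(x$term_map), " (",
      length(unique(x$term_map$category)), " categories)\n", sep = "")
  cat("  organs:        ", nrow(x$organ_map), " -> ",
      length(unique(x$organ_map$target_organ_system)),
      " target organ systems\n", sep = "")
  invisible(x)
}

#' Organ-system vocabulary of a terminology map
#'
#' @param map A `terminology_map`.
#' @return Sorted unique target-organ-system labels.
#' @export
organ_systems <- function(map) {
  stopifnot(inherits(map, "terminology_map"))
  sort(unique(map$organ_map$target_organ_system))
}

#' Write result tables and run metadata
#'
#' Writes each table of a named list as `<name>.csv` in `out_dir` (column
#' order as given; infinite likelihood ratios serialize as `Inf`), plus a
#' `run_metadata.json` recording inputs, thresholds, seed, package version and
#' timestamp. Re-running with the same inputs gives byte-identical CSVs; only
#' the metadata timestamp differs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param meta Named list merged into the metadata file (e.g. input paths,
#'   `alpha`, `seed`).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, out_dir, meta = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(names(tables) != ""))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p, progress = FALSE)
    paths <- c(paths, p)
  }
  meta_all <- c(
    meta,
    list(
      package_version = as.character(utils::packageVersion("toxconcord")),
      written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      tables = names(tables)
    )
  )
  mp <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta_all, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Write a dataset back to tab-delimited files
#'
#' Inverse of [read_dataset()]: writes `studies.txt` and `findings.txt` in the
#' input schema (dose levels joined with `;`, missing NOAEL written as
#' `"not identified"`, adverse as `yes`/`no`) so that reading them back
#' reproduces every record.
#'
#' @param dataset A `tox_dataset`.
#' @param out_dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "tox_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  st <- dataset$studies
  out_st <- tibble::tibble(
    study_id = st$study_id,
    molecule_id = st$molecule_id,
    modality = st$modality,
    species = st$species,
    duration_weeks = st$duration_weeks,
    therapeutic_area = st$therapeutic_area,
    route = st$route,
    dose_levels = vapply(st$dose_levels, function(d) paste(d, collapse = ";"),
                         character(1)),
    administrations_per_day = st$administrations_per_day,
    noael_dose_per_day = ifelse(is.na(st$noael_dose_per_day), "not identified",
                                as.character(st$noael_dose_per_day)),
    dose_units = st$dose_units
  )
  fd <- dataset$findings
  out_fd <- tibble::tibble(
    study_id = fd$study_id,
    category = fd$category,
    raw_term = fd$raw_term,
    organ = fd$organ,
    adverse = ifelse(fd$adverse, "yes", "no"),
    onset_dose_per_day = fd$onset_dose_per_day,
    severity = fd$severity,
    reversibility = fd$reversibility,
    notes = fd$notes
  )
  sp <- file.path(out_dir, "studies.txt")
  fp <- file.path(out_dir, "findings.txt")
  readr::write_tsv(out_st, sp, na = "", progress = FALSE)
  readr::write_tsv(out_fd, fp, na = "", progress = FALSE)
  invisible(c(sp, fp))
}
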