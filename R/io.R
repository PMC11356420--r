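#' Read and write feature tables as tab-separated text
#'
#' The canonical interchange format is TSV with a header row: metadata
#' columns `sample_id`, `batch`, `run_order`, `is_qc` first, then one column
#' per feature. Missing (below-detection-limit) entries are empty fields.
#' TSV rather than CSV avoids quoting ambiguity in lipid-style feature names
#' containing commas. Reading validates the structure: ragged rows, duplicate
#' sample ids, duplicate feature names, and non-numeric abundances are
#' rejected with the offending location named.
#'
#' @param path File path.
#' @return `read_feature_table()` returns the feature table tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    abort(sprintf("duplicate feature column(s): %s",
                  paste(unique(header[duplicated(header)]), collapse = ", ")))
  missing_meta <- setdiff(meta_cols, header)
  if (length(missing_meta))
    abort(sprintf("missing metadata column(s): %s",
                  paste(missing_meta, collapse = ", ")))
  feats <- setdiff(header, meta_cols)
  spec <- do.call(readr::cols, c(
    list(sample_id = readr::col_character(),
         batch = readr::col_integer(),
         run_order = readr::col_integer(),
         is_qc = readr::col_logical()),
    setNames(rep(list(readr::col_double()), length(feats)), feats)))
  data <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, na = "", progress = FALSE))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed feature table %s: e.g. row %d, column %d: expected %s, got '%s'",
                  path, probs$row[1], probs$col[1], probs$expected[1],
                  probs$actual[1]))
  }
  dup <- data$sample_id[duplicated(data$sample_id)]
  if (length(dup))
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  data
}

#' @rdname read_feature_table
#' @param data A feature table.
#' @export
write_feature_table <- function(data, path) {
  check_feature_table(data)
  readr::write_tsv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write participant (cohort) tables as TSV
#'
#' Missing covariate entries are empty fields; `race_ethnicity` and
#' `case_status` are restored as factors.
#'
#' @param path File path.
#' @return A tibble (read) or `path`, invisibly (write).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  data <- readr::read_tsv(path, na = "", progress = FALSE,
                          show_col_types = FALSE)
  if ("case_status" %in% names(data))
    data$case_status <- factor(data$case_status,
                               levels = c("control", "case_A", "case_B"))
  if ("race_ethnicity" %in% names(data))
    data$race_ethnicity <- factor(data$race_ethnicity, levels = race_levels)
  data
}

#' @rdname read_cohort_table
#' @param data A participant table.
#' @export
write_cohort_table <- function(data, path) {
  readr::write_tsv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a generated cohort to a directory
#'
#' Emits `participants.tsv`, one `features_<platform>.tsv` per platform, and
#' the truth sidecar `truth.tsv` (generator annotations, kept out of the
#' analysis-facing matrices).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "participants.tsv")
  write_cohort_table(cohort$participants, paths)
  for (p in names(cohort$features)) {
    fp <- file.path(dir, sprintf("features_%s.tsv", p))
    write_feature_table(cohort$features[[p]], fp)
    paths <- c(paths, fp)
  }
  tp <- file.path(dir, "truth.tsv")
  readr::write_tsv(cohort$truth, tp, progress = FALSE)
  invisible(c(paths, tp))
}

#' Read a YAML run configuration
#'
#' A single YAML document drives [orchestrate()]: a `cohort` block (fields of
#' [cohort_config()]; `seed` mandatory), an optional `preprocess` block
#' (fields of [preprocess_config()]), and an optional `evaluation` block
#' (`outcomes`, `platforms`, `covariate_modes`, `procedures`, `reps`,
#' `folds`, `seed`, `v`, `k`, `pooled`, `exclude_ht`).
#'
#' @param path Path to the YAML file.
#' @return A named list with elements `cohort` (a `cohort_config`),
#'   `preprocess` (a `preprocess_config`) and `evaluation` (a list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$cohort$seed)) abort("config must set cohort.seed")
  coh <- raw$cohort
  for (nm in c("platform_sizes", "n_signal_features", "covariate_missing_rates",
               "lod_missing_rate", "drift_amplitude", "tech_sd")) {
    if (!is.null(coh[[nm]])) coh[[nm]] <- unlist(coh[[nm]])
  }
  cohort <- do.call(cohort_config, coh)
  preprocess <- do.call(preprocess_config, raw$preprocess %||% list())
  list(cohort = cohort, preprocess = preprocess,
       evaluation = raw$evaluation %||% list())
}

#' Generate, preprocess and evaluate in one orchestrated run
#'
#' Runs the full pipeline from a configuration: generate the synthetic
#' cohort, write its tables, run the study grid, write the report tables and
#' a CV-AUC figure, and record a manifest (configuration snapshot, seeds,
#' stage row/column accounting, and an MD5 digest of every emitted artifact).
#' Reruns with the same configuration reproduce identical digests for the
#' deterministic stages. A stage failure halts the run with the failing
#' stage named.
#'
#' @param config A configuration list from [read_run_config()], or a path to
#'   a YAML file.
#' @param out_dir Output directory.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
orchestrate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  log <- list()

  cohort <- stage("generate", generate_cohort(config$cohort))
  stage("write_cohort", write_cohort(cohort, file.path(out_dir, "cohort")))
  log$generate <- list(
    participants = nrow(cohort$participants),
    features = purrr::map_int(cohort$features, ~length(feature_cols(.x))))

  ev <- config$evaluation
  procedures <- standard_procedures()
  if (!is.null(ev$procedures)) procedures <- procedures[unlist(ev$procedures)]
  lib <- default_sl_library()
  report <- stage("evaluate", run_study(
    cohort,
    outcomes = unlist(ev$outcomes) %||% c("A", "B"),
    platforms = unlist(ev$platforms) %||% names(cohort$features),
    covariate_modes = unlist(ev$covariate_modes) %||%
      c("metabolites_base", "metabolites_all"),
    procedures = procedures,
    reps = ev$reps %||% 100L, folds = ev$folds %||% 5L,
    seed = ev$seed %||% config$cohort$seed,
    library = lib, v = ev$v %||% 10L, k = ev$k %||% 20L,
    preprocess = config$preprocess,
    exclude_ht = isTRUE(ev$exclude_ht), pooled = isTRUE(ev$pooled)))
  log$evaluate <- list(n_reports = nrow(report$cv_auc))

  stage("write_reports", {
    readr::write_tsv(dplyr::select(report$cv_auc, -"report"),
                     file.path(out_dir, "cv_auc.tsv"), progress = FALSE)
    if (!is.null(report$selection)) {
      sel <- tidyr::unnest(report$selection, "stability")
      readr::write_tsv(sel, file.path(out_dir, "selection.tsv"),
                       progress = FALSE)
    }
    if (!is.null(report$pev)) {
      pv <- tidyr::unnest(dplyr::select(report$pev, -"joint_pev"), "report")
      readr::write_tsv(pv, file.path(out_dir, "pev.tsv"), progress = FALSE)
    }
    p <- plot_cv_auc(report$cv_auc)
    ggplot2::ggsave(file.path(out_dir, "cv_auc.pdf"), p,
                    width = 8, height = 5)
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    config = list(cohort = unclass(config$cohort),
                  preprocess = unclass(config$preprocess),
                  evaluation = ev),
    seeds = list(cohort = config$cohort$seed,
                 evaluation = ev$seed %||% config$cohort$seed,
                 imputation = config$preprocess$imputation_seed),
    stages = log,
    artifacts = purrr::map(setNames(files, sub(paste0(out_dir, "/?"), "",
                                               files)),
                           ~unname(tools::md5sum(.x))),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
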