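#' Build a pipeline run configuration
#'
#' Exactly one of `input` (CSV path or municipality tibble) or
#' `synthetic` (a [synthetic_config()]) must be given. Every published
#' constant of the evaluation design — the 80% coverage cut, the 5th/95th
#' trim percentiles, the stratum bounds — is a configurable default, so
#' sensitivity analyses need no code edits.
#'
#' @param input CSV path or municipality tibble, or `NULL`.
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param models `"both"`, `"model1"` or `"model2"`.
#' @param coverage_threshold coverage cut in percent.
#' @param trim_low,trim_high trim percentiles, `0 <= low < high <= 100`.
#' @param eps_eff,lambda_tol DEA tolerances.
#' @param expansion_denominator `"all"` or `"inefficient"`.
#' @param out_dir directory for report CSVs, or `NULL` to skip writing.
#' @param seed integer seed forwarded to the synthetic generator.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       models = c("both", "model1", "model2"),
                       coverage_threshold = 80,
                       trim_low = 5, trim_high = 95,
                       eps_eff = 1e-6, lambda_tol = 1e-6,
                       expansion_denominator = c("all", "inefficient"),
                       out_dir = NULL, seed = 1L) {
  models <- match.arg(models)
  expansion_denominator <- match.arg(expansion_denominator)
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of 'input' and 'synthetic' must be given",
         call. = FALSE)
  }
  if (!(trim_low >= 0 && trim_low < trim_high && trim_high <= 100)) {
    stop("need 0 <= trim_low < trim_high <= 100", call. = FALSE)
  }
  structure(list(input = input, synthetic = synthetic, models = models,
                 coverage_threshold = coverage_threshold,
                 trim_low = trim_low, trim_high = trim_high,
                 eps_eff = eps_eff, lambda_tol = lambda_tol,
                 expansion_denominator = expansion_denominator,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Preprocess a municipality table for one model
#'
#' The fixed stage order: exclusions, derived products, percentile trim,
#' stratification. Re-running the chain on its own retained output is a
#' no-op.
#'
#' @param table validated municipality tibble.
#' @param spec a [model_spec()].
#' @param coverage_threshold,trim_low,trim_high see [run_config()].
#' @return List with `strata` (named list of [stratum_data()]), `retained`
#'   (tibble), `log` (all exclusion stages), `thresholds`, `dmu_rule`.
#' @export
preprocess_model <- function(table, spec, coverage_threshold = 80,
                             trim_low = 5, trim_high = 95) {
  excl <- apply_exclusions(table, spec, coverage_threshold)
  der <- derive_products(excl$retained, spec)
  trim <- trim_percentiles(der, spec$trim_vars, trim_low, trim_high)
  strata <- stratify(trim$retained, spec)
  rule <- suppressWarnings(check_dmu_rule(strata))
  list(strata = strata, retained = trim$retained,
       log = dplyr::bind_rows(excl$log, trim$log),
       thresholds = trim$thresholds, dmu_rule = rule)
}

#' Run the full evaluation pipeline
#'
#' Generates or loads the municipality table, then per selected model:
#' exclusions, derived products, percentile trim, stratification, a DEA
#' frontier per stratum, classification, expansion targets, descriptive
#' statistics and the correlation screen; cross-classifies when both
#' models run. Writes report CSVs when `out_dir` is set and returns a
#' manifest of per-stage counts, warnings, and file paths.
#'
#' @param config a [run_config()].
#' @return A list of class `run_manifest`: `n_input`, per-model results
#'   (`classification`, `frontiers`, `expansion`, `stats`,
#'   `correlations`, `log`, `stage_counts`, `dmu_rule`), `cross`
#'   (when both models ran), `files`, `warnings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings <- character(0)

  table <- if (!is.null(config$synthetic)) {
    generate_municipalities(config$synthetic)$table
  } else if (is.character(config$input)) {
    read_municipalities(config$input)
  } else {
    tbl <- tibble::as_tibble(config$input)
    viol <- validate_municipalities(tbl)
    if (nrow(viol)) {
      stop("invalid input table: ",
           paste(viol$problem, collapse = "; "), call. = FALSE)
    }
    tbl
  }

  specs <- builtin_model_specs()
  wanted <- if (config$models == "both") c("model1", "model2") else
    config$models

  models <- list()
  for (mn in wanted) {
    spec <- specs[[mn]]
    pre <- withCallingHandlers(
      preprocess_model(table, spec, config$coverage_threshold,
                       config$trim_low, config$trim_high),
      message = function(m) {
        warnings <<- c(warnings, paste0(mn, ": ", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    for (i in which(!pre$dmu_rule$ok)) {
      warnings <- c(warnings, sprintf(
        "%s stratum %d: %d DMUs below the 3x(m+s)=%d adequacy rule",
        mn, pre$dmu_rule$stratum[i], pre$dmu_rule$n[i],
        pre$dmu_rule$required[i]))
    }
    frontiers <- purrr::map(pre$strata, dea_frontier,
                            eps_eff = config$eps_eff,
                            lambda_tol = config$lambda_tol)
    classification <- classify_dmus(frontiers)
    expansion <- aggregate_expansion(
      frontiers, denominator = config$expansion_denominator)
    stage_counts <- pre$log |>
      dplyr::count(.data$stage, name = "excluded")
    models[[mn]] <- list(
      spec = spec, strata = pre$strata, frontiers = frontiers,
      classification = classification, expansion = expansion,
      stats = descriptive_stats(pre$strata),
      correlations = purrr::map_dfr(
        # the screen needs n >= 3; tiny strata are simply not screened
        purrr::keep(pre$strata, ~ length(.x$dmu_ids) >= 3),
        function(d) {
          dplyr::mutate(correlation_screen(d), stratum = d$stratum,
                        .before = 1)
        }),
      log = pre$log, stage_counts = stage_counts,
      dmu_rule = pre$dmu_rule,
      n_retained = sum(purrr::map_int(pre$strata,
                                      ~ length(.x$dmu_ids))))
  }

  cross <- NULL
  if (length(models) == 2L) {
    cross <- cross_classify(models$model1$classification,
                            models$model2$classification)
  }

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(df, name) {
      path <- file.path(config$out_dir, name)
      readr::write_csv(df, path, progress = FALSE)
      files <<- c(files, path)
    }
    for (mn in names(models)) {
      mm <- models[[mn]]
      res <- purrr::map_dfr(mm$frontiers, function(fr) {
        td <- tidy(fr)
        td$reference_set <- purrr::map_chr(
          td$reference_set, paste, collapse = ";")
        td
      })
      emit(res, paste0(mn, "_results.csv"))
      emit(mm$classification$per_stratum, paste0(mn, "_classification.csv"))
      emit(mm$expansion, paste0(mn, "_expansion.csv"))
      emit(mm$stats, paste0(mn, "_descriptive_stats.csv"))
      emit(mm$correlations, paste0(mn, "_correlations.csv"))
      emit(mm$log, paste0(mn, "_exclusions.csv"))
    }
    if (!is.null(cross)) emit(cross$table, "cross_model_table.csv")
  }

  structure(list(n_input = nrow(table), models = models, cross = cross,
                 files = files, warnings = warnings),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", x$n_input, " municipalities in\n", sep = "")
  for (mn in names(x$models)) {
    mm <- x$models[[mn]]
    cat("  ", mn, ": ", mm$n_retained, " retained across ",
        length(mm$strata), " strata; excluded by stage: ",
        paste(sprintf("%s=%d", mm$stage_counts$stage,
                      mm$stage_counts$excluded), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$cross)) {
    cat("  cross-model sample: ", nrow(x$cross$per_dmu), "\n", sep = "")
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    - ", w, "\n", sep = "")
  }
  invisible(x)
}
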