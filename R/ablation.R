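#' The progressive mapping ablation cases
#'
#' Cases I–V cumulatively switch microscopy, immunohistochemistry, imaging
#' results, anatomical location, and finally the diagnosis labels from raw
#' terms to ontology mappings; the baseline maps nothing.
#'
#' @return named list of [mapping_mask] objects in fixed order `baseline`,
#'   `case_I` ... `case_V`.
#' @export
ablation_cases <- function() {
  list(
    baseline = mapping_mask(),
    case_I = mapping_mask(microscopy = "mapped"),
    case_II = mapping_mask(microscopy = "mapped",
                           immunohistochemistry = "mapped"),
    case_III = mapping_mask(microscopy = "mapped",
                            immunohistochemistry = "mapped",
                            imaging = "mapped"),
    case_IV = mapping_mask(microscopy = "mapped",
                           immunohistochemistry = "mapped",
                           imaging = "mapped", anatomy = "mapped"),
    case_V = mapping_mask(microscopy = "mapped",
                          immunohistochemistry = "mapped",
                          imaging = "mapped", anatomy = "mapped",
                          labels = "mapped")
  )
}

comparison_masks <- function() {
  list(
    baseline = mapping_mask(),
    inputs_mapped = mapping_mask(microscopy = "mapped",
                                 immunohistochemistry = "mapped",
                                 imaging = "mapped", anatomy = "mapped"),
    inputs_outputs_mapped = mapping_mask(microscopy = "mapped",
                                         immunohistochemistry = "mapped",
                                         imaging = "mapped",
                                         anatomy = "mapped",
                                         labels = "mapped")
  )
}

run_grid <- function(reports, ont, specs, cv, masks, config,
                     benchmark_executions = 1L) {
  table <- map_corpus(reports, ont, config)
  cells <- list()
  results <- list()
  for (case_name in names(masks)) {
    mask <- masks[[case_name]]
    X <- build_features(reports, table, mask)
    Y <- build_labels(reports, table, mask)
    for (spec_name in names(specs)) {
      cell_id <- paste(case_name, spec_name, sep = "|")
      res <- tryCatch({
        if (benchmark_executions > 1L) {
          bench <- runtime_benchmark(
            function() cross_validate(X, Y, specs[[spec_name]], cv),
            executions = benchmark_executions)
          out <- cross_validate(X, Y, specs[[spec_name]], cv)
          out$aggregate$runtime_seconds <- bench$mean_seconds
          out
        } else {
          cross_validate(X, Y, specs[[spec_name]], cv)
        }
      }, error = function(e) {
        structure(list(error = sprintf("cell %s: %s", cell_id,
                                       conditionMessage(e))),
                  class = "eval_error")
      })
      results[[cell_id]] <- res
      a <- if (inherits(res, "eval_error")) {
        data.frame(hamming_loss = NA_real_, balanced_accuracy = NA_real_,
                   recall = NA_real_, correct = NA_real_,
                   partially_correct = NA_real_, incorrect = NA_real_,
                   runtime_seconds = NA_real_, failed = TRUE)
      } else {
        cbind(as.data.frame(res$aggregate), failed = FALSE)
      }
      cells[[cell_id]] <- cbind(
        data.frame(case = case_name, model = spec_name,
                   stringsAsFactors = FALSE), a)
    }
  }
  grid <- do.call(rbind, cells)
  rownames(grid) <- NULL
  list(grid = grid, results = results, mapping_table = table)
}

experiment_report <- function(kind, grid, results, improvements = NULL) {
  structure(list(kind = kind, grid = grid, results = results,
                 improvements = improvements),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: %s>\n", x$kind))
  print(x$grid, digits = 4)
  if (!is.null(x$improvements)) {
    cat("\nRelative improvement in correct results (%):\n")
    print(x$improvements, digits = 4)
  }
  invisible(x)
}

#' Three-column comparison: baseline vs input mapping vs full mapping
#'
#' Evaluates `{baseline, inputs mapped, inputs + outputs mapped}` for each
#' model and derives the relative improvement in correct results of the
#' fully mapped case over the baseline.
#'
#' @param reports long-format report data frame.
#' @param ont an [ontology].
#' @param specs named list of [model_spec] objects.
#' @param cv a [cv_config].
#' @param config a [mapping_config].
#' @param benchmark_executions runs per cell for runtime measurement (the
#'   full seven-execution protocol is opt-in; grids default to one).
#' @return an `experiment_report` with the `case x model` grid, the
#'   improvement table, and per-cell `eval_result`s.
#' @export
run_comparison <- function(reports, ont, specs = default_model_specs(),
                           cv = cv_config(), config = mapping_config(),
                           benchmark_executions = 1L) {
  out <- run_grid(reports, ont, specs, cv, comparison_masks(), config,
                  benchmark_executions)
  grid <- out$grid
  improvements <- do.call(rbind, lapply(names(specs), function(m) {
    base <- grid$correct[grid$case == "baseline" & grid$model == m]
    full <- grid$correct[grid$case == "inputs_outputs_mapped" & grid$model == m]
    data.frame(model = m, correct_baseline = base, correct_mapped = full,
               improvement_pct = if (is.na(base) || base <= 0) NA_real_
                                 else relative_improvement(base, full),
               stringsAsFactors = FALSE)
  }))
  experiment_report("comparison", grid, out$results, improvements)
}

#' Progressive ablation: baseline and Cases I–V
#'
#' Evaluates the cumulative mapping cases for each model with all three
#' metrics and per-cell runtime.
#'
#' @inheritParams run_comparison
#' @return an `experiment_report` with a `6 cases x models` grid.
#' @export
run_cases <- function(reports, ont, specs = default_model_specs(),
                      cv = cv_config(), config = mapping_config(),
                      benchmark_executions = 1L) {
  out <- run_grid(reports, ont, specs, cv, ablation_cases(), config,
                  benchmark_executions)
  experiment_report("cases", out$grid, out$results)
}

#' Write an experiment report as TSV + JSON
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @param seed seed echoed into the metadata headers.
#' @return the directory, invisibly.
#' @export
write_experiment_report <- function(report, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_with_header(report$grid,
                        file.path(dir, sprintf("%s_grid.tsv", report$kind)),
                        seed = seed)
  if (!is.null(report$improvements)) {
    write_tsv_with_header(report$improvements,
                          file.path(dir, sprintf("%s_improvements.tsv",
                                                 report$kind)),
                          seed = seed)
  }
  payload <- list(kind = report$kind, grid = report$grid,
                  improvements = report$improvements, seed = seed)
  jsonlite::write_json(payload,
                       file.path(dir, sprintf("%s_report.json", report$kind)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
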