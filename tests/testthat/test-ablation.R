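# Small cohorts and shrunken ensembles keep these orchestration tests fast;
# the full-scale stated world is exercised in test-acceptance.R.

fast_specs <- function(seed = 1L) {
  list(logistic_regression = model_spec("logistic_regression", seed = seed),
       random_forest = model_spec("random_forest",
                                  list(ntree = 15L), seed = seed),
       gradient_tree_boosting = model_spec("gradient_tree_boosting",
                                           list(ntree = 15L), seed = seed))
}

small_reports <- function() {
  co <- cached("small_cohort", function() {
    generate_cohort(generator_config(n_patients = 80, target_vocab = 300,
                                     seed = 17))
  })
  co$reports
}

test_that("ablation cases are cumulative and in fixed order", {
  cases <- ablation_cases()
  expect_identical(names(cases),
                   c("baseline", "case_I", "case_II", "case_III", "case_IV",
                     "case_V"))
  order_ <- c("microscopy", "immunohistochemistry", "imaging", "anatomy",
              "labels")
  mapped_in <- function(mask) order_[unlist(mask[order_]) == "mapped"]
  prev <- character()
  for (nm in names(cases)) {
    cur <- mapped_in(cases[[nm]])
    expect_true(all(prev %in% cur), info = nm)
    prev <- cur
  }
  expect_identical(mapped_in(cases$case_V), order_)
  expect_identical(mapped_in(cases$baseline), character())
})

test_that("the comparison grid covers three cases x models with improvements", {
  reports <- small_reports()
  ont <- fixture_ontology()
  rep_ <- run_comparison(reports, ont, specs = fast_specs(),
                         cv = cv_config(folds = 5, repetitions = 1, seed = 3))
  expect_s3_class(rep_, "experiment_report")
  expect_equal(nrow(rep_$grid), 9L)
  expect_setequal(unique(rep_$grid$case),
                  c("baseline", "inputs_mapped", "inputs_outputs_mapped"))
  expect_false(any(rep_$grid$failed))
  # improvements recomputed from the grid via the relative formula
  for (i in seq_len(nrow(rep_$improvements))) {
    row <- rep_$improvements[i, ]
    if (!is.na(row$improvement_pct) && row$correct_baseline > 0) {
      expect_equal(row$improvement_pct,
                   relative_improvement(row$correct_baseline,
                                        row$correct_mapped))
    }
  }
})

test_that("the cases grid has 6 cases x 3 models and matching baselines", {
  reports <- small_reports()
  ont <- fixture_ontology()
  cv <- cv_config(folds = 5, repetitions = 1, seed = 3)
  rc <- run_cases(reports, ont, specs = fast_specs(), cv = cv)
  expect_equal(nrow(rc$grid), 18L)
  expect_true(all(c("hamming_loss", "balanced_accuracy", "recall",
                    "runtime_seconds") %in% names(rc$grid)))
  # baseline cells agree with the comparison grid under identical seeds
  cmp <- run_comparison(reports, ont, specs = fast_specs(), cv = cv)
  base_a <- rc$grid[rc$grid$case == "baseline",
                    c("model", "hamming_loss", "correct")]
  base_b <- cmp$grid[cmp$grid$case == "baseline",
                     c("model", "hamming_loss", "correct")]
  expect_equal(base_a[order(base_a$model), ],
               base_b[order(base_b$model), ], ignore_attr = TRUE)
})

test_that("a heterogeneity-free corpus makes mapping a near no-op", {
  # every surface form is already a preferred label: the mapped and raw
  # feature spaces are the same columns up to naming, so metrics coincide
  ont <- fixture_ontology()
  reports <- reports_from_list(list(
    p1 = list(microscopy = "neuronal loss", diagnosis = "hippocampal sclerosis"),
    p2 = list(microscopy = "astrogliosis", diagnosis = "gliosis"),
    p3 = list(microscopy = "neuronal loss", diagnosis = "hippocampal sclerosis"),
    p4 = list(microscopy = "cortical dyslamination",
              diagnosis = "malformation of cortical development"),
    p5 = list(microscopy = "astrogliosis", diagnosis = "gliosis"),
    p6 = list(microscopy = "cortical dyslamination",
              diagnosis = "malformation of cortical development"),
    p7 = list(microscopy = "neuronal loss", diagnosis = "hippocampal sclerosis"),
    p8 = list(microscopy = "astrogliosis", diagnosis = "gliosis"),
    p9 = list(microscopy = "cortical dyslamination",
              diagnosis = "malformation of cortical development"),
    p10 = list(microscopy = "neuronal loss", diagnosis = "hippocampal sclerosis")))
  cv <- cv_config(folds = 5, repetitions = 1, seed = 21)
  rep_ <- run_comparison(reports, ont,
                         specs = fast_specs(), cv = cv)
  g <- rep_$grid
  for (m in unique(g$model)) {
    expect_equal(g$correct[g$case == "baseline" & g$model == m],
                 g$correct[g$case == "inputs_outputs_mapped" & g$model == m],
                 info = m)
  }
})

test_that("experiment reports serialize to TSV and JSON", {
  reports <- small_reports()
  ont <- fixture_ontology()
  rep_ <- run_comparison(reports, ont,
                         specs = fast_specs()["logistic_regression"],
                         cv = cv_config(folds = 5, repetitions = 1, seed = 2))
  dir <- withr::local_tempdir()
  write_experiment_report(rep_, dir, seed = 2)
  expect_true(file.exists(file.path(dir, "comparison_grid.tsv")))
  expect_true(file.exists(file.path(dir, "comparison_report.json")))
  grid <- ontofeat:::read_tsv_skip_header(file.path(dir, "comparison_grid.tsv"))
  expect_equal(nrow(grid), 3L)
})
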