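test_that("the mini-ontology carries the structures the cascade relies on", {
  ont <- fixture_ontology()
  need <- c("HSType1", "HSType2", "HSType3", "GliosisWithoutHS",
            "CA1", "CA2", "CA3", "CA4", "DentateGyrus",
            "NeuronalLoss", "Astrogliosis", "NodularHeterotopia",
            "GlialCell", "Astrocyte", "BrainGlialTumor",
            "BrainGlialNeuronalTumor", "BrainNeuronalTumor", "Hamartoma",
            "EpithelialCyst", "Meningioma", "MetastaticTumor",
            "FCDType1", "FCDType2", "FCDType3", "BalloonCell", "Vimentin")
  expect_true(all(need %in% names(ont$classes)))
  # grading annotations use the 0-2 semiquantitative scale
  gradings <- Filter(Negate(is.null),
                     lapply(ont$classes, function(cl) cl$annotations$grading_value))
  expect_gte(length(gradings), 4L)
  expect_true(all(unlist(gradings) %in% 0:2))
  # HSType3 reaches its finding fillers in one hop
  expect_true("NeuronalLoss" %in%
                ont_related(ont, "HSType3", "hasNeuroPathologyFinding"))
  # required synonym anchor for the semantic example
  expect_true("astroglia" %in% ont$classes$Astrocyte$synonyms)
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- generator_config(n_patients = 40, target_vocab = 200, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$reports, b$reports)
  expect_identical(a$truth$oracle, b$truth$oracle)
})

test_that("label sampling honors prevalence and the dual-pathology rate", {
  cfg0 <- generator_config(n_patients = 50, dual_pathology_rate = 0, seed = 5)
  labs0 <- sample_labels(cfg0)
  expect_true(all(lengths(labs0) == 1L))

  cfg1 <- generator_config(n_patients = 50, dual_pathology_rate = 1, seed = 5)
  labs1 <- sample_labels(cfg1)
  expect_true(all(lengths(labs1) == 2L))
  expect_true(all(vapply(labs1, function(l) l[1] != l[2], TRUE)))

  cfg_bad <- generator_config(n_patients = 10, dual_pathology_rate = 0.5,
                              label_prevalence = c(OnlyOne = 1), seed = 5)
  expect_error(sample_labels(cfg_bad), "distinct second")
})

test_that("concept sampling is diagnosis-conditioned and never empty", {
  cfg <- generator_config(seed = 2)
  model <- ontofeat:::load_concept_model(cfg)
  set.seed(1)
  hits <- 0
  for (i in 1:50) {
    cs <- sample_concepts("HippocampalSclerosis", cfg, model)
    expect_gt(sum(lengths(cs)), 0)
    if (length(intersect(cs$microscopy, c("NeuronalLoss", "Astrogliosis")))) {
      hits <- hits + 1
    }
  }
  expect_gt(hits, 40) # signature concepts appear with high probability
  expect_error(sample_concepts("NotADiagnosis", cfg, model), "concept table")
})

test_that("noise-free single-surface rendering is verbatim", {
  ont <- fixture_ontology()
  cfg <- generator_config(lexical_noise_rate = 0, colocation_rate = 0,
                          richness_scale = 1, seed = 1)
  model <- ontofeat:::load_concept_model(cfg)
  pools <- list(imaging = list(FlowVoid = "flow voids"))
  set.seed(9)
  r <- render_surface("FlowVoid", "imaging", ont, cfg, pools, model)
  expect_identical(r$surface, "flow voids")
  expect_identical(r$classes, "FlowVoid")
})

test_that("composite renderings carry finding plus location oracle sets", {
  ont <- fixture_ontology()
  cfg <- generator_config(lexical_noise_rate = 0, colocation_rate = 1,
                          richness_scale = 1, seed = 1)
  model <- ontofeat:::load_concept_model(cfg)
  set.seed(4)
  found_composite <- FALSE
  for (i in 1:20) {
    r <- render_surface("NeuronalLoss", "microscopy", ont, cfg, model = model)
    expect_identical(r$classes[1], "NeuronalLoss")
    expect_length(r$classes, 2L)
    if (grepl(" (in|at) ", r$surface)) found_composite <- TRUE
    mapped <- map_term(raw_term(r$surface, "microscopy"), ont)
    expect_setequal(mapped$classes, r$classes)
  }
  expect_true(found_composite)
})

test_that("the oracle covers every generated surface form", {
  co <- fixture_cohort()
  oracle_keys <- paste(co$truth$oracle$surface, co$truth$oracle$category)
  report_keys <- unique(paste(co$reports$term, co$reports$category))
  expect_true(all(report_keys %in% oracle_keys))
})

test_that("mapping recovers at least 90% of the oracle at default noise", {
  co <- fixture_cohort() # lexical_noise_rate = 0.2
  rec <- oracle_recovery(fixture_mapping(), co)
  expect_gte(rec$rate, 0.9)
})

test_that("every patient keeps at least one diagnosis", {
  co <- fixture_cohort()
  dx <- co$reports[co$reports$category == "diagnosis", ]
  expect_setequal(unique(co$reports$patient_id), unique(dx$patient_id))
})

test_that("reduction pattern matches the published ratios on the tuned profile", {
  co <- generate_cohort(table2_profile(seed = 1))
  tab <- map_corpus(co$reports, co$ontology)
  vc <- vocab_counts(co$reports, tab)
  printed <- c(microscopy = 84.41, immunohistochemistry = 40.4,
               imaging = 62.38, anatomy = 63.47, diagnosis = 46.30)
  expect_true(all(abs(as.numeric(vc$reduction) - printed) <= 10))
})
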