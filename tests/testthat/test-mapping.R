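test_that("normalization lowercases, strips punctuation and stopwords", {
  expect_identical(normalize_term("Depletion of neuron in CA2"),
                   c("depletion", "neuron", "ca2"))
  expect_identical(normalize_term("CA2"), "ca2")
  expect_identical(
    normalize_term("Heterotropic neuronal nodules at periventricular site"),
    c("heterotropic", "neuronal", "nodules", "periventricular", "site"))
  expect_identical(normalize_term(""), character())
  expect_identical(normalize_term("  a,b;C!  "),
                   c("a", "b", "c"))
})

test_that("syntactic matching requires a full-term unique hit", {
  ont <- fixture_ontology()
  r <- match_syntactic(raw_term("microglia nodules", "microscopy"), ont)
  expect_identical(r$classes, "NodularHeterotopia")
  expect_identical(r$step, "syntactic")
  # a class's own preferred label maps to itself
  r2 <- match_syntactic(raw_term("Astrogliosis", "microscopy"), ont)
  expect_identical(r2$classes, "Astrogliosis")
  expect_identical(match_syntactic(raw_term("zzqx", "microscopy"), ont)$step,
                   "unmapped")
})

test_that("ambiguous surface forms resolve by preferred label or get flagged", {
  tiny <- tiny_ontology()
  # "alpha finding" is a synonym of both A and C: flagged, not auto-resolved
  amb <- match_syntactic(raw_term("alpha finding", "microscopy"), tiny)
  expect_identical(amb$step, "unmapped")
  expect_true(amb$needs_review)
  # "a finding" is A's preferred label and only A's
  pref <- match_syntactic(raw_term("a finding", "microscopy"), tiny)
  expect_identical(pref$classes, "A")
})

test_that("compositional matching consumes greedy longest spans", {
  ont <- fixture_ontology()
  for (phrase in c("depletion of neuron in CA2", "segmental cell loss in CA2",
                   "neuronal cell loss in CA2",
                   "reduced neuronal density in CA2")) {
    r <- map_term(raw_term(phrase, "microscopy"), ont)
    expect_setequal(r$classes, c("NeuronalLoss", "CA2"))
    expect_identical(r$step, "compositional")
  }
  expect_identical(
    match_compositional(raw_term("qq ww ee", "microscopy"), ont)$step,
    "unmapped")
})

test_that("compositional residual threshold controls single-class success", {
  ont <- fixture_ontology()
  # one class, residual 1/2 <= 0.5: success
  ok <- match_compositional(raw_term("marked astrogliosis", "microscopy"), ont)
  expect_identical(ok$classes, "Astrogliosis")
  expect_identical(ok$residual_tokens, "marked")
  # one class, residual 3/4 > 0.5: failure
  bad <- match_compositional(
    raw_term("qq ww ee astrogliosis", "microscopy"), ont)
  expect_identical(bad$step, "unmapped")
  # threshold is configurable
  loose <- match_compositional(
    raw_term("qq ww ee astrogliosis", "microscopy"), ont,
    mapping_config(max_residual = 0.8))
  expect_identical(loose$classes, "Astrogliosis")
})

test_that("semantic transformation anchors stems and expands one hop", {
  ont <- fixture_ontology()
  r <- map_term(raw_term("astroglial phenotype", "microscopy"), ont)
  expect_setequal(r$classes, c("GlialCell", "Astrocyte", "BrainGlialTumor"))
  expect_identical(r$step, "semantic")
  expect_identical(
    transform_semantic(raw_term("qqq www", "microscopy"), ont)$step,
    "unmapped")
  # anchor with no neighbors stays alone
  tiny <- ontology(list(list(id = "Solo", label = "glioma")))
  solo <- transform_semantic(raw_term("gliomatous change", "microscopy"), tiny)
  expect_identical(solo$classes, "Solo")
  expect_identical(solo$step, "semantic")
})

test_that("the cascade applies steps in fixed order and is deterministic", {
  ont <- fixture_ontology()
  # syntactic always wins for stored surface forms
  for (cl in ont$classes[c("NeuronalLoss", "CA2", "GFAP", "BrainTumor")]) {
    for (s in c(cl$label, cl$synonyms)) {
      r <- map_term(raw_term(s, "microscopy"), ont)
      expect_identical(r$step, "syntactic")
      expect_identical(r$classes, cl$id)
    }
  }
  a <- map_term(raw_term("depletion of neuron in CA2", "microscopy"), ont)
  b <- map_term(raw_term("depletion of neuron in CA2", "microscopy"), ont)
  expect_identical(a, b)
})

test_that("map_corpus maps distinct normalized terms once with provenance", {
  ont <- fixture_ontology()
  reports <- reports_from_list(list(
    p1 = list(microscopy = c("astrogliosis", "Astrogliosis"),
              diagnosis = "gliosis"),
    p2 = list(microscopy = "neuronal loss", diagnosis = "gliosis")))
  tab <- map_corpus(reports, ont)
  expect_s3_class(tab, "mapping_table")
  expect_equal(nrow(tab), 3L) # astrogliosis, neuronal loss, gliosis
  expect_true(all(tab$step == "syntactic"))
  expect_equal(nrow(attr(tab, "unmapped")), 0L)
  expect_equal(tab$frequency[tab$norm_key == "astrogliosis"], 2L)
  empty <- map_corpus(reports[0, ], ont)
  expect_equal(nrow(empty), 0L)
})

test_that("distinct mapped feature keys never exceed distinct raw terms", {
  co <- fixture_cohort()
  tab <- fixture_mapping()
  vc <- vocab_counts(co$reports, tab)
  expect_true(all(vc$mapped <= vc$raw))
})

test_that("review tables round-trip and reviewed overrides stick", {
  ont <- fixture_ontology()
  reports <- reports_from_list(list(
    p1 = list(microscopy = c("astrogliosis", "weird unknown thing"),
              diagnosis = "gliosis")))
  tab <- map_corpus(reports, ont)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_review_table(tab, path)
  back <- import_review_table(path, tab, ont)
  expect_identical(back$class_ids, tab$class_ids)

  # approve an override for the unmapped term
  df <- read.delim(path, stringsAsFactors = FALSE)
  i <- df$raw_text == "weird unknown thing"
  df$class_ids[i] <- "NonspecificChanges"
  df$approved[i] <- "yes"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  upd <- import_review_table(path, tab, ont)
  j <- upd$norm_key == "weird unknown thing"
  expect_true(upd$reviewed[j])
  expect_identical(upd$class_ids[j], "NonspecificChanges")

  # malformed rows fail loudly
  df$category[1] <- "xray"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(import_review_table(path, tab, ont), "row 1")
  df$category[1] <- "microscopy"
  df$class_ids[1] <- "NotAClass"
  df$approved[1] <- "yes"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(import_review_table(path, tab, ont), "NotAClass")
})
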