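test_that("lexicon fixture loads with the expected synonym structure", {
  ont <- fixture_ontology()
  nh <- ont$classes$NodularHeterotopia
  expect_gte(length(nh$synonyms), 4L)
  expect_true("bilateral periventricular heterotropia" %in% nh$synonyms)
  expect_true(length(ont$classes) >= 60 && length(ont$classes) <= 120)
})

test_that("ontology constructor enforces its invariants", {
  expect_error(ontology(list()), "empty ontology")
  expect_error(
    ontology(list(list(id = "A", label = "a", parents = "Ghost"))),
    "Ghost")
  expect_error(
    ontology(list(list(id = "A", label = "a"), list(id = "A", label = "b"))),
    "duplicate class id")
  expect_error(
    ontology(list(list(id = "A", label = "a",
                       annotations = list(grading_value = 5)))),
    "grading_value")
  expect_error(
    ontology(list(list(id = "A", label = "a", parents = "B"),
                  list(id = "B", label = "b", parents = "A"))),
    "cycle")
  expect_error(
    ontology(list(list(id = "A", label = "a")),
             relations = data.frame(property = "p", source = "A",
                                    target = "Z", quantifier = "some")),
    "unknown class")
})

test_that("lexicon writing round-trips the full terminology", {
  ont <- fixture_ontology()
  path <- withr::local_tempfile(fileext = ".json")
  write_lexicon(ont, path)
  ont2 <- load_lexicon(path)
  expect_identical(sort(names(ont$classes)), sort(names(ont2$classes)))
  for (id in names(ont$classes)) {
    expect_identical(ont$classes[[id]]$synonyms, ont2$classes[[id]]$synonyms)
    expect_identical(ont$classes[[id]]$parents, ont2$classes[[id]]$parents)
  }
  expect_equal(nrow(ont$relations), nrow(ont2$relations))
  expect_equal(length(ont$compositions), length(ont2$compositions))
})

test_that("label index covers every stored synonym after normalization", {
  ont <- fixture_ontology()
  for (cl in ont$classes) {
    for (s in c(cl$label, cl$synonyms)) {
      hit <- ontofeat:::index_lookup(ont$label_index,
                                     ontofeat:::normalize_key(s))
      expect_true(cl$id %in% hit)
    }
  }
})

test_that("ancestors computes the transitive isA closure", {
  ont <- fixture_ontology()
  expect_identical(ont_ancestors(ont, "NeuropathologyEntity"), character())
  expect_true("GlialCell" %in% ont_ancestors(ont, "Astrocyte"))
  chain <- ontology(list(list(id = "C", label = "c"),
                         list(id = "B", label = "b", parents = "C"),
                         list(id = "A", label = "a", parents = "B")))
  expect_setequal(ont_ancestors(chain, "A"), c("B", "C"))
  expect_error(ont_ancestors(ont, "Nope"), "unknown class id")
})

test_that("ancestors is idempotent under closure", {
  ont <- fixture_ontology()
  for (id in c("Astrocyte", "HSType3", "CA2", "FCDType2", "NodularHeterotopia")) {
    anc <- ont_ancestors(ont, id)
    for (a in anc) {
      expect_true(all(ont_ancestors(ont, a) %in% anc))
    }
  }
})

test_that("related returns one-hop neighborhoods under a property filter", {
  ont <- fixture_ontology()
  expect_identical(ont_related(ont, "CA1", "hasEtiology"), character())
  hs3 <- ont_related(ont, "HSType3", "hasNeuroPathologyFinding")
  expect_true(all(c("NeuronalLoss", "Astrogliosis") %in% hs3))
  # wildcard equals brute-force enumeration over the relation table
  for (id in c("Astrocyte", "HSType1", "BalloonCell")) {
    brute <- unique(ont$relations$target[ont$relations$source == id])
    expect_setequal(ont_related(ont, id, "*"), brute)
  }
})

test_that("OWL import projects classes, labels, synonyms and restrictions", {
  path <- withr::local_tempfile(fileext = ".owl")
  writeLines(owl_fixture_xml(), path)
  ont <- load_owl(path)
  expect_length(ont$classes, 3L)
  expect_identical(ont$classes$A$parents, "B")
  expect_true("x" %in% ont$classes$C$synonyms)
  expect_equal(nrow(ont$relations), 1L)
  expect_identical(ont$relations$property, "hasFinding")
  expect_identical(ont$relations$quantifier, "some")

  empty <- withr::local_tempfile(fileext = ".owl")
  writeLines(paste0(
    '<?xml version="1.0"?><rdf:RDF ',
    'xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
    'xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#" ',
    'xmlns:owl="http://www.w3.org/2002/07/owl#"/>'), empty)
  expect_error(load_owl(empty), "no classes")

  ttl <- withr::local_tempfile(fileext = ".ttl")
  writeLines("@prefix owl: <http://www.w3.org/2002/07/owl#> .", ttl)
  expect_error(load_owl(ttl), "Turtle")
})
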