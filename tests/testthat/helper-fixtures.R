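# Shared fixtures, built in code. Expensive objects (the default 312-patient
# cohort and its mapping table) are cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fixture_ontology <- function() cached("mini_ontology", mini_ontology)

# default stated-world cohort (seed 1) plus its corpus mapping
fixture_cohort <- function() {
  cached("cohort", function() generate_cohort(generator_config(seed = 1)))
}

fixture_mapping <- function() {
  cached("mapping", function() {
    co <- fixture_cohort()
    map_corpus(co$reports, co$ontology)
  })
}

full_mask <- function() {
  mapping_mask("mapped", "mapped", "mapped", "mapped", "mapped")
}

# A stated world in which microscopy carries the dominant (indeed, the only)
# diagnosis signal: the non-microscopy concept tables are flattened so every
# diagnosis shares one inclusion distribution, making those categories pure
# noise with respect to the labels. Surface richness is held at the
# published consolidation ratios (the table2_profile world, noise-free), at
# which the raw microscopy columns remain frequent enough for their signal
# to dominate impurity/coefficient importances.
microscopy_dominant_config <- function(seed) {
  model <- yaml::read_yaml(system.file("extdata", "concept_model.yaml",
                                       package = "ontofeat"))
  flat_cats <- c("immunohistochemistry", "imaging", "anatomy")
  pooled <- list()
  for (cat in flat_cats) {
    probs <- list()
    for (d in names(model$diagnoses)) {
      tab <- model$diagnoses[[d]][[cat]]
      for (cpt in names(tab)) probs[[cpt]] <- c(probs[[cpt]], tab[[cpt]])
    }
    pooled[[cat]] <- lapply(probs, mean)
  }
  for (d in names(model$diagnoses)) {
    for (cat in flat_cats) model$diagnoses[[d]][[cat]] <- pooled[[cat]]
  }
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(model, path)
  table2_profile(seed = seed, concept_model = path)
}

# a tiny hand-built terminology for unit tests
tiny_ontology <- function() {
  ontology(
    classes = list(
      list(id = "Root", label = "root thing"),
      list(id = "B", label = "b finding", parents = "Root"),
      list(id = "A", label = "a finding", synonyms = c("alpha finding", "x"),
           parents = "B"),
      list(id = "C", label = "c finding", synonyms = "alpha finding",
           parents = "Root"),
      list(id = "Loc", label = "left side", parents = "Root")
    ),
    relations = data.frame(
      property = c("hasSite", "hasSite"),
      source = c("A", "B"),
      target = c("Loc", "Root"),
      quantifier = "some", stringsAsFactors = FALSE)
  )
}

# tiny separable multilabel problem: label j is on iff feature j is on
separable_xy <- function(n = 40, L = 3, seed = 99) {
  set.seed(seed)
  Y <- matrix(0L, n, L, dimnames = list(sprintf("p%02d", 1:n),
                                        sprintf("lab%d", 1:L)))
  Y[cbind(1:n, rep(1:L, length.out = n))] <- 1L
  X <- Y
  colnames(X) <- sprintf("feat%d", 1:L)
  list(X = X, Y = Y)
}

# long-format report table from a per-patient spec list
reports_from_list <- function(spec) {
  do.call(rbind, lapply(names(spec), function(pid) {
    do.call(rbind, lapply(names(spec[[pid]]), function(cat) {
      data.frame(patient_id = pid, category = cat,
                 term = spec[[pid]][[cat]], stringsAsFactors = FALSE)
    }))
  }))
}

# independent brute-force metric oracles (explicit confusion counts)
oracle_hamming <- function(Yt, Yp) {
  bad <- 0
  for (i in seq_len(nrow(Yt))) {
    for (l in seq_len(ncol(Yt))) {
      if (Yt[i, l] != Yp[i, l]) bad <- bad + 1
    }
  }
  bad / (nrow(Yt) * ncol(Yt))
}

oracle_balanced_accuracy <- function(Yt, Yp) {
  vals <- c()
  for (l in seq_len(ncol(Yt))) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_len(nrow(Yt))) {
      if (Yt[i, l] == 1 && Yp[i, l] == 1) tp <- tp + 1
      if (Yt[i, l] == 0 && Yp[i, l] == 1) fp <- fp + 1
      if (Yt[i, l] == 0 && Yp[i, l] == 0) tn <- tn + 1
      if (Yt[i, l] == 1 && Yp[i, l] == 0) fn <- fn + 1
    }
    if ((tp + fn) == 0 || (tn + fp) == 0) next
    vals <- c(vals, (tp / (tp + fn) + tn / (tn + fp)) / 2)
  }
  mean(vals)
}

oracle_recall <- function(Yt, Yp) {
  vals <- c()
  for (l in seq_len(ncol(Yt))) {
    tp <- fn <- 0
    for (i in seq_len(nrow(Yt))) {
      if (Yt[i, l] == 1 && Yp[i, l] == 1) tp <- tp + 1
      if (Yt[i, l] == 1 && Yp[i, l] == 0) fn <- fn + 1
    }
    if ((tp + fn) == 0) next
    vals <- c(vals, tp / (tp + fn))
  }
  mean(vals)
}

# minimal RDF/XML OWL document for import tests
owl_fixture_xml <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"\n',
    '         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">\n',
    '  <owl:Class rdf:about="http://example.org/onto#B">\n',
    '    <rdfs:label>b class</rdfs:label>\n',
    '  </owl:Class>\n',
    '  <owl:Class rdf:about="http://example.org/onto#A">\n',
    '    <rdfs:label>a class</rdfs:label>\n',
    '    <rdfs:subClassOf rdf:resource="http://example.org/onto#B"/>\n',
    '  </owl:Class>\n',
    '  <owl:Class rdf:about="http://example.org/onto#C">\n',
    '    <rdfs:label>c class</rdfs:label>\n',
    '    <oboInOwl:hasExactSynonym>x</oboInOwl:hasExactSynonym>\n',
    '    <rdfs:subClassOf>\n',
    '      <owl:Restriction>\n',
    '        <owl:onProperty rdf:resource="http://example.org/onto#hasFinding"/>\n',
    '        <owl:someValuesFrom rdf:resource="http://example.org/onto#B"/>\n',
    '      </owl:Restriction>\n',
    '    </rdfs:subClassOf>\n',
    '  </owl:Class>\n',
    '</rdf:RDF>\n')
}
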