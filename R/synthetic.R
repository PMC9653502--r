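#' Synthetic cohort generator configuration
#'
#' The generator emulates the statistical structure of a surgical epilepsy
#' neuropathology cohort: 312 patients, 12 diagnosis classes at the
#' published prevalences plus a dual-pathology rate, diagnosis-conditioned
#' canonical findings per report category, and heterogeneous surface forms
#' (synonyms, descriptive modifiers, filler words, plural toggles, word
#' swaps) that collapse to far fewer ontology classes under mapping.
#'
#' @param n_patients cohort size.
#' @param label_prevalence named numeric vector of diagnosis weights; the
#'   default comes from the packaged concept model (the published cohort
#'   counts).
#' @param dual_pathology_rate probability that a patient carries a second
#'   distinct diagnosis (default 5/312).
#' @param concept_model path to the YAML concept model (diagnosis ->
#'   category -> concept inclusion probabilities); defaults to the packaged
#'   model.
#' @param synonyms_per_concept how many curated ontology synonyms seed each
#'   concept's surface pool (default 4).
#' @param lexical_noise_rate probability that a rendered surface receives
#'   one lexical perturbation (default 0.2).
#' @param noise_mix relative rates of the three perturbation types
#'   `filler`, `plural`, `swap`. Prepositional filler dominates because it
#'   is the most common benign variation in report language; word-order
#'   swaps, the only perturbation the cascade cannot always recover, are
#'   kept rare.
#' @param category_richness expected distinct surface forms per concept and
#'   category, before global scaling. Defaults follow the published
#'   per-category raw:mapped vocabulary ratios (microscopy is by far the
#'   most heterogeneous).
#' @param richness_scale global multiplier on `category_richness`; `NULL`
#'   (default) means it is calibrated so the corpus vocabulary approaches
#'   `target_vocab`.
#' @param target_vocab target number of distinct normalized terms across
#'   the corpus (default 1328); `NA` disables calibration.
#' @param vocab_tolerance relative tolerance for the calibration (0.15).
#' @param colocation_rate probability that a location-bearing microscopy
#'   finding renders as a "finding in location" composite.
#' @param zipf_exponent skew of the Zipf law governing surface-form choice
#'   (1 = classical Zipf; smaller = flatter tail, more distinct forms).
#' @param restatement_rate probability that an included concept is rendered
#'   a second time in different wording (reports commonly restate a finding
#'   in the narrative and the summary).
#' @param vocab_shares per-category share of the vocabulary target, used by
#'   the calibration; defaults to the published per-category raw term
#'   counts.
#' @param seed integer seed; the cohort is bit-identical for a fixed seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 312L,
                             label_prevalence = NULL,
                             dual_pathology_rate = 5 / 312,
                             concept_model = NULL,
                             synonyms_per_concept = 4L,
                             lexical_noise_rate = 0.2,
                             noise_mix = c(filler = 0.6, plural = 0.2,
                                           swap = 0.2),
                             category_richness = c(microscopy = 6.42,
                                                   immunohistochemistry = 1.68,
                                                   imaging = 2.66,
                                                   anatomy = 2.74,
                                                   diagnosis = 1.86),
                             richness_scale = NULL,
                             target_vocab = 1328L,
                             vocab_tolerance = 0.15,
                             colocation_rate = 0.5,
                             zipf_exponent = 0.7,
                             restatement_rate = 0.5,
                             vocab_shares = c(microscopy = 802,
                                              immunohistochemistry = 141,
                                              imaging = 218,
                                              anatomy = 167,
                                              diagnosis = 149),
                             seed = 1L) {
  stopifnot(n_patients >= 1L,
            dual_pathology_rate >= 0, dual_pathology_rate <= 1,
            lexical_noise_rate >= 0, lexical_noise_rate <= 1,
            all(names(category_richness) == REPORT_CATEGORIES))
  structure(list(n_patients = as.integer(n_patients),
                 label_prevalence = label_prevalence,
                 dual_pathology_rate = dual_pathology_rate,
                 concept_model = concept_model,
                 synonyms_per_concept = as.integer(synonyms_per_concept),
                 lexical_noise_rate = lexical_noise_rate,
                 noise_mix = noise_mix / sum(noise_mix),
                 category_richness = category_richness,
                 richness_scale = richness_scale,
                 target_vocab = target_vocab,
                 vocab_tolerance = vocab_tolerance,
                 colocation_rate = colocation_rate,
                 zipf_exponent = zipf_exponent,
                 restatement_rate = restatement_rate,
                 vocab_shares = vocab_shares / sum(vocab_shares),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generator profile tuned to the published vocabulary-reduction ratios
#'
#' A noise-free configuration with per-category surface richness fixed at
#' the published raw:mapped ratios (global scale 1, no vocabulary
#' calibration), used to check that mapping reproduces the per-category
#' consolidation pattern.
#'
#' @param seed integer seed.
#' @param ... further arguments passed to [generator_config()].
#' @return a `generator_config`.
#' @export
table2_profile <- function(seed = 1L, ...) {
  generator_config(lexical_noise_rate = 0, richness_scale = 1,
                   target_vocab = NA_integer_, seed = seed, ...)
}

#' The packaged fixture mini-ontology
#'
#' A ~100-class neuropathology terminology covering hippocampal sclerosis
#' subtypes with semiquantitative grading annotations, hippocampal
#' subfields and other anatomy, malformation-of-cortical-development and
#' tumor diagnoses, immunohistochemistry epitopes, imaging findings, and
#' the synonym sets exercised by the mapping cascade examples.
#'
#' @return an [ontology] object.
#' @export
mini_ontology <- function() {
  load_lexicon(system.file("extdata", "mini_ontology.json",
                           package = "ontofeat", mustWork = TRUE))
}

load_concept_model <- function(config) {
  path <- config$concept_model %||%
    system.file("extdata", "concept_model.yaml", package = "ontofeat",
                mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Sample per-patient diagnosis label sets
#'
#' A primary diagnosis is drawn from the categorical prevalence
#' distribution; with probability `dual_pathology_rate` a second, distinct
#' diagnosis is added (a "dual pathology" patient).
#'
#' @param config a [generator_config].
#' @param model optional pre-loaded concept model (list from the YAML).
#' @return list of character vectors of diagnosis class ids, one per
#'   patient.
#' @export
sample_labels <- function(config, model = load_concept_model(config)) {
  prev <- config$label_prevalence %||%
    vapply(model$diagnoses, function(d) as.numeric(d$weight), numeric(1))
  if (is.null(names(prev)) || any(!nzchar(names(prev)))) {
    stop("label prevalences must be named")
  }
  if (any(prev < 0) || sum(prev) <= 0) stop("prevalences not normalizable")
  prev <- prev[prev > 0]
  if (length(prev) < 2L && config$dual_pathology_rate > 0) {
    stop("cannot draw a distinct second diagnosis from a single label")
  }
  set.seed(derive_seed(config$seed, "labels"))
  primary <- sample(names(prev), config$n_patients, replace = TRUE,
                    prob = prev / sum(prev))
  dual <- rbinom(config$n_patients, 1L, config$dual_pathology_rate) == 1L
  lapply(seq_len(config$n_patients), function(i) {
    labs <- primary[[i]]
    if (dual[[i]]) {
      rest <- prev[names(prev) != labs]
      labs <- c(labs, sample(names(rest), 1L, prob = rest / sum(rest)))
    }
    labs
  })
}

#' Sample per-patient canonical finding concepts
#'
#' Independent inclusion draws over the concepts associated with each of
#' the patient's diagnoses (union over diagnoses for dual-pathology
#' patients). Every diagnosis has at least one high-probability signature
#' concept by construction of the concept model; a patient who draws no
#' concept at all is redrawn (bounded retries, then the first diagnosis's
#' strongest microscopy concept is forced).
#'
#' @param diagnoses character vector of diagnosis class ids for one
#'   patient.
#' @param config a [generator_config].
#' @param model pre-loaded concept model.
#' @return named list: category -> character vector of concept class ids.
#' @export
sample_concepts <- function(diagnoses, config,
                            model = load_concept_model(config)) {
  for (d in diagnoses) {
    if (is.null(model$diagnoses[[d]])) {
      stop(sprintf("diagnosis '%s' has no concept table", d))
    }
  }
  draw_once <- function() {
    out <- list()
    for (cat in INPUT_CATEGORIES) {
      probs <- list()
      for (d in diagnoses) {
        tab <- model$diagnoses[[d]][[cat]]
        for (concept in names(tab)) {
          p <- as.numeric(tab[[concept]])
          probs[[concept]] <- max(probs[[concept]] %||% 0, p)
        }
      }
      keep <- names(probs)[vapply(probs, function(p) runif(1) < p, TRUE)]
      out[[cat]] <- keep
    }
    out
  }
  for (attempt in seq_len(100L)) {
    out <- draw_once()
    if (sum(lengths(out)) > 0L) return(out)
  }
  tab <- model$diagnoses[[diagnoses[[1L]]]]$microscopy
  forced <- names(tab)[which.max(unlist(tab))]
  list(microscopy = forced, immunohistochemistry = character(),
       imaging = character(), anatomy = character())
}

# ---- surface rendering ----------------------------------------------------

# Toggle the grammatical number of a phrase's final token; returns NULL
# when no regular toggle exists. Shared with the fixture builder so that
# plural variants produced as noise remain in the lexicon.
plural_toggle <- function(phrase) {
  toks <- strsplit(phrase, " ", fixed = TRUE)[[1L]]
  last <- toks[[length(toks)]]
  n <- nchar(last)
  if (n < 4L) return(NULL)
  new <- NULL
  if (grepl("(ss|us|is)$", last)) {
    new <- NULL
  } else if (endsWith(last, "s")) {
    new <- substr(last, 1L, n - 1L)
  } else if (grepl("[bcdfghjklmnpqrtvwxyze]$", last)) {
    new <- paste0(last, "s")
  }
  if (is.null(new)) return(NULL)
  toks[[length(toks)]] <- new
  paste(toks, collapse = " ")
}

# Surface choice follows a Zipf law over the pool (canonical forms first):
# term frequencies in report language are heavily skewed, and a uniform
# choice would shatter the raw vocabulary into columns too rare to learn
# from, which no real corpus does.
zipf_draw <- function(pool, s = 0.7) {
  if (length(pool) == 1L) return(pool)
  sample(pool, 1L, prob = seq_along(pool)^(-s))
}

# Deterministic surface pool for one concept: curated synonyms first, then
# descriptive modifier variants, truncated to the requested richness.
surface_pool <- function(concept, ont, n_target, modifiers,
                         synonyms_per_concept) {
  cl <- ont$classes[[concept]]
  if (is.null(cl)) stop(sprintf("unknown concept '%s'", concept))
  bases <- unique(tolower(c(cl$label, cl$synonyms)))
  bases <- bases[seq_len(min(length(bases),
                             max(1L, synonyms_per_concept)))]
  variants <- as.vector(t(outer(modifiers, bases, paste)))
  utils::head(unique(c(bases, variants)), max(1L, n_target))
}

build_pools <- function(ont, model, config, scale) {
  modifiers <- unlist(model$modifiers)
  concepts <- list()
  for (d in names(model$diagnoses)) {
    for (cat in INPUT_CATEGORIES) {
      concepts[[cat]] <- unique(c(concepts[[cat]],
                                  names(model$diagnoses[[d]][[cat]])))
    }
  }
  concepts$diagnosis <- names(model$diagnoses)
  concepts$anatomy <- unique(c(concepts$anatomy,
                               unlist(model$locations, use.names = FALSE)))
  if (length(scale) == 1L) {
    scale <- setNames(rep(scale, length(REPORT_CATEGORIES)),
                      REPORT_CATEGORIES)
  }
  pools <- list()
  for (cat in names(concepts)) {
    rich <- config$category_richness[[cat]] * scale[[cat]]
    pools[[cat]] <- lapply(setNames(nm = concepts[[cat]]), function(cpt) {
      n_target <- max(1L, 1L + rpois(1L, max(rich - 1, 0)))
      surface_pool(cpt, ont, n_target, modifiers,
                   config$synonyms_per_concept)
    })
  }
  pools
}

apply_noise <- function(surface, config) {
  kind <- sample(names(config$noise_mix), 1L, prob = config$noise_mix)
  toks <- strsplit(surface, " ", fixed = TRUE)[[1L]]
  if (kind == "filler" && length(toks) >= 1L) {
    filler <- sample(c("of", "in", "at", "the"), 1L)
    pos <- sample.int(length(toks), 1L)
    return(paste(append(toks, filler, after = pos), collapse = " "))
  }
  if (kind == "plural") {
    out <- plural_toggle(surface)
    if (!is.null(out)) return(out)
    return(surface)
  }
  if (kind == "swap" && length(toks) >= 2L) {
    pos <- sample.int(length(toks) - 1L, 1L)
    toks[c(pos, pos + 1L)] <- toks[c(pos + 1L, pos)]
    return(paste(toks, collapse = " "))
  }
  surface
}

#' Render one concept as a heterogeneous surface form
#'
#' Uniform choice from the concept's surface pool; location-bearing
#' microscopy findings may render as "finding in location" composites
#' (exercising the compositional matcher); with probability
#' `config$lexical_noise_rate` one perturbation (filler-word insertion,
#' plural toggle, or adjacent-token swap) is applied. Draws from the
#' current RNG stream.
#'
#' @param concept a concept class id.
#' @param category its report category.
#' @param ont an [ontology].
#' @param config a [generator_config].
#' @param pools optional precomputed pools from the internal builder.
#' @param model pre-loaded concept model.
#' @return list with `surface` (the rendered string) and `classes` (the
#'   canonical oracle class set).
#' @export
render_surface <- function(concept, category, ont, config,
                           pools = NULL, model = load_concept_model(config)) {
  if (is.null(pools)) {
    pools <- build_pools(ont, model, config,
                         config$richness_scale %||% 1)
  }
  pool <- pools[[category]][[concept]]
  if (is.null(pool)) {
    pool <- surface_pool(concept, ont, 1L, character(),
                         config$synonyms_per_concept)
  }
  surface <- zipf_draw(pool, config$zipf_exponent %||% 0.7)
  classes <- concept
  locs <- model$locations[[concept]]
  if (category == "microscopy" && length(locs) &&
      runif(1) < config$colocation_rate) {
    loc <- if (length(locs) == 1L) locs else sample(unlist(locs), 1L)
    loc_pool <- pools$anatomy[[loc]] %||%
      surface_pool(loc, ont, 2L, character(), config$synonyms_per_concept)
    loc_surface <- zipf_draw(loc_pool, config$zipf_exponent %||% 0.7)
    surface <- paste(surface, sample(c("in", "at"), 1L), loc_surface)
    classes <- c(concept, loc)
  }
  if (runif(1) < config$lexical_noise_rate) {
    surface <- apply_noise(surface, config)
  }
  list(surface = surface, classes = classes)
}

render_cohort <- function(labels, concepts, ont, model, config, scale, iter) {
  set.seed(derive_seed(config$seed, sprintf("render-%d", iter)))
  pools <- build_pools(ont, model, config, scale)
  rows <- vector("list", length(labels) * 12L)
  oracle <- new.env(parent = emptyenv())
  nrow_ <- 0L
  for (i in seq_along(labels)) {
    pid <- sprintf("P%04d", i)
    per_cat <- c(concepts[[i]], list(diagnosis = labels[[i]]))
    for (cat in names(per_cat)) {
      for (concept in per_cat[[cat]]) {
        n_mentions <- 1L + (cat != "diagnosis" &&
                              runif(1) < config$restatement_rate)
        for (mention in seq_len(n_mentions)) {
          r <- render_surface(concept, cat, ont, config, pools, model)
          nrow_ <- nrow_ + 1L
          rows[[nrow_]] <- c(pid, cat, r$surface)
          assign(paste(r$surface, cat, sep = "\r"),
                 r$classes, envir = oracle)
        }
      }
    }
  }
  rows <- rows[seq_len(nrow_)]
  reports <- data.frame(
    patient_id = vapply(rows, `[[`, "", 1L),
    category = vapply(rows, `[[`, "", 2L),
    term = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  keys <- ls(oracle)
  oracle_df <- data.frame(
    surface = sub("\r.*$", "", keys),
    category = sub("^.*\r", "", keys),
    class_ids = vapply(keys, function(k) {
      paste(get(k, envir = oracle), collapse = ";")
    }, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  list(reports = reports, oracle = oracle_df)
}

#' Generate a full synthetic cohort
#'
#' Draws diagnosis label sets, diagnosis-conditioned canonical concepts,
#' and heterogeneous surface renderings; when `config$richness_scale` is
#' `NULL` the surface richness is calibrated (up to 6 deterministic
#' passes) so the distinct normalized vocabulary approaches
#' `config$target_vocab` within `config$vocab_tolerance` (a warning
#' reports the achieved count when the concept inventory cannot reach the
#' target). Fully reproducible from `config$seed`.
#'
#' @param config a [generator_config].
#' @return a list of class `synthetic_cohort` with elements `reports`
#'   (long-format data frame), `truth` (list: `oracle` surface-to-class
#'   table, `patients` per-patient diagnosis/concept truth), `ontology`,
#'   `vocab_size` (achieved distinct normalized terms) and
#'   `richness_scale` (the scale actually used).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  ont <- mini_ontology()
  model <- load_concept_model(config)
  labels <- sample_labels(config, model)
  set.seed(derive_seed(config$seed, "concepts"))
  concepts <- lapply(labels, sample_concepts, config = config, model = model)

  vocab_size <- function(reports) {
    length(unique(vapply(reports$term, normalize_key, "")))
  }
  vocab_by_category <- function(reports) {
    keys <- vapply(reports$term, normalize_key, "")
    counts <- tapply(keys, reports$category, function(k) length(unique(k)))
    out <- setNames(numeric(length(REPORT_CATEGORIES)), REPORT_CATEGORIES)
    out[names(counts)] <- counts
    out
  }

  scale <- config$richness_scale
  if (is.null(scale) && is.na(config$target_vocab)) scale <- 1
  if (!is.null(scale)) {
    out <- render_cohort(labels, concepts, ont, model, config, scale, 1L)
    achieved <- vocab_size(out$reports)
  } else {
    # per-category calibration toward the published vocabulary shares
    targets <- config$vocab_shares * config$target_vocab
    scale <- setNames(rep(1, length(REPORT_CATEGORIES)), REPORT_CATEGORIES)
    achieved <- NA_integer_
    for (iter in seq_len(6L)) {
      out <- render_cohort(labels, concepts, ont, model, config, scale, iter)
      achieved <- vocab_size(out$reports)
      if (abs(achieved - config$target_vocab) <=
            config$vocab_tolerance * config$target_vocab) break
      per_cat <- vocab_by_category(out$reports)
      scale <- pmin(pmax(scale * targets / pmax(per_cat, 1), 0.2), 40)
    }
    if (abs(achieved - config$target_vocab) >
          config$vocab_tolerance * config$target_vocab) {
      warning(sprintf(
        "target_vocab %d not reachable with the concept inventory; achieved %d",
        config$target_vocab, achieved))
    }
  }

  patients <- lapply(seq_along(labels), function(i) {
    list(patient_id = sprintf("P%04d", i), diagnoses = labels[[i]],
         concepts = concepts[[i]])
  })
  structure(list(reports = out$reports,
                 truth = list(oracle = out$oracle, patients = patients),
                 ontology = ont, config = config,
                 vocab_size = achieved, richness_scale = scale),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d report rows, %d distinct terms (mean scale %.2f)\n",
    length(x$truth$patients), nrow(x$reports), x$vocab_size,
    mean(x$richness_scale)))
  invisible(x)
}

#' Compare a mapping table against the generator's oracle
#'
#' An oracle entry is recovered when the corpus mapping of its surface form
#' yields exactly the canonical class set.
#'
#' @param table a `mapping_table` from [map_corpus()].
#' @param cohort a `synthetic_cohort`.
#' @return list with `recovered`, `total` and `rate`.
#' @export
oracle_recovery <- function(table, cohort) {
  oracle <- cohort$truth$oracle
  hits <- vapply(seq_len(nrow(oracle)), function(i) {
    key <- normalize_key(oracle$surface[[i]])
    entry <- lookup_mapping(table, key, oracle$category[[i]])
    if (is.null(entry)) return(FALSE)
    setequal(strsplit(entry$class_ids, ";", fixed = TRUE)[[1L]],
             strsplit(oracle$class_ids[[i]], ";", fixed = TRUE)[[1L]])
  }, TRUE)
  list(recovered = sum(hits), total = nrow(oracle),
       rate = mean(hits))
}
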