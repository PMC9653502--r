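#' In-memory terminology model
#'
#' An `ontology` object holds classes (with preferred labels, synonyms,
#' isA parents and free-form annotations such as semiquantitative grading
#' values), typed binary relations between classes (quantified OWL-style
#' object-property restrictions), and compositional class axioms (a class
#' defined as an AND/OR combination of property-class pairs). A normalized
#' label index over every preferred label and synonym supports the mapping
#' cascade.
#'
#' @param classes list of class records, each a list with elements `id`,
#'   `label`, and optionally `synonyms` (character), `parents` (character)
#'   and `annotations` (named list; `grading_value`, when present, must be
#'   0, 1 or 2).
#' @param relations data frame with columns `property`, `source`, `target`,
#'   `quantifier` (`"some"` or `"only"`).
#' @param compositions list of axioms, each a list with `defined_class`,
#'   `components` (data frame with columns `property`, `class`) and
#'   `connective` (`"AND"` or `"OR"`).
#' @return an object of class `ontology`.
#' @export
ontology <- function(classes, relations = NULL, compositions = NULL) {
  if (length(classes) == 0L) {
    stop("empty ontology: at least one class is required")
  }
  recs <- lapply(classes, function(cl) {
    if (is.null(cl$id) || !nzchar(cl$id)) stop("class without id")
    if (is.null(cl$label) || !nzchar(trimws(cl$label))) {
      stop(sprintf("class '%s' has an empty preferred label", cl$id))
    }
    list(
      id = as.character(cl$id),
      label = as.character(cl$label),
      synonyms = as.character(cl$synonyms %||% character()),
      parents = as.character(cl$parents %||% character()),
      annotations = as.list(cl$annotations %||% list())
    )
  })
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate class id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(recs) <- ids

  for (cl in recs) {
    gv <- cl$annotations$grading_value
    if (!is.null(gv) && !(length(gv) == 1L && gv %in% 0:2)) {
      stop(sprintf("class '%s': grading_value must be 0, 1 or 2", cl$id))
    }
    missing_parents <- setdiff(cl$parents, ids)
    if (length(missing_parents)) {
      stop(sprintf("class '%s': dangling parent reference '%s'",
                   cl$id, missing_parents[[1L]]))
    }
  }

  if (is.null(relations)) {
    relations <- data.frame(property = character(), source = character(),
                            target = character(), quantifier = character(),
                            stringsAsFactors = FALSE)
  }
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(relations)) {
    stopifnot(all(c("property", "source", "target", "quantifier") %in%
                    names(relations)))
    bad <- setdiff(c(relations$source, relations$target), ids)
    if (length(bad)) {
      stop(sprintf("relation references unknown class '%s'", bad[[1L]]))
    }
    if (!all(relations$quantifier %in% c("some", "only"))) {
      stop("relation quantifier must be 'some' or 'only'")
    }
  }

  compositions <- compositions %||% list()
  for (ax in compositions) {
    if (is.null(ax$defined_class) || !ax$defined_class %in% ids) {
      stop("composition axiom with unknown defined_class")
    }
    comp <- as.data.frame(ax$components, stringsAsFactors = FALSE)
    if (nrow(comp) < 1L) stop("composition axiom needs >= 1 component")
    bad <- setdiff(comp$class, ids)
    if (length(bad)) {
      stop(sprintf("composition component references unknown class '%s'",
                   bad[[1L]]))
    }
    if (!(ax$connective %||% "AND") %in% c("AND", "OR")) {
      stop("composition connective must be 'AND' or 'OR'")
    }
  }

  check_acyclic_isa(recs)

  obj <- structure(
    list(classes = recs, relations = relations, compositions = compositions),
    class = "ontology"
  )
  obj$label_index <- build_label_index(recs, preferred_only = FALSE)
  obj$pref_index <- build_label_index(recs, preferred_only = TRUE)
  obj
}

check_acyclic_isa <- function(recs) {
  color <- new.env(parent = emptyenv()) # 1 = in stack, 2 = done
  visit <- function(id, stack) {
    st <- get0(id, envir = color, ifnotfound = 0L)
    if (st == 2L) return(invisible())
    if (st == 1L) {
      stop(sprintf("isA cycle detected involving class '%s' (%s)",
                   id, paste(c(stack, id), collapse = " -> ")))
    }
    assign(id, 1L, envir = color)
    for (p in recs[[id]]$parents) visit(p, c(stack, id))
    assign(id, 2L, envir = color)
  }
  for (id in names(recs)) visit(id, character())
  invisible()
}

build_label_index <- function(recs, preferred_only = FALSE) {
  idx <- new.env(parent = emptyenv())
  add <- function(key, id) {
    if (!nzchar(key)) return(invisible())
    cur <- get0(key, envir = idx, ifnotfound = character())
    assign(key, unique(c(cur, id)), envir = idx)
  }
  for (cl in recs) {
    add(normalize_key(cl$label), cl$id)
    if (!preferred_only) {
      for (s in cl$synonyms) add(normalize_key(s), cl$id)
    }
  }
  idx
}

index_lookup <- function(index, key) {
  get0(key, envir = index, ifnotfound = character())
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> %d classes, %d relations, %d composition axioms\n",
    length(x$classes), nrow(x$relations), length(x$compositions)))
  invisible(x)
}

#' Read an ontology from the JSON lexicon dialect
#'
#' The lexicon dialect is the package's canonical plain-text terminology
#' format: a UTF-8 JSON object with a `classes` array (`id`, `label`,
#' `synonyms`, `parents`, `annotations`), a `relations` array (`property`,
#' `source`, `target`, `quantifier`) and a `compositions` array
#' (`defined_class`, `components` as `[property, class]` pairs,
#' `connective`).
#'
#' @param path path to a lexicon JSON file.
#' @return an [ontology] object.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("lexicon parse error in %s: %s",
                                     path, conditionMessage(e)))
  )
  if (length(raw$classes %||% list()) == 0L) stop("empty ontology")
  relations <- NULL
  if (length(raw$relations %||% list())) {
    relations <- do.call(rbind, lapply(raw$relations, function(r) {
      data.frame(property = r$property, source = r$source, target = r$target,
                 quantifier = r$quantifier %||% "some",
                 stringsAsFactors = FALSE)
    }))
  }
  compositions <- lapply(raw$compositions %||% list(), function(ax) {
    comp <- do.call(rbind, lapply(ax$components, function(p) {
      data.frame(property = p[[1L]], class = p[[2L]], stringsAsFactors = FALSE)
    }))
    list(defined_class = ax$defined_class, components = comp,
         connective = ax$connective %||% "AND")
  })
  ontology(raw$classes, relations, compositions)
}

#' Write an ontology in the JSON lexicon dialect
#'
#' @param ont an [ontology] object.
#' @param path output path.
#' @return `path`, invisibly. `load_lexicon(write_lexicon(ont))` round-trips
#'   classes, synonyms, parents, relations and compositions.
#' @export
write_lexicon <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  classes <- lapply(unname(ont$classes), function(cl) {
    out <- list(id = cl$id, label = cl$label)
    if (length(cl$synonyms)) out$synonyms <- as.list(cl$synonyms)
    if (length(cl$parents)) out$parents <- as.list(cl$parents)
    if (length(cl$annotations)) out$annotations <- cl$annotations
    out
  })
  relations <- lapply(seq_len(nrow(ont$relations)), function(i) {
    as.list(ont$relations[i, c("property", "source", "target", "quantifier")])
  })
  compositions <- lapply(ont$compositions, function(ax) {
    list(defined_class = ax$defined_class,
         components = lapply(seq_len(nrow(ax$components)), function(i) {
           list(ax$components$property[[i]], ax$components$class[[i]])
         }),
         connective = ax$connective)
  })
  jsonlite::write_json(
    list(classes = classes, relations = relations, compositions = compositions),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read an OWL 2 ontology (RDF/XML) as a best-effort projection
#'
#' Only the constructs needed by the mapping cascade are imported: named
#' classes with `rdfs:label`, annotation synonyms (any annotation property
#' whose name contains "synonym", case-insensitively), named subclass
#' axioms, and quantified existential/universal restrictions (which become
#' typed relations). Unparseable axioms are skipped with a message, never
#' fatal. Turtle input is not supported.
#'
#' @param path path to an RDF/XML OWL file.
#' @return an [ontology] object.
#' @export
load_owl <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  head_txt <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "\n")
  if (grepl("(^|\\n)\\s*(@prefix|@base|PREFIX\\s)", head_txt)) {
    stop("Turtle serializations are not supported; convert to RDF/XML")
  }
  if (!grepl("<", head_txt, fixed = TRUE)) {
    stop("only RDF/XML OWL serializations are supported (input does not look like XML)")
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("unreadable OWL file: %s",
                                                   conditionMessage(e))))
  ns <- xml2::xml_ns(doc)
  nodes <- xml2::xml_find_all(doc, ".//owl:Class[@rdf:about]", ns)
  if (length(nodes) == 0L) stop("no classes found in OWL file")

  frag <- function(iri) sub("^.*[#/]", "", iri)
  classes <- list()
  relations <- list()

  for (node in nodes) {
    iri <- xml2::xml_attr(node, "about")
    id <- frag(iri)
    lab <- xml2::xml_text(xml2::xml_find_first(node, "./rdfs:label", ns))
    if (is.na(lab) || !nzchar(lab)) lab <- id
    syns <- character()
    for (child in xml2::xml_children(node)) {
      if (grepl("synonym", xml2::xml_name(child), ignore.case = TRUE)) {
        txt <- xml2::xml_text(child)
        if (nzchar(txt)) syns <- c(syns, txt)
      }
    }
    parents <- character()
    for (sc in xml2::xml_find_all(node, "./rdfs:subClassOf", ns)) {
      res <- xml2::xml_attr(sc, "resource")
      if (!is.na(res)) {
        parents <- c(parents, frag(res))
        next
      }
      restr <- xml2::xml_find_first(sc, "./owl:Restriction", ns)
      if (!inherits(restr, "xml_missing")) {
        prop <- xml2::xml_attr(
          xml2::xml_find_first(restr, "./owl:onProperty", ns), "resource")
        some <- xml2::xml_attr(
          xml2::xml_find_first(restr, "./owl:someValuesFrom", ns), "resource")
        only <- xml2::xml_attr(
          xml2::xml_find_first(restr, "./owl:allValuesFrom", ns), "resource")
        filler <- if (!is.na(some)) some else only
        quant <- if (!is.na(some)) "some" else "only"
        if (!is.na(prop) && !is.na(filler)) {
          relations[[length(relations) + 1L]] <- data.frame(
            property = frag(prop), source = id, target = frag(filler),
            quantifier = quant, stringsAsFactors = FALSE)
        } else {
          message(sprintf("load_owl: skipping unparseable restriction on '%s'", id))
        }
      }
    }
    classes[[length(classes) + 1L]] <- list(
      id = id, label = lab, synonyms = unique(syns), parents = unique(parents))
  }

  ids <- vapply(classes, `[[`, "", "id")
  # drop references to classes the projection did not import
  classes <- lapply(classes, function(cl) {
    cl$parents <- intersect(cl$parents, ids)
    cl
  })
  rel <- if (length(relations)) do.call(rbind, relations) else NULL
  if (!is.null(rel)) {
    keep <- rel$source %in% ids & rel$target %in% ids
    if (any(!keep)) message("load_owl: skipping relations with unknown fillers")
    rel <- rel[keep, , drop = FALSE]
  }
  ontology(classes, rel)
}

#' Transitive isA closure of a class
#'
#' @param ont an [ontology].
#' @param class_id a class id present in `ont`.
#' @return character vector of ancestor ids (excluding `class_id` itself).
#' @export
ont_ancestors <- function(ont, class_id) {
  stopifnot(inherits(ont, "ontology"))
  if (!class_id %in% names(ont$classes)) {
    stop(sprintf("unknown class id '%s'", class_id))
  }
  out <- character()
  frontier <- ont$classes[[class_id]]$parents
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(lapply(new, function(id) ont$classes[[id]]$parents)))
  }
  unique(out)
}

#' One-hop related classes under a property filter
#'
#' Returns every relation target reachable from `class_id` in exactly one
#' hop. `property_id = "*"` is a wildcard over all properties.
#'
#' @param ont an [ontology].
#' @param class_id a class id present in `ont`.
#' @param property_id a property id, or `"*"` for any property.
#' @return character vector of target class ids.
#' @export
ont_related <- function(ont, class_id, property_id = "*") {
  stopifnot(inherits(ont, "ontology"))
  if (!class_id %in% names(ont$classes)) {
    stop(sprintf("unknown class id '%s'", class_id))
  }
  rel <- ont$relations
  hit <- rel$source == class_id
  if (!identical(property_id, "*")) hit <- hit & rel$property == property_id
  unique(rel$target[hit])
}
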