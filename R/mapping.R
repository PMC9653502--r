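#' Configuration for the term-mapping cascade
#'
#' @param stopwords tokens removed during normalization.
#' @param max_residual maximum fraction of tokens that may remain unmatched
#'   for a single-class compositional match to count as a success.
#' @param strip_suffixes suffixes stripped during semantic stem matching,
#'   tried longest first.
#' @param stem_slack maximum number of trailing characters by which a
#'   stripped token and an index key may differ and still be treated as the
#'   same stem.
#' @param min_stem length below which stems are never matched (guards
#'   against accidental short-stem collisions).
#' @param semantic_expand which one-hop neighborhoods feed semantic
#'   expansion: any subset of `"parents"` and `"relations"`.
#' @param max_expansion cap on the total number of classes returned by the
#'   semantic step (anchors are always kept).
#' @return an object of class `mapping_config`.
#' @export
mapping_config <- function(stopwords = c("of", "in", "at", "the", "with", "and"),
                           max_residual = 0.5,
                           strip_suffixes = c("ial", "ous", "al", "ic"),
                           stem_slack = 2L,
                           min_stem = 4L,
                           semantic_expand = c("parents", "relations"),
                           max_expansion = 3L) {
  stopifnot(max_residual >= 0, max_residual <= 1, max_expansion >= 1)
  structure(list(stopwords = stopwords,
                 max_residual = max_residual,
                 strip_suffixes = strip_suffixes[order(-nchar(strip_suffixes))],
                 stem_slack = as.integer(stem_slack),
                 min_stem = as.integer(min_stem),
                 semantic_expand = match.arg(semantic_expand,
                                             c("parents", "relations"),
                                             several.ok = TRUE),
                 max_expansion = as.integer(max_expansion)),
            class = "mapping_config")
}

REPORT_CATEGORIES <- c("microscopy", "immunohistochemistry", "imaging",
                       "anatomy", "diagnosis")

#' A category-tagged raw surface term
#'
#' @param text nonempty free-text term as written in a report.
#' @param category one of `microscopy`, `immunohistochemistry`, `imaging`,
#'   `anatomy`, `diagnosis`.
#' @return an object of class `raw_term`.
#' @export
raw_term <- function(text, category) {
  if (!nzchar(trimws(text))) stop("raw term text must be nonempty")
  category <- match.arg(category, REPORT_CATEGORIES)
  structure(list(text = text, category = category), class = "raw_term")
}

#' Normalize a surface string into a token sequence
#'
#' Lowercases, maps punctuation to spaces, collapses whitespace and drops
#' stopwords. Deterministic; an empty input yields an empty sequence.
#'
#' @param text character scalar.
#' @param stopwords character vector of tokens to drop.
#' @return character vector of tokens.
#' @export
normalize_term <- function(text,
                           stopwords = c("of", "in", "at", "the", "with", "and")) {
  s <- tolower(text)
  s <- gsub("[^a-z0-9]+", " ", s)
  toks <- strsplit(trimws(s), " +")[[1L]]
  toks[!toks %in% stopwords]
}

normalize_key <- function(text, stopwords = c("of", "in", "at", "the",
                                              "with", "and")) {
  paste(normalize_term(text, stopwords), collapse = " ")
}

mapping_result <- function(term, classes, step, residual = character(),
                           reviewed = FALSE, needs_review = FALSE) {
  stopifnot(step %in% c("syntactic", "compositional", "semantic", "unmapped"))
  if (step == "syntactic" && length(classes) != 1L) {
    stop("syntactic results carry exactly one class")
  }
  if ((step == "unmapped") != (length(classes) == 0L)) {
    stop("step is 'unmapped' iff the class set is empty")
  }
  structure(list(raw = term, classes = unname(classes), step = step,
                 residual_tokens = residual, reviewed = reviewed,
                 needs_review = needs_review),
            class = "mapping_result")
}

unmapped_result <- function(term, residual = character(), needs_review = FALSE) {
  mapping_result(term, character(), "unmapped", residual,
                 needs_review = needs_review)
}

# Resolve an index hit to a single class: unique hit wins; ambiguous hits
# are resolved in favor of a unique preferred-label match, else NULL.
resolve_hit <- function(ont, key) {
  ids <- index_lookup(ont$label_index, key)
  if (length(ids) == 1L) return(ids)
  if (length(ids) > 1L) {
    pref <- index_lookup(ont$pref_index, key)
    if (length(pref) == 1L) return(pref)
    return(structure(character(), ambiguous = TRUE))
  }
  character()
}

#' Step 1: syntactic matching
#'
#' Succeeds iff the full normalized term equals the normalized preferred
#' label or synonym of exactly one class. A surface form shared by several
#' classes is resolved by a unique preferred-label match; otherwise the term
#' is flagged for review and left to the rest of the cascade.
#'
#' @param term a [raw_term].
#' @param ont an [ontology].
#' @param config a [mapping_config].
#' @return a `mapping_result` with step `"syntactic"` or `"unmapped"`.
#' @export
match_syntactic <- function(term, ont, config = mapping_config()) {
  key <- normalize_key(term$text, config$stopwords)
  if (!nzchar(key)) return(unmapped_result(term))
  hit <- resolve_hit(ont, key)
  if (length(hit) == 1L) {
    mapping_result(term, hit, "syntactic")
  } else {
    unmapped_result(term, needs_review = isTRUE(attr(hit, "ambiguous")))
  }
}

#' Step 2: compositional span matching
#'
#' Greedy longest-span matching over the normalized token sequence:
#' repeatedly find the longest contiguous unconsumed span whose key equals a
#' normalized label or synonym, consume it, and continue on the remainder
#' (leftmost span wins among equal lengths). Succeeds iff at least two
#' classes were found, or one class was found and the residual token
#' fraction does not exceed `config$max_residual`.
#'
#' @inheritParams match_syntactic
#' @return a `mapping_result` with step `"compositional"` or `"unmapped"`.
#' @export
match_compositional <- function(term, ont, config = mapping_config()) {
  toks <- normalize_term(term$text, config$stopwords)
  n <- length(toks)
  if (n == 0L) return(unmapped_result(term))
  consumed <- rep(FALSE, n)
  classes <- character()
  repeat {
    found <- FALSE
    for (len in seq(n, 1L)) {
      if (found) break
      for (start in seq_len(n - len + 1L)) {
        span <- start:(start + len - 1L)
        if (any(consumed[span])) next
        key <- paste(toks[span], collapse = " ")
        hit <- resolve_hit(ont, key)
        if (length(hit) == 1L) {
          consumed[span] <- TRUE
          classes <- c(classes, hit)
          found <- TRUE
          break
        }
      }
    }
    if (!found) break
  }
  classes <- unique(classes)
  residual <- toks[!consumed]
  ok <- length(classes) >= 2L ||
    (length(classes) >= 1L && length(residual) / n <= config$max_residual)
  if (ok) {
    mapping_result(term, classes, "compositional", residual)
  } else {
    unmapped_result(term, residual)
  }
}

strip_suffix <- function(token, suffixes) {
  for (suf in suffixes) {
    if (nchar(token) > nchar(suf) && endsWith(token, suf)) {
      return(substr(token, 1L, nchar(token) - nchar(suf)))
    }
  }
  token
}

stem_matches <- function(stem, key_tok, config) {
  if (nchar(stem) < config$min_stem || nchar(key_tok) < config$min_stem) {
    return(stem == key_tok)
  }
  if (stem == key_tok) return(TRUE)
  (startsWith(key_tok, stem) && nchar(key_tok) - nchar(stem) <= config$stem_slack) ||
    (startsWith(stem, key_tok) && nchar(stem) - nchar(key_tok) <= config$stem_slack)
}

#' Step 3: semantic transformation
#'
#' Stem-level matching finds anchor classes: each query token is suffix
#' stripped and compared against the (token-wise stripped) label index; a
#' key matches when every one of its tokens agrees with a query token at
#' stem level. The result is the anchors plus their one-hop neighborhood
#' (isA parents and/or relation targets, per `config$semantic_expand`),
#' with the total class count capped at `config$max_expansion`.
#'
#' @inheritParams match_syntactic
#' @return a `mapping_result` with step `"semantic"` or `"unmapped"`.
#' @export
transform_semantic <- function(term, ont, config = mapping_config()) {
  toks <- normalize_term(term$text, config$stopwords)
  if (length(toks) == 0L) return(unmapped_result(term))
  stems <- vapply(toks, strip_suffix, "", suffixes = config$strip_suffixes)

  anchors <- character()
  matched <- rep(FALSE, length(toks))
  for (key in ls(ont$label_index)) {
    key_toks <- strsplit(key, " ", fixed = TRUE)[[1L]]
    key_stems <- vapply(key_toks, strip_suffix, "",
                        suffixes = config$strip_suffixes)
    if (length(key_stems) > length(stems)) next
    # every key token must align with a distinct query token at stem level
    used <- rep(FALSE, length(stems))
    ok <- TRUE
    for (ks in key_stems) {
      cand <- which(!used & vapply(stems, stem_matches, TRUE,
                                   key_tok = ks, config = config))
      if (length(cand) == 0L) { ok <- FALSE; break }
      used[cand[[1L]]] <- TRUE
    }
    if (!ok) next
    hit <- resolve_hit(ont, key)
    if (length(hit) == 1L) {
      anchors <- c(anchors, hit)
      matched <- matched | used
    }
  }
  anchors <- unique(anchors)
  if (length(anchors) == 0L) return(unmapped_result(term))

  out <- anchors
  for (a in anchors) {
    if (length(out) >= config$max_expansion) break
    neigh <- character()
    if ("parents" %in% config$semantic_expand) {
      neigh <- c(neigh, ont$classes[[a]]$parents)
    }
    if ("relations" %in% config$semantic_expand) {
      neigh <- c(neigh, ont_related(ont, a, "*"))
    }
    for (nb in setdiff(neigh, out)) {
      if (length(out) >= config$max_expansion) break
      out <- c(out, nb)
    }
  }
  mapping_result(term, out, "semantic", toks[!matched])
}

#' Map one term through the three-step cascade
#'
#' Applies syntactic matching, compositional span matching and semantic
#' transformation in that fixed order; the first success wins.
#'
#' @inheritParams match_syntactic
#' @return a `mapping_result`.
#' @export
map_term <- function(term, ont, config = mapping_config()) {
  res <- match_syntactic(term, ont, config)
  if (res$step != "unmapped") return(res)
  flagged <- res$needs_review
  res <- match_compositional(term, ont, config)
  if (res$step != "unmapped") return(res)
  res <- transform_semantic(term, ont, config)
  res$needs_review <- res$needs_review || flagged
  res
}

#' Map every distinct term of a report corpus
#'
#' Each distinct (normalized text, category) pair is mapped once. The
#' result is a mapping table with step provenance and term frequencies;
#' unmapped terms are summarized in the `unmapped` attribute, sorted by
#' corpus frequency.
#'
#' @param reports a long-format report data frame (columns `patient_id`,
#'   `category`, `term`), as produced by [generate_cohort()] or
#'   [read_reports()].
#' @param ont an [ontology].
#' @param config a [mapping_config].
#' @return an object of class `mapping_table`: a data frame with columns
#'   `raw_text` (first-seen surface form), `norm_key`, `category`,
#'   `class_ids` (semicolon separated), `step`, `residual`, `reviewed`,
#'   `needs_review`, `frequency`.
#' @export
map_corpus <- function(reports, ont, config = mapping_config()) {
  stopifnot(all(c("patient_id", "category", "term") %in% names(reports)))
  if (nrow(reports) == 0L) {
    return(empty_mapping_table())
  }
  keys <- vapply(reports$term, normalize_key, "", stopwords = config$stopwords)
  tab <- data.frame(norm_key = keys, category = reports$category,
                    raw_text = reports$term, stringsAsFactors = FALSE)
  grp <- paste(tab$norm_key, tab$category, sep = "\r")
  first <- !duplicated(grp)
  freq <- as.vector(table(grp)[grp[first]])
  entries <- tab[first, , drop = FALSE]

  rows <- lapply(seq_len(nrow(entries)), function(i) {
    term <- raw_term(entries$raw_text[[i]], entries$category[[i]])
    res <- map_term(term, ont, config)
    data.frame(raw_text = entries$raw_text[[i]],
               norm_key = entries$norm_key[[i]],
               category = entries$category[[i]],
               class_ids = paste(res$classes, collapse = ";"),
               step = res$step,
               residual = paste(res$residual_tokens, collapse = " "),
               reviewed = FALSE,
               needs_review = res$needs_review,
               frequency = freq[[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$category, out$norm_key), , drop = FALSE]
  rownames(out) <- NULL
  unmapped <- out[out$step == "unmapped",
                  c("raw_text", "category", "frequency"), drop = FALSE]
  unmapped <- unmapped[order(-unmapped$frequency), , drop = FALSE]
  structure(out, class = c("mapping_table", "data.frame"),
            unmapped = unmapped,
            provenance = data.frame(event = "map_corpus",
                                    n_entries = nrow(out),
                                    stringsAsFactors = FALSE))
}

empty_mapping_table <- function() {
  structure(
    data.frame(raw_text = character(), norm_key = character(),
               category = character(), class_ids = character(),
               step = character(), residual = character(),
               reviewed = logical(), needs_review = logical(),
               frequency = integer(), stringsAsFactors = FALSE),
    class = c("mapping_table", "data.frame"),
    unmapped = data.frame(raw_text = character(), category = character(),
                          frequency = integer(), stringsAsFactors = FALSE),
    provenance = data.frame(event = character(), n_entries = integer(),
                            stringsAsFactors = FALSE))
}

lookup_mapping <- function(table, norm_key, category) {
  i <- which(table$norm_key == norm_key & table$category == category)
  if (length(i) == 0L) return(NULL)
  table[i[[1L]], , drop = FALSE]
}

#' Export a mapping table for human review
#'
#' Writes a UTF-8 TSV with columns `raw_text`, `category`, `class_ids`
#' (semicolon separated), `step` and `approved` (`yes`/`no`), mirroring the
#' study's single-reviewer audit workflow.
#'
#' @param table a `mapping_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_review_table <- function(table, path) {
  stopifnot(inherits(table, "mapping_table"))
  if (nrow(table) == 0L) stop("cannot export an empty mapping table")
  out <- data.frame(raw_text = table$raw_text, category = table$category,
                    class_ids = table$class_ids, step = table$step,
                    approved = ifelse(table$reviewed, "yes", "no"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Import a reviewed mapping table
#'
#' Rows with `approved = yes` become reviewed entries whose class sets
#' override the automatic results; reviewed entries are never overwritten by
#' later automatic remapping.
#'
#' @param path a review TSV written by [export_review_table()] (possibly
#'   edited).
#' @param table the `mapping_table` to update.
#' @param ont the [ontology] used to validate class ids.
#' @return the updated `mapping_table`.
#' @export
import_review_table <- function(path, table, ont) {
  stopifnot(inherits(table, "mapping_table"), inherits(ont, "ontology"))
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("raw_text", "category", "class_ids", "step", "approved")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed review table: expected columns %s",
                 paste(need, collapse = ", ")))
  }
  prov <- attr(table, "provenance")
  for (i in seq_len(nrow(df))) {
    if (!df$category[[i]] %in% REPORT_CATEGORIES) {
      stop(sprintf("review table row %d: unknown category '%s'",
                   i, df$category[[i]]))
    }
    if (!df$approved[[i]] %in% c("yes", "no")) {
      stop(sprintf("review table row %d: approved must be yes or no", i))
    }
    if (df$approved[[i]] != "yes") next
    ids <- setdiff(strsplit(df$class_ids[[i]], ";", fixed = TRUE)[[1L]], "")
    bad <- setdiff(ids, names(ont$classes))
    if (length(bad)) {
      stop(sprintf("review table row %d: unknown class id '%s'", i, bad[[1L]]))
    }
    key <- normalize_key(df$raw_text[[i]])
    j <- which(table$norm_key == key & table$category == df$category[[i]])
    if (length(j) == 0L) {
      stop(sprintf("review table row %d: term not present in mapping table", i))
    }
    table$class_ids[j] <- paste(ids, collapse = ";")
    table$step[j] <- if (length(ids)) table$step[j] else "unmapped"
    table$reviewed[j] <- TRUE
    table$needs_review[j] <- FALSE
    prov <- rbind(prov, data.frame(event = sprintf("review:%s", key),
                                   n_entries = 1L, stringsAsFactors = FALSE))
  }
  attr(table, "provenance") <- prov
  table
}
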