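#' Per-category mapping mask
#'
#' Controls, per report category, whether features are built from ontology
#' classes (`"mapped"`) or from distinct normalized raw terms (`"raw"`);
#' `labels` controls the diagnosis label space the same way.
#'
#' @param microscopy,immunohistochemistry,imaging,anatomy,labels either
#'   `"raw"` or `"mapped"`.
#' @return an object of class `mapping_mask`.
#' @export
mapping_mask <- function(microscopy = "raw", immunohistochemistry = "raw",
                         imaging = "raw", anatomy = "raw", labels = "raw") {
  vals <- c(microscopy = microscopy,
            immunohistochemistry = immunohistochemistry,
            imaging = imaging, anatomy = anatomy, labels = labels)
  if (!all(vals %in% c("raw", "mapped"))) {
    stop("mask values must be 'raw' or 'mapped'")
  }
  structure(as.list(vals), class = "mapping_mask")
}

INPUT_CATEGORIES <- c("microscopy", "immunohistochemistry", "imaging", "anatomy")

validate_reports <- function(reports) {
  stopifnot(all(c("patient_id", "category", "term") %in% names(reports)))
  bad <- setdiff(unique(reports$category), REPORT_CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown report category '%s'", bad[[1L]]))
  }
  pids <- unique(reports$patient_id)
  has_dx <- unique(reports$patient_id[reports$category == "diagnosis"])
  missing <- setdiff(pids, has_dx)
  if (length(missing)) {
    stop(sprintf("patient '%s' has no diagnosis entry", missing[[1L]]))
  }
  invisible(reports)
}

# Feature keys for one term instance under a mask mode. Mapped categories
# yield one key per mapped ontology class (a "bag of classes"); terms that
# failed mapping fall back to their raw normalized key so that no term is
# silently dropped.
term_keys <- function(norm_key, category, mode, mapping_table) {
  if (mode == "raw") {
    return(data.frame(key = norm_key, kind = "raw_term",
                      stringsAsFactors = FALSE))
  }
  entry <- lookup_mapping(mapping_table, norm_key, category)
  if (is.null(entry) || entry$step == "unmapped" || !nzchar(entry$class_ids)) {
    return(data.frame(key = norm_key, kind = "raw_term",
                      stringsAsFactors = FALSE))
  }
  data.frame(key = strsplit(entry$class_ids, ";", fixed = TRUE)[[1L]],
             kind = "ontology_class", stringsAsFactors = FALSE)
}

build_indicator_matrix <- function(reports, mapping_table, modes, categories) {
  pids <- unique(reports$patient_id)
  cells <- list()
  meta <- list()
  fallback <- character()
  for (cat in categories) {
    sub <- reports[reports$category == cat, , drop = FALSE]
    if (nrow(sub) == 0L) next
    keys <- vapply(sub$term, normalize_key, "")
    uniq <- !duplicated(paste(sub$patient_id, keys))
    sub <- sub[uniq, , drop = FALSE]
    keys <- keys[uniq]
    key_map <- lapply(setNames(nm = unique(keys)), term_keys, category = cat,
                      mode = modes[[cat]], mapping_table = mapping_table)
    for (i in seq_len(nrow(sub))) {
      tk <- key_map[[keys[[i]]]]
      if (modes[[cat]] == "mapped" && any(tk$kind == "raw_term")) {
        fallback <- c(fallback, keys[[i]])
      }
      for (j in seq_len(nrow(tk))) {
        col <- paste(cat, tk$key[[j]], sep = ":")
        cells[[length(cells) + 1L]] <- c(sub$patient_id[[i]], col)
        if (is.null(meta[[col]])) {
          meta[[col]] <- data.frame(name = col, category = cat,
                                    key = tk$key[[j]], kind = tk$kind[[j]],
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  cols <- sort(names(meta))
  mat <- matrix(0L, nrow = length(pids), ncol = length(cols),
                dimnames = list(pids, cols))
  for (cell in cells) mat[cell[[1L]], cell[[2L]]] <- 1L
  col_meta <- if (length(cols)) {
    do.call(rbind, meta[cols])
  } else {
    data.frame(name = character(), category = character(),
               key = character(), kind = character(), stringsAsFactors = FALSE)
  }
  rownames(col_meta) <- NULL
  structure(mat, col_meta = col_meta, fallback_keys = unique(fallback))
}

#' Build the binary feature matrix for the four input categories
#'
#' For categories marked `mapped` in the mask, every ontology class in a
#' term's mapped set becomes one binary column; terms without a usable
#' mapping fall back to raw-term columns (recorded in the `fallback_keys`
#' attribute). For `raw` categories each distinct normalized term is a
#' column. An indicator is 1 when any term of the patient's report yields
#' that key. Column names are `category:key` so identical keys in different
#' categories stay distinct columns.
#'
#' @param reports long-format report data frame.
#' @param mapping_table a `mapping_table` from [map_corpus()].
#' @param mask a [mapping_mask].
#' @return binary integer matrix (patients x features) with a `col_meta`
#'   attribute describing each column.
#' @export
build_features <- function(reports, mapping_table, mask = mapping_mask()) {
  stopifnot(inherits(mask, "mapping_mask"))
  validate_reports(reports)
  build_indicator_matrix(reports, mapping_table,
                         modes = mask, categories = INPUT_CATEGORIES)
}

#' Build the multilabel diagnosis matrix
#'
#' In `mapped` mode synonymous raw diagnoses merge into ontology class
#' columns; in `raw` mode each distinct normalized diagnosis string is a
#' column. Every patient row is guaranteed at least one positive label.
#'
#' @inheritParams build_features
#' @return binary integer matrix (patients x labels) with a `col_meta`
#'   attribute.
#' @export
build_labels <- function(reports, mapping_table, mask = mapping_mask()) {
  stopifnot(inherits(mask, "mapping_mask"))
  validate_reports(reports)
  mat <- build_indicator_matrix(reports, mapping_table,
                                modes = list(diagnosis = mask$labels),
                                categories = "diagnosis")
  empty <- rownames(mat)[rowSums(mat) == 0L]
  if (length(empty)) {
    stop(sprintf("patient '%s' has no usable diagnosis label", empty[[1L]]))
  }
  mat
}

#' Vocabulary reduction from ontology mapping
#'
#' The consolidation statistic reported per category: the percentage
#' decrease from the raw distinct-term count to the mapped vocabulary size,
#' `100 * (raw - mapped) / raw`. Values are returned at full precision; the
#' print method shows two decimals.
#'
#' @param raw_vocab named numeric vector of per-category raw term counts.
#' @param mapped_vocab named numeric vector of per-category mapped
#'   vocabulary counts (same names).
#' @return named numeric vector of class `reduction_stats`.
#' @export
reduction_stats <- function(raw_vocab, mapped_vocab) {
  if (!all(names(raw_vocab) == names(mapped_vocab))) {
    stop("raw and mapped vocabularies must share category names")
  }
  if (any(raw_vocab <= 0)) stop("raw vocabulary counts must be positive")
  if (any(mapped_vocab < 0)) stop("mapped vocabulary counts must be nonnegative")
  if (any(mapped_vocab > raw_vocab)) {
    stop("mapped vocabulary cannot exceed raw vocabulary")
  }
  structure(100 * (raw_vocab - mapped_vocab) / raw_vocab,
            class = "reduction_stats")
}

#' @export
print.reduction_stats <- function(x, ...) {
  out <- format(round(unclass(x), 2), nsmall = 2)
  cat("Decrease in the number of terms (%):\n")
  for (nm in names(out)) cat(sprintf("  %-22s %s\n", nm, out[[nm]]))
  invisible(x)
}

#' Per-category vocabulary counts before and after mapping
#'
#' Raw counts are distinct normalized term strings per category; mapped
#' counts are the distinct feature keys the category produces in mapped
#' mode (ontology classes plus raw fallbacks of unmapped terms).
#'
#' @param reports long-format report data frame.
#' @param mapping_table a `mapping_table`.
#' @return a list with named vectors `raw` and `mapped` and the
#'   `reduction_stats` percentages in `$reduction`.
#' @export
vocab_counts <- function(reports, mapping_table) {
  validate_reports(reports)
  cats <- REPORT_CATEGORIES
  raw <- mapped <- setNames(numeric(length(cats)), cats)
  for (cat in cats) {
    sub <- reports[reports$category == cat, , drop = FALSE]
    keys <- unique(vapply(sub$term, normalize_key, ""))
    raw[[cat]] <- length(keys)
    mk <- unlist(lapply(keys, function(k) {
      term_keys(k, cat, "mapped", mapping_table)$key
    }))
    mapped[[cat]] <- length(unique(mk))
  }
  list(raw = raw, mapped = mapped, reduction = reduction_stats(raw, mapped))
}

#' Read / write report tables
#'
#' Reports travel as long-format TSV (columns `patient_id`, `category`,
#' `term`; metadata lines prefixed `#` are ignored) or as JSON with one
#' object per patient.
#'
#' @param path file path.
#' @return a long-format report data frame.
#' @export
read_reports <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(recs, function(r) {
      cats <- c(r$terms, list(diagnosis = r$diagnoses))
      do.call(rbind, lapply(names(cats), function(cat) {
        if (length(cats[[cat]]) == 0L) return(NULL)
        data.frame(patient_id = r$patient_id, category = cat,
                   term = unlist(cats[[cat]]), stringsAsFactors = FALSE)
      }))
    })
    df <- do.call(rbind, rows)
  } else {
    df <- read_tsv_skip_header(path)
  }
  validate_reports(df)
  df
}

#' @rdname read_reports
#' @param reports long-format report data frame.
#' @param config,seed optional metadata echoed into the TSV header.
#' @export
write_reports <- function(reports, path, config = NULL, seed = NULL) {
  validate_reports(reports)
  write_tsv_with_header(reports, path, config, seed)
}

#' Export a feature or label matrix as TSV
#'
#' Column metadata (category and kind per feature) is written as `#`
#' prefixed header lines above the matrix.
#'
#' @param mat a matrix from [build_features()] or [build_labels()].
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  meta <- attr(mat, "col_meta")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(metadata_header(), con)
  if (!is.null(meta)) {
    writeLines(sprintf("# column %s category=%s kind=%s",
                       meta$name, meta$category, meta$kind), con)
  }
  df <- data.frame(patient_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
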