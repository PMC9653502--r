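#' @useDynLib ontofeat, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats predict rbinom sd coef
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a global seed and a stream name
#'
#' All randomness in the package flows from one user-supplied seed; named
#' substreams keep independent stages (label sampling, concept sampling,
#' surface rendering, fold assignment, ...) decoupled so that changing one
#' stage does not perturb another. The result is always a valid 32-bit R
#' integer.
#'
#' @param seed integer scalar, the global seed.
#' @param stream character scalar naming the substream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# FNV-1a style hash of an arbitrary R object, for output metadata headers.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- (bitwXor(as.integer(h %% 2147483647), ch) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Standard metadata header written at the top of every output file.
metadata_header <- function(config = NULL, seed = NULL) {
  c(
    sprintf("# ontofeat version: %s", as.character(packageVersion("ontofeat"))),
    sprintf("# config hash: %s", config_hash(config)),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed))
  )
}

write_tsv_with_header <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(metadata_header(config, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_header <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#")
  read.delim(text = paste(lines[keep], collapse = "\n"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
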