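# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a child seed from a global seed
#'
#' Deterministically maps a (seed, stream) pair to a new 32-bit seed so that
#' independent simulation streams (mouse matrix, human matrix, qPCR table,
#' ...) can be regenerated in isolation while a single global seed controls
#' the whole study.
#'
#' @param seed Integer global seed.
#' @param stream Integer stream index (>= 0).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
childSeed <- function(seed, stream) {
  seed <- as.double(seed)
  stream <- as.double(stream)
  # multiplicative mix kept in double precision; 2^31-1 is a Mersenne prime
  as.integer((seed * 48271 + stream * 9973 + 1) %% (2^31 - 1))
}

# Canonical gene-symbol form used for cross-species matching.
canonicalSymbol <- function(x) toupper(trimws(x))

# Validate the expression-matrix contract: numeric matrix, unique finite
# dimnames, all values finite, >= 1 feature and >= `minSamples` samples.
checkExprMatrix <- function(m, minSamples = 2L, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("%s must carry feature and sample names", what)
  if (anyDuplicated(rownames(m)))
    stopf("duplicate feature id '%s' in %s",
          rownames(m)[duplicated(rownames(m))][1L], what)
  if (anyDuplicated(colnames(m)))
    stopf("duplicate sample id '%s' in %s",
          colnames(m)[duplicated(colnames(m))][1L], what)
  if (nrow(m) < 1L) stopf("%s has no features", what)
  if (ncol(m) < minSamples)
    stopf("%s needs at least %d samples, found %d", what, minSamples, ncol(m))
  if (!all(is.finite(m))) stopf("%s contains non-finite values", what)
  invisible(m)
}

# Samples of a design that belong to a group; errors on unknown labels.
groupSamples <- function(design, group) {
  if (!group %in% design$group)
    stopf("group '%s' not present in design table", group)
  design$sample_id[design$group == group]
}

# Population-denominator standard deviation of each row.
rowSdPop <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

writeJsonReport <- function(x, path) {
  # stable report dialect: UTF-8, keys sorted, no rounding
  sortKeys <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v))
      v <- lapply(v[order(names(v))], sortKeys)
    v
  }
  jsonlite::write_json(sortKeys(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
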