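#' @include utils.R
NULL

#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every sample (column) onto the same distribution: the mean of
#' the column order statistics. Ties within a column receive the mean of
#' the quantile values they span. This is the quantile-normalization step
#' of the RMA procedure, applied to an already-summarized probe-set
#' matrix; background correction and probe-level summarization require
#' probe-level data and are not part of this pipeline.
#'
#' @param m Numeric features-by-samples matrix (>= 2 samples).
#' @return Matrix of the same shape; within-column rank order preserved,
#'   all column distributions identical.
#' @export
quantileNormalize <- function(m) {
  checkExprMatrix(m, minSamples = 2L)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Standardize each row to mean 0, population-sd 1
#'
#' Rows with population standard deviation below `tol` cannot be
#' standardized; they are set to all-zero and reported in the
#' `"flagged_constant"` attribute. The population (n) denominator is used,
#' the clustering-literature convention; since standardization only
#' rescales rows, downstream correlation distances are identical either
#' way.
#'
#' @param m Numeric matrix.
#' @param tol Degeneracy tolerance on the row sd.
#' @return Matrix with standardized rows; attribute `flagged_constant`
#'   lists the ids of degenerate rows.
#' @export
standardizeRows <- function(m, tol = 1e-12) {
  mu <- rowMeans(m)
  sd <- rowSdPop(m)
  flat <- sd < tol
  sdSafe <- ifelse(flat, 1, sd)
  out <- (m - mu) / sdSafe
  out[flat, ] <- 0
  attr(out, "flagged_constant") <-
    if (is.null(rownames(m))) which(flat) else rownames(m)[flat]
  out
}

#' Clip matrix values to a fixed range
#'
#' @param m Numeric matrix.
#' @param lo,hi Range bounds, `lo < hi`. The cross-species display
#'   convention is `[-3, 3]`.
#' @return Clipped matrix.
#' @export
clipValues <- function(m, lo = -3, hi = 3) {
  if (!(lo < hi)) stopf("clip range invalid: lo (%g) must be < hi (%g)", lo, hi)
  m[m < lo] <- lo
  m[m > hi] <- hi
  m
}

#' Per-group mean expression profiles
#'
#' Collapses samples to one column per design group (arithmetic mean per
#' feature). Column order follows `vocabulary` when given, otherwise the
#' order of first appearance in the design.
#'
#' @param m Numeric features-by-samples matrix.
#' @param design Design data.frame (see [readDesignTable()]).
#' @param vocabulary Optional character vector fixing group column order.
#' @return Features-by-groups matrix of means.
#' @export
groupMeans <- function(m, design, vocabulary = NULL) {
  missing <- setdiff(colnames(m), design$sample_id)
  if (length(missing))
    stopf("sample '%s' has no design row", missing[1L])
  groups <- if (is.null(vocabulary)) unique(design$group) else vocabulary
  groups <- groups[groups %in% design$group]
  out <- vapply(groups, function(g) {
    ids <- intersect(design$sample_id[design$group == g], colnames(m))
    rowMeans(m[, ids, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), groups))
  out
}

#' Log2-transform a linear-scale matrix
#'
#' Applied only when the input is declared linear-scale
#' (`input_scale: linear` in a pipeline config); the pipeline otherwise
#' assumes log2 input.
#'
#' @param m Numeric matrix of positive linear-scale intensities.
#' @param pseudocount Added before the log to guard zeros.
#' @return Log2-scale matrix.
#' @export
log2Transform <- function(m, pseudocount = 0) {
  if (any(m + pseudocount <= 0))
    stopf("non-positive intensities; increase pseudocount")
  log2(m + pseudocount)
}
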