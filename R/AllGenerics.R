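#' @include AllClasses.R
NULL

#' Feature identifiers of a result object
#' @param x An object carrying per-feature results.
#' @return Character vector of identifiers.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Gene symbols of a gene-level object
#' @param x A gene-level object.
#' @return Character vector of gene symbols.
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' Expression values of a container
#' @param x A container holding an expression matrix.
#' @return Numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Features called significant by a SAM run
#' @param x A [SamResult-class].
#' @return Character vector of significant feature ids.
#' @export
setGeneric("significantFeatures",
           function(x) standardGeneric("significantFeatures"))

#' Probe-to-gene mapping provenance
#' @param x A [GeneMatrix-class].
#' @return Named list of per-gene contribution tables.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Species label of each sample
#' @param x An [IntegratedSet-class].
#' @return Named character vector.
#' @export
setGeneric("speciesOfSample", function(x) standardGeneric("speciesOfSample"))

#' Concordance rate of a report
#' @param x A [ConcordanceReport-class].
#' @param style `"raw"` (fraction), `"rounded"` (half-up integer percent)
#'   or `"display"` (0.5-resolution-then-half-up integer percent).
#' @return Numeric or integer scalar.
#' @export
setGeneric("concordRate",
           function(x, style = c("raw", "rounded", "display"))
             standardGeneric("concordRate"))

# ---- methods ---------------------------------------------------------------

#' @describeIn SamResult feature identifiers
#' @param x A `SamResult`.
#' @export
setMethod("featureIds", "SamResult", function(x) x@featureIds)

#' @describeIn SamResult ids of features called significant
#' @export
setMethod("significantFeatures", "SamResult", function(x) {
  x@featureIds[which(x@significant)]
})

#' @describeIn GeneMatrix gene symbols
#' @param x A `GeneMatrix`.
#' @export
setMethod("geneSymbols", "GeneMatrix", function(x) rownames(x@values))

#' @describeIn GeneMatrix gene-level expression values
#' @export
setMethod("exprValues", "GeneMatrix", function(x) x@values)

#' @describeIn GeneMatrix per-gene probe contributions
#' @export
setMethod("provenance", "GeneMatrix", function(x) x@provenance)

#' @describeIn IntegratedSet gene symbols of the common-ortholog block
#' @param x An `IntegratedSet`.
#' @export
setMethod("geneSymbols", "IntegratedSet", function(x) rownames(x@values))

#' @describeIn IntegratedSet integrated, clipped expression values
#' @export
setMethod("exprValues", "IntegratedSet", function(x) x@values)

#' @describeIn IntegratedSet species of each sample column
#' @export
setMethod("speciesOfSample", "IntegratedSet", function(x) x@speciesOfSample)

#' @describeIn ConcordanceReport gene symbols scored
#' @param x A `ConcordanceReport`.
#' @export
setMethod("geneSymbols", "ConcordanceReport", function(x) x@geneSymbols)

#' @describeIn ConcordanceReport the concordance rate in one of three styles
#' @param style Rendering of the rate.
#' @export
setMethod("concordRate", "ConcordanceReport", function(x, style = c("raw",
    "rounded", "display")) {
  switch(match.arg(style),
    raw = x@rate,
    rounded = x@ratePctRounded,
    display = x@ratePctDisplay
  )
})

#' Convert a LinkageTree to a base hclust object
#'
#' @param x A [LinkageTree-class] with at least two leaves.
#' @param ... Ignored.
#' @return An object of class `hclust`.
#' @export
as.hclust.LinkageTree <- function(x, ...) {
  n <- length(x@labels)
  if (n < 2L) stopf("cannot convert a single-leaf tree to hclust")
  structure(
    list(
      merge = x@merge, height = x@height, order = leafOrder(x@merge),
      labels = x@labels, method = x@method,
      call = match.call(), dist.method = "custom"
    ),
    class = "hclust"
  )
}

# leaf ordering by depth-first traversal of the merge matrix
leafOrder <- function(merge) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(nrow(merge))
}

setMethod("show", "SamResult", function(object) {
  n <- length(object@featureIds)
  nsig <- sum(object@significant, na.rm = TRUE)
  cat(sprintf("SamResult: %d features, comparison %s vs %s\n", n,
              object@params$groupB %||% "?", object@params$groupA %||% "?"))
  cat(sprintf("  s0 = %.4g", object@params$s0 %||% NA_real_))
  if (!is.na(object@delta)) {
    cat(sprintf(", delta = %.4g, est. FDR = %.3g, significant = %d (%d up, %d down)",
                object@delta, min(object@fdrEst, 1), nsig,
                sum(object@direction == "up"), sum(object@direction == "down")))
  } else {
    cat(" (permutation step not yet run)")
  }
  cat("\n")
})

setMethod("show", "LinkageTree", function(object) {
  cat(sprintf("LinkageTree (%s linkage): %d leaves, %d merges\n",
              object@method, length(object@labels), nrow(object@merge)))
})

setMethod("show", "GeneMatrix", function(object) {
  cat(sprintf("GeneMatrix: %d genes x %d samples\n",
              nrow(object@values), ncol(object@values)))
  multi <- sum(vapply(object@provenance, nrow, 1L) > 1L)
  cat(sprintf("  %d genes backed by >1 probe\n", multi))
})

setMethod("show", "IntegratedSet", function(object) {
  tab <- table(object@speciesOfSample)
  cat(sprintf("IntegratedSet: %d common ortholog genes x %d samples (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf(
    "ConcordanceReport: %d/%d genes direction-concordant (rate %.4f; %.2f%% raw, %d%% displayed)\n",
    object@nConcordant, object@nTotal, object@rate, 100 * object@rate,
    object@ratePctDisplay))
})

setMethod("show", "ConsensusClustering", function(object) {
  cat(sprintf("ConsensusClustering: consensus k* = %d (nominations: %s)\n",
              object@kStar,
              paste(sprintf("%s=%d", names(object@nominations),
                            object@nominations), collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
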