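#' @import methods
NULL

#' SAM differential-expression result
#'
#' Holds the per-feature SAM statistics for one two-class unpaired
#' comparison: the relative difference `d`, the pooled scatter `s`, group
#' means on the log2 scale, the linear-scale fold change, and — once
#' [permutationFdr()] has run — the permutation null order statistics, the
#' selected threshold `delta`, the estimated FDR at that threshold, and the
#' per-feature significance calls.
#'
#' @slot featureIds Character vector of feature identifiers.
#' @slot d Numeric, relative difference `(meanB - meanA) / (s + s0)`.
#' @slot s Numeric, pooled scatter per feature.
#' @slot meanA,meanB Numeric, per-group means (log2 scale).
#' @slot fc Numeric, linear fold change `2^(meanB - meanA)`.
#' @slot dbar Numeric, expected null order statistics (sorted-d scale);
#'   `NA` until the permutation step runs.
#' @slot delta Numeric(1), selected exceedance threshold (`Inf` when no
#'   threshold meets the FDR bound, `NA` before the permutation step).
#' @slot fdrEst Numeric(1), estimated FDR at `delta` (may exceed 1; clip in
#'   summaries).
#' @slot significant Logical per feature.
#' @slot direction Character per feature: `"up"`, `"down"` or `"none"`.
#' @slot params List of run parameters (s0, nPerm, nPermUsed, seed, fdrMax,
#'   fcCutoff, pi0, groups).
#' @export
setClass("SamResult",
  representation(
    featureIds = "character",
    d = "numeric",
    s = "numeric",
    meanA = "numeric",
    meanB = "numeric",
    fc = "numeric",
    dbar = "numeric",
    delta = "numeric",
    fdrEst = "numeric",
    significant = "logical",
    direction = "character",
    params = "list"
  )
)

setValidity("SamResult", function(object) {
  n <- length(object@featureIds)
  lens <- c(
    d = length(object@d), s = length(object@s),
    meanA = length(object@meanA), meanB = length(object@meanB),
    fc = length(object@fc), significant = length(object@significant),
    direction = length(object@direction)
  )
  if (any(lens != n))
    return("per-feature slots must all have the same length")
  if (anyDuplicated(object@featureIds))
    return("featureIds must be unique")
  if (any(object@fc <= 0, na.rm = TRUE))
    return("fold changes must be positive")
  TRUE
})

#' Agglomerative linkage tree
#'
#' A dendrogram produced by [averageLinkage()]: an hclust-style merge
#' matrix (negative entries are leaves, positive entries reference earlier
#' merges), the merge heights, and the leaf labels.
#'
#' @slot merge Integer matrix, `(n-1) x 2`.
#' @slot height Numeric merge heights.
#' @slot labels Character leaf labels.
#' @slot method Character(1), linkage method name.
#' @export
setClass("LinkageTree",
  representation(
    merge = "matrix",
    height = "numeric",
    labels = "character",
    method = "character"
  )
)

setValidity("LinkageTree", function(object) {
  n <- length(object@labels)
  if (n < 1L) return("tree needs at least one leaf")
  if (n == 1L) {
    if (nrow(object@merge) != 0L) return("single leaf admits no merges")
    return(TRUE)
  }
  if (nrow(object@merge) != n - 1L)
    return(sprintf("expected %d merges for %d leaves", n - 1L, n))
  if (length(object@height) != n - 1L)
    return("one height per merge required")
  TRUE
})

#' Gene-level expression matrix with mapping provenance
#'
#' Probe-level expression collapsed onto ortholog gene symbols by
#' [mapProbesToGenes()]. Each gene records which probes contributed and
#' with what split factor (1/m for a probe linked to m genes).
#'
#' @slot values Numeric matrix, genes x samples (log2 scale).
#' @slot provenance Named list; per gene a data.frame with columns
#'   `probe_id` and `split_factor`.
#' @export
setClass("GeneMatrix",
  representation(values = "matrix", provenance = "list")
)

setValidity("GeneMatrix", function(object) {
  if (is.null(rownames(object@values)))
    return("gene symbols required as rownames")
  if (anyDuplicated(rownames(object@values)))
    return("gene symbols must be unique")
  if (!all(is.finite(object@values)))
    return("values must be finite")
  if (!setequal(names(object@provenance), rownames(object@values)))
    return("provenance must cover exactly the genes in the matrix")
  if (any(!vapply(object@provenance, nrow, 1L)))
    return("every gene needs at least one contributing probe")
  TRUE
})

#' Integrated cross-species expression set
#'
#' The common-ortholog expression block built by [intersectAndIntegrate()]:
#' per-species row-standardized values on the shared (case-canonicalized)
#' gene symbols, columns ordered species A then species B, clipped to a
#' fixed display range.
#'
#' @slot values Numeric matrix, genes x samples, clipped.
#' @slot speciesOfSample Named character, species label per sample.
#' @slot counts Named integer: genes per input species and intersection size.
#' @export
setClass("IntegratedSet",
  representation(
    values = "matrix",
    speciesOfSample = "character",
    counts = "integer"
  )
)

setValidity("IntegratedSet", function(object) {
  if (!identical(colnames(object@values), names(object@speciesOfSample)))
    return("speciesOfSample must be named by the sample columns")
  if (anyDuplicated(rownames(object@values)))
    return("gene symbols must be unique")
  TRUE
})

#' Cross-species fold-change concordance report
#'
#' Per-gene tumor-vs-normal log2 fold changes in each species, a
#' direction-agreement flag, and the overall concordance rate in three
#' renderings: the raw fraction, the half-up integer percent, and the
#' display percent (rounded to the nearest 0.5 percent first, then half-up
#' to an integer).
#'
#' @slot geneSymbols Character.
#' @slot log2fcA,log2fcB Numeric per-gene log2 fold changes.
#' @slot concordant Logical per gene (same nonzero sign in both species).
#' @slot nTotal,nConcordant Integer counts.
#' @slot rate Numeric(1) in `[0, 1]`.
#' @slot ratePctRounded Integer(1), `round(100 * rate)` half-up.
#' @slot ratePctDisplay Integer(1), two-stage display rounding.
#' @export
setClass("ConcordanceReport",
  representation(
    geneSymbols = "character",
    log2fcA = "numeric",
    log2fcB = "numeric",
    concordant = "logical",
    nTotal = "integer",
    nConcordant = "integer",
    rate = "numeric",
    ratePctRounded = "integer",
    ratePctDisplay = "integer"
  )
)

setValidity("ConcordanceReport", function(object) {
  n <- length(object@geneSymbols)
  if (length(object@log2fcA) != n || length(object@log2fcB) != n ||
      length(object@concordant) != n)
    return("per-gene slots must have equal length")
  if (object@nConcordant > object@nTotal)
    return("nConcordant cannot exceed nTotal")
  if (object@rate < 0 || object@rate > 1)
    return("rate must lie in [0, 1]")
  TRUE
})

#' Consensus cluster-number estimate
#'
#' Result of [consensusClusterCount()]: the per-k quality table for the
#' three indices, each index's nomination, the consensus `kStar`, the
#' linkage tree, and the flat assignment at `kStar`.
#'
#' @slot kStar Integer(1), consensus cluster number.
#' @slot quality Data frame with one row per candidate k.
#' @slot nominations Named integer, one nomination per index.
#' @slot tree A [LinkageTree-class].
#' @slot assignment Named integer cluster ids at `kStar`.
#' @export
setClass("ConsensusClustering",
  representation(
    kStar = "integer",
    quality = "data.frame",
    nominations = "integer",
    tree = "LinkageTree",
    assignment = "integer"
  )
)
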