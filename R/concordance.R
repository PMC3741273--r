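#' @include AllClasses.R utils.R clustering.R
NULL

#' Per-gene tumor-vs-normal log2 fold change
#'
#' `log2fc(gene) = mean(log2 expr over tumor samples) - mean(over normal
#' samples)`.
#'
#' @param g A [GeneMatrix-class] or plain genes-by-samples log2 matrix.
#' @param design Design data.frame covering the matrix samples.
#' @param tumorGroup,normalGroup Group labels (either a single label or a
#'   vector of labels to pool, e.g. `c("T1", "T3")`).
#' @return Named numeric vector of log2 fold changes.
#' @export
foldChangeBySpecies <- function(g, design, tumorGroup, normalGroup) {
  v <- if (is(g, "GeneMatrix")) exprValues(g) else g
  pick <- function(groups) {
    for (gr in groups) groupSamples(design, gr)  # error on unknown label
    ids <- design$sample_id[design$group %in% groups]
    ids <- intersect(ids, colnames(v))
    if (!length(ids)) stopf("no samples of group(s) %s in the matrix",
                            paste(groups, collapse = ", "))
    ids
  }
  rowMeans(v[, pick(tumorGroup), drop = FALSE]) -
    rowMeans(v[, pick(normalGroup), drop = FALSE])
}

# paper-style display percent: round to the nearest 0.5 percent, then
# half-up to an integer (77.48 -> 77.5 -> 78)
displayPercent <- function(rate) {
  pct <- 100 * rate
  half <- floor(pct * 2 + 0.5) / 2
  as.integer(floor(half + 0.5))
}

halfUpPercent <- function(rate) as.integer(floor(100 * rate + 0.5))

#' Cross-species fold-change concordance
#'
#' A gene is concordant when its tumor-vs-normal log2 fold changes have
#' the same nonzero sign in both species (`concordance_mode = "sign"`,
#' the default) or additionally both reach a magnitude of at least
#' `log2(fcMin)` (`"sign_and_magnitude"`). Genes with an exactly zero
#' fold change in either species are counted non-concordant and flagged.
#'
#' The report carries the raw rate, the half-up integer percent, and the
#' display percent (rounded to the nearest 0.5 first and then half-up, so
#' 117/151 = 77.48% displays as 78%). All three are emitted so any
#' rounding discrepancy stays visible.
#'
#' @param fcA,fcB Named numeric log2 fold-change vectors on the same gene
#'   list in the same order (conventionally mouse then human).
#' @param mode Concordance definition, see above.
#' @param fcMin Linear fold-change magnitude for
#'   `"sign_and_magnitude"`.
#' @return A [ConcordanceReport-class].
#' @export
concordanceRate <- function(fcA, fcB, mode = c("sign", "sign_and_magnitude"),
                            fcMin = 2) {
  mode <- match.arg(mode)
  if (length(fcA) != length(fcB))
    stopf("fold-change vectors differ in length (%d vs %d)",
          length(fcA), length(fcB))
  if (!is.null(names(fcA)) && !is.null(names(fcB)) &&
      !identical(names(fcA), names(fcB)))
    stopf("fold-change vectors must be on the same gene list in the same order")
  genes <- names(fcA) %||% as.character(seq_along(fcA))

  zero <- fcA == 0 | fcB == 0
  if (any(zero))
    warnf("%d gene(s) with exactly zero fold change counted non-concordant",
          sum(zero))
  concordant <- !zero & sign(fcA) == sign(fcB)
  if (mode == "sign_and_magnitude")
    concordant <- concordant & abs(fcA) >= log2(fcMin) & abs(fcB) >= log2(fcMin)

  n <- length(genes)
  nc <- sum(concordant)
  rate <- nc / n
  new("ConcordanceReport",
      geneSymbols = genes, log2fcA = unname(fcA), log2fcB = unname(fcB),
      concordant = unname(concordant), nTotal = as.integer(n),
      nConcordant = as.integer(nc), rate = rate,
      ratePctRounded = halfUpPercent(rate),
      ratePctDisplay = displayPercent(rate))
}

#' Cluster the samples of an integrated cross-species set
#'
#' Clusters the sample columns with 1-Pearson distance and average
#' linkage, cuts at `k`, and reports, for every sample of the designated
#' tumor group of the first species, the second-species samples sharing
#' its cluster together with their disease-stage labels — the
#' co-clustering readout that shows which human stage the mouse tumors
#' join.
#'
#' @param s An [IntegratedSet-class] (>= 3 samples).
#' @param design Design data.frame covering all samples of `s`.
#' @param k Number of flat clusters.
#' @param tumorGroup Group label of the first-species tumor samples.
#' @param newickPath Optional path; when given the sample dendrogram is
#'   written there in Newick form.
#' @return List with `tree` ([LinkageTree-class]), `assignment` (named
#'   integer) and `coClustering` (data.frame: tumor sample, cluster,
#'   partner samples and their groups).
#' @export
crossSpeciesSampleClusters <- function(s, design, k, tumorGroup = "KO24",
                                       newickPath = NULL) {
  v <- exprValues(s)
  if (ncol(v) < 3L) stopf("need at least 3 samples to cluster")
  if (k < 1L || k > ncol(v)) stopf("k = %d out of range [1, %d]", k, ncol(v))
  D <- correlationDistance(t(v))
  tree <- averageLinkage(D)
  if (!is.null(newickPath)) writeNewick(tree, newickPath)
  assign <- cutTree(tree, k)

  species <- speciesOfSample(s)
  firstSpecies <- species[[1L]]
  grp <- stats::setNames(design$group, design$sample_id)
  tumorSamples <- names(species)[species == firstSpecies &
                                   grp[names(species)] == tumorGroup]
  rows <- lapply(tumorSamples, function(ts) {
    cl <- assign[[ts]]
    partners <- names(assign)[assign == cl &
                                species[names(assign)] != firstSpecies]
    data.frame(
      tumor_sample = ts, cluster = cl,
      partner_samples = paste(partners, collapse = ","),
      partner_groups = paste(grp[partners], collapse = ","),
      stringsAsFactors = FALSE)
  })
  coClustering <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tumor_sample = character(), cluster = integer(),
               partner_samples = character(), partner_groups = character(),
               stringsAsFactors = FALSE)
  list(tree = tree, assignment = assign, coClustering = coClustering)
}

#' Serialize a concordance report to a JSON-ready list
#'
#' @param report A [ConcordanceReport-class].
#' @return Nested list mirroring the report (genes, fold changes, flags,
#'   counts, raw and rounded rates).
#' @export
concordanceReportAsList <- function(report) {
  list(
    genes = lapply(seq_along(report@geneSymbols), function(i) list(
      gene = report@geneSymbols[i],
      log2fc_a = report@log2fcA[i],
      log2fc_b = report@log2fcB[i],
      concordant = report@concordant[i])),
    n_total = report@nTotal,
    n_concordant = report@nConcordant,
    rate = report@rate,
    rate_pct_raw = 100 * report@rate,
    rate_pct_rounded = report@ratePctRounded,
    rate_pct_display = report@ratePctDisplay)
}
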