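#' @include utils.R
NULL

# Delta-delta-Ct relative quantification for qPCR panel arrays, with
# housekeeping normalization (arithmetic mean of housekeeping Ct per
# sample, equivalent to the geometric mean of linear quantities) and a
# joint fold-change / p-value selection cutoff.

#' Read a qPCR Ct table from TSV
#'
#' Layout matches the expression-matrix dialect: header
#' `gene_id<TAB>sample...`, numeric cycle-threshold body. Wells reported
#' as undetermined should be encoded at the detection ceiling (40 cycles
#' by convention) before export.
#'
#' @param path Path to a TSV file.
#' @param ceiling Maximum admissible Ct (default 45).
#' @return Numeric genes-by-samples matrix of Ct values.
#' @export
readCtTable <- function(path, ceiling = 45) {
  ct <- readExprMatrix(path)
  if (any(ct <= 0) || any(ct > ceiling))
    stopf("Ct values must lie in (0, %g]", ceiling)
  ct
}

#' Delta-delta-Ct analysis of a qPCR Ct table
#'
#' Per sample, `dCt(g) = Ct(g) - mean(Ct over housekeeping genes)`; per
#' gene, `ddCt = mean dCt(test) - mean dCt(ref)` and the linear fold
#' change is `2^(-ddCt)`. P-values come from a two-sided Welch t-test on
#' the per-sample dCt values; a gene is selected when
#' `FC >= fcCutoff` or `FC <= 1/fcCutoff`, and `p < pMax`.
#'
#' Degenerate variance is guarded: when both groups have zero within-group
#' dCt variance the p-value is 0 if the means differ and 1 otherwise.
#'
#' @param ct Genes-by-samples Ct matrix (includes the housekeeping genes).
#' @param design Design data.frame.
#' @param groupTest,groupRef Group labels (>= 2 samples each).
#' @param housekeeping Character vector of housekeeping gene ids (all must
#'   be present in `ct`).
#' @param fcCutoff Linear fold-change cutoff (default 3).
#' @param pMax P-value cutoff (default 0.05).
#' @return Data frame with one row per gene: `gene_id`, `ddct`, `fc`,
#'   `direction`, `p_value`, `selected`, `housekeeping`.
#' @export
ddctAnalysis <- function(ct, design, groupTest, groupRef, housekeeping,
                         fcCutoff = 3, pMax = 0.05) {
  missingHk <- setdiff(housekeeping, rownames(ct))
  if (length(missingHk))
    stopf("housekeeping gene '%s' missing from the Ct table", missingHk[1L])
  if (length(housekeeping) < 1L) stopf("need at least one housekeeping gene")
  sT <- intersect(groupSamples(design, groupTest), colnames(ct))
  sR <- intersect(groupSamples(design, groupRef), colnames(ct))
  if (length(sT) < 2L) stopf("group '%s' has fewer than 2 samples", groupTest)
  if (length(sR) < 2L) stopf("group '%s' has fewer than 2 samples", groupRef)

  hkMean <- colMeans(ct[housekeeping, , drop = FALSE])
  dct <- sweep(ct, 2L, hkMean)

  welch <- function(x, y) {
    if (stats::var(x) == 0 && stats::var(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y)$p.value
  }

  ddct <- rowMeans(dct[, sT, drop = FALSE]) - rowMeans(dct[, sR, drop = FALSE])
  fc <- 2^(-ddct)
  p <- vapply(rownames(ct), function(g) welch(dct[g, sT], dct[g, sR]), 1)
  isHk <- rownames(ct) %in% housekeeping
  selected <- !isHk & (fc >= fcCutoff | fc <= 1 / fcCutoff) & p < pMax
  direction <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))

  out <- data.frame(
    gene_id = rownames(ct), ddct = unname(ddct), fc = unname(fc),
    direction = unname(direction), p_value = unname(p),
    selected = unname(selected), housekeeping = isHk,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
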