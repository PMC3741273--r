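#' @include AllClasses.R utils.R
NULL

#' Collapse probe-level expression onto ortholog gene symbols
#'
#' Applies the exclusion / average / split rules that reduce a
#' many-to-many probe-to-gene relation to one expression row per gene
#' symbol:
#'
#' * probes with no link in the ortholog table are excluded;
#' * a probe linked to `m` genes contributes `value / m` to each of them
#'   (`split_mode = "divide"`, the default) or its full value to each
#'   (`"replicate"`);
#' * each gene's value per sample is the arithmetic mean of its incoming
#'   probe contributions.
#'
#' The closed form is deterministic and independent of the row order of
#' both inputs; a probe linked to the same gene twice counts once.
#'
#' @param m Probe-level log2 matrix (probes x samples).
#' @param orth Ortholog table data.frame (`probe_id`, `gene_symbol`), as
#'   returned by [readOrthologTable()].
#' @param splitMode `"divide"` (split the value evenly across linked
#'   genes) or `"replicate"` (duplicate it).
#' @return A [GeneMatrix-class], genes sorted lexicographically.
#' @export
mapProbesToGenes <- function(m, orth, splitMode = c("divide", "replicate")) {
  splitMode <- match.arg(splitMode)
  orth <- unique(orth[c("probe_id", "gene_symbol")])
  orth <- orth[nzchar(trimws(orth$gene_symbol)), , drop = FALSE]
  links <- orth[orth$probe_id %in% rownames(m), , drop = FALSE]
  if (nrow(links) == 0L)
    stopf("no mappable probes: matrix and ortholog table share no probe ids")
  links <- links[order(links$gene_symbol, links$probe_id), , drop = FALSE]

  degree <- table(links$probe_id)             # genes per probe
  split <- if (splitMode == "divide")
    1 / as.numeric(degree[links$probe_id]) else
    rep(1, nrow(links))

  contrib <- m[links$probe_id, , drop = FALSE] * split
  geneF <- factor(links$gene_symbol, levels = unique(links$gene_symbol))
  sums <- rowsum(contrib, geneF)
  counts <- as.integer(table(geneF))
  values <- sums / counts
  dimnames(values) <- list(levels(geneF), colnames(m))

  prov <- split.data.frame(
    data.frame(probe_id = links$probe_id, split_factor = split,
               stringsAsFactors = FALSE),
    geneF)
  prov <- lapply(prov, function(d) { rownames(d) <- NULL; d })

  new("GeneMatrix", values = values, provenance = prov)
}

#' Intersect two species' gene matrices and build the integrated set
#'
#' Keeps genes mutually present on both species' arrays (case-insensitive
#' symbol match; the canonical form is trimmed upper-case), standardizes
#' each species' block row-wise (mean 0, population-sd 1) so the
#' expression scales are comparable, concatenates columns first-species
#' then second, and clips to the display range.
#'
#' @param speciesA,speciesB [GeneMatrix-class] objects (conventionally
#'   mouse then human).
#' @param labels Character(2), species labels for the sample map.
#' @param clip Numeric(2) clip range, default `c(-3, 3)`.
#' @return An [IntegratedSet-class]; its `counts` slot records each
#'   species' input gene count and the intersection size.
#' @export
intersectAndIntegrate <- function(speciesA, speciesB,
                                  labels = c("mouse", "human"),
                                  clip = c(-3, 3)) {
  vA <- exprValues(speciesA)
  vB <- exprValues(speciesB)
  if (nrow(vA) == 0L || nrow(vB) == 0L)
    stopf("both gene matrices must be nonempty")

  canonA <- canonicalSymbol(rownames(vA))
  canonB <- canonicalSymbol(rownames(vB))
  vA <- collapseCanonical(vA, canonA)
  vB <- collapseCanonical(vB, canonB)

  common <- sort(intersect(rownames(vA), rownames(vB)))
  if (length(common) == 0L)
    stopf("empty ortholog intersection (%d vs %d genes)", nrow(vA), nrow(vB))

  zA <- standardizeRows(vA[common, , drop = FALSE])
  zB <- standardizeRows(vB[common, , drop = FALSE])
  values <- clipValues(cbind(zA, zB), clip[1L], clip[2L])
  attr(values, "flagged_constant") <- NULL

  species <- stats::setNames(
    c(rep(labels[1L], ncol(zA)), rep(labels[2L], ncol(zB))),
    colnames(values))
  new("IntegratedSet", values = values, speciesOfSample = species,
      counts = c(genesA = nrow(vA), genesB = nrow(vB),
                 intersection = length(common)))
}

# average rows whose symbols collide after canonicalization (duplicate
# compression, same rule as the probe-level averaging)
collapseCanonical <- function(v, canon) {
  if (!anyDuplicated(canon)) {
    rownames(v) <- canon
    return(v)
  }
  f <- factor(canon, levels = unique(canon))
  out <- rowsum(v, f) / as.integer(table(f))
  rownames(out) <- levels(f)
  out
}
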