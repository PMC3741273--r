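#' @include utils.R
NULL

# Tabular I/O. One dialect only: tab-separated, decimal point, no
# thousands separators, NA rejected in expression matrices. Floats are
# written with shortest round-trip formatting (>= 6 significant digits) so
# golden files are bit-stable.

#' Read a features-by-samples expression matrix from TSV
#'
#' Expects a header row `feature_id<TAB>sample1<TAB>...` and a numeric
#' body on the log2 scale. Row and column order of the file is preserved.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
readExprMatrix <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("'%s': need a header and at least one feature", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncolTotal <- length(header)
  if (ncolTotal < 3L) stopf("'%s': need at least 2 sample columns", path)
  body <- cells[-1L]
  widths <- lengths(body)
  if (any(widths != ncolTotal))
    stopf("'%s': ragged row %d (expected %d fields, found %d)", path,
          which(widths != ncolTotal)[1L] + 1L, ncolTotal,
          widths[widths != ncolTotal][1L])
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stopf("'%s': duplicate feature id '%s'", path, ids[duplicated(ids)][1L])
  vals <- matrix(NA_real_, nrow = length(ids), ncol = ncolTotal - 1L,
                 dimnames = list(ids, header[-1L]))
  for (j in seq_len(ncolTotal - 1L)) {
    col <- vapply(body, `[[`, "", j + 1L)
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stopf("'%s': non-numeric value '%s' at row '%s', column '%s'", path,
            col[bad[1L]], ids[bad[1L]], header[j + 1L])
    vals[, j] <- num
  }
  checkExprMatrix(vals, minSamples = 2L, what = sprintf("matrix '%s'", path))
  vals
}

# shortest decimal representation that round-trips (R's default 15-digit
# formatting is round-trip safe and trims trailing zeros)
formatFloat <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                               trim = TRUE), "")
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix with dimnames (see [readExprMatrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExprMatrix <- function(m, path) {
  checkExprMatrix(m, minSamples = 2L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatFloat(m[i, ])), collapse = "\t")
  }, "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Columns `sample_id`, `species`, `group`, `replicate`. Unknown group
#' labels relative to `vocabulary` raise a warning, not an error.
#'
#' @param path Path to a TSV file.
#' @param vocabulary Optional character vector of permitted group labels.
#' @return A data.frame with the four design columns.
#' @export
readDesignTable <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  d <- utils::read.delim(path, colClasses = "character", sep = "\t",
                         quote = "", check.names = FALSE)
  if (nrow(d) == 0L) stopf("'%s': empty design table", path)
  need <- c("sample_id", "species", "group", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("'%s': missing design column(s): %s", path,
          paste(miss, collapse = ", "))
  d <- d[need]
  d$replicate <- as.integer(d$replicate)
  validateDesign(d, vocabulary = vocabulary)
}

validateDesign <- function(d, vocabulary = NULL) {
  if (anyDuplicated(d$sample_id))
    stopf("duplicate sample_id '%s' in design",
          d$sample_id[duplicated(d$sample_id)][1L])
  if (!all(d$species %in% c("mouse", "human")))
    stopf("species must be 'mouse' or 'human', found '%s'",
          setdiff(d$species, c("mouse", "human"))[1L])
  if (any(!is.finite(d$replicate)) || any(d$replicate < 1L))
    stopf("replicate must be an integer >= 1")
  if (!is.null(vocabulary)) {
    unknown <- setdiff(d$group, vocabulary)
    if (length(unknown))
      warnf("group label(s) outside declared vocabulary: %s",
            paste(unknown, collapse = ", "))
  }
  rownames(d) <- NULL
  d
}

#' Write a design table as TSV
#' @param d Design data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDesignTable <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a many-to-many probe-to-ortholog table from TSV
#'
#' The two-column distillation of a platform orthologs annotation file:
#' columns `probe_id` and `gene_symbol`. Rows with a blank gene symbol are
#' dropped (and counted in the `"n_dropped"` attribute), duplicate pairs
#' are collapsed, and records are returned sorted lexicographically by
#' (probe_id, gene_symbol) so the result is independent of input row order.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `probe_id`, `gene_symbol` and
#'   attribute `n_dropped`.
#' @export
readOrthologTable <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  d <- utils::read.delim(path, colClasses = "character", sep = "\t",
                         quote = "", check.names = FALSE)
  need <- c("probe_id", "gene_symbol")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("'%s': missing ortholog column(s): %s", path,
          paste(miss, collapse = ", "))
  d <- d[need]
  blank <- !nzchar(trimws(d$gene_symbol))
  nDropped <- sum(blank)
  d <- d[!blank, , drop = FALSE]
  d <- unique(d)
  d <- d[order(d$probe_id, d$gene_symbol), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "n_dropped") <- nDropped
  d
}

#' Write an ortholog table as TSV
#' @param t Ortholog data.frame (`probe_id`, `gene_symbol`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOrthologTable <- function(t, path) {
  utils::write.table(t[c("probe_id", "gene_symbol")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a linkage tree as a Newick dendrogram
#'
#' Branch lengths follow the ultrametric convention: each leaf sits at
#' depth half the merge height, so the path between two leaves equals
#' their cophenetic merge height. Labels containing Newick metacharacters
#' are quoted. A single-leaf tree is written as `LABEL;`.
#'
#' @param tree A [LinkageTree-class].
#' @param path Output path.
#' @return The Newick string, invisibly.
#' @export
writeNewick <- function(tree, path) {
  labs <- tree@labels
  meta <- grepl("[ \t()\\[\\]:;,']", labs)
  labs[meta] <- paste0("'", gsub("'", "''", labs[meta]), "'")
  if (length(labs) == 1L) {
    nwk <- paste0(labs, ";")
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  h <- as.hclust(tree)
  h$labels <- labs
  phy <- ape::as.phylo(h)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Stub: distill a vendor orthologs annotation file
#'
#' Parsing vendor annotation CSVs is out of scope; this stub documents the
#' expected distilled format: a TSV with columns `probe_id` (platform
#' probe-set id) and `gene_symbol` (ortholog gene symbol), one row per
#' link, blank symbols permitted. Annotation provenance (which annotation
#' release produced the links) is the caller's responsibility.
#'
#' @param path Vendor file path (unused).
#' @return Never returns; raises an informative error.
#' @export
convertVendorAnnotation <- function(path) {
  stopf(paste0(
    "vendor annotation parsing is not implemented; supply a TSV with ",
    "columns probe_id, gene_symbol (see ?readOrthologTable)"))
}
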