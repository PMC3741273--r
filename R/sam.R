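#' @include AllClasses.R utils.R
NULL

# Significance Analysis of Microarrays (two-class unpaired): regularized
# relative difference d = (meanB - meanA)/(s + s0), permutation null via
# balanced label reassignment, FDR from order-statistic exceedance with
# asymmetric (two one-sided) cutpoints, and a separate fold-change gate.

#' Parameters for a SAM run
#'
#' @param s0 Exchangeability (fudge) factor; `NULL` to tune via
#'   [tuneS0()].
#' @param nPerm Maximum number of label permutations. When the number of
#'   distinct balanced assignments is `<= nPerm`, all of them are used
#'   exactly once; otherwise `nPerm` seeded draws.
#' @param seed Integer seed for permutation draws.
#' @param fdrMax FDR bound used to select the exceedance threshold delta.
#' @param fcCutoff Linear fold-change gate (`>= 1`); a feature must show
#'   `fc >= fcCutoff` or `fc <= 1/fcCutoff` in addition to exceeding
#'   delta. The within-species screen uses 3, the cross-species screen
#'   relaxes to 2.
#' @param pi0 Prior fraction of null features in the FDR estimate; fixed
#'   at the conservative 1.0 by default.
#' @return A named list of validated parameters.
#' @export
samParams <- function(s0 = NULL, nPerm = 1000L, seed = 1L, fdrMax = 0.05,
                      fcCutoff = 3, pi0 = 1) {
  if (!is.null(s0) && s0 < 0) stopf("s0 must be nonnegative")
  if (nPerm < 1L) stopf("nPerm must be >= 1")
  if (fdrMax <= 0 || fdrMax >= 1) stopf("fdrMax must lie in (0, 1)")
  if (fcCutoff < 1) stopf("fcCutoff must be >= 1")
  if (pi0 <= 0 || pi0 > 1) stopf("pi0 must lie in (0, 1]")
  list(s0 = s0, nPerm = as.integer(nPerm), seed = as.integer(seed),
       fdrMax = fdrMax, fcCutoff = fcCutoff, pi0 = pi0)
}

# d, s, means and fc for a fixed column split; core kernel shared by the
# observed statistic and the permutation loop.
samKernel <- function(m, idxA, idxB, s0) {
  nA <- length(idxA); nB <- length(idxB)
  mA <- rowMeans(m[, idxA, drop = FALSE])
  mB <- rowMeans(m[, idxB, drop = FALSE])
  ssA <- rowSums((m[, idxA, drop = FALSE] - mA)^2)
  ssB <- rowSums((m[, idxB, drop = FALSE] - mB)^2)
  s <- sqrt((1 / nA + 1 / nB) * (ssA + ssB) / (nA + nB - 2))
  list(d = (mB - mA) / (s + s0), s = s, meanA = mA, meanB = mB)
}

#' Per-feature SAM statistics for one two-class comparison
#'
#' Computes the relative difference `d_i = (meanB - meanA)/(s_i + s0)`
#' with the pooled scatter
#' `s_i = sqrt((1/nA + 1/nB) (SS_A + SS_B)/(nA + nB - 2))`, and the
#' linear fold change `fc_i = 2^(meanB - meanA)` (the matrix is on the
#' log2 scale).
#'
#' @param m Log2 features-by-samples matrix.
#' @param design Design data.frame.
#' @param groupA,groupB Group labels; `d > 0` means higher in `groupB`.
#' @param s0 Nonnegative fudge factor.
#' @return A [SamResult-class] with the statistic slots filled and the
#'   permutation slots empty.
#' @export
samStatistic <- function(m, design, groupA, groupB, s0) {
  checkExprMatrix(m)
  if (s0 < 0) stopf("s0 must be nonnegative")
  sA <- groupSamples(design, groupA)
  sB <- groupSamples(design, groupB)
  sA <- intersect(sA, colnames(m)); sB <- intersect(sB, colnames(m))
  if (length(sA) < 2L) stopf("group '%s' has fewer than 2 samples", groupA)
  if (length(sB) < 2L) stopf("group '%s' has fewer than 2 samples", groupB)
  k <- samKernel(m, match(sA, colnames(m)), match(sB, colnames(m)), s0)
  n <- nrow(m)
  new("SamResult",
      featureIds = rownames(m), d = k$d, s = k$s,
      meanA = k$meanA, meanB = k$meanB, fc = 2^(k$meanB - k$meanA),
      dbar = rep(NA_real_, n), delta = NA_real_, fdrEst = NA_real_,
      significant = rep(NA, n), direction = rep("none", n),
      params = list(s0 = s0, groupA = groupA, groupB = groupB,
                    samplesA = sA, samplesB = sB))
}

#' Tune the SAM fudge factor s0
#'
#' Chooses s0 among candidate percentiles `{0, 5, ..., 95}` of the
#' pooled-scatter distribution, minimizing the coefficient of variation
#' of `mad(d)` across windows of the s distribution — the
#' coefficient-of-variation criterion of the SAM method. With fewer than
#' 50 features the windowed criterion is unstable and `median(s)` is
#' returned instead. Exact ties are resolved toward the smallest
#' candidate value.
#'
#' @inheritParams samStatistic
#' @param nWindows Number of s-quantile windows (capped by feature count).
#' @return The selected s0 (a nonnegative scalar).
#' @export
tuneS0 <- function(m, design, groupA, groupB, nWindows = 100L) {
  base <- samStatistic(m, design, groupA, groupB, s0 = 0)
  s <- base@s
  n <- length(s)
  if (n < 50L) return(stats::median(s))
  diff <- base@meanB - base@meanA
  cand <- unique(as.numeric(stats::quantile(s, seq(0, 0.95, by = 0.05),
                                            type = 7)))
  nw <- max(2L, min(as.integer(nWindows), floor(n / 10)))
  # window membership by s-quantile, fixed across candidates
  win <- cut(rank(s, ties.method = "first"),
             breaks = nw, labels = FALSE, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d <- diff / (s + a)
    mads <- vapply(split(d, win), stats::mad, 1)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2L) return(Inf)
    stats::sd(mads) / mean(mads)
  }, 1)
  best <- cv <= min(cv) + 1e-15
  min(cand[best])
}

# all balanced assignments of nA+nB samples to the "B" role (matrix, one
# column per permutation, rows = indices assigned to B)
allAssignments <- function(nA, nB) {
  utils::combn(nA + nB, nB)
}

#' Permutation FDR and significance calls for a SAM comparison
#'
#' Permutes the group labels of the pooled samples (all distinct balanced
#' assignments when their number is at most `params$nPerm`, otherwise
#' `nPerm` seeded draws), forms the expected null order statistics
#' `dbar_(i)`, and for each threshold delta on the grid of observed
#' exceedances calls features asymmetrically: sorted features with
#' `d_(i) - dbar_(i) > delta` (upper cutpoint `cutup` = smallest such
#' `d_(i)`) or `< -delta` (lower cutpoint `cutlow`). The FDR estimate at
#' delta is `pi0 *` median over permutations of the number of permuted d
#' values beyond the cutpoints, divided by the number called. The
#' selected delta is the smallest grid value with FDR at or below
#' `params$fdrMax` — the most permissive calling set that still meets the
#' bound. Significance additionally requires the fold-change gate, which
#' is applied after delta selection and does not influence it.
#'
#' When no grid value meets the bound the significant set is empty and
#' `delta = Inf` is recorded (not an error). With a fixed seed the whole
#' procedure is bit-reproducible. Order-statistic ties are broken by
#' feature-id lexicographic order.
#'
#' @param res A [SamResult-class] from [samStatistic()].
#' @inheritParams samStatistic
#' @param params A list from [samParams()]; `params$s0` must equal the s0
#'   used for `res` (it is taken from `res` if `NULL`).
#' @return `res` with `dbar`, `delta`, `fdrEst`, `significant` and
#'   `direction` filled; `params` gains `nPermUsed` and `exhaustive`.
#' @export
permutationFdr <- function(res, m, design, groupA, groupB, params) {
  s0 <- params$s0 %||% res@params$s0
  sA <- res@params$samplesA
  sB <- res@params$samplesB
  pool <- c(sA, sB)
  poolIdx <- match(pool, colnames(m))
  nA <- length(sA); nB <- length(sB)
  nAll <- choose(nA + nB, nB)

  # permutation assignments (columns = which pooled indices play role B)
  if (nAll <= params$nPerm) {
    assignB <- allAssignments(nA, nB)
    exhaustive <- TRUE
  } else {
    rs <- .Random.seed.save()
    on.exit(.Random.seed.restore(rs), add = TRUE)
    set.seed(params$seed)
    assignB <- vapply(seq_len(params$nPerm),
                      function(i) sort(sample(nA + nB, nB)),
                      integer(nB))
    exhaustive <- FALSE
  }
  nPermUsed <- ncol(assignB)

  nFeat <- nrow(m)
  # observed sorted d, ties by feature id for reproducibility
  ord <- order(res@d, res@featureIds)
  dSort <- res@d[ord]

  mp <- m[, poolIdx, drop = FALSE]
  permSorted <- matrix(NA_real_, nFeat, nPermUsed)
  for (p in seq_len(nPermUsed)) {
    ib <- assignB[, p]
    ia <- setdiff(seq_len(nA + nB), ib)
    permSorted[, p] <- sort(samKernel(mp, ia, ib, s0)$d)
  }
  dbar <- rowMeans(permSorted)
  exceed <- dSort - dbar

  # delta grid: 0 plus the unique observed |exceedances|
  grid <- sort(unique(c(0, abs(exceed))))

  # cutpoints per grid delta via prefix extrema in exceedance order
  ordUp <- order(exceed, decreasing = TRUE)   # largest exceedance first
  ordLo <- order(exceed)                      # most negative first
  prefMinUp <- cummin(dSort[ordUp])           # min d among top-m exceeders
  prefMaxLo <- cummax(dSort[ordLo])           # max d among bottom-m exceeders
  exceedAscSorted <- exceed[ordLo]
  # counts called at each delta (strict exceedance on both sides)
  nUp <- nFeat - findInterval(grid, exceedAscSorted)
  nLo <- findInterval(-grid, exceedAscSorted, left.open = TRUE)
  cutup <- ifelse(nUp > 0L, prefMinUp[pmax(nUp, 1L)], Inf)
  cutlow <- ifelse(nLo > 0L, prefMaxLo[pmax(nLo, 1L)], -Inf)

  # false-call counts per permutation at each grid delta
  falseMat <- matrix(0, length(grid), nPermUsed)
  for (p in seq_len(nPermUsed)) {
    v <- permSorted[, p]
    up <- nFeat - findInterval(cutup, v, left.open = TRUE)  # v >= cutup
    lo <- findInterval(cutlow, v)                           # v <= cutlow
    up[!is.finite(cutup)] <- 0L
    lo[!is.finite(cutlow)] <- 0L
    falseMat[, p] <- up + lo
  }
  medFalse <- apply(falseMat, 1L, stats::median)
  nCalled <- nUp + nLo
  fdr <- ifelse(nCalled > 0L, params$pi0 * medFalse / nCalled, 0)

  okIdx <- which(fdr <= params$fdrMax)
  if (length(okIdx)) {
    sel <- okIdx[1L]
    delta <- grid[sel]
    fdrEst <- fdr[sel]
    calledSorted <- exceed > delta | exceed < -delta
  } else {
    delta <- Inf
    fdrEst <- NA_real_
    calledSorted <- rep(FALSE, nFeat)
  }

  called <- logical(nFeat)
  called[ord] <- calledSorted
  fcPass <- res@fc >= params$fcCutoff | res@fc <= 1 / params$fcCutoff
  significant <- called & fcPass
  direction <- ifelse(!significant, "none",
                      ifelse(res@meanB > res@meanA, "up", "down"))

  res@dbar <- dbar
  res@delta <- delta
  res@fdrEst <- fdrEst
  res@significant <- significant
  res@direction <- direction
  res@params <- utils::modifyList(res@params, list(
    s0 = s0, nPerm = params$nPerm, nPermUsed = nPermUsed,
    exhaustive = exhaustive, seed = params$seed, fdrMax = params$fdrMax,
    fcCutoff = params$fcCutoff, pi0 = params$pi0))
  validObject(res)
  res
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed.restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}

#' Run one SAM comparison end to end
#'
#' Convenience wrapper: tunes s0 when `params$s0` is `NULL`, computes the
#' statistics and runs the permutation FDR step.
#'
#' @inheritParams samStatistic
#' @param params A list from [samParams()].
#' @return A completed [SamResult-class].
#' @export
samCompare <- function(m, design, groupA, groupB, params = samParams()) {
  s0 <- params$s0 %||% tuneS0(m, design, groupA, groupB)
  res <- samStatistic(m, design, groupA, groupB, s0 = s0)
  params$s0 <- s0
  permutationFdr(res, m, design, groupA, groupB, params)
}

#' Union of significant features across pairwise comparisons
#'
#' Runs one SAM comparison per listed group pair and pools the
#' significant feature sets — the four-way screen whose union feeds the
#' gene-pattern clustering. Per-feature provenance records which
#' comparisons each feature passed and in which direction.
#'
#' @inheritParams samStatistic
#' @param groupPairs List of 2-element character vectors
#'   `c(groupA, groupB)`.
#' @param params A list from [samParams()].
#' @return List with `union` (character vector, input feature order),
#'   `results` (named list of [SamResult-class]), and `provenance`
#'   (data.frame: feature_id, comparison, direction).
#' @export
pairwiseUnion <- function(m, design, groupPairs, params = samParams()) {
  if (length(groupPairs) == 0L) stopf("no group pairs supplied")
  keys <- vapply(groupPairs, function(p) paste(p[1L], p[2L], sep = "_vs_"), "")
  results <- list()
  prov <- list()
  for (i in seq_along(groupPairs)) {
    key <- keys[i]
    if (!is.null(results[[key]])) next  # duplicated pair: run once
    p <- groupPairs[[i]]
    r <- samCompare(m, design, p[1L], p[2L], params)
    results[[key]] <- r
    sig <- which(r@significant)
    if (length(sig))
      prov[[key]] <- data.frame(feature_id = r@featureIds[sig],
                                comparison = key,
                                direction = r@direction[sig],
                                stringsAsFactors = FALSE)
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(feature_id = character(), comparison = character(),
               direction = character(), stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  unionIds <- rownames(m)[rownames(m) %in% unique(prov$feature_id)]
  list(union = unionIds, results = results, provenance = prov)
}
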