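#' @include AllClasses.R utils.R
NULL

#' 1 - Pearson correlation distance between profiles
#'
#' @param profiles Numeric matrix, one profile per row, >= 2 columns.
#'   Every profile must have nonzero variance (constant profiles must be
#'   filtered or flagged upstream).
#' @return Symmetric distance matrix in `[0, 2]` with zero diagonal,
#'   dimnames taken from the profile rownames.
#' @export
correlationDistance <- function(profiles) {
  if (!is.matrix(profiles) || ncol(profiles) < 2L)
    stopf("profiles must be a matrix with >= 2 coordinates")
  sds <- rowSdPop(profiles)
  if (any(sds == 0)) {
    bad <- if (is.null(rownames(profiles))) which(sds == 0)[1L] else
      rownames(profiles)[sds == 0][1L]
    stopf("constant profile '%s' has no defined correlation", bad)
  }
  D <- 1 - stats::cor(t(profiles))
  D[D < 0] <- 0   # guard tiny negative rounding of perfectly correlated rows
  diag(D) <- 0
  D
}

#' Average-linkage agglomerative clustering
#'
#' At each step the pair of clusters with the smallest average
#' inter-cluster distance (mean over all cross-cluster point pairs) is
#' merged, using the Lance-Williams update. Ties are broken toward the
#' lexicographically smallest pair of cluster ids, where leaves carry ids
#' 1..n (input order) and the cluster created at step t carries id n+t —
#' a fixed rule so runs are reproducible even on degenerate distance
#' matrices. Under average linkage with a true distance input the merge
#' heights are monotone non-decreasing.
#'
#' @param D Symmetric numeric distance matrix with zero diagonal
#'   (dimnames used as leaf labels).
#' @return A [LinkageTree-class].
#' @export
averageLinkage <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stopf("D must be a square matrix")
  n <- nrow(D)
  if (n < 2L) stopf("need at least 2 items to cluster")
  if (max(abs(D - t(D))) > 1e-8) stopf("D must be symmetric")
  labels <- rownames(D) %||% as.character(seq_len(n))

  # cluster bookkeeping; ids: leaves 1..n, merge at step t gets id n+t.
  # inter-cluster distances are recomputed from the raw D as block means,
  # never incrementally, so heights do not accumulate rounding drift.
  members <- as.list(seq_len(n))
  ids <- seq_len(n)
  stepOf <- integer(2L * n)
  stepOf[seq_len(n)] <- -seq_len(n)

  cur <- D
  diag(cur) <- Inf

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (t in seq_len(n - 1L)) {
    k <- nrow(cur)
    m <- min(cur)
    hit <- which(cur == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    # tie-break: lexicographically smallest (id_i, id_j) pair
    p1 <- pmin(ids[hit[, 1L]], ids[hit[, 2L]])
    p2 <- pmax(ids[hit[, 1L]], ids[hit[, 2L]])
    pick <- order(p1, p2)[1L]
    a <- hit[pick, 1L]; b <- hit[pick, 2L]

    merge[t, ] <- orderMergeCodes(stepOf[ids[a]], stepOf[ids[b]])
    height[t] <- m

    newMembers <- sort(c(members[[a]], members[[b]]))
    keep <- setdiff(seq_len(k), c(a, b))
    newRow <- vapply(keep, function(o) {
      mean(D[newMembers, members[[o]], drop = FALSE])
    }, 1)

    members <- c(members[keep], list(newMembers))
    newId <- n + t
    stepOf[newId] <- t
    ids <- c(ids[keep], newId)
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newRow),
                 c(newRow, Inf))
    dimnames(cur) <- NULL
  }

  new("LinkageTree", merge = merge, height = height, labels = labels,
      method = "average")
}

# hclust merge-row convention: singletons before clusters, each in
# ascending (leaf index / step) order
orderMergeCodes <- function(ci, cj) {
  key <- function(c) if (c < 0L) c(0L, -c) else c(1L, c)
  ki <- key(ci); kj <- key(cj)
  if (ki[1L] < kj[1L] || (ki[1L] == kj[1L] && ki[2L] <= kj[2L]))
    c(ci, cj) else c(cj, ci)
}

#' Cut a linkage tree into k flat clusters
#'
#' Undoes the last `k - 1` merges. Cluster labels are 1..k in order of
#' first leaf appearance (leaf input order).
#'
#' @param tree A [LinkageTree-class].
#' @param k Number of clusters, `1 <= k <=` leaf count.
#' @return Named integer vector of cluster ids, one per leaf.
#' @export
cutTree <- function(tree, k) {
  n <- length(tree@labels)
  if (k < 1L || k > n) stopf("k = %d out of range [1, %d]", k, n)
  if (n == 1L) return(stats::setNames(1L, tree@labels))
  raw <- stats::cutree(as.hclust(tree), k = k)
  out <- match(raw, unique(raw))   # relabel by first appearance
  stats::setNames(as.integer(out), tree@labels)
}

#' Mean Silhouette index of a flat clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance
#' of item i to its own cluster and `b(i)` the smallest mean distance to
#' another cluster. Items in singleton clusters score 0 by convention.
#'
#' @param assign Integer cluster assignment (k >= 2).
#' @param D Distance matrix.
#' @return Mean silhouette width, in `[-1, 1]`.
#' @export
silhouetteIndex <- function(assign, D) {
  ks <- unique(assign)
  if (length(ks) < 2L) stopf("silhouette requires k >= 2")
  n <- length(assign)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, assign[i]), function(kk) {
      mean(D[i, assign == kk])
    }, 1))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Pair-count-weighted inter/intra cluster distance ratio
#'
#' Mean distance over all between-cluster point pairs divided by the mean
#' distance over all within-cluster point pairs ("weighted" = each pair
#' counts once, so larger clusters weigh proportionally).
#'
#' @param assign Integer cluster assignment.
#' @param D Distance matrix.
#' @return The ratio (positive scalar; > 1 for separated clusters,
#'   about 1 for arbitrary labels).
#' @export
interIntraRatio <- function(assign, D) {
  n <- length(assign)
  if (length(unique(assign)) < 2L)
    stopf("ratio requires k >= 2 (no inter-cluster pairs)")
  same <- outer(assign, assign, `==`)
  ut <- upper.tri(D)
  intra <- D[ut & same]
  inter <- D[ut & !same]
  if (!length(intra))
    stopf("all clusters are singletons: no intra-cluster pairs")
  mean(inter) / mean(intra)
}

#' Homogeneity, separation and their difference
#'
#' Homogeneity is the mean Pearson correlation of each item with its
#' cluster centroid; separation is the size-pair-weighted mean
#' correlation between cluster centroids; the combined score is
#' `H - S` (large when clusters are internally coherent and mutually
#' dissimilar). Items or centroids with zero variance contribute
#' correlation 0 and are flagged with a warning.
#'
#' @param assign Integer cluster assignment (k >= 2).
#' @param profiles Numeric matrix of (standardized) profiles, rows =
#'   items.
#' @return Named list: `homogeneity`, `separation`, `combined`.
#' @export
homogeneitySeparation <- function(assign, profiles) {
  ks <- sort(unique(assign))
  if (length(ks) < 2L) stopf("homogeneity/separation requires k >= 2")
  safeCor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  centroids <- t(vapply(ks, function(kk) {
    colMeans(profiles[assign == kk, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rs <- vapply(seq_len(nrow(profiles)), function(i) {
    safeCor(profiles[i, ], centroids[match(assign[i], ks), ])
  }, 1)
  if (anyNA(rs)) {
    warnf("%d item(s) with degenerate correlation contribute 0 to homogeneity",
          sum(is.na(rs)))
    rs[is.na(rs)] <- 0
  }
  H <- mean(rs)
  sizes <- as.integer(table(factor(assign, levels = ks)))
  num <- 0; den <- 0
  for (i in seq_along(ks)[-length(ks)]) {
    for (j in seq((i + 1L), length(ks))) {
      r <- safeCor(centroids[i, ], centroids[j, ])
      if (is.na(r)) { warnf("degenerate centroid pair contributes 0"); r <- 0 }
      w <- sizes[i] * sizes[j]
      num <- num + w * r
      den <- den + w
    }
  }
  S <- num / den
  list(homogeneity = H, separation = S, combined = H - S)
}

# nomination rules per index, given the per-k quality table
nominateK <- function(quality) {
  kv <- quality$k
  silK <- kv[which.max(quality$silhouette)]
  hsK <- kv[which.max(quality$combined_hs)]
  if (length(kv) >= 3L) {
    # knee of the (monotone-ish) ratio curve: the interior k where the
    # marginal gain collapses, i.e. the largest drop between the gain
    # entering k and the gain leaving it (maximum discrete concavity)
    r <- quality$inter_intra_ratio
    gainDrop <- (r[-c(1L, length(r))] - r[-c(length(r) - 1L, length(r))]) -
      (r[-c(1L, 2L)] - r[-c(1L, length(r))])
    ratioK <- kv[-c(1L, length(kv))][which.max(gainDrop)]
  } else {
    ratioK <- kv[which.max(quality$inter_intra_ratio)]
  }
  c(silhouette = silK, combined_hs = hsK, inter_intra = ratioK)
}

consensusRule <- function(noms) {
  tab <- table(noms)
  if (max(tab) >= 2L) return(as.integer(names(tab)[which.max(tab)]))
  # all three differ: the median nomination (silhouette nominee wins any
  # residual ambiguity, which cannot arise with three distinct integers)
  as.integer(sort(noms)[2L])
}

#' Consensus cluster-number estimate over three quality indices
#'
#' Clusters the profiles once (1-Pearson distance, average linkage), cuts
#' the tree at every k in `kRange`, and computes the Silhouette index,
#' the homogeneity-separation score and the weighted inter/intra ratio at
#' each k. Each index nominates a k (Silhouette and
#' homogeneity-separation: argmax; inter/intra ratio: the knee of its
#' curve, where the marginal gain in the ratio collapses). The consensus
#' is the majority nomination, or the median when all three differ.
#'
#' @param profiles Numeric matrix, one (standardized) profile per row.
#' @param kRange Integer candidate cluster numbers, within `[2, n - 1]`.
#' @return A [ConsensusClustering-class].
#' @export
consensusClusterCount <- function(profiles, kRange = 2:15) {
  if (length(kRange) == 0L) stopf("kRange is empty")
  n <- nrow(profiles)
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 2L || max(kRange) > n - 1L)
    stopf("kRange must lie within [2, %d]", n - 1L)
  D <- correlationDistance(profiles)
  tree <- averageLinkage(D)
  rows <- lapply(kRange, function(k) {
    assign <- cutTree(tree, k)
    hs <- homogeneitySeparation(assign, profiles)
    data.frame(k = k,
               silhouette = silhouetteIndex(assign, D),
               inter_intra_ratio = interIntraRatio(assign, D),
               homogeneity = hs$homogeneity,
               separation = hs$separation,
               combined_hs = hs$combined)
  })
  quality <- do.call(rbind, rows)
  noms <- nominateK(quality)
  kStar <- consensusRule(noms)
  new("ConsensusClustering",
      kStar = kStar, quality = quality, nominations = noms,
      tree = tree, assignment = cutTree(tree, kStar))
}
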