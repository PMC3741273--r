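# Independent oracles and small fixture builders shared across tests.

# Brute-force O(n^3) average linkage: explicit member lists, inter-cluster
# distances recomputed from the raw matrix at every step (block mean with
# the younger cluster's members as rows), ties broken toward the smallest
# (id_i, id_j) pair where leaves are 1..n and the merge at step t is n+t.
bruteAverageLinkage <- function(D) {
  # hclust merge-row convention: singletons first, ascending within kind
  orderCodes <- function(ci, cj) {
    key <- function(c) if (c < 0L) c(0L, -c) else c(1L, c)
    ki <- key(ci); kj <- key(cj)
    if (ki[1L] < kj[1L] || (ki[1L] == kj[1L] && ki[2L] <= kj[2L]))
      c(ci, cj) else c(cj, ci)
  }
  n <- nrow(D)
  members <- as.list(seq_len(n))
  ids <- seq_len(n)
  born <- rep(0L, n)                 # creation step per active cluster
  stepOf <- integer(2L * n)
  stepOf[seq_len(n)] <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (t in seq_len(n - 1L)) {
    k <- length(members)
    bestD <- Inf; bestPair <- c(Inf, Inf); bi <- bj <- NA_integer_
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        # younger cluster's members as the block rows
        if (born[i] >= born[j])
          dij <- mean(D[members[[i]], members[[j]], drop = FALSE])
        else
          dij <- mean(D[members[[j]], members[[i]], drop = FALSE])
        pair <- sort(c(ids[i], ids[j]))
        better <- dij < bestD ||
          (dij == bestD && (pair[1L] < bestPair[1L] ||
             (pair[1L] == bestPair[1L] && pair[2L] < bestPair[2L])))
        if (better) { bestD <- dij; bestPair <- pair; bi <- i; bj <- j }
      }
    }
    merge[t, ] <- orderCodes(stepOf[ids[bi]], stepOf[ids[bj]])
    height[t] <- bestD
    newMembers <- sort(c(members[[bi]], members[[bj]]))
    keep <- setdiff(seq_len(k), c(bi, bj))
    members <- c(members[keep], list(newMembers))
    ids <- c(ids[keep], n + t)
    born <- c(born[keep], t)
    stepOf[n + t] <- t
  }
  list(merge = merge, height = height)
}

# Literal silhouette implementation from the definition.
bruteSilhouette <- function(assign, D) {
  n <- length(assign)
  s <- numeric(n)
  for (i in seq_len(n)) {
    mine <- assign[i]
    sameIdx <- which(assign == mine & seq_len(n) != i)
    if (length(sameIdx) == 0L) { s[i] <- 0; next }
    a <- sum(D[i, sameIdx]) / length(sameIdx)
    b <- Inf
    for (other in setdiff(unique(assign), mine)) {
      idx <- which(assign == other)
      b <- min(b, sum(D[i, idx]) / length(idx))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

randomDistanceMatrix <- function(n, dim = 3L) {
  pts <- matrix(rnorm(n * dim), n)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("it", seq_len(n)), paste0("it", seq_len(n)))
  D
}

# small labelled expression fixture: groups A/B with 3 replicates each
makeTwoGroupFixture <- function(nFeat = 20, seed = 1, shift = 0,
                                shiftFeatures = integer(0), sd = 0.25,
                                baseline = 8) {
  set.seed(seed)
  m <- matrix(rnorm(nFeat * 6, baseline, sd), nFeat, 6,
              dimnames = list(sprintf("f%03d", seq_len(nFeat)),
                              paste0("s", 1:6)))
  m[shiftFeatures, 4:6] <- m[shiftFeatures, 4:6] + shift
  design <- data.frame(sample_id = paste0("s", 1:6), species = "mouse",
                       group = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  list(m = m, design = design)
}
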