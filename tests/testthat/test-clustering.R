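test_that("correlation distance matches direct Pearson computation", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(3, 2, 1))
  D <- correlationDistance(x)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "c"], 2)                      # perfect anticorrelation
  # r = 3 / (sqrt(2) * sqrt(14/3)) = 0.9819805
  expect_equal(D["a", "b"], 1 - 0.9819805, tolerance = 1e-5)
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 2))
  expect_error(correlationDistance(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant profile 'a'")
})

test_that("average linkage matches the brute-force oracle exactly", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    D <- randomDistanceMatrix(n)
    tree <- averageLinkage(D)
    oracle <- bruteAverageLinkage(D)
    expect_identical(tree@merge, oracle$merge)
    expect_equal(tree@height, oracle$height, tolerance = 0)
    # heights are monotone under average linkage on a metric input
    expect_true(all(diff(tree@height) >= -1e-12))
    # and agree with the reference implementation on tie-free instances
    h <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(sort(tree@height), sort(h$height), tolerance = 1e-12)
  }
})

test_that("degenerate and tied distance matrices merge deterministically", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  dimnames(D) <- list(paste0("L", 1:4), paste0("L", 1:4))
  tree <- averageLinkage(D)
  expect_equal(tree@height, rep(1, 3))
  # smallest id pair (leaves 1,2) merges first, then leaf 3 joins, then 4
  expect_identical(tree@merge[1, ], c(-1L, -2L))
  oracle <- bruteAverageLinkage(D)
  expect_identical(tree@merge, oracle$merge)

  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  t2 <- averageLinkage(D2)
  expect_equal(t2@height, 0.4)
  expect_error(averageLinkage(matrix(0, 1, 1)), "at least 2")
})

test_that("tree cutting undoes the last merges with stable labels", {
  set.seed(12)
  D <- randomDistanceMatrix(8)
  tree <- averageLinkage(D)
  expect_identical(unname(cutTree(tree, 1)), rep(1L, 8))
  expect_identical(unname(cutTree(tree, 8)), 1:8)  # singletons, appearance order
  expect_error(cutTree(tree, 9), "out of range")
  expect_error(cutTree(tree, 0), "out of range")

  # two well-separated blobs are recovered at k = 2
  set.seed(13)
  pts <- rbind(matrix(rnorm(10 * 3, 0, 0.1), 10),
               matrix(rnorm(10 * 3, 5, 0.1), 10))
  D2 <- as.matrix(dist(pts))
  a <- cutTree(averageLinkage(D2), 2)
  expect_identical(unname(a), rep(c(1L, 2L), each = 10))
})

test_that("silhouette matches the hand example, the oracle and cluster::", {
  # points {0,1} and {10,11} on a line: the outer points score
  # (10.5 - 1)/10.5, the inner ones (9.5 - 1)/9.5
  pts <- c(0, 1, 10, 11)
  D <- abs(outer(pts, pts, `-`))
  assign <- c(1L, 1L, 2L, 2L)
  expect_equal(silhouetteIndex(assign, D),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)),
               tolerance = 1e-9)

  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    k <- sample(2:4, 1)
    D <- randomDistanceMatrix(n)
    assign <- sample.int(k, n, replace = TRUE)
    if (length(unique(assign)) < 2) next
    expect_equal(silhouetteIndex(assign, D), bruteSilhouette(assign, D),
                 tolerance = 1e-12)
    sil <- cluster::silhouette(assign, stats::as.dist(D))
    expect_equal(silhouetteIndex(assign, D), mean(sil[, "sil_width"]),
                 tolerance = 1e-9)
    # permutation invariance of the labels
    relab <- sample.int(k)[assign]
    expect_equal(silhouetteIndex(relab, D), silhouetteIndex(assign, D))
  }

  # two singletons: convention s = 0
  expect_equal(silhouetteIndex(c(1L, 2L), matrix(c(0, 1, 1, 0), 2)), 0)
  expect_error(silhouetteIndex(rep(1L, 4), matrix(0, 4, 4)), "k >= 2")
})

test_that("inter/intra ratio uses pair-count weighting", {
  # 4 points, clusters {1,2} {3,4}, hand distances
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 0.2
  D[3, 4] <- D[4, 3] <- 0.4
  D[1, 3] <- D[3, 1] <- 2; D[1, 4] <- D[4, 1] <- 2.2
  D[2, 3] <- D[3, 2] <- 1.8; D[2, 4] <- D[4, 2] <- 2.4
  assign <- c(1L, 1L, 2L, 2L)
  expect_equal(interIntraRatio(assign, D),
               mean(c(2, 2.2, 1.8, 2.4)) / mean(c(0.2, 0.4)))
  expect_gt(interIntraRatio(assign, D), 1)

  # random labels on i.i.d. points give a ratio near 1
  set.seed(15)
  ratios <- replicate(20, {
    D <- randomDistanceMatrix(200)
    interIntraRatio(sample.int(3, 200, replace = TRUE), D)
  })
  expect_true(all(abs(ratios - 1) < 0.1))

  expect_error(interIntraRatio(1:4, randomDistanceMatrix(4)), "singleton")
})

test_that("homogeneity and separation behave at the limits", {
  # items identical to their centroids, near-orthogonal centroids
  c1 <- c(1, -1, 1, -1, 0, 0)
  c2 <- c(1, 1, -1, -1, 1, -1)
  profiles <- rbind(c1, c1, c2, c2)
  hs <- homogeneitySeparation(c(1L, 1L, 2L, 2L), profiles)
  expect_equal(hs$homogeneity, 1)
  expect_lt(abs(hs$separation), 0.35)
  expect_gt(hs$combined, 0.65)

  # one cluster split artificially in two: separation near 1
  set.seed(16)
  blob <- matrix(rnorm(20 * 6), 20, 6) + rep(c(2, -2, 1, -1, 0, 3), each = 20)
  hs2 <- homogeneitySeparation(rep(c(1L, 2L), each = 10), blob)
  expect_gt(hs2$separation, 0.8)
  expect_lt(hs2$combined, 0.3)

  # random assignment of i.i.d. profiles: combined centered near 0
  # (centroid-correlation sampling noise bounds how tight this can be)
  # H is ~1/sqrt(cluster size) by construction, S is centroid-correlation
  # noise, so "near 0" means an order of magnitude below the coherent case
  set.seed(17)
  combined <- replicate(20, {
    p <- matrix(rnorm(200 * 100), 200, 100)
    homogeneitySeparation(sample.int(2, 200, replace = TRUE), p)$combined
  })
  expect_lt(mean(abs(combined)), 0.2)
  expect_true(all(abs(combined) < 0.4))
})

test_that("consensus nomination follows majority, median and knee rules", {
  expect_identical(crossConcord:::consensusRule(
    c(silhouette = 7L, combined_hs = 7L, inter_intra = 7L)), 7L)
  expect_identical(crossConcord:::consensusRule(
    c(silhouette = 3L, combined_hs = 5L, inter_intra = 9L)), 5L)
  expect_identical(crossConcord:::consensusRule(
    c(silhouette = 4L, combined_hs = 9L, inter_intra = 4L)), 4L)

  # profiles drawn from well-separated archetypes are recovered
  set.seed(18)
  arch <- rbind(c(3, 0, 0, 0), c(0, 3, 0, 0), c(0, 0, 3, 0),
                c(0, 0, 0, 3), c(3, 3, 0, 0))
  profiles <- arch[rep(1:5, each = 12), ] + matrix(rnorm(60 * 4, 0, 0.2), 60)
  rownames(profiles) <- sprintf("g%02d", 1:60)
  cc <- consensusClusterCount(standardizeRows(profiles), 2:10)
  expect_identical(cc@kStar, 5L)
  expect_identical(length(unique(cc@assignment)), 5L)
  expect_identical(nrow(cc@quality), 9L)
  expect_error(consensusClusterCount(profiles, integer(0)), "empty")
})
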