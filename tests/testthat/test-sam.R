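test_that("the d statistic, scatter and fold change follow the formulas", {
  m <- rbind(f1 = c(1, 2, 3, 3, 4, 5),
             f2 = c(4, 4, 4, 4, 4, 4))
  colnames(m) <- paste0("s", 1:6)
  design <- data.frame(sample_id = paste0("s", 1:6), species = "mouse",
                       group = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2))
  r <- samStatistic(m, design, "A", "B", s0 = 0.1)
  expect_equal(r@s[["f1"]], sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r@d[["f1"]], 2 / (sqrt(2 / 3) + 0.1), tolerance = 1e-9)
  expect_equal(r@d[["f1"]], 2.1822, tolerance = 1e-3)
  expect_equal(r@fc[["f1"]], 4)
  # identical groups: null identity
  expect_equal(r@d[["f2"]], 0)
  expect_equal(r@fc[["f2"]], 1)

  # antisymmetry under group swap; fc maps to reciprocal
  r2 <- samStatistic(m, design, "B", "A", s0 = 0.1)
  expect_equal(r2@d, -r@d)
  expect_equal(r2@fc, 1 / r@fc)

  # scatter homogeneity: scaling deviations by c scales s by c
  mBig <- m
  mBig["f1", ] <- mean(m["f1", ]) + 3 * (m["f1", ] - mean(m["f1", ]))
  # scale deviations within each group around the group mean
  for (idx in list(1:3, 4:6))
    mBig["f1", idx] <- mean(m["f1", idx]) + 3 * (m["f1", idx] - mean(m["f1", idx]))
  r3 <- samStatistic(mBig, design, "A", "B", s0 = 0.1)
  expect_equal(r3@s[["f1"]], 3 * r@s[["f1"]], tolerance = 1e-9)

  expect_error(samStatistic(m, design, "A", "B", s0 = -1), "nonnegative")
  d2 <- design; d2$group <- c("A", "B", "B", "B", "B", "B")
  expect_error(samStatistic(m, d2, "A", "B", s0 = 0), "fewer than 2")
})

test_that("s0 tuning falls back and breaks ties toward the smallest candidate", {
  fx <- makeTwoGroupFixture(nFeat = 20, seed = 2)
  expect_equal(tuneS0(fx$m, fx$design, "A", "B"),
               median(samStatistic(fx$m, fx$design, "A", "B", 0)@s))

  # equal scatter for every feature: all candidates tie, smallest returned
  m <- matrix(8, 60, 6, dimnames = list(sprintf("f%02d", 1:60),
                                        paste0("s", 1:6)))
  m <- m + rep(c(-1, 0, 1, -1, 0, 1), each = 60)  # same within-group spread
  design <- data.frame(sample_id = paste0("s", 1:6), species = "mouse",
                       group = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2))
  s <- samStatistic(m, design, "A", "B", 0)@s
  expect_equal(diff(range(s)), 0)
  expect_equal(tuneS0(m, design, "A", "B"), min(s))

  # on a large null the tuned s0 stays within the s range
  fx2 <- makeTwoGroupFixture(nFeat = 2000, seed = 3)
  s0 <- tuneS0(fx2$m, fx2$design, "A", "B")
  sDist <- samStatistic(fx2$m, fx2$design, "A", "B", 0)@s
  expect_gte(s0, 0)
  expect_lte(s0, quantile(sDist, 0.95) + 1e-12)
})

test_that("permutation machinery enumerates balanced splits exhaustively", {
  fx <- makeTwoGroupFixture(nFeat = 60, seed = 4)
  params <- samParams(s0 = 0.1, nPerm = 100, seed = 1)
  r <- samStatistic(fx$m, fx$design, "A", "B", 0.1)
  out <- permutationFdr(r, fx$m, fx$design, "A", "B", params)
  expect_identical(out@params$nPermUsed, 20L)  # C(6,3)
  expect_true(out@params$exhaustive)
  expect_identical(length(out@dbar), 60L)

  # fixed seed reproducibility in the sampled regime
  fx2 <- makeTwoGroupFixture(nFeat = 40, seed = 5)
  design8 <- data.frame(sample_id = paste0("s", 1:6), species = "mouse",
                        group = rep(c("A", "B"), each = 3),
                        replicate = rep(1:3, 2))
  p2 <- samParams(s0 = 0.1, nPerm = 10, seed = 99)
  a <- permutationFdr(r, fx$m, fx$design, "A", "B", p2)
  b <- permutationFdr(r, fx$m, fx$design, "A", "B", p2)
  expect_identical(a@dbar, b@dbar)
  expect_identical(a@significant, b@significant)
  expect_false(a@params$exhaustive)
})

test_that("planted strong effects are called and the gate is monotone", {
  fx <- makeTwoGroupFixture(nFeat = 800, seed = 6, shift = 3,
                            shiftFeatures = 1:40)
  r3 <- samCompare(fx$m, fx$design, "A", "B",
                   samParams(nPerm = 20, seed = 1, fcCutoff = 3))
  planted <- rownames(fx$m)[1:40]
  expect_gte(mean(planted %in% significantFeatures(r3)), 0.9)

  # relaxing the fold-change gate can only enlarge the significant set
  r2 <- samCompare(fx$m, fx$design, "A", "B",
                   samParams(nPerm = 20, seed = 1, fcCutoff = 2))
  expect_true(all(significantFeatures(r3) %in% significantFeatures(r2)))
  # direction of planted up-shifts
  expect_true(all(r3@direction[match(significantFeatures(r3), r3@featureIds)]
                  %in% c("up", "down")))
  sigPlanted <- intersect(planted, significantFeatures(r3))
  expect_true(all(r3@direction[match(sigPlanted, r3@featureIds)] == "up"))
})

test_that("a pure null study yields no calls and delta = Inf is not an error", {
  fx <- makeTwoGroupFixture(nFeat = 500, seed = 7)
  r <- samCompare(fx$m, fx$design, "A", "B",
                  samParams(nPerm = 20, seed = 2, fcCutoff = 3))
  expect_identical(length(significantFeatures(r)), 0L)
})

test_that("pairwise union pools significant sets with provenance", {
  set.seed(8)
  m <- matrix(rnorm(300 * 12, 8, 0.25), 300, 12,
              dimnames = list(sprintf("f%03d", 1:300), sprintf("s%02d", 1:12)))
  design <- data.frame(
    sample_id = colnames(m), species = "mouse",
    group = rep(c("WT6", "KO6", "WT24", "KO24"), each = 3),
    replicate = rep(1:3, 4), stringsAsFactors = FALSE)
  # plant: f001-f010 KO24-specific, f011-f015 up with age in both genotypes
  ko24 <- design$sample_id[design$group == "KO24"]
  old <- design$sample_id[design$group %in% c("WT24", "KO24")]
  m[1:10, ko24] <- m[1:10, ko24] + 3
  m[11:15, old] <- m[11:15, old] + 3

  pairs <- list(c("WT6", "KO6"), c("WT24", "KO24"),
                c("WT6", "WT24"), c("KO6", "KO24"))
  params <- samParams(nPerm = 20, seed = 3, fcCutoff = 3)
  un <- pairwiseUnion(m, design, pairs, params)

  # oracle: union of individually run comparisons
  brute <- unique(unlist(lapply(pairs, function(p)
    significantFeatures(samCompare(m, design, p[1], p[2], params)))))
  expect_setequal(un$union, brute)
  expect_true(all(sprintf("f%03d", 1:10) %in% un$union))

  # KO24-specific features must not be flagged by the WT6-vs-KO6 screen
  provKo <- un$provenance[un$provenance$feature_id %in% sprintf("f%03d", 1:10), ]
  expect_false(any(provKo$comparison == "WT6_vs_KO6"))

  # idempotence when a pair repeats
  un2 <- pairwiseUnion(m, design, c(pairs, pairs[2]), params)
  expect_setequal(un2$union, un$union)
  expect_error(pairwiseUnion(m, design, list(), params), "no group pairs")
})
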