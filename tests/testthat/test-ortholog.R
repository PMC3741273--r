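makeOrth <- function(...) {
  d <- data.frame(rbind(...), stringsAsFactors = FALSE)
  names(d) <- c("probe_id", "gene_symbol")
  d
}

test_that("probe collapsing applies the exclusion/average/split rules", {
  m <- matrix(c(6, 4, 6, 9), 4, 2,
              dimnames = list(c("p0", "p1", "p2", "p3"), c("s1", "s2")))
  m[, 2] <- c(6, 4, 6, 9)

  # 1-1 identity
  g <- mapProbesToGenes(m, makeOrth(c("p0", "G0")))
  expect_equal(unname(exprValues(g)["G0", "s1"]), 6)

  # duplicates averaged: p1 = 4, p2 = 6 both -> G
  g2 <- mapProbesToGenes(m, makeOrth(c("p1", "G"), c("p2", "G")))
  expect_equal(unname(exprValues(g2)["G", "s1"]), 5)

  # even split: p0 = 6 -> G1, G2
  g3 <- mapProbesToGenes(m, makeOrth(c("p0", "G1"), c("p0", "G2")))
  expect_equal(unname(exprValues(g3)["G1", "s1"]), 3)
  expect_equal(unname(exprValues(g3)["G2", "s1"]), 3)

  # composite: p1 = 4 -> {G}, p2 = 6 -> {G, H}
  g4 <- mapProbesToGenes(m, makeOrth(c("p1", "G"), c("p2", "G"),
                                     c("p2", "H")))
  expect_equal(unname(exprValues(g4)["G", "s1"]), mean(c(4, 3)))
  expect_equal(unname(exprValues(g4)["H", "s1"]), 3)
  # provenance records the split factors
  expect_equal(provenance(g4)$G$split_factor, c(1, 0.5))

  # unmapped probes are excluded; no shared probes errors
  expect_false("p3" %in% unlist(lapply(provenance(g4), `[[`, "probe_id")))
  expect_error(mapProbesToGenes(m, makeOrth(c("q9", "G"))), "no mappable")
})

test_that("collapsing is order-invariant and conserves contribution mass", {
  set.seed(20)
  for (rep in 1:5) {
    nProbe <- 50
    m <- matrix(rnorm(nProbe * 3, 8, 2), nProbe, 3,
                dimnames = list(sprintf("p%03d", 1:nProbe), c("a", "b", "c")))
    orth <- data.frame(
      probe_id = sprintf("p%03d", sample(nProbe, 120, TRUE)),
      gene_symbol = sprintf("G%02d", sample(20, 120, TRUE)),
      stringsAsFactors = FALSE)
    orth <- unique(orth)
    g <- mapProbesToGenes(m, orth)

    # row order of both inputs is irrelevant
    g2 <- mapProbesToGenes(m[sample(nProbe), , drop = FALSE],
                           orth[sample(nrow(orth)), ])
    expect_equal(exprValues(g), exprValues(g2))

    # each mapped probe's contributions sum back to its value
    prov <- provenance(g)
    contribSum <- Reduce(`+`, lapply(prov, function(pr) {
      colSums(m[pr$probe_id, , drop = FALSE] * pr$split_factor)
    }))
    mapped <- unique(orth$probe_id)
    expect_equal(contribSum, colSums(m[mapped, ]), tolerance = 1e-9)

    # a duplicated link counts once
    gDup <- mapProbesToGenes(m, rbind(orth, orth[1, ]))
    expect_equal(exprValues(gDup), exprValues(g))
  }
})

test_that("replicate split mode duplicates instead of dividing", {
  m <- matrix(c(6, 6), 1, 2, dimnames = list("p0", c("s1", "s2")))
  orth <- makeOrth(c("p0", "G1"), c("p0", "G2"))
  g <- mapProbesToGenes(m, orth, splitMode = "replicate")
  expect_equal(unname(exprValues(g)["G1", "s1"]), 6)
  expect_equal(unname(exprValues(g)["G2", "s1"]), 6)
})

test_that("integration intersects case-canonically and standardizes per species", {
  vA <- matrix(rnorm(12, 8), 3, 4,
               dimnames = list(c("Afp", "Nlk", "Wif1"), paste0("m", 1:4)))
  vB <- matrix(rnorm(8, 8), 2, 4,
               dimnames = list(c("AFP", "SP5"), paste0("h", 1:4)))
  gA <- new("GeneMatrix", values = vA,
            provenance = setNames(lapply(rownames(vA), function(g)
              data.frame(probe_id = g, split_factor = 1)), rownames(vA)))
  gB <- new("GeneMatrix", values = vB,
            provenance = setNames(lapply(rownames(vB), function(g)
              data.frame(probe_id = g, split_factor = 1)), rownames(vB)))
  ii <- intersectAndIntegrate(gA, gB)
  expect_identical(geneSymbols(ii), "AFP")
  expect_identical(ii@counts[["intersection"]], 1L)
  expect_identical(unname(speciesOfSample(ii)),
                   rep(c("mouse", "human"), each = 4))
  expect_true(all(exprValues(ii) >= -3 & exprValues(ii) <= 3))

  # identical matrices passed twice intersect fully
  ii2 <- intersectAndIntegrate(gA, gA)
  expect_identical(ii2@counts[["intersection"]], 3L)

  # per-species standardization: each species block has row mean 0
  set.seed(21)
  vA2 <- matrix(rnorm(20, 10, 3), 4, 5,
                dimnames = list(paste0("g", 1:4), paste0("m", 1:5)))
  vB2 <- matrix(rnorm(20, 2, 0.5), 4, 5,
                dimnames = list(paste0("G", 1:4), paste0("h", 1:5)))
  mk <- function(v) new("GeneMatrix", values = v,
    provenance = setNames(lapply(rownames(v), function(g)
      data.frame(probe_id = g, split_factor = 1)), rownames(v)))
  ii3 <- intersectAndIntegrate(mk(vA2), mk(vB2))
  blockM <- exprValues(ii3)[, 1:5]; blockH <- exprValues(ii3)[, 6:10]
  expect_true(all(abs(rowMeans(blockM)) < 1e-9))
  expect_true(all(abs(rowMeans(blockH)) < 1e-9))

  rownames(vB2) <- paste0("X", 1:4)
  expect_error(intersectAndIntegrate(mk(vA2), mk(vB2)),
               "empty ortholog intersection")
})
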