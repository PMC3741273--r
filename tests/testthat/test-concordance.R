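test_that("fold changes equal brute-force group-mean differences", {
  set.seed(30)
  v <- matrix(rnorm(5 * 8, 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  design <- data.frame(sample_id = colnames(v), species = "human",
                       group = rep(c("normal", "T1", "T3"), c(2, 3, 3)),
                       replicate = c(1:2, 1:3, 1:3), stringsAsFactors = FALSE)
  fc <- foldChangeBySpecies(v, design, c("T1", "T3"), "normal")
  brute <- rowMeans(v[, 3:8]) - rowMeans(v[, 1:2])
  expect_equal(fc, brute)

  # equal groups give zero; simple arithmetic case
  v2 <- v; v2[1, ] <- 8
  expect_equal(unname(foldChangeBySpecies(v2, design, "T3", "normal")[1]), 0)
  v3 <- v; v3[2, 3:8] <- 10; v3[2, 1:2] <- 8
  expect_equal(unname(foldChangeBySpecies(v3, design, c("T1", "T3"),
                                          "normal")[2]), 2)
  expect_error(foldChangeBySpecies(v, design, "T9", "normal"), "T9")
})

test_that("the printed-arithmetic case 117/151 renders as 77.48% raw / 78 displayed", {
  fcM <- rep(1, 151)
  fcH <- c(rep(1, 117), rep(-1, 34))
  rep1 <- concordanceRate(fcM, fcH)
  expect_identical(rep1@nConcordant, 117L)
  expect_identical(rep1@nTotal, 151L)
  expect_equal(100 * concordRate(rep1, "raw"), 77.48, tolerance = 1e-3)
  expect_identical(concordRate(rep1, "rounded"), 77L)
  expect_identical(concordRate(rep1, "display"), 78L)
})

test_that("concordance is a sign rule with documented edge handling", {
  # enumeration: (+,-,+) vs (+,+,+) -> 2/3
  r <- concordanceRate(c(1, -1, 1), c(0.5, 2, 3))
  expect_equal(r@rate, 2 / 3)

  # identical vectors (no zeros) are fully concordant
  set.seed(31)
  fc <- rnorm(40)
  expect_equal(concordanceRate(fc, fc)@rate, 1)

  # invariance to positive rescaling, symmetry in species
  fcB <- rnorm(40)
  r1 <- concordanceRate(fc, fcB)
  expect_equal(concordanceRate(3.7 * fc, 0.2 * fcB)@rate, r1@rate)
  expect_equal(concordanceRate(fcB, fc)@rate, r1@rate)
  # negating one species flips the rate (no zeros present)
  expect_equal(concordanceRate(fc, -fcB)@rate, 1 - r1@rate)

  # zero fold changes are flagged and counted non-concordant
  expect_warning(rz <- concordanceRate(c(0, 1), c(1, 1)), "zero fold change")
  expect_equal(rz@rate, 0.5)
  expect_error(concordanceRate(1:3, 1:4), "length")

  # magnitude mode additionally requires 2-fold in both species
  rm <- concordanceRate(c(2, 0.5), c(2, 0.4), mode = "sign_and_magnitude")
  expect_identical(rm@nConcordant, 1L)
})

test_that("planted agreement rate is recovered binomially", {
  set.seed(32)
  hits <- replicate(100, {
    n <- 151
    agree <- runif(n) < 0.78
    fcM <- rnorm(n, 0, 2); fcM[fcM == 0] <- 1
    fcH <- abs(rnorm(n, 0, 2)) * sign(fcM) * ifelse(agree, 1, -1)
    abs(concordanceRate(fcM, fcH)@rate - 0.78) <= 0.07
  })
  expect_gte(mean(hits), 0.95)
})

test_that("sample co-clustering reports the human partners of mouse tumors", {
  set.seed(33)
  # planted shared signature: tumor samples (mouse KO24, human T1/T3) high
  genes <- sprintf("G%02d", 1:40)
  sig <- rnorm(40, 0, 1)
  build <- function(ids, tumor) {
    v <- vapply(seq_along(ids), function(i)
      (if (tumor[i]) sig else -sig) + rnorm(40, 0, 0.4), numeric(40))
    dimnames(v) <- list(genes, ids)
    v
  }
  mouseIds <- sprintf("m%02d", 1:12)
  humanIds <- sprintf("h%02d", 1:12)
  design <- data.frame(
    sample_id = c(mouseIds, humanIds),
    species = rep(c("mouse", "human"), each = 12),
    group = c(rep(c("WT6", "KO6", "WT24", "KO24"), each = 3),
              rep(c("normal", "T1", "T3"), c(2, 4, 6))),
    replicate = c(rep(1:3, 4), 1:2, 1:4, 1:6), stringsAsFactors = FALSE)
  tumor <- design$group %in% c("KO24", "T1", "T3")
  values <- cbind(build(mouseIds, tumor[1:12]), build(humanIds, tumor[13:24]))
  ii <- new("IntegratedSet", values = values,
            speciesOfSample = setNames(design$species, design$sample_id),
            counts = c(genesA = 40L, genesB = 40L, intersection = 40L))
  cc <- crossSpeciesSampleClusters(ii, design, k = 2, tumorGroup = "KO24")
  expect_identical(nrow(cc$coClustering), 3L)
  for (i in 1:3) {
    partners <- strsplit(cc$coClustering$partner_groups[i], ",")[[1]]
    expect_true("T3" %in% partners)
  }
  # identical profiles merge first
  v2 <- values; v2[, 2] <- v2[, 1]
  ii2 <- new("IntegratedSet", values = v2,
             speciesOfSample = ii@speciesOfSample, counts = ii@counts)
  tr <- averageLinkage(correlationDistance(t(v2)))
  expect_identical(sort(tr@merge[1, ]), c(-2L, -1L))
  # k = n gives singletons and no partners
  ccAll <- crossSpeciesSampleClusters(ii, design, k = 24)
  expect_true(all(ccAll$coClustering$partner_samples == ""))
})
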