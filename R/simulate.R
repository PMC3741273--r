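#' @include utils.R
NULL

# Seeded generators that emulate the structure of the dual-species study:
# a four-group mouse design (WT/KO x 6/24 months, 3 replicates), a human
# cohort of 2 normal + 4 early-tumor (T1) + 6 advanced-tumor (T3) samples,
# two probe-id namespaces linked to shared ortholog gene symbols by
# many-to-many tables, and a Wnt-panel qPCR plate. Every generator records
# a truth ledger; recovery tests read planted truth only from the ledger.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generators emulate: Gaussian
#' log2-intensity noise of sd 0.25 around per-gene baselines N(8, 2^2)
#' (microarray convention), planted tumor effects spanning roughly 3- to
#' 21-fold (`log2fcRange = c(1.6, 4.4)`), a cross-species
#' direction-agreement probability of 0.78, and the two cohort layouts
#' described above.
#'
#' @param seed Global integer seed; per-stream child seeds are derived
#'   with [childSeed()].
#' @param nProbesMouse,nProbesHuman Probes per platform.
#' @param nSharedGenes Ortholog gene symbols shared by the platforms.
#' @param fracMultiMap Probability that a gene gets a second probe, and
#'   that a probe links to a second gene (the many-to-many wiring rate).
#' @param baselineMean,baselineSd Per-gene baseline distribution (log2).
#' @param noiseSd Replicate noise sd (log2).
#' @param nDe Number of planted differentially expressed genes.
#' @param log2fcRange Planted |log2 fold change| interval.
#' @param concordanceFrac Probability a planted gene's tumor direction
#'   agrees across species.
#' @param mouseDesign,humanDesign Named integer vectors of group sizes.
#' @param nArchetypes Number of planted group-mean patterns for the
#'   four-group generator (2..8).
#' @param t1Attenuation Effect-size multiplier for human early-stage (T1)
#'   tumors relative to T3.
#' @param qpcrPanelSize Number of panel genes on the simulated qPCR plate.
#' @param qpcrNoiseSd Ct noise sd (cycles).
#' @param ctCeiling Undetermined-well Ct encoding.
#' @return Validated named list of class `"SimConfig"`.
#' @export
simConfig <- function(seed = 1L,
                      nProbesMouse = 2500L, nProbesHuman = 2500L,
                      nSharedGenes = 2000L, fracMultiMap = 0.15,
                      baselineMean = 8, baselineSd = 2, noiseSd = 0.25,
                      nDe = 155L, log2fcRange = c(1.6, 4.4),
                      concordanceFrac = 0.78,
                      mouseDesign = c(WT6 = 3L, KO6 = 3L, WT24 = 3L, KO24 = 3L),
                      humanDesign = c(normal = 2L, T1 = 4L, T3 = 6L),
                      nArchetypes = 5L, t1Attenuation = 0.6,
                      qpcrPanelSize = 84L, qpcrNoiseSd = 0.2,
                      ctCeiling = 40) {
  cfg <- list(seed = as.integer(seed), nProbesMouse = as.integer(nProbesMouse),
              nProbesHuman = as.integer(nProbesHuman),
              nSharedGenes = as.integer(nSharedGenes),
              fracMultiMap = fracMultiMap, baselineMean = baselineMean,
              baselineSd = baselineSd, noiseSd = noiseSd,
              nDe = as.integer(nDe), log2fcRange = log2fcRange,
              concordanceFrac = concordanceFrac,
              mouseDesign = mouseDesign, humanDesign = humanDesign,
              nArchetypes = as.integer(nArchetypes),
              t1Attenuation = t1Attenuation,
              qpcrPanelSize = as.integer(qpcrPanelSize),
              qpcrNoiseSd = qpcrNoiseSd, ctCeiling = ctCeiling)
  with(cfg, {
    if (any(c(nProbesMouse, nProbesHuman, nSharedGenes) < 1L))
      stopf("counts must be positive")
    if (fracMultiMap < 0 || fracMultiMap > 1 ||
        concordanceFrac < 0 || concordanceFrac > 1)
      stopf("probabilities must lie in [0, 1]")
    if (nDe > nSharedGenes) stopf("nDe exceeds nSharedGenes")
    if (any(log2fcRange <= 0) || diff(log2fcRange) < 0)
      stopf("log2fcRange must be a positive interval")
    if (nArchetypes < 2L || nArchetypes > 8L)
      stopf("nArchetypes must lie in [2, 8]")
  })
  structure(cfg, class = "SimConfig")
}

makeDesign <- function(groupSizes, species, prefixSep = "_") {
  data.frame(
    sample_id = unlist(lapply(names(groupSizes), function(g)
      paste0(g, prefixSep, seq_len(groupSizes[[g]])))),
    species = species,
    group = rep(names(groupSizes), groupSizes),
    replicate = unlist(lapply(groupSizes, seq_len)),
    stringsAsFactors = FALSE)
}

# wire probes to genes: one probe per gene, extra probes / extra gene
# links at rate fracMultiMap, plus unlinked filler probes up to nProbes
wirePlatform <- function(nGenes, nProbes, fracMultiMap, idFmt) {
  extraGenes <- which(stats::runif(nGenes) < fracMultiMap)
  extraGenes <- utils::head(extraGenes, max(nProbes - nGenes, 0L))
  nLinked <- nGenes + length(extraGenes)
  links <- data.frame(
    probe = c(seq_len(nGenes), nGenes + seq_along(extraGenes)),
    gene = c(seq_len(nGenes), extraGenes))
  multi <- which(stats::runif(nLinked) < fracMultiMap)
  if (length(multi))
    links <- rbind(links, data.frame(
      probe = multi,
      gene = sample.int(nGenes, length(multi), replace = TRUE)))
  links <- unique(links)
  links <- links[order(links$probe, links$gene), ]
  nP <- max(nProbes, nLinked)
  list(links = links, nProbes = nP, probeIds = sprintf(idFmt, seq_len(nP)))
}

#' Simulate a dual-species microarray study
#'
#' Draws gene-level true signals (baseline plus planted tumor effects
#' whose cross-species direction agrees with probability
#' `concordanceFrac`), wires probes to genes per `fracMultiMap`, and emits
#' probe-level matrices for both platforms, the two ortholog tables, the
#' combined design, and a truth ledger recording every planted effect,
#' link and agreement flag. Mouse tumor effects apply to the KO24 group;
#' human effects apply to T1 (attenuated) and T3 samples.
#'
#' Gene symbols are styled per species (mouse title-case, human
#' upper-case) so the case-canonical intersection path is exercised.
#'
#' @param cfg A [simConfig()] list.
#' @return List with elements `mouseExpr`, `humanExpr`, `mouseOrth`,
#'   `humanOrth`, `design`, `truth`.
#' @export
simulateTwoSpecies <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  rs <- .Random.seed.save(); on.exit(.Random.seed.restore(rs))

  N <- cfg$nSharedGenes
  symCanon <- sprintf("ORTH%04d", seq_len(N))
  symMouse <- paste0("Orth", sprintf("%04d", seq_len(N)))
  symHuman <- symCanon

  # stream 1: planted truth
  set.seed(childSeed(cfg$seed, 1L))
  deIdx <- sort(sample.int(N, cfg$nDe))
  mouseSign <- integer(N); humanSign <- integer(N)
  agree <- rep(NA, N)
  mouseSign[deIdx] <- sample(c(-1L, 1L), cfg$nDe, replace = TRUE)
  agree[deIdx] <- stats::runif(cfg$nDe) < cfg$concordanceFrac
  humanSign[deIdx] <- ifelse(agree[deIdx], mouseSign[deIdx], -mouseSign[deIdx])
  mouseMag <- humanMag <- numeric(N)
  mouseMag[deIdx] <- stats::runif(cfg$nDe, cfg$log2fcRange[1L],
                                  cfg$log2fcRange[2L])
  humanMag[deIdx] <- stats::runif(cfg$nDe, cfg$log2fcRange[1L],
                                  cfg$log2fcRange[2L])

  designM <- makeDesign(cfg$mouseDesign, "mouse")
  designH <- makeDesign(cfg$humanDesign, "human")

  oneSpecies <- function(stream, nProbes, idFmt, syms, effectOf, design) {
    set.seed(childSeed(cfg$seed, stream))
    baseline <- stats::rnorm(N, cfg$baselineMean, cfg$baselineSd)
    wiring <- wirePlatform(N, nProbes, cfg$fracMultiMap, idFmt)
    nP <- wiring$nProbes
    fillerBase <- stats::rnorm(nP, cfg$baselineMean, cfg$baselineSd)
    # per-sample gene signal then probe = mean over linked genes + noise
    expr <- matrix(NA_real_, nP, nrow(design),
                   dimnames = list(wiring$probeIds, design$sample_id))
    geneSignal <- vapply(design$group, function(grp) {
      baseline + effectOf(grp)
    }, numeric(N))
    linkSplit <- split(wiring$links$gene, wiring$links$probe)
    probeMean <- matrix(fillerBase, nP, nrow(design))
    for (p in names(linkSplit)) {
      pi <- as.integer(p)
      gs <- linkSplit[[p]]
      probeMean[pi, ] <- colMeans(geneSignal[gs, , drop = FALSE])
    }
    expr[] <- probeMean + stats::rnorm(length(probeMean), 0, cfg$noiseSd)
    orth <- data.frame(probe_id = wiring$probeIds[wiring$links$probe],
                       gene_symbol = syms[wiring$links$gene],
                       stringsAsFactors = FALSE)
    list(expr = expr, orth = orth, links = wiring$links)
  }

  mouseEffect <- function(grp) {
    e <- numeric(N)
    if (grp == "KO24") e <- mouseSign * mouseMag
    e
  }
  humanEffect <- function(grp) {
    scale <- switch(grp, T3 = 1, T1 = cfg$t1Attenuation, 0)
    humanSign * humanMag * scale
  }

  mouse <- oneSpecies(2L, cfg$nProbesMouse, "m%05d_at", symMouse,
                      mouseEffect, designM)
  human <- oneSpecies(3L, cfg$nProbesHuman, "h%05d_s_at", symHuman,
                      humanEffect, designH)

  truth <- list(
    config = unclass(cfg),
    genes = data.frame(
      symbol = symCanon, mouse_symbol = symMouse, human_symbol = symHuman,
      de = seq_len(N) %in% deIdx,
      mouse_sign = mouseSign, human_sign = humanSign,
      agree = agree, mouse_log2fc = mouseSign * mouseMag,
      human_log2fc = humanSign * humanMag, stringsAsFactors = FALSE),
    mouse_links = data.frame(
      probe_id = rownames(mouse$expr)[mouse$links$probe],
      symbol = symCanon[mouse$links$gene], stringsAsFactors = FALSE),
    human_links = data.frame(
      probe_id = rownames(human$expr)[human$links$probe],
      symbol = symCanon[human$links$gene], stringsAsFactors = FALSE))

  list(mouseExpr = mouse$expr, humanExpr = human$expr,
       mouseOrth = mouse$orth, humanOrth = human$orth,
       design = rbind(designM, designH), truth = truth)
}

fourGroupArchetypes <- function() {
  list(
    KO24_up   = c(0, 0, 0, 1),
    KO24_down = c(0, 0, 0, -1),
    age_up    = c(0, 0, 1, 1),
    age_down  = c(0, 0, -1, -1),
    KO_up     = c(0, 1, 0, 1),
    KO_down   = c(0, -1, 0, -1),
    WT24_up   = c(0, 0, 1, 0),
    KO6_up    = c(0, 1, 0, 0))
}

#' Simulate a four-group mouse study with planted pattern archetypes
#'
#' Planted features draw their four group-mean profiles (WT6, KO6, WT24,
#' KO24) from `nArchetypes` distinct patterns — KO24-high, KO24-low,
#' age-up in both genotypes, and so on — scaled by a per-feature
#' amplitude from `log2fcRange` plus a small pattern jitter; non-planted
#' features are flat. This is the structure the SAM union / gene-pattern
#' clustering stage assumes, so cluster-number recovery is testable.
#'
#' @param cfg A [simConfig()] list.
#' @return List with `expr` (probes x 12 samples), `design`, `truth`
#'   (ledger with per-feature archetype and amplitude).
#' @export
simulateFourGroup <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  rs <- .Random.seed.save(); on.exit(.Random.seed.restore(rs))
  set.seed(childSeed(cfg$seed, 11L))

  design <- makeDesign(cfg$mouseDesign, "mouse")
  groups <- names(cfg$mouseDesign)
  nFeat <- cfg$nProbesMouse
  ids <- sprintf("m%05d_at", seq_len(nFeat))
  arch <- fourGroupArchetypes()[seq_len(cfg$nArchetypes)]

  deIdx <- sort(sample.int(nFeat, min(cfg$nDe, nFeat)))
  archOf <- rep(NA_character_, nFeat)
  archOf[deIdx] <- rep(names(arch), length.out = length(deIdx))
  amp <- numeric(nFeat)
  amp[deIdx] <- stats::runif(length(deIdx), cfg$log2fcRange[1L],
                             cfg$log2fcRange[2L])
  baseline <- stats::rnorm(nFeat, cfg$baselineMean, cfg$baselineSd)

  groupMean <- matrix(baseline, nFeat, length(groups),
                      dimnames = list(ids, groups))
  for (i in deIdx) {
    pat <- arch[[archOf[i]]]
    groupMean[i, ] <- baseline[i] + amp[i] * pat + stats::rnorm(4L, 0, 0.1)
  }
  expr <- groupMean[, design$group, drop = FALSE] +
    stats::rnorm(nFeat * nrow(design), 0, cfg$noiseSd)
  colnames(expr) <- design$sample_id

  truth <- list(
    config = unclass(cfg),
    features = data.frame(feature_id = ids, de = seq_len(nFeat) %in% deIdx,
                          archetype = archOf, amplitude = amp,
                          stringsAsFactors = FALSE))
  list(expr = expr, design = design, truth = truth)
}

#' Simulate a qPCR panel Ct table
#'
#' Emulates a Wnt-pathway profiler plate: `qpcrPanelSize` panel genes
#' plus the five housekeeping genes (Gusb, Hprt1, Hsp90ab1, Gapdh, Actb),
#' measured in 3 WT24 vs 3 KO24 samples. Eleven panel genes carry planted
#' effects matching the pathway readout (8 up: Lef1, Nkd1, Ccnd1, Sfrp2,
#' Fosl1, Wnt5a, Wif1, Fgf4; 3 down: Ctnnbip1, Wnt2, Sfrp1); an
#' up-regulated gene's Ct drops by log2(FC) cycles in the test group.
#' Per-sample loading offsets affect all genes of a sample equally and
#' are removed by housekeeping normalization.
#'
#' @param cfg A [simConfig()] list.
#' @param plantedFc Named numeric vector of planted linear fold changes;
#'   `NULL` for the default 11-gene pattern, or an empty vector for a
#'   null plate.
#' @return List with `ct` (genes x samples), `design`, `housekeeping`,
#'   `truth`.
#' @export
simulateQpcr <- function(cfg = simConfig(), plantedFc = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  rs <- .Random.seed.save(); on.exit(.Random.seed.restore(rs))
  set.seed(childSeed(cfg$seed, 21L))

  housekeeping <- c("Gusb", "Hprt1", "Hsp90ab1", "Gapdh", "Actb")
  up <- c("Lef1", "Nkd1", "Ccnd1", "Sfrp2", "Fosl1", "Wnt5a", "Wif1", "Fgf4")
  down <- c("Ctnnbip1", "Wnt2", "Sfrp1")
  if (is.null(plantedFc)) {
    plantedFc <- c(stats::setNames(stats::runif(length(up), 3.5, 8), up),
                   stats::setNames(1 / stats::runif(length(down), 3.5, 8),
                                   down))
  }
  nFiller <- cfg$qpcrPanelSize - length(up) - length(down)
  panel <- c(up, down, sprintf("Panel%02d", seq_len(max(nFiller, 0L))))
  genes <- c(panel, housekeeping)

  design <- makeDesign(c(WT24 = 3L, KO24 = 3L), "mouse")
  baseCt <- stats::setNames(
    c(stats::runif(length(panel), 22, 30),
      stats::runif(length(housekeeping), 18, 22)), genes)

  shift <- stats::setNames(numeric(length(genes)), genes)
  pf <- plantedFc[names(plantedFc) %in% genes]
  shift[names(pf)] <- -log2(pf)   # lower Ct = higher expression

  loading <- stats::runif(nrow(design), -0.5, 0.5)
  ct <- matrix(baseCt, length(genes), nrow(design),
               dimnames = list(genes, design$sample_id))
  isTest <- design$group == "KO24"
  ct[, isTest] <- ct[, isTest] + shift
  ct <- sweep(ct, 2L, loading, `+`) +
    stats::rnorm(length(ct), 0, cfg$qpcrNoiseSd)
  ct[ct > cfg$ctCeiling] <- cfg$ctCeiling

  truth <- list(
    config = unclass(cfg),
    genes = data.frame(
      gene_id = genes,
      planted = genes %in% names(pf),
      planted_fc = ifelse(genes %in% names(pf), pf[genes], 1),
      direction = ifelse(genes %in% names(pf),
                         ifelse(pf[genes] > 1, "up", "down"), "none"),
      housekeeping = genes %in% housekeeping,
      stringsAsFactors = FALSE))
  list(ct = ct, design = design, housekeeping = housekeeping, truth = truth)
}

#' Write a simulated dual-species study to disk
#'
#' Emits the matrices, ortholog tables and design in the pipeline's TSV
#' dialects plus the truth ledger as JSON, so a study round-trips through
#' the table readers.
#'
#' @param sim Result of [simulateTwoSpecies()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeTwoSpeciesStudy <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mouse_expr = file.path(dir, "mouse_expr.tsv"),
    human_expr = file.path(dir, "human_expr.tsv"),
    mouse_orth = file.path(dir, "mouse_orthologs.tsv"),
    human_orth = file.path(dir, "human_orthologs.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.json"))
  writeExprMatrix(sim$mouseExpr, paths[["mouse_expr"]])
  writeExprMatrix(sim$humanExpr, paths[["human_expr"]])
  writeOrthologTable(sim$mouseOrth, paths[["mouse_orth"]])
  writeOrthologTable(sim$humanOrth, paths[["human_orth"]])
  writeDesignTable(sim$design, paths[["design"]])
  writeJsonReport(sim$truth, paths[["truth"]])
  invisible(paths)
}
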