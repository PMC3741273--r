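#' @include utils.R sam.R clustering.R ortholog.R concordance.R
NULL

#' Default pipeline configuration
#'
#' Builds the nested configuration list for [runPipeline()]. Input paths
#' must point to the TSV dialects of the table readers. The two
#' fold-change regimes mirror the analysis design: a strict within-species
#' screen (`fcCutoffWithin = 3`) feeding the gene-pattern clustering, and
#' a relaxed cross-species screen (`fcCutoffCross = 2`) feeding the
#' ortholog intersection.
#'
#' @param mouseMatrix,humanMatrix,mouseOrthologs,humanOrthologs,design
#'   Input file paths (one combined design covering both species).
#' @param outDir Output directory for the report bundle.
#' @param sam List: `fcCutoffWithin`, `fcCutoffCross`, `fdrMax`, `nPerm`,
#'   `seed`.
#' @param withinPairs List of mouse group pairs for the four-way screen.
#' @param clustering List: `kRange`.
#' @param integration List: `clip`, `splitMode`, `concordanceMode`.
#' @param contrasts List: `mouseTumor`, `mouseNormal`, `humanTumor`
#'   (labels pooled for the human screen), `humanNormal`, `coClusterK`.
#' @param groupVocabulary Declared group label vocabulary.
#' @param inputScale `"log2"` (default) or `"linear"` (log2 applied on
#'   read).
#' @param normalize Quantile-normalize each matrix before analysis.
#' @return Configuration list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(mouseMatrix, humanMatrix, mouseOrthologs,
                           humanOrthologs, design, outDir,
                           sam = list(), withinPairs = NULL,
                           clustering = list(), integration = list(),
                           contrasts = list(),
                           groupVocabulary = c("WT6", "KO6", "WT24", "KO24",
                                               "normal", "T1", "T3"),
                           inputScale = "log2", normalize = TRUE) {
  samDef <- list(fcCutoffWithin = 3, fcCutoffCross = 2, fdrMax = 0.05,
                 nPerm = 200L, seed = 17L)
  intDef <- list(clip = c(-3, 3), splitMode = "divide",
                 concordanceMode = "sign")
  conDef <- list(mouseTumor = "KO24", mouseNormal = "WT24",
                 humanTumor = c("T1", "T3"), humanNormal = "normal",
                 coClusterK = 2L)
  cfg <- list(
    paths = list(mouseMatrix = mouseMatrix, humanMatrix = humanMatrix,
                 mouseOrthologs = mouseOrthologs,
                 humanOrthologs = humanOrthologs, design = design),
    outDir = outDir,
    sam = utils::modifyList(samDef, sam),
    withinPairs = withinPairs %||% list(c("WT6", "KO6"), c("WT24", "KO24"),
                                        c("WT6", "WT24"), c("KO6", "KO24")),
    clustering = utils::modifyList(list(kRange = 2:15), clustering),
    integration = utils::modifyList(intDef, integration),
    contrasts = utils::modifyList(conDef, contrasts),
    groupVocabulary = groupVocabulary,
    inputScale = inputScale, normalize = normalize)
  if (cfg$sam$fcCutoffWithin < 1 || cfg$sam$fcCutoffCross < 1)
    stopf("fold-change cutoffs must be >= 1")
  structure(cfg, class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipelineConfig()] (paths at
#'   the top level or under `paths:`).
#' @return Configuration list of class `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$paths %||% y
  pipelineConfig(
    mouseMatrix = p$mouseMatrix, humanMatrix = p$humanMatrix,
    mouseOrthologs = p$mouseOrthologs, humanOrthologs = p$humanOrthologs,
    design = p$design, outDir = y$outDir,
    sam = y$sam %||% list(),
    withinPairs = y$withinPairs,
    clustering = y$clustering %||% list(),
    integration = y$integration %||% list(),
    contrasts = y$contrasts %||% list(),
    groupVocabulary = y$groupVocabulary %||% c("WT6", "KO6", "WT24", "KO24",
                                               "normal", "T1", "T3"),
    inputScale = y$inputScale %||% "log2",
    normalize = y$normalize %||% TRUE)
}

stageLog <- function(log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(log, stats::setNames(list(msg), stage))
}

#' Run the full cross-species comparison pipeline
#'
#' Orchestrates: preprocessing (optional quantile normalization),
#' within-species SAM across the four mouse group pairs and their union,
#' consensus clustering of the union's group-mean patterns, the
#' cross-species SAM screens at the relaxed cutoff, probe-to-ortholog
#' mapping, intersection and integration, sample co-clustering, and the
#' fold-change concordance report. Artifacts are written under
#' `cfg$outDir` in subdirectories `sam/`, `clusters/`, `orthologs/`,
#' `integrated/`, `concordance/`, plus a `manifest.json` recording the
#' seeds, the stage feature counts and an md5 hash of the configuration.
#' With a fixed seed the whole bundle is byte-reproducible.
#'
#' @param cfg A `"PipelineConfig"` list (from [pipelineConfig()] or
#'   [readPipelineConfig()]), or a path to a YAML config.
#' @return Invisibly, a list with the in-memory stage results
#'   (`union`, `consensus`, `integrated`, `coClustering`, `concordance`,
#'   `manifest`).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  stopifnot(inherits(cfg, "PipelineConfig"))
  out <- cfg$outDir
  for (d in c("sam", "clusters", "orthologs", "integrated", "concordance"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  log <- list()

  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  # ---- load + preprocess ---------------------------------------------------
  design <- runStage("load", readDesignTable(cfg$paths$design,
                                             vocabulary = cfg$groupVocabulary))
  mouseM <- runStage("load", readExprMatrix(cfg$paths$mouseMatrix))
  humanM <- runStage("load", readExprMatrix(cfg$paths$humanMatrix))
  orthM <- runStage("load", readOrthologTable(cfg$paths$mouseOrthologs))
  orthH <- runStage("load", readOrthologTable(cfg$paths$humanOrthologs))
  if (identical(cfg$inputScale, "linear")) {
    mouseM <- log2Transform(mouseM)
    humanM <- log2Transform(humanM)
  }
  if (isTRUE(cfg$normalize)) {
    mouseM <- quantileNormalize(mouseM)
    humanM <- quantileNormalize(humanM)
  }
  log <- stageLog(log, "load", "mouse %d probes x %d samples, human %d x %d",
                  nrow(mouseM), ncol(mouseM), nrow(humanM), ncol(humanM))

  # ---- within-species SAM union (four-way screen) --------------------------
  paramsWithin <- samParams(nPerm = cfg$sam$nPerm, seed = cfg$sam$seed,
                            fdrMax = cfg$sam$fdrMax,
                            fcCutoff = cfg$sam$fcCutoffWithin)
  un <- runStage("sam_union",
                 pairwiseUnion(mouseM, design, cfg$withinPairs, paramsWithin))
  log <- stageLog(log, "sam_union", "union of %d features over %d comparisons",
                  length(un$union), length(un$results))
  samJson <- list(
    comparisons = lapply(un$results, function(r) list(
      group_a = r@params$groupA, group_b = r@params$groupB,
      s0 = r@params$s0, delta = r@delta,
      fdr_est = if (is.na(r@fdrEst)) NULL else min(r@fdrEst, 1),
      n_perm_used = r@params$nPermUsed,
      n_significant = length(significantFeatures(r)))),
    union = un$union,
    provenance = un$provenance)
  writeJsonReport(samJson, file.path(out, "sam", "union.json"))

  # ---- gene-pattern clustering on group means ------------------------------
  consensus <- NULL
  if (length(un$union) >= 5L) {
    gm <- groupMeans(mouseM[un$union, , drop = FALSE],
                     design[design$species == "mouse", ],
                     vocabulary = cfg$groupVocabulary)
    gmz <- standardizeRows(gm)
    keep <- setdiff(rownames(gmz), attr(gmz, "flagged_constant"))
    gmz <- gmz[keep, , drop = FALSE]
    kr <- cfg$clustering$kRange
    kr <- kr[kr >= 2 & kr <= nrow(gmz) - 1L]
    if (length(kr)) {
      consensus <- runStage("clusters", consensusClusterCount(gmz, kr))
      writeJsonReport(list(
        k_star = consensus@kStar,
        nominations = as.list(consensus@nominations),
        quality = consensus@quality,
        clusters = as.list(consensus@assignment)),
        file.path(out, "clusters", "clusters.json"))
      writeNewick(consensus@tree, file.path(out, "clusters", "genes.nwk"))
      log <- stageLog(log, "clusters", "consensus k* = %d on %d profiles",
                      consensus@kStar, nrow(gmz))
    }
  }
  if (is.null(consensus))
    log <- stageLog(log, "clusters",
                    "union too small for clustering; stage skipped")

  # ---- cross-species screens at the relaxed cutoff -------------------------
  paramsCross <- samParams(nPerm = cfg$sam$nPerm, seed = cfg$sam$seed,
                           fdrMax = cfg$sam$fdrMax,
                           fcCutoff = cfg$sam$fcCutoffCross)
  ct <- cfg$contrasts
  designH <- design[design$species == "human", ]
  designH$group[designH$group %in% ct$humanTumor] <- "TUMOR"
  samMouse <- runStage("sam_cross",
    samCompare(mouseM, design, ct$mouseNormal, ct$mouseTumor, paramsCross))
  samHuman <- runStage("sam_cross",
    samCompare(humanM, designH, ct$humanNormal, "TUMOR", paramsCross))
  sigM <- significantFeatures(samMouse)
  sigH <- significantFeatures(samHuman)
  log <- stageLog(log, "sam_cross",
                  "mouse %d and human %d significant probes at fc >= %g",
                  length(sigM), length(sigH), cfg$sam$fcCutoffCross)
  if (length(sigM) == 0L || length(sigH) == 0L)
    stopf("pipeline stage 'sam_cross' failed: no significant probes")

  # ---- ortholog mapping + integration --------------------------------------
  geneM <- runStage("orthologs",
    mapProbesToGenes(mouseM[sigM, , drop = FALSE], orthM,
                     splitMode = cfg$integration$splitMode))
  geneH <- runStage("orthologs",
    mapProbesToGenes(humanM[sigH, , drop = FALSE], orthH,
                     splitMode = cfg$integration$splitMode))
  integrated <- runStage("orthologs",
    intersectAndIntegrate(geneM, geneH, clip = cfg$integration$clip))
  log <- stageLog(log, "orthologs",
                  "mapped %d + %d genes; intersection %d",
                  integrated@counts[["genesA"]], integrated@counts[["genesB"]],
                  integrated@counts[["intersection"]])
  writeExprMatrix(exprValues(integrated),
                  file.path(out, "integrated", "integrated.tsv"))
  writeJsonReport(list(
    genes_mouse = integrated@counts[["genesA"]],
    genes_human = integrated@counts[["genesB"]],
    intersection = integrated@counts[["intersection"]],
    gene_list = geneSymbols(integrated)),
    file.path(out, "orthologs", "intersection.json"))

  # ---- sample co-clustering ------------------------------------------------
  coCl <- runStage("integrated",
    crossSpeciesSampleClusters(integrated, design, k = ct$coClusterK,
                               tumorGroup = ct$mouseTumor,
                               newickPath = file.path(out, "integrated",
                                                      "samples.nwk")))
  writeJsonReport(list(assignment = as.list(coCl$assignment),
                       co_clustering = coCl$coClustering),
                  file.path(out, "integrated", "co_clustering.json"))

  # ---- concordance ---------------------------------------------------------
  common <- geneSymbols(integrated)
  vM <- collapseCanonical(exprValues(geneM),
                          canonicalSymbol(rownames(exprValues(geneM))))
  vH <- collapseCanonical(exprValues(geneH),
                          canonicalSymbol(rownames(exprValues(geneH))))
  fcM <- foldChangeBySpecies(vM[common, , drop = FALSE], design,
                             ct$mouseTumor, ct$mouseNormal)
  fcH <- foldChangeBySpecies(vH[common, , drop = FALSE], designH,
                             "TUMOR", ct$humanNormal)
  report <- runStage("concordance", concordanceRate(
    fcM, fcH, mode = cfg$integration$concordanceMode))
  writeJsonReport(concordanceReportAsList(report),
                  file.path(out, "concordance", "report.json"))
  log <- stageLog(log, "concordance", "%d/%d concordant (%.2f%%)",
                  report@nConcordant, report@nTotal, 100 * report@rate)

  # ---- manifest ------------------------------------------------------------
  cfgPath <- file.path(out, "config.json")
  writeJsonReport(unclass(cfg), cfgPath)
  manifest <- list(
    package_version = as.character(utils::packageVersion("crossConcord")),
    seed = cfg$sam$seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    stages = log)
  writeJsonReport(manifest, file.path(out, "manifest.json"))

  invisible(list(union = un, consensus = consensus, samMouse = samMouse,
                 samHuman = samHuman, geneMouse = geneM, geneHuman = geneH,
                 integrated = integrated, coClustering = coCl,
                 concordance = report, manifest = manifest))
}
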