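.writeTSV <- function(df, dir, name) {
  write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the full rootstock-by-environment analysis on a simulated study
#'
#' End-to-end driver: simulate the study (design, weather, counts,
#' annotation), normalize (median-of-ratios size factors, expression filter,
#' dispersion trend, VST, per-gene scaling), partition per-gene variance
#' over the design and keep the upper quartile of rootstock
#' variance-explained, cluster those genes with a hexagonal SOM and test
#' clusters for rootstock, build the daily composite weather table and its
#' ePCA, run the gPCA and the gPC x ePC interaction screen with Tukey
#' post-hoc slopes, and enrich the heavy-loader and significant-cluster gene
#' sets against the simulated annotation.
#'
#' Deterministic given `seed`; when `outDir` is given every stage's result
#' is written as a plain-text table.
#'
#' @param config a [simulationConfig()]; its seed is replaced by `seed`.
#' @param seed integer seed for the entire run.
#' @param outDir optional output directory (created if needed).
#' @param somEpochs SOM training epochs (default 500).
#' @param selectQuantile variance-explained percentile for gene selection.
#' @param effectThreshold variance fraction a model term must exceed.
#' @param cumVar cumulative variance target for component selection.
#' @param loaderZ heavy-loader threshold in loading sds.
#' @param maxEvalue,enrichAlpha enrichment E-value filter and alpha.
#' @return large list with elements `sim`, `sizeFactors`, `filtered`,
#'   `trend`, `vst`, `scaled`, `partition`, `selection`, `codebook`,
#'   `clusters`, `clusterSummary`, `envTable`, `epca`, `epcComponents`,
#'   `envPerSample`, `gpca`, `gpcComponents`, `gxe`, `flagged`, `posthoc`,
#'   `loaders`, `enrichment`.
#' @export
runPipeline <- function(config = simulationConfig(), seed = config$seed,
                        outDir = NULL, somEpochs = 500L,
                        selectQuantile = 0.75, effectThreshold = 0.05,
                        cumVar = 0.80, loaderZ = 1.96, maxEvalue = 1e-10,
                        enrichAlpha = 1e-5) {
  config$seed <- as.integer(seed)
  sim <- simulateStudy(config)
  cnt <- counts(sim$experiment)
  meta <- sampleTable(sim$experiment)

  sf <- tryCatch(estimateSizeFactors(cnt),
                 error = function(e) estimateSizeFactors(cnt,
                                                         pseudoReference = TRUE))
  filtered <- filterGenes(cnt, sizeFactors = sf)
  trend <- fitDispersionTrend(filtered, sf)
  expr <- vst(filtered, sf, trend)
  scaled <- scaleGenes(expr)
  const <- attr(scaled, "constantGenes")
  if (length(const)) scaled <- scaled[setdiff(rownames(scaled), const), ]

  mains <- c("tissue", "year", "phenology", "irrigation", "rootstock")
  mains <- mains[vapply(mains, function(v) length(unique(meta[[v]])) >= 2,
                        logical(1))]
  design <- buildDesign(meta, mains = mains)
  vp <- varianceExplained(expr, design)
  sel <- selectTopPercentile(vp, "rootstock", selectQuantile)
  selGenes <- intersect(sel$genes, rownames(scaled))

  cb <- initCodebook(scaled[selGenes, , drop = FALSE], somGrid(),
                     seed = config$seed + 11L)
  cb <- trainSOM(scaled[selGenes, , drop = FALSE], cb, epochs = somEpochs,
                 seed = config$seed + 12L)
  ct <- assignBMU(scaled[selGenes, , drop = FALSE], cb)
  ct <- retainCoreGenes(ct)
  ct <- clusterRootstockTest(scaled, ct, meta)
  cs <- clusterSummary(scaled, ct, meta)

  envTable <- buildEnvTable(sim$weather, allDays = TRUE)
  epca <- pcaTable(envTable, standardize = TRUE)
  eComp <- selectComponents(epca, cumVar)
  envPS <- attachEnv(meta, envTable, pcaScores(epca), components = eComp)

  gpca <- pcaTable(t(scaled), standardize = FALSE)
  gComp <- selectComponents(gpca, cumVar)
  gxe <- fitGpcModels(pcaScores(gpca), envPS, meta, gpcComponents = gComp)
  focal <- c("epc", "epc:rootstock", "tissue:rootstock",
             "epc:tissue:rootstock")
  flagged <- screenEffects(gxe$table, effectThreshold, terms = focal)

  rxeFlags <- flagged[flagged$term == "epc:rootstock", , drop = FALSE]
  posthoc <- lapply(seq_len(nrow(rxeFlags)), function(i) {
    m <- gxe$models[[as.character(rxeFlags$gpc[i])]][[
      as.character(rxeFlags$epc[i])]]
    c(list(gpc = rxeFlags$gpc[i], epc = rxeFlags$epc[i]), posthocSlopes(m))
  })

  loaderGpcs <- sort(unique(rxeFlags$gpc))
  loaders <- lapply(loaderGpcs, function(gk) heavyLoaders(gpca, gk, loaderZ))
  names(loaders) <- paste0("gPC", loaderGpcs)

  annFiltered <- filterAnnotation(sim$annotation, maxEvalue)
  universe <- intersect(unique(annFiltered$gene), rownames(scaled))
  enr <- list()
  for (nm in names(loaders)) for (side in c("positive", "negative")) {
    q <- intersect(loaders[[nm]][[side]], universe)
    if (length(q) == 0) next
    enr[[paste0(nm, "_", side)]] <-
      correctAndFlag(hypergeomEnrich(q, annFiltered, universe),
                     alpha = enrichAlpha)
  }
  sigNodes <- ct$nodes$node[ct$nodes$significant %in% TRUE]
  for (nd in sigNodes) {
    q <- intersect(ct$genes$gene[ct$genes$node == nd & ct$genes$retained],
                   universe)
    if (length(q) == 0) next
    enr[[paste0("cluster", nd)]] <-
      correctAndFlag(hypergeomEnrich(q, annFiltered, universe),
                     alpha = enrichAlpha)
  }

  res <- list(sim = sim, sizeFactors = sf, filtered = filtered,
              trend = trend, vst = expr, scaled = scaled, partition = vp,
              selection = sel, codebook = cb, clusters = ct,
              clusterSummary = cs, envTable = envTable, epca = epca,
              epcComponents = eComp, envPerSample = envPS, gpca = gpca,
              gpcComponents = gComp, gxe = gxe, flagged = flagged,
              posthoc = posthoc, loaders = loaders, enrichment = enr)
  if (!is.null(outDir)) writePipelineOutputs(res, outDir)
  res
}

#' Write every pipeline result as a plain-text table
#'
#' @param res result list from [runPipeline()].
#' @param outDir destination directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(counts(res$sim$experiment), file.path(outDir, "counts.tsv"))
  writeSampleTable(sampleTable(res$sim$experiment),
                   file.path(outDir, "metadata.tsv"))
  writeWeather(res$sim$weather, file.path(outDir, "weather.csv"))
  .writeTSV(res$sim$annotation, outDir, "annotation.tsv")
  .writeTSV(res$sim$truth, outDir, "truth.tsv")
  .writeTSV(data.frame(sample = names(res$sizeFactors),
                       sizeFactor = res$sizeFactors), outDir,
            "size_factors.tsv")
  tc <- trendCoefficients(res$trend)
  .writeTSV(data.frame(parameter = names(tc), value = unname(tc)), outDir,
            "dispersion_trend.tsv")
  .writeTSV(data.frame(gene = rownames(res$vst), res$vst,
                       check.names = FALSE), outDir, "vst_matrix.tsv")
  .writeTSV(data.frame(gene = rownames(res$partition$fractions),
                       res$partition$fractions, check.names = FALSE),
            outDir, "variance_partition.tsv")
  writeLines(res$selection$genes, file.path(outDir, "selected_genes.txt"))
  .writeTSV(data.frame(node = seq_len(nrow(somWeights(res$codebook))),
                       somWeights(res$codebook), check.names = FALSE),
            outDir, "som_codebook.tsv")
  .writeTSV(res$clusters$genes, outDir, "som_assignments.tsv")
  .writeTSV(res$clusters$nodes, outDir, "som_cluster_tests.tsv")
  .writeTSV(res$clusterSummary, outDir, "som_cluster_summary.tsv")
  write.table(res$envTable, file.path(outDir, "env_table.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  .writeTSV(data.frame(date = rownames(pcaScores(res$epca)),
                       pcaScores(res$epca), check.names = FALSE),
            outDir, "epca_scores.tsv")
  .writeTSV(data.frame(variable = rownames(pcaLoadings(res$epca)),
                       pcaLoadings(res$epca), check.names = FALSE),
            outDir, "epca_loadings.tsv")
  .writeTSV(data.frame(sample = rownames(pcaScores(res$gpca)),
                       pcaScores(res$gpca)[, res$gpcComponents,
                                           drop = FALSE],
                       check.names = FALSE), outDir, "gpca_scores.tsv")
  .writeTSV(res$gxe$table, outDir, "gxe_model_fractions.tsv")
  .writeTSV(res$flagged, outDir, "gxe_flagged.tsv")
  ph <- do.call(rbind, lapply(res$posthoc, function(x)
    data.frame(gpc = x$gpc, epc = x$epc, x$contrasts)))
  if (is.null(ph))
    ph <- data.frame(gpc = integer(), epc = integer(), pair = character(),
                     diff = numeric(), se = numeric(), t = numeric(),
                     p.tukey = numeric(), significant = logical())
  .writeTSV(ph, outDir, "gxe_posthoc.tsv")
  for (nm in names(res$loaders)) {
    writeLines(res$loaders[[nm]]$positive,
               file.path(outDir, paste0("loaders_", nm, "_positive.txt")))
    writeLines(res$loaders[[nm]]$negative,
               file.path(outDir, paste0("loaders_", nm, "_negative.txt")))
  }
  er <- do.call(rbind, lapply(names(res$enrichment), function(nm)
    data.frame(query = nm, as.data.frame(res$enrichment[[nm]]))))
  if (is.null(er))
    er <- data.frame(query = character(), term = character(),
                     source = character(), N = integer(), K = integer(),
                     n = integer(), k = integer(), p = numeric(),
                     p.corrected = numeric(), significant = logical())
  .writeTSV(er, outDir, "enrichment.tsv")
  invisible(list.files(outDir, full.names = TRUE))
}
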