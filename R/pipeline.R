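#' Run the full phosphoproteomics pipeline on a simulated (or supplied) dataset
#'
#' Orchestrates simulate -> normalize -> site mapping -> differential ->
#' cluster -> motifs/kinase enrichment (-> annotation ORA) -> report as one
#' reproducible run. All randomness derives from `config$seed` via fixed
#' per-stage offsets, so a rerun with the same configuration yields identical
#' numeric outputs.
#'
#' @param config a [simConfig()] object (the study-design preset by default).
#' @param quantFile,layoutFile,fastaFile optional input paths; when all three
#'   are given the pipeline analyzes the supplied dataset (read with
#'   [readQuantTable()], [readChannelLayout()] and [readFasta()]) instead of
#'   simulating, and no ground truth is attached.
#' @param outDir optional output directory; when given, all stage tables, a
#'   manifest and a plain-text report are written there.
#' @param gmt optional path to a GMT file for annotation ORA.
#' @param kRange candidate cluster counts for the elbow scan.
#' @param restarts k-means restarts.
#' @param motifPThreshold,motifMinOcc motif-x settings; the defaults are the
#'   relaxed synthetic-scale settings (see [motifX()]).
#' @param profileReference reference mode for [buildProfileMatrix()].
#' @param clusterInput cluster the significant set (default) or all
#'   quantified phosphopeptides.
#' @param alpha significance threshold for the significant set.
#' @return (invisibly) a list with every stage result: `quant`, `groundTruth`,
#'   `phospho` (protein-corrected table), `proteinTable`, `siteTable`,
#'   `siteStats`, `differential`, `significant`, `profile`, `elbow`, `model`,
#'   `profiles`, `correlations`, `motifs`, `kinaseEnrichment`, `ora`.
#' @export
runPipeline <- function(config = paperSimConfig(), quantFile = NULL,
                        layoutFile = NULL, fastaFile = NULL,
                        outDir = NULL, gmt = NULL,
                        kRange = 2:10, restarts = 50L,
                        motifPThreshold = 1e-3, motifMinOcc = 5L,
                        profileReference = "vehicle",
                        clusterInput = c("significant", "all"),
                        alpha = 0.01) {
  clusterInput <- match.arg(clusterInput)
  if (!is.null(quantFile)) {
    stopIfNot(!is.null(layoutFile) && !is.null(fastaFile),
              "file input needs quantFile, layoutFile and fastaFile")
    layout <- readChannelLayout(layoutFile)
    sim <- list(quant = readQuantTable(quantFile, layout),
                proteins = readFasta(fastaFile),
                groundTruth = list(peptides = data.frame()))
  } else {
    sim <- simulateQuant(config)
  }
  raw <- sim$quant

  proteinTable <- medianNormalize(bridgeNormalize(aggregateProteinQuant(raw)))
  phospho <- normalizeToProtein(
    aggregateToPhosphopeptide(medianNormalize(bridgeNormalize(raw))),
    proteinTable)

  phospho <- filterLocalization(phospho, threshold = 50)
  siteTable <- buildSiteTable(phospho, sim$proteins, h = 6L)
  siteStats <- siteStatistics(phospho)

  differential <- differentialTest(phospho, alpha = alpha)
  sigCounts <- lapply(names(defaultComparisons()), function(cmp)
    significantSets(differential, cmp, alpha = alpha)$counts)
  names(sigCounts) <- names(defaultComparisons())
  sigIds <- significantIds(differential, alpha = alpha)

  res <- list(quant = raw, groundTruth = sim$groundTruth,
              proteins = sim$proteins, proteinTable = proteinTable,
              phospho = phospho, siteTable = siteTable,
              siteStats = siteStats, differential = differential,
              significant = list(ids = sigIds, counts = sigCounts))

  clusterIds <- if (clusterInput == "significant") sigIds
                else rownames(phospho)
  if (length(clusterIds) > max(kRange)) {
    pm <- buildProfileMatrix(phospho, clusterIds,
                             reference = profileReference)
    elbow <- elbowSelectK(pm, kRange = kRange,
                          seed = deriveSeed(config$seed, "elbow"),
                          restarts = restarts)
    model <- kmeansFit(pm, elbow$k,
                       seed = deriveSeed(config$seed, "kmeans"),
                       restarts = restarts)
    res$profile <- pm
    res$elbow <- elbow
    res$model <- model
    res$profiles <- clusterProfiles(model, pm)
    res$correlations <- list(
      DMSO_0 = spearmanReplicateMatrix(phospho, "DMSO_0"),
      SB_0 = spearmanReplicateMatrix(phospho, "SB_0"))

    clusters <- clusterAssignments(model)
    allSites <- siteTable[!siteTable$ambiguous, , drop = FALSE]
    sigSites <- allSites[allSites$peptideId %in% names(clusters), ,
                         drop = FALSE]
    res$motifs <- clusterMotifs(sigSites, clusters,
                                background = allSites,
                                pThreshold = motifPThreshold,
                                minOcc = motifMinOcc)
    assignments <- assignKinases(sigSites)
    res$kinaseEnrichment <- kinaseClusterEnrichment(assignments, clusters)

    if (!is.null(gmt)) {
      sets <- readGmt(gmt)
      bgProt <- unique(rowData(phospho)$accession)
      res$ora <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
        fg <- unique(sigSites$accession[
          clusters[sigSites$peptideId] == cl])
        if (!length(fg)) return(NULL)
        o <- annotationOra(fg, bgProt, sets)
        if (nrow(o)) cbind(cluster = cl, o) else NULL
      }))
    }
  }

  if (!is.null(outDir)) writeRun(res, outDir, config)
  invisible(res)
}

# motif-x per cluster against the all-quantified-site background,
# run separately per center residue class
clusterMotifs <- function(sigSites, clusters, background, pThreshold,
                          minOcc) {
  out <- list()
  for (cl in sort(unique(clusters))) {
    inCl <- sigSites$peptideId %in% names(clusters)[clusters == cl]
    for (res in intersect(c("S", "T", "Y"), unique(sigSites$residue))) {
      fg <- sigSites$flank[inCl & sigSites$residue == res]
      bg <- background$flank[background$residue == res]
      if (length(fg) < minOcc) next
      m <- motifX(fg, bg, pThreshold = pThreshold, minOcc = minOcc)
      if (nrow(m)) {
        m$steps <- NULL
        out[[length(out) + 1L]] <- cbind(cluster = cl, m)
      }
    }
  }
  if (!length(out))
    return(data.frame(cluster = integer(), name = character(),
                      pattern = character(), score = numeric(),
                      fgMatches = integer(), fgTotal = integer(),
                      nFixed = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# serialize a pipeline run to TSVs + manifest + report
writeRun <- function(res, outDir, config) {
  tables <- list()
  tables$site_statistics <- data.frame(
    statistic = c(paste0("residue_", names(res$siteStats$residueProportions)),
                  paste0("sites_", names(res$siteStats$sitesPerPeptide))),
    proportion = c(res$siteStats$residueProportions,
                   res$siteStats$sitesPerPeptide))
  tables$differential <- res$differential
  tables$significant_counts <- do.call(rbind, lapply(
    names(res$significant$counts), function(cmp)
      data.frame(comparison = cmp, t(res$significant$counts[[cmp]]))))
  tables$site_table <- res$siteTable
  if (!is.null(res$model)) {
    tables$cluster_assignments <- data.frame(
      peptideId = names(clusterAssignments(res$model)),
      cluster = unname(clusterAssignments(res$model)))
    tables$inertia_curve <- data.frame(k = as.integer(names(res$elbow$wss)),
                                       wss = unname(res$elbow$wss))
    tables$cluster_profiles <- res$profiles
    tables$motifs <- res$motifs
    tables$kinase_enrichment <- res$kinaseEnrichment
    for (nm in names(res$correlations)) {
      m <- res$correlations[[nm]]
      tables[[paste0("spearman_", nm)]] <-
        data.frame(channel = rownames(m), as.data.frame(m),
                   check.names = FALSE)
    }
  }
  if (!is.null(res$ora)) tables$annotation_ora <- res$ora
  if (NROW(res$groundTruth$peptides))
    tables$ground_truth <- res$groundTruth$peptides
  cfg <- config
  cfg$layout <- as.data.frame(cfg$layout)
  writeResults(tables, outDir, seed = config$seed,
               config = unclass(cfg))
  Biostrings::writeXStringSet(res$proteins,
                              file.path(outDir, "proteins.fasta"))
  writeChannelLayout(as.data.frame(channelLayout(res$quant)),
                     file.path(outDir, "layout.yaml"))
  writeQuantTable(res$quant, file.path(outDir, "quant_raw.tsv"))
  writeReport(outDir)
  invisible(outDir)
}

#' Summarize a completed run directory as a plain-text report
#'
#' Reads the tables written by [runPipeline()] and writes `report.txt`:
#' site statistics, significant counts per comparison, selected k and cluster
#' sizes, top motifs, top kinase-enrichment rows and replicate correlations.
#' Missing stages are noted rather than failing.
#'
#' @param runDir a directory written by [runPipeline()].
#' @return (invisibly) the report lines.
#' @export
writeReport <- function(runDir) {
  readTsv <- function(nm) {
    p <- file.path(runDir, paste0(nm, ".tsv"))
    if (file.exists(p))
      utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    else NULL
  }
  lines <- c("phosphoTMT run report", strrep("=", 40))
  ss <- readTsv("site_statistics")
  if (!is.null(ss)) {
    lines <- c(lines, "", "Phosphosite statistics:",
               sprintf("  %-12s %.1f%%", ss$statistic, 100 * ss$proportion))
  } else lines <- c(lines, "", "[site statistics missing]")
  sc <- readTsv("significant_counts")
  if (!is.null(sc)) {
    lines <- c(lines, "", "Significant phosphopeptides (p < 0.01):",
               sprintf("  %-24s up %d (%d proteins), down %d (%d proteins)",
                       sc$comparison, sc$peptidesUp, sc$proteinsUp,
                       sc$peptidesDown, sc$proteinsDown))
  } else lines <- c(lines, "", "[differential results missing]")
  ca <- readTsv("cluster_assignments")
  if (!is.null(ca) && nrow(ca)) {
    sizes <- table(ca$cluster)
    lines <- c(lines, "",
               sprintf("Temporal clustering: k = %d", length(sizes)),
               sprintf("  cluster %s: %d phosphopeptides",
                       names(sizes), as.integer(sizes)))
  } else lines <- c(lines, "", "[clustering not run: too few significant rows]")
  mo <- readTsv("motifs")
  if (!is.null(mo) && nrow(mo)) {
    top <- utils::head(mo[order(-mo$score), ], 5L)
    lines <- c(lines, "", "Top motifs:",
               sprintf("  cluster %s: %-8s score %.1f (%d/%d fg)",
                       top$cluster, top$name, top$score, top$fgMatches,
                       top$fgTotal))
  } else lines <- c(lines, "", "[no motifs emitted]")
  ke <- readTsv("kinase_enrichment")
  if (!is.null(ke) && nrow(ke)) {
    top <- utils::head(ke, 5L)
    lines <- c(lines, "", "Top kinase enrichment:",
               sprintf("  %-10s cluster %s: fold %.2f, p %.3g, score %.2f",
                       top$kinase, top$cluster, top$fold, top$p, top$score))
  } else lines <- c(lines, "", "[no kinase enrichment rows]")
  writeLines(lines, file.path(runDir, "report.txt"))
  invisible(lines)
}
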