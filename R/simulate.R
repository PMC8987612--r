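#' Simulation configuration for synthetic multi-plex TMT phosphoproteomics
#'
#' Builds a validated configuration for [simulateProteome()] and
#' [simulateQuant()]. Defaults reproduce the emulated study design: four
#' conditions (vehicle and p38-inhibitor arms, unstimulated 0 min and
#' thrombin-stimulated 10 min) with replicate counts (2, 2, 3, 3) spread over
#' two TMT 10-plexes, each carrying a pooled bridge channel in reporter 126;
#' an S/T/Y phosphosite mix of 84.6/13.5/1.9 percent; a 78.5/19.9/1.6 percent
#' 1/2/3-site phosphopeptide mix; five planted temporal archetypes C1-C5 over
#' a background of unregulated phosphopeptides; and kinase motifs (RRxS in C1,
#' PxSP in C2) embedded around a fraction of the archetype sites.
#'
#' Archetype condition means are log2 offsets in the order
#' (DMSO_0, DMSO_Th10, SB_0, SB_Th10):
#' C1 (0, +1.5, 0, +0.4) thrombin-induced, inhibitor-suppressed;
#' C2 (0, +0.8, 0, +1.8) thrombin-induced, inhibitor-enhanced;
#' C3 (0, -1.2, +1.2, -0.6) thrombin-reduced, raised basal under inhibitor;
#' C4 (0, -1.0, 0, -1.0) thrombin-reduced, inhibitor-independent;
#' C5 (0, -0.8, -1.5, -1.9) thrombin-reduced, lowered basal under inhibitor.
#'
#' The qualitative shapes follow the observed cluster behaviours; the
#' magnitudes are free parameters chosen so that all five shapes remain
#' mutually distinguishable after profile scaling at the default noise level.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param nProteins number of synthetic proteins.
#' @param nBackground number of unregulated background phosphopeptides.
#' @param clusterSizes named integer vector of archetype sizes (C1..C5).
#' @param archetypeMeans 5 x 4 matrix of log2 condition offsets (rows C1..C5,
#'   columns DMSO_0, DMSO_Th10, SB_0, SB_Th10).
#' @param noiseSd per-measurement log2 noise standard deviation.
#' @param batchSd per-plex log2 batch-effect standard deviation.
#' @param loadSd per-channel log2 loading-factor standard deviation.
#' @param proteinSd per-protein, per-condition log2 abundance-effect sd.
#' @param siteMix target S/T/Y proportions of phosphosite residues.
#' @param sitesPerPeptide target 1/2/3-site phosphopeptide proportions.
#' @param motifFrac named fractions of C1 sites carrying R at -3/-2 (RRxS) and
#'   of C2 sites carrying P at -2/+1 (PxSP).
#' @param psmDupFrac fraction of phosphopeptides emitted as two PSM rows.
#' @param pepPerProtein non-phospho peptides per protein for protein-level
#'   quantitation.
#' @param locConfident fraction of sites drawn with localization score above
#'   the 50 percent confidence threshold.
#' @param baseLog2,baseSd mean and sd of per-peptide log2 base abundance; the
#'   default centres raw values near 100 signal-to-noise units.
#' @param layout channel layout; defaults to [defaultChannelLayout()].
#' @return a classed list (`SimConfig`).
#' @export
simConfig <- function(seed = 1L,
                      nProteins = 300L,
                      nBackground = 4500L,
                      clusterSizes = c(C1 = 150L, C2 = 120L, C3 = 100L,
                                       C4 = 80L, C5 = 50L),
                      archetypeMeans = defaultArchetypeMeans(),
                      noiseSd = 0.25,
                      batchSd = 0.3,
                      loadSd = 0.1,
                      proteinSd = 0,
                      siteMix = c(S = 0.846, T = 0.135, Y = 0.019),
                      sitesPerPeptide = c(0.785, 0.199, 0.016),
                      motifFrac = c(C1 = 0.6, C2 = 0.6),
                      psmDupFrac = 0.1,
                      pepPerProtein = 4L,
                      locConfident = 0.9,
                      baseLog2 = log2(100),
                      baseSd = 1,
                      layout = defaultChannelLayout()) {
  cfg <- list(seed = as.integer(seed), nProteins = as.integer(nProteins),
              nBackground = as.integer(nBackground),
              clusterSizes = clusterSizes, archetypeMeans = archetypeMeans,
              noiseSd = noiseSd, batchSd = batchSd, loadSd = loadSd,
              proteinSd = proteinSd, siteMix = siteMix,
              sitesPerPeptide = sitesPerPeptide, motifFrac = motifFrac,
              psmDupFrac = psmDupFrac, pepPerProtein = as.integer(pepPerProtein),
              locConfident = locConfident, baseLog2 = baseLog2, baseSd = baseSd,
              layout = layout)
  validateSimConfig(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  chkMix <- function(x, nm) {
    stopIfNot(all(x >= 0 & x <= 1), nm, " proportions must lie in [0,1]")
    stopIfNot(abs(sum(x) - 1) < 1e-9, nm, " proportions must sum to 1")
  }
  chkMix(cfg$siteMix, "siteMix")
  chkMix(cfg$sitesPerPeptide, "sitesPerPeptide")
  stopIfNot(all(cfg$motifFrac >= 0 & cfg$motifFrac <= 1),
            "motif fractions must lie in [0,1]")
  stopIfNot(all(c(cfg$noiseSd, cfg$batchSd, cfg$loadSd, cfg$proteinSd,
                  cfg$baseSd) >= 0), "standard deviations must be >= 0")
  stopIfNot(all(cfg$clusterSizes >= 0) && cfg$nBackground >= 0,
            "sizes must be >= 0")
  stopIfNot(cfg$psmDupFrac >= 0 && cfg$psmDupFrac <= 1,
            "psmDupFrac must lie in [0,1]")
  validateChannelLayout(cfg$layout)
  conds <- setdiff(.CONDITIONS, "BRIDGE")
  stopIfNot(all(conds %in% cfg$layout$condition),
            "layout must cover the four conditions")
  stopIfNot(identical(dim(cfg$archetypeMeans), c(5L, 4L)),
            "archetypeMeans must be 5 x 4")
  stopIfNot(!is.null(colnames(cfg$archetypeMeans)) &&
              all(conds %in% colnames(cfg$archetypeMeans)),
            "archetypeMeans needs the four condition columns")
  invisible(cfg)
}

#' @rdname simConfig
#' @export
defaultArchetypeMeans <- function() {
  m <- rbind(C1 = c(0, 1.5, 0, 0.4),
             C2 = c(0, 0.8, 0, 1.8),
             C3 = c(0, -1.2, 1.2, -0.6),
             C4 = c(0, -1.0, 0, -1.0),
             C5 = c(0, -0.8, -1.5, -1.9))
  colnames(m) <- c("DMSO_0", "DMSO_Th10", "SB_0", "SB_Th10")
  m
}

#' The study-design configuration preset
#'
#' Returns [simConfig()] at its defaults: the emulated experimental design
#' (replicate counts 2/2/3/3, two plexes bridged in reporter 126, the printed
#' S/T/Y and sites-per-peptide mixes) with five planted archetypes.
#' @param seed integer seed.
#' @param ... overrides forwarded to [simConfig()].
#' @return a `SimConfig`.
#' @export
paperSimConfig <- function(seed = 1L, ...) simConfig(seed = seed, ...)

#' Default two-plex bridged channel layout
#'
#' Ten samples — DMSO_0 x2, SB_0 x2, DMSO_Th10 x3, SB_Th10 x3 — spread over
#' two TMT plexes, each with a pooled bridge in reporter 126.
#' @return a layout `DataFrame`.
#' @export
defaultChannelLayout <- function() {
  layout <- data.frame(
    plex = rep(c("1", "2"), each = 6L),
    reporter = rep(c("126", "127N", "127C", "128N", "128C", "129N"), 2L),
    condition = c("BRIDGE", "DMSO_0", "SB_0", "DMSO_Th10", "SB_Th10",
                  "DMSO_Th10",
                  "BRIDGE", "DMSO_0", "SB_0", "SB_Th10", "DMSO_Th10",
                  "SB_Th10"),
    replicate = c(NA, 1L, 1L, 1L, 1L, 2L, NA, 2L, 2L, 2L, 3L, 3L),
    isBridge = rep(c(TRUE, rep(FALSE, 5L)), 2L)
  )
  as(layout, "DataFrame")
}

#' Simulate a synthetic proteome with a phosphosite plan
#'
#' Generates random protein sequences (uniform over the 20 residues), plans
#' one background/archetype phosphopeptide window per peptide with 1-3 sites
#' drawn from the configured sites-per-peptide mix and residues from the S/T/Y
#' mix, and embeds kinase consensus motifs around a configured fraction of C1
#' (R at -3 and -2 of an S site; "RRxS") and C2 (P at -2 and +1; "PxSP")
#' primary sites by writing the motif residues into the protein sequence.
#' Localization scores are drawn so that `locConfident` of sites exceed the 50
#' percent confidence threshold. Non-phospho peptides for protein-level
#' quantitation are planned per protein.
#'
#' @param config a [simConfig()] object.
#' @return list with `proteins` ([Biostrings::AAStringSet]), `sitePlan`
#'   (data.frame, one row per phosphopeptide: id, accession, window, archetype
#'   label, motif flag and site list-columns) and `proteinPeptides`
#'   (data.frame of non-phospho peptides).
#' @export
simulateProteome <- function(config) {
  validateSimConfig(config)
  withSeed(deriveSeed(config$seed, "proteome"), {
    nPep <- config$nBackground + sum(config$clusterSizes)
    labels <- c(rep("background", config$nBackground),
                rep(names(config$clusterSizes), config$clusterSizes))
    protLen <- sample(250:450, config$nProteins, replace = TRUE)
    prot <- lapply(protLen, function(L) sample(.AA20, L, replace = TRUE))
    acc <- sprintf("SYN%04d", seq_len(config$nProteins))
    names(prot) <- acc
    usedSites <- lapply(seq_len(config$nProteins), function(i) integer())

    pepProt <- sample.int(config$nProteins, nPep, replace = TRUE)
    pepLen <- sample(12:20, nPep, replace = TRUE)
    nSites <- sample.int(3L, nPep, replace = TRUE,
                         prob = config$sitesPerPeptide)
    start <- integer(nPep)
    relList <- vector("list", nPep)
    resList <- vector("list", nPep)
    scoreList <- vector("list", nPep)
    motifFlag <- logical(nPep)

    for (i in seq_len(nPep)) {
      pr <- pepProt[i]; L <- pepLen[i]; len <- protLen[pr]
      ok <- FALSE
      for (try in 1:25) {
        st <- sample(8:(len - L - 7L), 1L)
        rel <- sort(sample(4:(L - 3L), nSites[i]))
        abs <- st + rel - 1L
        if (!any(abs %in% usedSites[[pr]])) { ok <- TRUE; break }
      }
      if (!ok) { # crowded protein: fall back to any free single site
        rel <- sample(4:(L - 3L), 1L); nSites[i] <- 1L
        st <- sample(8:(len - L - 7L), 1L)
        abs <- st + rel - 1L
      }
      start[i] <- st
      relList[[i]] <- rel
      res <- sample(names(config$siteMix), length(rel), replace = TRUE,
                    prob = config$siteMix)
      # motif embedding on the primary (first) site of C1/C2 peptides
      lab <- labels[i]
      if (lab %in% names(config$motifFrac) &&
          stats::runif(1) < config$motifFrac[[lab]]) {
        a1 <- abs[1]
        flankPos <- if (lab == "C1") c(a1 - 3L, a1 - 2L) else c(a1 - 2L, a1 + 1L)
        if (!any(flankPos %in% c(usedSites[[pr]], abs))) {
          res[1] <- "S"
          prot[[pr]][flankPos] <- if (lab == "C1") "R" else "P"
          motifFlag[i] <- TRUE
        }
      }
      prot[[pr]][abs] <- res
      usedSites[[pr]] <- c(usedSites[[pr]], abs)
      resList[[i]] <- res
      conf <- stats::runif(length(rel)) < config$locConfident
      scoreList[[i]] <- ifelse(conf, stats::runif(length(rel), 55, 100),
                               stats::runif(length(rel), 5, 50))
    }

    # non-phospho peptides for the protein-level table
    ppProt <- rep(seq_len(config$nProteins), each = config$pepPerProtein)
    ppLen <- sample(12:20, length(ppProt), replace = TRUE)
    ppStart <- vapply(seq_along(ppProt), function(i)
      sample.int(protLen[ppProt[i]] - ppLen[i] + 1L, 1L), 1L)

    seqs <- vapply(prot, paste0, "", collapse = "")
    proteins <- Biostrings::AAStringSet(seqs)
    names(proteins) <- acc
    pepSeq <- substring(seqs[pepProt], start, start + pepLen - 1L)
    sitePlan <- data.frame(
      peptideId = sprintf("pep%05d", seq_len(nPep)),
      accession = acc[pepProt], start = start, length = pepLen,
      archetype = labels, motifEmbedded = motifFlag,
      nSites = nSites, peptide = pepSeq, stringsAsFactors = FALSE)
    sitePlan$sitePos <- relList
    sitePlan$siteRes <- resList
    sitePlan$siteScore <- scoreList
    proteinPeptides <- data.frame(
      peptideId = sprintf("npp%05d", seq_along(ppProt)),
      accession = acc[ppProt], start = ppStart, length = ppLen,
      peptide = substring(seqs[ppProt], ppStart, ppStart + ppLen - 1L),
      stringsAsFactors = FALSE)
    list(proteins = proteins, sitePlan = sitePlan,
         proteinPeptides = proteinPeptides)
  })
}

#' Simulate a raw multi-plex reporter-ion quantitation table
#'
#' The measurement model on the linear scale for sample channel `c` of
#' peptide `p` is
#' `value = 2^(b_p + mu_p[cond(c)] + protein(p, cond(c)) + batch(plex(c)) +
#' load(c) + eps)`, with `eps ~ N(0, noiseSd)` per measurement. The bridge
#' channel of each plex holds the arithmetic mean of the noise-free sample
#' signals of the whole experiment, multiplied by the plex batch factor and
#' its own noise draw — the simulated analogue of pooling an equal amount of
#' every sample. A configurable fraction of phosphopeptides is emitted as two
#' half-intensity PSM rows to exercise PSM aggregation.
#'
#' @param config a [simConfig()] object.
#' @param proteome optional result of [simulateProteome()]; generated from
#'   `config` when omitted.
#' @param proteinEffects optional accession x condition matrix of log2
#'   protein-abundance effects overriding the random `proteinSd` draws.
#' @return list with `quant` (a raw [TMTQuant-class] holding phospho PSM rows
#'   and non-phospho peptide rows), `proteins`, and `groundTruth` (per-peptide
#'   archetypes and true condition means, per-protein effects, per-plex batch
#'   and per-channel loading factors).
#' @export
simulateQuant <- function(config, proteome = NULL, proteinEffects = NULL) {
  validateSimConfig(config)
  if (is.null(proteome)) proteome <- simulateProteome(config)
  layout <- config$layout
  conds <- setdiff(.CONDITIONS, "BRIDGE")
  withSeed(deriveSeed(config$seed, "quant"), {
    plan <- proteome$sitePlan
    npp <- proteome$proteinPeptides
    acc <- names(proteome$proteins)

    if (is.null(proteinEffects)) {
      proteinEffects <- matrix(stats::rnorm(length(acc) * 4L,
                                            sd = config$proteinSd),
                               nrow = length(acc),
                               dimnames = list(acc, conds))
    }
    plexes <- unique(layout$plex)
    batch <- stats::setNames(stats::rnorm(length(plexes), sd = config$batchSd),
                             plexes)
    load <- ifelse(layout$isBridge, 0,
                   stats::rnorm(nrow(layout), sd = config$loadSd))

    # condition mean vectors per peptide (background = 0)
    mu <- matrix(0, nrow(plan), 4L, dimnames = list(plan$peptideId, conds))
    reg <- plan$archetype != "background"
    mu[reg, ] <- config$archetypeMeans[plan$archetype[reg], conds,
                                       drop = FALSE]

    base <- stats::rnorm(nrow(plan), config$baseLog2, config$baseSd)
    baseNpp <- stats::rnorm(nrow(npp), config$baseLog2, config$baseSd)

    # PSM duplication plan (phospho rows only)
    dup <- stats::runif(nrow(plan)) < config$psmDupFrac
    rowPep <- c(rep(seq_len(nrow(plan)), 1L + dup))
    ord <- order(rowPep)
    rowPep <- rowPep[ord]
    psmIdx <- stats::ave(rowPep, rowPep, FUN = seq_along)
    rowSplit <- ifelse(dup[rowPep], 0.5, 1)

    emit <- function(pepIdx, split, baseVec, muMat, accVec) {
      n <- length(pepIdx)
      sampleCols <- which(!layout$isBridge)
      # noise-free linear signal per sample channel
      log2S <- matrix(0, n, length(sampleCols))
      for (j in seq_along(sampleCols)) {
        cnd <- layout$condition[sampleCols[j]]
        log2S[, j] <- baseVec[pepIdx] + log2(split) + muMat[pepIdx, cnd] +
          proteinEffects[accVec[pepIdx], cnd]
      }
      S <- 2^log2S
      vals <- matrix(NA_real_, n, nrow(layout))
      for (j in seq_along(sampleCols)) {
        cidx <- sampleCols[j]
        eps <- stats::rnorm(n, sd = config$noiseSd)
        vals[, cidx] <- S[, j] *
          2^(batch[layout$plex[cidx]] + load[cidx] + eps)
      }
      bridgeMean <- rowMeans(S)
      for (cidx in which(layout$isBridge)) {
        eps <- stats::rnorm(n, sd = config$noiseSd)
        vals[, cidx] <- bridgeMean * 2^(batch[layout$plex[cidx]] + eps)
      }
      vals
    }

    valsPhos <- emit(rowPep, rowSplit, base, mu, plan$accession)
    muNpp <- matrix(0, nrow(npp), 4L, dimnames = list(NULL, conds))
    valsNpp <- emit(seq_len(nrow(npp)), rep(1, nrow(npp)), baseNpp, muNpp,
                    npp$accession)

    rdPhos <- DataFrame(
      psmId = paste0(plan$peptideId[rowPep], ".psm", psmIdx),
      peptide = plan$peptide[rowPep],
      accession = plan$accession[rowPep],
      isPhospho = TRUE,
      sitePos = IRanges::IntegerList(plan$sitePos[rowPep]),
      siteRes = IRanges::CharacterList(plan$siteRes[rowPep]),
      siteScore = IRanges::NumericList(plan$siteScore[rowPep]),
      peptideId = plan$peptideId[rowPep],
      archetype = plan$archetype[rowPep]
    )
    rdNpp <- DataFrame(
      psmId = paste0(npp$peptideId, ".psm1"),
      peptide = npp$peptide,
      accession = npp$accession,
      isPhospho = FALSE,
      sitePos = IRanges::IntegerList(lapply(seq_len(nrow(npp)),
                                            function(i) integer())),
      siteRes = IRanges::CharacterList(lapply(seq_len(nrow(npp)),
                                              function(i) character())),
      siteScore = IRanges::NumericList(lapply(seq_len(nrow(npp)),
                                              function(i) numeric())),
      peptideId = npp$peptideId,
      archetype = "none"
    )
    rd <- rbind(rdPhos, rdNpp)
    vals <- rbind(valsPhos, valsNpp)
    rownames(rd) <- rd$psmId
    quant <- TMTQuant(vals, rd, layout, stage = "raw")
    truth <- list(
      peptides = data.frame(peptideId = plan$peptideId,
                            accession = plan$accession,
                            archetype = plan$archetype,
                            motifEmbedded = plan$motifEmbedded, mu,
                            stringsAsFactors = FALSE),
      proteinEffects = proteinEffects,
      batch = batch,
      load = stats::setNames(load, paste(layout$plex, layout$reporter,
                                         sep = "."))
    )
    list(quant = quant, proteins = proteome$proteins, sitePlan = plan,
         groundTruth = truth)
  })
}
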