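test_that("protein aggregation sums peptide signal per channel", {
  q <- toyRawQuant()
  rd <- SummarizedExperiment::rowData(q)
  rd$isPhospho <- c(FALSE, FALSE, TRUE)
  rd$accession <- c("P1", "P1", "P2")
  SummarizedExperiment::rowData(q) <- rd
  agg <- aggregateProteinQuant(q)
  expect_identical(nrow(agg), 1L)
  expect_equal(unname(quantValues(agg)[1, ]),
               unname(quantValues(q)[1, ] + quantValues(q)[2, ]))
  # permuting row order leaves the aggregate unchanged
  q2 <- q[c(3, 1, 2), ]
  expect_equal(quantValues(aggregateProteinQuant(q2)), quantValues(agg))
})

test_that("bridge normalization divides by the plex bridge and drops bad rows", {
  q <- toyRawQuant()
  bn <- bridgeNormalize(q)
  expect_identical(quantStage(bn), "bridge_normalized")
  expect_identical(ncol(bn), 4L)
  # row 1: plex-1 bridge 10 with sample 20 gives 2; plex-2 bridge 5 likewise
  expect_equal(unname(quantValues(bn)[1, ]), c(2, 3, 2, 3))
  # row 2 has a flat bridge of 2 / 4: planted x2 / x0.5 plex effects vanish
  expect_equal(unname(quantValues(bn)[2, ]), c(1, 1, 1, 1))

  # bridge of 1 leaves sample values untouched
  v <- matrix(c(1, 7, 8, 1, 9, 11), nrow = 1)
  q1 <- toyRawQuant(v)
  expect_equal(unname(quantValues(bridgeNormalize(q1))[1, ]), c(7, 8, 9, 11))

  # zero or missing bridge drops the row and reports it
  v <- matrix(c(0, 7, 8, 1, 9, 11,
                1, 1, 1, 1, 1, 1), nrow = 2, byrow = TRUE)
  q0 <- toyRawQuant(v)
  bn0 <- bridgeNormalize(q0)
  expect_identical(nrow(bn0), 1L)
  expect_identical(S4Vectors::metadata(bn0)$bridgeReport$droppedRows, 1L)
})

test_that("two plexes with reciprocal batch factors align exactly after bridging", {
  # same peptide measured in both plexes; plex 1 scaled x2, plex 2 x0.5
  base <- c(4, 6)
  v <- matrix(c(mean(base) * 2, base[1] * 2, base[2] * 2,
                mean(base) * 0.5, base[1] * 0.5, base[2] * 0.5), nrow = 1)
  bn <- bridgeNormalize(toyRawQuant(v))
  vals <- quantValues(bn)
  expect_equal(unname(vals[1, 1:2]), unname(vals[1, 3:4]), tolerance = 1e-12)
})

test_that("median normalization equalizes channel medians and preserves scale", {
  # hand case: channel medians (2, 4), grand median 3 -> factors (1.5, 0.75)
  v <- matrix(c(1, 1, 2, 1, 2, 4,
                1, 2, 4, 1, 4, 8,
                1, 3, 6, 1, 6, 12), nrow = 3, byrow = TRUE)
  colnames(v) <- NULL
  bn <- bridgeNormalize(toyRawQuant(v))
  med <- apply(quantValues(bn), 2, median)
  mn <- medianNormalize(bn)
  rep <- S4Vectors::metadata(mn)$normReport
  expect_equal(unname(rep$scaleFactors), unname(median(med) / med))
  postMed <- apply(quantValues(mn), 2, median)
  expect_lt(max(abs(postMed / postMed[1] - 1)), 1e-9)
  # overall scale is the grand median of the pre-normalization medians
  expect_equal(unname(postMed[1]), median(med))

  # all-identical columns are unchanged
  v <- matrix(c(1, 2, 2, 1, 2, 2, 1, 5, 5, 1, 5, 5), nrow = 2, byrow = TRUE)
  bn <- bridgeNormalize(toyRawQuant(v))
  expect_equal(quantValues(medianNormalize(bn)), quantValues(bn))

  # zero median is an error
  v <- matrix(c(1, 0, 2, 1, 2, 2), nrow = 1)
  expect_error(medianNormalize(bridgeNormalize(toyRawQuant(v))),
               "zero or undefined median")
})

test_that("bridge + median normalization is idempotent", {
  sim <- simulateQuant(smallConfig(seed = 13, nBackground = 120L))
  mn <- medianNormalize(bridgeNormalize(sim$quant))
  again <- TMTQuant(quantValues(mn), SummarizedExperiment::rowData(mn),
                    channelLayout(mn), stage = "bridge_normalized")
  mn2 <- medianNormalize(again)
  expect_equal(quantValues(mn2), quantValues(mn), tolerance = 1e-12)
})

test_that("PSM aggregation sums by (sequence, site set) and keys correctly", {
  lay <- defaultChannelLayout()
  mk <- function(pep, pos, psm) S4Vectors::DataFrame(
    psmId = psm, peptide = pep, isPhospho = TRUE, accession = "P1",
    sitePos = IRanges::IntegerList(list(pos)),
    siteRes = IRanges::CharacterList(list(rep("S", length(pos)))),
    siteScore = IRanges::NumericList(list(rep(99, length(pos)))))
  rd <- rbind(mk("SAAAK", 1L, "a"), mk("SAAAK", 1L, "b"),
              mk("SAASK", c(1L, 4L), "c"), mk("SAASK", 1L, "d"))
  v <- matrix(rep(c(3, 5, 7, 11), 12), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  q <- TMTQuant(v, rd, lay, stage = "median_normalized")
  agg <- aggregateToPhosphopeptide(q)
  expect_identical(nrow(agg), 3L)
  rdA <- SummarizedExperiment::rowData(agg)
  # two PSMs of the same phosphopeptide sum channel-wise (3 + 5 = 8)
  i <- which(rdA$peptide == "SAAAK")
  expect_equal(unname(quantValues(agg)[i, 1]), 8)
  expect_identical(rdA$psmCount[i], 2L)
  # same sequence with a different site set is not merged
  expect_identical(sort(rdA$psmCount), c(1L, 1L, 2L))
})

test_that("protein correction removes protein-level trends only", {
  # phosphopeptide 8 over relative protein value 2 gives 4
  lay <- defaultChannelLayout()[!defaultChannelLayout()$isBridge, ]
  mkQuant <- function(vals, acc, stage) {
    rd <- S4Vectors::DataFrame(
      peptide = "SAAAK", accession = acc, isPhospho = TRUE,
      sitePos = IRanges::IntegerList(list(1L)),
      siteRes = IRanges::CharacterList(list("S")),
      siteScore = IRanges::NumericList(list(99)), psmCount = 1L)
    rownames(rd) <- paste0("row", seq_len(nrow(vals)))
    TMTQuant(vals, rd, lay, stage = stage)
  }
  phos <- mkQuant(matrix(8, 1, 10), "P1", "peptide_aggregated")
  protV <- matrix(c(rep(2, 5), rep(0.5, 5)) * 4, 1, 10)
  prot <- mkQuant(protV, "P1", "median_normalized")
  corr <- normalizeToProtein(phos, prot)
  rel <- protV / mean(protV)
  expect_equal(unname(quantValues(corr)[1, ]), unname(8 / rel[1, ]))

  # flat protein profile leaves the phosphopeptide unchanged
  protFlat <- mkQuant(matrix(6, 1, 10), "P1", "median_normalized")
  corrFlat <- normalizeToProtein(phos, protFlat)
  expect_equal(unname(quantValues(corrFlat)[1, ]), rep(8, 10))

  # absent protein passes through with a flag
  orphan <- mkQuant(matrix(8, 1, 10), "P9", "peptide_aggregated")
  corrNA <- normalizeToProtein(orphan, protFlat)
  expect_false(SummarizedExperiment::rowData(corrNA)$proteinCorrected)
  expect_equal(unname(quantValues(corrNA)[1, ]), rep(8, 10))
})

test_that("a planted protein-abundance change cancels out after correction", {
  cfg <- smallConfig(seed = 17, nBackground = 50L,
                     clusterSizes = c(C1 = 0L, C2 = 0L, C3 = 0L, C4 = 0L,
                                      C5 = 0L),
                     noiseSd = 0, batchSd = 0, loadSd = 0, psmDupFrac = 0)
  acc <- sprintf("SYN%04d", seq_len(cfg$nProteins))
  pe <- matrix(0, cfg$nProteins, 4L,
               dimnames = list(acc, c("DMSO_0", "DMSO_Th10", "SB_0",
                                      "SB_Th10")))
  shifted <- acc[1:36]  # 2-fold protein change in 30% of proteins
  pe[shifted, "DMSO_Th10"] <- 1
  sim <- simulateQuant(cfg, proteinEffects = pe)
  fcOf <- function(tab) {
    lay <- channelLayout(tab)
    rows <- SummarizedExperiment::rowData(tab)$accession %in% shifted
    vals <- quantValues(tab)[rows, , drop = FALSE]
    log2(rowMeans(vals[, conditionColumns(lay, "DMSO_Th10"), drop = FALSE]) /
         rowMeans(vals[, conditionColumns(lay, "DMSO_0"), drop = FALSE]))
  }
  # uncorrected: phosphopeptides inherit the protein fold change
  mn <- aggregateToPhosphopeptide(medianNormalize(bridgeNormalize(sim$quant)))
  fcRaw <- fcOf(mn)
  expect_gt(length(fcRaw), 0)
  expect_equal(unname(fcRaw), rep(1, length(fcRaw)), tolerance = 1e-9)
  # corrected: unchanged stoichiometry, fold change returns to log2 0
  fc <- fcOf(normalizeSim(sim))
  expect_equal(unname(fc), rep(0, length(fc)), tolerance = 1e-9)
})

test_that("stage transitions are enforced in order", {
  q <- toyRawQuant()
  expect_error(medianNormalize(q), "bridge-normalized")
  bn <- bridgeNormalize(q)
  expect_error(bridgeNormalize(bn), "raw")
  expect_error(aggregateToPhosphopeptide(bn), "median-normalized")
})
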