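# shared fixtures: built in code, no stored data

# scaled-down study-design configuration used throughout the suite
smallConfig <- function(seed = 1L, nProteins = 120L, nBackground = 800L,
                        clusterSizes = c(C1 = 40L, C2 = 35L, C3 = 30L,
                                         C4 = 25L, C5 = 20L), ...) {
  simConfig(seed = seed, nProteins = nProteins, nBackground = nBackground,
            clusterSizes = clusterSizes, ...)
}

# a hand-built raw TMTQuant: 2 plexes (bridge + 2 samples each)
toyRawQuant <- function(values = NULL) {
  layout <- S4Vectors::DataFrame(
    plex = c("1", "1", "1", "2", "2", "2"),
    reporter = c("126", "127N", "127C", "126", "127N", "127C"),
    condition = c("BRIDGE", "DMSO_0", "DMSO_Th10",
                  "BRIDGE", "DMSO_0", "DMSO_Th10"),
    replicate = c(NA, 1L, 1L, NA, 2L, 2L),
    isBridge = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  if (is.null(values))
    values <- matrix(c(10, 20, 30, 5, 10, 15,
                       2, 2, 2, 4, 4, 4,
                       1, 3, 9, 1, 3, 9), nrow = 3, byrow = TRUE)
  rd <- S4Vectors::DataFrame(
    psmId = paste0("psm", seq_len(nrow(values))),
    peptide = rep("AAASAAK", nrow(values)),
    accession = paste0("P", seq_len(nrow(values))),
    isPhospho = TRUE,
    sitePos = IRanges::IntegerList(rep(list(4L), nrow(values))),
    siteRes = IRanges::CharacterList(rep(list("S"), nrow(values))),
    siteScore = IRanges::NumericList(rep(list(99), nrow(values))))
  rownames(rd) <- rd$psmId
  TMTQuant(values, rd, layout, stage = "raw")
}

# a bridgeless sample-only TMTQuant at a late stage, for profile/stat tests
toySampleQuant <- function(values, stage = "protein_corrected",
                           nRep = c(DMSO_0 = 2L, DMSO_Th10 = 3L,
                                    SB_0 = 2L, SB_Th10 = 3L)) {
  cond <- rep(names(nRep), nRep)
  layout <- S4Vectors::DataFrame(
    plex = "1", reporter = as.character(seq_along(cond)),
    condition = cond,
    replicate = unlist(lapply(nRep, seq_len), use.names = FALSE),
    isBridge = FALSE)
  n <- nrow(values)
  rd <- S4Vectors::DataFrame(
    psmId = paste0("r", seq_len(n)),
    peptide = rep("AAASAAK", n),
    accession = paste0("P", seq_len(n)),
    isPhospho = TRUE,
    sitePos = IRanges::IntegerList(rep(list(4L), n)),
    siteRes = IRanges::CharacterList(rep(list("S"), n)),
    siteScore = IRanges::NumericList(rep(list(99), n)))
  rownames(rd) <- rd$psmId
  if (!is.null(rownames(values))) rownames(rd) <- rownames(values)
  TMTQuant(values, rd, layout, stage = stage)
}

# random 13-mer flanks with a fixed center residue
randomFlanks <- function(n, center = "S", h = 6L, seed = 1L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    f <- sample(aa, 2L * h + 1L, replace = TRUE)
    f[h + 1L] <- center
    paste(f, collapse = "")
  }, ""))
}

# chance-corrected agreement between two labelings
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  (sumij - expected) / ((sumA + sumB) / 2 - expected)
}

# map aggregated-phosphopeptide row names back to generator peptide ids
basePeptideId <- function(ids) sub("\\..*$", "", ids)

# the standard normalization chain on a simulation result
normalizeSim <- function(sim) {
  prot <- medianNormalize(bridgeNormalize(aggregateProteinQuant(sim$quant)))
  normalizeToProtein(
    aggregateToPhosphopeptide(medianNormalize(bridgeNormalize(sim$quant))),
    prot)
}
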