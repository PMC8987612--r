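# brute-force binomial upper tail P(X >= k), n <= 200
binomTailOracle <- function(k, n, q) {
  if (k > n) return(0)
  sum(choose(n, k:n) * q^(k:n) * (1 - q)^(n - (k:n)))
}

# exact hypergeometric upper tail by enumeration
hyperTailOracle <- function(k, K, N, n) {
  i <- max(k, 0):min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# flanks with chosen residues planted at fixed offsets from the center
plantedFlanks <- function(n, plant = list(), center = "S", seed = 1) {
  fl <- randomFlanks(n, center = center, seed = seed)
  for (off in names(plant)) {
    idx <- 7L + as.integer(off)
    substring(fl, idx, idx) <- plant[[off]]
  }
  fl
}

test_that("motif-x step probabilities match the brute-force binomial oracle", {
  # 40 of 100 foreground flanks carry R at -3; background frequency 0.05
  bg <- randomFlanks(400, seed = 2)
  substring(bg, 4, 4) <- "A"
  substring(bg[1:20], 4, 4) <- "R"
  fg <- randomFlanks(100, seed = 3)
  substring(fg, 4, 4) <- "A"
  substring(fg[1:40], 4, 4) <- "R"
  res <- motifX(fg, bg, pThreshold = 1e-3, minOcc = 20)
  expect_gte(nrow(res), 1L)
  step1 <- res$steps[[1]][1, ]
  expect_equal(step1$position, -3)
  expect_identical(step1$residue, "R")
  expect_equal(step1$k, 40)
  expect_equal(step1$p, binomTailOracle(40, 100, 0.05), tolerance = 1e-12)

  # fuzzed step-level agreement across several embeddings
  for (s in 1:5) {
    set.seed(s)
    nf <- sample(60:150, 1)
    frac <- runif(1, 0.4, 0.8)
    fg2 <- plantedFlanks(nf, seed = s + 10)
    k <- round(frac * nf)
    substring(fg2[seq_len(k)], 6, 6) <- "P"
    bg2 <- randomFlanks(500, seed = s + 20)
    res2 <- motifX(fg2, bg2, pThreshold = 1e-2, minOcc = 10)
    if (!nrow(res2)) next
    st <- res2$steps[[1]]
    for (j in seq_len(nrow(st)))
      expect_equal(st$p[j],
                   binomTailOracle(st$k[j], st$n[j], st$bgFreq[j]),
                   tolerance = 1e-12)
  }
})

test_that("motif-x stays silent when foreground matches background", {
  bg <- randomFlanks(500, seed = 5)
  fg <- bg[1:80]
  res <- motifX(fg, bg, pThreshold = 1e-6, minOcc = 20)
  expect_identical(nrow(res), 0L)

  # over 100 null draws at defaults, spurious motifs are rare
  emitted <- 0L
  for (s in 1:100) {
    fg <- randomFlanks(60, seed = 1000 + s)
    bg <- randomFlanks(400, seed = 2000 + s)
    if (nrow(motifX(fg, bg, pThreshold = 1e-6, minOcc = 20)) > 0)
      emitted <- emitted + 1L
  }
  expect_lte(emitted, 5L)
})

test_that("motif-x recovers an embedded basophilic RRxS consensus", {
  fg <- plantedFlanks(100, seed = 6)
  substring(fg[1:60], 4, 4) <- "R"
  substring(fg[1:60], 5, 5) <- "R"
  bg <- randomFlanks(1000, seed = 7)
  res <- motifX(fg, bg, pThreshold = 1e-3, minOcc = 5)
  expect_gte(nrow(res), 1L)
  top <- res[1, ]
  expect_identical(top$name, "RRxS")
  fixedAt <- sort(res$steps[[1]]$position)
  expect_equal(fixedAt, c(-3, -2))
  expect_identical(substring(top$pattern, 7, 7), "S")
  expect_gte(top$fgMatches, 55L)

  # mixed widths and empty background are rejected
  expect_error(motifX(c(fg, "SHORT"), bg), "mixed flank widths")
  expect_error(motifX(fg, character()), "empty background")
})

test_that("kinase assignment follows the consensus library and external tables", {
  st <- data.frame(
    peptideId = c("p1", "p2", "p3"),
    accession = c("A", "B", "C"),
    position = c(10L, 20L, 30L),
    residue = c("S", "S", "S"),
    score = 99,
    flank = c("AAARRASAAAAAA",   # R at -3/-2: PKA
              "AAAAPASPAAAAA",   # P at -2 and +1: MAPK + CDK
              "AAAAAASAAAAAA"),  # nothing
    ambiguous = FALSE)
  asn <- assignKinases(st)
  expect_setequal(asn$kinase[asn$peptideId == "p1"], "PKA")
  expect_setequal(asn$kinase[asn$peptideId == "p2"], c("MAPK", "CDK"))
  expect_false("p3" %in% asn$peptideId)

  # padding never matches a constraint
  st$flank[1] <- "___RRASAAAAAA"
  asnPad <- assignKinases(st)
  expect_true("PKA" %in% asnPad$kinase[asnPad$peptideId == "p1"])
  st$flank[1] <- "_____ASAAAAAA"
  expect_false("p1" %in% assignKinases(st)$peptideId)

  # external table bypasses the library
  ext <- data.frame(accession = "B", position = 20L, kinase = "AURKA")
  asnExt <- assignKinases(st, external = ext)
  expect_identical(asnExt$kinase, "AURKA")
  expect_identical(asnExt$peptideId, "p2")
  empty <- assignKinases(st, external = ext[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("kinase and annotation enrichment match exact hypergeometric tails", {
  # engineered counts: N = 50 assigned sites, K = 5 for the kinase,
  # cluster of n = 10 containing k = 3 of them
  cl <- c(rep("C1", 10), rep("C2", 40))
  names(cl) <- paste0("p", 1:50)
  asn <- data.frame(siteKey = paste0("s", 1:50),
                    peptideId = paste0("p", 1:50),
                    residue = "S",
                    kinase = "BASE")
  pka <- data.frame(siteKey = paste0("s", c(1:3, 48:49)),
                    peptideId = paste0("p", c(1:3, 48:49)),
                    residue = "S", kinase = "PKA")
  res <- kinaseClusterEnrichment(rbind(asn, pka), cl)
  row <- res[res$kinase == "PKA" & res$cluster == "C1", ]
  expect_identical(c(row$k, row$n, row$K, row$N), c(3L, 10L, 5L, 50L))
  expect_equal(row$p, hyperTailOracle(3, 5, 50, 10), tolerance = 1e-12)
  expect_equal(row$fold, (3 / 10) / (5 / 50), tolerance = 1e-12)
  expect_equal(row$score, row$fold * (-log10(row$p)), tolerance = 1e-12)
  # a kinase at background proportion has fold 1
  base <- res[res$kinase == "BASE" & res$cluster == "C1", ]
  expect_equal(base$fold, 1, tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$k <= pmin(res$n, res$K)))

  # annotation ORA shares the same exact tail
  sets <- list(T1 = list(description = "d", members = paste0("g", 1:5)),
               T0 = list(description = "none", members = "zzz"))
  ora <- annotationOra(paste0("g", c(1:3, 40:46)), paste0("g", 1:50), sets)
  expect_identical(nrow(ora), 1L)  # zero-overlap term skipped
  expect_identical(attr(ora, "skipped"), "T0")
  expect_equal(ora$p[1], hyperTailOracle(3, 5, 50, 10), tolerance = 1e-12)

  # exhaustive check against enumeration for N <= 30
  for (s in 1:10) {
    set.seed(s)
    N <- sample(10:30, 1); K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1); k <- sample(0:min(K, n), 1)
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyperTailOracle(k, K, N, n), tolerance = 1e-12)
  }

  # degenerate ORA cases
  oraAll <- annotationOra(paste0("g", 1:50), paste0("g", 1:50),
                          list(T1 = list(description = "d",
                                         members = paste0("g", 1:5))))
  expect_equal(oraAll$p, 1, tolerance = 1e-12)  # cluster == background
  ora0 <- annotationOra("g40", paste0("g", 1:50),
                        list(T1 = list(description = "d",
                                       members = paste0("g", 1:5))))
  expect_equal(ora0$p, 1, tolerance = 1e-12)  # k = 0
})

test_that("embedded C1 motifs surface as top kinase-cluster enrichment", {
  # only the basophilic C1 motif is embedded, mirroring the recovery design
  cfg <- smallConfig(seed = 47, nBackground = 300L,
                     clusterSizes = c(C1 = 50L, C2 = 40L, C3 = 0L, C4 = 0L,
                                      C5 = 0L),
                     motifFrac = c(C1 = 0.6, C2 = 0))
  sim <- simulateQuant(cfg)
  phos <- filterLocalization(normalizeSim(sim))
  st <- buildSiteTable(phos, sim$proteins)
  st <- st[!st$ambiguous, ]
  gt <- sim$groundTruth$peptides
  clusters <- gt$archetype[gt$archetype != "background"]
  names(clusters) <- gt$peptideId[gt$archetype != "background"]
  stC <- st
  stC$peptideId <- basePeptideId(stC$peptideId)
  asn <- assignKinases(stC)
  res <- kinaseClusterEnrichment(asn, clusters)
  expect_identical(res$kinase[1], "PKA")
  expect_identical(res$cluster[1], "C1")
})
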