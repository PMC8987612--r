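test_that("profile matrices are 0-min ratios with per-row min-max scaling", {
  # per-sample mode, hand-checkable values
  v <- matrix(c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2,     # flat at its control
                2, 2, 4, 4, 4, 2, 2, 8, 8, 8),    # ratios 1,2 then 1,4
              nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "up"), NULL))
  q <- toySampleQuant(v)
  pm <- buildProfileMatrix(q, mode = "sample")
  expect_identical(attr(pm, "degenerate"), "flat")
  expect_equal(unname(pm["flat", ]), rep(0.5, 10))
  # min-max: minimum ratio 1 -> 0, maximum ratio 4 -> 1, ratio 2 -> 1/3
  expect_equal(unname(pm["up", ]),
               c(0, 0, 1 / 3, 1 / 3, 1 / 3, 0, 0, 1, 1, 1))
  # non-degenerate rows span [0, 1] exactly
  expect_equal(unname(apply(pm, 1, min)), c(0.5, 0))
  expect_equal(unname(apply(pm["up", , drop = FALSE], 1, max)), 1)

  # mean mode collapses replicates to the four condition means
  pmm <- buildProfileMatrix(q, mode = "mean")
  expect_identical(dim(pmm), c(2L, 4L))
  expect_equal(unname(pmm["up", ]), c(0, 1 / 3, 0, 1))

  # arm reference pins both arms to their own 0-min control
  v2 <- matrix(c(2, 2, 4, 4, 4, 8, 8, 8, 8, 8), nrow = 1,
               dimnames = list("r", NULL))
  pma <- buildProfileMatrix(toySampleQuant(v2), reference = "arm",
                            mode = "mean")
  expect_equal(unname(pma[1, ]), c(0, 1, 0, 0))  # SB flat at its control
})

test_that("noise-free archetype profiles peak where planted", {
  cfg <- smallConfig(seed = 31, nBackground = 30L,
                     clusterSizes = c(C1 = 10L, C2 = 0L, C3 = 0L, C4 = 0L,
                                      C5 = 0L),
                     noiseSd = 0, batchSd = 0, loadSd = 0, psmDupFrac = 0)
  sim <- simulateQuant(cfg)
  phos <- normalizeSim(sim)
  gt <- sim$groundTruth$peptides
  ids <- rownames(phos)[basePeptideId(rownames(phos)) %in%
                          gt$peptideId[gt$archetype == "C1"]]
  pm <- buildProfileMatrix(phos, ids)
  # vehicle-thrombin condition column is the row maximum (scaled to 1)
  expect_true(all(pm[, "DMSO_Th10"] == 1))
  expect_true(all(pm[, "DMSO_0"] == 0))
})

test_that("k-means fits are exact on separable data and reproducible", {
  pm <- rbind(matrix(0, 5, 4), matrix(1, 6, 4)) +
    matrix(rnorm(44, sd = 1e-3), 11, 4)
  rownames(pm) <- paste0("r", 1:11)
  m <- kmeansFit(pm, 2, seed = 1)
  asn <- clusterAssignments(m)
  expect_identical(length(unique(asn[1:5])), 1L)
  expect_identical(length(unique(asn[6:11])), 1L)
  expect_false(asn[1] == asn[11])
  expect_lt(m@wss, 1e-3)

  # k equal to the number of distinct rows: zero inertia
  m2 <- kmeansFit(pm, 11, seed = 1, restarts = 200)
  expect_equal(m2@wss, 0, tolerance = 1e-20)

  # bit-reproducible under a fixed seed
  mA <- kmeansFit(pm, 3, seed = 9)
  mB <- kmeansFit(pm, 3, seed = 9)
  expect_identical(clusterAssignments(mA), clusterAssignments(mB))
  expect_identical(mA@wss, mB@wss)

  expect_error(kmeansFit(pm, 1), ">= 2")
  expect_error(kmeansFit(pm[1:2, ], 3), "at least k")
})

test_that("the elbow scan finds planted blob counts and validates its range", {
  set.seed(99)
  correct <- 0L
  for (s in 1:20) {
    centers <- matrix(c(0, 0, 0, 0, 5, 5, 0, 0, 0, 5, 5, 5), 3, 4,
                      byrow = TRUE)
    pm <- centers[rep(1:3, each = 30), ] + matrix(rnorm(360, sd = 0.3),
                                                  90, 4)
    rownames(pm) <- paste0("r", 1:90)
    sel <- elbowSelectK(pm, 2:8, seed = s, restarts = 15)
    expect_true(all(diff(sel$wss) <= 1e-8))  # inertia non-increasing in k
    if (sel$k == 3L) correct <- correct + 1L
  }
  expect_gte(correct, 18L)

  pm <- matrix(rnorm(80), 20, 4, dimnames = list(paste0("r", 1:20), NULL))
  expect_error(elbowSelectK(pm, 2:3), "at least 3")
  expect_error(elbowSelectK(pm, c(2, 4, 6)), "contiguous")
  expect_error(elbowSelectK(pm, 18:25), "rows - 1")
})

test_that("cluster recovery degrades with noise", {
  ariAt <- function(noise) {
    vals <- numeric(3)
    for (s in 1:3) {
      cfg <- smallConfig(seed = 40 + s, nProteins = 80L, nBackground = 100L,
                         clusterSizes = c(C1 = 25L, C2 = 25L, C3 = 25L,
                                          C4 = 25L, C5 = 25L),
                         noiseSd = noise)
      sim <- simulateQuant(cfg)
      phos <- normalizeSim(sim)
      gt <- sim$groundTruth$peptides
      ids <- rownames(phos)[basePeptideId(rownames(phos)) %in%
                              gt$peptideId[gt$archetype != "background"]]
      pm <- buildProfileMatrix(phos, ids)
      m <- kmeansFit(pm, 5, seed = s, restarts = 25)
      truth <- gt$archetype[match(basePeptideId(rownames(pm)),
                                  gt$peptideId)]
      vals[s] <- adjustedRandIndex(clusterAssignments(m), truth)
    }
    mean(vals)
  }
  expect_gte(ariAt(0.1), ariAt(0.5))
})

test_that("cluster profile summaries reflect membership and arms", {
  v <- matrix(c(2, 2, 4, 4, 4, 2, 2, 2, 2, 2), nrow = 1,
              dimnames = list("solo", NULL))
  q <- toySampleQuant(v)
  pm <- buildProfileMatrix(q, mode = "mean")
  m <- new("ClusterModel", k = 1L,
           assignments = c(solo = 1L), centroids = pm[1, , drop = FALSE],
           wss = 0, seed = 1L, restarts = 1L)
  prof <- clusterProfiles(m, pm)
  expect_identical(nrow(prof), 4L)
  expect_true(all(prof$sd == 0))  # single member, one value per cell
  dm10 <- prof$mean[prof$arm == "DMSO" & prof$time == 10]
  expect_equal(dm10, 1)  # scaled maximum sits in the vehicle 10-min cell
})

test_that("Spearman replicate correlations match hand-ranked values", {
  v <- matrix(c(1, 2, 3, 4, 5,
                2, 1, 4, 3, 5), ncol = 2)
  rownames(v) <- paste0("p", 1:5)
  q <- toySampleQuant(cbind(v, matrix(9, 5, 8)),
                      nRep = c(DMSO_0 = 2L, DMSO_Th10 = 3L, SB_0 = 2L,
                               SB_Th10 = 3L))
  m <- spearmanReplicateMatrix(q, "DMSO_0")
  # rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 = (1,1,1,1,0)
  expect_equal(m[1, 2], 1 - 6 * 4 / (5 * 24), tolerance = 1e-12)
  expect_equal(m[1, 2], 0.8)
  expect_identical(diag(m), c(`1.1` = 1, `1.2` = 1))
  expect_identical(m[1, 2], m[2, 1])

  # perfect rank reversal
  v2 <- cbind(1:5, 5:1)
  q2 <- toySampleQuant(cbind(v2, matrix(9, 5, 8)))
  expect_equal(spearmanReplicateMatrix(q2, "DMSO_0")[1, 2], -1)

  # constant replicate: undefined, reported missing with a warning
  v3 <- cbind(rep(2, 5), 1:5)
  q3 <- toySampleQuant(cbind(v3, matrix(9, 5, 8)))
  expect_warning(m3 <- spearmanReplicateMatrix(q3, "DMSO_0"), "constant")
  expect_true(is.na(m3[1, 2]))
})
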