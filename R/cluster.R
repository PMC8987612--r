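#' Build the temporal profile matrix for clustering
#'
#' Each selected phosphopeptide becomes one row of response ratios to a 0-min
#' control mean, min-max scaled per row to [0, 1]. With `mode = "mean"`
#' (default, the clustering input) the columns are the four condition means
#' in the order vehicle 0-min, vehicle 10-min, inhibitor 0-min, inhibitor
#' 10-min, so replicate noise is averaged out of the temporal shapes; with
#' `mode = "sample"` the columns are the individual non-bridge samples
#' (replicates ascending), mirroring a replicate-resolved heat map. With
#' `reference = "vehicle"` (default) ratios are taken to the pooled vehicle
#' (DMSO 0-min) control mean, which preserves basal differences between the
#' pretreatment arms in the profiles; `reference = "arm"` normalizes each arm
#' to its own 0-min control instead, which forces both arms to 1 at 0 min.
#' Constant rows are degenerate under min-max scaling and are set to 0.5 and
#' flagged; rows with a nonpositive control mean are excluded.
#'
#' @param object a normalized [TMTQuant-class].
#' @param ids row names to include (typically the significant set).
#' @param reference `"vehicle"` or `"arm"` (see above).
#' @param mode `"mean"` (condition means) or `"sample"` (per-sample columns).
#' @return numeric matrix with attributes `degenerate` (flagged row names)
#'   and `excluded` (dropped row names).
#' @export
buildProfileMatrix <- function(object, ids = rownames(object),
                               reference = c("vehicle", "arm"),
                               mode = c("mean", "sample")) {
  reference <- match.arg(reference)
  mode <- match.arg(mode)
  layout <- colData(object)
  vals <- quantValues(object)
  ids <- intersect(ids, rownames(vals))
  stopIfNot(length(ids) > 0, "no requested rows present in the table")
  ord <- sampleOrder(layout)
  sub <- vals[ids, ord, drop = FALSE]
  cond <- layout$condition[ord]
  dmso0 <- which(cond == "DMSO_0")
  sb0 <- which(cond == "SB_0")
  refMat <- matrix(NA_real_, nrow(sub), ncol(sub))
  if (reference == "vehicle") {
    refMat[] <- rowMeans(sub[, dmso0, drop = FALSE])
  } else {
    armSB <- grepl("^SB", cond)
    refMat[, !armSB] <- rowMeans(sub[, dmso0, drop = FALSE])
    refMat[, armSB] <- rowMeans(sub[, sb0, drop = FALSE])
  }
  ratios <- sub / refMat
  if (mode == "mean") {
    condOrder <- c("DMSO_0", "DMSO_Th10", "SB_0", "SB_Th10")
    ratios <- vapply(condOrder, function(cn)
      rowMeans(ratios[, cond == cn, drop = FALSE]),
      numeric(nrow(ratios)))
    if (is.null(dim(ratios)))
      ratios <- matrix(ratios, nrow = 1L, dimnames = list(NULL, condOrder))
    rownames(ratios) <- rownames(sub)
    cond <- condOrder
  }
  ctrlBad <- !apply(refMat, 1L, function(r) all(is.finite(r) & r > 0))
  naBad <- !apply(ratios, 1L, function(r) all(is.finite(r)))
  excluded <- ids[ctrlBad | naBad]
  pm <- ratios[!(ctrlBad | naBad), , drop = FALSE]
  rng <- apply(pm, 1L, function(r) diff(range(r)))
  degenerate <- rownames(pm)[rng == 0]
  scaled <- t(apply(pm, 1L, function(r) {
    d <- diff(range(r))
    if (d == 0) rep(0.5, length(r)) else (r - min(r)) / d
  }))
  dimnames(scaled) <- dimnames(pm)
  attr(scaled, "degenerate") <- degenerate
  attr(scaled, "excluded") <- excluded
  attr(scaled, "conditions") <- cond
  scaled
}

#' Fit k-means with seeded random restarts
#'
#' Lloyd's algorithm (Euclidean distance, via [stats::kmeans()]) run from
#' `restarts` seeded random initializations (centers drawn from distinct data
#' rows); the restart with the lowest total within-cluster sum of squares
#' wins. Restarts that collapse a cluster to empty are discarded. The fit is
#' deterministic for a fixed seed.
#'
#' @param pm profile matrix from [buildProfileMatrix()].
#' @param k number of clusters (>= 2, <= rows).
#' @param seed integer seed.
#' @param restarts number of random restarts.
#' @return a [ClusterModel-class].
#' @export
kmeansFit <- function(pm, k, seed = 1L, restarts = 50L) {
  stopIfNot(k >= 2L, "k must be >= 2")
  stopIfNot(nrow(pm) >= k, "need at least k rows")
  uniq <- unique(pm)
  stopIfNot(nrow(uniq) >= k, "need at least k distinct profiles")
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      idx <- sample.int(nrow(uniq), k)
      # empty-cluster (and non-convergence) restarts are discarded
      fit <- tryCatch(
        stats::kmeans(pm, centers = uniq[idx, , drop = FALSE],
                      iter.max = 100L, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  stopIfNot(!is.null(best), "all k-means restarts failed")
  new("ClusterModel", k = as.integer(k),
      assignments = stats::setNames(as.integer(best$cluster), rownames(pm)),
      centroids = best$centers, wss = best$tot.withinss,
      seed = as.integer(seed), restarts = as.integer(restarts))
}

#' Elbow-based selection of the cluster count
#'
#' Fits k-means over a contiguous range of k and selects the k with the
#' greatest curvature of the within-cluster sum-of-squares curve on the log
#' scale: the maximum second difference
#' `log W(k-1) - 2 log W(k) + log W(k+1)` over the interior of the range.
#' The log-scale second difference measures the change in *relative*
#' improvement from one k to the next and therefore locates the k at which
#' the inertia curve flattens — the visual elbow — rather than the largest
#' absolute drop, which for hierarchically separated groups always sits at
#' the coarsest split. The full inertia curve is returned for audit.
#'
#' @inheritParams kmeansFit
#' @param kRange contiguous integer range of candidate k (length >= 3).
#' @return list with `k` (selected), `wss` (named inertia curve) and
#'   `curvature` (named second differences).
#' @export
elbowSelectK <- function(pm, kRange = 2:10, seed = 1L, restarts = 50L) {
  kRange <- as.integer(kRange)
  stopIfNot(length(kRange) >= 3L, "kRange must contain at least 3 values")
  stopIfNot(all(diff(kRange) == 1L), "kRange must be contiguous")
  stopIfNot(min(kRange) >= 2L && max(kRange) <= nrow(pm) - 1L,
            "kRange must lie within [2, rows - 1]")
  wss <- vapply(kRange, function(k)
    kmeansFit(pm, k, seed = deriveSeed(seed, paste0("k", k)),
              restarts = restarts)@wss, 0)
  names(wss) <- kRange
  inner <- 2:(length(kRange) - 1L)
  lw <- log(wss)
  curv <- lw[inner - 1L] - 2 * lw[inner] + lw[inner + 1L]
  names(curv) <- kRange[inner]
  kSel <- kRange[inner][which.max(curv)]
  list(k = kSel, wss = wss, curvature = curv)
}

#' Per-cluster temporal profiles
#'
#' Mean and SD of the (scaled) profile values per cluster, treatment arm and
#' timepoint.
#'
#' @param model a [ClusterModel-class].
#' @param pm the profile matrix the model was fitted on.
#' @return data.frame with cluster, arm, time, mean, sd, n.
#' @export
clusterProfiles <- function(model, pm) {
  cond <- attr(pm, "conditions")
  stopIfNot(!is.null(cond), "pm must come from buildProfileMatrix()")
  asn <- clusterAssignments(model)
  arm <- ifelse(grepl("^SB", cond), "SB", "DMSO")
  time <- ifelse(grepl("Th10$", cond), 10L, 0L)
  out <- list()
  for (cl in seq_len(model@k)) {
    rows <- names(asn)[asn == cl]
    block <- pm[rows, , drop = FALSE]
    for (a in unique(arm)) for (tm in unique(time)) {
      cols <- which(arm == a & time == tm)
      if (!length(cols)) next
      v <- as.vector(block[, cols, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, arm = a, time = tm,
        mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
        n = length(rows))
    }
  }
  do.call(rbind, out)
}

#' Spearman correlation matrix of condition replicates
#'
#' Pairwise Spearman rank correlations over peptides between the replicate
#' channels of one condition. Constant vectors have undefined rank
#' correlation and yield `NA` with a warning.
#'
#' @param object a [TMTQuant-class].
#' @param condition condition label, e.g. `"DMSO_0"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanReplicateMatrix <- function(object, condition) {
  layout <- colData(object)
  cols <- conditionColumns(layout, condition)
  stopIfNot(length(cols) >= 2L, "need >= 2 replicates of ", condition)
  sub <- quantValues(object)[, cols, drop = FALSE]
  const <- apply(sub, 2L, function(v) stats::var(v[is.finite(v)]) == 0)
  if (any(const))
    warning("constant replicate vector: correlation undefined for ",
            paste(colnames(sub)[const], collapse = ", "))
  suppressWarnings(
    m <- stats::cor(sub, method = "spearman", use = "pairwise.complete.obs"))
  diag(m) <- ifelse(const, NA_real_, 1)
  m
}
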