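#' Aggregate non-phospho peptides to protein-level quantitation
#'
#' Protein-level values are the channel-wise sum of reporter signal-to-noise
#' over all (non-phospho) peptides of each protein. Missing peptide values are
#' ignored in the sum; a protein with no observed value in a channel gets
#' `NA`.
#'
#' @param object a raw [TMTQuant-class] containing non-phospho rows.
#' @return a raw [TMTQuant-class] with one row per protein accession.
#' @export
aggregateProteinQuant <- function(object) {
  stopIfNot(quantStage(object) == "raw",
            "protein aggregation expects a raw table")
  rd <- rowData(object)
  keep <- which(!rd$isPhospho)
  stopIfNot(length(keep) > 0, "no non-phospho rows to aggregate")
  vals <- quantValues(object)[keep, , drop = FALSE]
  accs <- rd$accession[keep]
  out <- rowsumNA(vals, accs)
  rdOut <- DataFrame(accession = rownames(out),
                     nPeptides = as.integer(table(accs)[rownames(out)]))
  rownames(rdOut) <- rownames(out)
  TMTQuant(out, rdOut, colData(object), stage = "raw")
}

# channel-wise sum by group, NA-aware (all-NA group/channel stays NA)
rowsumNA <- function(vals, groups) {
  groups <- as.character(groups)
  sums <- rowsum(ifelse(is.na(vals), 0, vals), groups)
  nobs <- rowsum((!is.na(vals)) * 1, groups)
  sums[nobs == 0] <- NA_real_
  sums[sort(rownames(sums)), , drop = FALSE]
}

#' Bridge-channel normalization
#'
#' Divides every sample channel by the pooled bridge channel of its plex,
#' row-wise, which cancels per-plex batch effects exactly for noise-free data.
#' Bridge columns are removed from the returned table; rows with a missing or
#' zero bridge value in any plex are dropped and counted in the report.
#'
#' @param object a raw [TMTQuant-class].
#' @return a [TMTQuant-class] at stage `"bridge_normalized"`; the drop count
#'   is stored in `metadata(x)$bridgeReport`.
#' @export
bridgeNormalize <- function(object) {
  stopIfNot(quantStage(object) == "raw",
            "bridge normalization expects a raw table")
  layout <- colData(object)
  vals <- quantValues(object)
  plexes <- unique(layout$plex)
  bad <- rep(FALSE, nrow(vals))
  out <- vals
  for (p in plexes) {
    bcol <- which(layout$plex == p & layout$isBridge)
    if (length(bcol) != 1L) stop("plex ", p, " lacks a unique bridge channel")
    b <- vals[, bcol]
    bad <- bad | is.na(b) | b <= 0
    scols <- which(layout$plex == p & !layout$isBridge)
    out[, scols] <- vals[, scols, drop = FALSE] / b
  }
  keepRows <- which(!bad)
  keepCols <- which(!layout$isBridge)
  res <- TMTQuant(out[keepRows, keepCols, drop = FALSE],
                  rowData(object)[keepRows, , drop = FALSE],
                  layout[keepCols, , drop = FALSE],
                  stage = "bridge_normalized")
  S4Vectors::metadata(res)$bridgeReport <-
    list(droppedRows = sum(bad), retainedRows = length(keepRows))
  res
}

#' Channel-median normalization
#'
#' Divides each reporter channel by its median and rescales by the grand
#' median of the pre-normalization channel medians, so the overall
#' signal-to-noise-like scale is preserved while all channel medians become
#' equal. Set `rescale = FALSE` for pure division to median 1.
#'
#' @param object a [TMTQuant-class] at stage `"bridge_normalized"`.
#' @return the normalized [TMTQuant-class] at stage `"median_normalized"`;
#'   per-channel scale factors are stored in `metadata(x)$normReport`.
#' @export
medianNormalize <- function(object) {
  medianNormalizeImpl(object, rescale = TRUE)
}

#' @rdname medianNormalize
#' @param ... not used.
#' @export
medianNormalizeRaw <- function(object, ...) {
  medianNormalizeImpl(object, rescale = FALSE)
}

medianNormalizeImpl <- function(object, rescale = TRUE) {
  stopIfNot(quantStage(object) == "bridge_normalized",
            "median normalization expects a bridge-normalized table")
  vals <- quantValues(object)
  stopIfNot(nrow(vals) >= 1L, "median normalization needs at least one row")
  med <- apply(vals, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(med) | med == 0))
    stop("channel ", colnames(vals)[which(!is.finite(med) | med == 0)[1]],
         " has zero or undefined median")
  grand <- if (rescale) stats::median(med) else 1
  factors <- grand / med
  out <- sweep(vals, 2L, factors, `*`)
  res <- TMTQuant(out, rowData(object), colData(object),
                  stage = "median_normalized")
  S4Vectors::metadata(res) <- S4Vectors::metadata(object)
  S4Vectors::metadata(res)$normReport <-
    list(scaleFactors = factors, channelMedians = med, grandMedian = grand)
  res
}

#' Aggregate PSM rows to unique phosphopeptides
#'
#' PSMs sharing the uniqueness key (peptide sequence, set of localized site
#' positions) are summed channel-wise; the PSM count per phosphopeptide is
#' recorded in `rowData(x)$psmCount`. Identical sequences with different site
#' sets remain separate rows. Non-phospho rows are dropped.
#'
#' @param object a [TMTQuant-class] at stage `"median_normalized"`.
#' @return a [TMTQuant-class] at stage `"peptide_aggregated"`.
#' @export
aggregateToPhosphopeptide <- function(object) {
  stopIfNot(quantStage(object) == "median_normalized",
            "phosphopeptide aggregation expects a median-normalized table")
  rd <- rowData(object)
  keep <- which(rd$isPhospho)
  stopIfNot(length(keep) > 0, "no phosphopeptide rows present")
  rd <- rd[keep, , drop = FALSE]
  vals <- quantValues(object)[keep, , drop = FALSE]
  key <- vapply(seq_len(nrow(rd)), function(i)
    paste0(rd$peptide[i], "|",
           paste(sort(rd$sitePos[[i]]), collapse = ",")), "")
  out <- rowsumNA(vals, key)
  first <- match(rownames(out), key)
  rdOut <- rd[first, , drop = FALSE]
  rdOut$psmCount <- as.integer(table(key)[rownames(out)])
  rdOut$psmId <- NULL
  rn <- if ("peptideId" %in% colnames(rdOut))
    make.unique(rdOut$peptideId) else rownames(out)
  rownames(rdOut) <- rn
  rownames(out) <- rn
  res <- TMTQuant(out, rdOut, colData(object), stage = "peptide_aggregated")
  S4Vectors::metadata(res) <- S4Vectors::metadata(object)
  res
}

#' Phosphopeptide-to-protein correction
#'
#' Divides each phosphopeptide profile by the *relative* channel profile of
#' its parent protein (the protein's normalized value divided by its own row
#' mean), removing protein-abundance trends without changing the
#' phosphopeptide scale. Phosphopeptides whose protein is absent from the
#' protein table pass through unchanged and are flagged
#' (`rowData(x)$proteinCorrected == FALSE`); rows whose protein profile
#' contains a zero or missing value are excluded and counted.
#'
#' @param object a phosphopeptide [TMTQuant-class] at stage
#'   `"peptide_aggregated"`.
#' @param proteinTable a protein-level [TMTQuant-class] at stage
#'   `"median_normalized"` on the same channel set.
#' @return a [TMTQuant-class] at stage `"protein_corrected"`; exclusion
#'   counts in `metadata(x)$proteinReport`.
#' @export
normalizeToProtein <- function(object, proteinTable) {
  stopIfNot(quantStage(object) == "peptide_aggregated",
            "protein correction expects a peptide-aggregated table")
  stopIfNot(quantStage(proteinTable) == "median_normalized",
            "protein table must be bridge- and median-normalized")
  stopIfNot(identical(colnames(object), colnames(proteinTable)),
            "phospho and protein tables must share the same channel set")
  pv <- quantValues(proteinTable)
  rel <- pv / rowMeans(pv, na.rm = TRUE)
  idx <- match(rowData(object)$accession, rowData(proteinTable)$accession)
  vals <- quantValues(object)
  corrected <- !is.na(idx)
  excluded <- rep(FALSE, nrow(vals))
  out <- vals
  for (i in which(corrected)) {
    r <- rel[idx[i], ]
    if (any(!is.finite(r) | r <= 0)) { excluded[i] <- TRUE; next }
    out[i, ] <- vals[i, ] / r
  }
  keep <- which(!excluded)
  rdOut <- rowData(object)[keep, , drop = FALSE]
  rdOut$proteinCorrected <- corrected[keep]
  res <- TMTQuant(out[keep, , drop = FALSE], rdOut, colData(object),
                  stage = "protein_corrected")
  S4Vectors::metadata(res) <- S4Vectors::metadata(object)
  S4Vectors::metadata(res)$proteinReport <-
    list(excludedZeroProtein = sum(excluded),
         uncorrectedMissingProtein = sum(!corrected[keep]))
  res
}
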