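#' Iterative consensus-motif extraction (motif-x style)
#'
#' Finds fixed-width phosphorylation consensus motifs by iteratively fixing
#' the most binomially over-represented (position, residue) pair. At each
#' step, for every non-center position and residue, the binomial tail
#' probability `P(X >= k_fg)` is computed with `n = |foreground|` and success
#' probability equal to the background frequency of that residue at that
#' position. The smallest p below `pThreshold` with at least `minOcc`
#' foreground occurrences is fixed (ties broken by larger count, then by
#' leftmost position), both sets are reduced to the matching sequences, and
#' the search repeats. When no candidate passes, the motif is emitted, its
#' matching sequences are removed from foreground and background, and the
#' search restarts on the remainder. The padding character `"_"` never
#' matches.
#'
#' Defaults (`pThreshold = 1e-6`, `minOcc = 20`) follow the usual motif-x
#' conventions for datasets of a few thousand sites; small synthetic runs
#' typically relax them (e.g. `1e-3` / `5`).
#'
#' @param foreground,background character vectors of flank windows of one
#'   common width `2h + 1` sharing the center-residue class.
#' @param pThreshold binomial significance threshold per step.
#' @param minOcc minimum foreground occurrences for a fixed residue.
#' @return data.frame with one row per motif: `name` (compact form such as
#'   `"RRxS"`), `pattern` (full-width, `.` wildcards), `score`
#'   (sum of -log10 step p), `fgMatches`, `fgTotal`, `nFixed`; the per-step
#'   traces are in the `steps` list-column.
#' @export
motifX <- function(foreground, background, pThreshold = 1e-6, minOcc = 20L) {
  stopIfNot(length(background) > 0, "empty background")
  stopIfNot(length(foreground) > 0, "empty foreground")
  w <- unique(nchar(c(foreground, background)))
  stopIfNot(length(w) == 1L, "mixed flank widths")
  stopIfNot(w %% 2L == 1L, "flank width must be odd")
  center <- (w + 1L) %/% 2L
  ctr <- unique(substring(foreground, center, center))
  stopIfNot(all(ctr %in% c("S", "T", "Y")),
            "foreground center residues must be S/T/Y")

  toMat <- function(x)
    matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
           nrow = length(x), ncol = w, byrow = TRUE)
  fgAll <- toMat(foreground)
  bgAll <- toMat(background)
  motifs <- list()

  repeat {
    if (nrow(fgAll) < minOcc) break
    fg <- fgAll; bg <- bgAll
    fixed <- list()   # per step: pos, res, k, n, bgFreq, p
    repeat {
      n <- nrow(fg)
      bestP <- Inf; bestK <- -1L; bestPos <- NA_integer_; bestRes <- NA
      bestQ <- NA_real_
      for (pos in setdiff(seq_len(w), center)) {
        counts <- table(fg[, pos])
        counts <- counts[names(counts) %in% .AA20]
        counts <- counts[counts >= minOcc]
        if (!length(counts)) next
        bgcol <- bg[, pos]
        nbg <- nrow(bg)
        for (res in names(counts)) {
          k <- as.integer(counts[[res]])
          q <- sum(bgcol == res) / nbg
          p <- stats::pbinom(k - 1L, n, q, lower.tail = FALSE)
          if (p < pThreshold &&
              (p < bestP ||
               (p == bestP && (k > bestK ||
                               (k == bestK && pos < bestPos))))) {
            bestP <- p; bestK <- k; bestPos <- pos; bestRes <- res
            bestQ <- q
          }
        }
      }
      if (!is.finite(bestP) || is.na(bestPos)) break
      fixed[[length(fixed) + 1L]] <- data.frame(
        position = bestPos - center, residue = bestRes, k = bestK, n = n,
        bgFreq = bestQ, p = bestP)
      fg <- fg[fg[, bestPos] == bestRes, , drop = FALSE]
      bg <- bg[bg[, bestPos] == bestRes, , drop = FALSE]
      if (nrow(bg) == 0L) break
    }
    if (!length(fixed)) break
    steps <- do.call(rbind, fixed)
    patt <- rep(".", w)
    patt[center] <- paste(sort(unique(ctr)), collapse = "")
    patt[steps$position + center] <- steps$residue
    span <- range(c(steps$position + center, center))
    name <- paste(gsub("\\.", "x", patt[span[1]:span[2]]), collapse = "")
    matchesMotif <- function(m) {
      ok <- rep(TRUE, nrow(m))
      for (s in seq_len(nrow(steps)))
        ok <- ok & m[, steps$position[s] + center] == steps$residue[s]
      ok
    }
    fgHit <- matchesMotif(fgAll)
    motifs[[length(motifs) + 1L]] <- data.frame(
      name = name, pattern = paste(patt, collapse = ""),
      score = sum(-log10(pmax(steps$p, .Machine$double.xmin))),
      fgMatches = sum(fgHit), fgTotal = nrow(fgAll),
      nFixed = nrow(steps), stringsAsFactors = FALSE)
    attr(motifs[[length(motifs)]], "steps") <- steps
    stopIfNot(sum(fgHit) > 0, "internal: motif matched no foreground")
    fgAll <- fgAll[!fgHit, , drop = FALSE]
    bgAll <- bgAll[!matchesMotif(bgAll), , drop = FALSE]
    if (nrow(bgAll) == 0L) break
  }
  if (!length(motifs))
    return(data.frame(name = character(), pattern = character(),
                      score = numeric(), fgMatches = integer(),
                      fgTotal = integer(), nFixed = integer(),
                      steps = I(list())))
  out <- do.call(rbind, motifs)
  out$steps <- I(lapply(motifs, attr, "steps"))
  out[order(-out$score), , drop = FALSE]
}

#' The shipped minimal kinase consensus-motif library
#'
#' A small library of textbook consensus patterns: basophilic PKA
#' (R at -3 and -2), proline-directed CDK (P at +1; `CDK_strict` additionally
#' requires K/R at +3), MAPK (P at -2 and +1), acidophilic CK2 (D/E at +3)
#' and the MK2/CAMK class (hydrophobic at -5 with R at -3). The library is an
#' editable YAML file (`system.file("extdata", "kinase_library.yaml",
#' package = "phosphoTMT")`); each entry lists the allowed center residues
#' and per-offset allowed residues.
#'
#' @param path optional path to an alternative YAML library.
#' @return named list of patterns (`center`, `constraints`).
#' @export
readKinaseLibrary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinase_library.yaml",
                        package = "phosphoTMT")
  lib <- yaml::read_yaml(path)
  for (nm in names(lib)) {
    k <- lib[[nm]]
    if (is.null(k$center) || is.null(k$constraints) || !length(k$constraints))
      stop("malformed kinase pattern '", nm, "'")
    offs <- suppressWarnings(as.integer(names(k$constraints)))
    if (anyNA(offs) || any(offs == 0L))
      stop("malformed constraint offsets for kinase '", nm, "'")
  }
  lib
}

#' Assign kinases to phosphosites by consensus motif (or external table)
#'
#' A kinase is assigned to a site when the site's center residue is in the
#' pattern's allowed center set and every position constraint matches the
#' flanking window (the `"_"` padding never matches). With an external
#' prediction table (columns accession, position, kinase) the library is
#' bypassed and assignments are joined on (accession, position).
#'
#' @param siteTable a [buildSiteTable()] result; ambiguous sites are skipped
#'   by default.
#' @param library kinase library as from [readKinaseLibrary()].
#' @param external optional external prediction data.frame.
#' @param includeAmbiguous also assign peptides flagged ambiguous.
#' @return data.frame with siteKey (`accession:position`), peptideId,
#'   residue, kinase; zero rows when nothing matches.
#' @export
assignKinases <- function(siteTable, library = readKinaseLibrary(),
                          external = NULL, includeAmbiguous = FALSE) {
  st <- siteTable
  if (!includeAmbiguous) st <- st[!st$ambiguous, , drop = FALSE]
  empty <- data.frame(siteKey = character(), peptideId = character(),
                      residue = character(), kinase = character())
  if (!nrow(st)) return(empty)
  key <- paste0(st$accession, ":", st$position)
  if (!is.null(external)) {
    if (!nrow(external)) return(empty)
    ekey <- paste0(external$accession, ":", external$position)
    idx <- match(ekey, key)
    ok <- !is.na(idx)
    return(data.frame(siteKey = ekey[ok], peptideId = st$peptideId[idx[ok]],
                      residue = st$residue[idx[ok]],
                      kinase = external$kinase[ok],
                      stringsAsFactors = FALSE))
  }
  w <- unique(nchar(st$flank))
  stopIfNot(length(w) == 1L, "mixed flank widths in site table")
  center <- (w + 1L) %/% 2L
  out <- list()
  for (nm in names(library)) {
    pat <- library[[nm]]
    ok <- st$residue %in% unlist(pat$center)
    for (off in names(pat$constraints)) {
      idx <- center + as.integer(off)
      if (idx < 1L || idx > w) { ok[] <- FALSE; break }
      ch <- substring(st$flank, idx, idx)
      ok <- ok & ch %in% unlist(pat$constraints[[off]])
    }
    if (any(ok))
      out[[nm]] <- data.frame(siteKey = key[ok], peptideId = st$peptideId[ok],
                              residue = st$residue[ok], kinase = nm,
                              stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cluster kinase enrichment
#'
#' For each (kinase, cluster) pair: the fold change of the in-cluster
#' proportion of kinase-assigned sites against the background proportion over
#' all assigned sites, a one-sided hypergeometric p-value, a BH q-value
#' across kinases within the cluster, and the combined score
#' `fold x (-log10 p)`; rows are ranked by the combined score. Pairs with
#' fewer than `minCount` in-cluster sites are dropped before ranking: the
#' fold of a one- or two-site overlap is numerically unstable and would
#' dominate the combined score without statistical support.
#'
#' @param assignments an [assignKinases()] result.
#' @param clusters named vector mapping peptideId to cluster label.
#' @param minCount minimum in-cluster assigned sites for a pair to be scored.
#' @return data.frame with kinase, cluster, k, n, K, N, fold, p, q, score.
#' @export
kinaseClusterEnrichment <- function(assignments, clusters, minCount = 3L) {
  a <- assignments[assignments$peptideId %in% names(clusters), , drop = FALSE]
  if (!nrow(a))
    return(data.frame(kinase = character(), cluster = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      q = numeric(), score = numeric()))
  a$cluster <- as.character(clusters[a$peptideId])
  sites <- unique(a[, c("siteKey", "cluster")])
  N <- nrow(sites)
  out <- list()
  for (cl in sort(unique(sites$cluster))) {
    n <- sum(sites$cluster == cl)
    rows <- list()
    for (kin in sort(unique(a$kinase))) {
      hitSites <- unique(a$siteKey[a$kinase == kin])
      K <- length(hitSites)
      k <- length(unique(a$siteKey[a$kinase == kin & a$cluster == cl]))
      p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
      fold <- (k / n) / (K / N)
      if (k < minCount) next
      rows[[kin]] <- data.frame(kinase = kin, cluster = cl, k = k, n = n,
                                K = K, N = N, fold = fold, p = p,
                                stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    block <- do.call(rbind, rows)
    block$q <- stats::p.adjust(block$p, method = "BH")
    out[[cl]] <- block
  }
  if (!length(out))
    return(data.frame(kinase = character(), cluster = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      q = numeric(), score = numeric()))
  res <- do.call(rbind, out)
  res$score <- res$fold * (-log10(pmax(res$p, .Machine$double.xmin)))
  res <- res[order(-res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Over-representation analysis of annotation sets
#'
#' One-sided hypergeometric test of each annotation term in a cluster's
#' protein set against a background protein set, with BH correction across
#' terms; ranked by p-value. Terms without background overlap are skipped.
#'
#' @param clusterProteins character vector of foreground protein identifiers
#'   (must be a subset of the background).
#' @param backgroundProteins character vector of background identifiers.
#' @param annotationSets a [readGmt()] result.
#' @return data.frame with term, description, k, n, K, N, fold, p, q.
#' @export
annotationOra <- function(clusterProteins, backgroundProteins,
                          annotationSets) {
  bg <- unique(backgroundProteins)
  fg <- unique(clusterProteins)
  stopIfNot(all(fg %in% bg), "cluster proteins must be a subset of background")
  N <- length(bg); n <- length(fg)
  rows <- list(); skipped <- character()
  for (term in names(annotationSets)) {
    members <- intersect(annotationSets[[term]]$members, bg)
    K <- length(members)
    if (K == 0L) { skipped <- c(skipped, term); next }
    k <- length(intersect(members, fg))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[term]] <- data.frame(
      term = term, description = annotationSets[[term]]$description,
      k = k, n = n, K = K, N = N, fold = (k / n) / (K / N), p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(term = character(), description = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      q = numeric())
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
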