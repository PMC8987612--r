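#' Two-sample test with automatic Welch correction
#'
#' Performs a two-sided two-sample t test on (log2-scale) relative abundances.
#' A pooled-variance Student's t test is used when a two-sided F test of
#' variance equality is not rejected at `varAlpha`; otherwise Welch's t test
#' with Welch-Satterthwaite degrees of freedom is used.
#'
#' @param a,b numeric vectors (each of length >= 2, finite).
#' @param varAlpha significance level of the variance-equality F test.
#' @return list with `t`, `df`, `p` and `test` (`"student"` or `"welch"`).
#' @export
twoSampleTest <- function(a, b, varAlpha = 0.05) {
  stopIfNot(length(a) >= 2 && length(b) >= 2,
            "each group needs at least 2 values")
  stopIfNot(all(is.finite(a)) && all(is.finite(b)),
            "values must be finite")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  test = "student"))
    # degenerate separation: maximal evidence, smallest representable p
    return(list(t = sign(mean(b) - mean(a)) * Inf,
                df = length(a) + length(b) - 2L,
                p = .Machine$double.xmin, test = "student"))
  }
  welch <- if (va == 0 || vb == 0) TRUE else
    stats::var.test(a, b)$p.value < varAlpha
  ht <- stats::t.test(b, a, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, test = if (welch) "welch" else "student")
}

#' Log2 fold change between group means
#'
#' `log2(mean(treated) / mean(reference))` on the linear relative-abundance
#' scale.
#'
#' @param reference,treated numeric vectors with positive means.
#' @return the log2 fold change.
#' @export
log2FoldChange <- function(reference, treated) {
  mr <- mean(reference); mt <- mean(treated)
  stopIfNot(mr > 0 && mt > 0, "group means must be positive")
  log2(mt / mr)
}

#' Pi-score prioritization statistic
#'
#' Combines fold change and significance into one signed value:
#' `pi = log2fc * (-log10 p)`. A p-value of exactly zero is clamped to the
#' smallest representable double with a warning.
#'
#' @param p p-value in (0, 1].
#' @param log2fc log2 fold change.
#' @return the pi-score.
#' @export
piScore <- function(p, log2fc) {
  if (any(p == 0)) {
    warning("p-value of 0 clamped to machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  stopIfNot(all(p > 0 & p <= 1), "p must lie in (0, 1]")
  log2fc * (-log10(p))
}

#' Default condition comparisons
#'
#' Thrombin response in the vehicle arm, thrombin response in the inhibitor
#' arm, and the inhibitor contrast between stimulated arms. In each label the
#' first condition is the treated group and the second the reference.
#' @return named list of `c(ref = , trt = )` pairs.
#' @export
defaultComparisons <- function() {
  list(DMSO_Th10_vs_DMSO_0 = c(ref = "DMSO_0", trt = "DMSO_Th10"),
       SB_Th10_vs_SB_0 = c(ref = "SB_0", trt = "SB_Th10"),
       DMSO_Th10_vs_SB_Th10 = c(ref = "SB_Th10", trt = "DMSO_Th10"))
}

#' Per-phosphopeptide differential statistics
#'
#' For every row and comparison: the log2 fold change of linear group means,
#' a two-sample t test on log2-transformed relative abundances (Student or
#' Welch, chosen by an F test of variance equality), the pi-score, a
#' Benjamini-Hochberg q-value per comparison, and the significance call at
#' `p < alpha`. Rows with a missing or nonpositive value in a compared
#' condition are excluded from that comparison (missing values are never
#' imputed as zero).
#'
#' @param object a [TMTQuant-class], normally at stage `"protein_corrected"`.
#' @param comparisons named list as from [defaultComparisons()].
#' @param alpha significance threshold on the raw p-value (default 0.01).
#' @return data.frame with one row per (phosphopeptide, comparison):
#'   id, accession, comparison, log2fc, t, df, pvalue, qvalue, test,
#'   piScore, significant, direction.
#' @export
differentialTest <- function(object, comparisons = defaultComparisons(),
                             alpha = 0.01) {
  layout <- colData(object)
  vals <- quantValues(object)
  rd <- rowData(object)
  ids <- rownames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(vals)))
  out <- list()
  for (lab in names(comparisons)) {
    cmp <- comparisons[[lab]]
    refCols <- conditionColumns(layout, cmp[["ref"]])
    trtCols <- conditionColumns(layout, cmp[["trt"]])
    stopIfNot(length(refCols) >= 2 && length(trtCols) >= 2,
              "comparison ", lab, " needs >= 2 replicates per group")
    sub <- vals[, c(refCols, trtCols), drop = FALSE]
    usable <- which(apply(sub, 1L, function(v) all(is.finite(v) & v > 0)))
    n <- length(usable)
    lfc <- tval <- dfv <- pv <- piv <- numeric(n)
    tst <- character(n)
    for (j in seq_len(n)) {
      i <- usable[j]
      refV <- vals[i, refCols]
      trtV <- vals[i, trtCols]
      ht <- twoSampleTest(log2(refV), log2(trtV))
      lfc[j] <- log2FoldChange(refV, trtV)
      tval[j] <- ht$t; dfv[j] <- ht$df; pv[j] <- ht$p; tst[j] <- ht$test
      piv[j] <- piScore(ht$p, lfc[j])
    }
    out[[lab]] <- data.frame(
      id = ids[usable],
      accession = if ("accession" %in% colnames(rd))
        rd$accession[usable] else NA_character_,
      comparison = lab,
      log2fc = lfc, t = tval, df = dfv, pvalue = pv,
      qvalue = stats::p.adjust(pv, method = "BH"),
      test = tst, piScore = piv,
      significant = pv < alpha,
      direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Significant up/down sets for one comparison
#'
#' Partitions the significant results (`p < alpha`) of one comparison by
#' direction and counts phosphopeptides and deduplicated unique proteins in
#' each direction.
#'
#' @param results a [differentialTest()] result.
#' @param comparison comparison label; required if `results` spans several.
#' @param alpha significance threshold (default 0.01).
#' @return list with `up`/`down` id vectors and a `counts` vector
#'   (peptidesUp, peptidesDown, proteinsUp, proteinsDown, total).
#' @export
significantSets <- function(results, comparison = NULL, alpha = 0.01) {
  if (!is.null(comparison))
    results <- results[results$comparison == comparison, , drop = FALSE]
  stopIfNot(length(unique(results$comparison)) <= 1L,
            "results span several comparisons; pick one")
  sig <- results[results$pvalue < alpha, , drop = FALSE]
  up <- sig[sig$log2fc > 0, , drop = FALSE]
  down <- sig[sig$log2fc < 0, , drop = FALSE]
  list(up = up$id, down = down$id,
       counts = c(peptidesUp = nrow(up), peptidesDown = nrow(down),
                  proteinsUp = length(unique(up$accession)),
                  proteinsDown = length(unique(down$accession)),
                  total = nrow(sig)))
}

#' Union of significant phosphopeptides across comparisons
#'
#' The default clustering input: ids significant (`p < alpha`) in at least one
#' comparison.
#' @inheritParams significantSets
#' @return character vector of ids.
#' @export
significantIds <- function(results, alpha = 0.01) {
  unique(results$id[results$pvalue < alpha])
}

#' Per-site condition summary with two-factor ANOVA
#'
#' Expresses one phosphopeptide's channels as relative abundance scaled to
#' the vehicle 0-min mean, summarizes mean and SD per condition, and runs a
#' two-factor ANOVA (pretreatment x stimulation, sequential sums of squares)
#' across the sample channels.
#'
#' @param object a [TMTQuant-class].
#' @param id row name of the phosphopeptide.
#' @return list with `summary` (data.frame condition, mean, sd, n) and
#'   `anova` (data.frame term, F, p).
#' @export
perSiteSummary <- function(object, id) {
  layout <- colData(object)
  vals <- quantValues(object)
  stopIfNot(id %in% rownames(vals), "row '", id, "' not found")
  v <- vals[id, ]
  keep <- which(!layout$isBridge & is.finite(v))
  conds <- setdiff(.CONDITIONS, "BRIDGE")
  stopIfNot(all(conds %in% layout$condition[keep]),
            "a condition is missing for row '", id, "'")
  ref <- mean(v[conditionColumns(layout, "DMSO_0")])
  stopIfNot(is.finite(ref) && ref > 0, "vehicle 0-min mean must be positive")
  relAb <- v[keep] / ref
  cond <- layout$condition[keep]
  smry <- do.call(rbind, lapply(conds, function(cn) data.frame(
    condition = cn, mean = mean(relAb[cond == cn]),
    sd = stats::sd(relAb[cond == cn]), n = sum(cond == cn))))
  pre <- factor(ifelse(grepl("^SB", cond), "SB", "DMSO"))
  stim <- factor(ifelse(grepl("Th10$", cond), "10", "0"))
  if (stats::var(relAb) == 0) {
    an <- data.frame(term = c("pretreatment", "stimulation", "interaction"),
                     F = 0, p = 1)
  } else {
    fit <- stats::aov(relAb ~ pre * stim)
    tab <- summary(fit)[[1]]
    an <- data.frame(term = c("pretreatment", "stimulation", "interaction"),
                     F = tab[1:3, "F value"], p = tab[1:3, "Pr(>F)"])
  }
  rownames(an) <- NULL
  list(summary = smry, anova = an)
}
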