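#' Filter phosphosites by localization confidence
#'
#' Retains phosphosites whose localization score is strictly greater than the
#' threshold (default 50 percent, the usual confidence cutoff). Filtering acts
#' on the site annotation only: peptides that lose all sites are excluded from
#' site-level analyses (their confident-site lists become empty) but remain in
#' the table for quantitation.
#'
#' @param object a [TMTQuant-class] with site list-columns.
#' @param threshold retain sites with score `> threshold` (percent).
#' @return the object with added rowData list-columns `confPos`/`confRes`
#'   (confidently localized positions/residues) and logical `anyConfident`.
#' @export
filterLocalization <- function(object, threshold = 50) {
  rd <- rowData(object)
  n <- nrow(rd)
  confPos <- vector("list", n); confRes <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- which(rd$siteScore[[i]] > threshold)
    confPos[[i]] <- rd$sitePos[[i]][keep]
    confRes[[i]] <- rd$siteRes[[i]][keep]
  }
  rd$confPos <- IRanges::IntegerList(confPos)
  rd$confRes <- IRanges::CharacterList(confRes)
  rd$anyConfident <- lengths(confPos) > 0L
  if (any(rd$isPhospho) && !any(rd$anyConfident[rd$isPhospho]))
    warning("no phosphosite passed the localization threshold of ", threshold)
  rowData(object) <- rd
  object
}

#' Map a peptide onto its protein by exact substring search
#'
#' Returns all 1-based offsets at which the peptide occurs in the protein
#' sequence. The absolute position of a peptide-relative site is
#' `offset + position - 1`.
#'
#' @param peptide peptide sequence (uppercase).
#' @param protein protein sequence (character or `AAString`).
#' @return integer vector of match offsets (empty if unmapped).
#' @export
mapPeptideToProtein <- function(peptide, protein) {
  hits <- gregexpr(peptide, as.character(protein), fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Extract the flanking window around a protein position
#'
#' Returns the inclusive substring `[position - h, position + h]`, padded
#' with `"_"` where the window runs past a terminus, so the result always has
#' length `2h + 1` with the site residue at its center.
#'
#' @param protein protein sequence (character or `AAString`).
#' @param position 1-based site position within the protein.
#' @param h half-width of the window (default 6, a 13-mer).
#' @return the flank string.
#' @export
extractFlank <- function(protein, position, h = 6L) {
  seq <- as.character(protein)
  len <- nchar(seq)
  stopIfNot(position >= 1L && position <= len,
            "position ", position, " outside protein of length ", len)
  lo <- max(1L, position - h)
  hi <- min(len, position + h)
  paste0(strrep("_", lo - (position - h)),
         substr(seq, lo, hi),
         strrep("_", (position + h) - hi))
}

#' Build a protein-coordinate site table with flanking windows
#'
#' For every confidently localized site of every phosphopeptide row, maps the
#' peptide into its protein by exact search, converts the peptide-relative
#' position to protein coordinates and extracts the flanking window. Peptides
#' matching at several offsets use the first (lowest) offset and are flagged
#' ambiguous (excluded from motif analyses by default); unmapped peptides are
#' dropped and counted.
#'
#' @param object a localization-filtered [TMTQuant-class] (see
#'   [filterLocalization()]).
#' @param proteins an [Biostrings::AAStringSet] protein database.
#' @param h flank half-width (default 6).
#' @return a data.frame with columns peptideId, accession, position, residue,
#'   score, flank, ambiguous; unmapped row count in `attr(x, "unmapped")`.
#' @export
buildSiteTable <- function(object, proteins, h = 6L) {
  rd <- rowData(object)
  stopIfNot(!is.null(rd$confPos), "run filterLocalization() first")
  seqs <- as.character(proteins)
  rows <- vector("list", nrow(rd))
  unmapped <- 0L
  for (i in which(rd$isPhospho & rd$anyConfident)) {
    acc <- rd$accession[i]
    if (!acc %in% names(seqs)) { unmapped <- unmapped + 1L; next }
    prot <- seqs[[acc]]
    offs <- mapPeptideToProtein(rd$peptide[i], prot)
    if (!length(offs)) { unmapped <- unmapped + 1L; next }
    pos <- offs[1] + rd$confPos[[i]] - 1L
    # score of the retained sites, aligned with confPos
    keep <- match(rd$confPos[[i]], rd$sitePos[[i]])
    rows[[i]] <- data.frame(
      peptideId = if ("peptideId" %in% colnames(rd)) rd$peptideId[i]
                  else rownames(rd)[i],
      accession = acc,
      position = pos,
      residue = rd$confRes[[i]],
      score = rd$siteScore[[i]][keep],
      flank = vapply(pos, function(p) extractFlank(prot, p, h), ""),
      ambiguous = length(offs) > 1L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(peptideId = character(), accession = character(),
                      position = integer(), residue = character(),
                      score = numeric(), flank = character(),
                      ambiguous = logical())
  attr(out, "unmapped") <- unmapped
  out
}

#' Descriptive phosphosite statistics
#'
#' Computes the S/T/Y residue proportions over confidently localized sites
#' and the 1/2/3+ sites-per-peptide proportions over phosphopeptides with at
#' least one confident site.
#'
#' @param object a localization-filtered phosphopeptide [TMTQuant-class].
#' @return list with `residueProportions` (named S/T/Y) and
#'   `sitesPerPeptide` (named "1","2","3+"); each sums to 1.
#' @export
siteStatistics <- function(object) {
  rd <- rowData(object)
  stopIfNot(!is.null(rd$confPos), "run filterLocalization() first")
  phos <- which(rd$isPhospho & rd$anyConfident)
  stopIfNot(length(phos) > 0, "no confidently localized phosphosites")
  res <- unlist(as.list(rd$confRes[phos]), use.names = FALSE)
  rp <- c(S = sum(res == "S"), T = sum(res == "T"), Y = sum(res == "Y"))
  rp <- rp / sum(rp)
  ns <- lengths(rd$confPos[phos])
  sp <- c("1" = sum(ns == 1L), "2" = sum(ns == 2L), "3+" = sum(ns >= 3L))
  sp <- sp / sum(sp)
  list(residueProportions = rp, sitesPerPeptide = sp)
}
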