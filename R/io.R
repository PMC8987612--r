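#' Read a peptide-level quantitation table
#'
#' Parses a delimited text export of peptide/PSM level reporter-ion
#' quantitation into a [TMTQuant-class] object at stage `"raw"`. The expected
#' schema has one metadata column each for PSM id, peptide sequence, protein
#' accession and phospho flag, a `sites` column with peptide-relative site
#' strings such as `"S5; T9"`, a matching `site_scores` column with
#' localization scores in percent (`"99.2; 61.0"`), and one numeric column per
#' channel named `<plex>.<reporter>` (e.g. `1.126`). Third-party exports with
#' different headers are adapted through `dialect`, a named list remapping any
#' of `psm`, `peptide`, `accession`, `phospho`, `sites`, `scores` to the
#' actual column names.
#'
#' Empty cells are read as missing (`NA`), never as zero; downstream tests
#' exclude rows with missing values in a compared condition.
#'
#' @param path file path of the delimited table.
#' @param layout a channel layout as returned by [readChannelLayout()]; the
#'   channel columns of the file must match `<plex>.<reporter>` of its rows.
#' @param dialect optional named list of column-name overrides.
#' @param sep field separator, default tab.
#' @return a [TMTQuant-class] with stage `"raw"`.
#' @export
readQuantTable <- function(path, layout, dialect = list(), sep = "\t") {
  cols <- list(psm = "psm_id", peptide = "peptide", accession = "accession",
               phospho = "phospho", sites = "sites", scores = "site_scores")
  cols[names(dialect)] <- dialect
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(cols))
    if (!cols[[nm]] %in% colnames(df))
      stop("quantitation table is missing required column '", cols[[nm]], "'")
  layout <- as(layout, "DataFrame")
  chan <- paste(layout$plex, layout$reporter, sep = ".")
  miss <- setdiff(chan, colnames(df))
  if (length(miss))
    stop("quantitation table is missing channel column(s): ",
         paste(miss, collapse = ", "))
  values <- as.matrix(df[, chan, drop = FALSE])
  mode(values) <- "double"
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity at row ", neg[1, 1], ", channel ",
         chan[neg[1, 2]])
  parsed <- parseSiteStrings(df[[cols$sites]], df[[cols$scores]])
  rd <- DataFrame(
    psmId = as.character(df[[cols$psm]]),
    peptide = toupper(as.character(df[[cols$peptide]])),
    accession = as.character(df[[cols$accession]]),
    isPhospho = as.logical(df[[cols$phospho]]),
    sitePos = parsed$pos, siteRes = parsed$res, siteScore = parsed$score
  )
  rownames(rd) <- make.unique(rd$psmId)
  TMTQuant(values, rd, layout, stage = "raw")
}

# "S5; T9" + "99.2; 61" -> parallel lists of positions, residues, scores
parseSiteStrings <- function(sites, scores) {
  n <- length(sites)
  pos <- vector("list", n); res <- vector("list", n); sco <- vector("list", n)
  for (i in seq_len(n)) {
    s <- trimws(strsplit(as.character(sites[i]), ";", fixed = TRUE)[[1]])
    s <- s[nzchar(s)]
    if (!length(s)) {
      pos[[i]] <- integer(); res[[i]] <- character(); sco[[i]] <- numeric()
      next
    }
    if (!all(grepl("^[STY][0-9]+$", s)))
      stop("malformed site string at row ", i, ": '", sites[i], "'")
    sc <- trimws(strsplit(as.character(scores[i]), ";", fixed = TRUE)[[1]])
    sc <- suppressWarnings(as.numeric(sc[nzchar(sc)]))
    if (length(sc) != length(s) || anyNA(sc))
      stop("site/score count mismatch at row ", i)
    pos[[i]] <- as.integer(sub("^[STY]", "", s))
    res[[i]] <- substring(s, 1L, 1L)
    sco[[i]] <- sc
  }
  list(pos = IRanges::IntegerList(pos), res = IRanges::CharacterList(res),
       score = IRanges::NumericList(sco))
}

#' Read a channel-layout configuration
#'
#' The layout is a YAML map `plexes -> plex id -> reporter -> sample`, where
#' `sample` is either the literal `BRIDGE` or `<condition>.<replicate>` with
#' condition one of `DMSO_0`, `SB_0`, `DMSO_Th10`, `SB_Th10`. Every plex must
#' carry exactly one bridge channel and every non-bridge condition needs at
#' least two replicates across the layout.
#'
#' @param path YAML file path.
#' @return a `DataFrame` with columns plex, reporter, condition, replicate,
#'   isBridge.
#' @export
readChannelLayout <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$plexes) || !length(doc$plexes))
    stop("layout file defines no plexes")
  rows <- list()
  for (plex in names(doc$plexes)) {
    plexMap <- doc$plexes[[plex]]
    if (!length(plexMap)) stop("plex ", plex, " has no channels")
    for (rep in names(plexMap)) {
      val <- as.character(plexMap[[rep]])
      if (identical(val, "BRIDGE")) {
        rows[[length(rows) + 1L]] <- data.frame(
          plex = plex, reporter = rep, condition = "BRIDGE",
          replicate = NA_integer_, isBridge = TRUE)
      } else {
        m <- regmatches(val, regexec("^([A-Za-z0-9_]+)\\.([0-9]+)$", val))[[1]]
        if (length(m) != 3L || !m[2] %in% setdiff(.CONDITIONS, "BRIDGE"))
          stop("malformed sample '", val, "' in plex ", plex,
               " (expected <condition>.<replicate> or BRIDGE)")
        rows[[length(rows) + 1L]] <- data.frame(
          plex = plex, reporter = rep, condition = m[2],
          replicate = as.integer(m[3]), isBridge = FALSE)
      }
    }
  }
  layout <- do.call(rbind, rows)
  validateChannelLayout(layout)
  as(layout, "DataFrame")
}

validateChannelLayout <- function(layout) {
  if (anyDuplicated(paste(layout$plex, layout$reporter)))
    stop("duplicate (plex, reporter) pair in layout")
  nb <- tapply(layout$isBridge, layout$plex, sum)
  if (any(nb == 0L))
    stop("plex ", names(nb)[which(nb == 0L)[1]], " has no bridge channel")
  if (any(nb > 1L))
    stop("plex ", names(nb)[which(nb > 1L)[1]],
         " has more than one bridge channel")
  tab <- table(layout$condition[!layout$isBridge])
  low <- names(tab)[tab < 2L]
  if (length(low))
    stop("condition ", low[1], " has fewer than 2 replicates in the layout")
  if (anyDuplicated(paste(layout$condition, layout$replicate)[!layout$isBridge]))
    stop("duplicate (condition, replicate) sample in layout")
  invisible(layout)
}

#' Write a channel layout to the YAML format read by [readChannelLayout()]
#' @param layout a layout `DataFrame`/`data.frame`.
#' @param path output path.
#' @export
writeChannelLayout <- function(layout, path) {
  plexes <- list()
  for (i in seq_len(nrow(layout))) {
    p <- as.character(layout$plex[i])
    v <- if (layout$isBridge[i]) "BRIDGE" else
      paste0(layout$condition[i], ".", layout$replicate[i])
    plexes[[p]][[as.character(layout$reporter[i])]] <- v
  }
  yaml::write_yaml(list(plexes = plexes), path)
  invisible(path)
}

#' Read a protein FASTA into a protein database
#'
#' The accession is the first whitespace-delimited token of each header.
#' Sequences must be non-empty over the 20 standard residues (plus `X`).
#'
#' @param path FASTA file path.
#' @return an [Biostrings::AAStringSet] keyed by accession.
#' @export
readFasta <- function(path) {
  db <- Biostrings::readAAStringSet(path)
  names(db) <- vapply(strsplit(names(db), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(db)))
    stop("duplicate accession in FASTA: ",
         names(db)[duplicated(names(db))][1])
  if (any(Biostrings::width(db) == 0L))
    stop("FASTA record with empty sequence: ",
         names(db)[Biostrings::width(db) == 0L][1])
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]",
               as.character(db))
  if (any(bad))
    stop("non-standard residue in sequence for ", names(db)[bad][1])
  db
}

#' Read a GMT annotation-set file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' members. Members are deduplicated; a line without members is an error.
#'
#' @param path GMT file path.
#' @return named list of terms; each element has `description` and `members`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file")
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line for term '", f[1], "' has no members")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT line for term '", f[1], "' has no members")
    sets[[f[1]]] <- list(description = f[2], members = members)
  }
  sets
}

#' Write pipeline result tables plus a run manifest
#'
#' Each element of `tables` is written as a TSV with its columns in the given
#' order; numeric content is deterministic for identical inputs. A
#' `manifest.json` records the seed, a hash of the configuration, the package
#' version and the MD5 of every written file.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory (created if needed).
#' @param seed integer seed recorded in the manifest.
#' @param config optional configuration object hashed into the manifest.
#' @return invisibly, the manifest as a list.
#' @export
writeResults <- function(tables, outDir, seed = NA_integer_, config = NULL) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(outDir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[nm] <- p
  }
  cfgHash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                force = TRUE), tmp)
    cfgHash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(
    package = "phosphoTMT",
    version = as.character(utils::packageVersion("phosphoTMT")),
    seed = seed,
    configHash = cfgHash,
    files = lapply(paths, function(p) list(path = basename(p),
                                           md5 = unname(tools::md5sum(p))))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outDir, "manifest.json"))
  invisible(manifest)
}

#' Write a TMTQuant object as a TSV readable by [readQuantTable()]
#' @param object a [TMTQuant-class].
#' @param path output path.
#' @export
writeQuantTable <- function(object, path) {
  rd <- rowData(object)
  siteStr <- vapply(seq_len(nrow(rd)), function(i)
    paste0(rd$siteRes[[i]], rd$sitePos[[i]], collapse = "; "), "")
  scoreStr <- vapply(seq_len(nrow(rd)), function(i)
    paste0(format(rd$siteScore[[i]], digits = 15, trim = TRUE),
           collapse = "; "), "")
  df <- data.frame(psm_id = rd$psmId, peptide = rd$peptide,
                   accession = rd$accession,
                   phospho = as.integer(rd$isPhospho),
                   sites = siteStr, site_scores = scoreStr,
                   check.names = FALSE)
  vals <- quantValues(object)
  for (j in seq_len(ncol(vals)))
    df[[colnames(vals)[j]]] <- format(vals[, j], digits = 15, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
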