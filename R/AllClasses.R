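#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
NULL

.STAGES <- c("raw", "bridge_normalized", "median_normalized",
             "peptide_aggregated", "protein_corrected")

.CONDITIONS <- c("DMSO_0", "SB_0", "DMSO_Th10", "SB_Th10", "BRIDGE")

#' TMTQuant: a reporter-ion quantitation container
#'
#' `TMTQuant` extends [SummarizedExperiment::SummarizedExperiment] and holds a
#' peptide (or PSM, or protein) by channel matrix of TMT reporter-ion values
#' together with peptide metadata (`rowData`) and the channel layout
#' (`colData`: plex, reporter, condition, replicate, bridge flag). A stage tag
#' records where the object sits in the normalization chain; transitions are
#' only allowed along `raw -> bridge_normalized -> median_normalized ->
#' peptide_aggregated -> protein_corrected`.
#'
#' @slot stage character(1), one of the five processing stages.
#'
#' @seealso [TMTQuant()], [bridgeNormalize()], [medianNormalize()]
#' @export
setClass("TMTQuant",
  contains = "SummarizedExperiment",
  slots = c(stage = "character"),
  prototype = prototype(stage = "raw")
)

setValidity("TMTQuant", function(object) {
  msg <- character()
  if (length(object@stage) != 1L || !object@stage %in% .STAGES)
    msg <- c(msg, sprintf("stage must be one of: %s",
                          paste(.STAGES, collapse = ", ")))
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' is required")
  x <- SummarizedExperiment::assay(object, "signal")
  if (any(x < 0, na.rm = TRUE))
    msg <- c(msg, "reporter values must be >= 0")
  cd <- SummarizedExperiment::colData(object)
  need <- c("plex", "reporter", "condition", "replicate", "isBridge")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, sprintf("colData must contain: %s",
                          paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(paste(cd$plex, cd$reporter)))
      msg <- c(msg, "(plex, reporter) pairs must be unique")
    if (!all(cd$condition %in% .CONDITIONS))
      msg <- c(msg, sprintf("conditions must be in {%s}",
                            paste(.CONDITIONS, collapse = ", ")))
    if (object@stage == "raw" && nrow(cd) > 0L) {
      nb <- tapply(cd$isBridge, cd$plex, sum)
      if (any(nb != 1L))
        msg <- c(msg, "each plex must carry exactly one bridge channel at stage 'raw'")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (all(c("sitePos", "siteRes", "siteScore") %in% colnames(rd)) &&
      "peptide" %in% colnames(rd) && nrow(rd) > 0L) {
    pos <- rd$sitePos
    res <- rd$siteRes
    sco <- rd$siteScore
    pep <- as.character(rd$peptide)
    for (i in seq_len(nrow(rd))) {
      pi <- pos[[i]]
      if (length(pi) == 0L) next
      if (any(pi < 1L | pi > nchar(pep[i]))) {
        msg <- c(msg, sprintf("row %d: site position outside peptide", i))
        break
      }
      if (any(substring(pep[i], pi, pi) != res[[i]])) {
        msg <- c(msg, sprintf(
          "row %d: peptide residue does not match annotated phosphosite residue", i))
        break
      }
      if (any(sco[[i]] < 0 | sco[[i]] > 100)) {
        msg <- c(msg, sprintf("row %d: localization score outside [0,100]", i))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TMTQuant object
#'
#' @param values numeric matrix, peptides/PSMs x channels, reporter
#'   signal-to-noise (raw) or relative abundance (normalized). `NA` encodes a
#'   missing measurement; negative values are rejected.
#' @param rowData a `DataFrame`/`data.frame` of per-row metadata. For
#'   phosphopeptide tables the columns `peptide`, `accession`, `psmId`,
#'   `isPhospho` and the site list-columns `sitePos` (integer positions,
#'   1-based within the peptide), `siteRes` (residue, one of S/T/Y) and
#'   `siteScore` (localization score in percent) are expected.
#' @param layout channel layout with columns plex, reporter, condition,
#'   replicate, isBridge; one row per column of `values` (see
#'   [readChannelLayout()]).
#' @param stage processing-stage tag.
#' @return a [TMTQuant-class] object.
#' @export
TMTQuant <- function(values, rowData, layout, stage = "raw") {
  values <- as.matrix(values)
  mode(values) <- "double"
  layout <- as(layout, "DataFrame")
  if (nrow(layout) != ncol(values))
    stop("layout has ", nrow(layout), " channels but values has ",
         ncol(values), " columns")
  cn <- paste(layout$plex, layout$reporter, sep = ".")
  colnames(values) <- cn
  rownames(layout) <- cn
  se <- SummarizedExperiment(
    assays = list(signal = values),
    rowData = as(rowData, "DataFrame"),
    colData = layout
  )
  new("TMTQuant", se, stage = stage)
}

#' @describeIn TMTQuant processing-stage tag of the object.
#' @param object,x a `TMTQuant` object.
#' @export
setGeneric("quantStage", function(object) standardGeneric("quantStage"))

#' @rdname TMTQuant
#' @export
setMethod("quantStage", "TMTQuant", function(object) object@stage)

#' @describeIn TMTQuant the channel layout (colData) as a `DataFrame`.
#' @export
setGeneric("channelLayout", function(object) standardGeneric("channelLayout"))

#' @rdname TMTQuant
#' @export
setMethod("channelLayout", "TMTQuant", function(object)
  SummarizedExperiment::colData(object))

#' @describeIn TMTQuant the reporter-value matrix (assay `"signal"`).
#' @export
setGeneric("quantValues", function(object) standardGeneric("quantValues"))

#' @rdname TMTQuant
#' @export
setMethod("quantValues", "TMTQuant", function(object)
  SummarizedExperiment::assay(object, "signal"))

setMethod("show", "TMTQuant", function(object) {
  cat(sprintf("TMTQuant [stage: %s] %d rows x %d channels (%d plex%s)\n",
              object@stage, nrow(object), ncol(object),
              length(unique(colData(object)$plex)),
              if (length(unique(colData(object)$plex)) == 1L) "" else "es"))
  tab <- table(colData(object)$condition)
  cat("  channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  rd <- rowData(object)
  if ("isPhospho" %in% colnames(rd))
    cat(sprintf("  phosphopeptide rows: %d / %d\n", sum(rd$isPhospho),
                nrow(rd)))
})

# stage transitions follow the fixed chain; called by each normalization step
.advanceStage <- function(object, to) {
  from <- object@stage
  if (match(to, .STAGES) != match(from, .STAGES) + 1L)
    stop("invalid stage transition: ", from, " -> ", to)
  object@stage <- to
  object
}

#' ClusterModel: a fitted k-means temporal clustering
#'
#' Holds the cluster count, row assignments, centroids and the within-cluster
#' sum of squares of the best restart, plus the seed/restart bookkeeping that
#' makes the fit reproducible.
#'
#' @slot k integer cluster count.
#' @slot assignments named integer vector, row id -> cluster in 1..k.
#' @slot centroids k x p numeric matrix.
#' @slot wss total within-cluster sum of squares of the selected fit.
#' @slot seed,restarts RNG seed and number of random restarts used.
#' @export
setClass("ClusterModel",
  slots = c(k = "integer", assignments = "integer", centroids = "matrix",
            wss = "numeric", seed = "integer", restarts = "integer")
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (length(object@assignments) &&
      !all(object@assignments %in% seq_len(object@k)))
    msg <- c(msg, "assignments must lie in 1..k")
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterModel", function(object) {
  sizes <- tabulate(object@assignments, nbins = object@k)
  cat(sprintf("ClusterModel: k = %d, n = %d, total WSS = %.4g\n",
              object@k, length(object@assignments), object@wss))
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
})

#' @describeIn ClusterModel cluster assignments as a named integer vector.
#' @param object a `ClusterModel`.
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname ClusterModel
#' @export
setMethod("clusterAssignments", "ClusterModel",
          function(object) object@assignments)

#' @describeIn ClusterModel centroid matrix (k x profile length).
#' @export
setGeneric("clusterCentroids",
           function(object) standardGeneric("clusterCentroids"))

#' @rdname ClusterModel
#' @export
setMethod("clusterCentroids", "ClusterModel", function(object) object@centroids)
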