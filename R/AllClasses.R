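#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData
NULL

#' Normalization parameters for qPCR panel data
#'
#' Holds the settings used to turn raw Cq values into delta-Cq values: the
#' normalization method, the reference (internal control) assays, and the
#' detection cutoff in PCR cycles.
#'
#' @slot method Either \code{"internal_control"} (delta-Cq relative to the
#'   mean Cq of the control assays detected in the same sample) or
#'   \code{"global_mean"} (relative to the mean of all detected assays in
#'   the sample).
#' @slot controlAssays Character vector of control assay identifiers; must
#'   be non-empty for the internal-control method.
#' @slot maxCycles Detection cutoff in cycles; Cq values at or above this
#'   are treated as absent.
#'
#' @seealso [normParams()], [normalizeCq()], [applyDetectionFilter()]
#' @exportClass NormParams
setClass("NormParams",
  slots = c(method = "character",
            controlAssays = "character",
            maxCycles = "numeric"))

setValidity("NormParams", function(object) {
  msg <- character()
  if (length(object@method) != 1L ||
      !object@method %in% c("internal_control", "global_mean"))
    msg <- c(msg, "method must be 'internal_control' or 'global_mean'")
  if (identical(object@method, "internal_control") &&
      length(object@controlAssays) == 0L)
    msg <- c(msg, "controlAssays must be non-empty for internal_control")
  if (length(object@maxCycles) != 1L || !is.finite(object@maxCycles) ||
      object@maxCycles <= 0)
    msg <- c(msg, "maxCycles must be a single positive number")
  if (anyDuplicated(object@controlAssays))
    msg <- c(msg, "controlAssays must be unique")
  if (length(msg)) msg else TRUE
})

#' The five internal-control miRNAs of the serum/plasma focus panel
#'
#' Reference miRNAs used for internal-control delta-Cq normalization of the
#' 179-assay serum/plasma qPCR panel. These were selected in the source
#' study from the literature as stably expressed in plasma.
#'
#' @return Character vector of five assay identifiers.
#' @examples
#' defaultControlAssays()
#' @export
defaultControlAssays <- function() {
  c("hsa-miR-425-5p", "hsa-miR-423-5p", "hsa-miR-103a-3p",
    "hsa-miR-191-5p", "hsa-miR-93-5p")
}

#' Construct normalization parameters
#'
#' @param method Normalization method, \code{"internal_control"} (default)
#'   or \code{"global_mean"}.
#' @param controlAssays Control assay identifiers; defaults to the five
#'   plasma internal-control miRNAs ([defaultControlAssays()]).
#' @param maxCycles Detection cutoff in PCR cycles (default 40); targets
#'   whose amplification has not crossed the threshold after this many
#'   cycles are considered absent.
#'
#' @return A [NormParams-class] object.
#' @examples
#' normParams()
#' normParams("global_mean", maxCycles = 35)
#' @export
normParams <- function(method = c("internal_control", "global_mean"),
                       controlAssays = defaultControlAssays(),
                       maxCycles = 40) {
  method <- match.arg(method)
  new("NormParams", method = method, controlAssays = as.character(controlAssays),
      maxCycles = maxCycles)
}

setMethod("show", "NormParams", function(object) {
  cat("NormParams:", object@method, "\n")
  if (identical(object@method, "internal_control"))
    cat("  controls:", paste(object@controlAssays, collapse = ", "), "\n")
  cat("  detection cutoff:", object@maxCycles, "cycles\n")
})

#' Raw qPCR Cq panel
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay matrix
#' named \code{"cq"} with miRNA assays in rows and samples in columns.
#' Cells are quantification-cycle (Cq) values in PCR cycles; \code{NA}
#' encodes an absent call (no amplification above threshold). Per-sample
#' annotations (subject, timepoint, drug, ...) live in \code{colData}.
#'
#' @seealso [CqSet()], [readCqTable()], [applyDetectionFilter()],
#'   [normalizeCq()]
#' @exportClass CqSet
setClass("CqSet", contains = "SummarizedExperiment")

.validGrid <- function(object, what) {
  msg <- character()
  if (!what %in% assayNames(object))
    return(sprintf("assay '%s' is missing", what))
  m <- assay(object, what)
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "assay and sample identifiers (dimnames) are required")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicated assay identifiers")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicated sample identifiers")
  }
  if (!is.numeric(m))
    msg <- c(msg, sprintf("'%s' values must be numeric", what))
  msg
}

setValidity("CqSet", function(object) {
  msg <- .validGrid(object, "cq")
  if (!length(msg)) {
    m <- assay(object, "cq")
    bad <- m[!is.na(m)]
    if (any(!is.finite(bad) | bad <= 0))
      msg <- c(msg, "finite Cq values must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CqSet from a Cq matrix
#'
#' @param cq Numeric matrix of Cq values, assays in rows, samples in
#'   columns, with dimnames set. \code{NA} means absent.
#' @param sampleData Optional \code{data.frame}/\code{DataFrame} of
#'   per-sample annotations (one row per sample).
#'
#' @return A [CqSet-class].
#' @examples
#' m <- matrix(c(25, 30, 26, 31), 2,
#'             dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' CqSet(m)
#' @export
CqSet <- function(cq, sampleData = NULL) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  if (is.null(sampleData))
    sampleData <- DataFrame(row.names = colnames(cq))
  new("CqSet", SummarizedExperiment(assays = list(cq = cq),
                                    colData = sampleData))
}

setMethod("show", "CqSet", function(object) {
  m <- assay(object, "cq")
  cat(sprintf("CqSet: %d assays x %d samples (%d absent calls)\n",
              nrow(m), ncol(m), sum(is.na(m))))
  callNextMethod()
})

#' Normalized delta-Cq panel
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay matrix
#' named \code{"deltaCq"} (assays in rows, samples in columns) together
#' with the [NormParams-class] that produced it. Delta-Cq is the target Cq
#' minus the per-sample reference mean, so a more abundant miRNA has a
#' lower delta-Cq (and a higher minus-delta-Cq). \code{NA} marks cells
#' whose underlying Cq was absent.
#'
#' @slot normalization The [NormParams-class] used.
#' @seealso [normalizeCq()], [normalization()]
#' @exportClass DeltaCqSet
setClass("DeltaCqSet", contains = "SummarizedExperiment",
         slots = c(normalization = "NormParams"))

setValidity("DeltaCqSet", function(object) {
  msg <- .validGrid(object, "deltaCq")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DeltaCqSet", function(object) {
  m <- assay(object, "deltaCq")
  cat(sprintf("DeltaCqSet: %d assays x %d samples (%s normalization)\n",
              nrow(m), ncol(m), object@normalization@method))
  callNextMethod()
})

#' Ordered up/down marker miRNA panel
#'
#' Identifiers of the marker miRNAs whose plasma levels rise
#' (\code{upAssays}) or fall (\code{downAssays}) after opioid dosing. The
#' two lists are disjoint and ordered (most distinct change first).
#'
#' @slot upAssays Character vector of upregulated marker assay ids.
#' @slot downAssays Character vector of downregulated marker assay ids.
#' @slot metadata List of free-form provenance (e.g. conflicting assays
#'   excluded during signature selection).
#' @seealso [MarkerPanel()], [defaultMorPanel()], [morSignalScore()]
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  slots = c(upAssays = "character", downAssays = "character",
            metadata = "list"))

setValidity("MarkerPanel", function(object) {
  msg <- character()
  if (anyDuplicated(object@upAssays) || anyDuplicated(object@downAssays))
    msg <- c(msg, "marker lists must not contain duplicates")
  if (length(intersect(object@upAssays, object@downAssays)))
    msg <- c(msg, "upAssays and downAssays must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a marker panel
#'
#' @param up Character vector of upregulated marker assay ids.
#' @param down Character vector of downregulated marker assay ids.
#' @param metadata Optional list of provenance annotations.
#' @return A [MarkerPanel-class].
#' @examples
#' MarkerPanel(c("miR-a"), c("miR-b", "miR-c"))
#' @export
MarkerPanel <- function(up = character(), down = character(),
                        metadata = list()) {
  new("MarkerPanel", upAssays = as.character(up),
      downAssays = as.character(down), metadata = metadata)
}

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel\n")
  cat("  up   (", length(object@upAssays), "):",
      paste(object@upAssays, collapse = ", "), "\n")
  cat("  down (", length(object@downAssays), "):",
      paste(object@downAssays, collapse = ", "), "\n")
  if (length(object@metadata$conflicts))
    cat("  direction conflicts excluded:",
        paste(object@metadata$conflicts, collapse = ", "), "\n")
})

#' Paired pre/post delta-Cq panel for one drug
#'
#' Subject-matched delta-Cq grids measured before dosing and 24 h after a
#' single dose of one opioid. Rows are subjects, columns assays; the two
#' grids share dimensions and ordering. A (subject, assay) pair enters the
#' paired analysis only if both timepoints are non-missing.
#'
#' @slot pre,post Numeric matrices (subjects x assays) of delta-Cq values.
#' @slot drugLabel Single string naming the drug.
#' @seealso [PairedPanel()], [pairedDifferential()],
#'   [generateHealthyPanel()]
#' @exportClass PairedPanel
setClass("PairedPanel",
  slots = c(pre = "matrix", post = "matrix", drugLabel = "character"))

setValidity("PairedPanel", function(object) {
  msg <- character()
  if (!identical(dim(object@pre), dim(object@post)))
    msg <- c(msg, "pre and post grids must share dimensions")
  if (!identical(dimnames(object@pre), dimnames(object@post)))
    msg <- c(msg, "pre and post grids must share subject/assay ids")
  if (is.null(rownames(object@pre)) || is.null(colnames(object@pre)))
    msg <- c(msg, "subject and assay identifiers (dimnames) are required")
  if (length(object@drugLabel) != 1L)
    msg <- c(msg, "drugLabel must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a paired pre/post panel
#'
#' @param pre,post Numeric matrices (subjects x assays) of delta-Cq values
#'   with matching dimnames; \code{NA} marks missing cells.
#' @param drugLabel Name of the drug (e.g. \code{"hydromorphone"}).
#' @return A [PairedPanel-class].
#' @export
PairedPanel <- function(pre, post, drugLabel = "drug") {
  new("PairedPanel", pre = as.matrix(pre), post = as.matrix(post),
      drugLabel = as.character(drugLabel))
}

setMethod("show", "PairedPanel", function(object) {
  cat(sprintf("PairedPanel (%s): %d subjects x %d assays\n",
              object@drugLabel, nrow(object@pre), ncol(object@pre)))
})

#' Per-patient MOR signal scores and class labels
#'
#' Result container of [classifyPatients()]: the MOR signal score, the
#' two-cluster class label (1 = putative high MOR signal, 2 = low;
#' \code{NA} = unassigned because of missing marker values), the marker
#' delta-Cq inputs, the panel used, and the dendrogram of the hierarchical
#' clustering for inspection.
#'
#' @slot patientIds Character vector of patient identifiers.
#' @slot score Numeric MOR signal scores (cycles; \code{NA} when any panel
#'   marker is missing).
#' @slot classLabel Integer class per patient (1, 2 or \code{NA}).
#' @slot markerValues Numeric matrix (patients x panel assays) of the
#'   delta-Cq inputs.
#' @slot panel The [MarkerPanel-class] used.
#' @slot clustering The \code{hclust} object (or \code{NULL} when scoring
#'   only).
#' @slot clusterParams List recording distance, linkage and k.
#' @seealso [scores()], [classLabels()], [scoreReport()]
#' @exportClass ScoreTable
setClass("ScoreTable",
  slots = c(patientIds = "character", score = "numeric",
            classLabel = "integer", markerValues = "matrix",
            panel = "MarkerPanel", clustering = "ANY",
            clusterParams = "list"))

setValidity("ScoreTable", function(object) {
  msg <- character()
  n <- length(object@patientIds)
  if (length(object@score) != n || length(object@classLabel) != n)
    msg <- c(msg, "score and classLabel must match patientIds in length")
  if (nrow(object@markerValues) != n)
    msg <- c(msg, "markerValues must have one row per patient")
  if (anyDuplicated(object@patientIds))
    msg <- c(msg, "patient identifiers must be unique")
  if (any(!object@classLabel[!is.na(object@classLabel)] %in% 1:2))
    msg <- c(msg, "class labels must be 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d patients (%d scored, class sizes: %s)\n",
              length(object@patientIds), sum(!is.na(object@score)),
              paste(table(factor(object@classLabel, 1:2)), collapse = "/")))
  rng <- range(object@score, na.rm = TRUE)
  cat(sprintf("  score range: %.1f .. %.1f cycles\n", rng[1], rng[2]))
})
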