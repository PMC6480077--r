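#' @rdname applyDetectionFilter
#' @export
setGeneric("applyDetectionFilter",
           function(x, params = normParams()) standardGeneric("applyDetectionFilter"))

#' @rdname normalizeCq
#' @export
setGeneric("normalizeCq",
           function(x, params = normParams()) standardGeneric("normalizeCq"))

#' @rdname pairedDifferential
#' @export
setGeneric("pairedDifferential",
           function(x, ...) standardGeneric("pairedDifferential"))

#' Accessors for marker panels
#'
#' @param x A [MarkerPanel-class].
#' @return `upAssays()` and `downAssays()` return character vectors of
#'   marker assay identifiers.
#' @examples
#' upAssays(defaultMorPanel())
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("upAssays", function(x) standardGeneric("upAssays"))

#' @rdname panel-accessors
#' @export
setGeneric("downAssays", function(x) standardGeneric("downAssays"))

#' @rdname panel-accessors
#' @export
setMethod("upAssays", "MarkerPanel", function(x) x@upAssays)

#' @rdname panel-accessors
#' @export
setMethod("downAssays", "MarkerPanel", function(x) x@downAssays)

#' Accessors for score tables
#'
#' @param x A [ScoreTable-class].
#' @return `scores()`: named numeric vector of MOR signal scores;
#'   `classLabels()`: named integer vector of class labels (1 = putative
#'   high MOR signal, 2 = low, `NA` = unassigned); `patientIds()`:
#'   character vector; `markerValues()`: the delta-Cq input matrix;
#'   `markerPanel()`: the [MarkerPanel-class] used; `clustering()`: the
#'   `hclust` object (or `NULL`).
#' @examples
#' t2 <- table2Fixture()
#' st <- classifyPatients(t2$markers, input = "neg_delta_cq")
#' head(scores(st))
#' table(classLabels(st))
#' @name scoretable-accessors
NULL

#' @rdname scoretable-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname scoretable-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname scoretable-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname scoretable-accessors
#' @export
setGeneric("markerValues", function(x) standardGeneric("markerValues"))

#' @rdname scoretable-accessors
#' @export
setGeneric("markerPanel", function(x) standardGeneric("markerPanel"))

#' @rdname scoretable-accessors
#' @export
setGeneric("clustering", function(x) standardGeneric("clustering"))

#' @rdname scoretable-accessors
#' @export
setMethod("scores", "ScoreTable",
          function(x) stats::setNames(x@score, x@patientIds))

#' @rdname scoretable-accessors
#' @export
setMethod("classLabels", "ScoreTable",
          function(x) stats::setNames(x@classLabel, x@patientIds))

#' @rdname scoretable-accessors
#' @export
setMethod("patientIds", "ScoreTable", function(x) x@patientIds)

#' @rdname scoretable-accessors
#' @export
setMethod("markerValues", "ScoreTable", function(x) x@markerValues)

#' @rdname scoretable-accessors
#' @export
setMethod("markerPanel", "ScoreTable", function(x) x@panel)

#' @rdname scoretable-accessors
#' @export
setMethod("clustering", "ScoreTable", function(x) x@clustering)

#' Normalization provenance of a delta-Cq panel
#'
#' @param x A [DeltaCqSet-class].
#' @return The [NormParams-class] used to produce the panel.
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' @rdname normalization
#' @export
setMethod("normalization", "DeltaCqSet", function(x) x@normalization)

#' Assays undetected in every sample
#'
#' After [applyDetectionFilter()], assays with an absent call in every
#' sample are retained in the matrix but flagged for exclusion from
#' downstream marker analysis.
#'
#' @param x A [CqSet-class] that has been through the detection filter.
#' @return Character vector of assay identifiers (empty if none).
#' @export
setGeneric("undetectedAssays", function(x) standardGeneric("undetectedAssays"))

#' @rdname undetectedAssays
#' @export
setMethod("undetectedAssays", "CqSet", function(x) {
  ua <- metadata(x)$undetectedAssays
  if (is.null(ua)) character() else ua
})
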