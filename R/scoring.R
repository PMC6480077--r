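#' Clustering settings for patient stratification
#'
#' @param distance Dissimilarity between patient marker profiles:
#'   \code{"correlation"} (1 - Pearson correlation; default),
#'   \code{"euclidean"} or \code{"manhattan"}. Correlation distance
#'   compares the shape of the up/down marker profile rather than its
#'   absolute level, which is what separates high- from low-MOR-signal
#'   patients; it is also the choice that reproduces the published
#'   two-class stratification of the 25-patient cohort, where Euclidean
#'   distance isolates the single most extreme patient instead.
#' @param linkage Agglomeration method: \code{"complete"} (default),
#'   \code{"average"}, \code{"ward"} (Ward D2) or \code{"mcquitty"}.
#' @param k Number of clusters to cut the dendrogram into (default 2).
#' @return A named list of class settings used by [classifyPatients()].
#' @examples
#' clusterSpec()
#' clusterSpec("euclidean", "average")
#' @export
clusterSpec <- function(distance = c("correlation", "euclidean", "manhattan"),
                        linkage = c("complete", "average", "ward", "mcquitty"),
                        k = 2L) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  list(distance = distance, linkage = linkage, k = k)
}

#' MOR signal score
#'
#' Composite score of putative MOR stimulation from the delta-Cq values
#' of the marker panel:
#' score = - sum(deltaCq of UP markers) + sum(deltaCq of DOWN markers).
#' Since lower delta-Cq means a more abundant miRNA, the score rises when
#' the UP markers are abundant and the DOWN markers are scarce.
#' Equivalently, on the minus-delta-Cq scale (as marker tables are often
#' printed), score = sum(-deltaCq of UP) - sum(-deltaCq of DOWN).
#'
#' @param x Either a named numeric vector of per-assay values for one
#'   patient, or a numeric matrix with patients in rows and assays in
#'   columns (colnames required).
#' @param panel A [MarkerPanel-class] (default [defaultMorPanel()]); both
#'   marker lists must be non-empty.
#' @param input \code{"delta_cq"} (default) when \code{x} holds delta-Cq
#'   values, or \code{"neg_delta_cq"} when it holds minus-delta-Cq values
#'   as printed in marker tables.
#' @return Numeric score(s) in cycles, named by patient for matrix input.
#'   A patient with any missing panel value gets \code{NA}.
#' @examples
#' t2 <- table2Fixture()
#' morSignalScore(t2$markers["#25", ], input = "neg_delta_cq")  # -16.4
#' @export
morSignalScore <- function(x, panel = defaultMorPanel(),
                           input = c("delta_cq", "neg_delta_cq")) {
  input <- match.arg(input)
  stopifnot(is(panel, "MarkerPanel"))
  if (!length(upAssays(panel)) || !length(downAssays(panel)))
    stop("marker panel must have both up and down assays for scoring")
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list("", names(x)))
  if (is.null(colnames(x))) stop("assay names are required on 'x'")
  need <- c(upAssays(panel), downAssays(panel))
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("panel assay(s) missing from input: ", paste(miss, collapse = ", "))
  d <- x[, need, drop = FALSE]
  if (input == "neg_delta_cq") d <- -d
  s <- -rowSums(d[, upAssays(panel), drop = FALSE]) +
    rowSums(d[, downAssays(panel), drop = FALSE])
  if (nrow(x) == 1L && identical(rownames(x), "")) unname(s) else s
}

#' Two-class stratification of patients by marker profile
#'
#' Computes per-patient MOR signal scores and partitions the patients
#' with complete marker rows into \code{k} groups by agglomerative
#' hierarchical clustering of their panel delta-Cq profiles. The cluster
#' with the higher mean MOR signal score is labelled class 1 (putative
#' high MOR signal), the other class 2, so labels do not depend on
#' dendrogram orientation. Patients with incomplete marker rows are left
#' unassigned (\code{NA}) and never abort the cohort analysis.
#'
#' @param markers Numeric matrix, patients in rows (rownames = patient
#'   ids), panel assays in columns.
#' @param panel A [MarkerPanel-class] (default [defaultMorPanel()]).
#' @param spec Clustering settings from [clusterSpec()].
#' @param input \code{"delta_cq"} or \code{"neg_delta_cq"} (see
#'   [morSignalScore()]). Both Euclidean and correlation dissimilarities
#'   are invariant to the global sign flip, so the partition does not
#'   depend on this choice; the scores do.
#' @return A [ScoreTable-class]; the \code{hclust} object is kept in the
#'   \code{clustering} slot so the merge order can be inspected.
#' @details At least three complete marker rows are required. Rows that
#'   are all identical (zero pairwise distance) or constant rows under
#'   correlation distance are degenerate and raise an error.
#' @examples
#' t2 <- table2Fixture()
#' st <- classifyPatients(t2$markers, input = "neg_delta_cq")
#' table(classLabels(st))
#' @importFrom stats hclust cutree dist cor setNames
#' @export
classifyPatients <- function(markers, panel = defaultMorPanel(),
                             spec = clusterSpec(),
                             input = c("delta_cq", "neg_delta_cq")) {
  input <- match.arg(input)
  markers <- as.matrix(markers)
  if (is.null(rownames(markers)))
    rownames(markers) <- as.character(seq_len(nrow(markers)))
  need <- c(upAssays(panel), downAssays(panel))
  miss <- setdiff(need, colnames(markers))
  if (length(miss))
    stop("panel assay(s) missing from marker matrix: ",
         paste(miss, collapse = ", "))
  m <- markers[, need, drop = FALSE]
  dcq <- if (input == "neg_delta_cq") -m else m
  score <- morSignalScore(dcq, panel, input = "delta_cq")
  complete <- rowSums(is.na(dcq)) == 0L
  if (sum(complete) < 3L)
    stop("need >= 3 patients with complete marker rows; got ",
         sum(complete))
  mc <- dcq[complete, , drop = FALSE]
  if (all(dist(mc) == 0))
    stop("degenerate input: all complete marker rows are identical")
  dd <- switch(spec$distance,
    correlation = {
      if (any(apply(mc, 1L, stats::sd) == 0))
        stop("correlation distance undefined for constant marker rows; ",
             "use distance = 'euclidean'")
      stats::as.dist(1 - cor(t(mc)))
    },
    euclidean = dist(mc),
    manhattan = dist(mc, method = "manhattan"))
  hc <- hclust(dd, method = switch(spec$linkage, ward = "ward.D2",
                                   spec$linkage))
  cl <- cutree(hc, k = spec$k)
  meanScore <- tapply(score[complete], cl, mean)
  lab <- rep(NA_integer_, nrow(dcq))
  # rank clusters by decreasing mean score: highest mean -> class 1
  rk <- rank(-meanScore, ties.method = "first")
  lab[complete] <- as.integer(rk[as.character(cl)])
  new("ScoreTable", patientIds = rownames(dcq),
      score = unname(score), classLabel = lab, markerValues = dcq,
      panel = panel, clustering = hc, clusterParams = spec)
}

#' Ranked per-patient score report
#'
#' Patients sorted by descending MOR signal score (ties kept in input
#' order, unscored patients last), with the class label and the marker
#' values on the minus-delta-Cq scale, rounded for reporting.
#'
#' @param st A [ScoreTable-class].
#' @param digits Decimal places for the report (default 1, matching how
#'   such marker tables are printed); \code{NULL} for full precision.
#' @return A \code{data.frame} with columns \code{patient_id},
#'   \code{class}, \code{score} and one minus-delta-Cq column per marker.
#' @examples
#' t2 <- table2Fixture()
#' st <- classifyPatients(t2$markers, input = "neg_delta_cq")
#' head(scoreReport(st))
#' @export
scoreReport <- function(st, digits = 1) {
  stopifnot(is(st, "ScoreTable"))
  rnd <- function(v) if (is.null(digits)) v else round(v, digits)
  negd <- -st@markerValues
  df <- data.frame(patient_id = st@patientIds, class = st@classLabel,
                   score = rnd(st@score), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (a in colnames(negd)) df[[a]] <- rnd(negd[, a])
  ord <- order(is.na(st@score), -ifelse(is.na(st@score), -Inf, st@score))
  df[ord, , drop = FALSE]
}
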