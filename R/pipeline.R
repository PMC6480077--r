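#' End-to-end marker selection from two paired drug panels
#'
#' Chains the selection stages of the biomarker workflow: per-drug paired
#' differential testing with BH FDR control, intersection into the common
#' up/down signature at \code{qThreshold}, and reduction to the
#' \code{kUp}/\code{kDown} most distinct markers ranked in the reference
#' drug's result (first panel by default, i.e. the hydromorphone arm in
#' the source design).
#'
#' @param panelA,panelB [PairedPanel-class]s for the two drugs; A is the
#'   ranking reference.
#' @param qThreshold FDR threshold for the common signature (default
#'   0.05).
#' @param kUp,kDown Markers kept per direction (default 4).
#' @return List with \code{panel} (the selected [MarkerPanel-class];
#'   empty when nothing passes the threshold), \code{differential} (list
#'   of the two per-drug result \code{data.frame}s), \code{common} (the
#'   pre-truncation panel), and \code{counts} (assays tested, significant
#'   per drug, common up/down, conflicts).
#' @examples
#' cfg <- synthConfig(seed = 1, plantedUp = NULL, plantedDown = NULL)
#' a <- generateHealthyPanel(cfg, "hydromorphone")$paired
#' b <- generateHealthyPanel(synthConfig(seed = 2), "oxycodone")$paired
#' sel <- runSelect(a, b)
#' sel$counts
#' @export
runSelect <- function(panelA, panelB, qThreshold = 0.05, kUp = 4,
                      kDown = 4) {
  stopifnot(is(panelA, "PairedPanel"), is(panelB, "PairedPanel"))
  da <- pairedDifferential(panelA)
  db <- pairedDifferential(panelB)
  common <- commonSignature(da, db, qThreshold)
  counts <- list(
    tested = c(sum(!is.na(da$q_value)), sum(!is.na(db$q_value))),
    significant = c(sum(da$q_value < qThreshold, na.rm = TRUE),
                    sum(db$q_value < qThreshold, na.rm = TRUE)),
    common_up = length(upAssays(common)),
    common_down = length(downAssays(common)),
    conflicts = length(common@metadata$conflicts))
  if (!length(upAssays(common)) && !length(downAssays(common))) {
    message("no markers pass q < ", qThreshold, " in both drugs")
    return(list(panel = common, differential = list(da, db),
                common = common, counts = counts))
  }
  sel <- selectTopMarkers(common, da, kUp = min(kUp, length(upAssays(common))),
                          kDown = min(kDown, length(downAssays(common))))
  list(panel = sel, differential = list(da, db), common = common,
       counts = counts)
}

#' End-to-end efficacy prediction from patient markers and VAS records
#'
#' Chains the prediction stages: MOR signal scoring and two-class
#' stratification of the patient marker profiles, per-patient delta-VAS
#' derivation from the daily records, and both association tests
#' (Spearman score vs delta VAS; Fisher class vs delta VAS > 0).
#'
#' @param markers Numeric matrix of patient marker values (patients x
#'   assays, rownames = patient ids), either delta-Cq or, as marker
#'   tables are usually printed, minus-delta-Cq (set \code{input}).
#' @param vas Either a long \code{data.frame} of daily VAS records for
#'   [efficacySummary()], or a \code{data.frame} already holding
#'   \code{patient_id} and \code{delta_vas}.
#' @param panel A [MarkerPanel-class] (default [defaultMorPanel()]).
#' @param spec Clustering settings from [clusterSpec()].
#' @param input \code{"delta_cq"} (default) or \code{"neg_delta_cq"}.
#' @param signif Significance threshold annotated on the report
#'   (default 0.01).
#' @return List with \code{scoreTable} ([ScoreTable-class]),
#'   \code{report} (the ranked [scoreReport()] \code{data.frame}),
#'   \code{efficacy} (per-patient summary) and \code{association} (from
#'   [associationReport()]).
#' @examples
#' t2 <- table2Fixture()
#' res <- runPredict(t2$markers,
#'                   data.frame(patient_id = rownames(t2$markers),
#'                              delta_vas = t2$deltaVas),
#'                   input = "neg_delta_cq")
#' res$association$n_evaluable
#' res$association$spearman$p_value
#' @export
runPredict <- function(markers, vas, panel = defaultMorPanel(),
                       spec = clusterSpec(),
                       input = c("delta_cq", "neg_delta_cq"),
                       signif = 0.01) {
  input <- match.arg(input)
  st <- classifyPatients(markers, panel = panel, spec = spec,
                         input = input)
  eff <- if (all(c("patient_id", "delta_vas") %in% names(vas)))
    as.data.frame(vas) else efficacySummary(vas)
  assoc <- associationReport(st, eff, signif = signif)
  list(scoreTable = st, report = scoreReport(st), efficacy = eff,
       association = assoc)
}
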