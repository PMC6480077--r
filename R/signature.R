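#' Paired differential test on a pre/post delta-Cq panel
#'
#' For every assay with at least two complete (pre, post) subject pairs,
#' tests the per-subject change ddCq = deltaCq(24 h) - deltaCq(0 h)
#' against zero with a paired t-test (two-sided p from the t distribution
#' on n - 1 degrees of freedom) and adjusts p-values across all tested
#' assays with the Benjamini-Hochberg step-up procedure. Because a lower
#' delta-Cq means a more abundant miRNA, a negative mean change is an
#' upregulation.
#'
#' @param x A [PairedPanel-class].
#' @param ... Unused.
#' @return A \code{data.frame} with one row per assay: \code{assay},
#'   \code{n_pairs}, \code{mean_change} (mean ddCq, cycles),
#'   \code{t_stat}, \code{df}, \code{p_value}, \code{q_value} (BH),
#'   \code{direction} (\code{"up"}, \code{"down"} or \code{"none"}), and
#'   \code{degenerate} (\code{TRUE} when the subject changes were
#'   identical and non-zero, in which case \code{p_value} is reported as 0
#'   by convention). Assays with fewer than two complete pairs carry
#'   \code{NA} test results and are excluded from the BH adjustment.
#' @details The test is run per assay within one drug's panel; q-values
#'   are therefore comparable within a panel, and common-signature
#'   selection across drugs intersects the per-panel calls.
#' @examples
#' pre <- matrix(rnorm(12), 3, 4,
#'               dimnames = list(paste0("s", 1:3), paste0("m", 1:4)))
#' post <- pre; post[, 1] <- post[, 1] - 2   # planted upregulation
#' pairedDifferential(PairedPanel(pre, post, "drugA"))
#' @importFrom stats pt p.adjust
#' @rdname pairedDifferential
#' @aliases pairedDifferential,PairedPanel-method
setMethod("pairedDifferential", "PairedPanel", function(x, ...) {
  d <- x@post - x@pre                      # subjects x assays
  ok <- !is.na(d)
  n <- colSums(ok)
  mu <- colMeans(d, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  ssd <- apply(d, 2L, stats::sd, na.rm = TRUE)
  testable <- n >= 2L
  if (!any(testable))
    stop("no assay has >= 2 complete pre/post pairs; nothing to test")
  tstat <- dfree <- pval <- rep(NA_real_, ncol(d))
  degen <- rep(FALSE, ncol(d))
  i <- which(testable)
  dfree[i] <- n[i] - 1
  zerovar <- testable & ssd == 0
  degen[zerovar & mu != 0] <- TRUE
  tstat[i] <- mu[i] / (ssd[i] / sqrt(n[i]))
  pval[i] <- 2 * pt(-abs(tstat[i]), dfree[i])
  # zero-variance, non-zero mean: t is infinite; report p = 0, flagged
  pval[degen] <- 0
  tstat[degen] <- sign(mu[degen]) * Inf
  # zero-variance, zero mean: no evidence either way
  pval[zerovar & mu == 0] <- 1
  tstat[zerovar & mu == 0] <- 0
  q <- rep(NA_real_, ncol(d))
  q[testable] <- p.adjust(pval[testable], method = "BH")
  direction <- rep(NA_character_, ncol(d))
  direction[testable] <- ifelse(mu[testable] < 0, "up",
                                ifelse(mu[testable] > 0, "down", "none"))
  data.frame(assay = colnames(d), n_pairs = n, mean_change = mu,
             t_stat = tstat, df = dfree, p_value = pval, q_value = q,
             direction = direction, degenerate = degen,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Common up/down signature across two drugs
#'
#' Intersects two per-drug differential results: an assay is a common
#' upregulated marker when its q-value is below the threshold in both
#' drugs with direction "up" in both, and analogously for downregulated
#' markers. Assays significant in both drugs but with conflicting
#' directions are excluded and reported in the panel metadata.
#'
#' @param a,b Differential result \code{data.frame}s from
#'   [pairedDifferential()] sharing an assay id space.
#' @param qThreshold FDR threshold (default 0.05).
#' @return A [MarkerPanel-class]; \code{metadata(panel)$conflicts} (slot
#'   \code{metadata}) lists direction-conflicting assays.
#' @examples
#' a <- data.frame(assay = c("m1", "m2"), q_value = c(0.01, 0.2),
#'                 direction = c("up", "down"), mean_change = c(-1, 1))
#' b <- data.frame(assay = c("m1", "m2"), q_value = c(0.04, 0.3),
#'                 direction = c("up", "down"), mean_change = c(-1, 1))
#' upAssays(commonSignature(a, b))
#' @export
commonSignature <- function(a, b, qThreshold = 0.05) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            qThreshold > 0, qThreshold < 1)
  shared <- intersect(a$assay, b$assay)
  ia <- match(shared, a$assay); ib <- match(shared, b$assay)
  sigA <- !is.na(a$q_value[ia]) & a$q_value[ia] < qThreshold
  sigB <- !is.na(b$q_value[ib]) & b$q_value[ib] < qThreshold
  both <- sigA & sigB
  dA <- a$direction[ia]; dB <- b$direction[ib]
  up <- shared[both & dA == "up" & dB == "up"]
  down <- shared[both & dA == "down" & dB == "down"]
  conflict <- shared[both & dA != dB & dA != "none" & dB != "none"]
  MarkerPanel(up, down, metadata = list(conflicts = conflict,
                                        qThreshold = qThreshold))
}

#' Keep the k most distinct markers per direction
#'
#' Operationalizes the "clearest change" selection: within each direction
#' of a candidate panel, keeps the \code{k} assays with the largest
#' absolute mean change in the reference differential result. Ties are
#' broken by smaller q-value, then lexicographic assay id, so the result
#' is deterministic.
#'
#' @param panel A candidate [MarkerPanel-class].
#' @param ref Reference differential result (\code{data.frame} from
#'   [pairedDifferential()]) supplying \code{mean_change} and
#'   \code{q_value}; the source analysis ranked by the hydromorphone arm.
#' @param kUp,kDown Number of markers to keep per direction (default 4).
#' @return A [MarkerPanel-class] with at most \code{kUp} + \code{kDown}
#'   assays, ordered most distinct first. If \code{k} exceeds the
#'   available assays, all are kept with a warning.
#' @export
selectTopMarkers <- function(panel, ref, kUp = 4, kDown = 4) {
  stopifnot(is(panel, "MarkerPanel"), is.data.frame(ref))
  pick <- function(ids, k, what) {
    if (!length(ids)) return(character())
    miss <- setdiff(ids, ref$assay)
    if (length(miss))
      stop("panel assay(s) absent from reference result: ",
           paste(miss, collapse = ", "))
    i <- match(ids, ref$assay)
    ord <- order(-abs(ref$mean_change[i]), ref$q_value[i], ids)
    if (k > length(ids)) {
      warning("requested ", k, " ", what, " markers but only ",
              length(ids), " available; keeping all")
      k <- length(ids)
    }
    ids[ord][seq_len(k)]
  }
  MarkerPanel(pick(upAssays(panel), kUp, "up"),
              pick(downAssays(panel), kDown, "down"),
              metadata = panel@metadata)
}

#' The published eight-miRNA MOR marker panel
#'
#' The fixed panel of four plasma miRNAs upregulated (MOR-UP) and four
#' downregulated (MOR-DOWN) 24 h after a single dose of hydromorphone or
#' oxycodone in healthy subjects, used as pharmacodynamic markers of MOR
#' stimulation.
#'
#' @return A [MarkerPanel-class] with
#'   UP = hsa-miR-423-3p, hsa-let-7a-5p, hsa-miR-26a-5p, hsa-let-7f-5p and
#'   DOWN = hsa-miR-144-3p, hsa-miR-451a, hsa-miR-215, hsa-miR-363-3p.
#' @examples
#' defaultMorPanel()
#' @export
defaultMorPanel <- function() {
  MarkerPanel(
    up = c("hsa-miR-423-3p", "hsa-let-7a-5p", "hsa-miR-26a-5p",
           "hsa-let-7f-5p"),
    down = c("hsa-miR-144-3p", "hsa-miR-451a", "hsa-miR-215",
             "hsa-miR-363-3p"))
}

#' Write / read a marker panel as a two-column TSV
#'
#' @param panel A [MarkerPanel-class] (for writing).
#' @param path File path.
#' @return `writeMarkerPanel()` returns `path` invisibly;
#'   `readMarkerPanel()` returns a [MarkerPanel-class].
#' @export
writeMarkerPanel <- function(panel, path) {
  df <- data.frame(
    assay = c(upAssays(panel), downAssays(panel)),
    direction = c(rep("up", length(upAssays(panel))),
                  rep("down", length(downAssays(panel)))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMarkerPanel
#' @export
readMarkerPanel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("assay", "direction") %in% names(df)))
    stop("marker panel file needs columns 'assay' and 'direction'")
  MarkerPanel(df$assay[df$direction == "up"],
              df$assay[df$direction == "down"])
}
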