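#' Baseline and treatment VAS windows
#'
#' Pain intensity is recorded once daily on a 0-100 mm Visual Analog
#' Scale over days -3, -2, -1 (morphine run-in), day 1 (before the first
#' hydromorphone dose) and days 2-4 (on hydromorphone). The baseline VAS
#' is the mean over available records among days \{-3, -2, -1, 1\}; the
#' treatment VAS is the mean over available records among days
#' \{2, 3, 4\}; delta VAS = treatment - baseline, negative when pain
#' improved. Missing days are averaged over, and the number of
#' contributing days is reported so stricter completeness policies can be
#' audited; an empty window makes the corresponding value missing.
#'
#' @param day Integer day indices in \{-3, -2, -1, 1, 2, 3, 4\}.
#' @param vas VAS values in mm (0-100), parallel to \code{day}.
#' @return `baselineVas()`: list with \code{value} (mm or \code{NA}) and
#'   \code{nDays}; `deltaVas()`: list with \code{delta}, \code{baseline},
#'   \code{baselineDays}, \code{treatment}, \code{treatmentDays}.
#' @examples
#' baselineVas(c(-3, -2, -1, 1), c(10, 12, 14, 16))$value  # 13
#' deltaVas(c(-3, -2, -1, 1, 2, 3, 4), c(10, 12, 14, 16, 9, 9, 12))$delta
#' @export
baselineVas <- function(day, vas) {
  .checkVas(day, vas)
  i <- day %in% c(-3, -2, -1, 1) & !is.na(vas)
  list(value = if (any(i)) mean(vas[i]) else NA_real_, nDays = sum(i))
}

#' @rdname baselineVas
#' @export
deltaVas <- function(day, vas) {
  .checkVas(day, vas)
  b <- baselineVas(day, vas)
  i <- day %in% c(2, 3, 4) & !is.na(vas)
  trt <- if (any(i)) mean(vas[i]) else NA_real_
  list(delta = trt - b$value, baseline = b$value, baselineDays = b$nDays,
       treatment = trt, treatmentDays = sum(i))
}

.checkVas <- function(day, vas) {
  stopifnot(length(day) == length(vas))
  if (!all(day %in% c(-3, -2, -1, 1, 2, 3, 4)))
    stop("day indices must be in {-3,-2,-1,1,2,3,4}")
  if (anyDuplicated(day))
    stop("at most one VAS record per day; duplicated day ",
         day[duplicated(day)][1])
  v <- vas[!is.na(vas)]
  if (any(v < 0 | v > 100)) stop("VAS values must be within [0, 100] mm")
  invisible(TRUE)
}

#' Per-patient efficacy summary from daily VAS records
#'
#' @param vas Long-format \code{data.frame} of daily VAS records.
#' @param patientCol,dayCol,vasCol Column names (defaults
#'   \code{"patient_id"}, \code{"day"}, \code{"vas"}).
#' @return A \code{data.frame} with one row per patient:
#'   \code{patient_id}, \code{baseline_vas}, \code{baseline_days},
#'   \code{treatment_vas}, \code{treatment_days}, \code{delta_vas} (mm,
#'   \code{NA} when a window is empty).
#' @examples
#' v <- data.frame(patient_id = "p1", day = c(-3, -2, -1, 1, 2, 3, 4),
#'                 vas = c(10, 12, 14, 16, 9, 9, 12))
#' efficacySummary(v)
#' @export
efficacySummary <- function(vas, patientCol = "patient_id",
                            dayCol = "day", vasCol = "vas") {
  stopifnot(is.data.frame(vas),
            all(c(patientCol, dayCol, vasCol) %in% names(vas)))
  ids <- unique(as.character(vas[[patientCol]]))
  rows <- lapply(ids, function(p) {
    i <- vas[[patientCol]] == p
    dv <- deltaVas(vas[[dayCol]][i], vas[[vasCol]][i])
    data.frame(patient_id = p, baseline_vas = dv$baseline,
               baseline_days = dv$baselineDays,
               treatment_vas = dv$treatment,
               treatment_days = dv$treatmentDays,
               delta_vas = dv$delta, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation between score and delta VAS
#'
#' Rank-order correlation on mid-ranks (ties averaged), with a two-sided
#' p-value from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' For small cohorts an exact permutation p-value (fraction of the n!
#' pairings with |rho| at least as large as observed) is available and,
#' with \code{method = "auto"}, reported alongside the approximation
#' whenever n <= 10.
#'
#' @param score,dvas Parallel numeric vectors; pairs with a missing value
#'   are excluded listwise.
#' @param method \code{"auto"} (default; exact added when n <= 10),
#'   \code{"approx"} or \code{"exact"} (n <= 10 only).
#' @return List with \code{rho}, \code{p_value}, \code{n},
#'   \code{method}, and \code{p_exact} when computed. If all (or all but
#'   one) values of either variable are tied, \code{rho} is undefined and
#'   reported as \code{NA} with \code{degenerate = TRUE}.
#' @examples
#' spearmanAssoc(1:6, c(2, 1, 4, 3, 6, 5))
#' @importFrom stats complete.cases
#' @export
spearmanAssoc <- function(score, dvas, method = c("auto", "approx", "exact")) {
  method <- match.arg(method)
  stopifnot(length(score) == length(dvas))
  ok <- complete.cases(score, dvas)
  x <- score[ok]; y <- dvas[ok]; n <- length(x)
  if (n < 4) stop("need >= 4 complete (score, delta VAS) pairs; got ", n)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "none", degenerate = TRUE))
  rho <- cor(x, y, method = "spearman")
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  pApprox <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tstat), n - 2)
  out <- list(rho = rho, p_value = pApprox, n = n, method = "approx",
              degenerate = FALSE)
  wantExact <- method == "exact" || (method == "auto" && n <= 10)
  if (wantExact) {
    if (n > 10)
      stop("exact permutation p is only available for n <= 10")
    out$p_exact <- .spearmanPermP(x, y)
    if (method == "exact") {
      out$p_value <- out$p_exact
      out$method <- "exact"
    } else out$method <- "approx+exact"
  }
  out
}

# exact two-sided permutation p for Spearman rho, full enumeration of the
# n! pairings in fixed-size chunks; handles ties via mid-ranks
.spearmanPermP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- .allPerms(n)
  sx <- scale(rx)[, 1]; sy <- scale(ry)[, 1]
  rhoAll <- abs(matrix(sx[perms], nrow(perms)) %*% sy) / (n - 1)
  mean(rhoAll >= obs - 1e-12)
}

# all permutations of seq_len(n) as a matrix (n! rows); n <= 10
.allPerms <- function(n) {
  p <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      out[rows, pos] <- k
      out[rows, -pos] <- p
    }
    p <- out
  }
  p
}

#' Fisher's exact test for responder enrichment by class
#'
#' Builds the 2x2 table of class (1 vs 2) against the delta-VAS
#' dichotomy (poorer: delta VAS > 0; improved-or-unchanged: delta VAS <=
#' 0) over evaluable patients (assigned class and non-missing delta VAS)
#' and tests enrichment with Fisher's exact test, two-sided by summing
#' the hypergeometric probabilities of all tables no more probable than
#' the observed one. The sample odds ratio (ad/bc) is reported, with the
#' Haldane 0.5 continuity correction applied for display when a cell is
#' zero.
#'
#' @param classLabel Integer class per patient (1, 2 or \code{NA}).
#' @param dvas Delta VAS per patient (mm, \code{NA} allowed).
#' @return List with \code{table} (2x2 counts), \code{p_value},
#'   \code{odds_ratio}, \code{haldane} (whether the correction was
#'   applied) and \code{n}.
#' @examples
#' cls <- rep(1:2, c(15, 8))
#' dv <- c(rep(1, 13), rep(-1, 2), rep(1, 1), rep(-1, 7))
#' fisherEnrichment(cls, dv)$p_value   # ~1.05e-3
#' @importFrom stats fisher.test
#' @export
fisherEnrichment <- function(classLabel, dvas) {
  stopifnot(length(classLabel) == length(dvas))
  ok <- !is.na(classLabel) & !is.na(dvas)
  cl <- classLabel[ok]; dv <- dvas[ok]
  for (k in 1:2)
    if (!any(cl == k))
      stop("class ", k, " has no evaluable patients")
  tab <- table(factor(cl, 1:2), factor(dv > 0, c(TRUE, FALSE)))
  dimnames(tab) <- list(class = c("1", "2"),
                        dvas = c("dVAS>0", "dVAS<=0"))
  ft <- fisher.test(tab, alternative = "two.sided")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(tab == 0)
  orr <- if (haldane) ((a + .5) * (d + .5)) / ((b + .5) * (cc + .5))
         else (a * d) / (b * cc)
  list(table = unclass(tab), p_value = ft$p.value, odds_ratio = orr,
       haldane = haldane, n = sum(tab))
}

#' Cohort-level association of MOR signal with analgesic efficacy
#'
#' Joins a score/class table with per-patient efficacy summaries on the
#' patient id, drops non-evaluable patients with a reason, and reports
#' both association tests: Spearman rank correlation of score vs delta
#' VAS, and Fisher's exact test of class against the delta VAS > 0
#' dichotomy. With a single represented class the Fisher test is skipped
#' with a reason while the correlation is still computed.
#'
#' @param st A [ScoreTable-class].
#' @param efficacy \code{data.frame} from [efficacySummary()] (needs
#'   \code{patient_id} and \code{delta_vas}), or any \code{data.frame}
#'   with those columns.
#' @param signif Significance threshold annotated on the report
#'   (default 0.01); informational only.
#' @return List with \code{n_total}, \code{n_evaluable},
#'   \code{spearman}, \code{fisher} (or a skip reason), \code{roster}
#'   (evaluable patients: id, score, class, delta VAS), and
#'   \code{excluded} (\code{data.frame} of dropped patients with reason
#'   codes \code{no_score}, \code{no_class}, \code{no_delta_vas},
#'   \code{no_efficacy_record}).
#' @examples
#' t2 <- table2Fixture()
#' st <- classifyPatients(t2$markers, input = "neg_delta_cq")
#' eff <- data.frame(patient_id = rownames(t2$markers),
#'                   delta_vas = t2$deltaVas)
#' rep <- associationReport(st, eff)
#' rep$n_evaluable
#' @export
associationReport <- function(st, efficacy, signif = 0.01) {
  stopifnot(is(st, "ScoreTable"), is.data.frame(efficacy),
            all(c("patient_id", "delta_vas") %in% names(efficacy)))
  ids <- patientIds(st)
  i <- match(ids, as.character(efficacy$patient_id))
  if (all(is.na(i))) stop("no shared patient ids between score table and ",
                          "efficacy records")
  dv <- efficacy$delta_vas[i]
  sc <- scores(st); cl <- classLabels(st)
  reason <- rep(NA_character_, length(ids))
  reason[is.na(i)] <- "no_efficacy_record"
  reason[is.na(reason) & is.na(dv)] <- "no_delta_vas"
  reason[is.na(reason) & is.na(sc)] <- "no_score"
  reason[is.na(reason) & is.na(cl)] <- "no_class"
  keep <- is.na(reason)
  roster <- data.frame(patient_id = ids, score = unname(sc),
                       class = unname(cl), delta_vas = dv,
                       stringsAsFactors = FALSE)[keep, , drop = FALSE]
  excluded <- data.frame(patient_id = ids[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  sp <- spearmanAssoc(roster$score, roster$delta_vas)
  fisher <- if (length(unique(roster$class)) < 2L)
    list(skipped = TRUE,
         reason = "only one class represented among evaluable patients")
  else fisherEnrichment(roster$class, roster$delta_vas)
  list(n_total = length(ids), n_evaluable = nrow(roster),
       signif_threshold = signif, spearman = sp, fisher = fisher,
       roster = roster, excluded = excluded)
}

#' Write an association report as JSON and the roster as TSV
#'
#' @param report List from [associationReport()].
#' @param jsonPath,rosterPath Output paths (either may be \code{NULL} to
#'   skip).
#' @return Invisibly, the paths written.
#' @importFrom jsonlite write_json
#' @export
writeAssociationReport <- function(report, jsonPath = NULL,
                                   rosterPath = NULL) {
  if (!is.null(jsonPath)) {
    out <- report
    out$roster <- NULL
    out$schema_version <- "1.0"
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(rosterPath))
    write.table(report$roster, rosterPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(jsonPath, rosterPath))
}
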