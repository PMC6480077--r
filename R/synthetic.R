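# Synthetic study-shaped data: paired pre/post Cq panels with planted drug
# effects, and patient cohorts whose latent MOR-signal class drives both
# the marker profile and the VAS trajectory. All randomness is drawn from
# one seeded generator per call; the caller's RNG state is untouched.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the source study's design: six healthy subjects per
#' drug, a 179-assay serum/plasma focus panel with the five internal
#' controls and the eight MOR markers, 25 cancer patients, and a planted
#' 1-cycle paired effect on the eight markers. Units are PCR cycles for
#' Cq-scale fields and mm for VAS-scale fields.
#'
#' @param seed Integer seed; mandatory, every generator call is fully
#'   deterministic given it.
#' @param nSubjects Healthy subjects per drug (default 6).
#' @param nAssays Panel size (default 179).
#' @param plantedUp,plantedDown Named numeric vectors: planted paired
#'   effect sizes in cycles per assay (default: the four MOR-UP and four
#'   MOR-DOWN markers at 1.0 cycle each). Must be disjoint and contained
#'   in the panel.
#' @param cqNoiseSd Subject-level noise sd on the Cq scale (cycles,
#'   default 0.5). The post-dose value is generated as the pre-dose value
#'   plus the planted shift plus fresh change noise of this sd, so the
#'   paired change ddCq has sd \code{cqNoiseSd}: pre/post measurements of
#'   one subject share that subject's biological assay level, as paired
#'   plasma panels do.
#' @param controlDriftSd Between-timepoint drift sd of the internal
#'   control assays (cycles, default 0.1); controls receive drift only,
#'   no planted effect.
#' @param nPatients Cohort size (default 25).
#' @param classProportions Probabilities of latent class 1 (high MOR
#'   signal) and class 2, summing to 1 (default \code{c(0.6, 0.4)}).
#' @param markerSeparation Between-class separation of each marker mean
#'   in cycles (default 2.0).
#' @param markerNoiseSd Within-class marker sd (cycles, default 0.7).
#' @param vasBaselineMean,vasBaselineSd Patient baseline pain in mm
#'   (defaults 14 and 8, matching the narrow cancer-pain range of a
#'   cohort titrated on morphine).
#' @param dvasEffect Expected difference in delta VAS between classes in
#'   mm (default 5): class 1 (high MOR signal, low headroom for further
#'   stimulation) shifts by \code{+dvasEffect/2} on treatment days,
#'   class 2 by \code{-dvasEffect/2}.
#' @param vasDayNoiseSd Day-to-day VAS noise (mm, default 3).
#' @param missingDayRate,missingAssayRate Fractions of VAS days / marker
#'   values dropped at random (defaults 0.05 and 0.02).
#' @param outlierFraction Fraction of Cq cells replaced by heavy-tailed
#'   contamination (default 0).
#' @return A validated list of class \code{"SynthConfig"}.
#' @examples
#' cfg <- synthConfig(seed = 1)
#' @export
synthConfig <- function(seed,
                        nSubjects = 6L, nAssays = 179L,
                        plantedUp = NULL, plantedDown = NULL,
                        cqNoiseSd = 0.5, controlDriftSd = 0.1,
                        nPatients = 25L, classProportions = c(0.6, 0.4),
                        markerSeparation = 2.0, markerNoiseSd = 0.7,
                        vasBaselineMean = 14, vasBaselineSd = 8,
                        dvasEffect = 5, vasDayNoiseSd = 3,
                        missingDayRate = 0.05, missingAssayRate = 0.02,
                        outlierFraction = 0) {
  if (missing(seed)) stop("'seed' is mandatory in a SynthConfig")
  pnl <- defaultMorPanel()
  if (is.null(plantedUp))
    plantedUp <- setNames(rep(1.0, 4), upAssays(pnl))
  if (is.null(plantedDown))
    plantedDown <- setNames(rep(1.0, 4), downAssays(pnl))
  cfg <- list(seed = as.integer(seed), nSubjects = as.integer(nSubjects),
              nAssays = as.integer(nAssays), plantedUp = plantedUp,
              plantedDown = plantedDown, cqNoiseSd = cqNoiseSd,
              controlDriftSd = controlDriftSd,
              nPatients = as.integer(nPatients),
              classProportions = classProportions,
              markerSeparation = markerSeparation,
              markerNoiseSd = markerNoiseSd,
              vasBaselineMean = vasBaselineMean,
              vasBaselineSd = vasBaselineSd, dvasEffect = dvasEffect,
              vasDayNoiseSd = vasDayNoiseSd,
              missingDayRate = missingDayRate,
              missingAssayRate = missingAssayRate,
              outlierFraction = outlierFraction)
  sds <- c(cfg$cqNoiseSd, cfg$controlDriftSd, cfg$markerNoiseSd,
           cfg$vasBaselineSd, cfg$vasDayNoiseSd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0")
  rates <- c(cfg$missingDayRate, cfg$missingAssayRate, cfg$outlierFraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be within [0, 1]")
  if (length(classProportions) != 2L ||
      abs(sum(classProportions) - 1) > 1e-8)
    stop("classProportions must be two values summing to 1")
  if (length(intersect(names(plantedUp), names(plantedDown))))
    stop("plantedUp and plantedDown must be disjoint")
  structure(cfg, class = "SynthConfig")
}

# panel assay universe: controls, markers, then synthetic filler
.synthAssays <- function(cfg) {
  pnl <- defaultMorPanel()
  fixed <- c(defaultControlAssays(), upAssays(pnl), downAssays(pnl))
  if (cfg$nAssays < length(fixed))
    stop("nAssays must be >= ", length(fixed))
  c(fixed, sprintf("syn-miR-%03d", seq_len(cfg$nAssays - length(fixed))))
}

#' Generate a paired pre/post healthy-subject Cq panel
#'
#' Emulates the healthy-subject design: per subject and assay, the
#' pre-dose Cq is an assay-specific baseline plus a subject offset plus
#' Gaussian noise; the 24-h post-dose Cq is the subject's own pre-dose
#' value shifted by the planted effect (minus the effect for planted-up
#' assays, since a lower Cq is an upregulation; plus for planted-down)
#' plus fresh change noise. Internal-control assays receive between-day
#' drift only. The raw panels are detection-filtered and
#' internal-control normalized into a [PairedPanel-class], and the
#' ground-truth planted effects are returned alongside.
#'
#' @param cfg A [synthConfig()]; all planted assays must be in the panel.
#' @param drugLabel Name for the simulated drug.
#' @return List with \code{cqPre}, \code{cqPost} ([CqSet-class]s),
#'   \code{paired} ([PairedPanel-class] of normalized delta-Cq), and
#'   \code{truth} (\code{data.frame}: assay, planted effect in cycles,
#'   direction).
#' @examples
#' hp <- generateHealthyPanel(synthConfig(seed = 1), "hydromorphone")
#' hp$paired
#' @importFrom stats rnorm runif rbinom
#' @export
generateHealthyPanel <- function(cfg, drugLabel = "drug") {
  stopifnot(inherits(cfg, "SynthConfig"))
  assays <- .synthAssays(cfg)
  bad <- setdiff(c(names(cfg$plantedUp), names(cfg$plantedDown)), assays)
  if (length(bad))
    stop("planted assay(s) not in the panel: ", paste(bad, collapse = ", "))
  ctl <- defaultControlAssays()
  nS <- cfg$nSubjects; nA <- cfg$nAssays
  .withSeed(cfg$seed, {
    base <- runif(nA, 22, 34)
    names(base) <- assays
    base[ctl] <- runif(length(ctl), 23, 26)   # controls: abundant, stable
    shift <- setNames(numeric(nA), assays)
    shift[names(cfg$plantedUp)] <- -cfg$plantedUp
    shift[names(cfg$plantedDown)] <- cfg$plantedDown
    subjects <- sprintf("subj%02d", seq_len(nS))
    pre <- outer(rnorm(nS, 0, 0.3), base, "+") +
      matrix(rnorm(nS * nA, 0, cfg$cqNoiseSd), nS)
    change <- matrix(rnorm(nS * nA, 0, cfg$cqNoiseSd), nS)
    change[, match(ctl, assays)] <- rnorm(nS * length(ctl), 0,
                                          cfg$controlDriftSd)
    post <- pre + matrix(rep(shift, each = nS), nS) +
      rnorm(nS, 0, 0.3) + change
    if (cfg$outlierFraction > 0) {
      k <- rbinom(1L, nS * nA, cfg$outlierFraction)
      idx <- sample(nS * nA, k)
      pre[idx] <- pre[idx] + rnorm(k, 0, 5 * cfg$cqNoiseSd)
    }
    dimnames(pre) <- dimnames(post) <- list(subjects, assays)
    prm <- normParams()
    toDelta <- function(m, tag) {
      cs <- CqSet(t(m), DataFrame(subject = subjects, timepoint = tag,
                                  drug = drugLabel, row.names = subjects))
      d <- assay(normalizeCq(applyDetectionFilter(cs, prm), prm),
                 "deltaCq")
      t(d)   # back to subjects x assays
    }
    dpre <- toDelta(pre, "0h"); dpost <- toDelta(post, "24h")
    rownames(dpre) <- rownames(dpost) <- subjects
    truth <- data.frame(
      assay = c(names(cfg$plantedUp), names(cfg$plantedDown)),
      effect = c(cfg$plantedUp, cfg$plantedDown),
      direction = rep(c("up", "down"),
                      c(length(cfg$plantedUp), length(cfg$plantedDown))),
      row.names = NULL, stringsAsFactors = FALSE)
    list(cqPre = CqSet(t(pre)), cqPost = CqSet(t(post)),
         paired = PairedPanel(dpre, dpost, drugLabel), truth = truth)
  })
}

# baseline minus-delta-Cq profile of the eight markers: round values near
# a typical pre-treatment plasma panel (UP markers scarce relative to the
# control mean, miR-451a abundant)
.markerBaseline <- function() {
  pnl <- defaultMorPanel()
  setNames(c(-2.3, 0.1, -1.7, -0.4, -0.9, 6.4, -3.8, -2.6),
           c(upAssays(pnl), downAssays(pnl)))
}

#' Generate a synthetic patient cohort
#'
#' Draws a latent MOR-signal class per patient and generates (i) the
#' eight-marker delta-Cq profile -- class 1 centred at a high
#' minus-delta-Cq for UP markers and low for DOWN markers, class 2
#' mirrored, with \code{markerSeparation} cycles between the class means
#' -- and (ii) a daily VAS trajectory: days -3..1 fluctuate around the
#' patient's baseline, days 2-4 add the class-dependent treatment shift
#' (+dvasEffect/2 for class 1, -dvasEffect/2 for class 2). VAS values
#' are clipped to [0, 100] mm and the clipping rate is reported;
#' missingness is injected at the configured rates.
#'
#' @param cfg A [synthConfig()].
#' @return List with \code{markers} (patients x 8 matrix of delta-Cq,
#'   \code{NA} for missing), \code{vas} (long \code{data.frame}:
#'   patient_id, day, vas), \code{truth} (\code{data.frame}: patient_id,
#'   class, expected_dvas) and \code{clipRate}.
#' @examples
#' coh <- generatePatientCohort(synthConfig(seed = 1))
#' head(coh$truth)
#' @export
generatePatientCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  pnl <- defaultMorPanel()
  mk <- c(upAssays(pnl), downAssays(pnl))
  dirSign <- setNames(rep(c(1, -1), each = 4), mk)  # -dCq scale: UP high in class 1
  nP <- cfg$nPatients
  .withSeed(cfg$seed, {
    ids <- sprintf("pt%02d", seq_len(nP))
    cls <- ifelse(runif(nP) < cfg$classProportions[1], 1L, 2L)
    clsSign <- ifelse(cls == 1L, 1, -1)
    mu <- sweep(outer(clsSign, dirSign) * cfg$markerSeparation / 2, 2L,
                .markerBaseline(), "+")
    negd <- mu + matrix(rnorm(nP * 8, 0, cfg$markerNoiseSd), nP)
    if (cfg$missingAssayRate > 0)
      negd[matrix(runif(nP * 8) < cfg$missingAssayRate, nP)] <- NA
    dimnames(negd) <- list(ids, mk)
    days <- c(-3, -2, -1, 1, 2, 3, 4)
    baseline <- rnorm(nP, cfg$vasBaselineMean, cfg$vasBaselineSd)
    shift <- ifelse(cls == 1L, cfg$dvasEffect / 2, -cfg$dvasEffect / 2)
    vasGrid <- outer(baseline, rep(1, length(days))) +
      outer(shift, as.numeric(days >= 2)) +
      matrix(rnorm(nP * length(days), 0, cfg$vasDayNoiseSd), nP)
    clipRate <- mean(vasGrid < 0 | vasGrid > 100)
    vasGrid <- pmin(pmax(vasGrid, 0), 100)
    keep <- matrix(runif(nP * length(days)) >= cfg$missingDayRate, nP)
    vas <- data.frame(
      patient_id = rep(ids, times = length(days)),
      day = rep(days, each = nP),
      vas = as.vector(vasGrid))[as.vector(keep), ]
    vas <- vas[order(match(vas$patient_id, ids), vas$day), ]
    rownames(vas) <- NULL
    truth <- data.frame(patient_id = ids, class = cls,
                        expected_dvas = shift, stringsAsFactors = FALSE)
    list(markers = -negd, vas = vas, truth = truth, clipRate = clipRate)
  })
}

#' The packaged 25-patient marker table
#'
#' Per-patient minus-delta-Cq values of the eight MOR marker miRNAs
#' measured in plasma of 25 cancer-pain patients before the switch from
#' morphine to hydromorphone, together with each patient's average delta
#' VAS (two patients missing), morphine:hydromorphone dose-conversion
#' arm, and severe-adverse-event flag. The published MOR signal score
#' column is returned separately as expected output for verification; it
#' is never used as an input.
#'
#' @return List with \code{markers} (25 x 8 matrix of minus-delta-Cq,
#'   rownames \code{"#1"}..\code{"#25"}, columns in printed order),
#'   \code{scorePrinted}, \code{deltaVas}, \code{doseRatio} and
#'   \code{sae} (all named by patient).
#' @examples
#' t2 <- table2Fixture()
#' nrow(t2$markers)                     # 25
#' t2$deltaVas[c("#9", "#17")]          # the two missing delta VAS
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "table2_markers.tsv", package = "miRMOR",
                      mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  mk <- as.matrix(df[, 2:9])
  rownames(mk) <- df$patient_id
  nm <- df$patient_id
  list(markers = mk,
       scorePrinted = setNames(df$mor_signal_score, nm),
       deltaVas = setNames(df$delta_vas, nm),
       doseRatio = setNames(df$dose_ratio, nm),
       sae = setNames(df$sae == 1, nm))
}
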