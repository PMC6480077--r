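#' Read a qPCR Cq panel table
#'
#' Reads a delimited text table of Cq values into a [CqSet-class]. Two
#' layouts are supported: \code{"wide"}, one row per sample with one
#' column per assay (first column = sample id), and \code{"long"}, one row
#' per (sample, assay, cq) triple. Non-numeric cells such as
#' \code{"Undetermined"} or empty strings map to absent calls (\code{NA}).
#'
#' @param path Path to a comma- or tab-delimited text file with a header
#'   row. The delimiter is sniffed from the header line.
#' @param layout \code{"wide"} or \code{"long"}.
#' @param absentTokens Character values (after trimming) interpreted as an
#'   absent call.
#'
#' @return A [CqSet-class] preserving the input sample and assay order.
#' @details Duplicate (sample, assay) keys, a missing header and
#'   non-rectangular wide rows are errors naming the offending row.
#' @seealso [writeCqTable()], [applyDetectionFilter()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample,assay,cq", "s1,miR-a,25.0", "s1,miR-b,30.0"), f)
#' readCqTable(f, layout = "long")
#' @importFrom utils read.table write.table
#' @export
readCqTable <- function(path, layout = c("wide", "long"),
                        absentTokens = c("Undetermined", "undetermined",
                                         "NA", "")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file (missing header): ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- tryCatch(
    read.table(path, header = TRUE, sep = sep, colClasses = "character",
               check.names = FALSE, strip.white = TRUE, fill = FALSE,
               quote = "\"", comment.char = ""),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  toCq <- function(x, where) {
    x <- trimws(x)
    out <- rep(NA_real_, length(x))
    num <- !is.na(x) & !(x %in% absentTokens)
    val <- suppressWarnings(as.numeric(x[num]))
    if (anyNA(val))
      stop("non-numeric Cq value '", x[num][which(is.na(val))[1]],
           "' in ", where, call. = FALSE)
    out[num] <- val
    out
  }
  if (layout == "long") {
    if (ncol(raw) < 3L)
      stop("long layout needs columns (sample, assay, cq); got ",
           ncol(raw), " columns")
    smp <- raw[[1L]]; asy <- raw[[2L]]
    key <- paste(smp, asy, sep = "\r")
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1L]
      stop(sprintf("duplicate (sample, assay) key at row %d: (%s, %s)",
                   d + 1L, smp[d], asy[d]))
    }
    cq <- toCq(raw[[3L]], "cq column")
    sids <- unique(smp); aids <- unique(asy)
    m <- matrix(NA_real_, length(aids), length(sids),
                dimnames = list(aids, sids))
    m[cbind(match(asy, aids), match(smp, sids))] <- cq
    CqSet(m)
  } else {
    if (ncol(raw) < 2L) stop("wide layout needs a sample column plus assays")
    sids <- raw[[1L]]
    if (anyDuplicated(sids))
      stop("duplicate sample id at row ",
           which(duplicated(sids))[1L] + 1L, ": ",
           sids[duplicated(sids)][1L])
    aids <- colnames(raw)[-1L]
    if (anyDuplicated(aids))
      stop("duplicate assay column: ", aids[duplicated(aids)][1L])
    m <- vapply(seq_along(aids), function(j)
      toCq(raw[[j + 1L]], sprintf("column '%s'", aids[j])),
      numeric(nrow(raw)))
    m <- matrix(m, nrow = nrow(raw),
                dimnames = list(NULL, aids))
    m <- t(m)                      # assays in rows
    colnames(m) <- sids
    CqSet(m)
  }
}

#' Write a Cq panel to a delimited text file
#'
#' Inverse of [readCqTable()]; absent calls are written as \code{"NA"}
#' (wide) or omitted rows are never produced (long writes every cell).
#'
#' @param x A [CqSet-class].
#' @param path Output path; a \code{.csv} extension selects commas,
#'   anything else tabs.
#' @param layout \code{"wide"} (samples in rows) or \code{"long"}.
#' @param digits Number of decimal places to print (default 4).
#' @return \code{path}, invisibly.
#' @export
writeCqTable <- function(x, path, layout = c("wide", "long"), digits = 4) {
  layout <- match.arg(layout)
  stopifnot(is(x, "CqSet"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- assay(x, "cq")
  fmt <- function(v) ifelse(is.na(v), "NA",
                            formatC(v, digits = digits, format = "f"))
  if (layout == "wide") {
    df <- data.frame(sample = colnames(m), check.names = FALSE)
    for (a in rownames(m)) df[[a]] <- fmt(m[a, ])
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(sample = rep(colnames(m), each = nrow(m)),
                     assay = rep(rownames(m), times = ncol(m)),
                     cq = fmt(as.vector(m)))
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Apply the 40-cycle detection filter
#'
#' Replaces every Cq at or above the detection cutoff with an absent call
#' (\code{NA}); all other cells are unchanged. Assays detected in zero
#' samples are retained in the matrix but flagged (see
#' [undetectedAssays()]) for exclusion from downstream analysis. The
#' filter is idempotent.
#'
#' @param x A [CqSet-class].
#' @param params A [NormParams-class]; only \code{maxCycles} is used here.
#' @return A filtered [CqSet-class].
#' @examples
#' m <- matrix(c(40, 39.9), 2, 1,
#'             dimnames = list(c("miR-a", "miR-b"), "s1"))
#' assay(applyDetectionFilter(CqSet(m)), "cq")
#' @rdname applyDetectionFilter
#' @aliases applyDetectionFilter,CqSet-method
setMethod("applyDetectionFilter", "CqSet", function(x, params = normParams()) {
  m <- assay(x, "cq")
  m[!is.na(m) & m >= params@maxCycles] <- NA_real_
  assay(x, "cq") <- m
  metadata(x)$undetectedAssays <- rownames(m)[rowSums(!is.na(m)) == 0L]
  metadata(x)$detectionCutoff <- params@maxCycles
  validObject(x)
  x
})

#' Delta-Cq normalization of a Cq panel
#'
#' Converts filtered Cq values to delta-Cq. With the internal-control
#' method, delta-Cq(sample, assay) = Cq(sample, assay) minus the mean Cq
#' of the control assays detected in that sample; with the global-mean
#' method the reference is the mean of all detected assays in the sample.
#' Absent cells stay missing. Control assays receive delta-Cq values too
#' (they are simply never part of a marker panel). Adding a constant to
#' every Cq of one sample leaves its delta-Cq row unchanged.
#'
#' @param x A [CqSet-class]; run [applyDetectionFilter()] first.
#' @param params A [NormParams-class].
#' @return A [DeltaCqSet-class] carrying the normalization provenance.
#' @details A sample in which no control assay is detected (internal
#'   control method) is a hard error listing the offending samples; no
#'   silent imputation is performed.
#' @examples
#' m <- matrix(c(20, 22, 25), 3, 1,
#'             dimnames = list(c("ctl-1", "ctl-2", "miR-t"), "s1"))
#' x <- CqSet(m)
#' p <- normParams(controlAssays = c("ctl-1", "ctl-2"))
#' assay(normalizeCq(applyDetectionFilter(x, p), p), "deltaCq")["miR-t", ]
#' @rdname normalizeCq
#' @aliases normalizeCq,CqSet-method
setMethod("normalizeCq", "CqSet", function(x, params = normParams()) {
  m <- assay(x, "cq")
  if (params@method == "internal_control") {
    ctl <- intersect(params@controlAssays, rownames(m))
    if (length(ctl) == 0L)
      stop("none of the control assays are present in the panel: ",
           paste(params@controlAssays, collapse = ", "))
    cm <- m[ctl, , drop = FALSE]
    nDet <- colSums(!is.na(cm))
    if (any(nDet == 0L))
      stop("no detected control assay in sample(s): ",
           paste(colnames(m)[nDet == 0L], collapse = ", "))
    ref <- colMeans(cm, na.rm = TRUE)
  } else {
    nDet <- colSums(!is.na(m))
    if (any(nDet == 0L))
      stop("no detected assay in sample(s): ",
           paste(colnames(m)[nDet == 0L], collapse = ", "))
    ref <- colMeans(m, na.rm = TRUE)
  }
  d <- sweep(m, 2L, ref, "-")
  se <- SummarizedExperiment(assays = list(deltaCq = d),
                             colData = colData(x))
  out <- new("DeltaCqSet", se, normalization = params)
  metadata(out)$referenceMean <- ref
  metadata(out)$undetectedAssays <- metadata(x)$undetectedAssays
  out
})

#' Write a delta-Cq matrix as TSV
#'
#' Writes samples in rows and assays in columns, \code{NA} for missing
#' cells, matching the dialect [readCqTable()] reads back in wide layout.
#'
#' @param x A [DeltaCqSet-class].
#' @param path Output path.
#' @param digits Decimal places (default 4).
#' @return \code{path}, invisibly.
#' @export
writeDeltaCq <- function(x, path, digits = 4) {
  stopifnot(is(x, "DeltaCqSet"))
  m <- assay(x, "deltaCq")
  df <- data.frame(sample = colnames(m), check.names = FALSE)
  for (a in rownames(m))
    df[[a]] <- ifelse(is.na(m[a, ]), "NA",
                      formatC(m[a, ], digits = digits, format = "f"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
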