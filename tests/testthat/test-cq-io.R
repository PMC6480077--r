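suppressPackageStartupMessages(library(SummarizedExperiment))

test_that("long and wide Cq tables are read faithfully", {
  f <- writeWideFixture(c("sample,assay,cq",
                          "s1,miR-a,25.0",
                          "s1,miR-b,30.0",
                          "s2,miR-a,26.5"))
  x <- readCqTable(f, layout = "long")
  expect_s4_class(x, "CqSet")
  m <- assay(x, "cq")
  expect_identical(dim(m), c(2L, 2L))
  expect_equal(m["miR-a", "s1"], 25.0)
  expect_equal(m["miR-b", "s1"], 30.0)
  expect_true(is.na(m["miR-b", "s2"]))   # pair never observed

  w <- writeWideFixture(c("sample\tmiR-a\tmiR-b",
                          "s1\t25.0\tUndetermined",
                          "s2\t26.0\t31.5"), ext = ".tsv")
  y <- readCqTable(w, layout = "wide")
  expect_true(is.na(assay(y, "cq")["miR-b", "s1"]))
  expect_equal(assay(y, "cq")["miR-b", "s2"], 31.5)
})

test_that("malformed tables raise parse errors naming the offender", {
  f <- writeWideFixture(c("sample,assay,cq",
                          "s1,miR-a,25.0",
                          "s1,miR-a,26.0"))
  expect_error(readCqTable(f, layout = "long"), "duplicate.*s1, miR-a")

  dupcol <- writeWideFixture(c("sample,miR-a,miR-a", "s1,25,26"))
  expect_error(readCqTable(dupcol, layout = "wide"), "duplicate assay")

  ragged <- writeWideFixture(c("sample,miR-a,miR-b", "s1,25", "s2,26,27"))
  expect_error(readCqTable(ragged, layout = "wide"))

  garbage <- writeWideFixture(c("sample,assay,cq", "s1,miR-a,abc"))
  expect_error(readCqTable(garbage, layout = "long"), "non-numeric")
})

test_that("Cq tables round-trip through write/read in both layouts", {
  set.seed(11)
  m <- matrix(round(runif(12, 20, 39), 3), 3, 4,
              dimnames = list(paste0("miR-", 1:3), paste0("s", 1:4)))
  m[2, 3] <- NA
  x <- CqSet(m)
  for (layout in c("wide", "long")) {
    f <- tempfile(fileext = ".tsv")
    writeCqTable(x, f, layout = layout)
    y <- readCqTable(f, layout = layout)
    expect_equal(assay(y, "cq")[rownames(m), colnames(m)], m,
                 tolerance = 1e-6)
  }
})

test_that("detection filter censors at the cycle cutoff and is idempotent", {
  m <- matrix(c(40.0, 39.9, 41.2, 25.0, 40.0, 40.0), 3, 2,
              dimnames = list(c("miR-a", "miR-b", "miR-c"),
                              c("s1", "s2")))
  x <- applyDetectionFilter(CqSet(m))
  got <- assay(x, "cq")
  expect_true(is.na(got["miR-a", "s1"]))      # exactly at cutoff: absent
  expect_equal(got["miR-b", "s1"], 39.9)      # below cutoff: unchanged
  expect_true(is.na(got["miR-c", "s1"]))
  expect_identical(undetectedAssays(x), "miR-c")  # absent in all samples
  twice <- applyDetectionFilter(x)
  expect_equal(assay(twice, "cq"), got)
  expect_identical(undetectedAssays(twice), undetectedAssays(x))
})

test_that("internal-control normalization subtracts the control mean", {
  m <- matrix(c(20, 22, 25, 21, 23, 24), 3, 2,
              dimnames = list(c("ctl-1", "ctl-2", "miR-t"),
                              c("s1", "s2")))
  p <- normParams(controlAssays = c("ctl-1", "ctl-2"))
  d <- assay(normalizeCq(applyDetectionFilter(CqSet(m), p), p), "deltaCq")
  expect_equal(d["miR-t", "s1"], 4.0)          # 25 - mean(20, 22)
  expect_equal(d["miR-t", "s2"], 2.0)
  expect_equal(d["ctl-1", "s1"], -1.0)         # controls get dCq too
  # target equal to the control average
  m2 <- m; m2["miR-t", "s1"] <- 21
  d2 <- assay(normalizeCq(applyDetectionFilter(CqSet(m2), p), p), "deltaCq")
  expect_equal(d2["miR-t", "s1"], 0)
})

test_that("normalization is invariant to per-sample Cq shifts", {
  set.seed(21)
  m <- matrix(runif(30, 20, 35), 6, 5,
              dimnames = list(c(defaultControlAssays()[1:3],
                                paste0("miR-", 1:3)),
                              paste0("s", 1:5)))
  p <- normParams(controlAssays = defaultControlAssays()[1:3])
  shifted <- m
  shifted[, "s2"] <- shifted[, "s2"] + 3
  for (method in c("internal_control", "global_mean")) {
    pm <- normParams(method, controlAssays = defaultControlAssays()[1:3])
    d0 <- assay(normalizeCq(CqSet(m), pm), "deltaCq")
    d1 <- assay(normalizeCq(CqSet(shifted), pm), "deltaCq")
    expect_equal(d1, d0, tolerance = 1e-12)
  }
})

test_that("missing controls are averaged over; none detected is an error", {
  m <- matrix(c(20, NA, 25, NA, 22, 24), 3, 2,
              dimnames = list(c("ctl-1", "ctl-2", "miR-t"),
                              c("s1", "s2")))
  p <- normParams(controlAssays = c("ctl-1", "ctl-2"))
  d <- assay(normalizeCq(CqSet(m), p), "deltaCq")
  expect_equal(d["miR-t", "s1"], 5.0)          # mean over the one detected
  expect_equal(d["miR-t", "s2"], 2.0)
  m2 <- m; m2["ctl-2", "s2"] <- NA
  expect_error(normalizeCq(CqSet(m2), p), "s2")

  expect_error(normalizeCq(CqSet(m), normParams(controlAssays = "nope")),
               "none of the control assays")
})

test_that("absent Cq cells propagate to missing delta-Cq and TSV output", {
  m <- matrix(c(20, 22, NA, 21, 23, 28), 3, 2,
              dimnames = list(c("ctl-1", "ctl-2", "miR-t"),
                              c("s1", "s2")))
  p <- normParams(controlAssays = c("ctl-1", "ctl-2"))
  dset <- normalizeCq(CqSet(m), p)
  expect_true(is.na(assay(dset, "deltaCq")["miR-t", "s1"]))
  expect_identical(normalization(dset)@method, "internal_control")
  f <- tempfile(fileext = ".tsv")
  writeDeltaCq(dset, f)
  back <- read.delim(f, check.names = FALSE)
  expect_true(is.na(back[back$sample == "s1", "miR-t"]))
  expect_equal(back[back$sample == "s2", "miR-t"], 6, tolerance = 1e-6)
})
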