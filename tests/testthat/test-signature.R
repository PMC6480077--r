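makePaired <- function(d, drug = "drugA") {
  # build a PairedPanel whose post - pre difference equals d exactly
  pre <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  PairedPanel(pre, d, drug)
}

test_that("paired differential matches t.test assay by assay", {
  set.seed(31)
  pre <- matrix(rnorm(40, 25), 5, 8,
                dimnames = list(paste0("s", 1:5), paste0("m", 1:8)))
  post <- pre + matrix(rnorm(40, 0, 1), 5, 8)
  res <- pairedDifferential(PairedPanel(pre, post, "x"))
  for (j in c(1, 4, 8)) {
    tt <- t.test(post[, j], pre[, j], paired = TRUE)
    expect_equal(res$t_stat[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[j], tt$p.value, tolerance = 1e-10)
    expect_equal(res$mean_change[j], unname(tt$estimate), tolerance = 1e-10)
  }
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$q_value <= 1))
})

test_that("degenerate and symmetric-null changes follow the conventions", {
  d <- cbind(const = rep(2, 4), alt = c(1, -1, 1, -1), zero = rep(0, 4))
  rownames(d) <- paste0("s", 1:4)
  res <- pairedDifferential(makePaired(d))
  expect_equal(res$p_value[res$assay == "const"], 0)   # zero variance
  expect_true(res$degenerate[res$assay == "const"])
  expect_equal(res$t_stat[res$assay == "alt"], 0)
  expect_equal(res$p_value[res$assay == "alt"], 1)
  expect_equal(res$direction[res$assay == "zero"], "none")
})

test_that("incomplete pairs are excluded; untestable assays carry NA", {
  d <- cbind(a = c(1, 2, NA, 3), b = c(1, NA, NA, NA))
  rownames(d) <- paste0("s", 1:4)
  res <- pairedDifferential(makePaired(d))
  expect_equal(res$n_pairs, c(3L, 1L))
  expect_true(is.na(res$p_value[2]))
  expect_true(is.na(res$q_value[2]))
  allBad <- matrix(NA_real_, 3, 2,
                   dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_error(pairedDifferential(makePaired(allBad)), "nothing to test")
})

test_that("BH adjustment matches the step-up oracle", {
  # hand example: p = (.01, .02, .03, .04) over m = 4 gives q = .04 each
  expect_equal(bhOracle(c(.01, .02, .03, .04)), rep(.04, 4))
  set.seed(32)
  for (m in c(10, 50, 200)) {
    d <- matrix(rnorm(4 * m), 4, m,
                dimnames = list(paste0("s", 1:4), paste0("m", seq_len(m))))
    res <- pairedDifferential(makePaired(d))
    expect_equal(res$q_value, bhOracle(res$p_value), tolerance = 1e-12)
  }
})

test_that("common signature intersects q and direction and flags conflicts", {
  a <- data.frame(assay = c("m1", "m2", "m3", "m4"),
                  q_value = c(0.01, 0.04, 0.2, 0.01),
                  direction = c("up", "down", "up", "up"),
                  mean_change = c(-1, 1, -1, -1))
  b <- data.frame(assay = c("m1", "m2", "m3", "m4"),
                  q_value = c(0.04, 0.02, 0.01, 0.03),
                  direction = c("up", "down", "up", "down"),
                  mean_change = c(-1, 1, -1, 1))
  pnl <- commonSignature(a, b, 0.05)
  expect_identical(upAssays(pnl), "m1")
  expect_identical(downAssays(pnl), "m2")     # m3 fails q in a
  expect_identical(pnl@metadata$conflicts, "m4")
})

test_that("negating all changes swaps up and down memberships exactly", {
  set.seed(33)
  d <- matrix(rnorm(6 * 40, 0, 1), 6, 40,
              dimnames = list(paste0("s", 1:6), paste0("m", 1:40)))
  d[, 1:5] <- d[, 1:5] - 2
  d[, 6:10] <- d[, 6:10] + 2
  r1 <- pairedDifferential(makePaired(d))
  r2 <- pairedDifferential(makePaired(-d))
  p1 <- commonSignature(r1, r1, 0.05)
  p2 <- commonSignature(r2, r2, 0.05)
  expect_setequal(upAssays(p2), downAssays(p1))
  expect_setequal(downAssays(p2), upAssays(p1))
})

test_that("top-marker selection ranks by |mean change| with fixed tie-breaks", {
  ref <- data.frame(assay = c("a", "b", "c", "d", "e"),
                    mean_change = c(-2.0, -1.0, -1.0, -0.5, 3.0),
                    q_value = c(0.01, 0.02, 0.001, 0.04, 0.01))
  pnl <- MarkerPanel(up = c("a", "b", "c", "d"), down = "e")
  sel <- selectTopMarkers(pnl, ref, kUp = 2, kDown = 1)
  expect_identical(upAssays(sel), c("a", "c"))  # tie b/c broken by q
  expect_identical(downAssays(sel), "e")
  # equal mean and q: lexicographic id
  ref2 <- ref; ref2$q_value[2:3] <- 0.02
  sel2 <- selectTopMarkers(pnl, ref2, kUp = 2, kDown = 1)
  expect_identical(upAssays(sel2), c("a", "b"))
  expect_warning(selectTopMarkers(pnl, ref, kUp = 9, kDown = 1),
                 "keeping all")
  expect_error(selectTopMarkers(MarkerPanel("zz", "e"), ref),
               "absent from reference")
})

test_that("the default MOR panel is the published 4 + 4 set", {
  pnl <- defaultMorPanel()
  expect_identical(upAssays(pnl),
                   c("hsa-miR-423-3p", "hsa-let-7a-5p", "hsa-miR-26a-5p",
                     "hsa-let-7f-5p"))
  expect_identical(downAssays(pnl),
                   c("hsa-miR-144-3p", "hsa-miR-451a", "hsa-miR-215",
                     "hsa-miR-363-3p"))
  expect_length(intersect(upAssays(pnl), downAssays(pnl)), 0)
  # usable on the packaged patient table without renaming
  t2 <- table2Fixture()
  expect_true(all(c(upAssays(pnl), downAssays(pnl)) %in%
                  colnames(t2$markers)))
})

test_that("marker panels round-trip through the TSV format", {
  f <- tempfile(fileext = ".tsv")
  writeMarkerPanel(defaultMorPanel(), f)
  back <- readMarkerPanel(f)
  expect_identical(upAssays(back), upAssays(defaultMorPanel()))
  expect_identical(downAssays(back), downAssays(defaultMorPanel()))
})
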