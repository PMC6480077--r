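test_that("baseline and delta VAS windows average available days", {
  b <- baselineVas(c(-3, -2, -1, 1), c(10, 12, 14, 16))
  expect_equal(b$value, 13)
  expect_equal(b$nDays, 4L)
  only1 <- baselineVas(c(1, 2), c(20, 9))
  expect_equal(only1$value, 20)          # day 2 is not a baseline day
  expect_equal(only1$nDays, 1L)
  expect_true(is.na(baselineVas(c(2, 3), c(9, 9))$value))

  dv <- deltaVas(c(-3, -2, -1, 1, 2, 3, 4), c(10, 12, 14, 16, 9, 9, 12))
  expect_equal(dv$delta, -3)
  expect_equal(dv$treatment, 10)
  expect_true(is.na(deltaVas(c(-3, -2), c(10, 10))$delta))  # no treatment window
  same <- deltaVas(c(-3, -2, -1, 1, 2, 3, 4), rep(15, 7))
  expect_equal(same$delta, 0)
})

test_that("all-days-present delta equals the two-window closed form", {
  set.seed(51)
  for (i in 1:10) {
    v <- runif(7, 0, 60)
    dv <- deltaVas(c(-3, -2, -1, 1, 2, 3, 4), v)
    expect_equal(dv$delta, mean(v[5:7]) - mean(v[1:4]), tolerance = 1e-12)
  }
})

test_that("VAS validation rejects out-of-range and duplicated days", {
  expect_error(deltaVas(c(1, 1), c(10, 11)), "one VAS record per day")
  expect_error(deltaVas(c(0), c(10)), "day indices")
  expect_error(deltaVas(c(1), c(130)), "within \\[0, 100\\]")
})

test_that("per-patient efficacy summary assembles both windows", {
  v <- rbind(
    data.frame(patient_id = "p1", day = c(-3, -2, -1, 1, 2, 3, 4),
               vas = c(10, 12, 14, 16, 9, 9, 12)),
    data.frame(patient_id = "p2", day = c(-1, 1), vas = c(20, 22)))
  eff <- efficacySummary(v)
  expect_equal(eff$delta_vas[eff$patient_id == "p1"], -3)
  expect_true(is.na(eff$delta_vas[eff$patient_id == "p2"]))
  expect_equal(eff$baseline_days, c(4L, 2L))
})

test_that("Spearman association has rho symmetries and the t-approx p", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y <- c(2, 0.5, 4.1, 1.4, 8, 3.1, 6)
  a <- spearmanAssoc(x, y, method = "approx")
  expect_equal(a$rho, cor(x, y, method = "spearman"))
  tstat <- a$rho * sqrt((a$n - 2) / (1 - a$rho^2))
  expect_equal(a$p_value, 2 * pt(-abs(tstat), a$n - 2))
  # sign flip and monotone-transform invariance
  b <- spearmanAssoc(x, -y, method = "approx")
  expect_equal(b$rho, -a$rho)
  expect_equal(b$p_value, a$p_value)
  cfun <- spearmanAssoc(exp(x), y^3 + 2, method = "approx")
  expect_equal(cfun$rho, a$rho)
  # perfect monotone pairs
  expect_equal(spearmanAssoc(1:5, c(2, 4, 8, 16, 32))$rho, 1)
  # degenerate: a constant variable has no rank order
  expect_true(spearmanAssoc(rep(1, 5), 1:5)$degenerate)
  expect_error(spearmanAssoc(1:3, 3:1), ">= 4")
})

test_that("exact permutation p matches enumeration and cor.test at small n", {
  set.seed(52)
  for (n in c(5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    ex <- spearmanAssoc(x, y, method = "exact")
    expect_equal(ex$p_value, spearmanPermOracle(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = TRUE))
    expect_equal(ex$p_value, ct$p.value, tolerance = 1e-9)
  }
  # ties are handled through mid-ranks in the enumeration as well
  x <- c(1, 1, 2, 3, 4, 4); y <- c(2, 1, 3, 3, 5, 4)
  ex <- spearmanAssoc(x, y, method = "exact")
  expect_equal(ex$p_value, spearmanPermOracle(x, y), tolerance = 1e-12)
  # auto mode reports both for small n
  both <- spearmanAssoc(x, y)
  expect_identical(both$method, "approx+exact")
  expect_true(!is.null(both$p_exact))
})

test_that("Fisher enrichment reproduces hand tables and conventions", {
  cls <- rep(1:2, c(15, 8))
  dv <- c(rep(5, 13), rep(-5, 2), rep(5, 1), rep(-5, 7))
  fe <- fisherEnrichment(cls, dv)
  expect_equal(unname(fe$table), matrix(c(13, 1, 2, 7), 2))
  expect_equal(fe$p_value, 1.05e-3, tolerance = 5e-3)
  expect_equal(fe$p_value, fisherOracle(13, 2, 1, 7), tolerance = 1e-12)
  expect_equal(fe$odds_ratio, (13 * 7) / (2 * 1))
  # perfectly balanced table
  bal <- fisherEnrichment(rep(1:2, each = 10), rep(c(5, -5), 10))
  expect_equal(bal$p_value, 1)
  # delta VAS of exactly zero counts as not-worsened
  zf <- fisherEnrichment(c(1, 1, 2, 2), c(0, 1, -1, 0))
  expect_equal(unname(zf$table), matrix(c(1, 0, 1, 2), 2))
  expect_true(zf$haldane)
  expect_error(fisherEnrichment(c(1, 1, NA), c(1, 2, 3)), "class 2")
})

test_that("association report joins, excludes and degrades gracefully", {
  t2 <- table2Fixture()
  st <- classifyPatients(t2$markers, input = "neg_delta_cq")
  eff <- data.frame(patient_id = rownames(t2$markers),
                    delta_vas = t2$deltaVas)
  rep <- associationReport(st, eff)
  expect_equal(rep$n_evaluable, 23)
  expect_setequal(rep$excluded$patient_id, c("#9", "#17"))
  expect_true(all(rep$excluded$reason == "no_delta_vas"))
  expect_equal(sum(rep$fisher$table), 23)
  # permuting patient order leaves the report unchanged
  set.seed(53)
  perm <- sample(25)
  st2 <- classifyPatients(t2$markers[perm, ], input = "neg_delta_cq")
  rep2 <- associationReport(st2, eff[perm, ])
  expect_equal(rep2$spearman$p_value, rep$spearman$p_value)
  expect_equal(rep2$fisher$p_value, rep$fisher$p_value)
  # single represented class: Fisher skipped, Spearman still computed
  one <- st
  one@classLabel <- rep(1L, 25)
  rep3 <- associationReport(one, eff)
  expect_true(rep3$fisher$skipped)
  expect_false(is.null(rep3$spearman$p_value))
  expect_error(associationReport(st, data.frame(patient_id = "zz",
                                                delta_vas = 1)),
               "no shared patient ids")
})

test_that("association reports serialize to JSON and TSV", {
  t2 <- table2Fixture()
  st <- classifyPatients(t2$markers, input = "neg_delta_cq")
  rep <- associationReport(st, data.frame(patient_id = rownames(t2$markers),
                                          delta_vas = t2$deltaVas))
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  writeAssociationReport(rep, jf, tf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$n_evaluable, 23)
  expect_equal(parsed$spearman$rho, rep$spearman$rho, tolerance = 1e-9)
  roster <- read.delim(tf, comment.char = "")
  expect_equal(nrow(roster), 23)
})
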