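# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# Benjamini-Hochberg step-up: sort, scale by m/rank, cumulative min from
# the largest p downwards, cap at 1
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided Fisher exact p for a 2x2 table by enumerating every table
# with the observed margins and summing hypergeometric probabilities not
# exceeding the observed one (with the classical tolerance factor)
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  xs <- lo:hi
  pr <- dhyper(xs, c1, n - c1, r1)
  pObs <- dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# exact two-sided Spearman permutation p by naive recursive enumeration
spearmanPermOracle <- function(x, y) {
  permute <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(permute(v[-i]), function(p) c(v[i], p)))
    out
  }
  obs <- abs(cor(x, y, method = "spearman"))
  hits <- vapply(permute(seq_along(y)), function(p)
    abs(cor(x, y[p], method = "spearman")) >= obs - 1e-12, logical(1))
  mean(hits)
}

# chance-corrected agreement between two partitions (ignoring NA labels)
ariOf <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  mclust::adjustedRandIndex(a[keep], b[keep])
}

# small wide Cq file on disk for IO tests
writeWideFixture <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
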