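code2 <- geneticCode("2")

test_that("neutrality regression recovers identity and flat responses", {
  x <- c(0.2, 0.3, 0.4, 0.5)
  f1 <- suppressWarnings(neutralityFit(x, x))       # perfect fit
  expect_equal(f1$slope, 1)
  expect_equal(f1$R2, 1)
  f0 <- suppressWarnings(neutralityFit(x, rep(0.45, 4)))
  expect_equal(f0$slope, 0)
  fd <- neutralityFit(rep(0.4, 4), x)
  expect_true(fd$degenerate)
  expect_true(is.na(fd$slope))
  expect_error(neutralityFit(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
})

test_that("expected-ENC curve is symmetric with maximum 60.5 at s = 0.5", {
  expect_equal(encExpected(0.5), 60.5)
  expect_equal(encExpected(0), 31)
  expect_equal(encExpected(1), 32)
  s <- seq(0.05, 0.95, by = 0.05)
  expect_equal(encExpected(s) - s, encExpected(1 - s) - (1 - s))
  expect_true(all(encExpected(s) <= 60.5))
  # deviation is positive for genes below the curve
  expect_gt(encDeviation(40, 0.5), 0)
})

test_that("PR2 coordinates sit at parity for balanced usage", {
  cts <- setNames(rep(0, 64), codonAlphabet())
  cts[c("GGA", "GGT", "GGG", "GGC")] <- 4   # Gly box, A=T, G=C
  p <- pr2(mitocodon:::codonCountTable(cts, code2))
  expect_equal(p$x, 0.5)
  expect_equal(p$y, 0.5)
  expect_identical(p$quadrant, "boundary")
})

test_that("PR2 is scale-invariant and assigns quadrants correctly", {
  cts <- setNames(rep(0, 64), codonAlphabet())
  cts[c("GGA", "GGT", "GGG", "GGC")] <- c(8, 2, 1, 5)  # A>T, C>G
  t1 <- mitocodon:::codonCountTable(cts, code2)
  t2 <- mitocodon:::codonCountTable(cts * 7, code2)
  p1 <- pr2(t1); p2 <- pr2(t2)
  expect_equal(p1$x, p2$x)
  expect_equal(p1$y, p2$y)
  expect_identical(p1$quadrant, "II")   # y > 0.5 (A-rich), x < 0.5 (C-rich)
  cts2 <- setNames(rep(0, 64), codonAlphabet())
  cts2[c("GGA", "GGT", "GGG", "GGC")] <- c(1, 5, 6, 2)
  expect_identical(pr2(mitocodon:::codonCountTable(cts2, code2))$quadrant,
                   "IV")
  expect_error(pr2(mitocodon:::codonCountTable(
    setNames(rep(0, 64), codonAlphabet()), code2)), "empty")
})

test_that("fourfold PR2 stratum uses only fully degenerate boxes", {
  # counts only in a 2-fold family must not reach the fourfold stratum
  cts <- setNames(rep(0, 64), codonAlphabet())
  cts[c("TTT", "TTC")] <- 10
  expect_error(pr2(mitocodon:::codonCountTable(cts, code2),
                   mode = "fourfold_only"))
  p <- pr2(mitocodon:::codonCountTable(cts, code2),
           mode = "all_synonymous")
  expect_equal(p$y, 0)  # A3 = 0, T3 = 10
  expect_equal(p$x, 0)  # G3 = 0, C3 = 10
})

test_that("codon classification respects its threshold logic", {
  mk <- function(v) {
    cts <- setNames(rep(0, 64), codonAlphabet())
    cts[names(v)] <- v
    rscu(mitocodon:::codonCountTable(cts, code2))
  }
  all_ <- mk(c(TTT = 15, TTC = 5, TAT = 5, TAC = 15))
  hi <- mk(c(TTT = 12, TTC = 4, TAT = 9, TAC = 11))
  lo <- mk(c(TTT = 12, TTC = 4, TAT = 1, TAC = 19))
  cls <- classifyCodons(all_, hi, lo)
  # TTT: RSCU 1.5 in both groups, delta 0 -> high-frequency only
  expect_true(cls["TTT", "hfc"])
  expect_false(cls["TTT", "high_expression"])
  expect_false(cls["TTT", "optimal"])
  # TAT: overall RSCU 0.5, delta 0.8 -> high-expression only
  expect_false(cls["TAT", "hfc"])
  expect_true(cls["TAT", "high_expression"])
  expect_false(cls["TAT", "optimal"])
  # TAC: overall RSCU 1.5, delta = 1.1 - 1.9 < 0 -> HFC only
  expect_true(cls["TAC", "hfc"])
  expect_false(cls["TAC", "optimal"])
})

test_that("optimal codons are always both high-frequency and high-expression", {
  set.seed(42)
  for (i in 1:25) {
    a <- rscu(mitocodon:::codonCountTable(randomCountTable(code2), code2))
    h <- rscu(mitocodon:::codonCountTable(randomCountTable(code2), code2))
    l <- rscu(mitocodon:::codonCountTable(randomCountTable(code2), code2))
    cls <- classifyCodons(a, h, l)
    ok <- !is.na(cls$optimal)
    expect_true(all(!cls$optimal[ok] |
                      (cls$hfc[ok] & cls$high_expression[ok])))
  }
})

test_that("high/low bias groups are disjoint quartiles by the ranking key", {
  sim <- fixtureSim()
  cdsSet <- vapply(sim$blocks, function(b) as.character(blockSeqs(b))[1],
                   character(1))
  idx <- usageIndices(cdsSet, code2, taxon = "t1")
  grp <- highLowGroups(idx, key = "ENC")
  expect_length(grp$high, 3)
  expect_length(grp$low, 3)
  expect_length(intersect(grp$high, grp$low), 0)
  expect_true(max(idx$ENC[idx$gene %in% grp$high]) <=
                min(idx$ENC[idx$gene %in% grp$low]))
})

test_that("index correlation matrices are symmetric with unit diagonal", {
  set.seed(11)
  m <- matrix(rnorm(13 * 5), 13, 5,
              dimnames = list(NULL, c("ENC", "GC3s", "CAI", "CBI", "FOP")))
  m[, "FOP"] <- m[, "CBI"] + rnorm(13, sd = 0.05)  # strongly coupled pair
  res <- indexCorrelation(m)
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 5))
  expect_lt(res$p["CBI", "FOP"], 0.001)
  expect_identical(res$stars["CBI", "FOP"], "***")
  # constant column flagged NA
  m2 <- cbind(m, K = rep(2, 13))
  res2 <- indexCorrelation(m2)
  expect_true(all(is.na(res2$r["K", colnames(m)])))
})

test_that("correlation p-values are calibrated on independent columns", {
  set.seed(202)
  reps <- 1000
  hits <- 0
  for (i in seq_len(reps)) {
    m <- matrix(rnorm(26), 13, 2, dimnames = list(NULL, c("u", "v")))
    if (indexCorrelation(m)$p["u", "v"] < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
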