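code2 <- geneticCode("2")

test_that("codon counting excludes stops and is additive", {
  t1 <- countCodons("ATGATGTAA", code2)
  expect_equal(unname(codonCounts(t1)[["ATG"]]), 2)
  expect_equal(t1@nCodons, 2)
  # AGA is a stop under table 2: dropped
  t2 <- countCodons("ATGAGA", code2)
  expect_equal(t2@nCodons, 1)
  # ambiguous codons skipped and tallied
  t3 <- countCodons("ATGNNTATG", code2)
  expect_equal(t3@nCodons, 2)
  expect_equal(t3@nAmbiguous, 1)
  # concatenation equals the sum of the parts
  a <- randomCDS(30, code2, seed = 1)
  b <- randomCDS(50, code2, seed = 2)
  expect_equal(codonCounts(countCodons(c(a, b), code2)),
               codonCounts(countCodons(a, code2)) +
                 codonCounts(countCodons(b, code2)))
})

test_that("RSCU reflects uniform and extreme synonym usage", {
  cts <- setNames(rep(0, 64), codonAlphabet())
  cts[c("TTT", "TTC")] <- c(5, 5)          # Phe, 2-fold, uniform
  cts[c("TAT", "TAC")] <- c(10, 0)         # Tyr, 2-fold, extreme
  r <- rscu(mitocodon:::codonCountTable(cts, code2))
  expect_equal(r["TTT", "rscu"], 1)
  expect_equal(r["TTC", "rscu"], 1)
  expect_equal(r["TAT", "rscu"], 2)
  expect_equal(r["TAC", "rscu"], 0)
  # empty families flagged NA, not dropped
  expect_true(all(is.na(r[r$aa == "P", "rscu"])))
  expect_equal(nrow(r), 60)                # all multi-synonym sense codons
})

test_that("RSCU family sums equal the degeneracy on random tables", {
  set.seed(99)
  for (i in 1:20) {
    cts <- randomCountTable(code2)
    r <- rscu(mitocodon:::codonCountTable(cts, code2))
    sums <- tapply(r$rscu, r$aa, sum)
    deg <- tapply(r$degeneracy, r$aa, unique)
    ok <- !is.na(sums)
    expect_equal(unname(sums[ok]), unname(deg[ok]), tolerance = 1e-12)
  }
})

test_that("ENC attains its limits and stays in [20, 61]", {
  code1 <- geneticCode("1")
  uni <- setNames(rep(100, 64), codonAlphabet())
  uni[stopCodons(code1)] <- 0
  expect_equal(as.numeric(enc(mitocodon:::codonCountTable(uni, code1))), 61)
  one <- setNames(rep(0, 64), codonAlphabet())
  for (f in codonFamilies(code1)) one[f[1]] <- 100
  expect_equal(as.numeric(enc(mitocodon:::codonCountTable(one, code1))), 20)
  set.seed(7)
  for (i in 1:20) {
    e <- as.numeric(enc(mitocodon:::codonCountTable(
      randomCountTable(code2), code2)))
    expect_gte(e, 20); expect_lte(e, 61)
  }
})

test_that("ENC is relabeling-invariant and decreases with concentration", {
  # swapping codon labels within a family leaves ENC unchanged
  cts <- randomCountTable(code2, seed = 31)
  t0 <- mitocodon:::codonCountTable(cts, code2)
  sw <- cts
  phe <- codonFamilies(code2)[["F"]]
  sw[phe] <- rev(sw[phe])
  expect_equal(as.numeric(enc(mitocodon:::codonCountTable(sw, code2))),
               as.numeric(enc(t0)))
  # concentrating each family's usage onto one codon lowers ENC
  conc <- setNames(rep(0, 64), codonAlphabet())
  for (f in codonFamilies(code2)) conc[f[1]] <- sum(cts[f])
  expect_lt(as.numeric(enc(mitocodon:::codonCountTable(conc, code2))),
            as.numeric(enc(t0)))
})

test_that("ENC, CAI, CBI and FOP agree with naive reference evaluation", {
  set.seed(1234)
  ref <- mitocodon:::codonCountTable(randomCountTable(code2, lambda = 40),
                                     code2)
  w <- caiWeights(ref)
  opt <- optimalCodonSet(ref)
  for (i in 1:100) {
    cts <- randomCountTable(code2)
    tab <- mitocodon:::codonCountTable(cts, code2)
    expect_equal(as.numeric(enc(tab)), bruteENC(cts, code2),
                 tolerance = 1e-9)
    expect_equal(suppressWarnings(cai(tab, w)), bruteCAI(cts, w),
                 tolerance = 1e-9)
    got <- cbiFop(tab, opt)
    want <- bruteCbiFop(cts, opt, code2)
    expect_equal(got$CBI, want$CBI, tolerance = 1e-9)
    expect_equal(got$FOP, want$FOP, tolerance = 1e-9)
  }
})

test_that("synonymous third-position frequencies form a simplex", {
  cts <- randomCountTable(code2, seed = 77)
  f <- x3s(mitocodon:::codonCountTable(cts, code2))
  expect_equal(f$A3s + f$T3s + f$G3s + f$C3s, 1, tolerance = 1e-12)
  expect_equal(f$GC3s, f$G3s + f$C3s, tolerance = 1e-12)
  # saturation: every synonymous third base G or C
  gc <- setNames(rep(0, 64), codonAlphabet())
  gc[c("GGG", "GGC", "CCC", "CCG")] <- 5
  expect_equal(x3s(mitocodon:::codonCountTable(gc, code2))$GC3s, 1)
  # legacy exclusion drops the named families from the denominator
  f2 <- x3s(mitocodon:::codonCountTable(cts, code2),
            legacyExclude = c("M", "W"))
  expect_false(isTRUE(all.equal(f$GC3s, f2$GC3s)))
})

test_that("GC3s is invariant under third-position-preserving codon swaps", {
  # Leu TTA -> CTA keeps the third base: GC3s must not move
  cts <- setNames(rep(0, 64), codonAlphabet())
  cts[c("TTA", "CTG", "GCA", "GCC")] <- c(6, 4, 3, 7)
  a <- x3s(mitocodon:::codonCountTable(cts, code2))
  sw <- cts
  sw[c("TTA", "CTA")] <- c(0, 6)
  b <- x3s(mitocodon:::codonCountTable(sw, code2))
  expect_equal(a$GC3s, b$GC3s)
  expect_equal(a$A3s, b$A3s)
})

test_that("CAI weights and limits behave per definition", {
  ref <- mitocodon:::codonCountTable(randomCountTable(code2, lambda = 30,
                                                      seed = 3), code2)
  w <- caiWeights(ref)
  # the most-used codon of each family gets weight 1
  r <- rscu(ref)
  for (aa in unique(r$aa)) {
    d <- r[r$aa == aa, ]
    if (all(is.na(d$rscu))) next
    expect_equal(unname(w[d$codon[which.max(d$rscu)]]), 1)
  }
  # a gene using only weight-1 codons has CAI = 1
  best <- names(w)[!is.na(w) & w == 1]
  gene <- setNames(rep(0, 64), codonAlphabet())
  gene[best] <- 3
  expect_equal(cai(mitocodon:::codonCountTable(gene, code2), w), 1)
  # unused reference codons floor with a warning
  ref2 <- setNames(rep(0, 64), codonAlphabet())
  ref2[c("TTT", "TAT", "TAC")] <- c(10, 5, 5)
  w2 <- caiWeights(mitocodon:::codonCountTable(ref2, code2))
  gene2 <- setNames(rep(0, 64), codonAlphabet())
  gene2[c("TTC")] <- 4    # TTC unused in reference -> w = 0
  expect_warning(
    v <- cai(mitocodon:::codonCountTable(gene2, code2), w2),
    "floored")
  expect_equal(v, 0.01)
})

test_that("CBI and FOP hit their reference points", {
  ref <- mitocodon:::codonCountTable(randomCountTable(code2, lambda = 30,
                                                      seed = 8), code2)
  opt <- optimalCodonSet(ref)
  onlyOpt <- setNames(rep(0, 64), codonAlphabet())
  onlyOpt[opt] <- 5
  got <- cbiFop(mitocodon:::codonCountTable(onlyOpt, code2), opt)
  expect_equal(got$FOP, 1)
  expect_equal(got$CBI, 1)
  # uniform synonym usage: CBI = 0 by construction
  uni <- setNames(rep(0, 64), codonAlphabet())
  uni[senseCodons(code2)] <- 6
  got2 <- cbiFop(mitocodon:::codonCountTable(uni, code2), opt)
  expect_equal(got2$CBI, 0, tolerance = 1e-12)
  expect_error(cbiFop(mitocodon:::codonCountTable(uni, code2),
                      character(0)), "empty")
})

test_that("GRAVY and aromaticity follow the translated protein", {
  # poly-Ile: Kyte-Doolittle 4.5
  polyI <- paste(rep("ATT", 10), collapse = "")
  ga <- gravyAromo(polyI, code2)
  expect_equal(ga$GRAVY, 4.5)
  expect_equal(ga$AROMO, 0)
  # aromatic-only protein
  aro <- paste(c("TTT", "TAT", "TGG"), collapse = "")
  expect_equal(gravyAromo(aro, code2)$AROMO, 1)
  # terminal stop excluded from the protein
  expect_equal(gravyAromo(paste0(polyI, "TAA"), code2)$L_aa, 10)
})

test_that("the per-gene index battery is coherent", {
  sim <- fixtureSim()
  cds <- as.character(blockSeqs(sim$blocks[["COX1"]]))[1]
  cdsSet <- setNames(
    vapply(sim$blocks, function(b) as.character(blockSeqs(b))[1],
           character(1)),
    names(sim$blocks))
  idx <- usageIndices(cdsSet, code2, taxon = "t1")
  expect_equal(nrow(idx), 13)
  expect_true(all(idx$ENC >= 20 & idx$ENC <= 61))
  expect_true(all(idx$CAI > 0 & idx$CAI <= 1))
  expect_true(all(idx$FOP >= 0 & idx$FOP <= 1))
  expect_true(all(idx$AROMO >= 0 & idx$AROMO <= 1))
  expect_equal(idx$GC12, (idx$GC1 + idx$GC2) / 2)
  # simulated blocks carry no terminal stop: L_aa equals the codon count
  expect_equal(idx$L_aa, unname(sim$config$genes[idx$gene]))
})
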