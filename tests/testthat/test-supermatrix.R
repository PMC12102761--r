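mkBlock <- function(nCodons, taxa = c("a", "b", "c"), gene = "g",
                    seed = 1) {
  set.seed(seed)
  seqs <- vapply(taxa, function(t)
    paste(sample(c("A", "C", "G", "T"), nCodons * 3, replace = TRUE),
          collapse = ""), character(1))
  alignmentBlock(seqs, gene = gene, codonFramed = TRUE)
}

test_that("codon-position stripping keeps exactly the requested columns", {
  b <- mkBlock(100)
  s12 <- stripCodonPositions(b, c(1, 2))
  expect_equal(Biostrings::width(blockSeqs(s12))[1], 200)
  s1 <- stripCodonPositions(b, 1)
  expect_equal(Biostrings::width(blockSeqs(s1))[1], 100)
  # keep everything is the identity
  s123 <- stripCodonPositions(b, 1:3)
  expect_identical(as.character(blockSeqs(s123)),
                   as.character(blockSeqs(b)))
  # stripping demands a codon-framed block
  flat <- alignmentBlock(as.character(blockSeqs(s12)), gene = "g",
                         codonFramed = FALSE)
  expect_error(stripCodonPositions(flat, 1), "not codon-framed")
  # composition: {1,2} then position 1 of the pairs equals {1} directly
  twoStep <- vapply(as.character(blockSeqs(s12)), function(s)
    paste(strsplit(s, "")[[1]][seq(1, 200, 2)], collapse = ""),
    character(1))
  expect_identical(unname(twoStep),
                   unname(as.character(blockSeqs(s1))))
})

test_that("concatenation is additive and tiles partitions exactly", {
  blocks <- list(ATP6 = mkBlock(40, gene = "ATP6", seed = 2),
                 COX1 = mkBlock(90, gene = "COX1", seed = 3),
                 NAD5 = mkBlock(120, gene = "NAD5", seed = 4))
  sm <- concatenateAlignments(blocks)
  w <- Biostrings::width(blockSeqs(sm$block))[1]
  expect_equal(w, (40 + 90 + 120) * 3)
  # partition table tiles [1, w] with no overlap, in canonical order
  p <- sm$partitions
  expect_identical(p$gene, c("ATP6", "COX1", "NAD5"))
  expect_equal(p$start[1], 1)
  expect_equal(p$end[nrow(p)], w)
  expect_true(all(p$start[-1] == head(p$end, -1) + 1))
  # columns are traceable: each partition's slice equals the source block
  s <- as.character(blockSeqs(sm$block))
  for (i in seq_len(nrow(p))) {
    g <- p$gene[i]
    expect_identical(unname(substr(s, p$start[i], p$end[i])),
                     unname(as.character(blockSeqs(blocks[[g]]))))
  }
})

test_that("third-position exclusion retains exactly 2/3 of codon sites", {
  blocks <- list(ATP6 = mkBlock(40, gene = "ATP6", seed = 5),
                 COX1 = mkBlock(60, gene = "COX1", seed = 6))
  full <- concatenateAlignments(blocks)
  p12 <- concatenateAlignments(blocks, keepPositions = c(1, 2))
  wFull <- Biostrings::width(blockSeqs(full$block))[1]
  w12 <- Biostrings::width(blockSeqs(p12$block))[1]
  expect_equal(w12, wFull * 2 / 3)
})

test_that("strip-then-concatenate commutes with concatenate-then-strip", {
  blocks <- list(ATP6 = mkBlock(30, gene = "ATP6", seed = 7),
                 COX2 = mkBlock(50, gene = "COX2", seed = 8))
  a <- concatenateAlignments(lapply(blocks, stripCodonPositions, keep = 1:2))
  b <- concatenateAlignments(blocks, keepPositions = 1:2)
  expect_identical(as.character(blockSeqs(a$block)),
                   as.character(blockSeqs(b$block)))
})

test_that("taxon-set mismatches error in strict mode and pad otherwise", {
  blocks <- list(ATP6 = mkBlock(30, gene = "ATP6", seed = 9),
                 COX1 = mkBlock(30, taxa = c("a", "b"), gene = "COX1",
                                seed = 10))
  expect_error(concatenateAlignments(blocks), "COX1")
  sm <- concatenateAlignments(blocks, strict = FALSE)
  s <- as.character(blockSeqs(sm$block))
  expect_match(s[["c"]], "-{90}$")
})

test_that("gap trimming drops gap-rich columns and whole codons, once", {
  seqs <- c(a = "ATG-CGTAA", b = "ATG-CGTAA", c = "ATGACGTAA")
  b1 <- alignmentBlock(seqs, codonFramed = FALSE)
  t1 <- gapTrim(b1, 0.5)
  expect_equal(Biostrings::width(blockSeqs(t1))[1], 8)  # one column out
  # codon-framed: the whole codon containing the gap column goes
  b2 <- alignmentBlock(seqs, codonFramed = TRUE)
  t2 <- gapTrim(b2, 0.5)
  expect_equal(Biostrings::width(blockSeqs(t2))[1], 6)
  expect_identical(as.character(blockSeqs(t2))[["a"]], "ATGTAA")
  # gap-free input unchanged; trimming is idempotent
  clean <- mkBlock(20, seed = 11)
  expect_identical(as.character(blockSeqs(gapTrim(clean, 0.5))),
                   as.character(blockSeqs(clean)))
  t3 <- gapTrim(t2, 0.5)
  expect_identical(as.character(blockSeqs(t3)),
                   as.character(blockSeqs(t2)))
  allGap <- alignmentBlock(c(a = "---", b = "---"), codonFramed = FALSE)
  expect_error(gapTrim(allGap, 0.5), "every column")
})

test_that("the five standard datasets assemble with correct site counts", {
  cds <- list(ATP6 = mkBlock(40, gene = "ATP6", seed = 12),
              COX1 = mkBlock(80, gene = "COX1", seed = 13))
  rna <- list(srRNA = alignmentBlock(
    vapply(c(a = 1, b = 2, c = 3), function(i) {
      set.seed(i); paste(sample(c("A", "C", "G", "T"), 100,
                                replace = TRUE), collapse = "")
    }, character(1)), gene = "srRNA"))
  pcg <- buildSupermatrix(cds, dataset = "PCGs")
  p12 <- buildSupermatrix(cds, dataset = "PCGs12")
  prna <- buildSupermatrix(cds, rna, dataset = "PCGsRNA")
  wid <- function(x) Biostrings::width(blockSeqs(x$block))[1]
  expect_equal(wid(pcg), 360)
  expect_equal(wid(p12), 240)
  expect_equal(wid(prna), 460)   # RNA partitions added whole
  p12rna <- buildSupermatrix(cds, rna, dataset = "PCGs12RNA")
  expect_equal(wid(p12rna), 340)
})

test_that("PHYLIP and NEXUS writers emit parseable matrices with charsets", {
  cds <- list(ATP6 = mkBlock(20, gene = "ATP6", seed = 14),
              COX1 = mkBlock(30, gene = "COX1", seed = 15))
  sm <- buildSupermatrix(cds, dataset = "PCGs")
  phy <- tempfile(fileext = ".phy")
  writePhylip(sm, phy)
  first <- readLines(phy, n = 1)
  expect_identical(first, "3 150")
  nex <- tempfile(fileext = ".nex")
  writeNexus(sm, nex)
  txt <- readLines(nex)
  expect_true(any(grepl("begin sets;", txt)))
  expect_true(any(grepl("charset ATP6 = 1-60;", txt)))
  expect_true(any(grepl("charset COX1 = 61-150;", txt)))
  # the data block is readable by ape
  back <- ape::read.nexus.data(nex)
  expect_length(back, 3)
  expect_length(back[[1]], 150)
})
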