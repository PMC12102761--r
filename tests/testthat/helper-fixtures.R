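# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# small 3-taxon simulation across all 13 genes (fast io/pipeline fixture)
fixtureSim <- function() {
  if (is.null(.fix$sim)) {
    genes <- c(ATP6 = 60, ATP8 = 25, COX1 = 90, COX2 = 55, COX3 = 50,
               CYTB = 70, NAD1 = 48, NAD2 = 52, NAD3 = 30, NAD4 = 66,
               NAD4L = 28, NAD5 = 95, NAD6 = 35)
    .fix$sim <- simulateCdsFamily(
      simConfig(nTaxa = 3, genes = genes, d = 0.15, seed = 101))
  }
  .fix$sim
}

fixtureRecords <- function() {
  if (is.null(.fix$recs)) .fix$recs <- emitGenBank(fixtureSim())
  .fix$recs
}

# the same records written to, and re-read from, GenBank flat files
fixtureParsedRecords <- function() {
  if (is.null(.fix$parsed)) {
    dir <- file.path(tempdir(), "mitocodon-fixture-gb")
    if (!dir.exists(dir)) {
      emitGenBank(fixtureSim(), dir = dir)
    }
    paths <- list.files(dir, pattern = "\\.gb$", full.names = TRUE)
    .fix$parsed <- lapply(paths, parseGenBank)
    names(.fix$parsed) <- vapply(.fix$parsed, taxon, character(1))
  }
  .fix$parsed
}
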