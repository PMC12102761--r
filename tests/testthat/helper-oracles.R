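# Independent naive reference implementations used as oracles.
# These deliberately use plain loops over the published formulas, not the
# package's vectorized code paths.

# Wright's ENC, naive: per-family homozygosity, class averages, sum m_k/Fbar_k
bruteENC <- function(counts, code) {
  fams <- codonFamilies(code)
  deg <- familyDegeneracy(code)
  Fh <- list()
  for (aa in names(fams)) {
    n <- 0
    for (cd in fams[[aa]]) n <- n + counts[[cd]]
    if (n <= 1) { Fh[[aa]] <- NA_real_; next }
    sp2 <- 0
    for (cd in fams[[aa]]) sp2 <- sp2 + (counts[[cd]] / n)^2
    Fh[[aa]] <- (n * sp2 - 1) / (n - 1)
  }
  total <- 0
  for (k in sort(unique(deg))) {
    mk <- sum(deg == k)
    if (k == 1) { total <- total + mk; next }
    vals <- c()
    for (aa in names(fams)[deg == k]) {
      f <- Fh[[aa]]
      if (!is.na(f) && f > 0) vals <- c(vals, f)
    }
    fbar <- if (length(vals)) mean(vals) else 1 / k
    total <- total + mk / fbar
  }
  min(max(total, 20), 61)
}

# CAI, naive: product of weights over codon occurrences, geometric mean
bruteCAI <- function(counts, weights, wFloor = 0.01) {
  logsum <- 0; n <- 0
  for (cd in names(weights)) {
    w <- weights[[cd]]
    if (is.na(w) || counts[[cd]] == 0) next
    if (w == 0) w <- wFloor
    logsum <- logsum + counts[[cd]] * log(w)
    n <- n + counts[[cd]]
  }
  exp(logsum / n)
}

# CBI and FOP, naive per definition
bruteCbiFop <- function(counts, optimal, code) {
  fams <- codonFamilies(code)
  nTot <- 0; nOpt <- 0; nRand <- 0
  for (aa in names(fams)) {
    cds <- fams[[aa]]
    if (!any(cds %in% optimal)) next
    nf <- 0
    for (cd in cds) nf <- nf + counts[[cd]]
    nTot <- nTot + nf
    for (cd in cds) if (cd %in% optimal) nOpt <- nOpt + counts[[cd]]
    nRand <- nRand + nf * sum(cds %in% optimal) / length(cds)
  }
  list(CBI = (nOpt - nRand) / (nTot - nRand), FOP = nOpt / nTot)
}

# Nei's pi by site-frequency accounting (gap-free alignments)
piSiteFreq <- function(seqs) {
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- nrow(chars)
  per <- apply(chars, 2, function(col) {
    cnt <- table(col)
    (n^2 - sum(cnt^2)) / (n * (n - 1))
  })
  sum(per) / ncol(chars)
}

# random codon-count table with stops zeroed
randomCountTable <- function(code, lambda = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cts <- stats::rpois(64, lambda)
  names(cts) <- codonAlphabet()
  cts[stopCodons(code)] <- 0
  cts
}

# random stop-free CDS string of n codons under a code
randomCDS <- function(n, code, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(senseCodons(code), n, replace = TRUE), collapse = "")
}
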