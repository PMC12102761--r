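# Kyte-Doolittle hydropathy scores, indexed by amino-acid letter
.kyteDoolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Count codons of one or more CDS
#'
#' Counts every in-frame codon of the supplied coding sequence(s) into a
#' single table.  Codons containing non-ACGT letters are skipped and tallied
#' as ambiguous.  Stop codons of the active code are dropped by default,
#' matching the convention of the usage indices.  Initiation codons are
#' counted as written (no forced-Met recoding).
#'
#' @param cds a nucleotide string, \linkS4class{DNAString},
#'   \linkS4class{DNAStringSet} or character vector; every element must have
#'   length a multiple of 3.
#' @param code a \linkS4class{GeneticCode}.
#' @param excludeStops drop stop codons from the counts (default TRUE).
#' @param context,taxon labels stored in the table.
#' @return a \linkS4class{CodonCountTable}.
#' @examples
#' countCodons("ATGATGTAA")  # TAA excluded: 2 x ATG
#' @export
countCodons <- function(cds, code = geneticCode("2"), excludeStops = TRUE,
                        context = "cds", taxon = "") {
  seqs <- vapply(as.list(cds), function(s) toupper(as.character(s)),
                 character(1))
  codons <- unlist(lapply(seqs, splitCodons), use.names = FALSE)
  nTotal <- length(codons)
  counts <- setNames(numeric(64), codonAlphabet())
  tab <- table(codons[codons %in% names(counts)])
  counts[names(tab)] <- as.numeric(tab)
  nAmb <- nTotal - sum(counts)
  if (excludeStops) counts[stopCodons(code)] <- 0
  new("CodonCountTable", context = context, taxon = taxon, counts = counts,
      code = code, nCodons = sum(counts), nAmbiguous = nAmb)
}

# build a CodonCountTable directly from a named count vector (tests, pooling)
codonCountTable <- function(counts, code = geneticCode("2"),
                            context = "counts", taxon = "") {
  full <- setNames(numeric(64), codonAlphabet())
  full[names(counts)] <- counts
  new("CodonCountTable", context = context, taxon = taxon, counts = full,
      code = code, nCodons = sum(full), nAmbiguous = 0)
}

#' Sum codon-count tables
#' @param ... \linkS4class{CodonCountTable}s under the same code.
#' @param context label for the pooled table.
#' @return a pooled \linkS4class{CodonCountTable}.
#' @export
poolCounts <- function(..., context = "pooled") {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]])) tabs <- tabs[[1]]
  counts <- Reduce(`+`, lapply(tabs, codonCounts))
  new("CodonCountTable", context = context,
      taxon = tabs[[1]]@taxon, counts = counts, code = tabs[[1]]@code,
      nCodons = sum(counts),
      nAmbiguous = sum(vapply(tabs, function(t) t@nAmbiguous, numeric(1))))
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of size k with family total n is
#' \eqn{k \cdot obs(c) / n}: the observed count relative to the expectation
#' under uniform synonym usage.  Values above 1 mark preferentially used
#' codons; within each family the values sum to the family's degeneracy.
#' Only amino acids with at least two synonyms are reported.
#'
#' @param counts a \linkS4class{CodonCountTable}.
#' @return \code{data.frame} with columns \code{codon}, \code{aa},
#'   \code{count}, \code{degeneracy}, \code{rscu} (\code{NA} for families
#'   with zero total, flagged, not an error).
#' @export
rscu <- function(counts) {
  code <- counts@code
  fams <- codonFamilies(code)
  fams <- fams[familyDegeneracy(code) >= 2L]
  cts <- codonCounts(counts)
  rows <- lapply(names(fams), function(aa) {
    cdns <- fams[[aa]]
    tot <- sum(cts[cdns])
    data.frame(codon = cdns, aa = aa, count = as.numeric(cts[cdns]),
               degeneracy = length(cdns),
               rscu = if (tot > 0) length(cdns) * cts[cdns] / tot
                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$codon
  out
}

#' Effective number of codons (Wright's estimator)
#'
#' Wright's homozygosity-based ENC, generalized to the synonymous-family
#' structure of the active genetic code (under the vertebrate mitochondrial
#' code there are no single-codon families, Arg is four-fold, and Leu/Ser
#' are six-fold).  For each family with sample size \eqn{n > 1} the
#' homozygosity is \eqn{\hat F = (n \sum p_i^2 - 1)/(n - 1)}; families are
#' averaged within each degeneracy class and ENC is the sum of
#' \eqn{m_k / \bar F_k} over classes (single-codon families contribute their
#' count directly).  Empty classes are imputed \eqn{\bar F_k = 1/k}; the
#' result is clamped to [20, 61].
#'
#' @param counts a \linkS4class{CodonCountTable}.
#' @return ENC value (numeric); attribute \code{"clamped"} records whether
#'   clamping was applied.
#' @export
enc <- function(counts) {
  code <- counts@code
  cts <- codonCounts(counts)
  deg <- familyDegeneracy(code)
  fams <- codonFamilies(code)
  Fhat <- vapply(names(fams), function(aa) {
    n <- sum(cts[fams[[aa]]])
    if (n <= 1) return(NA_real_)
    p <- cts[fams[[aa]]] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  classes <- sort(unique(deg))
  if (all(is.na(Fhat[deg >= 2])) && !any(deg == 1L))
    stop("no synonymous family has more than one codon observed")
  out <- 0
  for (k in classes) {
    mk <- sum(deg == k)
    if (k == 1L) { out <- out + mk; next }
    fk <- Fhat[deg == k]
    fk <- fk[!is.na(fk) & fk > 0]
    Fbar <- if (length(fk)) mean(fk) else 1 / k
    out <- out + mk / Fbar
  }
  clamped <- out < 20 || out > 61
  out <- min(max(out, 20), 61)
  attr(out, "clamped") <- clamped
  out
}

#' Base frequencies at synonymous third positions
#'
#' Frequencies of A/T/G/C at the third position of codons belonging to
#' synonymous families (at least two synonyms under the active code), with
#' stop codons excluded; \code{GC3s = G3s + C3s} over that denominator.
#' Under the standard code this is the classical "excluding Met, Trp and
#' stops" rule; under the vertebrate mitochondrial code Met and Trp are
#' two-fold families and are therefore retained, unless
#' \code{legacyExclude} names amino acids to drop for tool-lineage
#' comparability.
#'
#' @param counts a \linkS4class{CodonCountTable}.
#' @param legacyExclude optional amino-acid letters to exclude regardless of
#'   degeneracy (e.g. \code{c("M", "W")}).
#' @return named list: \code{A3s}, \code{T3s}, \code{G3s}, \code{C3s},
#'   \code{GC3s}.
#' @export
x3s <- function(counts, legacyExclude = character()) {
  code <- counts@code
  fams <- codonFamilies(code)
  keep <- familyDegeneracy(code) >= 2L & !(names(fams) %in% legacyExclude)
  cdns <- unlist(fams[keep], use.names = FALSE)
  cts <- codonCounts(counts)[cdns]
  denom <- sum(cts)
  if (denom == 0) stop("no codons in synonymous families")
  third <- substr(cdns, 3, 3)
  f <- vapply(c("A", "T", "G", "C"),
              function(b) sum(cts[third == b]) / denom, numeric(1))
  list(A3s = f[["A"]], T3s = f[["T"]], G3s = f[["G"]], C3s = f[["C"]],
       GC3s = f[["G"]] + f[["C"]])
}

#' Relative-adaptiveness weights for CAI
#'
#' Weights \eqn{w(c) = RSCU(c) / \max RSCU} within each synonymous family,
#' from a reference codon-usage table.  Codons of single-synonym families
#' are not weighted (they are excluded from CAI).
#'
#' @param reference a \linkS4class{CodonCountTable} describing the reference
#'   (e.g. the pooled usage of all genes).
#' @return named numeric vector of weights over multi-synonym sense codons.
#' @export
caiWeights <- function(reference) {
  r <- rscu(reference)
  w <- unlist(lapply(split(r, r$aa), function(d) {
    mx <- max(d$rscu)
    setNames(if (is.na(mx) || mx == 0) rep(NA_real_, nrow(d))
             else d$rscu / mx, d$codon)
  }))
  names(w) <- sub("^[^.]*\\.", "", names(w))
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative-adaptiveness weights over the gene's
#' codons, restricted to codons of multi-synonym families with a defined
#' weight.  Codons whose reference weight is zero receive a configurable
#' floor (default 0.01) with a warning.
#'
#' @param counts a \linkS4class{CodonCountTable} for the gene.
#' @param weights weight vector from \code{\link{caiWeights}}, or a
#'   \linkS4class{CodonCountTable} to derive one from.
#' @param wFloor substitute for zero weights.
#' @return CAI in [0, 1].
#' @export
cai <- function(counts, weights, wFloor = 0.01) {
  if (methods::is(weights, "CodonCountTable")) weights <- caiWeights(weights)
  cts <- codonCounts(counts)[names(weights)]
  use <- !is.na(weights) & cts > 0
  w <- weights[use]; n <- cts[use]
  if (any(w == 0)) {
    warning(sum(w == 0), " codon(s) unused in the reference; weight floored")
    w[w == 0] <- wFloor
  }
  if (sum(n) == 0) stop("gene has no codons in multi-synonym families")
  exp(sum(n * log(w)) / sum(n))
}

#' Pick the optimal codon of each synonymous family
#'
#' @param reference a \linkS4class{CodonCountTable}; the highest-RSCU codon
#'   of every multi-synonym family is taken as optimal (ties broken by codon
#'   alphabetical order for determinism).
#' @return character vector of optimal codons.
#' @export
optimalCodonSet <- function(reference) {
  r <- rscu(reference)
  vapply(split(r, r$aa), function(d) {
    d <- d[order(-ifelse(is.na(d$rscu), -Inf, d$rscu), d$codon), ]
    d$codon[1]
  }, character(1))
}

#' Codon bias index and frequency of optimal codons
#'
#' FOP is the fraction of a gene's codons (within families that have an
#' optimal member) that are optimal.  CBI rescales the optimal-codon count
#' against the expectation under uniform synonym usage:
#' \eqn{(N_{opt} - N_{rand}) / (N_{tot} - N_{rand})}, so 0 means random
#' usage and 1 exclusive use of optimal codons.
#'
#' @param counts a \linkS4class{CodonCountTable} for the gene.
#' @param optimal character vector of optimal codons (one per multi-synonym
#'   family), e.g. from \code{\link{optimalCodonSet}}.
#' @return named list with \code{CBI} and \code{FOP}.
#' @export
cbiFop <- function(counts, optimal) {
  if (!length(optimal)) stop("empty optimal codon set")
  code <- counts@code
  fams <- codonFamilies(code)
  fams <- fams[vapply(fams, function(cd) any(cd %in% optimal), logical(1))]
  cts <- codonCounts(counts)
  nTot <- 0; nOpt <- 0; nRand <- 0
  for (cdns in fams) {
    nf <- sum(cts[cdns])
    nTot <- nTot + nf
    nOpt <- nOpt + sum(cts[intersect(cdns, optimal)])
    nRand <- nRand + nf * length(intersect(cdns, optimal)) / length(cdns)
  }
  if (nTot == 0) stop("gene has no codons in families with an optimal codon")
  list(CBI = if (nTot > nRand) (nOpt - nRand) / (nTot - nRand) else NA_real_,
       FOP = nOpt / nTot)
}

#' GRAVY and aromaticity of the encoded protein
#'
#' GRAVY is the mean Kyte-Doolittle hydropathy over the translated protein
#' (terminal stop excluded); aromaticity is the fraction of Phe/Tyr/Trp
#' residues.
#'
#' @param cds nucleotide string, length a multiple of 3.
#' @param code a \linkS4class{GeneticCode}.
#' @return named list with \code{GRAVY}, \code{AROMO} and the protein length
#'   \code{L_aa}.
#' @export
gravyAromo <- function(cds, code = geneticCode("2")) {
  aa <- strsplit(translateCDS(cds, code), "")[[1]]
  aa <- aa[!is.na(aa) & aa != "*"]
  if (!length(aa)) stop("zero-length protein")
  list(GRAVY = mean(.kyteDoolittle[aa]),
       AROMO = mean(aa %in% c("F", "Y", "W")),
       L_aa = length(aa))
}

#' Per-gene codon-usage index battery
#'
#' Computes, for every gene of one taxon, the full index set: ENC, the
#' synonymous third-position frequencies (A3s/T3s/G3s/C3s/GC3s), the
#' positional GC contents (GC1/GC2/GC3/GC12), overall GC, CAI, CBI, FOP,
#' GRAVY, aromaticity and protein length.  The CAI reference and optimal
#' codon set default to the pooled usage of all supplied genes
#' (self-referential mitochondrial reference) and can be overridden.
#'
#' @param cdsSet named \linkS4class{DNAStringSet} (or character vector) of
#'   validated CDS, one per gene.
#' @param code a \linkS4class{GeneticCode}.
#' @param taxon taxon label for the output rows.
#' @param reference \linkS4class{CodonCountTable} used for CAI weights and
#'   the default optimal set; default: pooled counts of \code{cdsSet}.
#' @param optimal optimal codon set for CBI/FOP; default from
#'   \code{reference}.
#' @return \code{data.frame}, one row per gene.
#' @export
usageIndices <- function(cdsSet, code = geneticCode("2"), taxon = "",
                         reference = NULL, optimal = NULL) {
  seqs <- vapply(as.list(cdsSet), function(s) toupper(as.character(s)),
                 character(1))
  genes <- names(seqs)
  if (is.null(genes)) genes <- paste0("gene", seq_along(seqs))
  tabs <- lapply(seq_along(seqs), function(i)
    countCodons(seqs[i], code, context = genes[i], taxon = taxon))
  if (is.null(reference)) reference <- poolCounts(tabs)
  w <- caiWeights(reference)
  if (is.null(optimal)) optimal <- optimalCodonSet(reference)
  rows <- lapply(seq_along(seqs), function(i) {
    t3 <- x3s(tabs[[i]])
    pos <- codonPositionComposition(seqs[i], code)
    ga <- gravyAromo(seqs[i], code)
    bf <- cbiFop(tabs[[i]], optimal)
    comp <- baseComposition(seqs[i])
    data.frame(
      taxon = taxon, gene = genes[i],
      ENC = as.numeric(enc(tabs[[i]])),
      A3s = t3$A3s, T3s = t3$T3s, G3s = t3$G3s, C3s = t3$C3s,
      GC3s = t3$GC3s,
      GC1 = pos$GC1, GC2 = pos$GC2, GC3 = pos$GC3, GC12 = pos$GC12,
      GC = comp$g + comp$c,
      CAI = suppressWarnings(cai(tabs[[i]], w)),
      CBI = bf$CBI, FOP = bf$FOP,
      GRAVY = ga$GRAVY, AROMO = ga$AROMO, L_aa = ga$L_aa,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
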