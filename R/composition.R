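#' Base composition and strand skews of a sequence
#'
#' Counts A/T/G/C (ambiguity codes are tallied separately and excluded from
#' all fractions) and computes AT content and the strand skews
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C).
#'
#' @param seq nucleotide string or \linkS4class{DNAString}; gaps and
#'   ambiguity codes allowed.
#' @param context label carried into the result row.
#' @return one-row \code{data.frame} with columns \code{context}, counts
#'   \code{A,T,G,C}, \code{n_ambiguous}, fractions \code{a,t,g,c},
#'   \code{AT_content}, \code{AT_skew}, \code{GC_skew}.
#' @examples
#' baseComposition(strrep("AAATGC", 5))
#' @export
baseComposition <- function(seq, context = "sequence") {
  seq <- toupper(as.character(seq))
  seq <- gsub("-", "", seq)
  if (!nchar(seq)) stop("empty sequence")
  ch <- strsplit(seq, "")[[1]]
  A <- sum(ch == "A"); T_ <- sum(ch == "T")
  G <- sum(ch == "G"); C <- sum(ch == "C")
  amb <- length(ch) - (A + T_ + G + C)
  n <- A + T_ + G + C
  if (n == 0L) stop("sequence contains no unambiguous bases")
  data.frame(
    context = context, A = A, T = T_, G = G, C = C, n_ambiguous = amb,
    a = A / n, t = T_ / n, g = G / n, c = C / n,
    AT_content = (A + T_) / n,
    AT_skew = if (A + T_ > 0) (A - T_) / (A + T_) else NA_real_,
    GC_skew = if (G + C > 0) (G - C) / (G + C) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Pooled base composition per codon position
#'
#' Pools all codons of a set of frame-valid CDS and reports the composition
#' at each codon position, plus the derived GC1, GC2, GC3 and
#' GC12 = (GC1 + GC2)/2.
#'
#' @param cdsSet \linkS4class{DNAStringSet}, list or character vector of CDS
#'   sequences, each with length a multiple of 3.
#' @param code \linkS4class{GeneticCode} used to recognize stop codons.
#' @param excludeStops drop stop codons before pooling (default TRUE, the
#'   convention used by the usage indices).
#' @return list with \code{positions} (3-row \code{data.frame} of
#'   \code{\link{baseComposition}} rows for positions 1..3) and scalars
#'   \code{GC1}, \code{GC2}, \code{GC3}, \code{GC12}.
#' @export
codonPositionComposition <- function(cdsSet, code = geneticCode("2"),
                                     excludeStops = TRUE) {
  seqs <- vapply(as.list(cdsSet), function(s) toupper(as.character(s)),
                 character(1))
  codons <- unlist(lapply(seqs, splitCodons), use.names = FALSE)
  if (excludeStops) codons <- codons[!(codons %in% stopCodons(code))]
  if (!length(codons)) stop("no codons to pool")
  pos <- lapply(1:3, function(p) {
    baseComposition(paste(substr(codons, p, p), collapse = ""),
                    context = paste0("position", p))
  })
  posDf <- do.call(rbind, pos)
  gc <- posDf$g + posDf$c
  list(positions = posDf,
       GC1 = gc[1], GC2 = gc[2], GC3 = gc[3], GC12 = (gc[1] + gc[2]) / 2)
}

#' Gene-length matrix across records
#'
#' @param records list of \linkS4class{MitogenomeRecord}s.
#' @param kind feature kinds to include (default \code{"CDS"}).
#' @return numeric matrix gene x taxon of lengths in bp (\code{NA} marks a
#'   gene absent from a record), with a \code{"totals"} attribute holding the
#'   per-taxon sum over present genes.
#' @export
geneLengthTable <- function(records, kind = "CDS") {
  if (methods::is(records, "MitogenomeRecord")) records <- list(records)
  ftab <- featureTable(records)
  ftab <- ftab[ftab$kind %in% kind, , drop = FALSE]
  taxa <- vapply(records, taxon, character(1))
  genes <- intersect(canonicalGeneOrder(), unique(ftab$gene))
  genes <- c(genes, setdiff(unique(ftab$gene), genes))
  m <- matrix(NA_real_, length(genes), length(taxa),
              dimnames = list(genes, taxa))
  for (i in seq_len(nrow(ftab)))
    m[ftab$gene[i], ftab$taxon[i]] <- ftab$length[i]
  attr(m, "totals") <- colSums(m, na.rm = TRUE)
  m
}
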