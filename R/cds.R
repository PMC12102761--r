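#' Complete a truncated mitochondrial stop codon
#'
#' Mitochondrial protein-coding genes frequently end in the incomplete stop
#' codons \code{T} or \code{TA}; polyadenylation of the transcript completes
#' them to \code{TAA}.  This reproduces that completion on the DNA sequence:
#' if the length modulo 3 is 1 and the trailing base is \code{T}, two
#' \code{A}s are appended; if it is 2 and the trailing bases are \code{TA},
#' one \code{A} is appended.  In-frame sequences are returned unchanged.
#'
#' @param cds nucleotide string (coding orientation).
#' @return the completed sequence (character).
#' @examples
#' completeStop("ATGCTTT")    # ...T -> ...TAA
#' completeStop("ATGTTTTAG")  # unchanged
#' @export
completeStop <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  r <- n %% 3L
  if (r == 0L) return(cds)
  tail <- substr(cds, n - r + 1L, n)
  if (r == 1L && tail == "T") return(paste0(cds, "AA"))
  if (r == 2L && tail == "TA") return(paste0(cds, "A"))
  stop("trailing ", r, "-base remainder '", tail,
       "' is not a truncated stop (T/TA): frame problem")
}

#' Extract and validate protein-coding sequences from a mitogenome
#'
#' Pulls every CDS feature of a parsed record, completes truncated stop
#' codons, and validates each gene under the given genetic code: the length
#' must be a multiple of three, the first codon must belong to the start-codon
#' policy in force, and no internal stop codon may occur.
#'
#' @param record a \linkS4class{MitogenomeRecord}.
#' @param code a \linkS4class{GeneticCode}; default vertebrate mitochondrial.
#' @param starts permitted start codons.  Defaults to the code's policy
#'   (permissive \code{ATG}/\code{GTG}); pass \code{"ATG"} for strict mode.
#' @param completeStops complete truncated terminal stops before validating.
#' @return a named \linkS4class{DNAStringSet} of validated CDS (names are the
#'   normalized gene labels).
#' @examples
#' \dontrun{
#' rec <- parseGenBank("genome.gb")
#' cds <- extractCDS(rec)
#' }
#' @export
extractCDS <- function(record, code = geneticCode("2"),
                       starts = startCodons(code), completeStops = TRUE) {
  ft <- record@features
  idx <- which(ft$kind == "CDS")
  seqs <- character(0)
  for (i in idx) {
    gene <- ft$name[i]
    s <- as.character(record@geneSeqs[[i]])
    if (completeStops) s <- completeStop(s)
    if (nchar(s) %% 3L != 0L)
      stop("CDS ", gene, " in ", record@accession,
           ": length not a multiple of 3 after stop completion")
    cdn <- splitCodons(s)
    if (!(cdn[1] %in% starts))
      stop("CDS ", gene, " in ", record@accession, ": start codon ",
           cdn[1], " not in permitted set {",
           paste(starts, collapse = ", "), "}")
    aa <- translateCodons(cdn, code)
    internalStop <- which(aa[-length(aa)] == "*")
    if (length(internalStop))
      stop("CDS ", gene, " in ", record@accession,
           ": internal stop codon at codon position ", internalStop[1])
    seqs[gene] <- s
  }
  Biostrings::DNAStringSet(seqs)
}

#' Translate a CDS to protein under a code
#'
#' @param cds nucleotide string, length a multiple of 3.
#' @param code a \linkS4class{GeneticCode}.
#' @param dropStop drop a terminal stop codon from the translation.
#' @return amino-acid string.
#' @export
translateCDS <- function(cds, code = geneticCode("2"), dropStop = TRUE) {
  aa <- translateCodons(splitCodons(cds), code)
  if (dropStop && length(aa) && !is.na(aa[length(aa)]) &&
      aa[length(aa)] == "*")
    aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Read per-gene FASTA alignments from a directory or files
#'
#' One file per gene, each a multi-FASTA of homologous (aligned or unaligned
#' but equal-length) sequences named by taxon.
#'
#' @param paths FASTA file paths, or a directory containing \code{.fa} /
#'   \code{.fasta} files.
#' @param codonFramed mark blocks as codon-framed.
#' @return named list of \linkS4class{AlignmentBlock}s (names are the file
#'   base names, normalized where they match the gene vocabulary).
#' @export
readGeneFasta <- function(paths, codonFramed = TRUE) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
  blocks <- lapply(paths, function(p) {
    gene <- sub("\\.[^.]*$", "", basename(p))
    gene <- suppressWarnings(normalizeGeneName(gene, warn = FALSE))
    alignmentBlock(Biostrings::readDNAStringSet(p), gene = gene,
                   codonFramed = codonFramed)
  })
  names(blocks) <- vapply(blocks, blockGene, character(1))
  blocks
}

#' Write per-gene FASTA files
#'
#' @param blocks named list of \linkS4class{AlignmentBlock}s or
#'   \code{DNAStringSet}s.
#' @param dir output directory (created if absent).
#' @return the written paths, invisibly.
#' @export
writeGeneFasta <- function(blocks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(blocks), function(g) {
    x <- blocks[[g]]
    if (methods::is(x, "AlignmentBlock")) x <- blockSeqs(x)
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", g), ".fasta"))
    Biostrings::writeXStringSet(x, p)
    p
  }, character(1))
  invisible(paths)
}
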