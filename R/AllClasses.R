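#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @include genetic-code.R
NULL

#' Annotated circular mitochondrial genome
#'
#' One parsed mitogenome: the circular sequence plus a typed feature table.
#' Feature coordinates are 1-based inclusive on the forward (heavy) strand;
#' a feature whose \code{start > end} wraps across the origin of the circle.
#' Per-feature sequences are stored in coding orientation, i.e. light-strand
#' features are already reverse-complemented.
#'
#' @slot accession record accession string.
#' @slot taxon organism / taxon label.
#' @slot sequence the full genome as a \linkS4class{DNAString}.
#' @slot features \code{data.frame} with columns \code{name} (normalized gene
#'   label), \code{kind} (\code{CDS}, \code{tRNA}, \code{rRNA},
#'   \code{control_region}, \code{origin_light}), \code{start}, \code{end},
#'   \code{strand} (\code{H}/\code{L}).
#' @slot geneSeqs \linkS4class{DNAStringSet} of feature sequences in coding
#'   orientation, parallel to the rows of \code{features}.
#' @export
setClass("MitogenomeRecord",
  representation(
    accession = "character",
    taxon = "character",
    sequence = "DNAString",
    features = "data.frame",
    geneSeqs = "DNAStringSet"
  )
)

.featureKinds <- c("CDS", "tRNA", "rRNA", "control_region", "origin_light")

setValidity("MitogenomeRecord", function(object) {
  msg <- character()
  ft <- object@features
  need <- c("name", "kind", "start", "end", "strand")
  if (!all(need %in% names(ft)))
    return(paste("features must have columns", paste(need, collapse = ", ")))
  L <- length(object@sequence)
  if (nrow(ft)) {
    if (!all(ft$kind %in% .featureKinds))
      msg <- c(msg, "unknown feature kind")
    if (!all(ft$strand %in% c("H", "L")))
      msg <- c(msg, "strand must be H or L")
    if (any(ft$start < 1L | ft$start > L | ft$end < 1L | ft$end > L))
      msg <- c(msg, "feature coordinates outside [1, genome length]")
    explen <- ifelse(ft$start <= ft$end,
                     ft$end - ft$start + 1L,
                     (L - ft$start + 1L) + ft$end)
    if (length(object@geneSeqs) != nrow(ft))
      msg <- c(msg, "geneSeqs must parallel the feature table")
    else if (!all(Biostrings::width(object@geneSeqs) == explen))
      msg <- c(msg, "feature sequence lengths inconsistent with coordinates")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MitogenomeRecord accession of the record
#' @param x,object a \code{MitogenomeRecord}.
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname MitogenomeRecord-class
#' @export
setMethod("accession", "MitogenomeRecord", function(x) x@accession)

#' @describeIn MitogenomeRecord taxon label
#' @export
setGeneric("taxon", function(x) standardGeneric("taxon"))

#' @rdname MitogenomeRecord-class
#' @export
setMethod("taxon", "MitogenomeRecord", function(x) x@taxon)

#' @describeIn MitogenomeRecord genome sequence
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname MitogenomeRecord-class
#' @export
setMethod("genomeSeq", "MitogenomeRecord", function(x) x@sequence)

#' @describeIn MitogenomeRecord feature table (data.frame)
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname MitogenomeRecord-class
#' @export
setMethod("features", "MitogenomeRecord", function(x) x@features)

#' @describeIn MitogenomeRecord per-feature sequences in coding orientation
#' @export
setGeneric("geneSeqs", function(x) standardGeneric("geneSeqs"))

#' @rdname MitogenomeRecord-class
#' @export
setMethod("geneSeqs", "MitogenomeRecord", function(x) x@geneSeqs)

setMethod("length", "MitogenomeRecord", function(x) length(x@sequence))

setMethod("show", "MitogenomeRecord", function(object) {
  kinds <- table(factor(object@features$kind, levels = .featureKinds))
  cat("MitogenomeRecord ", object@accession, " (", object@taxon, ")\n",
      "  ", length(object@sequence), " bp circular; ",
      nrow(object@features), " features: ",
      paste(sprintf("%d %s", as.integer(kinds), names(kinds)),
            collapse = ", "), "\n", sep = "")
})

#' Codon counts for one context
#'
#' Counts of all 64 codons observed in one gene (or a concatenated gene set)
#' of one taxon, tied to the genetic code under which they were counted.
#'
#' @slot context label of the counted unit (gene name or set label).
#' @slot taxon taxon label.
#' @slot counts named numeric vector over all 64 codons.
#' @slot code the \linkS4class{GeneticCode} used.
#' @slot nCodons total codons counted (after any stop exclusion).
#' @slot nAmbiguous codons skipped because they contained non-ACGT letters.
#' @export
setClass("CodonCountTable",
  representation(
    context = "character",
    taxon = "character",
    counts = "numeric",
    code = "GeneticCode",
    nCodons = "numeric",
    nAmbiguous = "numeric"
  )
)

setValidity("CodonCountTable", function(object) {
  msg <- character()
  if (!setequal(names(object@counts), codonAlphabet()))
    msg <- c(msg, "counts must be named by the 64 codons")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (abs(sum(object@counts) - object@nCodons) > 1e-8)
    msg <- c(msg, "nCodons must equal the sum of counts")
  if (length(msg)) msg else TRUE
})

#' @describeIn CodonCountTable the named 64-codon count vector
#' @param x,object a \code{CodonCountTable}.
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))

#' @rdname CodonCountTable-class
#' @export
setMethod("codonCounts", "CodonCountTable", function(x) x@counts)

setMethod("show", "CodonCountTable", function(object) {
  cat("CodonCountTable [", object@taxon, "/", object@context, "]: ",
      object@nCodons, " codons under table ", object@code@id,
      if (object@nAmbiguous > 0)
        paste0(" (", object@nAmbiguous, " ambiguous skipped)") else "",
      "\n", sep = "")
})

#' Homologous alignment of one gene across taxa
#'
#' Equal-length (gapped) nucleotide sequences for one gene across two or more
#' taxa.  For codon-aware statistics the width must be a multiple of three
#' and gaps must occur in whole-codon triplets.
#'
#' @slot gene gene label.
#' @slot seqs named \linkS4class{DNAStringSet}, one sequence per taxon, all of
#'   equal width.
#' @slot codonFramed logical: whether the block is codon-framed.
#' @export
setClass("AlignmentBlock",
  representation(
    gene = "character",
    seqs = "DNAStringSet",
    codonFramed = "logical"
  )
)

setValidity("AlignmentBlock", function(object) {
  msg <- character()
  w <- Biostrings::width(object@seqs)
  if (length(object@seqs) < 2L)
    msg <- c(msg, "an alignment needs at least 2 sequences")
  if (length(unique(w)) > 1L)
    msg <- c(msg, "aligned sequences must have equal length")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "sequences must carry unique taxon names")
  if (isTRUE(object@codonFramed) && length(w) && w[1] %% 3L != 0L)
    msg <- c(msg, "codon-framed block width must be a multiple of 3")
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentBlock
#' @param seqs named character vector or \code{DNAStringSet} of equal-length
#'   aligned sequences.
#' @param gene gene label.
#' @param codonFramed logical; declare the block codon-framed (width divisible
#'   by 3, gaps in whole codons).
#' @return an \linkS4class{AlignmentBlock}.
#' @export
alignmentBlock <- function(seqs, gene = "gene", codonFramed = FALSE) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  new("AlignmentBlock", gene = gene, seqs = seqs,
      codonFramed = isTRUE(codonFramed))
}

#' @describeIn alignmentBlock the aligned sequences
#' @param x an \code{AlignmentBlock}.
#' @export
blockSeqs <- function(x) x@seqs

#' @describeIn alignmentBlock taxon labels of the block
#' @export
blockTaxa <- function(x) names(x@seqs)

#' @describeIn alignmentBlock gene label of the block
#' @export
blockGene <- function(x) x@gene

setMethod("length", "AlignmentBlock", function(x) length(x@seqs))

setMethod("show", "AlignmentBlock", function(object) {
  cat("AlignmentBlock ", object@gene, ": ", length(object@seqs),
      " taxa x ", if (length(object@seqs)) Biostrings::width(object@seqs)[1]
      else 0L, " columns",
      if (isTRUE(object@codonFramed)) " (codon-framed)" else "", "\n",
      sep = "")
})
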