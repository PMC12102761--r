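#' @import methods
#' @importFrom stats setNames
NULL

#' Genetic code with synonymous-family structure
#'
#' Wraps an NCBI translation table together with the derived structure that
#' codon-usage statistics need: the partition of sense codons into synonymous
#' families and the degeneracy of each family.  The default is the vertebrate
#' mitochondrial code (NCBI table 2), under which \code{TGA} encodes Trp,
#' \code{ATA} encodes Met and \code{AGA}/\code{AGG} are stops, so that Met and
#' Trp are two-fold families and Arg is four-fold.
#'
#' @slot id NCBI translation table identifier (e.g. \code{"2"}).
#' @slot codons named character vector of length 64 mapping codon to
#'   amino-acid letter, with \code{"*"} for stops.
#' @slot starts character vector of permitted initiation codons.
#' @slot stops character vector of stop codons.
#' @slot families named list mapping each amino acid to its sense codons.
#' @slot degeneracy named integer vector: synonym count per amino acid.
#'
#' @export
setClass("GeneticCode",
  representation(
    id = "character",
    codons = "character",
    starts = "character",
    stops = "character",
    families = "list",
    degeneracy = "integer"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@codons) != 64L)
    msg <- c(msg, "codon map must cover all 64 codons")
  if (!setequal(names(object@codons), codonAlphabet()))
    msg <- c(msg, "codon map names must be the 64 DNA codons")
  if (sum(object@degeneracy) != 64L - length(object@stops))
    msg <- c(msg, "family degeneracies must sum to the number of sense codons")
  if (!setequal(unlist(object@families, use.names = FALSE),
                setdiff(names(object@codons)[object@codons != "*"], NA)))
    msg <- c(msg, "families must partition the sense codons")
  if (length(msg)) msg else TRUE
})

#' All 64 DNA codons in fixed lexicographic order
#' @return character vector of length 64.
#' @export
codonAlphabet <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Construct a GeneticCode
#'
#' @param id NCBI translation table id passed to
#'   \code{\link[Biostrings]{getGeneticCode}}.  Default \code{"2"}
#'   (vertebrate mitochondrial).
#' @param starts permitted initiation codons.  The default \code{c("ATG",
#'   "GTG")} is the permissive mitochondrial policy; pass \code{"ATG"} for a
#'   strict policy or any custom set.
#' @return a \linkS4class{GeneticCode} object.
#' @examples
#' code <- geneticCode("2")
#' stopCodons(code)
#' @export
geneticCode <- function(id = "2", starts = c("ATG", "GTG")) {
  map <- Biostrings::getGeneticCode(as.character(id))
  map <- map[codonAlphabet()]
  stops <- names(map)[map == "*"]
  sense <- map[map != "*"]
  fams <- split(names(sense), factor(unname(sense)))
  deg <- vapply(fams, length, integer(1))
  new("GeneticCode",
    id = as.character(id), codons = map,
    starts = toupper(starts), stops = stops,
    families = fams, degeneracy = deg)
}

#' @describeIn geneticCode stop codons of a code
#' @param code a \linkS4class{GeneticCode}.
#' @export
stopCodons <- function(code) code@stops

#' @describeIn geneticCode start codons of a code
#' @export
startCodons <- function(code) code@starts

#' @describeIn geneticCode sense (non-stop) codons of a code
#' @export
senseCodons <- function(code) names(code@codons)[code@codons != "*"]

#' @describeIn geneticCode synonymous families (amino acid -> codons)
#' @export
codonFamilies <- function(code) code@families

#' @describeIn geneticCode degeneracy per amino-acid family
#' @export
familyDegeneracy <- function(code) code@degeneracy

#' Translate codons to amino-acid letters under a code
#' @param codons character vector of codons.
#' @param code a \linkS4class{GeneticCode}.
#' @return character vector of amino-acid letters (\code{"*"} for stops,
#'   \code{NA} for ambiguous codons).
#' @export
translateCodons <- function(codons, code) {
  unname(code@codons[toupper(codons)])
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode (NCBI table ", object@id, ")\n", sep = "")
  cat("  sense codons: ", length(senseCodons(object)),
      "; stops: ", paste(object@stops, collapse = ","), "\n", sep = "")
  cat("  starts: ", paste(object@starts, collapse = ","), "\n", sep = "")
  tab <- table(familyDegeneracy(object))
  cat("  families: ",
      paste(sprintf("%s x %s-fold", tab, names(tab)), collapse = ", "),
      "\n", sep = "")
})

# split a coding-orientation nucleotide string into codons (uppercase)
splitCodons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
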