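#' Controlled vocabulary for mitochondrial gene names
#'
#' Vertebrate mitogenomes carry 13 protein-coding genes, 22 tRNAs, two rRNAs,
#' the control region and the light-strand replication origin.  Annotation
#' sources label them inconsistently (\code{ND2} vs \code{NAD2}, \code{COI}
#' vs \code{COX1}, \code{cob} vs \code{CYTB}, ...); these helpers map the
#' common synonyms onto one canonical vocabulary.
#'
#' @name gene-vocabulary
NULL

#' The 13 canonical protein-coding gene names in report order
#' @return character vector of length 13.
#' @export
pcgNames <- function() {
  c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYTB",
    "NAD1", "NAD2", "NAD3", "NAD4", "NAD4L", "NAD5", "NAD6")
}

#' The 22 canonical tRNA labels
#' @return character vector of length 22.
#' @export
trnaNames <- function() {
  c("tRNA-Phe", "tRNA-Val", "tRNA-Leu(UUR)", "tRNA-Ile", "tRNA-Gln",
    "tRNA-Met", "tRNA-Trp", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys",
    "tRNA-Tyr", "tRNA-Ser(UCN)", "tRNA-Asp", "tRNA-Lys", "tRNA-Gly",
    "tRNA-Arg", "tRNA-His", "tRNA-Ser(AGY)", "tRNA-Leu(CUN)",
    "tRNA-Glu", "tRNA-Thr", "tRNA-Pro")
}

#' Canonical partition/report order: PCGs, rRNAs, tRNAs alphabetical
#' @return character vector of gene labels.
#' @export
canonicalGeneOrder <- function() {
  c(pcgNames(), "srRNA", "lrRNA", sort(trnaNames()), "CR", "OL")
}

# synonym -> canonical, keyed on an upper-cased, separator-stripped form
.geneSynonyms <- local({
  syn <- c(
    ATP6 = "ATP6", ATPASE6 = "ATP6", ATPASESUBUNIT6 = "ATP6",
    ATPSYNTHASEF0SUBUNIT6 = "ATP6", ATP8 = "ATP8", ATPASE8 = "ATP8",
    ATPSYNTHASEF0SUBUNIT8 = "ATP8",
    COX1 = "COX1", COI = "COX1", CO1 = "COX1", COXI = "COX1",
    CYTOCHROMECOXIDASESUBUNIT1 = "COX1", CYTOCHROMECOXIDASESUBUNITI = "COX1",
    MTCO1 = "COX1",
    COX2 = "COX2", COII = "COX2", CO2 = "COX2", COXII = "COX2",
    CYTOCHROMECOXIDASESUBUNIT2 = "COX2", CYTOCHROMECOXIDASESUBUNITII = "COX2",
    COX3 = "COX3", COIII = "COX3", CO3 = "COX3", COXIII = "COX3",
    CYTOCHROMECOXIDASESUBUNIT3 = "COX3", CYTOCHROMECOXIDASESUBUNITIII = "COX3",
    CYTB = "CYTB", COB = "CYTB", CYB = "CYTB", CYTOCHROMEB = "CYTB",
    MTCYB = "CYTB",
    NAD1 = "NAD1", ND1 = "NAD1", NADH1 = "NAD1",
    NADHDEHYDROGENASESUBUNIT1 = "NAD1",
    NAD2 = "NAD2", ND2 = "NAD2", NADH2 = "NAD2",
    NADHDEHYDROGENASESUBUNIT2 = "NAD2",
    NAD3 = "NAD3", ND3 = "NAD3", NADH3 = "NAD3",
    NADHDEHYDROGENASESUBUNIT3 = "NAD3",
    NAD4 = "NAD4", ND4 = "NAD4", NADH4 = "NAD4",
    NADHDEHYDROGENASESUBUNIT4 = "NAD4",
    NAD4L = "NAD4L", ND4L = "NAD4L", NADH4L = "NAD4L",
    NADHDEHYDROGENASESUBUNIT4L = "NAD4L",
    NAD5 = "NAD5", ND5 = "NAD5", NADH5 = "NAD5",
    NADHDEHYDROGENASESUBUNIT5 = "NAD5",
    NAD6 = "NAD6", ND6 = "NAD6", NADH6 = "NAD6",
    NADHDEHYDROGENASESUBUNIT6 = "NAD6",
    SRRNA = "srRNA", RRNS = "srRNA", `12S` = "srRNA", `12SRRNA` = "srRNA",
    `12SRIBOSOMALRNA` = "srRNA", SMALLSUBUNITRIBOSOMALRNA = "srRNA",
    LRRNA = "lrRNA", RRNL = "lrRNA", `16S` = "lrRNA", `16SRRNA` = "lrRNA",
    `16SRIBOSOMALRNA` = "lrRNA", LARGESUBUNITRIBOSOMALRNA = "lrRNA",
    CR = "CR", DLOOP = "CR", CONTROLREGION = "CR", MISCFEATURE = "CR",
    OL = "OL", REPORIGIN = "OL", ORIGINOFLSTRANDREPLICATION = "OL",
    LSTRANDREPLICATIONORIGIN = "OL", ORIL = "OL"
  )
  # tRNAs: trnF / tRNA-Phe / transfer RNA-Phe forms
  aa3 <- c(F = "Phe", V = "Val", L = "Leu", I = "Ile", Q = "Gln", M = "Met",
           W = "Trp", A = "Ala", N = "Asn", C = "Cys", Y = "Tyr", S = "Ser",
           D = "Asp", K = "Lys", G = "Gly", R = "Arg", H = "His", E = "Glu",
           T = "Thr", P = "Pro")
  for (one in names(aa3)) {
    can <- paste0("tRNA-", aa3[[one]])
    syn[[paste0("TRN", one)]] <- can
    syn[[toupper(gsub("[^A-Za-z0-9]", "", can))]] <- can
  }
  syn
})

.nameKey <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

#' Normalize a gene name to the canonical vocabulary
#'
#' @param name raw gene label(s) as annotated (e.g. \code{"ND2"},
#'   \code{"COI"}, \code{"trnF"}, \code{"D-loop"}).
#' @param warn warn on labels that cannot be mapped (they are returned
#'   verbatim, never dropped).
#' @return character vector of canonical labels.
#' @examples
#' normalizeGeneName(c("ND2", "COI", "cob"))
#' @export
normalizeGeneName <- function(name, warn = TRUE) {
  name <- as.character(name)
  # keep a tRNA anticodon disambiguator if present, e.g. trnL(UUR)
  antiRx <- "\\((UUR|CUN|UCN|AGY)\\)"
  antiM <- regexpr(antiRx, name)
  anti <- rep("", length(name))
  anti[antiM > 0] <- regmatches(name, antiM)
  base <- sub(antiRx, "", name)
  out <- unname(.geneSynonyms[.nameKey(base)])
  needAnti <- !is.na(out) & out %in% c("tRNA-Leu", "tRNA-Ser") & anti != ""
  out[needAnti] <- paste0(out[needAnti], anti[needAnti])
  bad <- is.na(out)
  if (any(bad)) {
    if (warn)
      warning("unmapped gene name(s) kept verbatim: ",
              paste(unique(name[bad]), collapse = ", "))
    out[bad] <- name[bad]
  }
  out
}
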