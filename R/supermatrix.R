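.datasetIds <- c("PCGs", "PCGs12", "PCGsRNA", "PCGs12RNA", "Mt")

#' Keep a subset of codon positions of a codon-framed alignment
#'
#' @param block a codon-framed \linkS4class{AlignmentBlock}.
#' @param keep subset of \code{c(1, 2, 3)}: codon positions to retain.
#' @return an \linkS4class{AlignmentBlock} whose \code{"provenance"}
#'   attribute maps every output column to its original column index.
#' @examples
#' b <- alignmentBlock(c(a = "ATGAAA", b = "ATGGGG"), codonFramed = TRUE)
#' stripCodonPositions(b, c(1, 2))
#' @export
stripCodonPositions <- function(block, keep = c(1, 2)) {
  stopifnot(all(keep %in% 1:3), length(keep) >= 1)
  if (!isTRUE(block@codonFramed))
    stop("block is not codon-framed; cannot strip codon positions")
  w <- Biostrings::width(block@seqs)[1]
  pos <- rep(1:3, w / 3L)
  cols <- which(pos %in% keep)
  m <- do.call(rbind, strsplit(as.character(block@seqs), ""))
  out <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
  res <- alignmentBlock(setNames(out, names(block@seqs)), gene = block@gene,
                        codonFramed = length(keep) == 3L)
  attr(res, "provenance") <- cols
  res
}

#' Remove gap-rich columns from an alignment
#'
#' Columns whose gap fraction exceeds \code{maxGapFraction} are removed;
#' in codon-framed blocks a whole codon is dropped whenever any of its three
#' columns fails, preserving the reading frame.  The operation is
#' idempotent.
#'
#' @param block an \linkS4class{AlignmentBlock}.
#' @param maxGapFraction threshold in [0, 1); default 0.5.
#' @return trimmed \linkS4class{AlignmentBlock} with a \code{"provenance"}
#'   attribute of retained original column indices.
#' @export
gapTrim <- function(block, maxGapFraction = 0.5) {
  m <- do.call(rbind, strsplit(as.character(block@seqs), ""))
  gapFrac <- colMeans(m == "-" | m == ".")
  bad <- gapFrac > maxGapFraction
  if (isTRUE(block@codonFramed)) {
    codon <- rep(seq_len(ncol(m) / 3L), each = 3L)
    bad <- codon %in% codon[bad]
  }
  if (all(bad)) stop("gap trimming removed every column")
  keep <- which(!bad)
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  res <- alignmentBlock(setNames(out, names(block@seqs)), gene = block@gene,
                        codonFramed = block@codonFramed)
  attr(res, "provenance") <- keep
  res
}

#' Concatenate gene alignments into a supermatrix
#'
#' Joins per-gene blocks in canonical gene order into one matrix and
#' returns the partition table that exactly tiles it.  Codon-framed blocks
#' may have third positions excluded first (the \code{PCGs12} construction,
#' which retains exactly 2/3 of the codon sites).
#'
#' @param blocks named list of \linkS4class{AlignmentBlock}s sharing a taxon
#'   set.
#' @param keepPositions codon positions retained in codon-framed blocks
#'   (default all); non-framed blocks are always taken whole.
#' @param strict error on taxon-set mismatches (default); otherwise missing
#'   taxa are padded with gaps.
#' @return list with \code{block} (the concatenated
#'   \linkS4class{AlignmentBlock}) and \code{partitions} (\code{data.frame}
#'   gene, start, end, positions).
#' @export
concatenateAlignments <- function(blocks, keepPositions = 1:3,
                                  strict = TRUE) {
  ord <- intersect(canonicalGeneOrder(), names(blocks))
  ord <- c(ord, setdiff(names(blocks), ord))
  blocks <- blocks[ord]
  taxa <- Reduce(union, lapply(blocks, blockTaxa))
  if (strict) {
    offenders <- names(blocks)[!vapply(blocks, function(b)
      setequal(blockTaxa(b), taxa), logical(1))]
    if (length(offenders))
      stop("taxon sets differ across blocks: ",
           paste(offenders, collapse = ", "))
  }
  pieces <- list(); parts <- list(); at <- 1L
  for (g in names(blocks)) {
    b <- blocks[[g]]
    posLabel <- "all"
    if (isTRUE(b@codonFramed) && !identical(sort(keepPositions), 1:3)) {
      b <- stripCodonPositions(b, keepPositions)
      posLabel <- paste(sort(keepPositions), collapse = "")
    }
    s <- as.character(blockSeqs(b))
    w <- nchar(s[1])
    miss <- setdiff(taxa, names(s))
    if (length(miss)) s[miss] <- strrep("-", w)
    pieces[[g]] <- s[taxa]
    parts[[g]] <- data.frame(gene = g, start = at, end = at + w - 1L,
                             positions = posLabel, stringsAsFactors = FALSE)
    at <- at + w
  }
  mat <- do.call(paste0, pieces)
  names(mat) <- taxa
  list(block = alignmentBlock(mat, gene = "supermatrix"),
       partitions = do.call(rbind, parts))
}

#' Build one of the five standard concatenated datasets
#'
#' \code{PCGs}: the 13 protein-coding genes; \code{PCGs12}: the same with
#' third codon positions excluded; \code{PCGsRNA} / \code{PCGs12RNA}: plus
#' the rRNA and tRNA partitions; \code{Mt}: additionally the control-region
#' and replication-origin partitions (an approximation of a whole-genome
#' alignment built from its annotated parts).
#'
#' @param cdsBlocks named list of codon-framed CDS
#'   \linkS4class{AlignmentBlock}s.
#' @param rnaBlocks optional named list of rRNA/tRNA blocks.
#' @param otherBlocks optional named list of further non-coding blocks
#'   (control region, OL), used by \code{Mt}.
#' @param dataset one of \code{"PCGs"}, \code{"PCGs12"}, \code{"PCGsRNA"},
#'   \code{"PCGs12RNA"}, \code{"Mt"}.
#' @param maxGapFraction optional gap-trim threshold applied per block
#'   before concatenation (\code{NULL} = no trimming).
#' @param strict passed to \code{\link{concatenateAlignments}}.
#' @return as \code{\link{concatenateAlignments}}.
#' @export
buildSupermatrix <- function(cdsBlocks, rnaBlocks = NULL,
                             otherBlocks = NULL,
                             dataset = c("PCGs", "PCGs12", "PCGsRNA",
                                         "PCGs12RNA", "Mt"),
                             maxGapFraction = NULL, strict = TRUE) {
  dataset <- match.arg(dataset)
  keep <- if (dataset %in% c("PCGs12", "PCGs12RNA")) c(1L, 2L) else 1:3
  blocks <- cdsBlocks
  if (dataset %in% c("PCGsRNA", "PCGs12RNA", "Mt"))
    blocks <- c(blocks, rnaBlocks)
  if (dataset == "Mt")
    blocks <- c(blocks, otherBlocks)
  if (!is.null(maxGapFraction))
    blocks <- lapply(blocks, gapTrim, maxGapFraction = maxGapFraction)
  out <- concatenateAlignments(blocks, keepPositions = keep,
                               strict = strict)
  out$dataset <- dataset
  out
}

#' Write a supermatrix as relaxed PHYLIP
#'
#' @param supermatrix result of \code{\link{concatenateAlignments}} or an
#'   \linkS4class{AlignmentBlock}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhylip <- function(supermatrix, path) {
  b <- if (methods::is(supermatrix, "AlignmentBlock")) supermatrix
       else supermatrix$block
  s <- as.character(blockSeqs(b))
  lines <- c(sprintf("%d %d", length(s), nchar(s[1])),
             sprintf("%s  %s", gsub("[ \t]", "_", names(s)), s))
  writeLines(lines, path)
  invisible(path)
}

#' Write a supermatrix as NEXUS with a sets block of charsets
#'
#' Emits a \code{data} block via \pkg{ape} and appends a \code{sets} block
#' with one charset per partition (codon-position charsets use step-3
#' ranges), consumable by external model-selection and tree software.
#'
#' @param supermatrix result of \code{\link{concatenateAlignments}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNexus <- function(supermatrix, path) {
  b <- supermatrix$block
  s <- strsplit(tolower(as.character(blockSeqs(b))), "")
  names(s) <- gsub("[ \t]", "_", blockTaxa(b))
  ape::write.nexus.data(s, file = path, interleaved = FALSE,
                        datablock = TRUE)
  parts <- supermatrix$partitions
  sets <- c("begin sets;", sprintf("  charset %s = %d-%d;",
                                   gsub("[^A-Za-z0-9_]", "_", parts$gene),
                                   parts$start, parts$end),
            "end;")
  cat(paste(sets, collapse = "\n"), "\n", file = path, append = TRUE)
  invisible(path)
}
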