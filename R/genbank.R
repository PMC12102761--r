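#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses a single circular mitochondrial record: LOCUS/ACCESSION/ORGANISM
#' header, the feature table (CDS, tRNA, rRNA, D-loop, rep_origin) and the
#' ORIGIN sequence.  Gene names are normalized to the package's controlled
#' vocabulary (\code{ND2} becomes \code{NAD2}, \code{COI} becomes
#' \code{COX1}, ...); unmappable names raise a warning and are kept verbatim.
#' Complemented locations are returned reverse-complemented into coding
#' orientation, and \code{join()} locations that span the origin of the
#' circle are stitched back together.
#'
#' @param path path to a GenBank flat file containing one record.
#' @return a \linkS4class{MitogenomeRecord}.
#' @seealso \code{\link{writeGenBank}}, \code{\link{extractCDS}}
#' @export
parseGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file: ", path)

  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
             grep("^ACCESSION", lines, value = TRUE)[1])
  if (is.na(acc)) acc <- strsplit(lines[1], "\\s+")[[1]][2]
  orgLine <- grep("^\\s+ORGANISM", lines, value = TRUE)[1]
  org <- if (is.na(orgLine)) "unknown" else
    sub("^\\s+ORGANISM\\s+", "", orgLine)

  oriAt <- grep("^ORIGIN", lines)
  if (!length(oriAt))
    stop("record has no ORIGIN sequence section: ", path)
  endAt <- grep("^//", lines)
  endAt <- if (length(endAt)) endAt[endAt > oriAt[1]][1] else length(lines) + 1L
  seqLines <- lines[(oriAt[1] + 1L):(endAt - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nchar(seq))
    stop("record has an empty sequence: ", path)
  genome <- Biostrings::DNAString(seq)
  L <- length(genome)

  featAt <- grep("^FEATURES", lines)
  feats <- list()
  if (length(featAt)) {
    block <- lines[(featAt[1] + 1L):(oriAt[1] - 1L)]
    keyIdx <- grep("^ {2,8}\\S", block)
    for (i in seq_along(keyIdx)) {
      from <- keyIdx[i]
      to <- if (i < length(keyIdx)) keyIdx[i + 1L] - 1L else length(block)
      key <- sub("^\\s+(\\S+).*$", "\\1", block[from])
      if (key %in% c("source", "gene")) next
      body <- paste(gsub("^\\s+", "", block[from:to]), collapse = " ")
      loc <- sub(paste0("^", key, "\\s+"), "", gsub("^\\s+", "", block[from]))
      # continuation lines of the location (rare) precede the first qualifier
      extra <- block[setdiff(from:to, from)]
      qual1 <- grep("^\\s*/", extra)
      if (length(extra) && (!length(qual1) || qual1[1] > 1)) {
        upto <- if (length(qual1)) qual1[1] - 1L else length(extra)
        loc <- paste0(loc, paste(gsub("\\s+", "", extra[seq_len(upto)]),
                                 collapse = ""))
      }
      loc <- gsub("\\s+", "", loc)
      getQ <- function(q) {
        m <- regmatches(body, regexpr(paste0("/", q, '="[^"]*"'), body))
        if (!length(m)) return(NA_character_)
        sub(paste0('^/', q, '="'), "", sub('"$', "", m))
      }
      feats[[length(feats) + 1L]] <- list(
        key = key, loc = loc,
        gene = getQ("gene"), product = getQ("product"), note = getQ("note"))
    }
  }

  rows <- lapply(feats, function(f) {
    p <- .parseLocation(f$loc, L)
    kind <- switch(f$key,
      CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
      "D-loop" = "control_region", rep_origin = "origin_light",
      misc_feature = "control_region", NA_character_)
    if (is.na(kind)) return(NULL)
    raw <- f$gene
    if (is.na(raw)) raw <- f$product
    if (is.na(raw)) raw <- f$note
    if (is.na(raw)) raw <- switch(kind, control_region = "CR",
                                  origin_light = "OL", "unknown")
    name <- switch(kind, control_region = "CR", origin_light = "OL",
                   normalizeGeneName(raw))
    data.frame(name = name, kind = kind, start = p$start, end = p$end,
               strand = if (p$complement) "L" else "H",
               stringsAsFactors = FALSE)
  })
  ft <- do.call(rbind, rows)
  if (!is.null(ft)) rownames(ft) <- NULL
  if (is.null(ft))
    ft <- data.frame(name = character(), kind = character(),
                     start = integer(), end = integer(),
                     strand = character(), stringsAsFactors = FALSE)
  gs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(ft)), function(i)
    as.character(featureSeq(genome, ft$start[i], ft$end[i], ft$strand[i])),
    character(1)))
  names(gs) <- ft$name
  new("MitogenomeRecord", accession = acc, taxon = org,
      sequence = genome, features = ft, geneSeqs = gs)
}

# location grammar: 123..456 | complement(X) | join(a..L,1..b)
.parseLocation <- function(loc, L) {
  comp <- grepl("^complement\\(", loc)
  inner <- sub("\\)$", "", sub("^complement\\(", "", loc))
  join <- grepl("^join\\(", inner)
  inner <- sub("\\)$", "", sub("^join\\(", "", inner))
  parts <- strsplit(inner, ",")[[1]]
  rng <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    xs <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  }, integer(2)))
  if (join && nrow(rng) == 2L && rng[1, 2] == L && rng[2, 1] == 1L) {
    list(start = rng[1, 1], end = rng[2, 2], complement = comp)  # wraps origin
  } else {
    list(start = min(rng), end = max(rng), complement = comp)
  }
}

#' Extract a feature subsequence from a circular genome
#'
#' Coordinates are 1-based inclusive; \code{start > end} wraps across the
#' origin (suffix then prefix).  Light-strand (\code{"L"}) features are
#' reverse-complemented into coding orientation.
#'
#' @param genome a \linkS4class{DNAString} (or string).
#' @param start,end 1-based inclusive coordinates.
#' @param strand \code{"H"} or \code{"L"}.
#' @return a \linkS4class{DNAString} in coding orientation.
#' @export
featureSeq <- function(genome, start, end, strand = "H") {
  if (!methods::is(genome, "DNAString"))
    genome <- Biostrings::DNAString(toupper(as.character(genome)))
  L <- length(genome)
  s <- if (start <= end) {
    Biostrings::subseq(genome, start, end)
  } else {
    Biostrings::xscat(Biostrings::subseq(genome, start, L),
                      Biostrings::subseq(genome, 1L, end))
  }
  if (identical(strand, "L")) Biostrings::reverseComplement(s) else s
}

#' Write a MitogenomeRecord as a GenBank flat file
#'
#' Emits a minimal but standard-conforming flat file (LOCUS, ACCESSION,
#' ORGANISM, feature table, ORIGIN) that \code{\link{parseGenBank}}
#' round-trips exactly: coordinates, strands and sequences are preserved.
#' Features wrapping the origin are written as \code{join(a..L,1..b)}.
#'
#' @param record a \linkS4class{MitogenomeRecord}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(record, path) {
  L <- length(record@sequence)
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular VRT %s",
            record@accession, L, format(Sys.Date(), "%d-%b-%Y")),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", record@taxon),
    sprintf("ACCESSION   %s", record@accession),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s", record@taxon),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    '                     /organelle="mitochondrion"')
  ft <- record@features
  key <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
           control_region = "D-loop", origin_light = "rep_origin")
  for (i in seq_len(nrow(ft))) {
    loc <- if (ft$start[i] <= ft$end[i])
      sprintf("%d..%d", ft$start[i], ft$end[i])
    else
      sprintf("join(%d..%d,1..%d)", ft$start[i], L, ft$end[i])
    if (ft$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
      sprintf("     %-15s %s", key[[ft$kind[i]]], loc),
      sprintf('                     /gene="%s"', ft$name[i]))
  }
  out <- c(out, "ORIGIN")
  seq <- tolower(as.character(record@sequence))
  starts <- seq(1L, nchar(seq), by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Tabulate features across records
#'
#' @param records a list of \linkS4class{MitogenomeRecord} objects.
#' @return a \code{data.frame} with one row per feature: accession, taxon,
#'   gene, kind, start, end, strand, length.
#' @export
featureTable <- function(records) {
  if (methods::is(records, "MitogenomeRecord")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    ft <- r@features
    data.frame(accession = r@accession, taxon = r@taxon,
               gene = ft$name, kind = ft$kind, start = ft$start,
               end = ft$end, strand = ft$strand,
               length = Biostrings::width(r@geneSeqs),
               stringsAsFactors = FALSE)
  }))
}
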