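.purines <- c("A", "G")

# split two aligned sequences into the site pairs both resolve (ACGT only)
.pairwiseSites <- function(si, sj) {
  a <- strsplit(toupper(as.character(si)), "")[[1]]
  b <- strsplit(toupper(as.character(sj)), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  list(a = a[ok], b = b[ok])
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Separates transitions (proportion P) from transversions (proportion Q)
#' over the pairwise-comparable sites (columns with a gap or ambiguity code
#' in either sequence are dropped) and applies Kimura's correction
#' \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)}.
#'
#' @param si,sj aligned nucleotide strings of equal length.
#' @return list with \code{sites} compared, \code{P}, \code{Q} and the
#'   distance \code{d} (\code{NA} with a warning when saturation makes a
#'   logarithm argument non-positive).
#' @examples
#' k2p("ACGTACGTAC", "ACGTACGTAC")$d  # 0
#' @export
k2p <- function(si, sj) {
  s <- .pairwiseSites(si, sj)
  n <- length(s$a)
  if (n == 0L) stop("no comparable sites")
  diff <- s$a != s$b
  ts <- diff & ((s$a %in% .purines) == (s$b %in% .purines))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  d <- if (arg1 <= 0 || arg2 <= 0) {
    warning("K2P distance undefined (saturation)")
    NA_real_
  } else -0.5 * log(arg1) - 0.25 * log(arg2)
  list(sites = n, P = P, Q = Q, d = d)
}

#' Nucleotide diversity (pi) of an alignment
#'
#' Nei's pi: the average, over all unordered sequence pairs, of the
#' proportion of differing sites.  Under the default complete-deletion
#' policy, columns containing a gap or ambiguity code in any sequence are
#' removed once for all pairs; under pairwise deletion each pair drops only
#' its own unresolved columns.
#'
#' @param block an \linkS4class{AlignmentBlock} (or named character vector /
#'   \code{DNAStringSet} of equal-length sequences).
#' @param siteHandling \code{"complete"} (default) or \code{"pairwise"}
#'   deletion.
#' @return pi (numeric).
#' @export
nucleotideDiversity <- function(block,
                                siteHandling = c("complete", "pairwise")) {
  siteHandling <- match.arg(siteHandling)
  seqs <- if (methods::is(block, "AlignmentBlock"))
    as.character(blockSeqs(block)) else
    vapply(as.list(block), function(s) toupper(as.character(s)),
           character(1))
  m <- length(seqs)
  if (m < 2L) stop("need at least 2 sequences")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  if (siteHandling == "complete") {
    ok <- apply(chars, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(ok)) stop("no comparable sites after complete deletion")
    chars <- chars[, ok, drop = FALSE]
  }
  pairs <- utils::combn(m, 2)
  d <- apply(pairs, 2, function(ij) {
    a <- chars[ij[1], ]; b <- chars[ij[2], ]
    if (siteHandling == "pairwise") {
      keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      a <- a[keep]; b <- b[keep]
    }
    if (!length(a)) stop("a sequence pair shares no comparable sites")
    mean(a != b)
  })
  mean(d)
}

# --- Nei-Gojobori (proportional) machinery ---------------------------------

.ngCache <- new.env(parent = emptyenv())

# per-codon potential synonymous site counts under a code.
# At each position, the synonymous fraction is taken among the non-stop
# single-base changes, so stop-bound mutations are redistributed pro rata
# and s + n = 3 holds exactly for every codon.
.ngSites <- function(code) {
  key <- paste0("sites_", code@id)
  if (!is.null(.ngCache[[key]])) return(.ngCache[[key]])
  sense <- senseCodons(code)
  bases <- c("A", "C", "G", "T")
  s <- vapply(sense, function(cdn) {
    aa <- translateCodons(cdn, code)
    tot <- 0
    for (p in 1:3) {
      alts <- paste0(substr(cdn, 1, p - 1),
                     setdiff(bases, substr(cdn, p, p)),
                     substr(cdn, p + 1, 3))
      altAA <- translateCodons(alts, code)
      nonstop <- altAA != "*"
      if (any(nonstop))
        tot <- tot + sum(altAA[nonstop] == aa) / sum(nonstop)
    }
    tot
  }, numeric(1))
  .ngCache[[key]] <- s
  s
}

# observed synonymous/nonsynonymous differences between two sense codons,
# averaged over all shortest substitution pathways; pathways passing through
# a stop codon are excluded (all pathways are used if every one is blocked)
.ngPathways <- function(c1, c2, code) {
  memoKey <- paste0("path_", code@id)
  if (is.null(.ngCache[[memoKey]]))
    .ngCache[[memoKey]] <- new.env(parent = emptyenv())
  memo <- .ngCache[[memoKey]]
  pk <- paste0(c1, c2)
  hit <- memo[[pk]]
  if (!is.null(hit)) return(hit)
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(dpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(dpos)
    else if (nd == 2L) list(dpos, rev(dpos))
    else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) dpos[i])
    }
  paths <- lapply(perms, function(ord) {
    cur <- c1
    syn <- 0; non <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- translateCodons(cur, code); a2 <- translateCodons(nxt, code)
      if (a2 == "*") blocked <- TRUE
      if (!is.na(a1) && !is.na(a2) && a1 == a2) syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    c(syn = syn, non = non, blocked = as.numeric(blocked))
  })
  pm <- do.call(rbind, paths)
  use <- pm[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(pm))
  out <- c(sd = mean(pm[use, "syn"]), nd = mean(pm[use, "non"]))
  memo[[pk]] <- out
  out
}

#' Nei-Gojobori synonymous and nonsynonymous substitution rates
#'
#' The original proportional method: potential synonymous (S) and
#' nonsynonymous (N) site counts are averaged over the two sequences (with
#' S + N = 3 x codons exactly); observed differences are partitioned by
#' averaging over all shortest substitution pathways between each codon
#' pair, excluding pathways through stop codons; the proportions
#' pS = Sd/S and pN = Nd/N receive the Jukes-Cantor correction
#' \eqn{K = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}.
#'
#' Codon columns containing a gap, an ambiguity code or a stop codon in
#' either sequence are excluded pairwise.
#'
#' @param si,sj codon-aligned CDS strings of equal length (multiple of 3).
#' @param code a \linkS4class{GeneticCode}.
#' @return list with \code{codons} compared, \code{S}, \code{N}, \code{Sd},
#'   \code{Nd}, \code{pS}, \code{pN}, \code{Ka}, \code{Ks} and
#'   \code{Ka_Ks} (\code{NA} when Ks is 0 or a proportion is at or beyond
#'   the 3/4 correction limit, with a warning).
#' @export
neiGojobori <- function(si, sj, code = geneticCode("2")) {
  ci <- splitCodons(si)
  cj <- splitCodons(sj)
  if (length(ci) != length(cj)) stop("codon alignments differ in length")
  sense <- senseCodons(code)
  ok <- ci %in% sense & cj %in% sense
  ci <- ci[ok]; cj <- cj[ok]
  if (!length(ci)) stop("no comparable codons")
  siteTab <- .ngSites(code)
  S <- (sum(siteTab[ci]) + sum(siteTab[cj])) / 2
  N <- 3 * length(ci) - S
  pairKey <- paste(ci, cj)
  uniq <- !duplicated(pairKey)
  diffs <- vapply(which(uniq), function(k) .ngPathways(ci[k], cj[k], code),
                  c(sd = 0, nd = 0))
  counts <- table(factor(pairKey, levels = pairKey[uniq]))
  Sd <- sum(diffs["sd", ] * as.numeric(counts))
  Nd <- sum(diffs["nd", ] * as.numeric(counts))
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) { warning("proportion at/beyond JC limit"); NA_real_ }
    else -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  list(codons = length(ci), S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, Ka = Ka, Ks = Ks,
       Ka_Ks = if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks)
}

#' Per-gene divergence summary across taxa
#'
#' For each gene alignment: nucleotide diversity (complete deletion), the
#' mean pairwise K2P distance, and the mean pairwise Ka/Ks (arithmetic mean
#' of the defined per-pair ratios by default; \code{"ratio_of_means"}
#' divides mean Ka by mean Ks instead).
#'
#' @param blocks named list of codon-framed \linkS4class{AlignmentBlock}s.
#' @param code a \linkS4class{GeneticCode}.
#' @param kaksAveraging \code{"mean_of_ratios"} (default) or
#'   \code{"ratio_of_means"}.
#' @return \code{data.frame} with one row per gene: \code{gene}, \code{Pi},
#'   \code{K2P}, \code{Ka_Ks}, \code{n_taxa}, in canonical gene order.
#' @export
divergenceSummary <- function(blocks, code = geneticCode("2"),
                              kaksAveraging = c("mean_of_ratios",
                                                "ratio_of_means")) {
  kaksAveraging <- match.arg(kaksAveraging)
  ord <- intersect(canonicalGeneOrder(), names(blocks))
  ord <- c(ord, setdiff(names(blocks), ord))
  rows <- lapply(ord, function(g) {
    b <- blocks[[g]]
    seqs <- as.character(blockSeqs(b))
    m <- length(seqs)
    pairs <- utils::combn(m, 2)
    k2ps <- apply(pairs, 2, function(ij)
      suppressWarnings(k2p(seqs[ij[1]], seqs[ij[2]])$d))
    ngs <- apply(pairs, 2, function(ij)
      suppressWarnings(neiGojobori(seqs[ij[1]], seqs[ij[2]], code)))
    ka <- vapply(ngs, `[[`, numeric(1), "Ka")
    ks <- vapply(ngs, `[[`, numeric(1), "Ks")
    ratio <- vapply(ngs, `[[`, numeric(1), "Ka_Ks")
    kaks <- if (kaksAveraging == "mean_of_ratios")
      mean(ratio, na.rm = TRUE)
    else mean(ka, na.rm = TRUE) / mean(ks, na.rm = TRUE)
    data.frame(gene = g,
               Pi = nucleotideDiversity(b),
               K2P = mean(k2ps, na.rm = TRUE),
               Ka_Ks = kaks, n_taxa = m, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
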