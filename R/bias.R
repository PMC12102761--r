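#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least-squares fit of the mean GC content at codon positions 1+2
#' (GC12) on the GC content at position 3 (GC3), across genes.  A slope near
#' 1 indicates that mutation pressure dominates codon usage; a slope near 0
#' indicates selection (weak dependence of the constrained positions on the
#' free one).
#'
#' @param gc3,gc12 numeric vectors per gene (fractions), or \code{gc3} may be
#'   a \code{data.frame} with columns \code{GC3} and \code{GC12}.
#' @param taxon label carried into the result.
#' @return list with \code{taxon}, \code{points} (data.frame), \code{slope},
#'   \code{intercept}, \code{R2}, \code{p_value} (two-sided t-test on the
#'   slope), \code{n}.  Zero variance in GC3 yields \code{NA} slope, flagged
#'   via \code{degenerate = TRUE}.
#' @export
neutralityFit <- function(gc3, gc12 = NULL, taxon = "") {
  if (is.data.frame(gc3)) { gc12 <- gc3$GC12; gc3 <- gc3$GC3 }
  if (length(gc3) < 3L) stop("need at least 3 genes for a neutrality fit")
  pts <- data.frame(GC3 = gc3, GC12 = gc12)
  if (stats::var(gc3) == 0)
    return(list(taxon = taxon, points = pts, slope = NA_real_,
                intercept = NA_real_, R2 = NA_real_, p_value = NA_real_,
                n = length(gc3), degenerate = TRUE))
  fit <- stats::lm(GC12 ~ GC3, data = pts)
  sm <- summary(fit)
  list(taxon = taxon, points = pts,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       R2 = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(gc3), degenerate = FALSE)
}

#' Expected ENC under mutation pressure alone
#'
#' The null ENC-GC3s curve: \eqn{ENC = 2 + s + 29/(s^2 + (1-s)^2)} with
#' \eqn{s} the GC3s fraction.  Genes falling below the curve use fewer
#' codons than composition alone predicts, implicating selection.
#'
#' @param gc3s GC3s fraction(s) in [0, 1].
#' @return expected ENC value(s); maximal (60.5) at s = 0.5.
#' @examples
#' encExpected(0.5)  # 60.5
#' @export
encExpected <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Relative deviation of observed ENC from the mutation-pressure expectation
#'
#' @param encObs observed ENC value(s).
#' @param gc3s matching GC3s fraction(s).
#' @return \code{(ENC_exp - ENC_obs) / ENC_exp}; positive values fall below
#'   the curve.
#' @export
encDeviation <- function(encObs, gc3s) {
  e <- encExpected(gc3s)
  (e - encObs) / e
}

# third-position counts over a PR2 stratum
.thirdPositionCounts <- function(counts, mode) {
  code <- counts@code
  if (mode == "fourfold_only") {
    boxes <- unique(substr(codonAlphabet(), 1, 2))
    cdns <- unlist(lapply(boxes, function(b) {
      four <- paste0(b, c("A", "C", "G", "T"))
      aa <- translateCodons(four, code)
      if (!anyNA(aa) && length(unique(aa)) == 1L && aa[1] != "*") four
      else character(0)
    }))
  } else {
    fams <- codonFamilies(code)
    cdns <- unlist(fams[familyDegeneracy(code) >= 2L], use.names = FALSE)
  }
  cts <- codonCounts(counts)[cdns]
  third <- substr(cdns, 3, 3)
  vapply(c("A", "T", "G", "C"), function(b) sum(cts[third == b]), numeric(1))
}

#' PR2-bias coordinates of a gene
#'
#' Parity rule 2 states that without strand-specific mutation or selection
#' pressure, A = T and G = C within each strand.  The PR2 plot places each
#' gene at \eqn{x = G_3/(G_3+C_3)}, \eqn{y = A_3/(A_3+T_3)} computed at
#' third codon positions; deviation from (0.5, 0.5) reveals the bias.
#' Quadrants follow the mathematical convention relative to (0.5, 0.5):
#' I upper-right, II upper-left, III lower-left, IV lower-right.
#'
#' @param counts a \linkS4class{CodonCountTable}.
#' @param mode \code{"fourfold_only"} (default; third positions of fully
#'   degenerate codon boxes) or \code{"all_synonymous"}.
#' @return list with \code{x}, \code{y}, \code{quadrant} (\code{"I"} ...
#'   \code{"IV"}, or \code{"boundary"} when a coordinate equals 0.5).
#' @export
pr2 <- function(counts, mode = c("fourfold_only", "all_synonymous")) {
  mode <- match.arg(mode)
  n3 <- .thirdPositionCounts(counts, mode)
  if (sum(n3) == 0) stop("empty PR2 stratum")
  if (n3[["G"]] + n3[["C"]] == 0 || n3[["A"]] + n3[["T"]] == 0)
    stop("PR2 coordinates undefined: zero denominator")
  x <- n3[["G"]] / (n3[["G"]] + n3[["C"]])
  y <- n3[["A"]] / (n3[["A"]] + n3[["T"]])
  quadrant <- if (x == 0.5 || y == 0.5) "boundary"
    else if (x > 0.5 && y > 0.5) "I"
    else if (x < 0.5 && y > 0.5) "II"
    else if (x < 0.5 && y < 0.5) "III"
    else "IV"
  list(x = unname(x), y = unname(y), quadrant = quadrant)
}

#' Split genes into high- and low-bias groups
#'
#' The high-expression proxy group used for the \eqn{\Delta RSCU} analysis:
#' genes are ranked by a bias key (ENC by default, ascending: the most
#' biased, lowest-ENC genes form the "high" group) and the top and bottom
#' quartile-sized groups are returned.
#'
#' @param indexTable output of \code{\link{usageIndices}} for one taxon.
#' @param key ranking column, \code{"ENC"} (ascending) or \code{"CAI"}
#'   (descending).
#' @param groupSize genes per group; default a quartile of the gene count.
#' @return list with \code{high} and \code{low} gene-name vectors and the
#'   policy metadata.
#' @export
highLowGroups <- function(indexTable, key = c("ENC", "CAI"),
                          groupSize = NULL) {
  key <- match.arg(key)
  if (is.null(groupSize)) groupSize <- max(1L, nrow(indexTable) %/% 4L)
  ord <- order(indexTable[[key]],
               decreasing = identical(key, "CAI"))
  genes <- indexTable$gene[ord]
  list(high = genes[seq_len(groupSize)],
       low = rev(genes)[seq_len(groupSize)],
       key = key, groupSize = groupSize)
}

#' Classify codons as high-frequency, high-expression and optimal
#'
#' Combines three RSCU tables: the full gene set, a high-bias group and a
#' low-bias group.  \eqn{\Delta RSCU = RSCU_{high} - RSCU_{low}};
#' high-frequency codons (HFC) have overall RSCU > 1, high-expression codons
#' have \eqn{\Delta RSCU} > 0.08, and optimal codons satisfy both.
#'
#' @param rscuAll,rscuHigh,rscuLow RSCU \code{data.frame}s from
#'   \code{\link{rscu}} on the respective codon-count tables.
#' @param rscuThreshold,deltaThreshold classification thresholds (defaults
#'   1.0 and 0.08).
#' @return \code{data.frame} per multi-synonym sense codon: \code{codon},
#'   \code{aa}, \code{rscu}, \code{dRSCU}, logicals \code{hfc},
#'   \code{high_expression}, \code{optimal}, and \code{ending} (third base).
#'   Family gaps in either group yield \code{NA} \eqn{\Delta RSCU}, flagged
#'   not dropped.
#' @export
classifyCodons <- function(rscuAll, rscuHigh, rscuLow,
                           rscuThreshold = 1.0, deltaThreshold = 0.08) {
  stopifnot(identical(rscuAll$codon, rscuHigh$codon),
            identical(rscuAll$codon, rscuLow$codon))
  d <- rscuHigh$rscu - rscuLow$rscu
  out <- data.frame(
    codon = rscuAll$codon, aa = rscuAll$aa, rscu = rscuAll$rscu,
    dRSCU = d,
    hfc = rscuAll$rscu > rscuThreshold,
    high_expression = d > deltaThreshold,
    stringsAsFactors = FALSE)
  out$optimal <- out$hfc & out$high_expression
  out$ending <- substr(out$codon, 3, 3)
  rownames(out) <- out$codon
  attr(out, "thresholds") <- c(rscu = rscuThreshold, delta = deltaThreshold)
  out
}

#' Pairwise Pearson correlations among codon-usage indices
#'
#' @param indexTable numeric matrix or the output of
#'   \code{\link{usageIndices}} (non-numeric columns dropped), genes in rows,
#'   indices in columns.
#' @return list of matrices \code{r} (Pearson correlations, unit diagonal),
#'   \code{p} (two-sided p-values) and \code{stars} (\code{"*"} < 0.05,
#'   \code{"**"} < 0.01, \code{"***"} < 0.001).  Constant columns yield
#'   \code{NA}, flagged not dropped.
#' @export
indexCorrelation <- function(indexTable) {
  if (is.data.frame(indexTable))
    indexTable <- as.matrix(
      indexTable[vapply(indexTable, is.numeric, logical(1))])
  if (nrow(indexTable) < 3L) stop("need at least 3 genes")
  k <- ncol(indexTable)
  nm <- colnames(indexTable)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ct <- tryCatch(
      suppressWarnings(stats::cor.test(indexTable[, i], indexTable[, j],
                                       method = "pearson")),
      error = function(e) NULL)
    if (!is.null(ct) && is.finite(ct$estimate)) {
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = list(nm, nm))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  list(r = r, p = p, stars = stars)
}
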