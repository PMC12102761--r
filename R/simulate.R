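#' Simulation configuration for synthetic CDS families
#'
#' Defaults emulate a small clade of fish mitogenomes: 7 taxa, the 13
#' protein-coding genes at their typical mitochondrial lengths (about 3,800
#' codons in total), an A-rich third codon position (GC3 about 0.40 with
#' positive AT skew and strongly negative GC skew), a transition bias of 2,
#' strong purifying selection (omega = 0.05) and a pairwise divergence of
#' 0.2 substitutions per site.
#'
#' @param nTaxa number of taxa on the star tree.
#' @param genes named integer vector: codons per gene (sense codons; the
#'   terminal stop is added only when records are emitted).
#' @param targetGC3 target G+C fraction at third codon positions of the root.
#' @param atSkew3,gcSkew3 target third-position skews of the root.
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param d expected pairwise divergence between any two tips, in
#'   substitutions per nucleotide site (each tip sits d/2 from the root).
#' @param codeId NCBI translation table id.
#' @param seed mandatory integer seed; there is no silent nondeterminism.
#' @return a \code{SimulationConfig} list.
#' @export
simConfig <- function(nTaxa = 7,
                      genes = c(ATP6 = 227, ATP8 = 55, COX1 = 516,
                                COX2 = 230, COX3 = 261, CYTB = 380,
                                NAD1 = 324, NAD2 = 348, NAD3 = 116,
                                NAD4 = 460, NAD4L = 98, NAD5 = 611,
                                NAD6 = 173),
                      targetGC3 = 0.405, atSkew3 = 0.30, gcSkew3 = -0.45,
                      kappa = 2, omega = 0.05, d = 0.2,
                      codeId = "2", seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory in a SimulationConfig")
  stopifnot(nTaxa >= 2, all(genes > 0), kappa > 0, omega >= 0, d >= 0,
            targetGC3 > 0, targetGC3 < 1)
  structure(list(nTaxa = nTaxa, genes = genes, targetGC3 = targetGC3,
                 atSkew3 = atSkew3, gcSkew3 = gcSkew3, kappa = kappa,
                 omega = omega, d = d, codeId = codeId,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# third-position base probabilities implied by the composition targets
.pos3Probs <- function(gc3, atSkew, gcSkew) {
  at <- 1 - gc3
  p <- c(A = at * (1 + atSkew) / 2, T = at * (1 - atSkew) / 2,
         G = gc3 * (1 + gcSkew) / 2, C = gc3 * (1 - gcSkew) / 2)
  if (any(p < 0)) stop("unattainable composition target: ",
                       "skew incompatible with GC3")
  p
}

# substitution structure: for each sense codon, reachable sense codons by a
# single base change with relative rates kappa^ts * omega^nonsyn
.rateStructure <- function(code, kappa, omega) {
  key <- paste("rates", code@id, kappa, omega, sep = "_")
  if (!is.null(.ngCache[[key]])) return(.ngCache[[key]])
  bases <- c("A", "C", "G", "T")
  sense <- senseCodons(code)
  struct <- lapply(sense, function(cdn) {
    aa <- translateCodons(cdn, code)
    tgt <- character(0); rate <- numeric(0)
    for (p in 1:3) {
      from <- substr(cdn, p, p)
      for (b in setdiff(bases, from)) {
        nxt <- cdn
        substr(nxt, p, p) <- b
        aa2 <- translateCodons(nxt, code)
        if (aa2 == "*") next
        r <- 1
        if ((from %in% .purines) == (b %in% .purines)) r <- r * kappa
        if (aa2 != aa) r <- r * omega
        tgt <- c(tgt, nxt); rate <- c(rate, r)
      }
    }
    list(targets = tgt, rates = rate, total = sum(rate))
  })
  names(struct) <- sense
  .ngCache[[key]] <- struct
  struct
}

# evolve a codon vector along one branch of expected length bl (subs/nt
# site), Gillespie per site; returns new codons and substitution tallies
.evolveBranch <- function(codons, struct, Rbar, bl, code) {
  nSyn <- 0L; nNon <- 0L; nTs <- 0L; nTv <- 0L
  if (bl > 0) {
    Tend <- 3 * bl / Rbar
    for (i in seq_along(codons)) {
      cur <- codons[i]
      t <- stats::rexp(1, struct[[cur]]$total)
      while (t <= Tend) {
        st <- struct[[cur]]
        nxt <- sample(length(st$targets), 1, prob = st$rates)
        tgt <- st$targets[nxt]
        dpos <- which(strsplit(cur, "")[[1]] != strsplit(tgt, "")[[1]])
        b1 <- substr(cur, dpos, dpos); b2 <- substr(tgt, dpos, dpos)
        if ((b1 %in% .purines) == (b2 %in% .purines)) nTs <- nTs + 1L
        else nTv <- nTv + 1L
        if (translateCodons(cur, code) == translateCodons(tgt, code))
          nSyn <- nSyn + 1L else nNon <- nNon + 1L
        cur <- tgt
        t <- t + stats::rexp(1, struct[[cur]]$total)
      }
      codons[i] <- cur
    }
  }
  list(codons = codons, nSyn = nSyn, nNonsyn = nNon, nTs = nTs, nTv = nTv)
}

#' Simulate homologous CDS families on a star tree
#'
#' For each gene a root coding sequence is drawn codon by codon from the
#' composition targets (uniform first and second positions, third-position
#' base probabilities from \code{targetGC3} and the skews; stop codons
#' rejected; the initiation codon is held fixed so annotated records remain
#' valid).  Each tip then evolves independently along a branch of d/2
#' expected substitutions per nucleotide site under a codon-level Markov
#' process with relative rates \eqn{\kappa^{ts} \omega^{nonsyn}}
#' (substitutions into stop codons forbidden), normalized against the mean
#' leaving rate of the root sequence.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with \code{blocks} (named list of codon-framed
#'   \linkS4class{AlignmentBlock}s, taxa \code{t1..tn}), \code{truth}
#'   (\code{data.frame} of realized substitution counts per gene and tip)
#'   and \code{config}.
#' @export
simulateCdsFamily <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  code <- geneticCode(config$codeId)
  struct <- .rateStructure(code, config$kappa, config$omega)
  p3 <- .pos3Probs(config$targetGC3, config$atSkew3, config$gcSkew3)
  bases <- c("A", "C", "G", "T")
  sense <- senseCodons(code)
  taxa <- paste0("t", seq_len(config$nTaxa))
  blocks <- list(); truthRows <- list()
  # third base drawn from the target distribution first, then a first-two-
  # base box among those forming a sense codon: the realized third-position
  # marginal matches the target exactly (no stop-rejection bias)
  boxes <- unique(substr(sense, 1, 2))
  boxFor <- lapply(setNames(nm = names(p3)), function(b3)
    boxes[paste0(boxes, b3) %in% sense])
  for (g in names(config$genes)) {
    n <- config$genes[[g]]
    b3 <- sample(names(p3), n, replace = TRUE, prob = p3)
    root <- vapply(b3, function(b)
      paste0(sample(boxFor[[b]], 1), b), character(1))
    root[1] <- "ATG"
    Rbar <- mean(vapply(root[-1], function(c) struct[[c]]$total, numeric(1)))
    tips <- lapply(taxa, function(tx) {
      ev <- .evolveBranch(root[-1], struct, Rbar, config$d / 2, code)
      truthRows[[length(truthRows) + 1L]] <<- data.frame(
        gene = g, taxon = tx, nSub = ev$nSyn + ev$nNonsyn,
        nSyn = ev$nSyn, nNonsyn = ev$nNonsyn, nTs = ev$nTs, nTv = ev$nTv,
        stringsAsFactors = FALSE)
      paste(c(root[1], ev$codons), collapse = "")
    })
    names(tips) <- taxa
    blocks[[g]] <- alignmentBlock(unlist(tips), gene = g,
                                  codonFramed = TRUE)
  }
  list(blocks = blocks, truth = do.call(rbind, truthRows), config = config)
}

# random non-coding sequence with mito-like AT richness
.randomSeq <- function(n, atContent = 0.56) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(atContent / 2, atContent / 2,
                        (1 - atContent) / 2, (1 - atContent) / 2)),
        collapse = "")
}

# simplified vertebrate mitogenome feature layout: name, kind, strand
.mitoLayout <- function() {
  rbind(
    data.frame(name = "tRNA-Phe", kind = "tRNA", strand = "H"),
    data.frame(name = "srRNA", kind = "rRNA", strand = "H"),
    data.frame(name = "tRNA-Val", kind = "tRNA", strand = "H"),
    data.frame(name = "lrRNA", kind = "rRNA", strand = "H"),
    data.frame(name = "tRNA-Leu(UUR)", kind = "tRNA", strand = "H"),
    data.frame(name = "NAD1", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-Ile", kind = "tRNA", strand = "H"),
    data.frame(name = "tRNA-Gln", kind = "tRNA", strand = "L"),
    data.frame(name = "tRNA-Met", kind = "tRNA", strand = "H"),
    data.frame(name = "NAD2", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-Trp", kind = "tRNA", strand = "H"),
    data.frame(name = "tRNA-Ala", kind = "tRNA", strand = "L"),
    data.frame(name = "tRNA-Asn", kind = "tRNA", strand = "L"),
    data.frame(name = "OL", kind = "origin_light", strand = "H"),
    data.frame(name = "tRNA-Cys", kind = "tRNA", strand = "L"),
    data.frame(name = "tRNA-Tyr", kind = "tRNA", strand = "L"),
    data.frame(name = "COX1", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-Ser(UCN)", kind = "tRNA", strand = "L"),
    data.frame(name = "tRNA-Asp", kind = "tRNA", strand = "H"),
    data.frame(name = "COX2", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-Lys", kind = "tRNA", strand = "H"),
    data.frame(name = "ATP8", kind = "CDS", strand = "H"),
    data.frame(name = "ATP6", kind = "CDS", strand = "H"),
    data.frame(name = "COX3", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-Gly", kind = "tRNA", strand = "H"),
    data.frame(name = "NAD3", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-Arg", kind = "tRNA", strand = "H"),
    data.frame(name = "NAD4L", kind = "CDS", strand = "H"),
    data.frame(name = "NAD4", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-His", kind = "tRNA", strand = "H"),
    data.frame(name = "tRNA-Ser(AGY)", kind = "tRNA", strand = "H"),
    data.frame(name = "tRNA-Leu(CUN)", kind = "tRNA", strand = "H"),
    data.frame(name = "NAD5", kind = "CDS", strand = "H"),
    data.frame(name = "NAD6", kind = "CDS", strand = "L"),
    data.frame(name = "tRNA-Glu", kind = "tRNA", strand = "L"),
    data.frame(name = "CYTB", kind = "CDS", strand = "H"),
    data.frame(name = "tRNA-Thr", kind = "tRNA", strand = "H"),
    data.frame(name = "tRNA-Pro", kind = "tRNA", strand = "L"),
    data.frame(name = "CR", kind = "control_region", strand = "H"))
}

#' Emit simulated taxa as annotated mitogenome records
#'
#' Builds one minimal annotated circular genome per taxon from simulated CDS
#' blocks: the 13 protein-coding genes in the standard vertebrate layout
#' (NAD6 on the light strand), 22 placeholder tRNAs (8 on the light strand),
#' two rRNAs, a light-strand replication origin and a control region whose
#' length varies across taxa.  COX1 is GTG-initiated, COX2 carries a
#' truncated stop (\code{T}), all other genes end in \code{TAA}, and the
#' genome is rotated so the control region spans the origin of the circle --
#' together exercising every parsing path.
#'
#' @param sim result of \code{\link{simulateCdsFamily}} (must contain the 13
#'   canonical genes).
#' @param dir optional directory: when given, one GenBank flat file per
#'   taxon is written there.
#' @param crLength base control-region length; taxon i receives
#'   \code{crLength + 37 * (i - 1)}.
#' @return named list of \linkS4class{MitogenomeRecord}s (invisibly also
#'   written to \code{dir} if given).
#' @export
emitGenBank <- function(sim, dir = NULL, crLength = 800) {
  set.seed(sim$config$seed + 1L)
  layout <- .mitoLayout()
  taxa <- blockTaxa(sim$blocks[[1]])
  trnaLen <- setNames(sample(66:73, 22, replace = TRUE), trnaNames())
  rrnaLen <- c(srRNA = 950, lrRNA = 1680)
  olLen <- 32
  records <- list()
  for (ti in seq_along(taxa)) {
    tx <- taxa[ti]
    segs <- character(nrow(layout))
    for (i in seq_len(nrow(layout))) {
      nm <- layout$name[i]; kd <- layout$kind[i]
      if (kd == "CDS") {
        s <- as.character(blockSeqs(sim$blocks[[nm]])[[tx]])
        if (nm == "COX1") s <- paste0("GTG", substr(s, 4, nchar(s)))
        s <- paste0(s, if (nm == "COX2") "T" else "TAA")
        segs[i] <- s
      } else if (kd == "tRNA") {
        segs[i] <- .randomSeq(trnaLen[[nm]])
      } else if (kd == "rRNA") {
        segs[i] <- .randomSeq(rrnaLen[[nm]])
      } else if (kd == "origin_light") {
        segs[i] <- .randomSeq(olLen)
      } else {
        segs[i] <- .randomSeq(crLength + 37L * (ti - 1L))
      }
    }
    # genome holds the H-strand: L-strand features appear reverse-complemented
    genomeSegs <- ifelse(layout$strand == "L",
      vapply(segs, function(s) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))), character(1)), segs)
    ends <- cumsum(nchar(genomeSegs))
    starts <- ends - nchar(genomeSegs) + 1L
    L <- ends[length(ends)]
    # rotate so the control region wraps the origin
    off <- starts[nrow(layout)] + (nchar(genomeSegs[nrow(layout)]) %/% 2L)
    rot <- function(p) ((p - 1L - off) %% L) + 1L
    genome <- paste(genomeSegs, collapse = "")
    genome <- paste0(substr(genome, off + 1L, L), substr(genome, 1L, off))
    ft <- data.frame(name = layout$name, kind = layout$kind,
                     start = rot(starts), end = rot(ends),
                     strand = layout$strand, stringsAsFactors = FALSE)
    gs <- Biostrings::DNAStringSet(segs)
    names(gs) <- layout$name
    records[[tx]] <- new("MitogenomeRecord",
      accession = sprintf("SYN%04d", ti), taxon = tx,
      sequence = Biostrings::DNAString(genome),
      features = ft, geneSeqs = gs)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeGenBank(records[[tx]], file.path(dir, paste0(tx, ".gb")))
    }
  }
  records
}
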