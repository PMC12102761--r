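# write a TSV with numeric columns fixed at 4 decimals so reruns are
# byte-identical
.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 4, format = "f")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# per-taxon gene blocks from validated CDS sets, terminal stops stripped;
# genes whose lengths disagree across taxa are truncated to the shortest
# (a crude stand-in for external alignment, which is out of scope)
.cdsBlocks <- function(cdsByTaxon, code) {
  genes <- Reduce(intersect, lapply(cdsByTaxon, names))
  blocks <- list()
  for (g in genes) {
    seqs <- vapply(cdsByTaxon, function(cs) {
      s <- as.character(cs[[g]])
      cdn <- splitCodons(s)
      if (cdn[length(cdn)] %in% stopCodons(code))
        cdn <- cdn[-length(cdn)]
      paste(cdn, collapse = "")
    }, character(1))
    w <- nchar(seqs)
    if (length(unique(w)) > 1L) {
      warning("gene ", g, ": unequal CDS lengths across taxa; ",
              "truncating to the shortest")
      seqs <- substr(seqs, 1L, min(w))
    }
    blocks[[g]] <- alignmentBlock(seqs, gene = g, codonFramed = TRUE)
  }
  blocks
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Orchestrates extraction, composition, codon-usage indices, bias
#' diagnostics, per-gene divergence and supermatrix construction over a set
#' of annotated mitogenomes, writing paper-style TSV tables plus a run
#' manifest.  Reruns with identical inputs and options reproduce
#' byte-identical tables (numeric output fixed at 4 decimals).
#'
#' @param input a directory of GenBank flat files, a character vector of
#'   file paths, or a named list of \linkS4class{MitogenomeRecord}s.
#' @param outDir output directory (created).
#' @param codeId NCBI translation table id.
#' @param groupKey,groupSize high/low-bias grouping policy for the optimal
#'   codon analysis (see \code{\link{highLowGroups}}).
#' @param kaksAveraging see \code{\link{divergenceSummary}}.
#' @param pr2Mode see \code{\link{pr2}}.
#' @param datasets supermatrix datasets to emit.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the computed tables and the manifest.
#' @export
runPipeline <- function(input, outDir, codeId = "2",
                        groupKey = "ENC", groupSize = 3L,
                        kaksAveraging = "mean_of_ratios",
                        pr2Mode = "fourfold_only",
                        datasets = c("PCGs", "PCGs12"),
                        quiet = FALSE) {
  say <- function(...) if (!quiet) message("[mitocodon] ", ...)
  t0 <- Sys.time()
  if (is.character(input)) {
    paths <- if (length(input) == 1L && dir.exists(input))
      list.files(input, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
    else input
    if (!length(paths)) stop("no GenBank files found in input")
    say("parsing ", length(paths), " GenBank records")
    records <- lapply(paths, parseGenBank)
    names(records) <- vapply(records, taxon, character(1))
  } else {
    records <- input
    if (!length(records)) stop("no input records")
  }
  code <- geneticCode(codeId)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  biasDir <- file.path(outDir, "bias")
  if (!dir.exists(biasDir)) dir.create(biasDir)

  say("extracting and validating CDS")
  cdsByTaxon <- lapply(records, extractCDS, code = code)

  say("composition")
  compRows <- list()
  for (tx in names(records)) {
    compRows[[length(compRows) + 1L]] <- cbind(
      taxon = tx, baseComposition(genomeSeq(records[[tx]]),
                                  context = "whole_genome"))
    pcg <- paste(as.character(cdsByTaxon[[tx]]), collapse = "")
    compRows[[length(compRows) + 1L]] <- cbind(
      taxon = tx, baseComposition(pcg, context = "PCGs"))
    pos <- codonPositionComposition(as.character(cdsByTaxon[[tx]]), code)
    compRows[[length(compRows) + 1L]] <- cbind(taxon = tx, pos$positions)
  }
  composition <- do.call(rbind, compRows)
  .writeTsv(composition, file.path(outDir, "composition.tsv"))

  say("codon usage indices")
  pooledRef <- poolCounts(lapply(names(records), function(tx)
    countCodons(as.character(cdsByTaxon[[tx]]), code,
                context = "pooled", taxon = tx)),
    context = "all_taxa_PCGs")
  indices <- do.call(rbind, lapply(names(records), function(tx)
    usageIndices(cdsByTaxon[[tx]], code, taxon = tx,
                 reference = pooledRef)))
  .writeTsv(indices, file.path(outDir, "indices.tsv"))

  rscuTab <- do.call(rbind, lapply(names(records), function(tx) {
    r <- rscu(countCodons(as.character(cdsByTaxon[[tx]]), code,
                          context = "PCGs", taxon = tx))
    cbind(taxon = tx, r)
  }))
  .writeTsv(rscuTab, file.path(outDir, "rscu.tsv"))

  say("bias diagnostics")
  neut <- do.call(rbind, lapply(names(records), function(tx) {
    d <- indices[indices$taxon == tx, ]
    f <- neutralityFit(d$GC3, d$GC12, taxon = tx)
    data.frame(taxon = tx, slope = f$slope, intercept = f$intercept,
               R2 = f$R2, p_value = f$p_value, n_genes = f$n)
  }))
  .writeTsv(neut, file.path(biasDir, "neutrality.tsv"))

  encTab <- cbind(indices[, c("taxon", "gene", "ENC", "GC3s")],
                  ENC_expected = encExpected(indices$GC3s),
                  deviation = encDeviation(indices$ENC, indices$GC3s))
  .writeTsv(encTab, file.path(biasDir, "enc_gc3.tsv"))

  pr2Tab <- do.call(rbind, lapply(names(records), function(tx) {
    do.call(rbind, lapply(names(cdsByTaxon[[tx]]), function(g) {
      pt <- pr2(countCodons(as.character(cdsByTaxon[[tx]][[g]]), code,
                            context = g, taxon = tx), mode = pr2Mode)
      data.frame(taxon = tx, gene = g, x = pt$x, y = pt$y,
                 quadrant = pt$quadrant, stringsAsFactors = FALSE)
    }))
  }))
  .writeTsv(pr2Tab, file.path(biasDir, "pr2.tsv"))

  classTab <- do.call(rbind, lapply(names(records), function(tx) {
    d <- indices[indices$taxon == tx, ]
    grp <- highLowGroups(d, key = groupKey, groupSize = groupSize)
    mk <- function(genes) countCodons(
      as.character(cdsByTaxon[[tx]][genes]), code,
      context = paste(genes, collapse = "+"), taxon = tx)
    cls <- classifyCodons(
      rscu(mk(d$gene)), rscu(mk(grp$high)), rscu(mk(grp$low)))
    cbind(taxon = tx, high_group = paste(grp$high, collapse = ","),
          low_group = paste(grp$low, collapse = ","), cls)
  }))
  .writeTsv(classTab, file.path(biasDir, "codon_classes.tsv"))

  say("divergence statistics")
  blocks <- .cdsBlocks(cdsByTaxon, code)
  divergence <- divergenceSummary(blocks, code,
                                  kaksAveraging = kaksAveraging)
  .writeTsv(divergence, file.path(outDir, "divergence.tsv"))

  say("supermatrices")
  smFiles <- character(0)
  for (ds in datasets) {
    sm <- buildSupermatrix(blocks, dataset = ds)
    base <- file.path(outDir, paste0("supermatrix_", ds))
    writePhylip(sm, paste0(base, ".phy"))
    writeNexus(sm, paste0(base, ".nex"))
    .writeTsv(sm$partitions, paste0(base, ".partitions.tsv"))
    smFiles <- c(smFiles, paste0(base, c(".phy", ".nex")))
  }

  cfg <- list(codeId = codeId, groupKey = groupKey,
              groupSize = as.integer(groupSize),
              kaksAveraging = kaksAveraging, pr2Mode = pr2Mode,
              datasets = datasets,
              taxa = names(records),
              accessions = vapply(records, accession, character(1)))
  tmp <- tempfile()
  saveRDS(cfg, tmp)
  manifest <- list(
    package = "mitocodon",
    version = as.character(utils::packageVersion("mitocodon")),
    config = cfg,
    config_hash = unname(tools::md5sum(tmp)),
    outputs = list.files(outDir, recursive = TRUE))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done in ", round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        1), "s")
  invisible(list(records = records, composition = composition,
                 indices = indices, rscu = rscuTab, neutrality = neut,
                 encPlot = encTab, pr2 = pr2Tab, codonClasses = classTab,
                 divergence = divergence, manifest = manifest))
}
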