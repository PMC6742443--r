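## End-to-end orchestration: map -> stoichiometry -> blocks -> isoform
## enumeration and scoring, with optional junction re-assembly and repeat
## scan, writing standard artifacts plus a machine-readable JSON report.

#' Run the isoform-inference pipeline
#'
#' Executes the full analysis on a set of primary units and long reads:
#' tiling and reverse read mapping, informative-read selection, unit paths,
#' coverage-based copy-number classification, secondary building blocks,
#' junction-graph construction, isoform enumeration and frequency scoring,
#' the junction-fragment abundance table, and a repeat scan of the units.
#' All parameters default to the values the method was designed around
#' (2 kb / 1 kb path tiling, 2 kb / 0.5 kb coverage tiling, 1.8 kb / 80\%
#' identity acceptance, 10 distinct fragments).
#'
#' @param unitSeqs named character vector or \code{DNAStringSet} of primary
#'   units.
#' @param reads long reads (\code{DNAStringSet}).
#' @param outdir optional output directory for TSV/FASTA/JSON artifacts.
#' @param window,step path tiling geometry.
#' @param covWindow,covStep coverage tiling geometry.
#' @param minDistinct informative-read threshold.
#' @param minIdentity alignment identity threshold.
#' @param minBlockSupport building-block support threshold.
#' @param scanRepeats run \code{\link{findRepeats}} on the units.
#' @param seed seed recorded in the report (mapping is deterministic).
#' @return list (class \code{PipelineReport}) with \code{parameters},
#'   \code{copyNumbers}, \code{coverage}, \code{informativeReads},
#'   \code{paths}, \code{blocks}, \code{isoforms}, \code{frequencies},
#'   \code{junctions}, and \code{repeats}.
#' @export
runPipeline <- function(unitSeqs, reads, outdir = NULL,
                        window = 2000L, step = 1000L,
                        covWindow = 2000L, covStep = 500L,
                        minDistinct = 10L, minIdentity = 0.8,
                        minBlockSupport = 2L, scanRepeats = TRUE,
                        seed = 1L) {
  unitSeqs <- setNames(as.character(unitSeqs), names(unitSeqs))
  params <- list(window = window, step = step, covWindow = covWindow,
                 covStep = covStep, minDistinct = minDistinct,
                 minIdentity = minIdentity,
                 minBlockSupport = minBlockSupport, seed = seed,
                 nUnits = length(unitSeqs), nReads = length(reads))

  tiling <- makeTiling(unitSeqs, window = window, step = step)
  hits <- mapTilingToReads(tiling, reads, minIdentity = minIdentity)
  informative <- selectInformativeReads(hits, minDistinct)
  hitsInf <- hits[hits$readId %in% informative, , drop = FALSE]
  paths <- unitPaths(hitsInf, tiling, window = window, step = step)

  readsInf <- reads[informative]
  coverage <- unitCoverage(unitSeqs, readsInf, window = covWindow,
                           step = covStep, minIdentity = minIdentity)
  cnTable <- classifyCopyNumber(coverage)
  cn <- setNames(cnTable$copyNumber, cnTable$unit)

  blocks <- buildingBlocks(paths, cn, minSupport = minBlockSupport)
  graph <- buildJunctionGraph(blocks, cn,
                              unitLengths = nchar(unitSeqs))
  isoforms <- enumerateIsoforms(graph)
  freqs <- NULL
  if (length(isoforms) >= 2L) {
    sc <- scoreIsoforms(isoforms, blocks, copyNumbers = cn)
    freqs <- sc$frequencies
  } else if (length(isoforms) == 1L) {
    freqs <- setNames(1, isoforms[[1]]@label)
  }

  pairBlocks <- blocks[blocks$length == 2L, , drop = FALSE]
  junctions <- NULL
  if (nrow(pairBlocks)) {
    jl <- junctionLibrary(unitSeqs, pairBlocks$block)
    junctions <- junctionAbundance(jl, readsInf,
                                   minIdentity = minIdentity)$summary
  }
  repeats <- if (scanRepeats) findRepeats(unitSeqs) else NULL

  report <- structure(list(
    parameters = params, coverage = coverage, copyNumbers = cnTable,
    informativeReads = informative, paths = paths, blocks = blocks,
    isoforms = isoforms, frequencies = freqs, junctions = junctions,
    repeats = repeats), class = "PipelineReport")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeHitTable(hitsInf, file.path(outdir, "hits.tsv"))
    write.table(paths, file.path(outdir, "unit_paths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(coverage, file.path(outdir, "coverage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cnTable, file.path(outdir, "copy_numbers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(blocks, file.path(outdir, "blocks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(junctions))
      write.table(junctions, file.path(outdir, "junctions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(repeats))
      write.table(repeats, file.path(outdir, "repeats.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (length(isoforms)) {
      writeIsoformReport(isoforms, freqs, unitSeqs, outdir)
    }
    jsonlite::write_json(
      list(parameters = params,
           copyNumbers = setNames(as.list(cnTable$copyNumber), cnTable$unit),
           nInformativeReads = length(informative),
           blocks = blocks,
           isoforms = lapply(isoforms, function(i) list(
             label = i@label,
             arrangement = paste(i@arrangement, collapse = ","),
             length = totalLength(i))),
           frequencies = as.list(freqs)),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport\n")
  cat("  informative reads:", length(x$informativeReads), "\n")
  cat("  copy numbers:",
      paste(sprintf("%s=%d", x$copyNumbers$unit, x$copyNumbers$copyNumber),
            collapse = " "), "\n")
  cat("  blocks:", nrow(x$blocks), " isoforms:", length(x$isoforms), "\n")
  if (!is.null(x$frequencies))
    cat("  frequencies:",
        paste(sprintf("%s=%.3f", names(x$frequencies), x$frequencies),
              collapse = " "), "\n")
  invisible(x)
}

#' Write isoform FASTA, TSV and annotation tracks
#'
#' Emits the arrangement table (label, arrangement, length, frequency), one
#' FASTA sequence per isoform (built from the unit sequences), a BED file of
#' unit coordinates (0-based half-open) and a GFF3 file (1-based inclusive,
#' stated in the header).
#'
#' @param isoforms list of \code{\link{IsoformModel}}s.
#' @param frequencies named numeric vector (optional).
#' @param unitSeqs named unit sequences.
#' @param outdir output directory.
#' @export
writeIsoformReport <- function(isoforms, frequencies = NULL, unitSeqs,
                               outdir) {
  units <- setNames(as.character(unitSeqs), names(unitSeqs))
  labels <- vapply(isoforms, function(i) i@label, character(1))
  tsv <- data.frame(
    label = labels,
    arrangement = vapply(isoforms, function(i)
      paste(i@arrangement, collapse = ","), character(1)),
    length = vapply(isoforms, totalLength, numeric(1)),
    frequency = if (is.null(frequencies)) NA_real_
                else unname(frequencies[labels]))
  write.table(tsv, file.path(outdir, "isoforms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seqs <- vapply(isoforms, function(iso) {
    paste(vapply(seq_along(iso@arrangement), function(j) {
      tok <- iso@arrangement[j]
      s <- units[[.tokenUnit(tok)]]
      if (.tokenStrand(tok) == "-") .revcompChr(s) else s
    }, character(1)), collapse = "")
  }, character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- labels
  Biostrings::writeXStringSet(ss, file.path(outdir, "isoforms.fasta"),
                              width = 60L)
  bed <- gff <- list()
  for (iso in isoforms) {
    uc <- isoformUnitCoords(iso)
    bed[[iso@label]] <- data.frame(chrom = iso@label, start = uc$start,
                                   end = uc$end, name = uc$unit, score = 0,
                                   strand = uc$strand)
    gff[[iso@label]] <- data.frame(
      seqid = iso@label, source = "mitoforms", type = "region",
      start = uc$start + 1L, end = uc$end, score = ".",
      strand = uc$strand, phase = ".",
      attributes = paste0("ID=", uc$unit))
  }
  bed <- do.call(rbind, bed)
  write.table(bed, file.path(outdir, "isoform_units.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  gffFile <- file.path(outdir, "isoform_units.gff3")
  writeLines(c("##gff-version 3",
               "# coordinates are 1-based inclusive"), gffFile)
  suppressWarnings(
    write.table(do.call(rbind, gff), gffFile, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, append = TRUE))
  invisible(tsv)
}
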