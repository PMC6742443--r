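## Two-dimensional distance matrices from mate pairs and Hi-C split reads,
## and detection of minor recombinant isoforms from their off-diagonal
## signatures.

#' DistanceMatrix: binned 2D counts of intra-molecule pair distances
#'
#' @slot reference reference isoform id.
#' @slot binSize bin size in bp (1000 by default).
#' @slot counts square symmetric count matrix over reference bins; each pair
#'   increments (i, j) and (j, i), so the matrix sums to twice the pair
#'   count.
#' @slot totalPairs number of pairs binned.
#' @slot refLength reference length (bp).
#' @slot circular logical.
#' @export
setClass("DistanceMatrix",
         representation(reference = "character", binSize = "numeric",
                        counts = "matrix", totalPairs = "numeric",
                        refLength = "numeric", circular = "logical"))

setValidity("DistanceMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("count matrix must be square")
  if (!isTRUE(all.equal(m, t(m)))) return("count matrix must be symmetric")
  if (sum(m) != 2 * object@totalPairs)
    return("matrix total must equal twice the pair count")
  TRUE
})

#' @export
setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix on", object@reference, "\n")
  cat(sprintf("  %d x %d bins of %d bp; %d pairs\n",
              nrow(object@counts), ncol(object@counts),
              as.integer(object@binSize), as.integer(object@totalPairs)))
})

#' @describeIn pairDistanceMatrix bin count matrix accessor
#' @param x a \code{DistanceMatrix}.
#' @export
binCounts <- function(x) x@counts

#' Map short-read pairs onto a reference
#'
#' Both mates are placed by exact-seed search plus substitution-only
#' verification (the doubled sequence handles circular wrap-around).  A
#' mate is unique when no second placement scores within 5 mismatches of
#' the best; restricting to unique pairs mirrors the treatment of
#' short-repeat analyses where multi-mapping is ambiguous.
#'
#' @param read1,read2 \code{DNAStringSet}s of mates (parallel).
#' @param reference reference sequence (character or \code{DNAString}).
#' @param circular treat the reference as circular (default TRUE).
#' @param uniqueOnly drop pairs with a multi-mapping mate (default FALSE).
#' @param maxMismatch per-mate mismatch budget (default 6).
#' @param k seed size.
#' @return data.frame with leftmost 0-based \code{pos1}, \code{pos2},
#'   \code{mapped}, \code{unique} per pair (unmapped/dropped pairs removed).
#' @export
mapShortReadPairs <- function(read1, read2, reference, circular = TRUE,
                              uniqueOnly = FALSE, maxMismatch = 6L, k = 15L) {
  ref <- as.character(reference)
  L <- nchar(ref)
  ext <- if (circular) paste0(ref, substr(ref, 1L, min(L, 500L))) else ref
  m1 <- cpp_map_short_reads(as.character(read1), ext, L, k = k,
                            maxMismatch = maxMismatch)
  m2 <- cpp_map_short_reads(as.character(read2), ext, L, k = k,
                            maxMismatch = maxMismatch)
  ok <- m1$mapped & m2$mapped
  if (uniqueOnly) ok <- ok & m1$unique & m2$unique
  data.frame(pos1 = m1$pos[ok], pos2 = m2$pos[ok],
             unique = (m1$unique & m2$unique)[ok],
             stringsAsFactors = FALSE)
}

#' Build a 2D pair-distance matrix
#'
#' Distances are computed from the leftmost mapped coordinates (the shorter
#' arc on circular references); pairs at 1 kb or less are excluded, a
#' uniform random subsample of the requested size is taken (all pairs when
#' fewer), and counts are binned symmetrically.
#'
#' @param pairs data.frame with \code{pos1}, \code{pos2} (0-based leftmost
#'   coordinates), e.g. from \code{\link{mapShortReadPairs}}.
#' @param refLength reference length (bp).
#' @param binSize bin size (default 1000 bp).
#' @param minDistance distance filter (default 1000 bp, exclusive).
#' @param subsample subsample size (default 320000; use \code{Inf} for all).
#' @param seed RNG seed for the subsample.
#' @param circular shorter-arc distances (default TRUE).
#' @param reference reference label.
#' @return a \code{\link{DistanceMatrix}}.
#' @export
pairDistanceMatrix <- function(pairs, refLength, binSize = 1000L,
                               minDistance = 1000L, subsample = 320000L,
                               seed = 1L, circular = TRUE,
                               reference = "ref") {
  if (refLength < binSize)
    stop("reference shorter than one bin")
  d <- abs(pairs$pos1 - pairs$pos2)
  if (circular) d <- pmin(d, refLength - d)
  keep <- d > minDistance
  p1 <- pairs$pos1[keep]; p2 <- pairs$pos2[keep]
  n <- length(p1)
  if (is.finite(subsample) && n > subsample) {
    set.seed(.substream(seed, .SEED_SUBSAMPLE))
    i <- sample.int(n, subsample)
    p1 <- p1[i]; p2 <- p2[i]
    n <- subsample
  }
  nb <- as.integer(ceiling(refLength / binSize))
  b1 <- pmin(as.integer(p1 %/% binSize) + 1L, nb)
  b2 <- pmin(as.integer(p2 %/% binSize) + 1L, nb)
  m <- matrix(tabulate((b2 - 1L) * nb + b1, nb * nb) +
              tabulate((b1 - 1L) * nb + b2, nb * nb), nb, nb)
  new("DistanceMatrix", reference = reference, binSize = as.numeric(binSize),
      counts = m, totalPairs = as.numeric(n),
      refLength = as.numeric(refLength), circular = circular)
}

#' Write a distance matrix as sparse TSV (bin_i, bin_j, count)
#'
#' @param mat a \code{\link{DistanceMatrix}}.
#' @param file output path.
#' @export
writeDistanceMatrix <- function(mat, file) {
  m <- mat@counts
  idx <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   count = m[idx])
  df <- df[order(df$bin_i, df$bin_j), ]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Plot a distance matrix
#'
#' Simple heat-map of log-scaled bin counts.
#'
#' @param mat a \code{\link{DistanceMatrix}}.
#' @param main title.
#' @export
plotDistanceMatrix <- function(mat, main = mat@reference) {
  m <- log1p(mat@counts)
  graphics::image(seq_len(nrow(m)) - 0.5, seq_len(ncol(m)) - 0.5, m,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = sprintf("bin (%d bp)", as.integer(mat@binSize)),
                  ylab = "bin", main = main, useRaster = TRUE)
}

## ---------------------------------------------------------------------------
## Hi-C split reads

#' Split Hi-C reads at the GATC-GATC ligation scar
#'
#' Reads containing the "GATCGATC" dimer are split at its midpoint, each
#' sub-read retaining one GATC; a read with k dimers yields k consecutive
#' sub-read pairs.  Reads without the dimer are discarded.  Downstream the
#' pairs are treated exactly like mate pairs (subsample default 640,000).
#'
#' @param reads \code{DNAStringSet} or character vector.
#' @return list with \code{read1}, \code{read2} (\code{DNAStringSet}) and
#'   \code{fromRead} (source read ids).
#' @examples
#' splitHiCReads(c(r1 = "AAGATCGATCTT"))   # "AAGATC" / "GATCTT"
#' @export
splitHiCReads <- function(reads) {
  ids <- names(reads)
  rs <- as.character(reads)
  if (is.null(ids)) ids <- sprintf("hic%06d", seq_along(rs))
  r1 <- r2 <- from <- character(0)
  for (i in seq_along(rs)) {
    hits <- gregexpr("GATCGATC", rs[i], fixed = TRUE)[[1]]
    if (hits[1] < 0) next
    cuts <- as.integer(hits) + 3L         # last base of the left GATC
    bounds <- c(0L, cuts, nchar(rs[i]))
    subs <- substring(rs[i], head(bounds, -1L) + 1L, bounds[-1L])
    for (j in seq_len(length(subs) - 1L)) {
      r1 <- c(r1, subs[j]); r2 <- c(r2, subs[j + 1L])
      from <- c(from, ids[i])
    }
  }
  list(read1 = Biostrings::DNAStringSet(r1),
       read2 = Biostrings::DNAStringSet(r2),
       fromRead = from)
}

## ---------------------------------------------------------------------------
## Minor-isoform detection

## pairs supporting a junction: left read end within [qLeft - span, qLeft],
## right read start in the matching window beyond qRight + repeatLength,
## with flank distances summing to insert - readLength
.junctionSpanCount <- function(mat, qLeft, qRight, repeatLength,
                               insertMean, insertSd, readLength,
                               nSigma = 3) {
  bin <- mat@binSize
  nb <- nrow(mat@counts)
  tTarget <- insertMean - readLength - repeatLength
  tol <- nSigma * insertSd + 2 * bin
  span <- insertMean + tol
  iRange <- floor((qLeft - span) / bin):floor((qLeft - readLength) / bin)
  jRange <- floor((qRight + repeatLength) / bin):
            floor((qRight + repeatLength + span) / bin)
  iRange <- iRange[iRange >= 0 & iRange < nb]
  jRange <- jRange[jRange >= 0 & jRange < nb]
  total <- 0
  for (bi in iRange) {
    x <- (bi + 0.5) * bin
    for (bj in jRange) {
      y <- (bj + 0.5) * bin
      t <- (qLeft - x) + (y - qRight - repeatLength)
      if (abs(t - tTarget) <= tol)
        total <- total + mat@counts[bi + 1L, bj + 1L]
    }
  }
  total
}

#' Detect a minor recombinant isoform from off-diagonal mate-pair signal
#'
#' For a dispersed repeat with copies at \code{p1} and \code{p2} on the
#' reference, crossover molecules place one read upstream of one copy and
#' its mate downstream of the other, producing short diagonals displaced
#' from the main diagonal.  The recombination frequency is estimated as the
#' off-diagonal mask count over the sum of mask and matched-geometry
#' main-diagonal counts at the two junctions, pooled over libraries.
#'
#' @param matrices a \code{\link{DistanceMatrix}} or list of them (one per
#'   insert-size library), built from unique mappings.
#' @param p1,p2 0-based start positions of the repeat copies (p1 < p2).
#' @param repeatLength repeat length (bp).
#' @param insertMean,insertSd insert size mean(s) and SD(s), parallel to
#'   \code{matrices}.
#' @param readLength mate read length (default 100).
#' @return object of class \code{RecombSignature}: list with \code{p1},
#'   \code{p2}, \code{repeatLength}, \code{maskCount}, \code{diagCount},
#'   \code{frequency} (fraction in [0, 1]) and \code{flag}
#'   (\code{"ok"} or \code{"unestimable"} when the mask would overlap the
#'   main diagonal).
#' @export
detectRecombination <- function(matrices, p1, p2, repeatLength,
                                insertMean, insertSd, readLength = 100L) {
  if (is(matrices, "DistanceMatrix")) matrices <- list(matrices)
  stopifnot(p1 < p2)
  nLib <- length(matrices)
  insertMean <- rep_len(insertMean, nLib)
  insertSd <- rep_len(insertSd, nLib)
  maskCount <- diagCount <- 0
  flag <- "ok"
  for (li in seq_len(nLib)) {
    mat <- matrices[[li]]
    if ((p2 - p1) < insertMean[li] + 3 * insertSd[li] + 2 * mat@binSize) {
      flag <- "unestimable"
      next
    }
    ## off-diagonal bands: the two crossover junctions
    maskCount <- maskCount +
      .junctionSpanCount(mat, p1, p2, repeatLength, insertMean[li],
                         insertSd[li], readLength) +
      .junctionSpanCount(mat, p2, p1, repeatLength, insertMean[li],
                         insertSd[li], readLength)
    ## matched-geometry reference: the parental junctions at each copy
    diagCount <- diagCount +
      .junctionSpanCount(mat, p1, p1, repeatLength, insertMean[li],
                         insertSd[li], readLength) +
      .junctionSpanCount(mat, p2, p2, repeatLength, insertMean[li],
                         insertSd[li], readLength)
  }
  freq <- if (maskCount + diagCount > 0) maskCount / (maskCount + diagCount)
          else NA_real_
  structure(list(p1 = p1, p2 = p2, repeatLength = repeatLength,
                 maskCount = maskCount, diagCount = diagCount,
                 frequency = freq, flag = flag),
            class = "RecombSignature")
}

#' @export
print.RecombSignature <- function(x, ...) {
  cat(sprintf(
    "RecombSignature: repeat %d bp at %d / %d; mask %d, diagonal %d\n",
    x$repeatLength, x$p1, x$p2, as.integer(x$maskCount),
    as.integer(x$diagCount)))
  if (x$flag == "ok")
    cat(sprintf("  estimated recombination frequency: %.2f%%\n",
                100 * x$frequency))
  else cat("  flag:", x$flag, "\n")
  invisible(x)
}
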