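## Copy-number estimation from tiling coverage and junction abundance
## quantification via breakpoint analysis of sorted alignment lengths.

#' Per-fragment long-read coverage of the primary units
#'
#' Tiles each unit with a 2 kb window at 0.5 kb step and counts, per
#' fragment, the reads carrying an alignment at least \code{minAln} bp long
#' at \code{minIdentity} or better.  Because all dispersed medium-size
#' repeats are shorter than the 1.8 kb acceptance length, alignments arising
#' from repeated sequence alone do not contribute counts.
#'
#' @param unitSeqs named character vector or \code{DNAStringSet}.
#' @param reads informative long reads (\code{DNAStringSet}).
#' @param window,step coverage tiling geometry (defaults 2000 / 500).
#' @param minAln minimum accepted alignment length (default 1800 bp).
#' @param minIdentity minimum identity (default 0.8).
#' @param maxInternalGap longest tolerated gap inside an accepted alignment.
#' @param ... further arguments to \code{\link{mapTilingToReads}}.
#' @return data.frame with \code{unit}, \code{index}, \code{start},
#'   \code{end}, \code{count} (one row per coverage fragment).
#' @export
unitCoverage <- function(unitSeqs, reads, window = 2000L, step = 500L,
                         minAln = 1800L, minIdentity = 0.8,
                         maxInternalGap = 50L, ...) {
  if (length(reads) == 0L) stop("informative read set is empty")
  tiling <- makeTiling(unitSeqs, window = window, step = step)
  hits <- mapTilingToReads(tiling, reads, minIdentity = minIdentity,
                           minLen = min(minAln, window) - 100L, ...)
  ok <- hits$alnLen >= pmin(minAln, tiling$end[match(hits$fragId, tiling$fragId)] -
                              tiling$start[match(hits$fragId, tiling$fragId)] - 100L) &
        hits$identity >= minIdentity & hits$maxGap <= maxInternalGap
  counts <- table(factor(hits$fragId[ok], levels = tiling$fragId))
  data.frame(unit = tiling$unit, index = tiling$index,
             start = tiling$start, end = tiling$end,
             count = as.integer(counts), stringsAsFactors = FALSE)
}

#' Mean interior coverage per unit
#'
#' Excludes the first and last two fragments of each unit (the terminal
#' coverage dip) whenever at least five fragments are available.
#'
#' @param coverage data.frame from \code{\link{unitCoverage}}.
#' @return named numeric vector of per-unit interior means.
#' @export
interiorCoverage <- function(coverage) {
  vapply(split(coverage, coverage$unit), function(d) {
    d <- d[order(d$index), ]
    if (nrow(d) >= 5L) d <- d[3:(nrow(d) - 2L), ]
    mean(d$count)
  }, numeric(1))
}

#' Classify unit copy numbers from coverage ratios
#'
#' Divides each unit's mean interior coverage by an iteratively re-estimated
#' single-copy baseline (median over units currently classified 1x) and
#' rounds the ratio.  Units whose ratio sits more than \code{flagTol} from
#' the nearest integer are flagged rather than silently rounded:
#' frequency-weighted sub-stoichiometric repeats surface this way.
#'
#' @param coverage data.frame from \code{\link{unitCoverage}} (or a named
#'   numeric vector of per-unit mean coverages).
#' @param flagTol flagging distance from the nearest integer (default 0.25).
#' @param maxIter baseline re-estimation iterations.
#' @return data.frame with \code{unit}, \code{meanCoverage}, \code{ratio},
#'   \code{copyNumber}, \code{flagged}.
#' @export
classifyCopyNumber <- function(coverage, flagTol = 0.25, maxIter = 10L) {
  means <- if (is.data.frame(coverage)) interiorCoverage(coverage)
           else coverage
  if (length(means) < 2L) {
    return(data.frame(unit = names(means), meanCoverage = unname(means),
                      ratio = 1, copyNumber = 1L, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  base <- median(means)
  for (it in seq_len(maxIter)) {
    cn <- pmax(1L, as.integer(round(means / base)))
    newBase <- if (any(cn == 1L)) median(means[cn == 1L])
               else median(means / cn)
    if (abs(newBase - base) < 1e-9) break
    base <- newBase
  }
  ratio <- means / base
  cn <- pmax(1L, as.integer(round(ratio)))
  flagged <- abs(ratio - cn) > flagTol
  if (all(flagged))
    stop("no stable single-copy baseline: all units deviate from integer ",
         "coverage ratios")
  data.frame(unit = names(means), meanCoverage = unname(means),
             ratio = unname(ratio), copyNumber = unname(cn),
             flagged = unname(flagged), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Junction library and abundance

.flankSeq <- function(units, token, side, flank) {
  u <- .tokenUnit(token); s <- .tokenStrand(token)
  seq <- units[[u]]
  L <- nchar(seq)
  fl <- min(flank, L)
  ## side "out" = the end of the oriented unit (its 3' terminus),
  ## side "in"  = the start of the oriented unit (its 5' terminus)
  fwdTail <- substr(seq, L - fl + 1L, L)
  fwdHead <- substr(seq, 1L, fl)
  if (s == "+") {
    if (side == "out") fwdTail else fwdHead
  } else {
    if (side == "out") .revcompChr(fwdHead) else .revcompChr(fwdTail)
  }
}

#' Build the junction-spanning fragment library
#'
#' One fragment per distinct oriented junction: \code{flank} bp of sequence
#' from the 3' terminus of the left oriented unit followed by \code{flank}
#' bp from the 5' terminus of the right unit (2 kb total by default).
#' Reverse-complement duplicate junctions are merged; when a unit is shorter
#' than the flank, its full length is used and the actual flank recorded.
#'
#' @param unitSeqs named character vector or \code{DNAStringSet}.
#' @param junctions data.frame with token columns \code{left}, \code{right},
#'   or a character vector of comma-joined pairs ("W+,Z+").
#' @param flank flank size in bp (default 1000).
#' @return data.frame with \code{junctionId}, \code{left}, \code{right},
#'   \code{leftFlank}, \code{rightFlank}, \code{seq}.
#' @export
junctionLibrary <- function(unitSeqs, junctions, flank = 1000L) {
  units <- as.list(setNames(as.character(unitSeqs), names(unitSeqs)))
  if (is.character(junctions)) {
    tk <- strsplit(junctions, ",", fixed = TRUE)
    junctions <- data.frame(left = vapply(tk, `[`, character(1), 1L),
                            right = vapply(tk, `[`, character(1), 2L),
                            stringsAsFactors = FALSE)
  }
  seen <- character(0)
  out <- list()
  for (i in seq_len(nrow(junctions))) {
    l <- junctions$left[i]; r <- junctions$right[i]
    canon <- .minByKey(c(l, r), reverseArrangement(c(l, r)))
    key <- .arrKey(canon)
    if (key %in% seen) next
    seen <- c(seen, key)
    l <- canon[1]; r <- canon[2]
    lf <- min(flank, nchar(units[[.tokenUnit(l)]]))
    rf <- min(flank, nchar(units[[.tokenUnit(r)]]))
    out[[key]] <- data.frame(
      junctionId = paste0(l, "|", r), left = l, right = r,
      leftFlank = lf, rightFlank = rf,
      seq = paste0(.flankSeq(units, l, "out", flank),
                   .flankSeq(units, r, "in", flank)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify junction abundance by breakpoint analysis
#'
#' Aligns every junction fragment to every read and counts, per junction,
#' the reads carrying one uninterrupted alignment (a single chained
#' alignment of at least \code{minUninterrupted} bp with no internal gap
#' longer than \code{maxInternalGap}).  Fragmented alignments, arising from
#' reads that carry the junction components in other arrangements, fall
#' below the threshold; the transition from complete to segmented alignments
#' in the sorted length vector (the breakpoint) reflects each junction's
#' share of the molecule pool.
#'
#' @param junctionLib data.frame from \code{\link{junctionLibrary}}.
#' @param reads informative long reads.
#' @param minUninterrupted acceptance length (default 1800 bp; fragments
#'   shorter than 2 kb are accepted at their length minus 200 bp).
#' @param minIdentity minimum identity (default 0.8).
#' @param maxInternalGap longest gap tolerated inside an uninterrupted
#'   alignment (default 50 bp).
#' @param ... further arguments to \code{\link{mapTilingToReads}}.
#' @return list with \code{summary} (data.frame: \code{junctionId},
#'   \code{support}, \code{poolFraction}, \code{breakpointIndex}) and
#'   \code{curves} (named list of sorted alignment-length vectors, longest
#'   first).
#' @export
junctionAbundance <- function(junctionLib, reads, minUninterrupted = 1800L,
                              minIdentity = 0.8, maxInternalGap = 50L, ...) {
  frags <- data.frame(fragId = junctionLib$junctionId,
                      unit = junctionLib$junctionId,
                      index = seq_len(nrow(junctionLib)) - 1L,
                      start = 0L, end = nchar(junctionLib$seq),
                      seq = junctionLib$seq, stringsAsFactors = FALSE)
  hits <- mapTilingToReads(frags, reads, minIdentity = minIdentity,
                           minLen = 300L, ...)
  nReads <- length(reads)
  curves <- list()
  support <- integer(nrow(junctionLib))
  for (i in seq_len(nrow(junctionLib))) {
    jid <- junctionLib$junctionId[i]
    thr <- min(minUninterrupted, nchar(junctionLib$seq[i]) - 200L)
    h <- hits[hits$fragId == jid, , drop = FALSE]
    if (nrow(h)) {
      ## best alignment per read; gap-broken alignments do not qualify
      eff <- ifelse(h$maxGap <= maxInternalGap, h$alnLen, pmin(h$alnLen, thr - 1L))
      best <- tapply(eff, h$readId, max)
      lens <- sort(as.integer(best), decreasing = TRUE)
    } else lens <- integer(0)
    curves[[jid]] <- lens
    support[i] <- sum(lens >= thr)
  }
  list(summary = data.frame(junctionId = junctionLib$junctionId,
                            support = support,
                            poolFraction = support / max(1L, nReads),
                            breakpointIndex = support,
                            stringsAsFactors = FALSE),
       curves = curves)
}

#' Breakpoint in a sorted alignment-length vector
#'
#' @param lengths alignment lengths (any order).
#' @param threshold uninterrupted-alignment threshold (default 1800).
#' @return list with \code{support} (number of alignments at or above the
#'   threshold) and \code{breakpointIndex} (index of the transition in the
#'   descending-sorted vector).
#' @examples
#' alignmentBreakpoint(c(2000, 2000, 1900, 1200, 800))  # support 3
#' @export
alignmentBreakpoint <- function(lengths, threshold = 1800L) {
  lens <- sort(lengths, decreasing = TRUE)
  s <- sum(lens >= threshold)
  list(support = s, breakpointIndex = s, sorted = lens)
}
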