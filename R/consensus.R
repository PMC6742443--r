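## Junction re-assembly from trimmed long reads and short-read majority
## polishing, both via draft-anchored column voting.

#' Trim junction-supporting reads to a window around the junction
#'
#' For every read whose unit path contains the junction (in either
#' traversal direction), extracts up to \code{flank} bp on each side of the
#' junction offset, clipped at read ends; segments shorter than
#' \code{minTotal} bp are discarded.
#'
#' @param reads long reads (\code{DNAStringSet}).
#' @param paths data.frame from \code{\link{unitPaths}}.
#' @param junction length-2 token vector, e.g. \code{c("W+", "Z+")}.
#' @param flank bases kept on each side (default 3000, i.e. 4-6 kb windows).
#' @param minTotal minimum segment length kept (default 1000).
#' @return list with \code{junction}, \code{segments} (\code{DNAStringSet}
#'   named by read id); zero segments produces a warning.
#' @export
trimJunctionReads <- function(reads, paths, junction, flank = 3000L,
                              minTotal = 1000L) {
  .checkTokens(junction)
  stopifnot(length(junction) == 2L)
  rcJunction <- reverseArrangement(junction)
  toks <- pathTokens(paths)
  offList <- strsplit(paths$offsets[!paths$ambiguous], ",", fixed = TRUE)
  segs <- character(0)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    off <- as.integer(offList[[i]])
    rid <- names(toks)[i]
    if (!(rid %in% names(reads))) next
    rseq <- as.character(reads[[rid]])
    L <- nchar(rseq)
    for (j in seq_len(length(tk) - 1L)) {
      pair <- c(tk[j], tk[j + 1L])
      hitFwd <- identical(pair, junction)
      hitRev <- identical(pair, rcJunction)
      if (!hitFwd && !hitRev) next
      ## junction position ~ start of the second run
      pos <- off[j + 1L]
      lo <- max(0L, pos - flank)
      hi <- min(L, pos + flank)
      if (hi - lo < minTotal) next
      segs[paste0(rid, ".", j)] <- substr(rseq, lo + 1L, hi)
    }
  }
  if (!length(segs))
    warning("no reads support junction ", paste(junction, collapse = ","))
  list(junction = junction,
       segments = Biostrings::DNAStringSet(segs))
}

.voteConsensus <- function(draft, pile, minDepth, applyIndels = TRUE,
                           indelFraction = 0.5) {
  L <- nchar(draft)
  bases <- c("A", "C", "G", "T", "-")
  cm <- pile$counts
  depth <- pile$depth
  draftCh <- strsplit(draft, "", fixed = TRUE)[[1]]
  outCh <- draftCh
  changes <- list()
  for (p in seq_len(L)) {
    if (depth[p] < minDepth) next
    cnt <- cm[, p]
    best <- max(cnt)
    winners <- bases[cnt == best]
    dIdx <- match(draftCh[p], bases)
    draftCount <- if (!is.na(dIdx)) cnt[dIdx] else -1L
    if (draftCount == best) next          # ties keep the draft base
    if (best <= depth[p] / 2) next        # require a strict majority
    w <- winners[1]
    if (w == "-") {
      if (!applyIndels) next
      changes[[length(changes) + 1L]] <- data.frame(
        position = p - 1L, type = "del", before = draftCh[p], after = "",
        depth = depth[p], support = best, stringsAsFactors = FALSE)
      outCh[p] <- ""
    } else {
      changes[[length(changes) + 1L]] <- data.frame(
        position = p - 1L, type = "sub", before = draftCh[p], after = w,
        depth = depth[p], support = best, stringsAsFactors = FALSE)
      outCh[p] <- w
    }
  }
  if (applyIndels && length(pile$insPos)) {
    for (ii in seq_along(pile$insPos)) {
      p <- pile$insPos[ii]                 # insertion before column p (0-based)
      localDepth <- if (p >= 1 && p <= L) depth[p]
                    else if (p > L) depth[L] else depth[1]
      if (localDepth < minDepth) next
      if (pile$insCount[ii] <= indelFraction * localDepth) next
      ## insertion before 0-based column p => before outCh[p + 1]
      if (p < L) outCh[p + 1L] <- paste0(pile$insSeq[ii], outCh[p + 1L])
      else outCh[L] <- paste0(outCh[L], pile$insSeq[ii])
      changes[[length(changes) + 1L]] <- data.frame(
        position = p, type = "ins", before = "", after = pile$insSeq[ii],
        depth = localDepth, support = pile$insCount[ii],
        stringsAsFactors = FALSE)
    }
  }
  list(seq = paste(outCh, collapse = ""),
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(position = integer(0), type = character(0),
                                 before = character(0), after = character(0),
                                 depth = integer(0), support = integer(0),
                                 stringsAsFactors = FALSE),
       depth = depth)
}

#' Draft-anchored consensus of junction read segments
#'
#' Aligns every segment to the draft (the concatenated unit flanks) and
#' calls a per-column majority base; columns with fewer than \code{minDepth}
#' supporting segments, and 50/50 ties, retain the draft base.  Deletions
#' and insertions supported by a majority of covering segments are applied.
#'
#' @param segments \code{DNAStringSet} (or the list from
#'   \code{\link{trimJunctionReads}}).
#' @param draft draft sequence (character or \code{DNAString}).
#' @param minDepth minimum segments covering a column before it may be
#'   revised (default 2).
#' @param band,k,stride alignment parameters (see \code{\link{alignLocal}}).
#' @return list with \code{consensus} (character), \code{nSegments} used,
#'   \code{changes} (data.frame: 0-based \code{position}, \code{type},
#'   \code{before}, \code{after}, \code{depth}, \code{support}), and
#'   \code{flagged} (TRUE when fewer than 3 segments aligned).
#' @export
consensusFromReads <- function(segments, draft, minDepth = 2L, band = 80L,
                               k = 15L, stride = 20L) {
  if (is.list(segments) && !is.null(segments$segments))
    segments <- segments$segments
  draft <- as.character(draft)
  segs <- as.character(segments)
  if (!length(segs)) {
    warning("no segments; returning the draft unchanged")
    return(list(consensus = draft, nSegments = 0L,
                changes = NULL, flagged = TRUE))
  }
  pile <- cpp_pileup(draft, segs, k = k, stride = stride, band = band,
                     minSeeds = 2L)
  v <- .voteConsensus(draft, pile, minDepth = minDepth)
  list(consensus = v$seq, nSegments = pile$nAligned,
       changes = v$changes, flagged = pile$nAligned < 3L)
}

#' Polish a contig with short reads by majority vote
#'
#' Maps short reads to the contig and applies per-column majority base
#' calls, including simple indel pileup: insertions or deletions supported
#' by more than half of the covering reads are applied.  Columns covered by
#' fewer than \code{minCoverage} reads are left untouched (with a warning
#' when they exceed 10\% of the contig).  Polishing is idempotent: a second
#' pass on its own output yields zero changes.
#'
#' @param contig sequence to polish (character or \code{DNAString}).
#' @param shortReads \code{DNAStringSet} (mates may simply be concatenated).
#' @param minCoverage minimum depth for a column to be edited (default 3).
#' @param band,k,stride alignment parameters sized for 100 nt reads.
#' @return list with \code{polished} (character) and \code{changes}
#'   (data.frame as in \code{\link{consensusFromReads}}).
#' @export
polishWithShortReads <- function(contig, shortReads, minCoverage = 3L,
                                 band = 30L, k = 13L, stride = 10L) {
  contig <- as.character(contig)
  segs <- as.character(shortReads)
  pile <- cpp_pileup(contig, segs, k = k, stride = stride, band = band,
                     minSeeds = 2L)
  lowCov <- sum(pile$depth < minCoverage)
  if (lowCov > 0.1 * nchar(contig))
    warning(sprintf("%d of %d columns below %dx coverage were left untouched",
                    lowCov, nchar(contig), minCoverage))
  v <- .voteConsensus(contig, pile, minDepth = minCoverage)
  list(polished = v$seq, changes = v$changes, depth = v$depth)
}
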