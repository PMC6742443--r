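## Reverse read mapping: tiling-fragment construction, seeded local
## alignment of fragments onto long reads, informative-read selection,
## plastid filtering and per-read unit-path reconstruction.

#' Tile primary units into overlapping fragments
#'
#' Applies a sliding window to each unit: windows start at 0, step,
#' 2*step, ...; when the last regular window does not reach the unit end one
#' extra tail fragment [L - window, L) is appended so that unit termini
#' (where junction evidence lives) are always covered.  Units shorter than
#' the window yield a single whole-unit fragment.
#'
#' @param unitSeqs named character vector or \code{DNAStringSet} of unit
#'   sequences.
#' @param window,step window and step sizes in bp (defaults 2000 / 1000).
#' @return data.frame with \code{fragId}, \code{unit}, \code{index}
#'   (0-based), \code{start}, \code{end} (0-based half-open) and \code{seq}.
#' @examples
#' makeTiling(c(T = paste(rep("ACGT", 888), collapse = "")))[, 1:5]
#' @export
makeTiling <- function(unitSeqs, window = 2000L, step = 1000L) {
  if (length(unitSeqs) == 0L) stop("no units supplied")
  if (!(window >= step && step >= 1)) stop("need window >= step >= 1")
  seqs <- setNames(as.character(unitSeqs), names(unitSeqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("unit", seq_along(seqs))
  out <- vector("list", length(seqs))
  for (ui in seq_along(seqs)) {
    u <- names(seqs)[ui]
    L <- nchar(seqs[ui])
    if (L <= window) {
      starts <- 0L
      ends <- L
    } else {
      starts <- seq(0L, L - window, by = step)
      ends <- starts + window
      if (max(ends) < L) {
        starts <- c(starts, L - window)
        ends <- c(ends, L)
      }
    }
    out[[ui]] <- data.frame(
      fragId = sprintf("%s.%03d", u, seq_along(starts) - 1L),
      unit = u, index = seq_along(starts) - 1L,
      start = as.integer(starts), end = as.integer(ends),
      seq = substring(seqs[ui], starts + 1L, ends),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Seeded, chained local alignment of one query against one target
#'
#' Exact k-mer seeds are clustered by diagonal and each cluster is verified
#' by a banded Smith-Waterman around that diagonal; maximal local alignments
#' with identity and length above the thresholds are reported on both
#' strands.  Deterministic given its inputs; zero hits is a valid result.
#'
#' @param query,target sequences (character or \code{DNAString}).
#' @param minIdentity minimum identity fraction (default 0.8).
#' @param minLen minimum alignment length in bp.
#' @param k seed length; \code{stride} spacing of sampled seeds along the
#'   query (default adapts to query length); \code{band} half-width of the
#'   verification band.
#' @return data.frame with \code{queryStart}, \code{queryEnd} (forward query
#'   coordinates), \code{targetStart}, \code{targetEnd}, \code{strand},
#'   \code{identity}, \code{alnLen}, \code{maxGap} (all 0-based half-open).
#' @export
alignLocal <- function(query, target, minIdentity = 0.8, minLen = 50L,
                       k = 15L, stride = NULL, band = 60L) {
  query <- as.character(query); target <- as.character(target)
  if (!nchar(query) || !nchar(target)) stop("sequences must be non-empty")
  if (is.null(stride)) stride <- max(5L, nchar(query) %/% 100L)
  h <- cpp_map_fragments(target, query, k = k, stride = stride, band = band,
                         minIdentity = minIdentity, minLen = minLen,
                         minSeeds = 2L)
  data.frame(queryStart = h$fragStart, queryEnd = h$fragEnd,
             targetStart = h$readStart, targetEnd = h$readEnd,
             strand = h$strand, identity = h$identity,
             alnLen = h$alnLen, maxGap = h$maxGap,
             stringsAsFactors = FALSE)[order(-h$alnLen * h$identity), ]
}

#' Map tiling fragments onto long reads
#'
#' The reverse-read-mapping step: every tiling fragment is aligned to every
#' read (both strands) and verified hits are returned as a per-read hit
#' table sorted by read offset.
#'
#' @param fragments tiling table from \code{\link{makeTiling}}.
#' @param reads \code{DNAStringSet} (or named character vector) of long
#'   reads.
#' @param minIdentity,minLen hit acceptance thresholds.
#' @param k,stride,band,minSeeds seeding/verification parameters.
#' @return data.frame with \code{readId}, \code{fragId}, \code{unit},
#'   \code{fragIndex}, \code{readStart}, \code{readEnd}, \code{fragStart},
#'   \code{fragEnd}, \code{strand}, \code{identity}, \code{alnLen},
#'   \code{maxGap} (0-based half-open).
#' @export
mapTilingToReads <- function(fragments, reads, minIdentity = 0.8,
                             minLen = 200L, k = 15L, stride = 40L,
                             band = 30L, minSeeds = 3L) {
  rid <- names(reads)
  rs <- as.character(reads)
  if (is.null(rid)) rid <- sprintf("read%06d", seq_along(rs))
  h <- cpp_map_fragments(rs, fragments$seq, k = k, stride = stride,
                         band = band, minIdentity = minIdentity,
                         minLen = minLen, minSeeds = minSeeds)
  out <- data.frame(
    readId = rid[h$readIdx],
    fragId = fragments$fragId[h$fragIdx],
    unit = fragments$unit[h$fragIdx],
    fragIndex = fragments$index[h$fragIdx],
    readStart = h$readStart, readEnd = h$readEnd,
    fragStart = h$fragStart, fragEnd = h$fragEnd,
    strand = h$strand, identity = h$identity,
    alnLen = h$alnLen, maxGap = h$maxGap,
    stringsAsFactors = FALSE)
  out[order(out$readId, out$readStart), , drop = FALSE]
}

#' Write a hit table as tab-delimited text
#'
#' Columns follow the exchange format: read_id, fragment_id, unit,
#' frag_index, read_start, read_end, strand, identity, aln_len (0-based,
#' half-open).
#'
#' @param hits hit table from \code{\link{mapTilingToReads}}.
#' @param file output path.
#' @export
writeHitTable <- function(hits, file) {
  df <- data.frame(read_id = hits$readId, fragment_id = hits$fragId,
                   unit = hits$unit, frag_index = hits$fragIndex,
                   read_start = hits$readStart, read_end = hits$readEnd,
                   strand = hits$strand,
                   identity = round(hits$identity, 4),
                   aln_len = hits$alnLen)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Select maximally informative reads
#'
#' Keeps reads whose hit lists cover at least \code{minDistinctFragments}
#' distinct tiling fragments (duplicate hits to one fragment count once).
#' The default of 10 suits a 314 kb genome; 12 was appropriate for the
#' slightly shorter-read saligna data set.
#'
#' @param hits hit table from \code{\link{mapTilingToReads}}.
#' @param minDistinctFragments threshold (>= 1).
#' @return character vector of read ids.
#' @export
selectInformativeReads <- function(hits, minDistinctFragments = 10L) {
  if (minDistinctFragments < 1) stop("minDistinctFragments must be >= 1")
  if (!nrow(hits)) return(character(0))
  n <- tapply(hits$fragId, hits$readId, function(x) length(unique(x)))
  sort(names(n)[n >= minDistinctFragments])
}

#' Filter read pairs matching a plastid decoy
#'
#' Discards a pair when either mate aligns to the decoy over at least
#' \code{lengthFraction} of its length at \code{similarityFraction} identity
#' or better; the unmapped remainder is returned for mitochondrial analysis.
#'
#' @param read1,read2 \code{DNAStringSet}s of mates (parallel).
#' @param decoy decoy sequence(s) (character or \code{DNAStringSet}).
#' @param lengthFraction,similarityFraction mapping stringency (default 0.9
#'   and 0.9).
#' @return list with filtered \code{read1}, \code{read2} and the logical
#'   \code{keep} vector.
#' @export
filterPlastid <- function(read1, read2, decoy, lengthFraction = 0.9,
                          similarityFraction = 0.9) {
  decoy <- as.character(decoy)
  .mapsToDecoy <- function(reads) {
    rs <- as.character(reads)
    hit <- rep(FALSE, length(rs))
    h <- cpp_map_fragments(decoy, rs, k = 11L, stride = 4L, band = 20L,
                           minIdentity = similarityFraction,
                           minLen = 20L, minSeeds = 2L)
    if (nrow(h)) {
      need <- ceiling(lengthFraction * nchar(rs[h$fragIdx]))
      hit[unique(h$fragIdx[h$alnLen >= need])] <- TRUE
    }
    hit
  }
  drop <- .mapsToDecoy(read1) | .mapsToDecoy(read2)
  list(read1 = read1[!drop], read2 = read2[!drop], keep = !drop)
}

#' Reconstruct per-read unit paths from fragment hits
#'
#' Collapses runs of consecutive same-unit fragment hits into oriented unit
#' tokens: monotonically increasing fragment indices give '+', decreasing
#' give '-'.  Runs shorter than \code{minRun} fragments are discarded unless
#' the unit is too short to produce more than one fragment (length below
#' window + step).  Reads in which two units claim more than half of the
#' same read span are flagged ambiguous and excluded from the path set.
#'
#' @param hits hit table from \code{\link{mapTilingToReads}}.
#' @param tiling tiling table from \code{\link{makeTiling}} (supplies
#'   per-unit fragment counts and lengths).
#' @param window,step the tiling geometry used.
#' @param minRun minimum fragments per accepted run (default 2).
#' @return data.frame with one row per read: \code{readId}, \code{path}
#'   (comma-joined tokens, e.g. "W+,Z+"), \code{offsets} (comma-joined
#'   0-based read offsets of each run start), \code{nUnits},
#'   \code{ambiguous}.
#' @export
unitPaths <- function(hits, tiling, window = 2000L, step = 1000L,
                      minRun = 2L) {
  unitLen <- tapply(tiling$end, tiling$unit, max)
  shortUnit <- unitLen < window + step
  res <- list()
  for (rid in unique(hits$readId)) {
    hh <- hits[hits$readId == rid, , drop = FALSE]
    hh <- hh[order(hh$readStart), , drop = FALSE]
    runs <- list()
    cur <- NULL
    flush <- function(runs, cur) { if (!is.null(cur)) c(runs, list(cur)) else runs }
    for (i in seq_len(nrow(hh))) {
      row <- hh[i, ]
      extend <- FALSE
      if (!is.null(cur) && row$unit == cur$unit && row$strand == cur$strand) {
        di <- row$fragIndex - cur$lastIndex
        gap <- row$readStart - cur$lastStart
        okIdx <- if (row$strand == "+") di >= 1 && di <= 3
                 else di <= -1 && di >= -3
        if (okIdx && gap <= (abs(di) * step + window))
          extend <- TRUE
        else if (di == 0 && gap < step %/% 2)
          next   # duplicate hit on the same fragment
      }
      if (extend) {
        cur$n <- cur$n + 1L
        cur$lastIndex <- row$fragIndex
        cur$lastStart <- row$readStart
        cur$end <- max(cur$end, row$readEnd)
      } else {
        runs <- flush(runs, cur)
        cur <- list(unit = row$unit, strand = row$strand, n = 1L,
                    firstIndex = row$fragIndex, lastIndex = row$fragIndex,
                    lastStart = row$readStart, start = row$readStart,
                    end = row$readEnd)
      }
    }
    runs <- flush(runs, cur)
    if (!length(runs)) next
    keep <- vapply(runs, function(r)
      r$n >= minRun || isTRUE(shortUnit[[r$unit]]), logical(1))
    runs <- runs[keep]
    if (!length(runs)) next
    # re-join runs split by a discarded stray hit
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      di <- r$firstIndex - last$lastIndex
      joinable <- r$unit == last$unit && r$strand == last$strand &&
        (if (r$strand == "+") di >= 1 && di <= 4 else di <= -1 && di >= -4) &&
        (r$start - last$lastStart) <= (abs(di) * step + window)
      if (joinable) {
        last$n <- last$n + r$n
        last$lastIndex <- r$lastIndex
        last$lastStart <- r$lastStart
        last$end <- max(last$end, r$end)
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- r
    }
    runs <- merged
    # ambiguity: two accepted runs overlapping > 50% of the shorter one
    ambiguous <- FALSE
    if (length(runs) > 1) {
      for (i in seq_len(length(runs) - 1L)) {
        a <- runs[[i]]; b <- runs[[i + 1L]]
        ov <- min(a$end, b$end) - max(a$start, b$start)
        if (ov > 0.5 * min(a$end - a$start, b$end - b$start) &&
            a$unit != b$unit)
          ambiguous <- TRUE
      }
    }
    toks <- vapply(runs, function(r) paste0(r$unit, r$strand), character(1))
    offs <- vapply(runs, function(r) r$start, numeric(1))
    res[[rid]] <- data.frame(
      readId = rid, path = paste(toks, collapse = ","),
      offsets = paste(offs, collapse = ","),
      nUnits = length(toks), ambiguous = ambiguous,
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(readId = character(0), path = character(0),
                      offsets = character(0), nUnits = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Split path strings into token vectors
#'
#' @param paths data.frame from \code{\link{unitPaths}} (or a character
#'   vector of comma-joined paths).
#' @param includeAmbiguous keep reads flagged ambiguous (default FALSE).
#' @return named list of character token vectors.
#' @export
pathTokens <- function(paths, includeAmbiguous = FALSE) {
  if (is.data.frame(paths)) {
    if (!includeAmbiguous) paths <- paths[!paths$ambiguous, , drop = FALSE]
    setNames(strsplit(paths$path, ",", fixed = TRUE), paths$readId)
  } else {
    strsplit(paths, ",", fixed = TRUE)
  }
}
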