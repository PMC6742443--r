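## Near-identical repeat discovery: exact-word seeds with ungapped X-drop
## extension under strongly mismatch-averse scoring (+1 / -20), which
## surfaces only recently duplicated or gene-converted copies.

.kmersOf <- function(seq, word) {
  n <- nchar(seq)
  if (n < word) return(character(0))
  substring(seq, seq_len(n - word + 1L), seq_len(n - word + 1L) + word - 1L)
}

## seed pairs between two k-mer vectors (positions are 0-based starts)
.sharedSeeds <- function(kA, kB, selfDirect = FALSE) {
  common <- intersect(kA, kB)
  if (!length(common)) return(NULL)
  selA <- kA %in% common
  selB <- kB %in% common
  posA <- split(which(selA) - 1L, kA[selA])
  posB <- split(which(selB) - 1L, kB[selB])
  out <- vector("list", length(common))
  for (i in seq_along(common)) {
    km <- common[i]
    grid <- expand.grid(a = posA[[km]], b = posB[[km]],
                        KEEP.OUT.ATTRS = FALSE)
    if (selfDirect) grid <- grid[grid$a < grid$b, , drop = FALSE]
    out[[i]] <- grid
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) NULL else res
}

## extend seeds grouped by diagonal; returns merged maximal segments
.extendDiagonals <- function(seqA, seqB, seeds, word, reward, penalty,
                             xdrop, minScore) {
  if (is.null(seeds)) return(NULL)
  d <- seeds$b - seeds$a
  segs <- list()
  for (diag in unique(d)) {
    pos <- sort(seeds$a[d == diag])
    covered <- integer(0)
    for (p in pos) {
      if (length(covered) && p < covered[2] && p >= covered[1]) next
      e <- cpp_ungapped_extend(seqA, seqB, p, p + diag, word,
                               reward = reward, penalty = penalty,
                               xdrop = xdrop)
      if (e$score < minScore) next
      covered <- c(e$startA, e$endA)
      segs[[length(segs) + 1L]] <- data.frame(
        startA = e$startA, endA = e$endA,
        startB = e$startB, endB = e$endB,
        score = e$score, length = e$length, identity = e$identity)
    }
  }
  if (!length(segs)) return(NULL)
  segs <- do.call(rbind, segs)
  unique(segs)
}

.sizeClass <- function(len) {
  ifelse(len >= 1000, "large", ifelse(len >= 100, "intermediate", "short"))
}

#' Find near-identical repeats
#'
#' Exact word seeds (both strands) extended without gaps under
#' (+\code{reward}, -\code{penalty}) scoring with an X-drop; maximal
#' segments containing a full word and scoring at least \code{minScore} are
#' reported.  Trivial self-hits (identical coordinates) are excluded, and a
#' matched pair is reported once in canonical order (sequence A before B,
#' then by coordinate).  With the default -20 mismatch penalty a copy with
#' a few percent divergence no longer extends: the scan is deliberately
#' restricted to nearly identical repeats.
#'
#' @param sequences named character vector or \code{DNAStringSet} (one or
#'   more units or whole isoforms).
#' @param word exact seed length (default 50).
#' @param reward,penalty match reward and (positive) mismatch penalty.
#' @param minScore minimum segment score (default 50, one full word).
#' @param xdrop X-drop termination threshold (default 40, i.e. two
#'   mismatches).
#' @param mode \code{"both"} (default), \code{"within"} (each sequence
#'   against itself) or \code{"between"} (distinct sequence pairs only).
#' @return data.frame with \code{idA}, \code{startA}, \code{endA},
#'   \code{idB}, \code{startB}, \code{endB} (0-based half-open, forward
#'   strand coordinates), \code{orientation} (\code{direct} or
#'   \code{inverted}), \code{length}, \code{identity}, \code{score},
#'   \code{class} (large >= 1 kb, intermediate 100-999, short < 100).
#' @export
findRepeats <- function(sequences, word = 50L, reward = 1L, penalty = 20L,
                        minScore = 50L, xdrop = 40L,
                        mode = c("both", "within", "between")) {
  mode <- match.arg(mode)
  seqs <- setNames(as.character(sequences), names(sequences))
  if (!length(seqs) || any(!nchar(seqs))) stop("sequences must be non-empty")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ids <- names(seqs)
  kms <- lapply(seqs, .kmersOf, word = word)
  out <- list()
  addMatches <- function(idA, idB, segs, orientation, LB) {
    if (is.null(segs)) return()
    if (orientation == "inverted") {
      ## coordinates of B were computed on revcomp(B): map back
      sB <- LB - segs$endB
      eB <- LB - segs$startB
      segs$startB <- sB; segs$endB <- eB
    }
    segs$idA <- idA; segs$idB <- idB; segs$orientation <- orientation
    out[[length(out) + 1L]] <<- segs
  }
  pairIdx <- list()
  for (i in seq_along(seqs)) for (j in i:length(seqs)) {
    if (mode == "within" && i != j) next
    if (mode == "between" && i == j) next
    pairIdx[[length(pairIdx) + 1L]] <- c(i, j)
  }
  for (p in pairIdx) {
    i <- p[1]; j <- p[2]
    A <- seqs[i]; B <- seqs[j]
    ## direct orientation
    seeds <- .sharedSeeds(kms[[i]], kms[[j]], selfDirect = (i == j))
    addMatches(ids[i], ids[j],
               .extendDiagonals(A, B, seeds, word, reward, penalty,
                                xdrop, minScore), "direct", nchar(B))
    ## inverted orientation: compare A against revcomp(B)
    Brc <- .revcompChr(B)
    kBrc <- .kmersOf(Brc, word)
    seedsI <- .sharedSeeds(kms[[i]], kBrc, selfDirect = FALSE)
    segsI <- .extendDiagonals(A, Brc, seedsI, word, reward, penalty,
                              xdrop, minScore)
    addMatches(ids[i], ids[j], segsI, "inverted", nchar(B))
  }
  if (!length(out))
    return(data.frame(idA = character(0), startA = integer(0),
                      endA = integer(0), idB = character(0),
                      startB = integer(0), endB = integer(0),
                      orientation = character(0), length = integer(0),
                      identity = numeric(0), score = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- data.frame(idA = res$idA, startA = res$startA, endA = res$endA,
                    idB = res$idB, startB = res$startB, endB = res$endB,
                    orientation = res$orientation, length = res$length,
                    identity = res$identity, score = res$score,
                    class = .sizeClass(res$length),
                    stringsAsFactors = FALSE)
  ## canonical order within self-comparisons: A interval before B interval
  swap <- res$idA == res$idB & res$startA > res$startB
  if (any(swap)) {
    tmp <- res[swap, c("startA", "endA")]
    res[swap, c("startA", "endA")] <- res[swap, c("startB", "endB")]
    res[swap, c("startB", "endB")] <- tmp
  }
  ## drop trivial self-hits (identical coordinates)
  res <- res[!(res$idA == res$idB & res$startA == res$startB &
                 res$endA == res$endB & res$orientation == "direct"), ,
             drop = FALSE]
  res <- unique(res)
  res <- res[order(res$idA, res$startA, res$idB, res$startB,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify repeat matches by size and role
#'
#' Attaches size-class labels and distinguishes hinge repeats (matches
#' covering at least 90\% of a unit present at copy number two, the
#' frequently recombining isomerisation sites) from dispersed repeats.
#'
#' @param matches data.frame from \code{\link{findRepeats}}.
#' @param copyNumbers named integer vector of unit copy numbers.
#' @param unitLengths named numeric vector of unit lengths (bp).
#' @return the matches with an added \code{role} column (\code{"hinge"} or
#'   \code{"dispersed"}).
#' @export
classifyRepeats <- function(matches, copyNumbers = NULL,
                            unitLengths = NULL) {
  role <- rep("dispersed", nrow(matches))
  if (!is.null(copyNumbers) && !is.null(unitLengths)) {
    for (i in seq_len(nrow(matches))) {
      for (side in c("A", "B")) {
        id <- matches[[paste0("id", side)]][i]
        if (!is.null(copyNumbers[id]) && !is.na(copyNumbers[id]) &&
            copyNumbers[id] >= 2L &&
            matches$length[i] >= 0.9 * unitLengths[id]) {
          role[i] <- "hinge"
        }
      }
    }
  }
  matches$role <- role
  matches
}
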