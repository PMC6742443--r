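# Shared fixtures and independent oracles for the test suite.
# All synthetic data are generated in code at test time.

toyLens <- c(A = 8000, B = 7000, C = 6000, D = 5000, R = 2000)

toyFixture <- function() genomeFixture("toy", names(toyLens), toyLens,
                                       repeats = "R")

# two circular isoforms differing by the exchange of B and C between the
# two copies of the hinge repeat R
toyIsoformPair <- function(frequencies = c(0.5, 0.5)) {
  fx <- toyFixture()
  list(alpha = isoformModel("alpha", c("A+", "R+", "B+", "C+", "R+", "D+"),
                            fixture = fx, frequency = frequencies[1]),
       beta = isoformModel("beta", c("A+", "R+", "C+", "B+", "R+", "D+"),
                           fixture = fx, frequency = frequencies[2]))
}

# one toy end-to-end mapping shared by several test files (computed once)
.toyCache <- new.env(parent = emptyenv())
toyPipeline <- function() {
  if (!exists("res", .toyCache)) {
    iso <- toyIsoformPair()
    cfg <- simulationConfig(iso, seed = 7L, coverage = 60,
                            readLengthMean = 8000, readLengthSd = 2000)
    truth <- generateGenome(cfg)
    reads <- simulateLongReads(truth)
    tiling <- makeTiling(unitSequences(truth))
    hits <- mapTilingToReads(tiling, reads)
    informative <- selectInformativeReads(hits, 5L)
    paths <- unitPaths(hits[hits$readId %in% informative, ], tiling)
    cn <- trueCopyNumbers(truth)
    blocks <- buildingBlocks(paths, cn)
    assign("res", list(iso = iso, cfg = cfg, truth = truth, reads = reads,
                       tiling = tiling, hits = hits,
                       informative = informative, paths = paths,
                       cn = cn, blocks = blocks), .toyCache)
  }
  get("res", .toyCache)
}

# ---------------------------------------------------------------------------
# Brute-force isoform enumeration oracle: all permutations of the unit
# instance multiset with all strand assignments, filtered by adjacency and
# block constraints, canonicalised and deduplicated.  Independent of the
# backtracking enumerator.

bruteForceIsoforms <- function(copyNumbers, blocks) {
  pairKeys <- blocks[lengths(strsplit(blocks, ",")) == 2]
  conKeys <- blocks[lengths(strsplit(blocks, ",")) >= 3]
  instances <- rep(names(copyNumbers), copyNumbers)
  n <- length(instances)
  canonPair <- function(a, b)
    paste(.mfMinByKey(c(a, b), rev(.mfFlip(c(a, b)))), collapse = ",")
  isRep <- copyNumbers >= 2L
  conRuns <- vapply(strsplit(conKeys, ","), function(tk)
    paste(sort(sub("[+-]$", "", tk[-c(1, length(tk))])), collapse = "/"),
    character(1))
  results <- character(0)
  perms <- permuteMultiset(instances)
  for (p in perms) {
    for (mask in 0:(2^n - 1)) {
      strands <- ifelse(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L,
                        "-", "+")
      toks <- paste0(p, strands)
      ok <- TRUE
      for (i in seq_len(n)) {
        a <- toks[i]; b <- toks[if (i == n) 1L else i + 1L]
        if (!(canonPair(a, b) %in% pairKeys)) { ok <- FALSE; break }
      }
      if (!ok) next
      # block constraints on repeat-centred windows of the circular walk
      if (length(conKeys)) {
        toks2 <- c(toks, toks)
        rep2 <- isRep[sub("[+-]$", "", toks2)]
        i <- 2L
        while (i <= n + 1L && ok) {
          if (rep2[i] && !rep2[i - 1L]) {
            j <- i
            while (j + 1L <= 2L * n && rep2[j + 1L]) j <- j + 1L
            if (j + 1L <= 2L * n && !rep2[j + 1L]) {
              w <- toks2[(i - 1L):(j + 1L)]
              runKey <- paste(sort(sub("[+-]$", "",
                                       w[-c(1, length(w))])), collapse = "/")
              if (runKey %in% conRuns) {
                wk <- paste(.mfMinByKey(w, rev(.mfFlip(w))), collapse = ",")
                if (!(wk %in% conKeys)) ok <- FALSE
              }
            }
            i <- j + 1L
          } else i <- i + 1L
        }
      }
      if (!ok) next
      results <- c(results,
                   paste(canonicalArrangement(toks), collapse = ","))
    }
  }
  sort(unique(results))
}

# all distinct permutations of a multiset (recursive)
permuteMultiset <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (u in unique(x)) {
    rest <- x[-match(u, x)]
    for (p in permuteMultiset(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  out
}

.mfFlip <- function(tokens) {
  s <- substr(tokens, nchar(tokens), nchar(tokens))
  paste0(sub("[+-]$", "", tokens), ifelse(s == "+", "-", "+"))
}

.mfMinByKey <- function(a, b) {
  k <- c(paste(a, collapse = ","), paste(b, collapse = ","))
  list(a, b)[[order(k, method = "radix")[1]]]
}

# ---------------------------------------------------------------------------
# Quadratic ungapped repeat-scan oracle: every diagonal of every sequence
# pair, exact word runs extended with the same X-drop rule.

oracleRepeatScan <- function(seqs, word = 50L, reward = 1L, penalty = 20L,
                             minScore = 50L, xdrop = 40L) {
  ids <- names(seqs)
  seqs <- setNames(as.character(seqs), ids)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  out <- list()
  # X-drop extension along the 0/1 match vector of one diagonal
  extendOnDiag <- function(m, seedStart, seedLen) {
    score <- seedLen * reward
    best <- score; hi <- seedStart + seedLen - 1L
    i <- hi + 1L; s <- score
    while (i <= length(m)) {
      s <- s + if (m[i]) reward else -penalty
      if (s > best) { best <- s; hi <- i }
      if (best - s > xdrop) break
      i <- i + 1L
    }
    final <- best; lo <- seedStart
    i <- seedStart - 1L; s <- best
    while (i >= 1L) {
      s <- s + if (m[i]) reward else -penalty
      if (s > final) { final <- s; lo <- i }
      if (final - s > xdrop) break
      i <- i - 1L
    }
    list(lo = lo, hi = hi, score = final)
  }
  scanPair <- function(a, b, idA, idB, orientation, self) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    La <- length(ca); Lb <- length(cb)
    for (d in (-(La - 1)):(Lb - 1)) {
      ia <- max(1, 1 - d):min(La, Lb - d)
      if (length(ia) < word) next
      if (self && orientation == "direct" && d == 0) next
      m <- ca[ia] == cb[ia + d]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      pos <- which(r$values & r$lengths >= word)
      usedUpTo <- -Inf
      for (pi in pos) {
        if (starts[pi] <= usedUpTo) next
        e <- extendOnDiag(m, starts[pi], word)
        if (e$score < minScore) next
        usedUpTo <- e$hi
        out[[length(out) + 1L]] <<- data.frame(
          idA = idA, startA = ia[e$lo] - 1L, endA = ia[e$hi],
          idB = idB, startB = ia[e$lo] + d - 1L, endB = ia[e$hi] + d,
          orientation = orientation, length = e$hi - e$lo + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_along(seqs)) for (j in i:length(seqs)) {
    scanPair(seqs[i], seqs[j], ids[i], ids[j], "direct", i == j)
    scanPair(seqs[i], rc(seqs[j]), ids[i], ids[j], "inverted", FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  # map inverted B coordinates back to forward strand
  inv <- res$orientation == "inverted"
  if (any(inv)) {
    Lb <- nchar(seqs[res$idB[inv]])
    sB <- Lb - res$endB[inv]; eB <- Lb - res$startB[inv]
    res$startB[inv] <- sB; res$endB[inv] <- eB
  }
  swap <- res$idA == res$idB & res$startA > res$startB
  if (any(swap)) {
    tmp <- res[swap, c("startA", "endA")]
    res[swap, c("startA", "endA")] <- res[swap, c("startB", "endB")]
    res[swap, c("startB", "endB")] <- tmp
  }
  res <- res[!(res$idA == res$idB & res$startA == res$startB &
                 res$endA == res$endB & res$orientation == "direct"), ]
  res <- unique(res[, c("idA", "startA", "endA", "idB", "startB", "endB",
                        "orientation", "length")])
  res[order(res$idA, res$startA, res$idB, res$startB, method = "radix"), ]
}

# deterministic random DNA under a local seed, leaving the global RNG alone
seededDNA <- function(n, seed) {
  withr::with_seed(seed, randomDNA(n))
}
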