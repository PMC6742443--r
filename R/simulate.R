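## Synthetic recombining mitochondrial genomes and read sets with ground
## truth.  All randomness flows from a single config seed through named
## substreams (genome, longreads, matepairs, hic, subsample) so that stages
## are independently reproducible.

.SEED_GENOME <- 101L
.SEED_LONGREADS <- 202L
.SEED_MATEPAIRS <- 303L
.SEED_HIC <- 404L
.SEED_SUBSAMPLE <- 505L

.substream <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

## ---------------------------------------------------------------------------
## SimulationConfig

#' Simulation configuration
#'
#' Bundles the study conditions for one simulated genome: the isoform mixture,
#' long-read length distribution and error rates, coverage, mate-pair library
#' geometry, Hi-C distance decay and the master seed.  Defaults follow the
#' sequencing design the pipeline was built for: 250x long-read coverage,
#' lognormal read lengths with mean 15 kb, 1\% substitution / 1\% insertion /
#' 1\% deletion long-read error, 100 nt short reads with 0.1\% substitution
#' error, and mate-pair inserts of 2.5 and 10 kb.
#'
#' @param isoforms list of \code{\link{IsoformModel}}s (the molecule pool).
#' @param frequencies molecule-pool fractions, one per isoform; defaults to
#'   the frequencies stored in the models, or equal fractions.  Must sum to 1.
#' @param seed master RNG seed (integer).
#' @param coverage target long-read coverage (x).
#' @param readLengthMean,readLengthSd long-read length distribution
#'   (lognormal, parameterised by mean and SD in bp).
#' @param errorRates named vector \code{c(sub=, ins=, del=)} of per-base
#'   long-read error rates, each in [0, 0.2].
#' @param shortReadLength,shortReadError short-read length (nt) and per-base
#'   substitution rate.
#' @param insertSizes,insertSd mate-pair insert means and SDs (bp; recycled).
#' @param hicExponent Hi-C contact distance decay exponent (power law).
#' @param unitSeqs optional named \code{DNAStringSet} of unit sequences; units
#'   not supplied are generated as seeded i.i.d. uniform random DNA.
#' @param plantedRepeats optional list of planted exact repeats, each a list
#'   with \code{sourceUnit}, \code{sourceStart} (0-based), \code{length},
#'   \code{targetUnit}, \code{targetStart}, and optional
#'   \code{orientation} (\code{"direct"} or \code{"inverted"}).
#' @return a validated \code{SimulationConfig} (list).
#' @export
simulationConfig <- function(isoforms, frequencies = NULL, seed = 1L,
                             coverage = 250,
                             readLengthMean = 15000, readLengthSd = 5000,
                             errorRates = c(sub = 0.01, ins = 0.01, del = 0.01),
                             shortReadLength = 100L, shortReadError = 0.001,
                             insertSizes = c(2500, 10000), insertSd = NULL,
                             hicExponent = 3, unitSeqs = NULL,
                             plantedRepeats = NULL) {
  if (!is.list(isoforms) || !length(isoforms) ||
      !all(vapply(isoforms, is, logical(1), "IsoformModel")))
    stop("'isoforms' must be a non-empty list of IsoformModel objects")
  if (is.null(frequencies)) {
    frequencies <- vapply(isoforms, function(i) i@frequency, numeric(1))
    if (anyNA(frequencies))
      frequencies <- rep(1 / length(isoforms), length(isoforms))
  }
  if (length(frequencies) != length(isoforms))
    stop("one frequency per isoform required")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("isoform frequencies must sum to 1 (got ", sum(frequencies), ")")
  er <- errorRates[c("sub", "ins", "del")]
  if (anyNA(er) || any(er < 0) || any(er > 0.2))
    stop("errorRates must name sub, ins, del rates each in [0, 0.2]")
  if (coverage <= 0) stop("coverage must be > 0")
  if (is.null(insertSd)) insertSd <- 0.1 * insertSizes
  structure(list(
    isoforms = isoforms, frequencies = frequencies, seed = as.integer(seed),
    coverage = coverage, readLengthMean = readLengthMean,
    readLengthSd = readLengthSd, errorRates = er,
    shortReadLength = as.integer(shortReadLength),
    shortReadError = shortReadError,
    insertSizes = insertSizes, insertSd = insertSd,
    hicExponent = hicExponent, unitSeqs = unitSeqs,
    plantedRepeats = plantedRepeats), class = "SimulationConfig")
}

## ---------------------------------------------------------------------------
## GroundTruth

#' GroundTruth: a simulated genome with full provenance
#'
#' @slot unitSeqs \code{DNAStringSet} of primary-unit sequences.
#' @slot isoforms list of \code{\link{IsoformModel}}s.
#' @slot isoformSeqs \code{DNAStringSet}, one sequence per isoform.
#' @slot frequencies numeric molecule-pool fractions.
#' @slot unitCoords data.frame (isoform, unit, strand, start, end; 0-based
#'   half-open) tiling each isoform exactly.
#' @slot junctions data.frame of the true oriented junction multiset.
#' @slot config the generating \code{SimulationConfig}.
#' @export
setClass("GroundTruth",
         representation(unitSeqs = "ANY", isoforms = "list",
                        isoformSeqs = "ANY", frequencies = "numeric",
                        unitCoords = "data.frame", junctions = "data.frame",
                        config = "ANY"))

setValidity("GroundTruth", function(object) {
  if (length(object@isoforms) != length(object@isoformSeqs))
    return("one sequence per isoform required")
  for (i in seq_along(object@isoforms)) {
    uc <- object@unitCoords[object@unitCoords$isoform ==
                              object@isoforms[[i]]@label, ]
    if (nrow(uc)) {
      if (uc$start[1] != 0 ||
          uc$end[nrow(uc)] != length(object@isoformSeqs[[i]]) ||
          (nrow(uc) > 1 && any(uc$start[-1] != uc$end[-nrow(uc)])))
        return("unit coordinates must tile each isoform exactly")
    }
  }
  TRUE
})

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@isoforms), "isoform(s)\n")
  for (i in seq_along(object@isoforms))
    cat(sprintf("  %-8s %8d bp  frequency %.3f\n",
                object@isoforms[[i]]@label,
                length(object@isoformSeqs[[i]]), object@frequencies[i]))
})

#' GroundTruth accessors
#' @param truth a \code{\link{GroundTruth}}.
#' @return \code{isoformSequences}, \code{unitSequences}:
#'   \code{DNAStringSet}; \code{trueJunctions}, \code{trueUnitCoords}:
#'   data.frame; \code{trueCopyNumbers}: named integer vector (maximal
#'   per-isoform multiplicity of each unit).
#' @export
isoformSequences <- function(truth) truth@isoformSeqs

#' @rdname isoformSequences
#' @export
unitSequences <- function(truth) truth@unitSeqs

#' @rdname isoformSequences
#' @export
trueJunctions <- function(truth) truth@junctions

#' @rdname isoformSequences
#' @export
trueUnitCoords <- function(truth) truth@unitCoords

#' @rdname isoformSequences
#' @export
trueCopyNumbers <- function(truth) {
  cn <- integer(0)
  for (iso in truth@isoforms) {
    m <- table(.tokenUnit(iso@arrangement))
    for (u in names(m)) cn[u] <- max(cn[u], m[[u]], na.rm = TRUE)
  }
  cn
}

## ---------------------------------------------------------------------------
## Genome generation

.revcompChr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Generate a synthetic multi-isoform genome
#'
#' Emits seeded random unit sequences (unless supplied), plants exact repeat
#' copies, and concatenates oriented units into one sequence per isoform.
#' Identical seeds give byte-identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\link{GroundTruth}}.
#' @export
generateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.substream(config$seed, .SEED_GENOME))
  lens <- integer(0)
  for (iso in config$isoforms) {
    ul <- iso@unitLengths
    for (u in names(ul)) {
      if (u %in% names(lens) && lens[[u]] != ul[[u]])
        stop("conflicting lengths for unit ", u, " across isoforms")
      lens[u] <- ul[[u]]
    }
  }
  units <- character(0)
  for (u in names(lens)) {
    supplied <- !is.null(config$unitSeqs) && u %in% names(config$unitSeqs)
    units[u] <- if (supplied) as.character(config$unitSeqs[[u]])
                else randomDNA(lens[u])
    if (nchar(units[u]) != lens[u])
      stop("supplied sequence for unit ", u, " has the wrong length")
  }
  for (pr in config$plantedRepeats) {
    src <- substr(units[pr$sourceUnit], pr$sourceStart + 1L,
                  pr$sourceStart + pr$length)
    if (!is.null(pr$orientation) && pr$orientation == "inverted")
      src <- .revcompChr(src)
    tgt <- units[pr$targetUnit]
    units[pr$targetUnit] <- paste0(
      substr(tgt, 1L, pr$targetStart),
      src,
      substr(tgt, pr$targetStart + pr$length + 1L, nchar(tgt)))
  }
  isoSeqs <- character(length(config$isoforms))
  coords <- junc <- list()
  for (i in seq_along(config$isoforms)) {
    iso <- config$isoforms[[i]]
    toks <- iso@arrangement
    miss <- setdiff(.tokenUnit(toks), names(units))
    if (length(miss)) stop("isoform ", iso@label,
                           " references unknown unit(s): ",
                           paste(miss, collapse = ", "))
    pieces <- vapply(seq_along(toks), function(j) {
      s <- units[.tokenUnit(toks[j])]
      if (.tokenStrand(toks[j]) == "-") .revcompChr(s) else s
    }, character(1))
    isoSeqs[i] <- paste(pieces, collapse = "")
    uc <- isoformUnitCoords(iso)
    uc$isoform <- iso@label
    coords[[i]] <- uc
    pair <- cbind(toks, c(toks[-1], if (iso@topology == "circular") toks[1]))
    if (nrow(pair) && is.na(pair[nrow(pair), 2]))
      pair <- pair[-nrow(pair), , drop = FALSE]
    junc[[i]] <- data.frame(isoform = iso@label, left = pair[, 1],
                            right = pair[, 2], stringsAsFactors = FALSE)
  }
  isoSet <- Biostrings::DNAStringSet(isoSeqs)
  names(isoSet) <- vapply(config$isoforms, function(i) i@label, character(1))
  unitSet <- Biostrings::DNAStringSet(units)
  new("GroundTruth", unitSeqs = unitSet, isoforms = config$isoforms,
      isoformSeqs = isoSet, frequencies = config$frequencies,
      unitCoords = do.call(rbind, coords),
      junctions = do.call(rbind, junc), config = config)
}

## molecule pool shared by the read samplers: sequences, frequencies,
## topologies.  Accepts a GroundTruth or a plain list(seqs=, frequencies=).
.molecules <- function(x) {
  if (is(x, "GroundTruth")) {
    topo <- vapply(x@isoforms, function(i) i@topology, character(1))
    list(seqs = as.character(x@isoformSeqs), frequencies = x@frequencies,
         circular = topo == "circular", config = x@config)
  } else if (is.list(x) && !is.null(x$seqs)) {
    n <- length(x$seqs)
    list(seqs = setNames(as.character(x$seqs), names(x$seqs)),
         frequencies = if (is.null(x$frequencies)) rep(1 / n, n)
                       else x$frequencies,
         circular = if (is.null(x$circular)) rep(TRUE, n) else x$circular,
         config = x$config)
  } else stop("expected a GroundTruth or list(seqs=, frequencies=)")
}

## per-base error process: substitutions, insertions, deletions
.mutate <- function(seq, sub, ins, del) {
  if (sub == 0 && ins == 0 && del == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  u <- runif(n)
  delHit <- u < del
  subHit <- !delHit & u < del + sub
  if (any(subHit)) {
    bases <- c("A", "C", "G", "T")
    repl <- bases[(match(ch[subHit], bases) - 1L +
                     sample(1:3, sum(subHit), replace = TRUE)) %% 4L + 1L]
    ch[subHit] <- repl
  }
  insHit <- runif(n) < ins
  if (any(insHit)) {
    ch[insHit] <- paste0(ch[insHit],
                         sample(c("A", "C", "G", "T"), sum(insHit),
                                replace = TRUE))
  }
  ch[delHit] <- ""
  paste(ch, collapse = "")
}

## place exactly nErr random substitutions in a read
.substituteBases <- function(seq, nErr) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), min(nErr, length(ch)))
  bases <- c("A", "C", "G", "T")
  ch[pos] <- bases[(match(ch[pos], bases) - 1L +
                      sample(1:3, length(pos), replace = TRUE)) %% 4L + 1L]
  paste(ch, collapse = "")
}

## extract [start, start+len) from a (possibly circular) molecule, 0-based
.extract <- function(seq, start, len, circular) {
  L <- nchar(seq)
  start <- start %% L
  if (start + len <= L) return(substr(seq, start + 1L, start + len))
  if (!circular) stop("window beyond the end of a linear molecule")
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, start + len - L))
}

## ---------------------------------------------------------------------------
## Long reads

#' Sample long reads from a simulated genome
#'
#' Reads are drawn from molecules proportional to frequency times length,
#' with uniform start positions (wrap-around on circular molecules), lengths
#' from the configured lognormal (truncated to one genome length), random
#' strand, and per-base substitution/insertion/deletion errors.  Total bases
#' approximate coverage times the frequency-weighted mean molecule length.
#'
#' @param truth a \code{\link{GroundTruth}} (or molecule-pool list).
#' @param coverage,readLengthMean,readLengthSd,errorRates overrides of the
#'   config values.
#' @return \code{DNAStringSet} with provenance in
#'   \code{S4Vectors::mcols}: \code{isoform}, \code{start} (0-based),
#'   \code{strand}, \code{trueLength}.
#' @export
simulateLongReads <- function(truth, coverage = NULL, readLengthMean = NULL,
                              readLengthSd = NULL, errorRates = NULL) {
  mol <- .molecules(truth)
  cfg <- mol$config
  if (is.null(coverage)) coverage <- cfg$coverage
  if (is.null(readLengthMean)) readLengthMean <- cfg$readLengthMean
  if (is.null(readLengthSd)) readLengthSd <- cfg$readLengthSd
  if (is.null(errorRates)) errorRates <- cfg$errorRates
  set.seed(.substream(cfg$seed, .SEED_LONGREADS))

  lens <- nchar(mol$seqs)
  w <- mol$frequencies * lens
  meanLen <- sum(mol$frequencies * lens)
  if (!all(mol$circular) &&
      readLengthMean > min(lens[!mol$circular]))
    stop("mean read length exceeds the length of a linear molecule")
  targetBases <- coverage * meanLen
  m <- readLengthMean; s <- readLengthSd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  nGuess <- ceiling(targetBases / m * 1.3) + 10L

  isoIdx <- sample.int(length(lens), nGuess, replace = TRUE, prob = w)
  rl <- pmax(500L, as.integer(round(rlnorm(nGuess, meanlog, sdlog))))
  rl <- pmin(rl, lens[isoIdx])
  keep <- cumsum(as.numeric(rl)) <= targetBases
  if (any(keep)) {
    last <- max(which(keep))
    isoIdx <- isoIdx[seq_len(last + 1L)]   # first read past target included
    rl <- rl[seq_len(last + 1L)]
  } else {
    isoIdx <- isoIdx[1L]; rl <- rl[1L]
  }
  n <- length(isoIdx)
  start <- integer(n); strand <- character(n); out <- character(n)
  for (i in seq_len(n)) {
    L <- lens[isoIdx[i]]
    circ <- mol$circular[isoIdx[i]]
    s0 <- if (circ) as.integer(floor(runif(1, 0, L)))
          else as.integer(floor(runif(1, 0, max(1L, L - rl[i] + 1L))))
    raw <- .extract(mol$seqs[isoIdx[i]], s0, rl[i], circ)
    st <- sample(c("+", "-"), 1L)
    if (st == "-") raw <- .revcompChr(raw)
    out[i] <- .mutate(raw, errorRates[["sub"]], errorRates[["ins"]],
                      errorRates[["del"]])
    start[i] <- s0; strand[i] <- st
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- sprintf("read%06d", seq_len(n))
  isoLabels <- names(mol$seqs)
  if (is.null(isoLabels)) isoLabels <- as.character(seq_along(lens))
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    isoform = isoLabels[isoIdx], start = start, strand = strand,
    trueLength = rl)
  res
}

## ---------------------------------------------------------------------------
## Mate pairs

#' Sample mate-pair reads
#'
#' Two short reads whose outer distance follows a truncated normal around the
#' nominal insert size, on a molecule chosen by frequency times length.  The
#' first read is forward at the left end of the insert; the second is the
#' reverse complement of the right end.  Pairs may span the circular origin.
#'
#' @param truth \code{\link{GroundTruth}} or molecule-pool list.
#' @param n number of pairs.
#' @param insertMean,insertSd insert size mean and SD (bp).
#' @param readLength read length (nt; default from config).
#' @param errorRate per-base substitution rate (default from config).
#' @return list with \code{read1}, \code{read2} (\code{DNAStringSet}) and
#'   \code{provenance} (isoform, pos1, pos2 leftmost 0-based coordinates,
#'   insert).
#' @export
simulateMatePairs <- function(truth, n, insertMean, insertSd,
                              readLength = NULL, errorRate = NULL) {
  mol <- .molecules(truth)
  cfg <- mol$config
  if (is.null(readLength))
    readLength <- if (!is.null(cfg)) cfg$shortReadLength else 100L
  if (is.null(errorRate))
    errorRate <- if (!is.null(cfg)) cfg$shortReadError else 0
  if (insertMean <= 2 * readLength)
    stop("insert mean must exceed twice the read length")
  seed <- if (!is.null(cfg)) cfg$seed else 1L
  set.seed(.substream(seed + as.integer(insertMean) %% 1000L,
                      .SEED_MATEPAIRS))

  lens <- nchar(mol$seqs)
  w <- mol$frequencies * lens
  isoIdx <- sample.int(length(lens), n, replace = TRUE, prob = w)
  d <- as.integer(round(rnorm(n, insertMean, insertSd)))
  d <- pmax(d, 2L * readLength + 1L)
  d <- pmin(d, lens[isoIdx])
  u <- runif(n)
  L <- lens[isoIdx]
  s <- ifelse(mol$circular[isoIdx],
              as.integer(floor(u * L)),
              as.integer(floor(u * pmax(1L, L - d + 1L))))
  ## doubled sequences make circular extraction a plain substring
  doubled <- vapply(seq_along(mol$seqs), function(i)
    if (mol$circular[i])
      paste0(mol$seqs[i], substr(mol$seqs[i], 1L,
                                 min(lens[i], insertMean + 6L * insertSd +
                                       readLength)))
    else mol$seqs[i], character(1))
  r1 <- substring(doubled[isoIdx], s + 1L, s + readLength)
  p2 <- s + d - readLength
  r2 <- substring(doubled[isoIdx], p2 + 1L, p2 + readLength)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r2)))
  if (errorRate > 0) {
    nErr1 <- rbinom(n, readLength, errorRate)
    nErr2 <- rbinom(n, readLength, errorRate)
    for (i in which(nErr1 > 0L)) r1[i] <- .substituteBases(r1[i], nErr1[i])
    for (i in which(nErr2 > 0L)) r2[i] <- .substituteBases(r2[i], nErr2[i])
  }
  isoLabels <- names(mol$seqs)
  if (is.null(isoLabels)) isoLabels <- as.character(seq_along(lens))
  read1 <- Biostrings::DNAStringSet(r1)
  read2 <- Biostrings::DNAStringSet(r2)
  names(read1) <- sprintf("pair%07d/1", seq_len(n))
  names(read2) <- sprintf("pair%07d/2", seq_len(n))
  list(read1 = read1, read2 = read2,
       provenance = data.frame(
         isoform = isoLabels[isoIdx], pos1 = s,
         pos2 = (s + d - readLength) %% lens[isoIdx],
         insert = d, stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------------------
## Hi-C ligation chimeras

#' Sample Hi-C chimeric reads
#'
#' Mbo-I-style proximity ligation: two GATC-bounded loci on one molecule,
#' separation drawn from a power law with the configured decay exponent, are
#' joined into one read carrying the GATC-GATC ligation scar: the end of the
#' left fragment (terminating in its GATC) followed by the start of the right
#' fragment (beginning with its GATC).
#'
#' @param truth \code{\link{GroundTruth}} or molecule-pool list.
#' @param n number of chimeric reads.
#' @param exponent power-law decay exponent (> 1; default from config).
#' @param minSep minimum separation (bp).
#' @param armRange min/max bases retained on each side of the scar.
#' @return \code{DNAStringSet} with provenance in \code{S4Vectors::mcols}:
#'   \code{isoform}, \code{site1}, \code{site2} (GATC motif starts, 0-based),
#'   \code{joinOffset} (0-based offset of "GATCGATC" in the read).
#' @export
simulateHiCPairs <- function(truth, n, exponent = NULL, minSep = 1000,
                             armRange = c(50L, 150L)) {
  mol <- .molecules(truth)
  cfg <- mol$config
  if (is.null(exponent))
    exponent <- if (!is.null(cfg)) cfg$hicExponent else 3
  if (exponent <= 1) stop("power-law exponent must exceed 1")
  seed <- if (!is.null(cfg)) cfg$seed else 1L
  set.seed(.substream(seed, .SEED_HIC))

  sites <- lapply(mol$seqs, function(s)
    as.integer(gregexpr("GATC", s, fixed = TRUE)[[1]]) - 1L)
  ok <- vapply(sites, function(p) length(p) >= 2 && p[1] >= 0, logical(1))
  if (!any(ok)) stop("no GATC sites in the genome; Hi-C cannot be simulated")

  lens <- nchar(mol$seqs)
  w <- mol$frequencies * lens * ok
  isoIdx <- sample.int(length(lens), n, replace = TRUE, prob = w)
  out <- character(n)
  s1 <- s2 <- joff <- integer(n)
  for (i in seq_len(n)) {
    ii <- isoIdx[i]
    L <- lens[ii]
    pos <- sites[[ii]]
    p1 <- sample(pos, 1L)
    # Pareto separation, capped at half the molecule
    d <- minSep * (1 - runif(1))^(-1 / (exponent - 1))
    d <- min(d, L / 2)
    dir <- sample(c(-1L, 1L), 1L)
    target <- (p1 + dir * as.integer(round(d))) %% L
    circDist <- pmin((pos - target) %% L, (target - pos) %% L)
    p2 <- pos[which.min(circDist)]
    a <- sample(armRange[1]:armRange[2], 1L)
    b <- sample(armRange[1]:armRange[2], 1L)
    left <- .extract(mol$seqs[ii], (p1 + 4L - a) %% L, a, mol$circular[ii])
    right <- .extract(mol$seqs[ii], p2, b + 4L, mol$circular[ii])
    out[i] <- paste0(left, right)
    s1[i] <- p1; s2[i] <- p2; joff[i] <- a - 4L
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- sprintf("hic%07d", seq_len(n))
  isoLabels <- names(mol$seqs)
  if (is.null(isoLabels)) isoLabels <- as.character(seq_along(lens))
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    isoform = isoLabels[isoIdx], site1 = s1, site2 = s2, joinOffset = joff)
  res
}

## ---------------------------------------------------------------------------
## Crossover products at a planted repeat

#' Recombination products of a direct-repeat crossover
#'
#' For a circular molecule with two direct copies of a repeat at positions
#' \code{p1 < p2} (0-based starts, length \code{repeatLength}), intramolecular
#' crossover between the copies splits the circle into two subcircles, each
#' retaining one repeat copy and carrying one novel junction.  These are the
#' minor recombinant isoforms whose mate-pair signature
#' \code{\link{detectRecombination}} looks for.
#'
#' @param seq character or \code{DNAString}: the parent circular sequence.
#' @param p1,p2 0-based start positions of the two repeat copies.
#' @param repeatLength repeat length (bp).
#' @return \code{DNAStringSet} of the two product circles (lengths
#'   \code{p2 - p1} and \code{L - (p2 - p1)}).
#' @export
crossoverProducts <- function(seq, p1, p2, repeatLength) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (!(p1 >= 0 && p1 < p2 && p2 + repeatLength <= L))
    stop("repeat copies must be ordered and inside the sequence")
  prodA <- substr(seq, p1 + 1L, p2)                       # copy1 ... C-REP-B
  prodB <- paste0(substr(seq, p2 + 1L, L), substr(seq, 1L, p1))  # A-REP-D
  res <- Biostrings::DNAStringSet(c(prodA, prodB))
  names(res) <- c("crossoverA", "crossoverB")
  res
}
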