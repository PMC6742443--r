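## Core domain types: genome fixtures, oriented-unit arrangements, isoform
## models, and small physical-conversion helpers shared by all stages.
##
## Coordinate convention: 0-based, half-open everywhere internally; 1-based
## inclusive only in exported GFF3-style tables (stated per format).

## ---------------------------------------------------------------------------
## Oriented-unit tokens
##
## An oriented unit is a token "<name><strand>", e.g. "K+" or "UV-".  An
## arrangement is a character vector of tokens; circular arrangements are
## read as closed walks (last token adjacent to first).

.tokenUnit <- function(tokens) sub("[+-]$", "", tokens)
.tokenStrand <- function(tokens) substr(tokens, nchar(tokens), nchar(tokens))

.checkTokens <- function(tokens) {
  ok <- grepl("^[A-Za-z0-9_.]+[+-]$", tokens)
  if (!all(ok))
    stop("malformed oriented-unit token(s): ",
         paste(tokens[!ok], collapse = ", "))
  invisible(tokens)
}

.flipTokens <- function(tokens) {
  s <- .tokenStrand(tokens)
  paste0(.tokenUnit(tokens), ifelse(s == "+", "-", "+"))
}

#' Reverse-complement traversal of an arrangement
#'
#' Reverses the order of the oriented-unit tokens and flips every strand,
#' i.e. the same walk read along the opposite DNA strand.
#'
#' @param tokens character vector of oriented-unit tokens such as
#'   \code{c("W+", "Z+")}.
#' @return character vector of the reflected arrangement.
#' @examples
#' reverseArrangement(c("W+", "Z-"))
#' @export
reverseArrangement <- function(tokens) {
  .checkTokens(tokens)
  rev(.flipTokens(tokens))
}

.arrKey <- function(tokens) paste(tokens, collapse = ",")

## lexicographically smaller of two token vectors, locale-independent
.minByKey <- function(a, b) {
  k <- c(.arrKey(a), .arrKey(b))
  list(a, b)[[order(k, method = "radix")[1]]]
}

#' Canonical form of an arrangement
#'
#' Circular arrangements of oriented units are only defined up to rotation
#' and up to reading along the opposite strand, and published linearizations
#' of circularly permuted genomes are arbitrary.  The canonical form is the
#' lexicographically minimal token string over all rotations of the
#' arrangement and of its reverse-complement traversal; linear arrangements
#' take the minimum of the arrangement and its reflection only.  The map is
#' idempotent.
#'
#' @param tokens character vector of oriented-unit tokens.
#' @param topology \code{"circular"} (default) or \code{"linear"}.
#' @return character vector: the canonical arrangement.
#' @examples
#' canonicalArrangement(c("B+", "A+"))          # -> c("A+", "B+")
#' canonicalArrangement(c("A+", "B-"))
#' @export
canonicalArrangement <- function(tokens, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  .checkTokens(tokens)
  if (length(tokens) == 0L) stop("arrangement must be non-empty")
  refl <- reverseArrangement(tokens)
  if (topology == "linear") {
    keys <- c(.arrKey(tokens), .arrKey(refl))
    return(list(tokens, refl)[[order(keys, method = "radix")[1]]])
  }
  n <- length(tokens)
  rots <- function(x) lapply(seq_len(n) - 1L,
                             function(k) c(x[seq_len(n) > k], x[seq_len(k)]))
  cand <- c(rots(tokens), rots(refl))
  keys <- vapply(cand, .arrKey, character(1))
  cand[[order(keys, method = "radix")[1]]]
}

## ---------------------------------------------------------------------------
## GenomeFixture

#' GenomeFixture: the primary structural units of one species
#'
#' Holds the ordered unit table (name, length, copy number, repeat flag) for
#' a mitochondrial genome.  Built-in fixtures for \emph{Lactuca sativa}
#' (11 units, 314,646 bp) and \emph{L. saligna} (10 units, 323,254 bp) are
#' available through \code{\link{loadFixture}}.
#'
#' @slot species character label.
#' @slot units data.frame with columns \code{name}, \code{length},
#'   \code{copyNumber}, \code{isRepeat}.
#' @export
setClass("GenomeFixture",
         representation(species = "character", units = "data.frame"))

setValidity("GenomeFixture", function(object) {
  u <- object@units
  need <- c("name", "length", "copyNumber", "isRepeat")
  if (!all(need %in% names(u)))
    return(paste("units table must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(u$name)) return("unit names must be unique")
  if (any(u$length < 1)) return("unit lengths must be >= 1")
  if (any(u$copyNumber < 1)) return("copy numbers must be >= 1")
  if (!identical(u$isRepeat, u$copyNumber >= 2L))
    return("isRepeat must equal copyNumber >= 2")
  TRUE
})

#' @describeIn GenomeFixture number of units
#' @param x,object a \code{GenomeFixture}.
#' @export
setMethod("length", "GenomeFixture", function(x) nrow(x@units))

#' @export
setMethod("show", "GenomeFixture", function(object) {
  cat("GenomeFixture:", object@species, "\n")
  cat(" ", nrow(object@units), "units,",
      sum(object@units$length), "bp non-redundant;",
      sum(object@units$isRepeat), "repeat unit(s):",
      paste(object@units$name[object@units$isRepeat], collapse = ", "), "\n")
})

#' Unit accessors for GenomeFixture
#'
#' @param fixture a \code{GenomeFixture}.
#' @return \code{unitNames}: character vector; \code{unitLengths},
#'   \code{copyNumbers}: named numeric vectors; \code{repeatUnits}:
#'   character vector of units with copy number >= 2.
#' @export
unitNames <- function(fixture) fixture@units$name

#' @rdname unitNames
#' @export
unitLengths <- function(fixture) setNames(fixture@units$length, fixture@units$name)

#' @rdname unitNames
#' @export
copyNumbers <- function(fixture) setNames(fixture@units$copyNumber, fixture@units$name)

#' @rdname unitNames
#' @export
repeatUnits <- function(fixture) fixture@units$name[fixture@units$isRepeat]

#' Construct a genome fixture from a unit table
#'
#' @param species character label.
#' @param names,lengths unit names and lengths (bp), parallel vectors.
#' @param repeats character vector of unit names present at copy number two.
#' @return a \code{GenomeFixture}.
#' @examples
#' genomeFixture("toy", c("A", "B", "R"), c(10000, 8000, 2000), repeats = "R")
#' @export
genomeFixture <- function(species, names, lengths, repeats = character(0)) {
  bad <- setdiff(repeats, names)
  if (length(bad)) stop("repeat unit(s) not in unit list: ",
                        paste(bad, collapse = ", "))
  cn <- ifelse(names %in% repeats, 2L, 1L)
  new("GenomeFixture", species = species,
      units = data.frame(name = names, length = as.integer(lengths),
                         copyNumber = cn, isRepeat = cn >= 2L,
                         stringsAsFactors = FALSE))
}

#' Built-in Lactuca unit-length fixtures
#'
#' Returns the hard-coded primary structural unit tables: 11 units summing to
#' 314,646 bp for \emph{L. sativa} (repeats M, N, R, T: the M-N pair behaves
#' as a single long repeat) and 10 units summing to 323,254 bp for
#' \emph{L. saligna} (repeats M, R, T).  With \code{splitUV = TRUE} the
#' composite saligna unit UV is split into U (38,613 bp) and V (51,410 bp),
#' mirroring the conceptual split used when comparing the two species; the
#' split point is a constructed convention, not a deposited coordinate.
#'
#' @param species \code{"sativa"} or \code{"saligna"}.
#' @param splitUV logical; saligna only, split unit UV into U and V.
#' @return a \code{\link{GenomeFixture}}.
#' @examples
#' sum(unitLengths(loadFixture("sativa")))   # 314646
#' sum(unitLengths(loadFixture("saligna")))  # 323254
#' @export
loadFixture <- function(species, splitUV = FALSE) {
  if (!is.character(species) || length(species) != 1L ||
      !(species %in% c("sativa", "saligna")))
    stop("unknown species '", species,
         "'; supported fixtures: sativa, saligna")
  if (species == "sativa") {
    fx <- genomeFixture("Lactuca sativa",
      names   = c("K", "L", "W", "U", "M", "P", "Z", "Q", "R", "N", "T"),
      lengths = c(78272, 44054, 53983, 38613, 30580, 20468, 19295, 11283,
                  10430, 4116, 3552),
      repeats = c("M", "N", "R", "T"))
  } else {
    if (splitUV) {
      fx <- genomeFixture("Lactuca saligna",
        names   = c("K", "L", "U", "V", "M", "P", "Z", "Q", "R", "S", "T"),
        lengths = c(79109, 43583, 38613, 51410, 30534, 20420, 19278, 11083,
                    10433, 14743, 4048),
        repeats = c("M", "R", "T"))
    } else {
      fx <- genomeFixture("Lactuca saligna",
        names   = c("K", "L", "UV", "M", "P", "Z", "Q", "R", "S", "T"),
        lengths = c(79109, 43583, 90023, 30534, 20420, 19278, 11083, 10433,
                    14743, 4048),
        repeats = c("M", "R", "T"))
    }
  }
  fx
}

#' Genome length implied by unit copy numbers
#'
#' Sum over units of length times copy number.  Units absent from
#' \code{copyNumbers} default to copy number one.
#'
#' @param fixture a \code{\link{GenomeFixture}}.
#' @param copyNumbers named numeric vector of per-unit copy numbers.
#' @return total length in bp.
#' @examples
#' isoformLength(loadFixture("sativa"),
#'               c(M = 2, N = 2, R = 2, T = 2))  # 363324
#' @export
isoformLength <- function(fixture, copyNumbers = NULL) {
  len <- unitLengths(fixture)
  cn <- setNames(rep(1, length(len)), names(len))
  if (!is.null(copyNumbers)) {
    bad <- setdiff(names(copyNumbers), names(len))
    if (length(bad)) stop("unknown unit name(s): ", paste(bad, collapse = ", "))
    cn[names(copyNumbers)] <- copyNumbers
  }
  sum(len * cn)
}

## ---------------------------------------------------------------------------
## Physical conversion: fluorescence-microscopy contour length

.KB_PER_UM <- 3.0   # contour conversion: 10 um of B-form DNA ~ 30 kb

#' Convert contour length between micrometres and kilobases
#'
#' Fluorescence microscopy measures molecule contour length in micrometres;
#' the conversion factor is fixed at 3.0 kb per micrometre (10 um
#' corresponding to approximately 30 kb of uncompacted DNA), matching the
#' arithmetic used for genome-scale molecules (121 um for a ~363 kb genome).
#'
#' @param um,kb non-negative lengths.
#' @return converted length (kb or um).
#' @examples
#' umToKb(37.6)  # ~113 kb
#' kbToUm(363)   # 121 um
#' @export
umToKb <- function(um) {
  if (any(um < 0)) stop("contour length must be non-negative")
  .KB_PER_UM * um
}

#' @rdname umToKb
#' @export
kbToUm <- function(kb) {
  if (any(kb < 0)) stop("contour length must be non-negative")
  kb / .KB_PER_UM
}

#' @rdname umToKb
#' @param lengthUm contour length(s) in micrometres.
#' @return \code{contourMeasure}: data.frame with \code{length_um} and
#'   \code{length_kb}.
#' @export
contourMeasure <- function(lengthUm) {
  data.frame(length_um = lengthUm, length_kb = umToKb(lengthUm))
}

## ---------------------------------------------------------------------------
## IsoformModel

#' IsoformModel: one full-genome arrangement of oriented units
#'
#' @slot label character, e.g. "alpha".
#' @slot topology \code{"circular"} or \code{"linear"}.
#' @slot arrangement character vector of oriented-unit tokens.
#' @slot unitLengths named numeric vector of unit lengths (bp).
#' @slot frequency estimated fraction of the molecule pool, in [0, 1]
#'   (\code{NA} when unknown).
#' @export
setClass("IsoformModel",
         representation(label = "character", topology = "character",
                        arrangement = "character", unitLengths = "numeric",
                        frequency = "numeric"))

setValidity("IsoformModel", function(object) {
  if (!(object@topology %in% c("circular", "linear")))
    return("topology must be 'circular' or 'linear'")
  if (length(object@arrangement) == 0L) return("arrangement must be non-empty")
  u <- .tokenUnit(object@arrangement)
  if (!all(u %in% names(object@unitLengths)))
    return("arrangement names unit(s) without a length")
  if (!all(.tokenStrand(object@arrangement) %in% c("+", "-")))
    return("strand must be '+' or '-'")
  f <- object@frequency
  if (length(f) != 1L || (!is.na(f) && (f < 0 || f > 1)))
    return("frequency must be a single value in [0, 1] or NA")
  TRUE
})

#' Construct an isoform model
#'
#' @param label isoform label.
#' @param arrangement character vector of oriented-unit tokens
#'   (e.g. \code{c("K+", "T+", "Q-")}).
#' @param fixture a \code{\link{GenomeFixture}} supplying unit lengths; the
#'   multiplicity of every unit in the arrangement must not exceed its copy
#'   number.  Alternatively pass \code{unitLengths} directly.
#' @param unitLengths named numeric vector, used when \code{fixture} is NULL
#'   (no copy-number check is possible then).
#' @param topology \code{"circular"} (default) or \code{"linear"}.
#' @param frequency fraction of the molecule pool, or NA.
#' @param canonical store the arrangement in canonical rotation (default TRUE
#'   for circular isoforms).
#' @return an \code{IsoformModel}.
#' @export
isoformModel <- function(label, arrangement, fixture = NULL,
                         unitLengths = NULL, topology = "circular",
                         frequency = NA_real_, canonical = TRUE) {
  .checkTokens(arrangement)
  if (!is.null(fixture)) {
    unitLengths <- unitLengths(fixture)
    cn <- copyNumbers(fixture)
    mult <- table(.tokenUnit(arrangement))
    bad <- setdiff(names(mult), names(cn))
    if (length(bad)) stop("arrangement names unknown unit(s): ",
                          paste(bad, collapse = ", "))
    over <- names(mult)[as.vector(mult) > cn[names(mult)]]
    if (length(over))
      stop("unit multiplicity exceeds copy number for: ",
           paste(over, collapse = ", "))
  }
  if (is.null(unitLengths)) stop("supply 'fixture' or 'unitLengths'")
  if (canonical) arrangement <- canonicalArrangement(arrangement, topology)
  new("IsoformModel", label = label, topology = topology,
      arrangement = arrangement,
      unitLengths = unitLengths[unique(.tokenUnit(arrangement))],
      frequency = as.numeric(frequency))
}

#' @describeIn isoformModel total length (bp) of the arrangement
#' @param iso an \code{IsoformModel}.
#' @export
totalLength <- function(iso) {
  sum(iso@unitLengths[.tokenUnit(iso@arrangement)])
}

#' @describeIn isoformModel the oriented-unit tokens
#' @export
arrangement <- function(iso) iso@arrangement

#' @export
setMethod("show", "IsoformModel", function(object) {
  cat("IsoformModel", object@label, sprintf("(%s)", object@topology), "\n")
  cat(" ", paste(object@arrangement, collapse = " "), "\n")
  cat(" ", totalLength(object), "bp",
      if (!is.na(object@frequency))
        sprintf("; frequency %.3f", object@frequency) else "", "\n", sep = "")
})

#' Reduce an isoform model to canonical form
#'
#' Applies \code{\link{canonicalArrangement}} to the stored arrangement;
#' idempotent.
#'
#' @param iso an \code{\link{IsoformModel}}.
#' @return the isoform with canonical arrangement.
#' @export
canonicalizeIsoform <- function(iso) {
  iso@arrangement <- canonicalArrangement(iso@arrangement, iso@topology)
  validObject(iso)
  iso
}

#' Unit coordinates along an isoform
#'
#' Tiles the isoform sequence with its oriented units: 0-based, half-open
#' intervals with no gaps or overlaps.
#'
#' @param iso an \code{\link{IsoformModel}}.
#' @return data.frame with \code{unit}, \code{strand}, \code{start},
#'   \code{end} (0-based half-open).
#' @export
isoformUnitCoords <- function(iso) {
  u <- .tokenUnit(iso@arrangement)
  len <- unname(iso@unitLengths[u])
  end <- cumsum(len)
  data.frame(unit = u, strand = .tokenStrand(iso@arrangement),
             start = c(0, head(end, -1L)), end = end,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Built-in isoform sets

#' Built-in major-isoform arrangements for the Lactuca fixtures
#'
#' Returns a list of \code{\link{IsoformModel}}s consistent with every
#' published structural constraint: for sativa, two circular isoforms alpha
#' and beta of 363,324 bp that contain the unit order M-N-K-M-N-W-Z and
#' differ by the exchange of units P and U between the repeat hinges R and T;
#' for saligna, two circular isoforms of 368,269 bp (UV split into U and V)
#' whose repeat-phased triples are exactly P-T-Q, P-T-L, K-T-L, K-T-Q around
#' T and Z-R-P, Z-R-U, L-R-U, L-R-P around R, with the integrated linear
#' plasmid unit S flanked by M on both sides.  The full unit orders are
#' constructed (the deposited arrangements were never printed in full), and
#' frequencies default to the equal stoichiometry observed for the major
#' isoforms.
#'
#' @param species \code{"sativa"} or \code{"saligna"}.
#' @return named list of two \code{IsoformModel}s (\code{alpha}, \code{beta}).
#' @examples
#' totalLength(majorIsoforms("sativa")$alpha)   # 363324
#' @export
majorIsoforms <- function(species) {
  if (species == "sativa") {
    fx <- loadFixture("sativa")
    arrA <- c("Q+", "M+", "N+", "K+", "M+", "N+", "W+", "Z+",
              "R+", "P+", "T+", "L+", "R+", "U+", "T+")
    arrB <- c("Q+", "M+", "N+", "K+", "M+", "N+", "W+", "Z+",
              "R+", "U+", "T+", "L+", "R+", "P+", "T+")
  } else if (species == "saligna") {
    fx <- loadFixture("saligna", splitUV = TRUE)
    arrA <- c("Q+", "T+", "P+", "R+", "L+", "T+", "K+", "Z+",
              "R+", "U+", "M+", "S+", "M+", "V+")
    arrB <- c("Z+", "R+", "P+", "T+", "L+", "R+", "U+", "M+",
              "S+", "M+", "V+", "K+", "T+", "Q+")
  } else stop("unknown species '", species,
              "'; supported: sativa, saligna")
  list(alpha = isoformModel("alpha", arrA, fixture = fx, frequency = 0.5),
       beta  = isoformModel("beta",  arrB, fixture = fx, frequency = 0.5))
}

## ---------------------------------------------------------------------------
## FASTA / manifest export

#' Random DNA sequence
#'
#' Uniform i.i.d. bases from the current RNG stream.
#' @param n length in bp.
#' @return a character string.
#' @export
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Export a fixture as FASTA plus a TSV manifest
#'
#' Writes one seeded random sequence of the fixed length per unit (wrapped
#' FASTA) and a manifest with unit, length and copy number.
#'
#' @param fixture a \code{\link{GenomeFixture}}.
#' @param fastaFile,manifestFile output paths (NULL to skip either).
#' @param seed RNG seed for the unit sequences.
#' @param width FASTA line width (60 or 80).
#' @return invisibly, the \code{Biostrings::DNAStringSet} of unit sequences.
#' @export
writeFixtureFasta <- function(fixture, fastaFile = NULL, manifestFile = NULL,
                              seed = 1L, width = 60L) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(
    vapply(unitLengths(fixture), randomDNA, character(1)))
  names(seqs) <- unitNames(fixture)
  if (!is.null(fastaFile))
    Biostrings::writeXStringSet(seqs, fastaFile, width = width)
  if (!is.null(manifestFile)) {
    u <- fixture@units
    write.table(u[, c("name", "length", "copyNumber")], manifestFile,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(seqs)
}
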