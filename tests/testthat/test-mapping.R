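test_that("makeTiling implements the window, step and tail rules", {
  # 3 kb unit: two windows, no tail needed
  t1 <- makeTiling(c(U = seededDNA(3000, 1)))
  expect_equal(t1$start, c(0, 1000))
  expect_equal(t1$end, c(2000, 3000))
  # 3,552 bp unit (the T analogue): tail fragment [1552, 3552)
  t2 <- makeTiling(c(T = seededDNA(3552, 2)))
  expect_equal(t2$start, c(0, 1000, 1552))
  expect_equal(t2$end, c(2000, 3000, 3552))
  # unit shorter than the window: one whole-unit fragment
  t3 <- makeTiling(c(S = seededDNA(1200, 3)))
  expect_equal(nrow(t3), 1L)
  expect_equal(c(t3$start, t3$end), c(0, 1200))
  # fragments reassemble the unit exactly: union covers [0, L)
  for (tt in list(t1, t2, t3)) {
    cov <- rep(FALSE, max(tt$end))
    for (i in seq_len(nrow(tt))) cov[(tt$start[i] + 1):tt$end[i]] <- TRUE
    expect_true(all(cov))
    expect_equal(nchar(tt$seq), tt$end - tt$start)
  }
  expect_error(makeTiling(character(0)), "no units")
  expect_error(makeTiling(c(U = "ACGT"), window = 10, step = 20),
               "window >= step")
})

test_that("alignLocal finds exact, reverse-complement and mutated matches", {
  target <- seededDNA(10000, 4)
  q <- substr(target, 3001, 5000)
  h <- alignLocal(q, target)
  expect_equal(h$identity[1], 1)
  expect_equal(h$alnLen[1], 2000)
  expect_equal(c(h$targetStart[1], h$targetEnd[1]), c(3000, 5000))
  expect_equal(h$strand[1], "+")
  # reverse complement maps on the minus strand, same interval
  qrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  h2 <- alignLocal(qrc, target)
  expect_equal(h2$strand[1], "-")
  expect_equal(c(h2$targetStart[1], h2$targetEnd[1]), c(3000, 5000))
  # 5% substitutions: identity near 0.95 over the same interval
  qmut <- withr::with_seed(5, mitoforms:::.substituteBases(q, 100))
  h3 <- alignLocal(qmut, target)
  expect_lt(abs(h3$identity[1] - 0.95), 0.01)
  expect_lt(abs(h3$targetStart[1] - 3000), 25)
  # zero hits on unrelated sequence is a valid result
  h4 <- alignLocal(seededDNA(500, 6), target)
  expect_equal(nrow(h4), 0L)
})

test_that("alignLocal agrees with full dynamic-programming local alignment", {
  # oracle: Biostrings Smith-Waterman on instances up to 300 bp
  withr::with_seed(8, {
    for (i in 1:15) {
      target <- randomDNA(1500)
      s <- sample(200:1100, 1)
      q <- mitoforms:::.substituteBases(substr(target, s, s + 299), 15)
      h <- alignLocal(q, target, minLen = 100)[1, ]
      pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(q),
                                          Biostrings::DNAString(target),
                                          type = "local")
      expect_lte(abs(h$targetStart - (Biostrings::start(
        Biostrings::subject(pa)) - 1L)), 2)
      expect_lte(abs(h$targetEnd - Biostrings::end(
        Biostrings::subject(pa))), 2)
      oId <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      expect_lte(abs(h$identity - oId), 0.02)
    }
  })
})

test_that("tiling maps onto reads in index order across junctions", {
  toy <- toyPipeline()
  # an error-free read over one full unit yields hits in index order
  unitA <- as.character(unitSequences(toy$truth)[["A"]])
  tiling <- toy$tiling
  h <- mapTilingToReads(tiling, Biostrings::DNAStringSet(c(rd = unitA)))
  hA <- h[h$unit == "A", ]
  expect_gte(nrow(hA), 7)   # 8 kb unit: 7 full windows + tail
  expect_true(all(diff(hA$fragIndex) > 0))
  expect_true(all(hA$strand == "+"))
  # an unrelated random read yields no hits
  h0 <- mapTilingToReads(tiling,
                         Biostrings::DNAStringSet(c(rd = seededDNA(5000, 9))))
  expect_equal(nrow(h0), 0L)
  # a read spanning the A|R junction shows terminal A then initial R hits
  gen <- as.character(isoformSequences(toy$truth)[["alpha"]])
  jread <- substr(gen, 8000 - 3999, 8000 + 2000)   # unit A tail + all of R
  hj <- mapTilingToReads(tiling, Biostrings::DNAStringSet(c(rd = jread)))
  hj <- hj[order(hj$readStart), ]
  units <- rle(hj$unit)$values
  expect_equal(units, c("A", "R"))
})

test_that("informative-read selection counts distinct fragments", {
  hits <- data.frame(
    readId = c(rep("r1", 12), rep("r2", 9), rep("r3", 12)),
    fragId = c(sprintf("A.%03d", 1:10), "A.001", "A.002",  # r1: 10 distinct
               sprintf("A.%03d", 1:9),                     # r2: 9 distinct
               sprintf("B.%03d", rep(1:6, 2))),            # r3: 6 distinct
    stringsAsFactors = FALSE)
  kept <- selectInformativeReads(hits, 10L)
  expect_identical(kept, "r1")
  expect_error(selectInformativeReads(hits, 0L), ">= 1")
})

test_that("plastid filtering drops pairs matching the decoy", {
  decoy <- seededDNA(20000, 10)
  mito <- seededDNA(20000, 11)
  r1 <- Biostrings::DNAStringSet(c(
    p1 = substr(decoy, 501, 600),              # exact decoy substring
    p2 = substr(mito, 1001, 1100),             # mitochondrial
    p3 = paste0(substr(decoy, 901, 980),       # 80% decoy chimera
                substr(mito, 2001, 2020))))
  r2 <- Biostrings::DNAStringSet(c(
    p1 = substr(mito, 3001, 3100),
    p2 = substr(mito, 4001, 4100),
    p3 = substr(mito, 5001, 5100)))
  out <- filterPlastid(r1, r2, decoy)
  expect_equal(unname(out$keep), c(FALSE, TRUE, TRUE))
  expect_equal(length(out$read1), 2L)
})

test_that("unit paths collapse runs with orientation and reject strays", {
  toy <- toyPipeline()
  # every informative unambiguous path is a contiguous subwalk of a
  # generating isoform (or its reverse complement) - checked via provenance
  doubledWalk <- function(iso) {
    toks <- iso@arrangement
    c(toks, toks)
  }
  walks <- lapply(toy$iso, function(i) doubledWalk(i))
  isSubwalk <- function(p, w) {
    wk <- paste(w, collapse = ",")
    grepl(paste(p, collapse = ","), wk, fixed = TRUE) ||
      grepl(paste(reverseArrangement(p), collapse = ","), wk, fixed = TRUE)
  }
  toks <- pathTokens(toy$paths)
  prov <- S4Vectors::mcols(toy$reads)
  ok <- vapply(names(toks), function(rid) {
    isoLabel <- prov$isoform[match(rid, names(toy$reads))]
    isSubwalk(toks[[rid]], walks[[isoLabel]])
  }, logical(1))
  expect_true(all(ok))
  # antitone fragment indices give a minus-strand token
  tiling <- toy$tiling
  unitB <- as.character(unitSequences(toy$truth)[["B"]])
  rcB <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unitB)))
  h <- mapTilingToReads(tiling, Biostrings::DNAStringSet(c(rd = rcB)))
  p <- unitPaths(h, tiling)
  expect_equal(p$path, "B-")
  # a single stray fragment hit inside another unit's run is dropped
  gen <- as.character(isoformSequences(toy$truth)[["alpha"]])
  rd <- substr(gen, 1001, 7000)    # inside unit A
  h2 <- mapTilingToReads(tiling, Biostrings::DNAStringSet(c(rd = rd)))
  stray <- h2[1, ]
  stray$unit <- "C"; stray$fragId <- "C.002"; stray$fragIndex <- 2L
  stray$readStart <- 2500L; stray$readEnd <- 4500L
  p2 <- unitPaths(rbind(h2, stray), tiling)
  expect_equal(p2$path, "A+")
})
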