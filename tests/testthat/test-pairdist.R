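test_that("distance matrices bin symmetrically and conserve counts", {
  pairs <- data.frame(pos1 = c(1500, 500, 7500), pos2 = c(3500, 1200, 7600))
  m <- pairDistanceMatrix(pairs, refLength = 10000, binSize = 1000,
                          subsample = Inf)
  cm <- binCounts(m)
  # pair at 1,500 / 3,500 increments bins (2,4) and (4,2) (1-based)
  expect_equal(cm[2, 4], 1)
  expect_equal(cm[4, 2], 1)
  # pairs at distance <= 1 kb are excluded (700 and 100 here)
  expect_equal(m@totalPairs, 1)
  expect_equal(sum(cm), 2 * m@totalPairs)
  expect_true(isTRUE(all.equal(cm, t(cm))))
  expect_error(pairDistanceMatrix(pairs, refLength = 500), "one bin")
})

test_that("subsampling is seeded and bounded", {
  withr::with_seed(71, {
    pairs <- data.frame(pos1 = sample(0:49999, 5000, replace = TRUE),
                        pos2 = sample(0:49999, 5000, replace = TRUE))
  })
  m1 <- pairDistanceMatrix(pairs, 50000, subsample = 1000, seed = 5)
  m2 <- pairDistanceMatrix(pairs, 50000, subsample = 1000, seed = 5)
  expect_equal(m1@totalPairs, 1000)
  expect_identical(binCounts(m1), binCounts(m2))
})

test_that("single-isoform mate pairs concentrate near the diagonal", {
  fx <- genomeFixture("one", "X", 60000)
  iso <- isoformModel("solo", "X+", fixture = fx, frequency = 1)
  tr <- generateGenome(simulationConfig(list(iso), seed = 73))
  mp <- simulateMatePairs(tr, n = 20000L, insertMean = 10000,
                          insertSd = 500)
  mapped <- mapShortReadPairs(mp$read1, mp$read2,
                              as.character(isoformSequences(tr)[[1]]))
  m <- pairDistanceMatrix(mapped, 60000, subsample = Inf)
  cm <- binCounts(m)
  nb <- nrow(cm)
  offd <- abs(row(cm) - col(cm))
  circOff <- pmin(offd, nb - offd)
  expect_gte(sum(cm[circOff <= 12]) / sum(cm), 0.99)
})

test_that("Hi-C reads split at the scar and rejoin exactly", {
  sp <- splitHiCReads(c(r1 = "AAGATCGATCTT"))
  expect_equal(as.character(sp$read1[[1]]), "AAGATC")
  expect_equal(as.character(sp$read2[[1]]), "GATCTT")
  # rejoining the sub-reads restores the original read
  expect_equal(paste0(as.character(sp$read1[[1]]),
                      as.character(sp$read2[[1]])), "AAGATCGATCTT")
  # reads without the dimer are discarded
  sp0 <- splitHiCReads(c(r1 = "AAGATCAGATCTT"))
  expect_equal(length(sp0$read1), 0L)
  # k dimers yield k consecutive pairs
  sp2 <- splitHiCReads(c(r1 = "AAGATCGATCTTGATCGATCCC"))
  expect_equal(length(sp2$read1), 2L)
  expect_equal(as.character(sp2$read2[[1]]), as.character(sp2$read1[[2]]))
})

test_that("simulated Hi-C pairs reconstruct contact distances", {
  fx <- genomeFixture("one", "X", 50000)
  iso <- isoformModel("solo", "X+", fixture = fx, frequency = 1)
  tr <- generateGenome(simulationConfig(list(iso), seed = 74))
  ref <- as.character(isoformSequences(tr)[[1]])
  hic <- simulateHiCPairs(tr, n = 2000, exponent = 3)
  sp <- splitHiCReads(hic)
  mapped <- mapShortReadPairs(sp$read1, sp$read2, ref)
  expect_gt(nrow(mapped), 1800)
  m <- pairDistanceMatrix(mapped, 50000, subsample = Inf)
  # strong distance decay: most contacts within 10 kb
  cm <- binCounts(m)
  nb <- nrow(cm)
  circOff <- pmin(abs(row(cm) - col(cm)), nb - abs(row(cm) - col(cm)))
  expect_gt(sum(cm[circOff <= 10]) / sum(cm), 0.5)
})

test_that("large-repeat hinges leave duplicated off-diagonal bands", {
  # a 6 kb repeat at two genome positions: multi-mapped pairs pile up at
  # bins relating the two copies when best placements are used
  parent <- seededDNA(60000, 75)
  p1 <- 10000L; p2 <- 35000L; repLen <- 6000L
  substr(parent, p2 + 1, p2 + repLen) <- substr(parent, p1 + 1, p1 + repLen)
  pool <- list(seqs = c(ref = parent), frequencies = 1, circular = TRUE,
               config = list(seed = 76L, shortReadLength = 100L,
                             shortReadError = 0))
  mp <- simulateMatePairs(pool, n = 30000L, insertMean = 5000,
                          insertSd = 300)
  mapped <- mapShortReadPairs(mp$read1, mp$read2, parent,
                              uniqueOnly = FALSE)
  m <- pairDistanceMatrix(mapped, 60000, subsample = Inf)
  cm <- binCounts(m)
  # reads inside copy 2 collapse onto copy 1, so their mates downstream of
  # copy 2 create a band pairing the copy-1 bins with bins one insert
  # beyond copy 2
  b <- function(x) x %/% 1000 + 1
  mask <- cm[b(p1):b(p1 + repLen), b(p2 + 4000):b(p2 + 11000)]
  # background: a same-size window at the same displacement in repeat-free
  # territory (no physical pairs at ~30 kb separation in a 5 kb library)
  bg <- cm[b(17000):b(23000), b(46900):b(52900)]
  expect_gte(sum(mask), 10 * max(1, sum(bg)))
})

test_that("a planted minor isoform is detected near its true frequency", {
  parent <- seededDNA(100000, 77)
  p1 <- 25000L; p2 <- 65000L; repLen <- 500L
  substr(parent, p2 + 1, p2 + repLen) <- substr(parent, p1 + 1, p1 + repLen)
  prods <- crossoverProducts(parent, p1, p2, repLen)
  pool <- list(seqs = c(major = parent, as.character(prods)),
               frequencies = c(9, 1, 1) / 11, circular = rep(TRUE, 3),
               config = list(seed = 78L, shortReadLength = 100L,
                             shortReadError = 0.001))
  mp <- simulateMatePairs(pool, n = 60000L, insertMean = 5000,
                          insertSd = 500)
  mapped <- mapShortReadPairs(mp$read1, mp$read2, parent, uniqueOnly = TRUE)
  m <- pairDistanceMatrix(mapped, 100000, subsample = Inf)
  sig <- detectRecombination(m, p1, p2, repLen, insertMean = 5000,
                             insertSd = 500)
  expect_equal(sig$flag, "ok")
  expect_gt(sig$frequency, 0.05)
  expect_lt(sig$frequency, 0.15)
  # monotonicity across planted frequencies
  est <- vapply(c(0.02, 0.10, 0.30), function(f) {
    pool$frequencies <- c(1 - f, f / 2, f / 2) /
      sum(c(1 - f, f / 2, f / 2))
    pool$config$seed <- 79L
    mp <- simulateMatePairs(pool, n = 40000L, insertMean = 5000,
                            insertSd = 500)
    mapped <- mapShortReadPairs(mp$read1, mp$read2, parent,
                                uniqueOnly = TRUE)
    m <- pairDistanceMatrix(mapped, 100000, subsample = Inf)
    detectRecombination(m, p1, p2, repLen, insertMean = 5000,
                        insertSd = 500)$frequency
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  # copies closer than the insert span are flagged unestimable
  sigBad <- detectRecombination(m, p1, p1 + 3000L, repLen,
                                insertMean = 5000, insertSd = 500)
  expect_equal(sigBad$flag, "unestimable")
})
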