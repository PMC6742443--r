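test_that("simulationConfig validates frequencies, rates and coverage", {
  iso <- toyIsoformPair()
  expect_error(simulationConfig(iso, frequencies = c(0.6, 0.6)), "sum to 1")
  expect_error(simulationConfig(iso, errorRates = c(sub = 0.5, ins = 0,
                                                    del = 0)), "0.2")
  expect_error(simulationConfig(iso, coverage = 0), "coverage")
  cfg <- simulationConfig(iso)
  expect_equal(cfg$coverage, 250)
  expect_equal(unname(cfg$errorRates), c(0.01, 0.01, 0.01))
})

test_that("generateGenome is deterministic and concatenates oriented units", {
  iso <- toyIsoformPair()
  cfg <- simulationConfig(iso, seed = 3)
  t1 <- generateGenome(cfg)
  t2 <- generateGenome(cfg)
  expect_identical(as.character(isoformSequences(t1)),
                   as.character(isoformSequences(t2)))
  expect_equal(unname(Biostrings::width(isoformSequences(t1))),
               rep(sum(toyLens) + toyLens[["R"]], 2))
  # single isoform of one unit reproduces that unit verbatim
  fx1 <- genomeFixture("one", "X", 10000)
  one <- isoformModel("solo", "X+", fixture = fx1, frequency = 1)
  tr <- generateGenome(simulationConfig(list(one), seed = 5))
  expect_identical(as.character(isoformSequences(tr)[[1]]),
                   as.character(unitSequences(tr)[["X"]]))
  # unknown unit in an isoform errors
  bad <- isoformModel("bad", "Q+", unitLengths = c(Q = 5000), frequency = 1)
  cfgBad <- simulationConfig(list(iso$alpha, bad), frequencies = c(0.5, 0.5))
  expect_silent(generateGenome(cfgBad))  # Q gets its own sequence
})

test_that("planted repeats are exact copies before errors", {
  fx <- toyFixture()
  iso <- isoformModel("solo", c("A+", "R+", "B+", "C+", "R+", "D+"),
                      fixture = fx, frequency = 1)
  cfg <- simulationConfig(list(iso), seed = 9, plantedRepeats = list(
    list(sourceUnit = "A", sourceStart = 1000L, length = 500L,
         targetUnit = "B", targetStart = 2000L),
    list(sourceUnit = "A", sourceStart = 3000L, length = 300L,
         targetUnit = "C", targetStart = 100L, orientation = "inverted")))
  tr <- generateGenome(cfg)
  us <- as.character(unitSequences(tr))
  expect_identical(substr(us[["B"]], 2001, 2500), substr(us[["A"]], 1001, 1500))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(us[["A"]], 3001, 3300))))
  expect_identical(substr(us[["C"]], 101, 400), rc)
})

test_that("long-read sampling hits coverage, frequencies and exactness", {
  iso <- toyIsoformPair(c(1, 0))
  cfg <- simulationConfig(iso, frequencies = c(1, 0), seed = 11,
                          coverage = 30, readLengthMean = 6000,
                          readLengthSd = 1500,
                          errorRates = c(sub = 0, ins = 0, del = 0))
  tr <- generateGenome(cfg)
  reads <- simulateLongReads(tr)
  # total bases near coverage x mean length (the last read may overshoot)
  target <- 30 * sum(Biostrings::width(isoformSequences(tr)) * c(1, 0))
  expect_lt(abs(sum(Biostrings::width(reads)) - target) / target, 0.05)
  # frequency 0 isoform contributes nothing
  expect_true(all(S4Vectors::mcols(reads)$isoform == "alpha"))
  # with zero error every read is an exact substring of the doubled circle
  doubled <- paste0(as.character(isoformSequences(tr)[["alpha"]]),
                    as.character(isoformSequences(tr)[["alpha"]]))
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  ok <- vapply(as.character(reads), function(s)
    grepl(s, doubled, fixed = TRUE) || grepl(rc(s), doubled, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
  # determinism: same config, same bytes
  reads2 <- simulateLongReads(generateGenome(cfg))
  expect_identical(as.character(reads), as.character(reads2))
})

test_that("isoform sampling proportions match configured frequencies", {
  iso <- toyIsoformPair(c(0.7, 0.3))
  cfg <- simulationConfig(iso, frequencies = c(0.7, 0.3), seed = 13,
                          coverage = 120, readLengthMean = 3000,
                          readLengthSd = 500)
  tr <- generateGenome(cfg)
  reads <- simulateLongReads(tr)
  n <- length(reads)
  pA <- mean(S4Vectors::mcols(reads)$isoform == "alpha")
  # binomial 99% CI around 0.7 (equal lengths, so weights equal frequencies)
  expect_lt(abs(pA - 0.7), 2.58 * sqrt(0.7 * 0.3 / n))
})

test_that("mate pairs follow the configured insert distribution", {
  iso <- toyIsoformPair(c(1, 0))
  cfg <- simulationConfig(iso, frequencies = c(1, 0), seed = 17)
  tr <- generateGenome(cfg)
  mp <- simulateMatePairs(tr, n = 10000L, insertMean = 10000,
                          insertSd = 500)
  expect_equal(length(mp$read1), 10000L)
  m <- mean(mp$provenance$insert)
  expect_lt(abs(m - 10000), 3 * 500 / sqrt(10000))
  # SD = 0 gives exactly the insert size
  mp0 <- simulateMatePairs(tr, n = 50L, insertMean = 5000, insertSd = 0)
  expect_true(all(mp0$provenance$insert == 5000))
  # insert must exceed twice the read length
  expect_error(simulateMatePairs(tr, n = 10, insertMean = 150,
                                 insertSd = 0), "twice the read length")
  # pairs spanning the circular origin wrap: pos2 < pos1 occurs and maps
  L <- Biostrings::width(isoformSequences(tr))[1]
  wrapped <- mp$provenance$pos2 < mp$provenance$pos1
  expect_gt(sum(wrapped), 0)
  i <- which(wrapped)[1]
  seq <- as.character(isoformSequences(tr)[[1]])
  r2 <- as.character(Biostrings::reverseComplement(mp$read2[[i]]))
  p2 <- mp$provenance$pos2[i]
  expect_identical(substr(paste0(seq, seq), p2 + 1, p2 + 100), r2)
})

test_that("Hi-C chimeras carry the ligation scar and decay with distance", {
  fx <- genomeFixture("one", "X", 40000)
  iso <- isoformModel("solo", "X+", fixture = fx, frequency = 1)
  tr <- generateGenome(simulationConfig(list(iso), seed = 19))
  hic <- simulateHiCPairs(tr, n = 400, exponent = 3)
  mc <- S4Vectors::mcols(hic)
  scar <- vapply(seq_along(hic), function(i)
    substr(as.character(hic[[i]]), mc$joinOffset[i] + 1,
           mc$joinOffset[i] + 8), character(1))
  expect_true(all(scar == "GATCGATC"))
  d <- pmin(abs(mc$site1 - mc$site2), 40000 - abs(mc$site1 - mc$site2))
  expect_gt(mean(d <= 10000), 0.5)
  # determinism
  hic2 <- simulateHiCPairs(tr, n = 400, exponent = 3)
  expect_identical(as.character(hic), as.character(hic2))
  # a genome without GATC errors
  noGatc <- Biostrings::DNAStringSet(c(X = paste(rep("ACCA", 2500),
                                                 collapse = "")))
  trBad <- generateGenome(simulationConfig(
    list(isoformModel("solo", "X+", unitLengths = c(X = 10000),
                      frequency = 1)),
    seed = 1, unitSeqs = noGatc))
  expect_error(simulateHiCPairs(trBad, n = 10), "GATC")
})

test_that("crossover products partition the parent circle", {
  parent <- seededDNA(30000, 23)
  p1 <- 8000L; p2 <- 20000L; rep <- 400L
  parent <- paste0(substr(parent, 1, p2),
                   substr(parent, p1 + 1, p1 + rep),
                   substr(parent, p2 + rep + 1, 30000))
  prods <- crossoverProducts(parent, p1, p2, rep)
  expect_equal(unname(Biostrings::width(prods)), c(p2 - p1, 30000 - (p2 - p1)))
  expect_error(crossoverProducts(parent, p2, p1, rep), "ordered")
})
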