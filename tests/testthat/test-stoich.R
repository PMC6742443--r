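test_that("interior coverage is flat for 1x units and doubled for repeats", {
  toy <- toyPipeline()
  cov <- unitCoverage(unitSequences(toy$truth),
                      toy$reads[toy$informative])
  ic <- interiorCoverage(cov)
  # interior fragment counts of a 1x unit are roughly constant
  dA <- cov[cov$unit == "A", ]
  dA <- dA[order(dA$index), ]
  interior <- dA$count[3:(nrow(dA) - 2)]
  expect_lt(sd(interior) / mean(interior), 0.2)
  # the 2x hinge runs at about twice the single-copy level
  base <- median(ic[c("A", "B", "C", "D")])
  expect_lt(abs(ic[["R"]] / base - 2), 0.4)
  cnt <- classifyCopyNumber(cov)
  expect_equal(setNames(cnt$copyNumber, cnt$unit)[c("A", "B", "C", "D", "R")],
               c(A = 1L, B = 1L, C = 1L, D = 1L, R = 2L))
})

test_that("sub-threshold alignments from short planted repeats do not count", {
  # a 600 bp repeat copied between two otherwise unrelated units can only
  # produce alignments below the 1.8 kb acceptance length
  fx <- genomeFixture("toy2", c("X", "Y"), c(6000, 6000))
  iso <- isoformModel("solo", c("X+", "Y+"), fixture = fx, frequency = 1)
  cfg <- simulationConfig(list(iso), seed = 31, coverage = 40,
                          plantedRepeats = list(
                            list(sourceUnit = "X", sourceStart = 2000L,
                                 length = 600L, targetUnit = "Y",
                                 targetStart = 3000L)))
  tr <- generateGenome(cfg)
  # reads drawn from unit X only: any alignment to Y can only cover the
  # planted 600 bp copy and stays below the acceptance length
  xSeq <- as.character(unitSequences(tr)[["X"]])
  reads <- Biostrings::DNAStringSet(vapply(seq(1, 2000, by = 100),
    function(s) substr(xSeq, s, s + 3999), character(1)))
  names(reads) <- sprintf("x%02d", seq_along(reads))
  cov <- unitCoverage(unitSequences(tr), reads)
  yCounts <- cov$count[cov$unit == "Y"]
  expect_true(all(yCounts == 0))
  expect_gt(sum(cov$count[cov$unit == "X"]), 0)
})

test_that("copy-number classification flags non-integer ratios", {
  means <- c(A = 100, B = 98, C = 103, D = 101, S = 150)
  cnt <- classifyCopyNumber(means)
  expect_true(cnt$flagged[cnt$unit == "S"])
  expect_false(any(cnt$flagged[cnt$unit != "S"]))
  # a single unit alone is copy number 1 by convention, low confidence
  one <- classifyCopyNumber(c(X = 77))
  expect_equal(one$copyNumber, 1L)
  expect_true(one$flagged)
})

test_that("junction library merges orientations and limits flanks", {
  units <- c(A = seededDNA(3000, 41), B = seededDNA(2500, 42),
             S = seededDNA(800, 43))
  # (A+,B+) and its reverse complement (B-,A-) are one junction
  jl <- junctionLibrary(units, c("A+,B+", "B-,A-"))
  expect_equal(nrow(jl), 1L)
  expect_equal(nchar(jl$seq), 2000)
  expect_identical(substr(jl$seq, 1, 1000), substr(units[["A"]], 2001, 3000))
  expect_identical(substr(jl$seq, 1001, 2000), substr(units[["B"]], 1, 1000))
  # a unit shorter than the flank contributes its full length
  jl2 <- junctionLibrary(units, c("S+,A+"))
  expect_equal(nchar(jl2$seq), 1800)
  expect_setequal(c(jl2$leftFlank, jl2$rightFlank), c(800, 1000))
})

test_that("breakpoint counting follows the uninterrupted-alignment rule", {
  bp <- alignmentBreakpoint(c(2000, 2000, 1900, 1200, 800))
  expect_equal(bp$support, 3L)
  expect_equal(bp$breakpointIndex, 3L)
  expect_equal(bp$sorted, c(2000, 2000, 1900, 1200, 800))
})

test_that("junction abundance separates real from absent junctions", {
  toy <- toyPipeline()
  units <- as.character(unitSequences(toy$truth))
  # A|R occurs in both isoforms; B|D occurs in neither
  jl <- junctionLibrary(units, c("A+,R+", "B+,D+"))
  ja <- junctionAbundance(jl, toy$reads[toy$informative])
  s <- setNames(ja$summary$support, ja$summary$junctionId)
  real <- s[grep("A", names(s))]
  absent <- s[grep("B", names(s))]
  expect_gt(unname(real), 10)
  expect_lt(unname(absent), 0.1 * unname(real))
  # the sorted curve for the real junction starts at the full fragment length
  curve <- ja$curves[[grep("A", names(ja$curves))]]
  expect_gte(curve[1], 1800)
})

test_that("alternative junctions at equal frequency get equal support", {
  toy <- toyPipeline()
  units <- as.character(unitSequences(toy$truth))
  # R's exits: R->B (alpha) and R->C (beta), planted at 50/50
  jl <- junctionLibrary(units, c("R+,B+", "R+,C+"))
  ja <- junctionAbundance(jl, toy$reads[toy$informative])
  s <- ja$summary$support
  expect_gt(min(s), 5)
  p <- suppressWarnings(chisq.test(s)$p.value)
  expect_gt(p, 0.01)
})

test_that("junction support obeys flow conservation through the hinge", {
  toy <- toyPipeline()
  units <- as.character(unitSequences(toy$truth))
  # entries into R: A->R and C->R / B->R; exits: R->B / R->C and R->D
  jl <- junctionLibrary(units, c("A+,R+", "C+,R+", "B+,R+",
                                 "R+,B+", "R+,C+", "R+,D+"))
  ja <- junctionAbundance(jl, toy$reads[toy$informative])
  s <- setNames(ja$summary$support, ja$summary$junctionId)
  into <- sum(s[c("A+|R+", "C+|R+", "B+|R+")], na.rm = TRUE)
  # exits appear under their canonical ids
  exits <- sum(s[setdiff(names(s), c("A+|R+", "C+|R+", "B+|R+"))])
  expect_lt(abs(into - exits), 4 * sqrt((into + exits) / 2))
})
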