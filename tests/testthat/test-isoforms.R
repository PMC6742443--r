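test_that("building blocks canonicalise orientation and honour support", {
  cn <- c(A = 1L, B = 1L, R = 2L)
  # a path and its reverse-complement traversal are one block
  paths <- list(r1 = c("A+", "B+"), r2 = c("B-", "A-"))
  bl <- buildingBlocks(paths, cn, minSupport = 2L)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$block, "A+,B+")
  expect_equal(bl$support, 2L)
  # repeat-centred windows require a non-repeat flank on both sides
  paths2 <- list(r1 = c("A+", "R+", "B+"), r2 = c("A+", "R+", "B+"),
                 r3 = c("R+", "B+"))
  bl2 <- buildingBlocks(paths2, cn, minSupport = 2L)
  expect_true("A+,R+,B+" %in% bl2$block)
  # support below the threshold is dropped
  bl3 <- buildingBlocks(list(r1 = c("A+", "R+", "B+")), cn, minSupport = 2L)
  expect_false("A+,R+,B+" %in% bl3$block)
})

test_that("the simulated hinge exchange yields the expected triple sets", {
  toy <- toyPipeline()
  tri <- toy$blocks[toy$blocks$length == 3, ]
  mid <- vapply(strsplit(tri$block, ","), function(x)
    sub("[+-]$", "", x[2]), character(1))
  rTri <- sort(tri$block[mid == "R"])
  expect_setequal(rTri, sort(c("A+,R+,B+", "A+,R+,C+",
                               "C+,R+,D+", "B+,R+,D+")))
})

test_that("graph construction validates units and stores constraints", {
  cn <- c(A = 1L, B = 1L, R = 2L)
  g <- buildJunctionGraph(c("A+,R+", "B-,R-", "A+,R+,B+"), cn,
                          unitLengths = c(A = 5000, B = 4000, R = 1000))
  expect_s3_class(g, "JunctionGraph")
  expect_equal(length(g$constraints), 1L)
  expect_error(buildJunctionGraph(c("A+,Q+"), cn), "absent from copyNumbers")
})

test_that("a simple cycle enumerates to exactly one isoform", {
  cn <- c(A = 1L, B = 1L, C = 1L)
  g <- buildJunctionGraph(c("A+,B+", "B+,C+", "A-,C-"), cn,
                          unitLengths = c(A = 10, B = 20, C = 30))
  isos <- enumerateIsoforms(g)
  expect_equal(length(isos), 1L)
  expect_equal(arrangement(isos[[1]]), c("A+", "B+", "C+"))
  expect_equal(totalLength(isos[[1]]), 60)
  # empty block list: no adjacencies, no walk, diagnostic attached
  g0 <- buildJunctionGraph(character(0), cn,
                           unitLengths = c(A = 10, B = 20, C = 30))
  isos0 <- enumerateIsoforms(g0)
  expect_equal(length(isos0), 0L)
  expect_match(attr(isos0, "diagnostic"), "adjacency")
})

test_that("enumeration equals the brute-force oracle on small graphs", {
  withr::with_seed(61, {
    for (trial in 1:6) {
      # random circular genome over <= 6 unit instances with one repeat
      nUnique <- sample(3:5, 1)
      units <- LETTERS[seq_len(nUnique)]
      cn <- setNames(rep(1L, nUnique), units)
      cn[sample(nUnique, 1)] <- 2L
      if (sum(cn) > 6) cn[cn == 2L][1] <- 1L
      instances <- rep(names(cn), cn)
      walk <- paste0(sample(instances),
                     sample(c("+", "-"), length(instances), replace = TRUE))
      # blocks observed from the walk: all pairs plus repeat windows
      isRep <- cn >= 2L
      n <- length(walk)
      pairs <- vapply(seq_len(n), function(i) {
        p <- c(walk[i], walk[if (i == n) 1L else i + 1L])
        paste(mitoforms:::.canonBlock(p), collapse = ",")
      }, character(1))
      wins <- mitoforms:::.repeatWindows(c(walk, walk[1:2]), isRep)
      winKeys <- vapply(wins, function(w)
        paste(mitoforms:::.canonBlock(w), collapse = ","), character(1))
      blocks <- unique(c(pairs, winKeys))
      g <- buildJunctionGraph(blocks, cn,
                              unitLengths = setNames(
                                rep(1000, nUnique), units))
      isos <- enumerateIsoforms(g)
      got <- sort(vapply(isos, function(i)
        paste(arrangement(i), collapse = ","), character(1)))
      want <- bruteForceIsoforms(cn, blocks)
      expect_identical(got, want)
      # the generating walk itself is always recovered
      expect_true(paste(canonicalArrangement(walk), collapse = ",") %in% got)
    }
  })
})

test_that("enumerated isoforms conserve length across modules", {
  toy <- toyPipeline()
  g <- buildJunctionGraph(toy$blocks, toy$cn, unitLengths = toyLens)
  isos <- enumerateIsoforms(g)
  fx <- toyFixture()
  for (iso in isos) {
    mult <- table(sub("[+-]$", "", arrangement(iso)))
    expect_equal(totalLength(iso),
                 isoformLength(fx, setNames(as.integer(mult), names(mult))))
  }
})

test_that("frequency scoring recovers planted mixtures from block supports", {
  iso <- toyIsoformPair()
  # clean multinomial draws at 0.7 / 0.3 from the isoform block sets
  blocks <- data.frame(
    block = c("A+,R+,B+", "C+,R+,D+",    # alpha windows
              "A+,R+,C+", "B+,R+,D+"),   # beta windows
    length = 3L,
    support = c(140, 140, 60, 60), stringsAsFactors = FALSE)
  sc <- scoreIsoforms(list(iso$alpha, iso$beta), blocks)
  expect_lt(abs(sc$frequencies[["alpha"]] - 0.7), 0.01)
  expect_false(sc$flagged)
  # a pure mixture pins the estimate to one
  blocks$support <- c(100, 100, 0, 0)
  sc1 <- scoreIsoforms(list(iso$alpha, iso$beta), blocks)
  expect_lt(abs(sc1$frequencies[["alpha"]] - 1), 0.01)
  # isoforms indistinguishable by the supplied blocks are flagged and tied
  shared <- data.frame(block = "A+,R+", length = 2L, support = 50L,
                       stringsAsFactors = FALSE)
  sc2 <- scoreIsoforms(list(iso$alpha, iso$beta), shared)
  expect_true(sc2$flagged)
  expect_equal(unname(sc2$frequencies), c(0.5, 0.5))
})

test_that("simulate-infer round trip returns the generating isoforms", {
  toy <- toyPipeline()
  g <- buildJunctionGraph(toy$blocks, toy$cn, unitLengths = toyLens)
  isos <- enumerateIsoforms(g)
  got <- vapply(isos, function(i) paste(arrangement(i), collapse = ","),
                character(1))
  want <- vapply(toy$iso, function(i)
    paste(canonicalArrangement(i@arrangement), collapse = ","), character(1))
  expect_true(all(want %in% got))
  # and the frequencies are recovered to first order
  sc <- scoreIsoforms(isos, toy$blocks)
  est <- sc$frequencies[match(want["alpha"], got)]
  expect_lt(abs(unname(est) - 0.5), 0.15)
})
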