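# Drift profiling, region calling, and the recursive scanner.

test_that("segmentation parameters are validated", {
  expect_s4_class(SegmentationParams(), "SegmentationParams")
  expect_error(SegmentationParams(window = 350), "odd")
  expect_error(SegmentationParams(window = 1), "odd")
  expect_error(SegmentationParams(threshold = 0), "threshold")
  expect_error(SegmentationParams(threshold = 1.5), "threshold")
  expect_error(SegmentationParams(window = 351, minLength = 100), "minLength")
  expect_error(SegmentationParams(mergeGap = -1), "mergeGap")
  expect_error(SegmentationParams(depth = -1), "depth")
  expect_error(SegmentationParams(mode = "fourier"), "mode")
})

test_that("drift profile is per-step displacement over a clamped window", {
  # motionless trace
  tr0 <- tpWalk("ACG")
  expect_error(driftProfile(tr0, window = 351), "larger than trace")
  still <- new("WalkTrace", positions = rep(0 + 0i, 61),
               moved = rep(FALSE, 60), seqid = "still")
  expect_equal(driftProfile(still, window = 5), rep(0, 60))
  # straight-line walk: interior exactly 1, edges still in (0, 1]
  step <- complex(real = -0.5, imaginary = -sqrt(3) / 2)
  straight <- new("WalkTrace", positions = cumsum(c(0 + 0i, rep(step, 60))),
                  moved = rep(TRUE, 60), seqid = "line")
  for (w in c(5, 21)) {
    p <- driftProfile(straight, window = w)
    h <- w %/% 2
    expect_equal(p[(h + 1):(60 - h)], rep(1, 60 - 2 * h))
    expect_true(all(p > 0 & p <= 1 + 1e-9))
  }
  # random traces stay within [0, 1]
  set.seed(31)
  p <- driftProfile(tpWalk(charsToString(randomChars(2000))), window = 351)
  expect_length(p, 2000)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(mean(p), 0.1)
})

test_that("real-part-slope mode uses the signed real difference", {
  step <- complex(real = -0.5, imaginary = -sqrt(3) / 2)
  straight <- new("WalkTrace", positions = cumsum(c(0 + 0i, rep(step, 30))),
                  moved = rep(TRUE, 30), seqid = "line")
  p <- driftProfile(straight, window = 5, mode = "real-part-slope")
  expect_equal(p[4], -0.5)   # negative real drift stays negative
})

test_that("region calling thresholds, merges, drops and scores runs", {
  params <- SegmentationParams(window = 51, minLength = 200,
                               mergeGap = 100, refineBoundaries = FALSE)
  expect_equal(nrow(callRegions(rep(0, 5000), params)), 0)
  # ideal step profile reproduces the designed interval exactly
  prof <- rep(0, 10244)
  prof[2000:7243] <- 1
  calls <- callRegions(prof, params)
  expect_equal(calls$start, 2000)
  expect_equal(calls$end, 7243)
  expect_equal(calls$score, 1)
  # two runs inside the merge gap become one call
  prof2 <- rep(0, 3000)
  prof2[1000:1400] <- 0.5
  prof2[1450:1900] <- 0.5
  merged <- callRegions(prof2, params)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(1000, 1900))
  # the same runs separated beyond the gap stay separate
  prof3 <- rep(0, 3000)
  prof3[1000:1400] <- 0.5
  prof3[1550:1990] <- 0.5
  expect_equal(nrow(callRegions(prof3, params)), 2)
  # short runs are dropped
  prof4 <- rep(0, 3000)
  prof4[1000:1100] <- 1
  expect_equal(nrow(callRegions(prof4, params)), 0)
})

test_that("raising the threshold never increases called bases (merge-free)", {
  set.seed(41)
  for (rep in 1:10) {
    # smooth nonnegative profile
    raw <- stats::filter(runif(3000), rep(1 / 101, 101), sides = 2)
    prof <- as.numeric(raw)
    prof[is.na(prof)] <- 0
    base <- SegmentationParams(window = 51, minLength = 51, mergeGap = 0,
                               refineBoundaries = FALSE)
    taus <- sort(runif(4, 0.3, 0.7))
    called <- vapply(taus, function(tau) {
      p <- SegmentationParams(window = 51, minLength = 51, mergeGap = 0,
                              threshold = tau, refineBoundaries = FALSE)
      cc <- callRegions(prof, p)
      sum(cc$end - cc$start + 1)
    }, numeric(1))
    expect_true(all(diff(called) <= 0))
  }
})

test_that("a single codon-biased insert is called within 100 bases of truth", {
  fx <- buildFixture(10000, insertLengths = 3000, insertPositions = 5000,
                     seed = 1)
  calls <- scanSequence(fx$sequence)
  expect_equal(length(calls), 1)
  err <- boundaryErrors(calls, fx$truth)
  expect_true(all(err <= 100))
  expect_true(all(calls$score > 0.15))
})

test_that("calls are disjoint and sorted; pure background yields none", {
  fx <- buildFixture(20000, insertLengths = c(3000, 3000),
                     insertPositions = c(4000, 15000), seed = 9)
  calls <- scanSequence(fx$sequence)
  expect_equal(length(calls), 2)
  s <- GenomicRanges::start(calls); e <- GenomicRanges::end(calls)
  expect_true(all(diff(s) > 0))
  expect_true(all(s[-1] > e[-length(e)]))   # disjoint
  # each truth interval recovered within 100 bases
  for (i in 1:2) {
    err <- boundaryErrors(calls[i], fx$truth[i])
    expect_true(all(err <= 100))
  }
  bg <- randomBackground(10000, seed = 13)
  expect_equal(length(scanSequence(bg)), 0)
})

test_that("refinement is a no-op when the first pass finds everything", {
  fx <- buildFixture(8000, insertLengths = 3000, insertPositions = 3000,
                     seed = 55)
  d0 <- refineRecursive(fx$sequence, SegmentationParams(depth = 0))
  d3 <- refineRecursive(fx$sequence, SegmentationParams(depth = 3))
  expect_equal(d0[, c("start", "end", "score")],
               d3[, c("start", "end", "score")])
  expect_true(all(d0$pass == 1))
  # driftless input returns an empty frame at any depth
  none <- refineRecursive(randomBackground(5000, seed = 3),
                          SegmentationParams(depth = 2))
  expect_equal(nrow(none), 0)
})

test_that("recursive calls from deeper passes map back to original coordinates", {
  # force a second pass by hiding a region from pass 1: scan with a high
  # threshold profile on pass 1 is not parameterisable per pass, so
  # instead check the recursion exhaustively via provenance on a
  # two-insert fixture where both passes run
  fx <- buildFixture(20000, insertLengths = c(3000, 3000),
                     insertPositions = c(4000, 15000), seed = 9)
  df <- refineRecursive(fx$sequence, SegmentationParams(depth = 2))
  expect_true(all(df$pass >= 1))
  expect_true(all(df$start >= 1 &
                    df$end <= length(fx$sequence)))
  expect_true(!is.unsorted(df$start))
  # flanking re-scan never calls across an excision join: all calls from
  # later passes are disjoint from pass-1 calls
  p1 <- df[df$pass == 1, ]
  pn <- df[df$pass > 1, ]
  if (nrow(pn) > 0) {
    for (i in seq_len(nrow(pn)))
      expect_true(all(pn$start[i] > p1$end | pn$end[i] < p1$start))
  }
})

test_that("both-strand scanning reports reverse-complement calls with strand", {
  fx <- buildFixture(6000, insertLengths = 2400, insertPositions = 3000,
                     seed = 19)
  rc <- Biostrings::reverseComplement(fx$sequence)
  xs <- Biostrings::DNAStringSet(rc)
  names(xs) <- "rcfix"
  calls <- scanSequence(xs, bothStrands = TRUE)
  minus <- calls[BiocGenerics::strand(calls) == "-"]
  expect_gte(length(minus), 1)
  # the minus-strand call covers the insert in forward coordinates
  N <- length(fx$sequence)
  truRC <- c(N - 5399 + 1, N - 3000 + 1)   # insert 3000..5399 mirrored
  expect_lt(abs(GenomicRanges::start(minus)[1] - truRC[1]), 200)
  expect_lt(abs(GenomicRanges::end(minus)[1] - truRC[2]), 200)
})
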