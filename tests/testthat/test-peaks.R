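mkTrack <- function(pos0, L = 100000L, chrom = "chr1", antibody = "ab",
                    condition = "control") {
  sl <- setNames(as.integer(L), chrom)
  gr <- GRanges(rep(chrom, length(pos0)), IRanges(pos0 + 1L, pos0 + 1L))
  seqlevels(gr) <- names(sl); seqlengths(gr) <- sl
  TagTrack(gr, antibody, condition)
}

test_that("window binning follows fixed tiling from position zero", {
  tr <- mkTrack(c(0L, 199L, 200L), L = 1000L)
  b <- binTags(tr, 200)
  expect_equal(b$count, c(2L, 1L, 0L, 0L, 0L))
  expect_equal(b$start, c(1L, 201L, 401L, 601L, 801L))
  expect_equal(sum(b$count), 3L)                 # conservation
  empty <- mkTrack(integer(), L = 1000L)
  expect_true(all(binTags(empty, 200)$count == 0L))
})

test_that("island p-values equal the Poisson survival closed form", {
  # single eligible window with count 10 against a small scaled expectation
  cfg <- peakCallingConfig("broad", pCutoff = 1e-5, pseudocount = 0.25)
  treat <- mkTrack(rep(100L, 10L), L = 10000L)
  ctrl <- mkTrack(sample.int(10000L, 10L) - 1L, L = 10000L)
  pk <- callIslands(treat, ctrl, cfg)
  expect_equal(length(pk), 1L)
  expect_equal(pk$pvalue, ppois(pk$count - 1, pk$expected,
                                lower.tail = FALSE))
  # closed-form agreement of the enrichment statistic with a direct series
  for (lam in c(0.1, 1, 10))
    for (cnt in c(1L, 5L, 20L))
      expect_equal(poissonEnrichmentP(cnt, lam),
                   oraclePoissonUpper(cnt, lam), tolerance = 1e-13)
})

test_that("no tags or self-comparison yield no islands", {
  cfg <- peakCallingConfig("broad")
  empty <- mkTrack(integer(), L = 100000L)
  ctrl <- mkTrack(sample.int(100000L, 200L) - 1L, L = 100000L)
  expect_equal(length(callIslands(empty, ctrl, cfg)), 0L)
  # identical treatment and control: nothing survives a strong cutoff
  set.seed(21)
  pos <- sample.int(100000L, 500L, replace = TRUE) - 1L
  same <- callIslands(mkTrack(pos), mkTrack(pos), cfg)
  expect_equal(length(same), 0L)
})

test_that("islands match brute-force enumeration on toy genomes", {
  set.seed(17)
  for (rep_ in 1:4) {
    sl <- c(chrA = 30000L, chrB = 20000L)
    treat <- randomTagTrack(300L, sl,
      hotspots = list(list(chrom = "chrA", start = 5000L, end = 5600L,
                           n = 60L),
                      list(chrom = "chrB", start = 9000L, end = 9400L,
                           n = 40L)))
    ctrl <- randomTagTrack(300L, sl, condition = "input")
    for (cfg in list(peakCallingConfig("broad", pCutoff = 1e-5),
                     peakCallingConfig("narrow"))) {
      got <- callIslands(treat, ctrl, cfg)
      want <- oracleIslands(treat, ctrl, cfg)
      if (is.null(want)) {
        expect_equal(length(got), 0L)
      } else {
        expect_equal(as.character(seqnames(got)), want$chrom)
        expect_equal(start(got), want$start)
        expect_equal(end(got), want$end)
        expect_equal(got$count, want$count)
        expect_equal(got$expected, want$expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("gaps between called islands always exceed the gap parameter", {
  set.seed(31)
  sl <- c(chrA = 50000L)
  treat <- randomTagTrack(2000L, sl)
  ctrl <- randomTagTrack(500L, sl, condition = "input")
  cfg <- peakCallingConfig("broad", pCutoff = 0.5, windowP = 0.5)
  pk <- callIslands(treat, ctrl, cfg)
  expect_gt(length(pk), 1L)
  expect_true(all(start(pk)[-1L] - end(pk)[-length(pk)] - 1L > cfg$gap))
})

test_that("loosening the island cutoff only adds islands", {
  set.seed(8)
  sl <- c(chrA = 50000L)
  treat <- randomTagTrack(800L, sl,
    hotspots = list(list(chrom = "chrA", start = 10000L, end = 10800L,
                         n = 50L)))
  ctrl <- randomTagTrack(800L, sl, condition = "input")
  strict <- callIslands(treat, ctrl,
                        peakCallingConfig("broad", pCutoff = 1e-8))
  loose <- callIslands(treat, ctrl,
                       peakCallingConfig("broad", pCutoff = 1e-3))
  expect_true(all(countOverlaps(strict, loose, type = "equal") == 1L))
})

test_that("differential calling is the condition swap of the same caller", {
  set.seed(5)
  sl <- c(chrA = 100000L)
  # fold-enriched region present only in condition A
  a <- randomTagTrack(1000L, sl, condition = "control",
    hotspots = list(list(chrom = "chrA", start = 40000L, end = 41000L,
                         n = 120L)))
  b <- randomTagTrack(1000L, sl, condition = "kd")
  cfg <- peakCallingConfig("narrow")
  aOverB <- callDifferential(a, b, cfg)
  bOverA <- callDifferential(b, a, cfg)
  expect_true(any(start(aOverB) <= 41000 & end(aOverB) >= 40000))
  expect_equal(length(bOverA), 0L)
  # the conditional binomial p-value of each island matches a direct
  # recomputation from the raw tag counts in its span
  for (i in seq_along(aOverB)) {
    t_ <- sum(countOverlaps(tagPositions(a), aOverB[i]))
    c_ <- sum(countOverlaps(tagPositions(b), aOverB[i]))
    q <- tagCount(a) / (tagCount(a) + tagCount(b))
    expect_equal(aOverB$pvalue[i],
                 pbinom(t_ - 1, t_ + c_, q, lower.tail = FALSE))
  }
  # self-comparison never yields differential islands
  expect_equal(length(callDifferential(a, a, cfg)), 0L)
})

test_that("classification derives COMMON/INCREASE/DECREASE from overlaps", {
  sl <- c(chr1 = 100000L)
  g <- function(s, e) dfToGr(data.frame(chrom = "chr1", start = s, end = e),
                             sl)
  # identical standard sets, no differential peaks: all COMMON
  std <- g(c(1000, 5000), c(1400, 5400))
  cp <- classifyPeaks(std, std, std[0], std[0], antibody = "X")
  expect_equal(length(peakClass(cp, "COMMON")), 2L)
  expect_equal(length(peakClass(cp, "INCREASE")), 0L)
  expect_equal(length(peakClass(cp, "DECREASE")), 0L)
  # a ctrl-only peak overlapped by a ctrl-over-kd differential peak
  ctrl <- g(1000, 1400); kd <- g(50000, 50400)
  dCK <- g(1100, 1300)
  cp2 <- classifyPeaks(ctrl, kd, dCK, kd[0], antibody = "X")
  expect_equal(start(peakClass(cp2, "DECREASE")), 1000L)
  expect_equal(length(peakClass(cp2, "COMMON")), 0L)
})

test_that("INCREASE/DECREASE conflicts resolve by larger overlap, ties drop", {
  sl <- c(chr1 = 100000L)
  g <- function(s, e) dfToGr(data.frame(chrom = "chr1", start = s, end = e),
                             sl)
  ctrl <- g(1000, 2000); kd <- g(1500, 2500)       # overlapping standards
  dCK <- g(1000, 1100)                             # 101 bp of ctrl peak
  dKC <- g(1500, 2400)                             # 901 bp of kd peak
  cp <- classifyPeaks(ctrl, kd, dCK, dKC, antibody = "X")
  expect_equal(length(peakClass(cp, "INCREASE")), 1L)   # larger overlap wins
  expect_equal(length(peakClass(cp, "DECREASE")), 0L)
  # exact tie: both dropped and recorded
  dCK2 <- g(1901, 2000)                            # 100 bp of ctrl peak
  dKC2 <- g(1500, 1599)                            # 100 bp of kd peak
  cp2 <- classifyPeaks(ctrl, kd, dCK2, dKC2, antibody = "X")
  expect_equal(length(peakClass(cp2, "INCREASE")), 0L)
  expect_equal(length(peakClass(cp2, "DECREASE")), 0L)
  expect_equal(length(cp2@dropped), 2L)
})
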