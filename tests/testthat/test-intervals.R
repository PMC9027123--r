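test_that("half-open abutting intervals do not overlap, identity pairs fully", {
  a <- GRanges("chr1", IRanges(1, 100))      # [0,100) half-open
  b <- GRanges("chr1", IRanges(101, 200))    # [100,200)
  expect_equal(nrow(overlapPairs(a, b)), 0L)

  x <- GRanges("chr1", IRanges(c(1, 50), c(40, 120)))
  p <- overlapPairs(x, x)
  self <- p[p$aIdx == p$bIdx, ]
  expect_equal(nrow(self), 2L)
  expect_equal(self$intWidth, width(x))
})

test_that("overlap intersections match the exhaustive per-pair oracle", {
  # a = {[0,100),[200,300)}, b = {[50,250)} -> {[50,100),[200,250)}
  a <- GRanges("chr1", IRanges(c(1, 201), c(100, 300)))
  b <- GRanges("chr1", IRanges(51, 250))
  p <- overlapPairs(a, b)
  expect_equal(p$intStart, c(51, 201))
  expect_equal(p$intEnd, c(100, 250))

  set.seed(42)
  adf <- randomIntervalDf(120, c("chrA", "chrB"), 50000L)
  bdf <- randomIntervalDf(120, c("chrA", "chrB"), 50000L)
  got <- overlapPairs(dfToGr(adf), dfToGr(bdf))
  want <- oracleOverlapPairs(adf, bdf)
  expect_equal(got, want)
})

test_that("overlap is symmetric in its arguments", {
  set.seed(7)
  adf <- randomIntervalDf(60, "chrA", 20000L)
  bdf <- randomIntervalDf(60, "chrA", 20000L)
  ab <- overlapPairs(dfToGr(adf), dfToGr(bdf))
  ba <- overlapPairs(dfToGr(bdf), dfToGr(adf))
  expect_setequal(paste(ab$aIdx, ab$bIdx), paste(ba$bIdx, ba$aIdx))
})

test_that("merge joins across gaps up to the cap and is idempotent", {
  sl <- c(chr1 = 100000L)
  # gap exactly 600 merges; 601 does not
  x <- dfToGr(data.frame(chrom = "chr1", start = c(1, 801),
                         end = c(200, 1000)), sl)
  expect_equal(as.data.frame(mergeIntervals(x, 600))[, 2:3],
               data.frame(start = 1L, end = 1000L))
  y <- dfToGr(data.frame(chrom = "chr1", start = c(1, 802),
                         end = c(200, 1000)), sl)
  expect_equal(length(mergeIntervals(y, 600)), 2L)
  # single interval unchanged
  z <- dfToGr(data.frame(chrom = "chr1", start = 5, end = 50), sl)
  expect_equal(start(mergeIntervals(z, 600)), 5L)

  set.seed(13)
  df <- randomIntervalDf(200, "chr1", 50000L)
  for (gap in c(0L, 10L, 600L)) {
    m <- mergeIntervals(dfToGr(df, sl), gap)
    o <- oracleMergePerBase(df, gap, sl)
    expect_equal(data.frame(start = start(m), end = end(m)),
                 o[, c("start", "end")], ignore_attr = TRUE)
    expect_identical(mergeIntervals(m, gap), m)   # idempotence
    if (length(m) > 1L)                            # island-gap invariant
      expect_true(all(start(m)[-1L] - end(m)[-length(m)] - 1L > gap))
  }
})

test_that("nearest assignment respects the cap and matches the scan oracle", {
  q <- GRanges("chr1", IRanges(10001, 10001))
  s <- GRanges("chr1", IRanges(c(50001, 200001), c(51000, 201000)))
  nn <- nearestWithin(q, s, maxDistance = 100000)
  expect_equal(nn$subjectIdx, 1L)
  expect_equal(nn$distance, 50001L - 10001L - 1L)
  # only the far subject: outside the cap
  nn2 <- nearestWithin(q, s[2], maxDistance = 100000)
  expect_true(is.na(nn2$subjectIdx))
  # overlapping subject at distance 0
  nn3 <- nearestWithin(GRanges("chr1", IRanges(50500, 50600)), s, 100000)
  expect_equal(nn3$distance, 0L)
  # empty subjects
  expect_true(is.na(nearestWithin(q, s[0], 1e5)$subjectIdx))

  set.seed(3)
  qdf <- randomIntervalDf(80, c("chrA", "chrB"), 100000L)
  sdf <- randomIntervalDf(40, c("chrA", "chrB"), 100000L)
  got <- nearestWithin(dfToGr(qdf), dfToGr(sdf), maxDistance = 5000)
  want <- oracleNearestScan(qdf, sdf, 5000)
  expect_equal(got$distance, want$distance)
  # subject identity may differ only between equal-distance ties; the
  # package breaks ties towards the smaller start
  mism <- which(!is.na(got$subjectIdx) & got$subjectIdx != want$subjectIdx)
  expect_equal(sdf$start[got$subjectIdx[mism]],
               sdf$start[want$subjectIdx[mism]])
})

test_that("BED round trip is coordinate-exact for BED3 and BED6", {
  sl <- c(chrX = 100000L)
  gr <- dfToGr(data.frame(chrom = "chrX", start = c(1, 500, 99901),
                          end = c(100, 1500, 100000)), sl)
  f3 <- tempfile(fileext = ".bed")
  writeBed(gr, f3)
  back <- readBed(f3, seqlengths = sl)
  expect_identical(ranges(back), ranges(gr))
  # BED6 with names and scores
  gr$gene_id <- c("a", "b", "c")
  f6 <- tempfile(fileext = ".bed")
  writeBed(gr, f6, name = "gene_id", score = c(1, 2, 3))
  back6 <- readBed(f6, seqlengths = sl)
  expect_identical(ranges(back6), ranges(gr))
  expect_equal(back6$name, c("a", "b", "c"))
  expect_equal(as.numeric(back6$score), c(1, 2, 3))
})

test_that("gene models load from BED6 and minimal GTF identically", {
  sl <- c(chr1 = 50000L)
  gr <- dfToGr(data.frame(chrom = "chr1", start = c(1001, 9001),
                          end = c(3000, 12000)), sl)
  strand(gr) <- c("+", "-")
  gr$gene_id <- c("g1", "g2")
  fb <- tempfile(fileext = ".bed")
  writeBed(gr, fb, name = "gene_id")
  fromBed <- readGeneModels(fb, seqlengths = sl)
  expect_identical(ranges(fromBed), ranges(gr))
  expect_equal(fromBed$gene_id, c("g1", "g2"))

  fg <- tempfile(fileext = ".gtf")
  writeLines(sprintf(
    'chr1\tsynth\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    start(gr), end(gr), strand(gr), gr$gene_id), fg)
  fromGtf <- readGeneModels(fg, seqlengths = sl)
  expect_identical(ranges(fromGtf), ranges(gr))
  expect_equal(as.character(strand(fromGtf)), c("+", "-"))
  expect_equal(fromGtf$gene_id, c("g1", "g2"))
})
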