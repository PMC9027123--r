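#' @include enhancer.R
NULL

#' Per-peak tag coverage matrix around peak centres
#'
#' For each peak centre, counts tags at every offset in `-halfwidth ..
#' +halfwidth`. Peaks are collapsed to their centre base; offsets reaching
#' past a chromosome end simply accumulate no tags (the corresponding
#' centres are flagged).
#'
#' @param track a [TagTrack-class].
#' @param peaks `GRanges` of peaks (centres are taken as the midpoint) or of
#'   1 bp centre positions.
#' @param halfwidth window half-width in bp (default 2500).
#' @return Integer matrix of dimension `length(peaks)` x `2 * halfwidth +
#'   1`, with offset colnames; attribute `clipped` flags centres whose
#'   window crossed a chromosome boundary.
#' @export
coverageMatrix <- function(track, peaks, halfwidth = 2500L) {
  stopifnot(is(track, "TagTrack"), is(peaks, "GRanges"), halfwidth >= 0)
  halfwidth <- as.integer(halfwidth)
  offsets <- -halfwidth:halfwidth
  centre <- (start(peaks) + end(peaks)) %/% 2L
  n <- length(peaks)
  mat <- matrix(0L, nrow = n, ncol = length(offsets),
                dimnames = list(NULL, offsets))
  sl <- seqlengths(peaks)[as.character(seqnames(peaks))]
  clipped <- centre - halfwidth < 1L |
    (!is.na(sl) & centre + halfwidth > sl)
  if (n && tagCount(track)) {
    wins <- GRanges(seqnames(peaks),
                    IRanges(pmax(centre - halfwidth, 1L),
                            centre + halfwidth))
    tags <- tagPositions(track)
    seqlevels(wins) <- seqlevels(tags)
    h <- findOverlaps(wins, tags, ignore.strand = TRUE)
    if (length(h)) {
      off <- start(tags)[subjectHits(h)] - centre[queryHits(h)]
      # tags can stack on one base: accumulate into a flat bin index
      li <- (off + halfwidth) * n + queryHits(h)
      mat <- mat + matrix(tabulate(li, nbins = n * length(offsets)),
                          nrow = n, dimnames = dimnames(mat))
    }
  }
  attr(mat, "clipped") <- as.logical(clipped)
  mat
}

#' Average a coverage matrix and smooth it with LOESS
#'
#' Column means of the per-peak coverage matrix give the raw average
#' binding profile; local linear regression (LOESS, tricube weights,
#' degree 1, exact fit surface) over the offsets smooths it. Local linear
#' smoothing reproduces constant and exactly linear profiles.
#'
#' @param mat coverage matrix from [coverageMatrix()] (>= 1 row).
#' @param span LOESS span (default 0.3).
#' @return A `data.frame` of class `CoverageProfile` with columns `offset`,
#'   `mean`, `smoothed`; attributes `nPeaks` and `span`.
#' @export
averageAndSmooth <- function(mat, span = 0.3) {
  if (!is.matrix(mat) || nrow(mat) < 1L)
    stop("coverage matrix must have at least one row")
  stopifnot(span > 0)
  offset <- as.integer(colnames(mat))
  mu <- colMeans(mat)
  fit <- loess(mu ~ offset, span = span, degree = 1, family = "gaussian",
               surface = "direct")
  sm <- as.numeric(predict(fit, data.frame(offset = offset)))
  out <- data.frame(offset = offset, mean = as.numeric(mu), smoothed = sm)
  attr(out, "nPeaks") <- nrow(mat)
  attr(out, "span") <- span
  class(out) <- c("CoverageProfile", "data.frame")
  out
}

#' Average binding profile of a track over peak centres
#'
#' Convenience wrapper: [coverageMatrix()] then [averageAndSmooth()].
#'
#' @inheritParams coverageMatrix
#' @inheritParams averageAndSmooth
#' @return A `CoverageProfile` data frame.
#' @export
bindingProfile <- function(track, peaks, halfwidth = 2500L, span = 0.3) {
  averageAndSmooth(coverageMatrix(track, peaks, halfwidth), span)
}

#' Plot a binding profile
#'
#' @param x a `CoverageProfile` from [averageAndSmooth()].
#' @param main plot title.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plotProfile <- function(x, main = "Average binding profile", ...) {
  stopifnot(inherits(x, "CoverageProfile"))
  plot(x$offset, x$mean, type = "l", col = "grey70",
       xlab = "distance from peak centre (bp)", ylab = "mean coverage",
       main = main, ...)
  lines(x$offset, x$smoothed, col = "firebrick", lwd = 2)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Dot plot of permutation-test results
#'
#' One dot per antibody-category-partition row: colour encodes the
#' direction of correlation (aquamarine positive, red negative), size the
#' significance tier (small grey = none, small coloured = significant,
#' large coloured = highly significant).
#'
#' @param results `data.frame` from [runPermutationTests()].
#' @param ... passed to [plot()].
#' @return `results`, invisibly.
#' @export
plotPermutationDots <- function(results, ...) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  xs <- factor(paste(results$category, results$partition, sep = "/"))
  ys <- factor(results$antibody)
  col <- ifelse(results$tier == "none", "grey60",
                ifelse(results$direction == "positive", "aquamarine3",
                       "firebrick"))
  cexs <- c(none = 0.8, significant = 1.4,
            `highly-significant` = 2.4)[results$tier]
  plot(as.integer(xs), as.integer(ys), pch = 19, col = col, cex = cexs,
       xaxt = "n", yaxt = "n", xlab = "peak category / partition",
       ylab = "antibody", xlim = c(0.5, nlevels(xs) + 0.5),
       ylim = c(0.5, nlevels(ys) + 0.5), ...)
  axis(1, at = seq_len(nlevels(xs)), labels = levels(xs), las = 2,
       cex.axis = 0.7)
  axis(2, at = seq_len(nlevels(ys)), labels = levels(ys), las = 1,
       cex.axis = 0.8)
  invisible(results)
}

#' Render the two-contrast log2FC matrix as a heatmap
#'
#' Blue-white-red image of the zero-substituted matrix from
#' [heatmapMatrix()]; rows keep their deterministic order (no clustering).
#'
#' @param m matrix from [heatmapMatrix()].
#' @param ... passed to [image()].
#' @return `m`, invisibly.
#' @export
plotHeatmapMatrix <- function(m, ...) {
  stopifnot(is.matrix(m), ncol(m) == 2L)
  pal <- colorRampPalette(c("blue", "white", "red"))(101)
  lim <- max(abs(m), 1e-9)
  image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
        col = pal, zlim = c(-lim, lim), axes = FALSE, ...)
  axis(1, at = c(0, 1), labels = colnames(m))
  invisible(m)
}
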