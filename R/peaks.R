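#' @include intervals.R
NULL

#' Peak-calling configuration
#'
#' Parameters of the window/gap island caller. Two modes mirror the two
#' peak-caller families used for this kind of data: `"broad"` (histone-mark
#' style: 200 bp windows joined across gaps up to 600 bp, island p-value
#' cut-off 1e-10 by default, 1e-5 recommended for H3K27ac-like marks) and
#' `"narrow"` (transcription-factor style: 50 bp windows, no gap, cut-off
#' 1e-5).
#'
#' @param mode `"broad"` or `"narrow"`; sets the defaults below.
#' @param window window size in bp (> 0).
#' @param gap maximum gap in bp bridged when joining eligible windows into
#'   islands.
#' @param pCutoff island-level Poisson p-value cut-off; islands with
#'   `p >= pCutoff` are discarded.
#' @param windowP per-window eligibility threshold applied before island
#'   aggregation (default 0.01).
#' @param pseudocount tags added to each control window before library-size
#'   scaling, so the Poisson rate is never zero (default 0.25).
#' @param backgroundFloor if `TRUE` (default), the per-window expectation is
#'   floored at the treatment's genome-wide average tag count per window,
#'   so that a window whose control happens to be empty is still judged
#'   against the global background rather than the pseudocount alone.
#' @param localWindow width in bp of the local-background window (default
#'   1000; 0 disables): the expectation is additionally floored at the
#'   control's average rate over this window centred on each tiling
#'   window, damping single-window control fluctuations the way local
#'   lambda estimation does in model-based callers.
#' @return A list of class `PeakCallingConfig`.
#' @examples
#' peakCallingConfig("broad")                     # 200/600, p < 1e-10
#' peakCallingConfig("broad", pCutoff = 1e-5)     # H3K27ac-like
#' peakCallingConfig("narrow")                    # 50/0, p < 1e-5
#' @export
peakCallingConfig <- function(mode = c("broad", "narrow"), window = NULL,
                              gap = NULL, pCutoff = NULL, windowP = 0.01,
                              pseudocount = 0.25, backgroundFloor = TRUE,
                              localWindow = 1000L) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- if (mode == "broad") 200L else 50L
  if (is.null(gap)) gap <- if (mode == "broad") 600L else 0L
  if (is.null(pCutoff)) pCutoff <- if (mode == "broad") 1e-10 else 1e-5
  stopifnot(window > 0, gap >= 0, pCutoff > 0, pCutoff < 1,
            windowP > 0, windowP <= 1, pseudocount >= 0, localWindow >= 0)
  structure(list(mode = mode, window = as.integer(window),
                 gap = as.integer(gap), pCutoff = pCutoff,
                 windowP = windowP, pseudocount = pseudocount,
                 backgroundFloor = isTRUE(backgroundFloor),
                 localWindow = as.integer(localWindow)),
            class = "PeakCallingConfig")
}

.tagPos0 <- function(track) {
  # 0-based tag positions split by chromosome, plus the genome seqlengths
  gr <- tagPositions(track)
  sl <- seqlengths(gr)
  pos <- split(start(gr) - 1L, factor(as.character(seqnames(gr)),
                                      levels = names(sl)))
  list(pos = pos, seqlengths = sl)
}

#' Count tags in fixed non-overlapping windows
#'
#' Tiles each chromosome from position 0 in fixed windows of `window` bp; a
#' tag belongs to the window containing its position. The last window is
#' truncated at the chromosome end.
#'
#' @param track a [TagTrack-class].
#' @param window window size in bp.
#' @return A `data.frame` with columns `chrom`, `windowIndex` (0-based),
#'   `start`, `end` (1-based closed window span) and `count`, covering every
#'   window of the genome.
#' @export
binTags <- function(track, window) {
  stopifnot(is(track, "TagTrack"), window > 0)
  window <- as.integer(window)
  tp <- .tagPos0(track)
  res <- lapply(names(tp$seqlengths), function(chrom) {
    L <- tp$seqlengths[[chrom]]
    nW <- as.integer(ceiling(L / window))
    counts <- tabulate(tp$pos[[chrom]] %/% window + 1L, nbins = nW)
    idx <- seq_len(nW) - 1L
    data.frame(chrom = chrom, windowIndex = idx,
               start = idx * window + 1L,
               end = pmin((idx + 1L) * window, L),
               count = counts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Poisson upper-tail enrichment p-value
#'
#' `P(X >= count)` for `X ~ Poisson(lambda)` -- the island and window
#' enrichment statistic. Vectorised.
#'
#' @param count observed tag count(s).
#' @param lambda expected count(s) under the control.
#' @return Numeric p-value(s) in (0, 1].
#' @export
poissonEnrichmentP <- function(count, lambda) {
  stopifnot(all(count >= 0), all(lambda > 0))
  ppois(count - 1, lambda, lower.tail = FALSE)
}

#' Call enrichment islands against a control track
#'
#' The generic window/gap island caller. Each chromosome is tiled in fixed
#' windows ([binTags()]). A window is *eligible* when its Poisson upper-tail
#' p-value against the library-size-scaled control expectation (control
#' count plus pseudocount, times treatment/control library ratio, floored
#' at the treatment's genome-wide background when `cfg$backgroundFloor`)
#' falls below `cfg$windowP`. Eligible windows are joined into islands across gaps
#' of up to `cfg$gap` bp ([mergeIntervals()]). Each island is then scored
#' jointly: its p-value is the Poisson upper tail of its total tag count
#' against the summed scaled control expectation of all windows it spans
#' (including bridged gap windows), and islands with `p >= cfg$pCutoff` are
#' discarded.
#'
#' @param treatment,control [TagTrack-class] objects on the same genome.
#'   For standard peak calling the control is the input track; for
#'   differential calling it is the other condition (see
#'   [callDifferential()]).
#' @param cfg a [peakCallingConfig()].
#' @return `GRanges` of islands with metadata columns `count` (island tag
#'   total), `expected` (scaled control expectation) and `pvalue`.
#' @export
callIslands <- function(treatment, control, cfg = peakCallingConfig()) {
  .callEngine(treatment, control, cfg, stat = "poisson")
}

# shared island engine; stat selects the island-level test:
#  - "poisson": upper tail of the island count vs the scaled control
#    expectation (standard calling against an input track)
#  - "binomial": exact conditional test of the two counts,
#    P(Bin(t + c, nT/(nT + nC)) >= t) -- calibrated for
#    condition-vs-condition comparisons where both tracks carry signal
.callEngine <- function(treatment, control, cfg, stat) {
  stopifnot(is(treatment, "TagTrack"), is(control, "TagTrack"),
            inherits(cfg, "PeakCallingConfig"))
  tt <- .tagPos0(treatment); ct <- .tagPos0(control)
  if (!identical(tt$seqlengths, ct$seqlengths))
    stop("treatment and control must be on the same genome")
  w <- cfg$window
  nT <- tagCount(treatment); nC <- tagCount(control)
  scale <- if (nC > 0) nT / nC else 1
  floorLambda <- if (cfg$backgroundFloor)
    nT / sum(as.numeric(tt$seqlengths)) * w else 0
  perChrom <- lapply(names(tt$seqlengths), function(chrom) {
    L <- tt$seqlengths[[chrom]]
    nW <- as.integer(ceiling(L / w))
    tc <- tabulate(tt$pos[[chrom]] %/% w + 1L, nbins = nW)
    cc <- tabulate(ct$pos[[chrom]] %/% w + 1L, nbins = nW)
    lambda <- pmax((cc + cfg$pseudocount) * scale, floorLambda)
    if (cfg$localWindow > 0) {
      half <- as.integer(ceiling(cfg$localWindow / (2 * w)))
      cum <- c(0, cumsum(cc))
      i0 <- pmax(seq_len(nW) - half, 1L)
      i1 <- pmin(seq_len(nW) + half, nW)
      localMean <- (cum[i1 + 1L] - cum[i0]) / (i1 - i0 + 1L)
      lambda <- pmax(lambda, (localMean + cfg$pseudocount) * scale)
    }
    elig <- which(tc > 0 &
                  ppois(tc - 1, lambda, lower.tail = FALSE) < cfg$windowP)
    if (!length(elig)) return(NULL)
    wins <- GRanges(chrom,
                    IRanges(start = (elig - 1L) * w + 1L,
                            end = pmin(elig * w, L)))
    isl <- mergeIntervals(wins, maxGap = cfg$gap)
    i0 <- (start(isl) - 1L) %/% w + 1L         # first window of each island
    i1 <- (end(isl) - 1L) %/% w + 1L           # last window of each island
    cumT <- c(0, cumsum(tc)); cumL <- c(0, cumsum(lambda))
    cnt <- as.integer(cumT[i1 + 1L] - cumT[i0])
    expd <- cumL[i1 + 1L] - cumL[i0]
    if (stat == "binomial" && nC > 0) {
      cumC <- c(0, cumsum(cc))
      ctrlCnt <- as.integer(cumC[i1 + 1L] - cumC[i0])
      q <- nT / (nT + nC)
      pv <- pbinom(cnt - 1, cnt + ctrlCnt, q, lower.tail = FALSE)
      expd <- ctrlCnt * scale
    } else {
      pv <- ppois(cnt - 1, expd, lower.tail = FALSE)
    }
    keep <- pv < cfg$pCutoff
    if (!any(keep)) return(NULL)
    isl <- isl[keep]
    mcols(isl) <- DataFrame(count = cnt[keep], expected = expd[keep],
                            pvalue = pv[keep])
    isl
  })
  perChrom <- perChrom[!vapply(perChrom, is.null, logical(1))]
  if (!length(perChrom)) {
    out <- GRanges(seqlengths = tt$seqlengths)
    mcols(out) <- DataFrame(count = integer(), expected = numeric(),
                            pvalue = numeric())
    return(out)
  }
  out <- suppressWarnings(do.call(c, unname(perChrom)))
  seqlevels(out) <- names(tt$seqlengths)
  seqlengths(out) <- tt$seqlengths
  sort(out, ignore.strand = TRUE)
}

#' Differential peak calling by condition swap
#'
#' Runs the same window/gap island machinery with the second condition
#' standing in for the control track, so that returned islands are regions
#' enriched in `condA` over `condB`. Swapping the arguments yields the
#' reciprocal set. Because both tracks carry real signal in this
#' comparison, the island-level p-value is the exact conditional binomial
#' test of the two island tag counts, `P(Bin(t + c, nA / (nA + nB)) >= t)`
#' -- the calibrated two-sample Poisson comparison -- rather than the
#' Poisson survival against an estimated expectation used when calling
#' against an input track.
#'
#' @param condA,condB [TagTrack-class] objects for the two conditions.
#' @param cfg a [peakCallingConfig()].
#' @return `GRanges` of regions enriched in `condA` over `condB`, with
#'   metadata columns `count` (condA island tags), `expected` (scaled condB
#'   tags) and `pvalue`.
#' @seealso [callIslands()], [classifyPeaks()]
#' @export
callDifferential <- function(condA, condB, cfg = peakCallingConfig()) {
  .callEngine(condA, condB, cfg, stat = "binomial")
}

.overlapBp <- function(x, set) {
  # per-element total bp of x covered by the (reduced) set
  set <- GenomicRanges::reduce(set, ignore.strand = TRUE)
  h <- findOverlaps(x, set, ignore.strand = TRUE)
  ov <- pmin(end(x)[queryHits(h)], end(set)[subjectHits(h)]) -
        pmax(start(x)[queryHits(h)], start(set)[subjectHits(h)]) + 1L
  out <- integer(length(x))
  if (length(h)) {
    s <- tapply(ov, queryHits(h), sum)
    out[as.integer(names(s))] <- as.integer(s)
  }
  out
}

#' Classify peaks as COMMON / INCREASE / DECREASE
#'
#' Derives the three differential occupancy classes for one antibody from
#' its four peak sets. DECREASE regions are control standard peaks that
#' overlap a control-over-knockdown differential peak; INCREASE regions are
#' knockdown standard peaks that overlap a knockdown-over-control
#' differential peak; COMMON regions are control standard peaks overlapped
#' by a knockdown standard peak. A classified region therefore always shows
#' both a significant enrichment against the input control and a
#' significant enrichment between the conditions. Reported intervals are the
#' standard-peak intervals.
#'
#' When a DECREASE region and an INCREASE region overlap each other, the
#' class whose differential peaks cover more bp of the standard peak wins;
#' on a tie both regions are dropped and kept in the `dropped` slot.
#'
#' @param ctrlPeaks,kdPeaks standard peaks per condition (vs input).
#' @param diffCtrlOverKd,diffKdOverCtrl differential peaks from
#'   [callDifferential()] in the two directions.
#' @param antibody antibody label stored on the result.
#' @param minOverlap minimum bp overlap for all classifications (default 1).
#' @return A [ClassifiedPeaks-class] object.
#' @export
classifyPeaks <- function(ctrlPeaks, kdPeaks, diffCtrlOverKd, diffKdOverCtrl,
                          antibody = "", minOverlap = 1L) {
  stopifnot(is(ctrlPeaks, "GRanges"), is(kdPeaks, "GRanges"),
            is(diffCtrlOverKd, "GRanges"), is(diffKdOverCtrl, "GRanges"))
  ovl <- function(x, set) {
    if (!length(x) || !length(set)) return(x[0])
    x[countOverlaps(x, set, minoverlap = as.integer(minOverlap),
                    ignore.strand = TRUE) > 0]
  }
  dec <- ovl(ctrlPeaks, diffCtrlOverKd)
  inc <- ovl(kdPeaks, diffKdOverCtrl)
  com <- ovl(ctrlPeaks, kdPeaks)
  dropped <- ctrlPeaks[0]
  if (length(dec) && length(inc)) {
    h <- findOverlaps(dec, inc, ignore.strand = TRUE)
    if (length(h)) {
      bpDec <- .overlapBp(dec, diffCtrlOverKd)
      bpInc <- .overlapBp(inc, diffKdOverCtrl)
      dropD <- logical(length(dec)); dropI <- logical(length(inc))
      for (j in seq_along(h)) {
        d <- queryHits(h)[j]; i <- subjectHits(h)[j]
        if (bpDec[d] > bpInc[i]) dropI[i] <- TRUE
        else if (bpDec[d] < bpInc[i]) dropD[d] <- TRUE
        else { dropD[d] <- TRUE; dropI[i] <- TRUE }   # tie: drop both
      }
      dropped <- suppressWarnings(c(granges(dec[dropD]),
                                    granges(inc[dropI])))
      dec <- dec[!dropD]; inc <- inc[!dropI]
    }
  }
  new("ClassifiedPeaks", antibody = as.character(antibody),
      ctrl = ctrlPeaks, kd = kdPeaks, common = com,
      increase = inc, decrease = dec, dropped = dropped)
}
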