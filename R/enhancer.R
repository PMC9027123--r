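#' @include permutation.R
NULL

#' Extend enhancer anchors to fixed-length centred intervals
#'
#' Each 1 bp anchor at (0-based) position `c` becomes the half-open
#' interval `[c - (L-1)/2, c + (L+1)/2)` of odd length `L` (default 3001),
#' centred on the anchor base. Wider input intervals are collapsed to their
#' centre base first. Intervals clipped at a chromosome edge are flagged.
#'
#' @param anchors `GRanges` of anchors (1 bp or wider).
#' @param length odd target length in bp (default 3001).
#' @return `GRanges` parallel to `anchors` with logical metadata column
#'   `clipped`; other metadata columns are preserved.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5001),
#'                             seqlengths = c(chr1 = 1e6))
#' extendEnhancers(a)  # chr1:3501-6501, width 3001
#' @export
extendEnhancers <- function(anchors, length = 3001L) {
  stopifnot(is(anchors, "GRanges"))
  length <- as.integer(length)
  if (length < 1L || length %% 2L == 0L)
    stop("target length must be a positive odd number of bp")
  half <- (length - 1L) %/% 2L
  centre <- (start(anchors) + end(anchors)) %/% 2L
  s <- centre - half; e <- centre + half
  sl <- seqlengths(anchors)[as.character(seqnames(anchors))]
  sClip <- pmax(s, 1L)
  eClip <- if (any(is.na(sl))) e else pmin(e, sl)
  out <- GRanges(seqnames(anchors), IRanges(sClip, eClip),
                 seqinfo = seqinfo(anchors))
  mcols(out) <- mcols(anchors)
  out$clipped <- (sClip != s) | (eClip != e)
  out
}

#' Fraction of enhancers bound, per peak set
#'
#' @param enhancers `GRanges` of (extended) enhancer intervals.
#' @param peakSets named list of `GRanges` peak sets (e.g. per condition or
#'   per class).
#' @return `data.frame` with columns `set`, `n_bound`, `n_total`,
#'   `fraction` (the exact rational `n_bound / n_total`).
#' @export
enhancerBindingFractions <- function(enhancers, peakSets) {
  stopifnot(is(enhancers, "GRanges"), is.list(peakSets),
            !is.null(names(peakSets)))
  if (!length(enhancers)) stop("no enhancers supplied")
  rows <- lapply(names(peakSets), function(nm) {
    nb <- sum(countOverlaps(enhancers, peakSets[[nm]],
                            ignore.strand = TRUE) > 0)
    data.frame(set = nm, n_bound = nb, n_total = length(enhancers),
               fraction = nb / length(enhancers), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential peak class at each enhancer
#'
#' Assigns each (extended) enhancer the differential class of the
#' classified peaks it overlaps: `DECREASE` or `INCREASE` when only one
#' class overlaps; when both do, the class covering more bp of the enhancer
#' wins and ties give `"ambiguous"`; enhancers overlapping neither get
#' `"none"`.
#'
#' @param enhancers `GRanges` of extended enhancer intervals.
#' @param classified a [ClassifiedPeaks-class] object (canonically for
#'   Smarca4).
#' @return Character vector parallel to `enhancers` with values
#'   `"DECREASE"`, `"INCREASE"`, `"ambiguous"`, `"none"`.
#' @export
enhancerPeakClass <- function(enhancers, classified) {
  stopifnot(is(enhancers, "GRanges"), is(classified, "ClassifiedPeaks"))
  bpD <- .overlapBp(enhancers, peakClass(classified, "DECREASE"))
  bpI <- .overlapBp(enhancers, peakClass(classified, "INCREASE"))
  out <- rep("none", length(enhancers))
  out[bpD > bpI] <- "DECREASE"
  out[bpI > bpD] <- "INCREASE"
  out[bpD > 0 & bpI > 0 & bpD == bpI] <- "ambiguous"
  out
}

#' Link enhancers to genes and summarise expression by differential class
#'
#' Links each enhancer to its nearest gene within `cap` bp
#' ([nearestWithin()]), classifies enhancers by their differential peak
#' class ([enhancerPeakClass()]), and reports, per class, the fractions of
#' linked significantly up- and downregulated genes. When a membership
#' table is supplied, the analogous summary over *gene regions* (genes
#' carrying a DECREASE or INCREASE membership of the classified antibody)
#' is computed for side-by-side comparison.
#'
#' @param enhancers `GRanges` of extended enhancer intervals.
#' @param genes `GRanges` of gene bodies with `gene_id`.
#' @param de DE `data.frame` (`gene_id`, `log2FC`, `padj`).
#' @param classified [ClassifiedPeaks-class] used for the enhancer classes.
#' @param cap maximum linkage distance in bp (default 100000).
#' @param membership optional [assignPeaks()] table for the gene-region
#'   summary.
#' @param alpha,lfcMin DE significance thresholds (see [filterDE()]).
#' @return A list with `links` (per-enhancer `data.frame`: `enhancer`,
#'   `gene_id`, `distance`, `class`, `direction`) and `summary`
#'   (`region_type`, `class`, `n_linked_sig`, `n_up`, `n_down`, `frac_up`,
#'   `frac_down`; classes with no linked significant genes are reported
#'   with `NA` fractions).
#' @export
linkAndSummarise <- function(enhancers, genes, de, classified,
                             cap = 100000L, membership = NULL,
                             alpha = 0.05, lfcMin = 0.58) {
  stopifnot(is(enhancers, "GRanges"), is(genes, "GRanges"),
            !is.null(genes$gene_id))
  flt <- filterDE(de, alpha, lfcMin)
  dirOf <- function(ids) {
    d <- rep("ns", length(ids))
    d[ids %in% flt$up$gene_id] <- "up"
    d[ids %in% flt$down$gene_id] <- "down"
    d
  }
  nn <- nearestWithin(enhancers, genes, maxDistance = cap)
  cls <- enhancerPeakClass(enhancers, classified)
  linkedGene <- ifelse(is.na(nn$subjectIdx), NA_character_,
                       genes$gene_id[nn$subjectIdx])
  links <- data.frame(enhancer = seq_along(enhancers),
                      gene_id = linkedGene, distance = nn$distance,
                      class = cls,
                      direction = ifelse(is.na(linkedGene), NA_character_,
                                         dirOf(linkedGene)),
                      stringsAsFactors = FALSE)
  summarise <- function(classVec, geneVec, regionType) {
    rows <- lapply(c("DECREASE", "INCREASE"), function(cl) {
      g <- unique(geneVec[classVec == cl & !is.na(geneVec)])
      d <- dirOf(g)
      nUp <- sum(d == "up"); nDown <- sum(d == "down")
      nSig <- nUp + nDown
      data.frame(region_type = regionType, class = cl, n_linked_sig = nSig,
                 n_up = nUp, n_down = nDown,
                 frac_up = if (nSig > 0) nUp / nSig else NA_real_,
                 frac_down = if (nSig > 0) nDown / nSig else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  summary <- summarise(links$class, links$gene_id, "enhancer")
  if (!is.null(membership)) {
    m <- membership[membership$antibody == antibody(classified) &
                    membership$class %in% c("DECREASE", "INCREASE"), ,
                    drop = FALSE]
    summary <- rbind(summarise(m$class, m$gene_id, "gene"), summary)
  }
  rownames(summary) <- NULL
  list(links = links, summary = summary)
}
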