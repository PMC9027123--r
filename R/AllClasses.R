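#' @include chipshift-package.R
NULL

.TAG_CONDITIONS <- c("control", "kd", "input")
.PEAK_CLASSES <- c("ctrl", "kd", "COMMON", "INCREASE", "DECREASE")

#' TagTrack: single-base sequencing tag positions for one track
#'
#' A `TagTrack` holds the 1 bp tag positions of one ChIP (or input control)
#' track as a [GenomicRanges::GRanges] of width-1 ranges, together with the
#' antibody and condition labels. Chromosome lengths must be present in the
#' `seqinfo` of the ranges; they define the genome that window tiling and
#' simulation operate on.
#'
#' @slot tags `GRanges` of width-1 tag positions with seqlengths set.
#' @slot antibody single character, e.g. `"Smarca4"`, or `"input"`.
#' @slot condition one of `"control"`, `"kd"`, `"input"`.
#'
#' @seealso [TagTrack()] for the constructor, [callIslands()] for peak
#'   calling on tracks.
#' @name TagTrack-class
#' @aliases TagTrack-class
#' @exportClass TagTrack
setClass("TagTrack",
  representation(tags = "GRanges", antibody = "character",
                 condition = "character"))

setValidity("TagTrack", function(object) {
  msg <- character()
  if (length(object@antibody) != 1L || is.na(object@antibody))
    msg <- c(msg, "'antibody' must be a single non-NA string")
  if (length(object@condition) != 1L ||
      !object@condition %in% .TAG_CONDITIONS)
    msg <- c(msg, sprintf("'condition' must be one of %s",
                          paste(.TAG_CONDITIONS, collapse = ", ")))
  if (length(object@tags)) {
    if (any(width(object@tags) != 1L))
      msg <- c(msg, "all tag ranges must have width 1")
    sl <- seqlengths(object@tags)
    if (any(is.na(sl)))
      msg <- c(msg, "seqlengths must be set for every chromosome")
    else {
      idx <- as.integer(seqnames(object@tags))
      if (any(start(object@tags) < 1L) ||
          any(end(object@tags) > sl[idx]))
        msg <- c(msg, "tag positions must lie within chromosome bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TagTrack
#'
#' @param tags `GRanges` of width-1 tag positions; `seqlengths` must be set.
#' @param antibody antibody label (use `"input"` for input-control tracks).
#' @param condition `"control"`, `"kd"` or `"input"`.
#' @return A [TagTrack-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1),
#'                              seqlengths = c(chr1 = 1000))
#' TagTrack(gr, antibody = "Smarca4", condition = "control")
#' @export
TagTrack <- function(tags, antibody, condition) {
  new("TagTrack", tags = tags, antibody = as.character(antibody),
      condition = as.character(condition))
}

#' @describeIn TagTrack-class tag positions as a `GRanges`.
#' @param x,object a `TagTrack`.
#' @export
setGeneric("tagPositions", function(x) standardGeneric("tagPositions"))

#' @rdname TagTrack-class
#' @export
setMethod("tagPositions", "TagTrack", function(x) x@tags)

#' @describeIn TagTrack-class antibody label.
#' @export
setGeneric("antibody", function(x) standardGeneric("antibody"))

#' @rdname TagTrack-class
#' @export
setMethod("antibody", "TagTrack", function(x) x@antibody)

#' @describeIn TagTrack-class condition label.
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname TagTrack-class
#' @export
setMethod("condition", "TagTrack", function(x) x@condition)

#' @describeIn TagTrack-class number of tags.
#' @export
setGeneric("tagCount", function(x) standardGeneric("tagCount"))

#' @rdname TagTrack-class
#' @export
setMethod("tagCount", "TagTrack", function(x) length(x@tags))

setMethod("show", "TagTrack", function(object) {
  cat(sprintf("TagTrack: %s / %s\n", object@antibody, object@condition))
  cat(sprintf("  %d tags on %d sequence(s)\n", length(object@tags),
              length(seqlevelsInUse(object@tags))))
})

#' ClassifiedPeaks: standard and differential peak sets for one antibody
#'
#' Holds the two standard per-condition peak sets and the three derived
#' differential classes for one antibody. DECREASE regions are control
#' standard peaks that also show significant enrichment of control over
#' knockdown; INCREASE regions are knockdown standard peaks with the
#' reciprocal differential enrichment; COMMON regions are control standard
#' peaks overlapped by a knockdown standard peak. Regions that qualified for
#' both differential classes and could not be resolved are kept in `dropped`.
#'
#' @slot antibody antibody label.
#' @slot ctrl,kd standard peaks per condition (`GRanges` with `count`,
#'   `expected`, `pvalue` metadata columns).
#' @slot common,increase,decrease the derived classes (`GRanges`).
#' @slot dropped regions discarded by the tie rule of conflict resolution.
#'
#' @seealso [classifyPeaks()], [peakClass()]
#' @name ClassifiedPeaks-class
#' @exportClass ClassifiedPeaks
setClass("ClassifiedPeaks",
  representation(antibody = "character", ctrl = "GRanges", kd = "GRanges",
                 common = "GRanges", increase = "GRanges",
                 decrease = "GRanges", dropped = "GRanges"))

setValidity("ClassifiedPeaks", function(object) {
  msg <- character()
  if (length(object@antibody) != 1L)
    msg <- c(msg, "'antibody' must be a single string")
  if (length(object@increase) && length(object@decrease) &&
      sum(countOverlaps(object@increase, object@decrease)) > 0)
    msg <- c(msg, "INCREASE and DECREASE regions must not overlap")
  if (length(msg)) msg else TRUE
})

#' Extract one peak class from a ClassifiedPeaks object
#'
#' @param x a [ClassifiedPeaks-class] object.
#' @param class one of `"ctrl"`, `"kd"`, `"COMMON"`, `"INCREASE"`,
#'   `"DECREASE"`.
#' @return A `GRanges` of the requested class.
#' @export
setGeneric("peakClass", function(x, class) standardGeneric("peakClass"))

#' @rdname peakClass
#' @export
setMethod("peakClass", "ClassifiedPeaks", function(x, class) {
  class <- match.arg(class, .PEAK_CLASSES)
  switch(class, ctrl = x@ctrl, kd = x@kd, COMMON = x@common,
         INCREASE = x@increase, DECREASE = x@decrease)
})

#' @rdname ClassifiedPeaks-class
#' @param x,object a `ClassifiedPeaks`.
#' @export
setMethod("antibody", "ClassifiedPeaks", function(x) x@antibody)

setMethod("show", "ClassifiedPeaks", function(object) {
  cat(sprintf("ClassifiedPeaks: %s\n", object@antibody))
  cat(sprintf("  ctrl: %d  kd: %d  COMMON: %d  INCREASE: %d  DECREASE: %d",
              length(object@ctrl), length(object@kd), length(object@common),
              length(object@increase), length(object@decrease)))
  if (length(object@dropped))
    cat(sprintf("  (dropped: %d)", length(object@dropped)))
  cat("\n")
})

#' PermutationResult: outcome of one binding-pattern permutation test
#'
#' Summarises one Monte-Carlo permutation test of whether genes carrying a
#' concurrent ChIP signal are over- or under-represented in the DECREASE
#' partition of a basic gene set (see [permutationTest()]).
#'
#' @slot antibody,category optional labels of the signal tested.
#' @slot N basic-set size; @slot nD DECREASE-partition size; @slot k number
#'   of basic-set genes carrying the signal.
#' @slot observed observed count of signal genes in the DECREASE partition.
#' @slot expected expectation `k * nD / N` under the null.
#' @slot nullMean mean of the Monte-Carlo null sample.
#' @slot pLower,pUpper add-one-smoothed empirical tail probabilities.
#' @slot pValue two-sided empirical p-value (doubled smaller tail, capped
#'   at 1).
#' @slot direction `"positive"`, `"negative"` or `"none"` correlation of the
#'   signal with the DECREASE partition.
#' @slot tier `"none"`, `"significant"` or `"highly-significant"`.
#' @slot nPermutations number of shuffles.
#'
#' @name PermutationResult-class
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(antibody = "character", category = "character",
                 N = "integer", nD = "integer", k = "integer",
                 observed = "integer", expected = "numeric",
                 nullMean = "numeric", pLower = "numeric",
                 pUpper = "numeric", pValue = "numeric",
                 direction = "character", tier = "character",
                 nPermutations = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (!object@tier %in% c("none", "significant", "highly-significant"))
    msg <- c(msg, "invalid tier")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
  lab <- if (nzchar(object@antibody))
    sprintf(" [%s/%s]", object@antibody, object@category) else ""
  cat(sprintf("PermutationResult%s\n", lab))
  cat(sprintf("  N=%d, nD=%d, k=%d; observed=%d, expected=%.2f\n",
              object@N, object@nD, object@k, object@observed,
              object@expected))
  cat(sprintf("  p=%.4g (%s), tier: %s; B=%d\n", object@pValue,
              object@direction, object@tier, object@nPermutations))
})

#' SyntheticStudy: a fully simulated knockdown study with planted truth
#'
#' Container for everything [simulateStudy()] generates: gene models,
#' enhancer anchors, per-antibody-and-condition tag tracks, a differential
#' expression table, and the planted ground truth that the downstream
#' pipeline is expected to recover.
#'
#' @slot genes `GRanges` of gene bodies with `gene_id` and strand.
#' @slot enhancers `GRanges` of 1 bp enhancer anchors with `enhancer_id`.
#' @slot tags named list of [TagTrack-class] objects
#'   (`"<antibody>.<condition>"` plus `"input"`).
#' @slot de `data.frame` with columns `gene_id`, `log2FC`, `padj`.
#' @slot truth list of three data frames: `occupancy` (gene_id, antibody,
#'   class in none/stable/gained/lost), `expression` (gene_id, direction in
#'   up/down/null), `enhancers` (enhancer_id, chrom, anchor, bound_in,
#'   linked_gene).
#' @slot params list of the generator parameters used.
#'
#' @name SyntheticStudy-class
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  representation(genes = "GRanges", enhancers = "GRanges", tags = "list",
                 de = "data.frame", truth = "list", params = "list"))

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  if (length(object@genes) && is.null(object@genes$gene_id))
    msg <- c(msg, "genes must carry a gene_id column")
  if (length(object@tags) && !all(vapply(object@tags, is, logical(1),
                                         "TagTrack")))
    msg <- c(msg, "tags must be a list of TagTrack objects")
  occ <- object@truth$occupancy
  if (!is.null(occ) && anyDuplicated(occ[c("gene_id", "antibody")]))
    msg <- c(msg, "occupancy truth must have one row per gene x antibody")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticStudy-class gene models (`GRanges`).
#' @param x,object a `SyntheticStudy`.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("geneModels", "SyntheticStudy", function(x) x@genes)

#' @describeIn SyntheticStudy-class enhancer anchors (`GRanges`).
#' @export
setGeneric("enhancerAnchors", function(x) standardGeneric("enhancerAnchors"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("enhancerAnchors", "SyntheticStudy", function(x) x@enhancers)

#' @describeIn SyntheticStudy-class named list of tag tracks.
#' @export
setGeneric("tagTracks", function(x) standardGeneric("tagTracks"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("tagTracks", "SyntheticStudy", function(x) x@tags)

#' @describeIn SyntheticStudy-class the differential expression table.
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("deTable", "SyntheticStudy", function(x) x@de)

#' @describeIn SyntheticStudy-class the planted ground truth (list of
#'   data frames).
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname SyntheticStudy-class
#' @export
setMethod("plantedTruth", "SyntheticStudy", function(x) x@truth)

setMethod("show", "SyntheticStudy", function(object) {
  sl <- seqlengths(object@genes)
  cat("SyntheticStudy\n")
  cat(sprintf("  genome: %d chromosome(s), %.3g bp total\n",
              length(sl), sum(as.numeric(sl))))
  cat(sprintf("  genes: %d  enhancers: %d  tag tracks: %d\n",
              length(object@genes), length(object@enhancers),
              length(object@tags)))
  dirs <- table(object@truth$expression$direction)
  cat(sprintf("  planted expression: %s\n",
              paste(names(dirs), dirs, sep = "=", collapse = " ")))
})
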