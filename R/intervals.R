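#' @include AllClasses.R
NULL

# Interval arithmetic. All public objects are standard GRanges (1-based,
# closed, the Bioconductor convention); BED I/O converts to and from the
# 0-based half-open convention on disk. Strand is ignored throughout --
# strand only matters in the TSS logic of the annotation step.

#' Report overlapping interval pairs with their intersections
#'
#' Finds all pairs of intervals from `a` and `b` on the same chromosome whose
#' intersection is at least `minOverlap` bp. Chromosome names are matched
#' literally.
#'
#' @param a,b `GRanges`.
#' @param minOverlap minimum intersection width in bp (default 1).
#' @return A `data.frame` with one row per pair: `aIdx`, `bIdx` (indices into
#'   `a` and `b`), `chrom`, `intStart`, `intEnd` (1-based closed intersection
#'   span) and `intWidth`. Rows are ordered by chromosome, then `a` start,
#'   then `b` start. Empty inputs give a zero-row frame.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 250))
#' overlapPairs(a, b)
#' @export
overlapPairs <- function(a, b, minOverlap = 1L) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), minOverlap >= 1L)
  h <- findOverlaps(a, b, minoverlap = as.integer(minOverlap),
                    ignore.strand = TRUE)
  qi <- queryHits(h); si <- subjectHits(h)
  is_ <- pmax(start(a)[qi], start(b)[si])
  ie_ <- pmin(end(a)[qi], end(b)[si])
  out <- data.frame(
    aIdx = qi, bIdx = si,
    chrom = as.character(seqnames(a))[qi],
    intStart = is_, intEnd = ie_, intWidth = ie_ - is_ + 1L,
    stringsAsFactors = FALSE)
  ord <- order(out$chrom, start(a)[qi], start(b)[si], qi, si)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge intervals, coalescing across gaps
#'
#' Coalesces, transitively, any two intervals on the same chromosome whose
#' gap (next start minus previous end, in half-open terms) is at most
#' `maxGap` bp. A gap of exactly `maxGap` merges; `maxGap = 0` merges only
#' overlapping or abutting intervals.
#'
#' @param x `GRanges`.
#' @param maxGap maximum gap bridged, in bp (default 0).
#' @return A sorted, non-overlapping `GRanges`.
#' @examples
#' x <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 801), c(200, 1000)))
#' mergeIntervals(x, maxGap = 600)  # one interval chr1:1-1000
#' @export
mergeIntervals <- function(x, maxGap = 0L) {
  stopifnot(is(x, "GRanges"), maxGap >= 0L)
  GenomicRanges::reduce(x, min.gapwidth = as.integer(maxGap) + 1L,
                        ignore.strand = TRUE)
}

#' Assign each query interval its nearest subject within a distance cap
#'
#' Distance is 0 for overlapping (or abutting) intervals, otherwise the
#' number of bases strictly between the closest edges. Queries with no
#' subject within `maxDistance` get `NA`. Distance ties are broken towards
#' the subject with the smaller start (then the smaller index); set
#' `verbose = TRUE` to keep all tied subjects.
#'
#' @param query,subjects `GRanges`.
#' @param maxDistance distance cap in bp.
#' @param verbose if `TRUE`, return one row per tied nearest subject.
#' @return A `data.frame` with columns `queryIdx`, `subjectIdx`, `distance`
#'   (the latter two `NA` for unassigned queries), one row per query (or per
#'   tie when `verbose`).
#' @examples
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 10001))
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 51000))
#' nearestWithin(q, s, maxDistance = 100000)
#' @export
nearestWithin <- function(query, subjects, maxDistance, verbose = FALSE) {
  stopifnot(is(query, "GRanges"), is(subjects, "GRanges"), maxDistance >= 0)
  n <- length(query)
  out <- data.frame(queryIdx = seq_len(n), subjectIdx = NA_integer_,
                    distance = NA_integer_)
  if (n == 0L || length(subjects) == 0L) return(out)
  h <- distanceToNearest(query, subjects, select = "all",
                         ignore.strand = TRUE)
  if (!length(h)) return(out)
  d <- mcols(h)$distance
  keep <- d <= maxDistance
  qi <- queryHits(h)[keep]; si <- subjectHits(h)[keep]; d <- d[keep]
  if (!length(qi)) return(out)
  if (verbose) {
    out <- data.frame(queryIdx = qi, subjectIdx = si, distance = d)
    missing <- setdiff(seq_len(n), qi)
    if (length(missing))
      out <- rbind(out, data.frame(queryIdx = missing,
                                   subjectIdx = NA_integer_,
                                   distance = NA_integer_))
    out <- out[order(out$queryIdx, start(subjects)[out$subjectIdx],
                     out$subjectIdx, na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # deterministic tie-break: smaller subject start, then smaller index
  ord <- order(qi, start(subjects)[si], si)
  qi <- qi[ord]; si <- si[ord]; d <- d[ord]
  first <- !duplicated(qi)
  out$subjectIdx[qi[first]] <- si[first]
  out$distance[qi[first]] <- d[first]
  out
}

#' Read a BED file as GRanges
#'
#' Reads BED3/BED6 (0-based half-open on disk) into a 1-based `GRanges`.
#' Chromosome names are used literally; no aliasing is applied.
#'
#' @param path file path.
#' @param seqlengths optional named vector of chromosome lengths to attach.
#' @return A `GRanges`; BED name/score/strand columns are preserved when
#'   present.
#' @export
readBed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr
}

#' Write GRanges as BED
#'
#' Writes BED3 or BED6 (0-based half-open), column-exact, so that a
#' `writeBed()` / [readBed()] round trip reproduces coordinates bit for bit.
#'
#' @param x `GRanges`.
#' @param path output file path.
#' @param name optional character vector (or metadata column name) for BED
#'   column 4; triggers BED6 output.
#' @param score optional numeric vector (or metadata column name) for BED
#'   column 5.
#' @return The path, invisibly.
#' @export
writeBed <- function(x, path, name = NULL, score = NULL) {
  stopifnot(is(x, "GRanges"))
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x))
  pick <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.character(v) && length(v) == 1L && v %in% names(mcols(x)))
      return(mcols(x)[[v]])
    v
  }
  nm <- pick(name); sc <- pick(score)
  if (!is.null(nm) || !is.null(sc)) {
    df$name <- if (is.null(nm)) rep_len(".", length(x))
               else as.character(nm)
    df$score <- if (is.null(sc)) rep_len(0, length(x)) else sc
    df$strand <- sub("\\*", ".", as.character(strand(x)))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GTF/GFF
#'
#' BED6 input uses the name column as `gene_id`. GTF/GFF input (1-based
#' closed on disk, converted on read by the importer) keeps only features of
#' type `"gene"` and requires a `gene_id` attribute.
#'
#' @param path file path; format inferred from the extension
#'   (`.bed` vs `.gtf`/`.gff`/`.gff3`).
#' @param seqlengths optional named chromosome lengths.
#' @return `GRanges` with a `gene_id` metadata column and strand.
#' @export
readGeneModels <- function(path, seqlengths = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(mcols(gr)))
      gr <- gr[mcols(gr)$type == "gene"]
    if (is.null(gr$gene_id))
      stop("GTF/GFF gene models require a gene_id attribute")
    mcols(gr) <- DataFrame(gene_id = as.character(gr$gene_id))
  } else {
    gr <- readBed(path)
    if (is.null(gr$name))
      stop("BED gene models require a name column (gene_id)")
    mcols(gr) <- DataFrame(gene_id = as.character(gr$name))
  }
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr
}
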