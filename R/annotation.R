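#' @include peaks.R
NULL

#' Annotation configuration
#'
#' @param upstreamPad bp added upstream of the TSS when building gene
#'   regions (default 1000).
#' @param tssFlank half-width in bp of the TSS window (default 1000, i.e. a
#'   2 kb window centred on the TSS).
#' @return A list of class `AnnotationConfig`.
#' @export
annotationConfig <- function(upstreamPad = 1000L, tssFlank = 1000L) {
  stopifnot(upstreamPad >= 0, tssFlank >= 0)
  structure(list(upstreamPad = as.integer(upstreamPad),
                 tssFlank = as.integer(tssFlank)),
            class = "AnnotationConfig")
}

.tss0 <- function(genes) {
  # 0-based TSS coordinate: start of the interval on +, (half-open) end on -
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes) - 1L)
}

#' Gene regions: 1 kb upstream of the TSS through the TES
#'
#' Extends each gene body upstream of its transcription start site,
#' strand-aware: a plus-strand gene spanning `[s, e)` (half-open) becomes
#' `[s - upstreamPad, e)`; a minus-strand gene becomes `[s, e + upstreamPad)`.
#' Regions are clipped at chromosome bounds.
#'
#' @param genes `GRanges` of gene bodies with strand and a `gene_id` column.
#' @param cfg an [annotationConfig()].
#' @return `GRanges` of gene regions, parallel to `genes`, with `gene_id`.
#' @export
geneRegions <- function(genes, cfg = annotationConfig()) {
  stopifnot(is(genes, "GRanges"))
  minus <- as.character(strand(genes)) == "-"
  s <- ifelse(minus, start(genes), start(genes) - cfg$upstreamPad)
  e <- ifelse(minus, end(genes) + cfg$upstreamPad, end(genes))
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  s <- pmax(s, 1L)
  if (!any(is.na(sl))) e <- pmin(e, sl)
  out <- GRanges(seqnames(genes), IRanges(s, e), strand = strand(genes),
                 seqinfo = seqinfo(genes))
  mcols(out) <- mcols(genes)
  out
}

#' TSS regions: a window centred on the transcription start site
#'
#' Builds the half-open window `[TSS - tssFlank, TSS + tssFlank)` around
#' each gene's strand-aware TSS (interval start on plus-strand genes,
#' interval end on minus-strand genes), clipped at chromosome bounds.
#'
#' @inheritParams geneRegions
#' @return `GRanges` of TSS windows, parallel to `genes`, with `gene_id`.
#' @export
tssRegions <- function(genes, cfg = annotationConfig()) {
  stopifnot(is(genes, "GRanges"))
  t0 <- .tss0(genes)
  s <- t0 - cfg$tssFlank + 1L           # 1-based start of [t0 - f, t0 + f)
  e <- t0 + cfg$tssFlank
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  s <- pmax(s, 1L)
  if (!any(is.na(sl))) e <- pmin(e, sl)
  out <- GRanges(seqnames(genes), IRanges(s, e), strand = strand(genes),
                 seqinfo = seqinfo(genes))
  mcols(out) <- mcols(genes)
  out
}

#' Assign classified peaks to genes via gene and TSS regions
#'
#' Keeps only peaks overlapping at least one gene region ([geneRegions()])
#' or TSS window ([tssRegions()]); all other peaks are dropped. Surviving
#' peaks are assigned to every overlapping gene (a peak spanning several
#' gene/TSS intervals contributes to each). The result is a per-gene,
#' per-antibody, per-class membership table; gene-region and TSS-window
#' hits feed the same memberships, with a provenance column recording which
#' rule fired.
#'
#' @param classified a [ClassifiedPeaks-class] object, or a named list of
#'   them (one per antibody).
#' @param genes `GRanges` of gene bodies with `gene_id` and strand.
#' @param cfg an [annotationConfig()].
#' @return A `data.frame` with columns `gene_id`, `antibody`, `class`
#'   (`ctrl`, `kd`, `COMMON`, `INCREASE`, `DECREASE`), `n_peaks` (distinct
#'   peaks assigned) and `provenance` (`"gene"`, `"tss"` or `"both"`).
#' @export
assignPeaks <- function(classified, genes, cfg = annotationConfig()) {
  if (is(classified, "ClassifiedPeaks")) classified <- list(classified)
  stopifnot(all(vapply(classified, is, logical(1), "ClassifiedPeaks")),
            is(genes, "GRanges"), !is.null(genes$gene_id))
  gr <- geneRegions(genes, cfg)
  tr <- tssRegions(genes, cfg)
  rows <- list()
  for (cp in classified) {
    for (cls in .PEAK_CLASSES) {
      pk <- peakClass(cp, cls)
      if (!length(pk)) next
      hG <- findOverlaps(pk, gr, ignore.strand = TRUE)
      hT <- findOverlaps(pk, tr, ignore.strand = TRUE)
      if (!length(hG) && !length(hT)) next
      m <- rbind(
        data.frame(peak = queryHits(hG), gene = subjectHits(hG),
                   via = rep_len("gene", length(hG)),
                   stringsAsFactors = FALSE),
        data.frame(peak = queryHits(hT), gene = subjectHits(hT),
                   via = rep_len("tss", length(hT)),
                   stringsAsFactors = FALSE))
      agg <- split(m, m$gene)
      rows[[length(rows) + 1L]] <- do.call(rbind, lapply(agg, function(d) {
        via <- unique(d$via)
        data.frame(gene_id = genes$gene_id[d$gene[1L]],
                   antibody = antibody(cp), class = cls,
                   n_peaks = length(unique(d$peak)),
                   provenance = if (length(via) == 2L) "both" else via,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), antibody = character(),
                      class = character(), n_peaks = integer(),
                      provenance = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$antibody,
                   match(out$class, .PEAK_CLASSES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
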