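#' @include profiles.R
NULL

#' Specification of a synthetic genome
#'
#' Describes the small multi-chromosome genome on which a synthetic
#' knockdown study is simulated. Genes are placed without overlap and with
#' a minimum inter-gene gap inside a "gene zone" that leaves the tail of
#' each chromosome free, so that deliberately unlinked enhancers can be
#' planted beyond the nearest-gene distance cap.
#'
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param nGenes total number of genes.
#' @param geneLengthRange length-2 vector of minimum and maximum gene
#'   length in bp.
#' @param nEnhancers total number of enhancer anchors.
#' @param minGeneGap minimum gap between consecutive genes (and from
#'   chromosome start), bp.
#' @param geneZoneReserve bp reserved at the end of each chromosome, kept
#'   gene-free for unlinked enhancers.
#' @param enhancerMargin minimum distance of enhancer anchors from
#'   chromosome ends, bp.
#' @param unlinkedFraction fraction of enhancers planted farther from every
#'   gene than the linkage cap.
#' @param seed RNG seed.
#' @return A list of class `SyntheticGenomeSpec`.
#' @export
syntheticGenomeSpec <- function(chromLengths = c(chr1 = 4e6, chr2 = 4e6),
                                nGenes = 200L,
                                geneLengthRange = c(1000L, 3000L),
                                nEnhancers = 60L, minGeneGap = 12000L,
                                geneZoneReserve = 250000L,
                                enhancerMargin = 5000L,
                                unlinkedFraction = 0.1, seed = 1L) {
  stopifnot(length(chromLengths) >= 1, !is.null(names(chromLengths)),
            all(chromLengths > 0), nGenes > 0,
            length(geneLengthRange) == 2,
            geneLengthRange[1] > 0,
            geneLengthRange[1] <= geneLengthRange[2],
            nEnhancers >= 0, minGeneGap >= 0, geneZoneReserve >= 0,
            enhancerMargin >= 0,
            unlinkedFraction >= 0, unlinkedFraction <= 1)
  structure(list(chromLengths = chromLengths, nGenes = as.integer(nGenes),
                 geneLengthRange = as.integer(geneLengthRange),
                 nEnhancers = as.integer(nEnhancers),
                 minGeneGap = as.integer(minGeneGap),
                 geneZoneReserve = as.integer(geneZoneReserve),
                 enhancerMargin = as.integer(enhancerMargin),
                 unlinkedFraction = unlinkedFraction,
                 seed = as.integer(seed)),
            class = "SyntheticGenomeSpec")
}

#' Default regulatory archetypes for the synthetic study
#'
#' Each gene is assigned one archetype that couples its planted expression
#' direction with its occupancy classes per antibody (classes: `none`,
#' `stable`, `gained` = gained after knockdown, `lost` = lost after
#' knockdown). The defaults plant the regulatory logic the pipeline is
#' meant to resolve: genes that lose the remodeller (Smarca4) upon
#' knockdown and go down, a smaller "unexpected" group that gains it and
#' still goes down, genes that gain it and go up, stably bound silent
#' genes, and unbound null genes. The broad mark (H3K27me3) is planted as
#' gained on the lost-and-down genes, giving the permutation test a real
#' positive signal to find.
#'
#' @return A `data.frame` with columns `name`, `prob`, `expression`, and
#'   one occupancy-class column per antibody.
#' @export
defaultArchetypes <- function() {
  data.frame(
    name = c("lost.down", "gained.down", "gained.up", "stable.null",
             "silent"),
    prob = c(0.20, 0.10, 0.15, 0.15, 0.40),
    expression = c("down", "down", "up", "null", "null"),
    Smarca4 = c("lost", "gained", "gained", "stable", "none"),
    H3K27me3 = c("gained", "none", "none", "stable", "none"),
    stringsAsFactors = FALSE)
}

.placeNonOverlapping <- function(n, lengths, zoneStart, zoneEnd, minGap) {
  # deterministic non-overlapping placement: lengths plus minimum gaps are
  # laid out left to right and the remaining slack is spread by sorted
  # uniform draws
  need <- sum(lengths) + (n + 1) * minGap
  avail <- zoneEnd - zoneStart
  if (need > avail)
    stop("cannot place ", n, " genes in ", avail,
         " bp without overlap (need ", need, " bp)")
  slack <- avail - need
  u <- sort(runif(n, 0, slack))
  starts0 <- zoneStart + minGap + floor(u) +
    cumsum(c(0, lengths[-n])) + (seq_len(n) - 1) * minGap
  as.integer(starts0)   # 0-based starts
}

#' Simulate a genome: gene models, enhancer anchors, planted truth
#'
#' Places non-overlapping genes (uniform random lengths within the
#' configured range, strand uniform at random) on each chromosome, assigns
#' each gene an archetype (planted occupancy classes per antibody plus an
#' expression direction), and plants enhancer anchors: linked enhancers
#' sit 4 kb upstream of a gene's interval (so their nearest gene within
#' the cap is unambiguous and their peaks stay clear of gene and TSS
#' regions), unlinked enhancers sit in the reserved gene-free chromosome
#' tail, beyond the linkage cap. Enhancer occupancy (bound in control, kd,
#' both or neither) is coupled to the linked gene's expression direction:
#' down genes get control-only-bound enhancers, up genes kd-only-bound
#' ones, null genes either both or neither.
#'
#' Deterministic given `spec$seed`.
#'
#' @param spec a [syntheticGenomeSpec()].
#' @param archetypes archetype table, see [defaultArchetypes()].
#' @return A list with `genes` (`GRanges`), `enhancers` (`GRanges` of 1 bp
#'   anchors), and `truth` (list of `occupancy`, `expression`, `enhancers`
#'   data frames).
#' @export
simulateGenome <- function(spec, archetypes = defaultArchetypes()) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"),
            is.data.frame(archetypes),
            all(c("name", "prob", "expression") %in% names(archetypes)))
  antibodies <- setdiff(names(archetypes), c("name", "prob", "expression"))
  stopifnot(length(antibodies) >= 1)
  set.seed(spec$seed)
  sl <- spec$chromLengths
  si <- Seqinfo(names(sl), seqlengths = as.integer(sl))
  # allocate genes to chromosomes proportional to length (largest remainder)
  frac <- sl / sum(sl) * spec$nGenes
  nPer <- floor(frac)
  rem <- spec$nGenes - sum(nPer)
  if (rem > 0) {
    ord <- order(frac - nPer, decreasing = TRUE)
    nPer[ord[seq_len(rem)]] <- nPer[ord[seq_len(rem)]] + 1
  }
  geneRows <- list(); gid <- 0L
  for (chrom in names(sl)) {
    n <- nPer[[chrom]]
    if (n == 0) next
    lens <- as.integer(round(runif(n, spec$geneLengthRange[1],
                                   spec$geneLengthRange[2])))
    zoneEnd <- max(sl[[chrom]] - spec$geneZoneReserve, 0)
    starts0 <- .placeNonOverlapping(n, lens, 0, zoneEnd, spec$minGeneGap)
    str <- sample(c("+", "-"), n, replace = TRUE)
    geneRows[[chrom]] <- data.frame(
      chrom = chrom, start0 = starts0, end0 = starts0 + lens,
      strand = str,
      gene_id = sprintf("gene%04d", gid + seq_len(n)),
      stringsAsFactors = FALSE)
    gid <- gid + n
  }
  gdf <- do.call(rbind, geneRows)
  genes <- GRanges(gdf$chrom, IRanges(gdf$start0 + 1L, gdf$end0),
                   strand = gdf$strand, seqinfo = si)
  genes$gene_id <- gdf$gene_id
  # archetype assignment
  arch <- sample(archetypes$name, spec$nGenes, replace = TRUE,
                 prob = archetypes$prob)
  ai <- match(arch, archetypes$name)
  expression <- data.frame(gene_id = genes$gene_id,
                           direction = archetypes$expression[ai],
                           archetype = arch, stringsAsFactors = FALSE)
  occupancy <- do.call(rbind, lapply(antibodies, function(ab)
    data.frame(gene_id = genes$gene_id, antibody = ab,
               class = archetypes[[ab]][ai], stringsAsFactors = FALSE)))
  rownames(occupancy) <- NULL
  # enhancers
  enh <- .plantEnhancers(spec, genes, expression, si)
  list(genes = genes, enhancers = enh$anchors,
       truth = list(occupancy = occupancy, expression = expression,
                    enhancers = enh$truth))
}

.plantEnhancers <- function(spec, genes, expression, si) {
  sl <- spec$chromLengths
  nE <- spec$nEnhancers
  if (nE == 0) {
    anchors <- GRanges(seqinfo = si)
    anchors$enhancer_id <- character()
    return(list(anchors = anchors,
                truth = data.frame(enhancer_id = character(),
                                   chrom = character(), anchor = integer(),
                                   bound_in = character(),
                                   linked_gene = character(),
                                   stringsAsFactors = FALSE)))
  }
  nUnlinked <- as.integer(round(spec$unlinkedFraction * nE))
  nLinked <- nE - nUnlinked
  stopifnot(nLinked <= length(genes))
  target <- sort(sample(length(genes), nLinked))
  # anchor base (1-based) 4 kb upstream of the gene interval start: nearer
  # to its gene than to any neighbour (gene gaps are larger), outside the
  # gene and TSS regions, and its local peak cannot spill into them
  anchor1 <- start(genes)[target] - 4000L
  chrom <- as.character(seqnames(genes))[target]
  dirs <- expression$direction[target]
  bound <- ifelse(dirs == "down", "control",
                  ifelse(dirs == "up", "kd",
                         sample(c("both", "neither"), nLinked,
                                replace = TRUE)))
  linked <- genes$gene_id[target]
  if (nUnlinked > 0) {
    # spread unlinked anchors over the reserved gene-free chromosome
    # tails, at least 5 kb apart so neighbouring extended intervals and
    # their local peaks cannot touch each other
    chromsU <- sort(sample(names(sl), nUnlinked, replace = TRUE))
    posU <- unlist(lapply(unique(chromsU), function(ch) {
      nCh <- sum(chromsU == ch)
      .placeNonOverlapping(nCh, rep(1L, nCh),
                           zoneStart = sl[[ch]] - 80000L,
                           zoneEnd = sl[[ch]] - spec$enhancerMargin,
                           minGap = 5000L)
    }), use.names = FALSE)
    anchor1 <- c(anchor1, posU)
    chrom <- c(chrom, chromsU)
    bound <- c(bound, sample(c("control", "kd", "both", "neither"),
                             nUnlinked, replace = TRUE))
    linked <- c(linked, rep(NA_character_, nUnlinked))
  }
  ord <- order(factor(chrom, levels = names(sl)), anchor1)
  anchor1 <- anchor1[ord]; chrom <- chrom[ord]
  bound <- bound[ord]; linked <- linked[ord]
  ids <- sprintf("enh%03d", seq_len(nE))
  anchors <- GRanges(chrom, IRanges(anchor1, anchor1), seqinfo = si)
  anchors$enhancer_id <- ids
  list(anchors = anchors,
       truth = data.frame(enhancer_id = ids, chrom = chrom,
                          anchor = anchor1, bound_in = bound,
                          linked_gene = linked, stringsAsFactors = FALSE))
}

.occupiedInCondition <- function(class, condition) {
  # class: none/stable/gained/lost; gained = enriched only after knockdown
  (class == "stable") |
    (class == "gained" & condition == "kd") |
    (class == "lost" & condition == "control")
}

.enhBoundInCondition <- function(boundIn, condition) {
  (boundIn == "both") |
    (boundIn == "kd" & condition == "kd") |
    (boundIn == "control" & condition == "control")
}

#' Simulate ChIP tag tracks from planted truth
#'
#' Tags are 1 bp positions drawn from a two-component mixture: a uniform
#' Poisson background over each chromosome (`backgroundRate` tags/bp) plus
#' a fold-elevated rate over `peakWidth` bp windows centred on the TSS of
#' every gene occupied in the given condition (and, for the enhancer
#' antibody, on every enhancer anchor bound in that condition). Regions
#' planted as gained after knockdown receive enrichment only in the kd
#' track, lost regions only in the control track, stable regions in both.
#' The input track contains background only.
#'
#' @param genome output of [simulateGenome()] (genes, enhancers, truth).
#' @param antibodies antibodies to simulate (default: those in the
#'   occupancy truth).
#' @param backgroundRate background tag density, tags/bp (default 0.005).
#' @param enrichmentFold rate multiplier inside occupied windows (>= 1,
#'   default 50).
#' @param peakWidth width of the enriched window in bp (default 1000).
#' @param nTagsTarget optional target for the expected number of background
#'   tags per track; scales `backgroundRate` accordingly. Zero is an error.
#' @param enhancerAntibody antibody whose tracks also carry enhancer
#'   enrichment (default `"Smarca4"`).
#' @param seed RNG seed.
#' @return Named list of [TagTrack-class]: one per antibody and condition
#'   (`"<antibody>.control"`, `"<antibody>.kd"`) plus a shared `"input"`.
#' @export
simulateChipTags <- function(genome, antibodies = NULL,
                             backgroundRate = 0.005, enrichmentFold = 50,
                             peakWidth = 1000L, nTagsTarget = NULL,
                             enhancerAntibody = "Smarca4", seed = 1L) {
  stopifnot(backgroundRate > 0, enrichmentFold >= 1, peakWidth > 0)
  truth <- genome$truth
  if (is.null(antibodies)) antibodies <- unique(truth$occupancy$antibody)
  sl <- seqlengths(genome$genes)
  if (!is.null(nTagsTarget)) {
    if (nTagsTarget <= 0) stop("nTagsTarget must be a positive tag count")
    backgroundRate <- nTagsTarget / sum(as.numeric(sl))
  }
  set.seed(seed)
  half <- as.integer(peakWidth) %/% 2L
  genes <- genome$genes
  tssBase <- ifelse(as.character(strand(genes)) == "-", end(genes),
                    start(genes))
  geneChrom <- as.character(seqnames(genes))
  enhTruth <- truth$enhancers
  drawTrack <- function(antibody, condition, withSignal) {
    posL <- list()
    for (chrom in names(sl)) {
      L <- sl[[chrom]]
      nBg <- rpois(1, backgroundRate * L)
      p <- if (nBg > 0) sample.int(L, nBg, replace = TRUE) else integer()
      posL[[chrom]] <- p
    }
    if (withSignal) {
      occ <- truth$occupancy[truth$occupancy$antibody == antibody, ,
                             drop = FALSE]
      gi <- match(occ$gene_id, genes$gene_id)
      on <- .occupiedInCondition(occ$class, condition)
      centres <- tssBase[gi][on]; chroms <- geneChrom[gi][on]
      if (antibody == enhancerAntibody && nrow(enhTruth)) {
        eOn <- .enhBoundInCondition(enhTruth$bound_in, condition)
        centres <- c(centres, enhTruth$anchor[eOn])
        chroms <- c(chroms, enhTruth$chrom[eOn])
      }
      extraRate <- backgroundRate * (enrichmentFold - 1)
      for (j in seq_along(centres)) {
        lo <- max(centres[j] - half, 1L)
        hi <- min(centres[j] + half, sl[[chroms[j]]])
        nX <- rpois(1, extraRate * (hi - lo + 1L))
        if (nX > 0)
          posL[[chroms[j]]] <- c(posL[[chroms[j]]],
                                 lo + sample.int(hi - lo + 1L, nX,
                                                 replace = TRUE) - 1L)
      }
    }
    pos <- unlist(lapply(names(sl), function(ch) sort(posL[[ch]])),
                  use.names = FALSE)
    chromRep <- rep(names(sl),
                    vapply(names(sl), function(ch) length(posL[[ch]]),
                           integer(1)))
    gr <- GRanges(chromRep, IRanges(pos, pos),
                  seqinfo = Seqinfo(names(sl),
                                    seqlengths = as.integer(sl)))
    TagTrack(gr, antibody = antibody, condition = condition)
  }
  tracks <- list()
  for (ab in antibodies) {
    tracks[[paste0(ab, ".control")]] <- drawTrack(ab, "control", TRUE)
    tracks[[paste0(ab, ".kd")]] <- drawTrack(ab, "kd", TRUE)
  }
  tracks[["input"]] <- drawTrack("input", "input", FALSE)
  tracks
}

#' Simulate a differential expression table from planted truth
#'
#' Planted up/down genes get `log2FC = +/- effectSizeLog2 + noise` and an
#' adjusted p-value drawn uniformly below 0.05; null genes get `log2FC ~
#' Normal(0, nullSd)` and an adjusted p-value drawn uniformly above 0.05.
#' Only the filter semantics matter downstream, so p-values are assigned by
#' class rather than fitted from counts.
#'
#' @param genome output of [simulateGenome()].
#' @param effectSizeLog2 planted absolute log2 fold change (> 0; values
#'   above 0.58 make planted genes pass the default filter).
#' @param nullSd standard deviation of log2FC noise (planted and null).
#' @param seed RNG seed.
#' @return `data.frame` with columns `gene_id`, `log2FC`, `padj`.
#' @export
simulateDETable <- function(genome, effectSizeLog2 = 2, nullSd = 0.1,
                            seed = 1L) {
  stopifnot(effectSizeLog2 > 0, nullSd >= 0)
  expr <- genome$truth$expression
  set.seed(seed)
  n <- nrow(expr)
  sign_ <- c(up = 1, down = -1, null = 0)[expr$direction]
  lfc <- sign_ * effectSizeLog2 + rnorm(n, 0, nullSd)
  padj <- ifelse(expr$direction == "null", runif(n, 0.05, 1),
                 runif(n, 0, 0.05))
  data.frame(gene_id = expr$gene_id, log2FC = lfc, padj = padj,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic knockdown study
#'
#' Chains [simulateGenome()], [simulateChipTags()] and [simulateDETable()],
#' deriving the three stage seeds from `spec$seed` (`seed`, `seed + 1`,
#' `seed + 2`), and returns everything in a [SyntheticStudy-class].
#'
#' @inheritParams simulateGenome
#' @inheritParams simulateChipTags
#' @inheritParams simulateDETable
#' @return A [SyntheticStudy-class] object.
#' @examples
#' study <- simulateStudy(syntheticGenomeSpec(
#'   chromLengths = c(chr1 = 1e6), nGenes = 20, nEnhancers = 8, seed = 7))
#' study
#' @export
simulateStudy <- function(spec = syntheticGenomeSpec(),
                          archetypes = defaultArchetypes(),
                          backgroundRate = 0.005, enrichmentFold = 50,
                          peakWidth = 1000L, nTagsTarget = NULL,
                          enhancerAntibody = "Smarca4",
                          effectSizeLog2 = 2, nullSd = 0.1) {
  genome <- simulateGenome(spec, archetypes)
  tags <- simulateChipTags(genome, backgroundRate = backgroundRate,
                           enrichmentFold = enrichmentFold,
                           peakWidth = peakWidth,
                           nTagsTarget = nTagsTarget,
                           enhancerAntibody = enhancerAntibody,
                           seed = spec$seed + 1L)
  de <- simulateDETable(genome, effectSizeLog2 = effectSizeLog2,
                        nullSd = nullSd, seed = spec$seed + 2L)
  new("SyntheticStudy", genes = genome$genes,
      enhancers = genome$enhancers, tags = tags, de = de,
      truth = genome$truth,
      params = list(spec = spec, archetypes = archetypes,
                    backgroundRate = backgroundRate,
                    enrichmentFold = enrichmentFold,
                    peakWidth = as.integer(peakWidth),
                    enhancerAntibody = enhancerAntibody,
                    effectSizeLog2 = effectSizeLog2, nullSd = nullSd))
}

#' Write a synthetic study to disk
#'
#' Writes the gene annotation (BED6), enhancer anchors (BED3), tag tracks
#' (BED3, one file per track), the DE table and the planted-truth tables
#' (TSV) into a directory.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBed(geneModels(study), file.path(dir, "genes.bed"),
           name = "gene_id")
  writeBed(enhancerAnchors(study), file.path(dir, "enhancers.bed"))
  tagDir <- file.path(dir, "tags")
  dir.create(tagDir, showWarnings = FALSE)
  for (nm in names(tagTracks(study)))
    writeBed(tagPositions(tagTracks(study)[[nm]]),
             file.path(tagDir, paste0(nm, ".bed")))
  wTsv <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
  wTsv(deTable(study), "de.tsv")
  wTsv(plantedTruth(study)$occupancy, "truth_occupancy.tsv")
  wTsv(plantedTruth(study)$expression, "truth_expression.tsv")
  wTsv(plantedTruth(study)$enhancers, "truth_enhancers.tsv")
  invisible(dir)
}
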