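#' @include annotation.R
NULL

.checkDeTable <- function(de) {
  need <- c("gene_id", "log2FC", "padj")
  if (!all(need %in% names(de)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(de$gene_id) | !is.finite(de$log2FC))
  if (length(bad))
    stop("malformed DE table row(s): ", paste(head(bad, 5L), collapse = ", "))
  invisible(de)
}

#' Filter a differential expression table
#'
#' Retains genes with adjusted p-value strictly below `alpha` and absolute
#' log2 fold change strictly above `lfcMin`, split by direction. Missing
#' adjusted p-values are treated as non-significant.
#'
#' @param de `data.frame` with columns `gene_id`, `log2FC`, `padj`.
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param lfcMin absolute log2 fold-change threshold (default 0.58).
#' @return A list of class `DEFilter` with data frames `up`
#'   (`log2FC > lfcMin`), `down` (`log2FC < -lfcMin`) and `excluded`; the
#'   three partition the input.
#' @examples
#' de <- data.frame(gene_id = c("a", "b"), log2FC = c(0.6, 0.5),
#'                  padj = c(0.04, 0.04))
#' filterDE(de)$up$gene_id   # "a" only: 0.5 fails the fold-change bound
#' @export
filterDE <- function(de, alpha = 0.05, lfcMin = 0.58) {
  .checkDeTable(de)
  sig <- !is.na(de$padj) & de$padj < alpha
  up <- sig & de$log2FC > lfcMin
  down <- sig & de$log2FC < -lfcMin
  structure(list(up = de[up, , drop = FALSE],
                 down = de[down, , drop = FALSE],
                 excluded = de[!(up | down), , drop = FALSE],
                 alpha = alpha, lfcMin = lfcMin),
            class = "DEFilter")
}

#' Merge expression contrasts with peak-class memberships
#'
#' Joins a DE table with the gene/antibody/class membership table from
#' [assignPeaks()] by gene id. Genes present in the DE table but carrying no
#' surviving peak are kept with empty memberships and flagged; membership
#' rows whose gene is absent from the DE table are dropped (no expression
#' contrast to merge with).
#'
#' @param de `data.frame` with `gene_id`, `log2FC`, `padj`; gene ids must be
#'   unique.
#' @param membership membership table from [assignPeaks()].
#' @param alpha,lfcMin significance thresholds used to derive the
#'   `direction` column (see [filterDE()]).
#' @return A long `data.frame`: `gene_id`, `log2FC`, `padj`, `direction`
#'   (`up`/`down`/`ns`), `has_binding`, and for binding rows `antibody`,
#'   `class`, `n_peaks` (NA otherwise).
#' @export
mergeExpressionBinding <- function(de, membership, alpha = 0.05,
                                   lfcMin = 0.58) {
  .checkDeTable(de)
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene ids in DE table")
  flt <- filterDE(de, alpha, lfcMin)
  direction <- rep("ns", nrow(de))
  direction[de$gene_id %in% flt$up$gene_id] <- "up"
  direction[de$gene_id %in% flt$down$gene_id] <- "down"
  names(direction) <- de$gene_id
  m <- membership[membership$gene_id %in% de$gene_id, , drop = FALSE]
  bound <- unique(m$gene_id)
  idx <- match(m$gene_id, de$gene_id)
  withB <- data.frame(gene_id = m$gene_id, log2FC = de$log2FC[idx],
                      padj = de$padj[idx],
                      direction = direction[m$gene_id],
                      has_binding = TRUE, antibody = m$antibody,
                      class = m$class, n_peaks = m$n_peaks,
                      stringsAsFactors = FALSE)
  lone <- de[!de$gene_id %in% bound, , drop = FALSE]
  noB <- data.frame(gene_id = lone$gene_id, log2FC = lone$log2FC,
                    padj = lone$padj, direction = direction[lone$gene_id],
                    has_binding = FALSE, antibody = NA_character_,
                    class = NA_character_, n_peaks = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- rbind(withB, noB)
  out <- out[order(out$gene_id, out$antibody, out$class,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Six-way comparison of two knockdown expression contrasts
#'
#' Categorises genes by their response to two subunit knockdowns (Smarcb1 =
#' "B1", Smarca4 = "A4" in the canonical use). "Repressed" genes go up after
#' knockdown of the subunit; "activated" genes go down. Core categories
#' require a concordant significant change in both tables; "X-not-Y"
#' categories require significance in X and the absence of that direction's
#' significant change in Y. Genes significant in opposite directions in the
#' two tables are reported as `"discordant"` in the single-label output, or
#' receive both applicable "X-not-Y" labels when `multiLabel = TRUE`.
#'
#' @param b1De,a4De DE `data.frame`s over a shared gene-id namespace.
#' @param pMax adjusted p-value threshold (default 0.05).
#' @param lfcMin absolute log2FC threshold per table; a single value or a
#'   length-2 vector `(b1, a4)` (default 0.58).
#' @param multiLabel emit one row per applicable label for discordant genes.
#' @return `data.frame` with `gene_id` and `category` (one of
#'   `core-esBAF-repressed`, `core-esBAF-activated`, `B1-repressed-not-A4`,
#'   `B1-activated-not-A4`, `A4-repressed-not-B1`, `A4-activated-not-B1`,
#'   `discordant`); genes significant in neither table are omitted.
#' @export
sixWayCategories <- function(b1De, a4De, pMax = 0.05, lfcMin = 0.58,
                             multiLabel = FALSE) {
  .checkDeTable(b1De); .checkDeTable(a4De)
  lfcMin <- rep_len(lfcMin, 2L)
  stat <- function(de, ids, lfc) {
    i <- match(ids, de$gene_id)
    sig <- !is.na(i) & !is.na(de$padj[i]) & de$padj[i] < pMax
    list(rep = sig & de$log2FC[i] > lfc,      # up after kd
         act = sig & de$log2FC[i] < -lfc)     # down after kd
  }
  ids <- sort(unique(c(b1De$gene_id, a4De$gene_id)))
  b1 <- stat(b1De, ids, lfcMin[1L]); a4 <- stat(a4De, ids, lfcMin[2L])
  rows <- list()
  add <- function(id, cat)
    rows[[length(rows) + 1L]] <<- data.frame(gene_id = id, category = cat,
                                             stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    id <- ids[j]
    bR <- b1$rep[j]; bA <- b1$act[j]; aR <- a4$rep[j]; aA <- a4$act[j]
    if (!(bR || bA || aR || aA)) next
    if (bR && aR) add(id, "core-esBAF-repressed")
    else if (bA && aA) add(id, "core-esBAF-activated")
    else if ((bR && aA) || (bA && aR)) {      # discordant
      if (multiLabel) {
        if (bR) add(id, "B1-repressed-not-A4")
        if (bA) add(id, "B1-activated-not-A4")
        if (aR) add(id, "A4-repressed-not-B1")
        if (aA) add(id, "A4-activated-not-B1")
      } else add(id, "discordant")
    }
    else if (bR) add(id, "B1-repressed-not-A4")
    else if (bA) add(id, "B1-activated-not-A4")
    else if (aR) add(id, "A4-repressed-not-B1")
    else if (aA) add(id, "A4-activated-not-B1")
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), category = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-contrast log2FC matrix with zero substitution
#'
#' Builds the gene-by-contrast matrix behind the two-knockdown heatmap:
#' rows are all genes with adjusted p-value below `alpha` in at least one
#' table; each cell carries the table's log2 fold change, replaced by 0
#' when that table has `padj > alpha` or `|log2FC| < lfcMin` (or the gene is
#' absent). Rows are ordered by gene id; no clustering is applied.
#'
#' @inheritParams sixWayCategories
#' @param alpha p-value threshold for inclusion and substitution (0.05).
#' @return Numeric matrix with rownames `gene_id` and columns `b1`, `a4`.
#' @export
heatmapMatrix <- function(b1De, a4De, alpha = 0.05, lfcMin = 0.58) {
  .checkDeTable(b1De); .checkDeTable(a4De)
  sigIds <- function(de) de$gene_id[!is.na(de$padj) & de$padj < alpha]
  ids <- sort(unique(c(sigIds(b1De), sigIds(a4De))))
  cell <- function(de, ids) {
    i <- match(ids, de$gene_id)
    v <- de$log2FC[i]
    p <- de$padj[i]
    zero <- is.na(i) | is.na(p) | p > alpha | abs(v) < lfcMin
    v[zero] <- 0
    v
  }
  m <- cbind(b1 = cell(b1De, ids), a4 = cell(a4De, ids))
  rownames(m) <- ids
  m
}
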