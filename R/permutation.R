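#' @include integration.R
NULL

#' Bonferroni-adjusted per-test significance threshold
#'
#' @param alpha family-wise significance level.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a positive count")
  alpha / m
}

#' Build the basic gene set for the binding-pattern permutation test
#'
#' The basic set consists of significantly downregulated genes that carry a
#' *differential* peak membership (DECREASE or INCREASE) for the reference
#' antibody, split by that category into a D-group and an I-group. Genes
#' whose only reference-antibody signal is a standard or COMMON peak are
#' excluded. A gene with memberships in both differential categories (rare:
#' peak-level conflict resolution makes peaks exclusive, but a gene can own
#' several peaks) is placed with the category backed by more peaks; on a
#' tie it is dropped with a warning.
#'
#' @param deDown `data.frame` of significantly downregulated genes (e.g.
#'   `filterDE(de)$down`).
#' @param membership membership table from [assignPeaks()].
#' @param refAntibody the antibody whose differential classes define the
#'   partition (default `"Smarca4"`).
#' @return A list of class `BasicGeneSet` with character vectors `D` and `I`
#'   of gene ids. An empty basic set is signalled with a warning.
#' @export
buildBasicSet <- function(deDown, membership, refAntibody = "Smarca4") {
  stopifnot(is.data.frame(deDown), "gene_id" %in% names(deDown))
  m <- membership[membership$antibody == refAntibody &
                  membership$class %in% c("DECREASE", "INCREASE") &
                  membership$gene_id %in% deDown$gene_id, , drop = FALSE]
  D <- character(); I <- character()
  for (id in unique(m$gene_id)) {
    rows <- m[m$gene_id == id, , drop = FALSE]
    if (nrow(rows) == 1L) {
      if (rows$class == "DECREASE") D <- c(D, id) else I <- c(I, id)
    } else {
      nd <- sum(rows$n_peaks[rows$class == "DECREASE"])
      ni <- sum(rows$n_peaks[rows$class == "INCREASE"])
      if (nd > ni) D <- c(D, id)
      else if (ni > nd) I <- c(I, id)
      else warning("gene ", id, " tied between DECREASE and INCREASE; ",
                   "dropped from basic set")
    }
  }
  if (!length(D) && !length(I))
    warning("empty basic set: no downregulated genes with differential ",
            refAntibody, " signal")
  structure(list(D = sort(D), I = sort(I), refAntibody = refAntibody),
            class = "BasicGeneSet")
}

#' Count genes in a group with a concurrent ChIP signal
#'
#' @param group character vector of gene ids.
#' @param membership membership table from [assignPeaks()].
#' @param antibody,category the signal counted: the antibody and one of
#'   `ctrl`, `kd`, `DECREASE`, `INCREASE`, `COMMON`.
#' @return Number of `group` genes with at least one peak of that
#'   antibody and category.
#' @export
countConcurrent <- function(group, membership, antibody, category) {
  category <- match.arg(category, .PEAK_CLASSES)
  hit <- membership$gene_id[membership$antibody == antibody &
                            membership$class == category]
  sum(group %in% hit)
}

#' Monte-Carlo permutation test of a binding pattern
#'
#' Tests whether the `k` basic-set genes carrying a given ChIP signal are
#' over- or under-represented in the D-group (size `nD`) of a basic set of
#' `N` genes. Each of `nPermutations` shuffles redistributes the `k`
#' signal labels uniformly over the `N` genes and records the D-group count
#' `x*`; a uniform placement of `k` labels among `N` genes split `nD`/`N -
#' nD` makes `x*` hypergeometric, and the shuffle is drawn accordingly.
#' Empirical tail probabilities use add-one smoothing,
#' `(#\{x* as-or-more-extreme\} + 1) / (B + 1)`, so reported p-values are
#' never zero; the two-sided p-value is the doubled smaller tail, capped at
#' 1.
#'
#' The significance decision follows the two-sided quantile rule: the
#' observed count is significant when it falls within the lowest or highest
#' `tailAlpha` fraction of shuffles (default 0.025 per tail), Bonferroni
#' adjusted over `m` tests ([bonferroniThreshold()]). An observed count more
#' extreme than every shuffle is tiered `"highly-significant"`.
#'
#' @param N basic-set size.
#' @param nD D-group size (`nD <= N`).
#' @param k number of basic-set genes carrying the signal (`k <= N`).
#' @param xObs observed D-group count (`0 <= xObs <= min(k, nD)`).
#' @param nPermutations number of shuffles B (default 1e6).
#' @param tailAlpha per-tail significance level before correction
#'   (default 0.025).
#' @param m number of tests in the family for Bonferroni (default 1).
#' @param seed optional RNG seed for reproducibility.
#' @param antibody,category optional labels stored on the result.
#' @return A [PermutationResult-class] object.
#' @examples
#' permutationTest(N = 10, nD = 5, k = 5, xObs = 5,
#'                 nPermutations = 1e5, seed = 1)
#' @export
permutationTest <- function(N, nD, k, xObs, nPermutations = 1e6,
                            tailAlpha = 0.025, m = 1L, seed = NULL,
                            antibody = "", category = "") {
  N <- as.integer(N); nD <- as.integer(nD); k <- as.integer(k)
  xObs <- as.integer(xObs); B <- as.integer(nPermutations)
  if (k > N || nD > N) stop("k and nD must not exceed N")
  if (xObs < max(0L, k + nD - N) || xObs > min(k, nD))
    stop("xObs outside the feasible range for (N, nD, k)")
  stopifnot(B >= 1L, tailAlpha > 0, tailAlpha < 0.5)
  if (!is.null(seed)) set.seed(seed)
  xStar <- rhyper(B, m = k, n = N - k, k = nD)
  nLow <- sum(xStar <= xObs); nHigh <- sum(xStar >= xObs)
  pLower <- (nLow + 1) / (B + 1)
  pUpper <- (nHigh + 1) / (B + 1)
  pValue <- min(1, 2 * min(pLower, pUpper))
  expected <- k * nD / N
  direction <- if (xObs > expected) "positive"
               else if (xObs < expected) "negative" else "none"
  adjTail <- bonferroniThreshold(tailAlpha * 2, m) / 2
  significant <- (nLow / B) <= adjTail || (nHigh / B) <= adjTail
  tier <- if (xObs > max(xStar) || xObs < min(xStar)) "highly-significant"
          else if (significant) "significant" else "none"
  new("PermutationResult", antibody = as.character(antibody),
      category = as.character(category), N = N, nD = nD, k = k,
      observed = xObs, expected = expected, nullMean = mean(xStar),
      pLower = pLower, pUpper = pUpper, pValue = pValue,
      direction = direction, tier = tier, nPermutations = B)
}

#' Run the full battery of binding-pattern permutation tests
#'
#' For every antibody and peak category, counts the basic-set genes with a
#' concurrent signal ([countConcurrent()]) and runs [permutationTest()] on
#' the D-group count. The Bonferroni family size `m` defaults to the number
#' of antibody-category combinations tested. Each combination yields two
#' mirrored rows (partitions `D` and `I`): the I-partition observed count is
#' `k - xObs` and shares the two-sided p-value by symmetry, with the
#' direction flipped.
#'
#' @param basicSet a `BasicGeneSet` from [buildBasicSet()].
#' @param membership membership table from [assignPeaks()].
#' @param antibodies character vector of antibodies to test (the reference
#'   antibody of the basic set is excluded automatically).
#' @param categories peak categories to test (default all five).
#' @param nPermutations,tailAlpha see [permutationTest()].
#' @param seed base seed; each combination uses `seed +` its index.
#' @return A `data.frame`, one row per antibody-category-partition, with the
#'   counts, p-values, direction and tier; attributes `m` and
#'   `adjustedTailAlpha` record the correction.
#' @export
runPermutationTests <- function(basicSet, membership, antibodies,
                                categories = .PEAK_CLASSES,
                                nPermutations = 1e6, tailAlpha = 0.025,
                                seed = 1L) {
  stopifnot(inherits(basicSet, "BasicGeneSet"))
  antibodies <- setdiff(antibodies, basicSet$refAntibody)
  N <- length(basicSet$D) + length(basicSet$I)
  nD <- length(basicSet$D)
  if (N == 0L) stop("cannot test an empty basic set")
  combos <- expand.grid(category = categories, antibody = antibodies,
                        stringsAsFactors = FALSE)
  m <- nrow(combos)
  rows <- vector("list", 2L * m)
  for (j in seq_len(m)) {
    ab <- combos$antibody[j]; cat_ <- combos$category[j]
    xD <- countConcurrent(basicSet$D, membership, ab, cat_)
    xI <- countConcurrent(basicSet$I, membership, ab, cat_)
    k <- xD + xI
    res <- permutationTest(N, nD, k, xD, nPermutations = nPermutations,
                           tailAlpha = tailAlpha, m = m,
                           seed = seed + j, antibody = ab,
                           category = cat_)
    asRow <- function(partition, obs, dir)
      data.frame(antibody = ab, category = cat_, partition = partition,
                 N = N, n_group = if (partition == "D") nD else N - nD,
                 k = k, observed = obs, expected = if (partition == "D")
                   res@expected else k - res@expected,
                 null_mean = if (partition == "D") res@nullMean
                   else k - res@nullMean,
                 p_lower = if (partition == "D") res@pLower else res@pUpper,
                 p_upper = if (partition == "D") res@pUpper else res@pLower,
                 p_value = res@pValue, direction = dir, tier = res@tier,
                 stringsAsFactors = FALSE)
    flip <- c(positive = "negative", negative = "positive", none = "none")
    rows[[2L * j - 1L]] <- asRow("D", xD, res@direction)
    rows[[2L * j]] <- asRow("I", xI, unname(flip[res@direction]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "adjustedTailAlpha") <- tailAlpha / m
  out
}
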