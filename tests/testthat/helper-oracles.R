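# Brute-force oracles, written independently of the package internals.
# Coordinates in these helpers are plain 1-based closed integers carried in
# data frames; conversion to GRanges happens only at the package boundary.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

dfToGr <- function(df, seqlengths = NULL) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  if (!is.null(seqlengths)) {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- seqlengths
  }
  gr
}

randomIntervalDf <- function(n, chroms, L, maxWidth = 500L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - maxWidth, n, replace = TRUE)
  width <- sample.int(maxWidth, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width - 1L,
             stringsAsFactors = FALSE)
}

# exhaustive pairwise scan: intersection of closed intervals
oracleOverlapPairs <- function(a, b, minOverlap = 1L) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (e - s + 1L >= minOverlap)
      rows[[length(rows) + 1L]] <- data.frame(
        aIdx = i, bIdx = j, chrom = a$chrom[i], intStart = s, intEnd = e,
        intWidth = e - s + 1L, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(aIdx = integer(), bIdx = integer(),
                      chrom = character(), intStart = integer(),
                      intEnd = integer(), intWidth = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, a$start[out$aIdx], b$start[out$bIdx],
                   out$aIdx, out$bIdx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base membership oracle: paint bases, close gaps <= maxGap, read runs
oracleMergePerBase <- function(df, maxGap, seqlengths) {
  rows <- list()
  for (chrom in names(seqlengths)) {
    sub <- df[df$chrom == chrom, , drop = FALSE]
    if (!nrow(sub)) next
    L <- seqlengths[[chrom]]
    cov <- logical(L)
    for (i in seq_len(nrow(sub))) cov[sub$start[i]:sub$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # fill interior gaps of length <= maxGap
    for (j in seq_along(r$values))
      if (!r$values[j] && j > 1L && j < length(r$values) &&
          r$lengths[j] <= maxGap)
        cov[starts[j]:ends[j]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      rows[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                  end = ends[keep],
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exhaustive distance scan; distance = bases strictly between closed spans
oracleNearestScan <- function(q, s, cap) {
  out <- data.frame(queryIdx = seq_len(nrow(q)), subjectIdx = NA_integer_,
                    distance = NA_integer_)
  for (i in seq_len(nrow(q))) {
    best <- NULL; bestD <- Inf
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] != s$chrom[j]) next
      d <- max(0L, s$start[j] - q$end[i] - 1L, q$start[i] - s$end[j] - 1L)
      better <- d < bestD ||
        (d == bestD && !is.null(best) && s$start[j] < s$start[best])
      if (better) { best <- j; bestD <- d }
    }
    if (!is.null(best) && bestD <= cap) {
      out$subjectIdx[i] <- best
      out$distance[i] <- bestD
    }
  }
  out
}

# upper-tail Poisson probability by direct series summation
oraclePoissonUpper <- function(count, lambda, extra = 3000L) {
  i <- seq(count, count + extra)
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# brute-force island enumeration: per-window counts by tag loops, explicit
# eligibility, transitive gap closure, island-level Poisson filter
oracleIslands <- function(treatment, control, cfg) {
  tp <- chipshift::tagPositions(treatment)
  cp <- chipshift::tagPositions(control)
  sl <- GenomeInfoDb::seqlengths(tp)
  w <- cfg$window
  nT <- length(tp); nC <- length(cp)
  scale <- if (nC > 0) nT / nC else 1
  floorLam <- if (isTRUE(cfg$backgroundFloor))
    nT / sum(as.numeric(sl)) * w else 0
  rows <- list()
  for (chrom in names(sl)) {
    L <- sl[[chrom]]
    nW <- as.integer(ceiling(L / w))
    tPos <- BiocGenerics::start(tp[GenomeInfoDb::seqnames(tp) == chrom])
    cPos <- BiocGenerics::start(cp[GenomeInfoDb::seqnames(cp) == chrom])
    tc <- integer(nW); cc <- integer(nW)
    for (p in tPos) { k <- (p - 1L) %/% w + 1L; tc[k] <- tc[k] + 1L }
    for (p in cPos) { k <- (p - 1L) %/% w + 1L; cc[k] <- cc[k] + 1L }
    lambda <- pmax((cc + cfg$pseudocount) * scale, floorLam)
    if (cfg$localWindow > 0) {
      half <- as.integer(ceiling(cfg$localWindow / (2 * w)))
      for (k in seq_len(nW)) {
        span <- max(1L, k - half):min(nW, k + half)
        lambda[k] <- max(lambda[k],
                         (mean(cc[span]) + cfg$pseudocount) * scale)
      }
    }
    elig <- integer()
    for (k in seq_len(nW))
      if (tc[k] > 0 &&
          oraclePoissonUpper(tc[k], lambda[k]) < cfg$windowP)
        elig <- c(elig, k)
    if (!length(elig)) next
    # transitive closure: windows i, j joined when the bp gap between them
    # ((j - i - 1) * w) is at most cfg$gap
    groups <- list(); cur <- elig[1L]
    if (length(elig) > 1L) for (k in elig[-1L]) {
      if ((k - cur[length(cur)] - 1L) * w <= cfg$gap) cur <- c(cur, k)
      else { groups[[length(groups) + 1L]] <- cur; cur <- k }
    }
    groups[[length(groups) + 1L]] <- cur
    for (g in groups) {
      span <- seq(min(g), max(g))
      cnt <- sum(tc[span]); lam <- sum(lambda[span])
      pv <- oraclePoissonUpper(cnt, lam)
      if (pv < cfg$pCutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = (min(g) - 1L) * w + 1L,
          end = min(max(g) * w, L), count = cnt, expected = lam,
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

randomTagTrack <- function(n, seqlengths, antibody = "ab",
                           condition = "control", hotspots = NULL) {
  chrom <- sample(names(seqlengths), n, replace = TRUE)
  pos <- vapply(chrom, function(ch) sample.int(seqlengths[[ch]], 1L),
                integer(1))
  if (!is.null(hotspots)) {
    for (h in hotspots) {
      extra <- sample(seq(h$start, h$end), h$n, replace = TRUE)
      chrom <- c(chrom, rep(h$chrom, h$n)); pos <- c(pos, extra)
    }
  }
  gr <- GRanges(chrom, IRanges(pos, pos))
  seqlevels(gr) <- names(seqlengths)
  seqlengths(gr) <- seqlengths
  chipshift::TagTrack(gr, antibody = antibody, condition = condition)
}

# one small study, simulated once per test run and reused
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- chipshift::simulateStudy(chipshift::syntheticGenomeSpec(
        chromLengths = c(chr1 = 1.5e6, chr2 = 1.5e6), nGenes = 60,
        nEnhancers = 20, seed = 11))
    cache
  }
})
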