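test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroniThreshold(0.05, 20), 0.0025)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  for (m in c(1, 3, 17)) expect_lte(bonferroniThreshold(0.05, m), 0.05)
  expect_error(bonferroniThreshold(0.05, 0))
})

test_that("basic set keeps only downregulated genes with differential signal", {
  down <- data.frame(gene_id = c("gA", "gB", "gC", "gD"))
  mem <- data.frame(
    gene_id = c("gA", "gB", "gC", "gE"),
    antibody = "Smarca4",
    class = c("DECREASE", "INCREASE", "COMMON", "DECREASE"),
    n_peaks = 1L, provenance = "tss", stringsAsFactors = FALSE)
  bs <- buildBasicSet(down, mem)
  expect_equal(bs$D, "gA")
  expect_equal(bs$I, "gB")
  # gC has only COMMON signal, gD none, gE is not downregulated
  expect_false(any(c("gC", "gD", "gE") %in% c(bs$D, bs$I)))
  # empty basic set is signalled
  expect_warning(buildBasicSet(data.frame(gene_id = "zz"), mem), "empty")
})

test_that("concurrent-signal counts equal an exhaustive scan", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:50)
  mem <- data.frame(
    gene_id = sample(genes, 120, replace = TRUE),
    antibody = sample(c("Ezh2", "H3K4me3"), 120, replace = TRUE),
    class = sample(c("ctrl", "kd", "COMMON", "INCREASE", "DECREASE"),
                   120, replace = TRUE),
    n_peaks = 1L, provenance = "tss", stringsAsFactors = FALSE)
  grp <- sample(genes, 20)
  for (ab in c("Ezh2", "H3K4me3")) for (cl in c("kd", "COMMON")) {
    brute <- sum(vapply(grp, function(g)
      any(mem$gene_id == g & mem$antibody == ab & mem$class == cl),
      logical(1)))
    expect_equal(countConcurrent(grp, mem, ab, cl), brute)
  }
  expect_equal(countConcurrent(grp, mem[0, ], "Ezh2", "kd"), 0L)
  allMem <- data.frame(gene_id = grp, antibody = "Ezh2", class = "kd",
                       n_peaks = 1L, provenance = "tss")
  expect_equal(countConcurrent(grp, allMem, "Ezh2", "kd"), length(grp))
})

test_that("shuffle null equals the hypergeometric distribution", {
  B <- 20000L
  grid <- expand.grid(N = c(10L, 25L, 40L), frac = c(0.3, 0.5),
                      kfrac = c(0.2, 0.6))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]
    nD <- max(1L, as.integer(round(grid$frac[i] * N)))
    k <- max(1L, as.integer(round(grid$kfrac[i] * N)))
    xObs <- as.integer(round(k * nD / N))
    res <- permutationTest(N, nD, k, xObs, nPermutations = B, seed = 100 + i)
    exactLow <- phyper(xObs, k, N - k, nD)
    exactHigh <- phyper(xObs - 1, k, N - k, nD, lower.tail = FALSE)
    tol <- function(p) 3 * sqrt(p * (1 - p) / B) + 2 / (B + 1)
    expect_lt(abs(res@pLower - exactLow), tol(exactLow))
    expect_lt(abs(res@pUpper - exactHigh), tol(exactHigh))
  }
})

test_that("worked example: all five signal genes in a balanced half", {
  # N=10, nD=5, k=5, xObs=5: exact upper tail C(5,5)C(5,0)/C(10,5) = 1/252
  exact <- 1 / choose(10, 5)
  expect_equal(phyper(4, 5, 5, 5, lower.tail = FALSE), exact)
  res <- permutationTest(10, 5, 5, 5, nPermutations = 1e5, seed = 9)
  expect_lt(abs(res@pUpper - exact),
            3 * sqrt(exact * (1 - exact) / 1e5) + 2 / (1e5 + 1))
  expect_equal(res@direction, "positive")
})

test_that("saturated signal is never significant", {
  res <- permutationTest(N = 20, nD = 8, k = 20, xObs = 8,
                         nPermutations = 1000, seed = 2)
  expect_equal(res@pValue, 1)
  expect_equal(res@tier, "none")
  expect_equal(res@direction, "none")
})

test_that("counts beyond every shuffle are tiered highly significant", {
  # N=40, nD=20, k=12, xObs=12: upper tail ~ 1.3e-5, essentially never drawn
  res <- permutationTest(40, 20, 12, 12, nPermutations = 20000, seed = 3)
  expect_equal(res@tier, "highly-significant")
  expect_equal(res@direction, "positive")
})

test_that("results are reproducible and symmetric between partitions", {
  a <- permutationTest(30, 12, 9, 7, nPermutations = 5000, seed = 77)
  b <- permutationTest(30, 12, 9, 7, nPermutations = 5000, seed = 77)
  expect_equal(a@pValue, b@pValue)
  expect_equal(a@nullMean, b@nullMean)
  # testing the I-group with the mirrored count gives the same two-sided p
  i <- permutationTest(30, 30 - 12, 9, 9 - 7, nPermutations = 5000,
                       seed = 77)
  exact2 <- function(x, N, nD, k)
    min(1, 2 * min(phyper(x, k, N - k, nD),
                   phyper(x - 1, k, N - k, nD, lower.tail = FALSE)))
  expect_equal(exact2(7, 30, 12, 9), exact2(2, 30, 18, 9))
  expect_lt(abs(a@pValue - i@pValue), 0.05)
})

test_that("contract violations are rejected", {
  expect_error(permutationTest(10, 11, 5, 3), "exceed")
  expect_error(permutationTest(10, 5, 11, 3), "exceed")
  expect_error(permutationTest(10, 5, 5, 6), "feasible")
})

test_that("battery runner mirrors D and I rows and sets the family size", {
  set.seed(50)
  bs <- structure(list(D = sprintf("d%02d", 1:12),
                       I = sprintf("i%02d", 1:6),
                       refAntibody = "Smarca4"),
                  class = "BasicGeneSet")
  mem <- data.frame(
    gene_id = c(bs$D[1:8], bs$I[1:2]),
    antibody = "Ezh2", class = "kd", n_peaks = 1L, provenance = "tss",
    stringsAsFactors = FALSE)
  out <- runPermutationTests(bs, mem, antibodies = "Ezh2",
                             categories = c("kd", "COMMON"),
                             nPermutations = 5000, seed = 4)
  expect_equal(nrow(out), 4L)             # 2 categories x 2 partitions
  expect_equal(attr(out, "m"), 2L)
  dRow <- out[out$category == "kd" & out$partition == "D", ]
  iRow <- out[out$category == "kd" & out$partition == "I", ]
  expect_equal(dRow$observed + iRow$observed, dRow$k)
  expect_equal(dRow$p_value, iRow$p_value)
  expect_true(dRow$direction != iRow$direction ||
              dRow$direction == "none")
})
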