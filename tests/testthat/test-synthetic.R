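test_that("genome simulation is seeded-deterministic and respects bounds", {
  spec <- syntheticGenomeSpec(chromLengths = c(chrA = 1e6), nGenes = 50,
                              nEnhancers = 10, seed = 1)
  g1 <- simulateGenome(spec)
  g2 <- simulateGenome(spec)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$truth, g2$truth)
  expect_equal(length(g1$genes), 50L)
  # non-overlap on the single chromosome
  s <- sort(g1$genes, ignore.strand = TRUE)
  expect_true(all(start(s)[-1L] > end(s)[-length(s)]))
  expect_true(all(end(g1$genes) <= 1e6))
  # degenerate length range forces exact gene lengths
  specFix <- syntheticGenomeSpec(chromLengths = c(chrA = 1e6), nGenes = 30,
                                 geneLengthRange = c(1000, 1000),
                                 nEnhancers = 0, seed = 2)
  expect_true(all(width(simulateGenome(specFix)$genes) == 1000L))
  # impossible placement errors out
  tiny <- syntheticGenomeSpec(chromLengths = c(chrA = 5e4), nGenes = 50,
                              geneZoneReserve = 0, seed = 3)
  expect_error(simulateGenome(tiny), "place")
})

test_that("planted truth covers every gene and enhancer exactly once", {
  study <- smallStudy()
  tr <- plantedTruth(study)
  genes <- geneModels(study)$gene_id
  expect_setequal(tr$expression$gene_id, genes)
  expect_equal(nrow(tr$expression), length(genes))
  for (ab in unique(tr$occupancy$antibody)) {
    sub <- tr$occupancy[tr$occupancy$antibody == ab, ]
    expect_setequal(sub$gene_id, genes)
    expect_equal(anyDuplicated(sub$gene_id), 0L)
  }
  expect_equal(anyDuplicated(tr$enhancers$enhancer_id), 0L)
  expect_equal(nrow(tr$enhancers), length(enhancerAnchors(study)))
})

test_that("tag simulation respects bounds, conditions and determinism", {
  spec <- syntheticGenomeSpec(chromLengths = c(chrA = 5e5), nGenes = 10,
                              nEnhancers = 4, seed = 21)
  genome <- simulateGenome(spec)
  t1 <- simulateChipTags(genome, seed = 5)
  t2 <- simulateChipTags(genome, seed = 5)
  expect_identical(lapply(t1, tagPositions), lapply(t2, tagPositions))
  for (tk in t1) {
    gr <- tagPositions(tk)
    expect_true(all(start(gr) >= 1L))
    expect_true(all(end(gr) <= seqlengths(gr)[as.character(seqnames(gr))]))
    expect_true(all(width(gr) == 1L))
  }
  expect_error(simulateChipTags(genome, nTagsTarget = 0), "positive")
})

test_that("a lone stable peak at near-zero background captures the tags", {
  # one stable gene, fold 50, almost-zero background: nearly every tag
  # falls inside its peak window in both conditions
  spec <- syntheticGenomeSpec(chromLengths = c(chrA = 1e6), nGenes = 1,
                              nEnhancers = 0, seed = 31)
  arch <- data.frame(name = "stable", prob = 1, expression = "null",
                     Smarca4 = "stable", stringsAsFactors = FALSE)
  genome <- simulateGenome(spec, archetypes = arch)
  # two-component mixture: expected in-window fraction is
  # fold * w / (L + (fold - 1) * w); fold 5e4, w 1001, L 1e6 gives ~0.98
  tags <- simulateChipTags(genome, backgroundRate = 2e-5,
                           enrichmentFold = 5e4, peakWidth = 1000L,
                           seed = 7)
  gene <- genome$genes
  tss <- if (as.character(strand(gene)) == "-") end(gene) else start(gene)
  for (cond in c("control", "kd")) {
    pos <- start(tagPositions(tags[[paste0("Smarca4.", cond)]]))
    inWin <- mean(pos >= tss - 500 & pos <= tss + 500)
    expect_gte(inWin, 0.95)
  }
  # input never carries the planted signal
  posIn <- start(tagPositions(tags[["input"]]))
  expect_lt(sum(posIn >= tss - 500 & posIn <= tss + 500), 10)
})

test_that("unit enrichment fold gives a statistically uniform track", {
  spec <- syntheticGenomeSpec(chromLengths = c(chrA = 1e6), nGenes = 20,
                              nEnhancers = 0, seed = 41)
  genome <- simulateGenome(spec)
  tags <- simulateChipTags(genome, backgroundRate = 0.01,
                           enrichmentFold = 1, seed = 11)
  pos <- start(tagPositions(tags[["Smarca4.control"]]))
  # expected tags in any fixed window = rate x width; chi-square over
  # 20 windows of 50 kb should not explode
  cnt <- tabulate((pos - 1L) %/% 50000L + 1L, nbins = 20L)
  expect_gt(suppressWarnings(
    stats::chisq.test(cnt)$p.value), 1e-4)
})

test_that("DE table semantics follow the planted classes", {
  spec <- syntheticGenomeSpec(chromLengths = c(chrA = 1.5e6), nGenes = 60,
                              nEnhancers = 0, seed = 51)
  genome <- simulateGenome(spec)
  de <- simulateDETable(genome, effectSizeLog2 = 2, nullSd = 0.1, seed = 3)
  expect_identical(de, simulateDETable(genome, effectSizeLog2 = 2,
                                       nullSd = 0.1, seed = 3))
  truth <- genome$truth$expression
  flt <- filterDE(de)
  expect_setequal(flt$up$gene_id, truth$gene_id[truth$direction == "up"])
  expect_setequal(flt$down$gene_id,
                  truth$gene_id[truth$direction == "down"])
  # a truth with no planted signal filters to nothing
  archNull <- data.frame(name = "silent", prob = 1, expression = "null",
                         Smarca4 = "none", stringsAsFactors = FALSE)
  gNull <- simulateGenome(syntheticGenomeSpec(
    chromLengths = c(chrA = 5e5), nGenes = 10, nEnhancers = 0, seed = 6),
    archetypes = archNull)
  fltNull <- filterDE(simulateDETable(gNull, seed = 1))
  expect_equal(nrow(fltNull$up), 0L)
  expect_equal(nrow(fltNull$down), 0L)
})

test_that("study writer produces the documented plain-text layout", {
  study <- smallStudy()
  dir <- tempfile("study_")
  writeStudy(study, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genes.bed", "enhancers.bed", "de.tsv", "truth_occupancy.tsv",
      "truth_expression.tsv", "truth_enhancers.tsv")))))
  genesBack <- readGeneModels(file.path(dir, "genes.bed"),
                              seqlengths = seqlengths(geneModels(study)))
  expect_identical(ranges(genesBack), ranges(geneModels(study)))
  expect_equal(genesBack$gene_id, geneModels(study)$gene_id)
  tagFiles <- list.files(file.path(dir, "tags"), full.names = TRUE)
  expect_equal(length(tagFiles), length(tagTracks(study)))
})
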