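---
title: "Methods: differential chromatin occupancy with chipshift"
author: "chipshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential chromatin occupancy with chipshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipshift)
```

# The scientific setting

chipshift models a common experimental design in chromatin biology: a
factor (here, a core subunit of the esBAF / SWI-SNF chromatin remodeller,
such as Smarcb1) is depleted by an inducible knockdown, and the
consequences are read out twice — as ChIP-seq of the remodeller ATPase
(Smarca4), of Polycomb components (Ezh2, H3K27me3) and of active histone
marks (H3K27ac, H3K4me3) in control versus knockdown cells, and as RNA-seq
differential expression over the same contrast. The analytical questions
are: where does occupancy change, which genes do those changes belong to,
how do they relate to expression changes, and are particular co-binding
patterns over- or under-represented among the genes that respond?

The package implements that analysis chain as reusable, tested components,
and pairs it with a synthetic-data generator that plants a known answer so
every stage can be verified end to end.

# Island peak calling

`callIslands()` is a generic window/gap island caller in the SICER
tradition. Each chromosome is tiled from position 0 in fixed,
non-overlapping windows (broad mode: 200 bp, joined across gaps up to
600 bp; narrow mode for transcription-factor-like signals: 50 bp, no gap).
A window with tag count $t$ is *eligible* when its Poisson upper-tail
probability against the expectation $\lambda$ falls below a screening
threshold (0.01 by default). Eligible windows are joined into islands
across gaps up to the configured maximum, and each island is scored
jointly: its p-value is $P(X \ge T)$ for $X \sim
\mathrm{Poisson}(\Lambda)$, with $T$ the island's total tag count and
$\Lambda$ the summed expectation over every window the island spans.
Islands with $p \ge$ the cut-off are discarded; the defaults are $10^{-10}$
for broad marks, $10^{-5}$ for narrow mode and recommended for
acetylation-type marks.

The expectation for a window is built from the control track in three
guarded steps:

* scaled control count: $(c + 0.25) \cdot n_T / n_C$, where 0.25 is a
  pseudocount and $n_T / n_C$ the library-size ratio;
* a *local-background floor*: the control rate averaged over a 1 kb
  window centred on the tiling window (one-sided maximum). Single-window
  control fluctuations otherwise dominate narrow-mode comparisons;
  damping them with a wider local estimate is the same reasoning behind
  local lambda estimation in model-based callers;
* a *genome-background floor*: the treatment's genome-wide mean tag count
  per window, so that a window whose control happens to be empty is
  judged against the global background rather than the pseudocount alone.

Both floors are on by default and configurable (`peakCallingConfig()`).

# Differential calling and classification

Differential occupancy is obtained by the condition swap: the same island
machinery is run with the knockdown track standing in for the control
(`callDifferential()`), and vice versa. One deliberate design choice
departs from a pure swap: the island-level statistic in differential mode
is the exact conditional binomial test of the two island counts,

$$p = P\!\left(\mathrm{Bin}\!\left(t + c,\ \tfrac{n_A}{n_A + n_B}\right)
\ge t\right),$$

rather than the Poisson survival against the scaled control expectation.
When both tracks carry real signal — precisely the situation at stably
bound regions — the Poisson form treats the estimated control rate as
known and is badly anticonservative at high counts (at island counts
around 250, its $10^{-5}$ cut-off is crossed by chance roughly once per
thousand islands, which a genome of hundreds of bound regions turns into
regular false differential calls). Conditioning on the total count gives
the standard calibrated comparison of two Poisson rates. Standard peak
calling against an input track keeps the Poisson survival statistic
exactly.

`classifyPeaks()` then derives the three occupancy classes for one
antibody. DECREASE regions are control standard peaks overlapping a
control-over-knockdown differential peak; INCREASE regions are knockdown
standard peaks overlapping the reciprocal differential peak; COMMON
regions are control standard peaks overlapped by a knockdown standard
peak. A classified region therefore always shows enrichment against its
input *and* between the conditions. When a DECREASE and an INCREASE
region overlap one another, the class whose differential peaks cover more
bp of the standard peak wins; exact ties drop both regions (kept in a
`dropped` slot for inspection). The minimum overlap for all these rules
is 1 bp and configurable; no smaller default is defensible without
further information.

# Gene annotation and expression integration

Gene regions run from 1 kb upstream of the transcription start site to the
transcription end site, strand-aware; TSS regions are 2 kb windows centred
on the TSS. `assignPeaks()` drops every peak that touches neither, and
assigns the survivors to *all* overlapping genes (a peak spanning two
promoters counts for both); gene-body and TSS-window hits feed the same
membership, with a provenance column recording which rule fired.

`filterDE()` applies the expression thresholds with strict inequalities:
adjusted $p < 0.05$ and $|\log_2 \mathrm{FC}| > 0.58$ (about 1.5-fold).
`mergeExpressionBinding()` joins the two worlds by gene id, keeping
expressed genes without binding (flagged) and rejecting duplicated gene
ids. `sixWayCategories()` compares two knockdown contrasts
(Smarcb1-style vs Smarca4-style) into core-repressed / core-activated /
one-not-the-other categories; genes significant in opposite directions in
the two tables get a `discordant` label in the single-label output, or
both applicable side labels in the multi-label variant, because forcing
them into either side silently misstates one of the two contrasts.
`heatmapMatrix()` builds the zero-substituted two-column log2FC matrix
(cells with $p > 0.05$ or $|\log_2 \mathrm{FC}| < 0.58$ become 0, rows
ordered by gene id, no clustering).

# The binding-pattern permutation test

The test asks whether genes carrying a concurrent ChIP signal (any
antibody, any of the five peak categories) are over- or under-represented
in one partition of a *basic gene set*: significantly downregulated genes
that carry a differential peak of the reference antibody (Smarca4),
partitioned into a DECREASE group and an INCREASE group.

Each of $B$ shuffles (1,000,000 by default) redistributes the $k$ signal
labels uniformly over the $N$ basic-set genes and records how many land in
the D-group of size $n_D$. A uniform placement of $k$ labels among $N$
genes makes that count hypergeometric, so the shuffle is drawn from
$\mathrm{Hypergeom}(N, k, n_D)$ — equivalent to, and enormously faster
than, physically permuting label vectors, while remaining a genuine
Monte-Carlo sample. Empirical tail probabilities use add-one smoothing,
$(\#\{x^* \text{ as-or-more-extreme}\} + 1)/(B + 1)$, so a reported p-value
is never zero; the two-sided p-value is the doubled smaller tail, capped
at 1. The significance decision follows the two-sided quantile rule — the
observed count must fall in the lowest or highest 2.5% of shuffles —
Bonferroni-corrected over the number of antibody-category combinations
actually tested. An observed count more extreme than *every* shuffle is
tiered "highly significant"; this captures the regime $p < 1/(B+1)$ that
add-one smoothing cannot resolve. Testing the I-group is the mirror image
($x \mapsto k - x$) and shares the two-sided p-value, so the battery
runner reports both partitions from one null sample.

# Enhancer analysis

Enhancer anchors are 1 bp positions (wider inputs are collapsed to their
centre base), extended to 3001 bp intervals centred on the anchor; the odd
length keeps the anchor exactly central, and intervals clipped at a
chromosome edge are flagged. Binding fractions per condition and class are
exact ratios. Each enhancer links to its nearest gene within 100 kb —
distance 0 when overlapping, otherwise the bases strictly between the
closest edges, ties broken towards the smaller gene start — and per
differential class at the enhancer the linked significantly-changed genes
are split into up and down fractions, next to the analogous summary over
gene-region memberships. Enhancers overlapping gene bodies are retained:
the gene-versus-enhancer comparison is made without exclusions, and a
configurable flag would be the place to change that.

# Binding profiles

`coverageMatrix()` counts tags at every offset within ±2.5 kb of each peak
centre; `averageAndSmooth()` takes column means and smooths with LOESS
(local linear, tricube weights, span 0.3, exact-fit surface). Span and
degree are not dictated by anything in the data; degree 1 is chosen
because local-linear fits reproduce constant and exactly linear profiles
(a property the tests assert to $10^{-9}$), and span 0.3 preserves a
peak-shaped bump while suppressing single-offset noise.

# The synthetic-data generator

`simulateStudy()` builds the entire study from one seed: genome, gene
models, enhancer anchors, tag tracks, expression table and the planted
truth tables.

* **Genome and genes.** Two 4 Mb chromosomes and 200 genes by default.
  Genes (1–3 kb, strand uniform at random) are placed without overlap and
  at least 12 kb apart by a deterministic stick-breaking layout; the
  spacing guarantees that a peak at one gene's TSS cannot reach a
  neighbour's gene or TSS region, so membership recovery is unambiguous.
  The last 250 kb of each chromosome is kept gene-free.
* **Archetypes.** Each gene draws one regulatory archetype coupling its
  occupancy classes to its expression direction: remodeller lost and
  downregulated (20%, also gaining the Polycomb mark H3K27me3),
  remodeller gained yet downregulated (10%, the "unexpected" pattern),
  gained and upregulated (15%), stably bound and unchanged (15%), and
  unbound null genes (40%). These proportions give every downstream
  stage non-trivial work: both basic-set partitions are populated and the
  permutation test has a real positive association to find.
* **Tags.** 1 bp positions from a uniform Poisson background (0.005
  tags/bp) plus a 50-fold elevated rate over 1 kb windows centred on the
  TSS of occupied genes and on bound enhancer anchors; "gained" regions
  are enriched only in the knockdown track, "lost" only in control,
  "stable" in both; the input track is background only.
* **Expression.** Planted genes get $\log_2 \mathrm{FC} = \pm 2$ plus
  N(0, 0.1) noise and adjusted p-values uniform below 0.05; null genes
  get N(0, 0.1) and p-values uniform above 0.05. P-values are assigned by
  class, not fitted from counts: only the filter semantics matter
  downstream, and the fitting stage is explicitly out of the package's
  scope.
* **Enhancers.** Linked enhancers sit 4 kb upstream of a gene interval —
  closer to that gene than to any neighbour, far enough that their local
  peak cannot touch gene or TSS regions — with occupancy coupled to the
  gene's direction (down genes get control-only-bound enhancers, up genes
  knockdown-only, null genes both-or-neither). One in ten enhancers is
  planted in the gene-free chromosome tail, beyond the 100 kb cap, at
  least 5 kb apart, to exercise the unlinked path.

What the generator does **not** emulate: reads with length, fragment-size
and strand-shift structure, sequencing error, mappability and copy-number
artefacts, duplicate towers, overdispersion beyond Poisson, correlated
replicates, and realistic gene-density or enhancer-distance
distributions. A pipeline that passes the planted-truth tests is
therefore verified for its *logic* — windowing, statistics, overlap and
merge semantics, bookkeeping — not validated against the messiness of
real libraries.

# Numerical and reproducibility choices

Coordinates are BED-convention half-open on disk and standard 1-based
`GRanges` in memory; the conversion happens only in the readers and
writers. Island p-values agree with the closed-form Poisson survival
function to at least 12 significant digits (asserted across counts 0–100
and rates 0.1–10). The pipeline derives every stage seed from one global
seed, records seeds and parameters in a manifest without timestamps, and
two runs with the same configuration produce byte-identical outputs.

Problem sizes in the test suite are chosen to make brute-force oracles
exact and affordable: interval operations are checked against per-base
scans on 100 kb toy genomes with a thousand random intervals, the island
caller against explicit window enumeration on 20 genomes up to 50 kb, the
permutation null against hypergeometric tail probabilities at $10^5$
shuffles, and the full pipeline against planted truth at the default
200-gene scale.

# Known limitations

* The caller has no duplicate filtering, fragment-model or FDR machinery;
  it reproduces island statistics, not any specific external tool.
* Gene-level memberships can in principle mix differential classes when a
  gene owns several peaks; the basic-set builder resolves this by peak
  count and drops exact ties with a warning.
* The conditional binomial differential test conditions on total counts
  and ignores biological replication (the design has none).
* Enhancer classes rely on overlap of the extended 3001 bp interval;
  enhancers closer than ~3 kb to each other can share peaks and become
  ambiguous — real catalogues contain such pairs, the generator avoids
  planting them.
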