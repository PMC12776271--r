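---
title: "Methods: quantifying TF regulatory rewiring from paired RNA and ATAC profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying TF regulatory rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnrewire)
```

# The analysis problem

Inducible restoration of a transcription factor (TF) in a cancer cell line —
for example re-expressing a full-length tumor-suppressor isoform in leukemia
cells that carry a dominant-negative variant — produces a paired
before/after design: RNA-seq and ATAC-seq in a control condition (`CON`) and
an induced condition (`IND`), typically replicated across two or more cell
lines. The scientific questions are which genes and chromatin regions
respond, which TF motifs gain or lose protection (footprints) in accessible
chromatin, how the TF-to-target-gene regulatory network rewires between
conditions, and how two factors' ChIP cistromes redistribute over shared
regulatory elements.

`grnrewire` implements this analysis end to end and couples it to a fully
seeded synthetic-data generator, so every stage can be validated against a
known ground truth without any external download.

# Differential testing

Counts (gene-level RNA, peak-level ATAC) are normalized with the
median-of-ratios estimator: sample $j$'s size factor is
$\mathrm{median}_i\, k_{ij}/(\prod_j k_{ij})^{1/m}$ over features with a
nonzero geometric mean, rescaled so the factors have geometric mean one.
Per-feature negative-binomial dispersions $\alpha$ use the method of
moments, $\hat\alpha = (s^2 - \bar x)/\bar x^2$ on normalized counts pooled
within condition and averaged across the two conditions, truncated at zero.

The test is a blocked Wald test on the log2 ratio of normalized condition
means. Within each cell-line block $b$,

$$\widehat{\mathrm{LFC}}_b = \log_2 \frac{\bar x_{b,\mathrm{IND}} + 0.5}
{\bar x_{b,\mathrm{CON}} + 0.5},$$

with a delta-method standard error from the NB variance
$\mu + \alpha \mu^2$ of the per-sample normalized counts. Blocks are
combined by inverse-variance weighting — the analogue of an additive
`~ cell_line + condition` design — and the combined statistic gets a
two-sided normal p-value and Benjamini–Hochberg adjustment. Calls use the
conventional rule padj < 0.05 and |log2FC| > 1. The 0.5 pseudo-count keeps
fold changes finite; all-zero features are reported with log2FC 0 and p 1
rather than `NA` so result tables stay rectangular.

This is deliberately a transparent simplification of shrinkage-based NB
frameworks: no dispersion shrinkage, no outlier replacement, no LFC
moderation. The downstream analysis depends on the call thresholds, not on
those refinements; the cost is somewhat noisier dispersion estimates, which
the calibration study below quantifies.

# Motif scanning and families

Position frequency matrices (JASPAR text format) become position
probability matrices with a background-weighted pseudocount
($p = (c + 0.8\,\mathrm{bg})/(C + 0.8)$; 0.8 is a common default and is
configurable since conventions differ), and log2-odds matrices against a
uniform background. Peaks are resized to 400 bp windows around summits and
scanned on both strands. A hit's **match fraction** rescales its log-odds
score between the motif's minimum and maximum attainable scores; the scan
keeps hits at or above 0.70. This min–max convention makes a "70% match"
well defined for any motif; `N` bases score as background (contribution 0).
`best_central` mode keeps, per peak and motif, the hit closest to the
window center (ties: higher score, then the + strand), which stabilizes
positional profiles. Positional densities bin offsets in 20 bp intervals
over [-200, 200) and divide by the number of peaks in the set.

Set-level enrichment compares the fraction of foreground peaks with a hit
(500 bp windows) against a background; the default background shuffles each
foreground sequence's mononucleotides with a fixed seed, which preserves
composition exactly at desk scale without a genome-wide GC-binned null (the
trade-off: dinucleotide structure is not preserved). Significance is a
two-sided Fisher exact test on the hit/miss table with BH adjustment, and
effect size is $\log_2((f_{fg}+10^{-3})/(f_{bg}+10^{-3}))$.

Motif families come from average-linkage hierarchical clustering of
$1 - \rho$, where $\rho$ is the Pearson correlation of flattened, aligned
probability matrices maximized over all ungapped offsets and the reverse
complement (minimum overlap four columns), cut at similarity 0.8. Families
are labelled by the member with the highest mean within-family similarity —
a data-driven stand-in for curated name-based family labels.

# Footprinting

Each fragment contributes two Tn5 insertion events, at the 5' end + 4 bp
and the 3' end - 5 bp (the standard dyad-center correction). Insertions
are accumulated in 200 bp windows around motif midpoints, and a motif's raw
footprint score is the mean over sites of

$$\log_2 \frac{\text{mean flank insertions} + 0.1}
{\text{mean center insertions} + 0.1},$$

with 30 bp flanks abutting the motif span; deeper protection gives a
higher score. Window and flank sizes are configurable since published
footprinting pipelines do not agree on them. Raw scores are min–max
normalized across the motif panel within each condition, which puts the
conventional 0.2 difference threshold on a meaningful [0, 1] scale for a
log-ratio score that is otherwise unbounded; the implication, documented
here deliberately, is that the delta is panel-relative, so panels should
contain a spread of binding strengths (real panels with hundreds of motifs
do; the synthetic footprint scenario includes bound, condition-specific,
and never-bound motifs for the same reason). Condition differences are
tested by permuting per-site raw scores between condition labels
(two-sided, add-one correction) rather than a background-distribution
z-test: exact at desk scale and assumption-free. A motif is called when
$|\Delta| \ge 0.2$ and $p < 0.05$; motifs with fewer than 20 sites are
skipped. No sequence-bias correction is applied — synthetic fragments are
bias-free — which is the main caveat for transferring the stage to real
ATAC data.

# Network construction and rewiring

A candidate edge TF → gene exists when a peak assigned to the gene carries
the TF's motif. Peak-to-gene assignment is promoter-first: a summit inside
[TSS - 3 kb, TSS + 3 kb) assigns to that gene (nearest TSS on ties),
otherwise the nearest TSS within 100 kb, otherwise unassigned. The edge
score is the geometric mean of three [0, 1] quantities: the best hit's
match fraction, the linking peak's accessibility quantile rank within the
condition's mean normalized ATAC signal, and the absolute Pearson
correlation between TF and target expression across the condition's
samples (pooled over cell lines, log2 normalized counts). Edges are kept
when score > 0.5 and |r| > 0.3; with several linking peaks the max-score
peak is kept. This surrogate replaces trained paired-expression-chromatin
models whose priors are not reproducible from first principles; keeping
every component on [0, 1] preserves the interpretability of the 0.5 score
cutoff, at the cost of treating the three evidence channels as
exchangeable.

Networks are compared by normalized out-degree, degree = targets/(N - 1)
with N the node count of that network (out-degree, because the quantity of
interest is regulatory influence over targets), averaged over replicate
networks when given; TFs absent from a network have degree 0 so the
condition difference is always defined. The TF–TF projection weights pairs
by shared-target counts; edge-set overlap is reported both as the
intersection-over-union and per network. The per-TF summary joins degree
change, expression response (`Activated` / `Repressed` / `Unchanged` from
the differential-expression status), and footprint change, keeping TFs
with missing modalities.

Both retention thresholds are applied simultaneously; relaxing either one
only adds edges (a monotonicity the tests assert).

# Cistrome stratification

For two factors profiled in both conditions, each factor's peaks split
into condition-specific and shared by any-overlap (>= 1 bp); simple
any-overlap is used because published shared-peak percentages on such
designs are consistent with it, and no reciprocal-fraction rule is
imposed. Shared counts are reported from both sides (plus a union-merged
region list) since "shared" is ambiguous between the two. Genomic context
is decided by the summit with priority promoter (±3 kb of a TSS) >
intragenic (within TSS..TES) > distal intergenic, which matches the
distance-to-TSS phrasing of the convention; group-level tables count DARs
by any-overlap with group peaks and differential genes among deduplicated
gene assignments (a gene with two linked peaks counts once).
Redistribution of one factor's lost peaks onto the other's gains is the
any-overlap fraction, with the promoter-proximal share of the
redistributed subset.

# The synthetic generator: what it emulates

`sim_config()` fixes the study conditions once; a single seed makes every
stage bit-reproducible. The defaults model a two-condition, two-cell-line
bulk design:

* **Layout** — two 1 Mb chromosomes, 160 genes on an even grid (unique
  TSSs), 240 non-overlapping 300 bp peaks placed deterministically, half
  promoter-proximal (±3 kb) and half distal, so truth fractions are exact
  by construction rather than sampled.
* **Counts** — NB with dispersion 0.05 around log2-uniform baselines in
  [2, 8]; per-feature cell-line offsets of sd 0.5 log2 for the non-reference
  line (an additive block effect, no block×condition interaction, mirroring
  an additive design formula); per-sample library-size multipliers in
  [0.7, 1.4] so size-factor estimation is non-trivial. Differential
  features are the first ⌈fraction·n⌉ after a seeded shuffle (±2 log2 by
  default), giving exact truth cardinalities.
* **Regulation** — each TF's consensus (width-18 sharp synthetic PWMs;
  at the 70% match threshold a random 400 bp window produces a spurious
  hit with probability ≈ 0.03, so scan hits are dominated by planted
  sites) is written into peaks assigned to distinct non-TF genes, one
  latent per edge: a per-sample TF activity (sd 1.3–1.45 log2) shared
  between the TF and its targets yields a planted TF–target expression
  correlation of about 0.8. Network-wired genes draw baselines from the
  expressed half of the range, since co-expression is only recoverable for
  quantifiable transcripts. Rewired TFs carry edges in exactly one
  condition; bound peaks gain accessibility in the bound condition.
* **Fragments** — per peak, Poisson-many fragments whose two insertion
  endpoints are uniform over the peak except across bound motif spans,
  where density is multiplied by (1 - protection) in the bound condition;
  coordinates are stored so the +4/-5 shifts recover the sampled insertion
  positions exactly.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: Tn5 sequence bias and duplicate artifacts,
GC-dependent coverage, overdispersion heterogeneity across features,
correlated motif co-occurrence, indirect (cofactor-mediated) binding, and
any block×condition interaction.

# Validation scenarios and problem sizes

`scenario_config()` pins the validation studies; the choices below are the
package's own and are stated here so the reported numbers are
interpretable.

| scenario | design | checks |
|---|---|---|
| `differential` | 2,000 genes, 6 vs 6 in 2 blocks, 10% DE at lfc 2 | recall ≥ 0.9, empirical FDR ≤ 0.1 |
| `null` | as above, nothing planted | raw p < 0.05 fraction in [0.03, 0.07] |
| `network` | 8 TFs × 12 sites, 10 vs 10 | edge F1 ≥ 0.8 per condition |
| `rewiring` | 20 TFs × 18 sites, 2 rewired, 12 vs 12 | rewired TFs fill the top \|Δdegree\| decile |
| `footprint` | 6 motifs × 200 sites, protection 0.8, one IND-only TF | only that TF called |

Two sizes deserve their rationale. The network scenario uses 10 samples
per condition because the |r| > 0.3 edge filter is nearly uninformative at
very small n: under the null, |r| exceeds 0.3 in 56% of draws at n = 6
versus 40% at n = 10, so n = 10 is the smallest design in which the
correlation filter — a fixed part of the method — has discriminatory
power. The differential scenarios keep 6 vs 6, the more typical bulk
design, where the blocked Wald test is calibrated on its own (measured
null fractions 0.042–0.059 across seeds). The permutation-p calibration
check uses 150 null motifs × 30 sites with 400 permutations and a
Kolmogorov–Smirnov test at α = 0.01.

# Numerical choices and degenerate inputs

Ties in `best_central` resolve by score then + strand; accessibility ranks
use midranks; an all-equal footprint panel min–max normalizes to 0.5; a
zero-range denominator in the match fraction cannot occur for width ≥ 4
PFMs with positive column sums (enforced). Correlations on constant
expression vectors are treated as 0 (the edge is dropped). Empty networks
warn and report degree 0; empty overlap warns and reports missing values.
Dispersion estimates are floored at $10^{-8}$ inside the Wald variance
only, so reported dispersions can be exactly 0 for constant features.

# Limitations

The NB test's normal reference is slightly anticonservative at very small
per-block sample sizes; the surrogate edge score has no calibrated null
model (thresholds, not p-values, define the network); min–max normalized
footprint deltas are panel-relative; and the shuffled enrichment
background does not model GC-binned genomic sampling. All are documented
trade-offs in favor of transparency and desk-scale reproducibility.
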