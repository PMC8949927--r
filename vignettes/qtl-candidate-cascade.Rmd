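---
title: "Methods: interval mapping and the candidate-gene cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval mapping and the candidate-gene cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`qtlcascade` covers the desk side of a mouse diabetes-QTL study: linkage
analysis of an (NZOxB6)N2 backcross, haplotype-based and expression-based
narrowing of the critical interval on chromosome 13 (78.0–120.4 Mbp), and
single-cell annotation of the surviving candidates. Wet-lab stages
(phenotyping, genotyping chemistry, array/sequencing preprocessing,
overexpression assays) are out of scope; every input is produced by the
package's seeded generators in the same on-disk formats a real study would
use (TSV, VCF 4.2, BED/GFF3, MatrixMarket).

# The linkage model

## Genotype probabilities

An N2 backcross has two genotype classes, homozygous N/N and heterozygous
N/B, expected 1:1. Along a chromosome the genotype sequence is a two-state
Markov chain whose transition probability between loci at map distance *d*
Morgan is the Haldane recombination fraction r(d) = (1 − e^(−2d))/2 —
crossovers Poisson, no interference. Because the chain is Markov,
conditioning a pseudomarker genotype on the *nearest informative* flanking
marker on each side is exact, not an approximation:

P(g | g_L, g_R) ∝ T(g_L → g; r_L) · T(g → g_R; r_R),

with T the stay/switch probability. One-sided conditioning applies at
chromosome ends or past runs of missing calls; an individual with no
informative marker on either side receives the (0.5, 0.5) prior (the
generator's default missing rate is 0, configurable via `cross_spec()`).

## EM scan and LOD

At each grid position the phenotype is a mixture
y_i ~ Σ_g p_ig N(μ_g, σ²) with a **common σ across classes** (the standard
interval-mapping model; nothing in the source material suggests
heteroscedastic classes). The E-step computes posterior class weights, the
M-step weighted class means and the pooled variance; LOD is the log₁₀
likelihood ratio against the single-normal MLE. Implementation notes:

* The EM runs **vectorized across all grid positions simultaneously**
  (matrices of n × positions), iterating until the largest per-position
  log-likelihood change is below 1e−8 or 1000 iterations (warn). The
  log-likelihood is checked to be non-decreasing each iteration and the
  flag is exposed as `attr(curve, "monotone")`.
* At a fully typed marker the mixture collapses and the LOD equals the
  one-predictor regression closed form (n/2)·log₁₀(RSS₀/RSS₁); the test
  suite asserts agreement to 1e−6 at every marker.
* Variances are floored at 1e−12 and mixture densities at 1e−300 to keep
  degenerate positions finite; zero phenotypic variance is an error.
* Grid: marker positions plus a 0.5 Mbp pseudomarker lattice
  (≈ 0.25 cM under the fixture map) — finer than the marker spacing and
  cheap at this scale. Ties at the maximum break to the leftmost position.

## Permutations

Genome-wide significance follows the standard permutation scheme: the
phenotype vector is shuffled against genotype rows, the full scan re-run,
and the maximum LOD recorded; the threshold is the empirical (1 − α)
quantile with **type-7 linear interpolation** (determinism; R's default).
The convention of 1000 permutations at α = 0.01 is the package default;
the precondition n_perm ≥ 100 can only be bypassed by supplying explicit
permutations through the testing hook, which also supports the degenerate
identity-permutation check (threshold = observed maximum). A property test
verifies the achieved genome-wide type-I error on 50 null cohorts at 200
permutations stays inside exact binomial bounds for α = 0.05 and 0.01.

## Peak effects

At the peak marker, traits are summarized per genotype class (n, mean,
SEM). Two classes are compared by Welch's t-test; three (congenic B/B, N/B,
N/N) by one-way ANOVA followed by pairwise Bonferroni-adjusted t-tests
(p_adj = min(1, 3·p) for three comparisons). Classes with fewer than two
members are excluded with a warning; zero-variance groups return a defined
result (p = 1 for identical means) rather than an error.

# Haplotype-window filter

The critical interval is tiled into **half-open 250 kb windows anchored at
78.0 Mbp** (not at coordinate 0 — the filter describes the critical region;
the anchor is an argument). 42.4 Mbp gives 170 windows, the last one a
150 kb partial. Choices the convention leaves open, decided here:

* "Exceeding a threshold of 100 SNPs/window" is read as **strict >**
  (`strict = FALSE` gives ≥). A count of exactly 100 is not polymorphic.
* Windows **tile** rather than slide ("each 250 kb window").
* The trailing partial window is tested against the same absolute
  threshold, with no density rescaling — a documented caveat, favoring
  simplicity; under-length windows are thereby conservative.
* A SNP exactly on a boundary belongs to the right-hand window.
* Strain calls are taken as homozygous (inbred catalogs); the VCF reader
  maps any non-`1/1` genotype to the reference allele.
* Gene retention is **any-overlap of the gene body** (closed coordinates
  against half-open windows); no promoter extension, since no rule is
  stated.

Window counting is verified against a brute-force per-SNP assignment
oracle, count conservation, and threshold monotonicity of the retained
gene set.

# Expression filter and cascade

LFC is the **difference of group means of log2(x + 1)** — the mean-of-logs
convention of array toolchains; the pseudocount keeps all-zero genes
defined (LFC 0, p 1). The pass criterion is LFC-only, strict |LFC| > 1; the
Welch p-value is reported but not gated, and no multiple-testing correction
is applied to the interval-wide screen — both deliberate properties of this
screening convention, flagged as caveats for reuse on real data. qPCR relative
quantification is 2^(−ΔCt) against a reference gene (Actb/Eef2/Tbp-style),
dropping samples with missing reference Ct.

`build_cascade()` produces one row per interval gene with the boolean
chain: in-interval, polymorphic-block overlap, DE-parental, DE-congenic;
final candidates are the four-way intersection. The ob/ob contrast and the
top single-cell cluster are attached as annotations, not filters — they
inform interpretation without gating candidacy, since the congenic contrast
is the confirmatory strain comparison while the ob/ob comparison involves a
different genetic background. Filter sets naming genes outside the annotation
are an error (inconsistent inputs), and the pipeline asserts nestedness
final ⊆ DE-parental ⊆ polymorphic ⊆ interval on every run.

# Single-cell profiling

Counts are normalized per cell to 10 000 total then log1p-transformed (the
default of the cited droplet toolchains; the target is an argument), with
zero-total cells dropped. Dot-plot statistics per (cluster, gene) are the
fraction of cells with **raw count > 0** and the mean normalized
expression; a brute-force per-cell loop is the test oracle. The
proliferating cluster is the argmax of the marker mean (Mki67, the mouse
gene symbol for the Ki-67 proliferation marker), ties breaking
alphabetically with a warning.

# The synthetic world

The generators state a world once; they are not tuned against outcomes.

* **Map**: chromosome 13 markers every 2 Mbp (70–120 Mbp) plus rs4222065
  at 112.5 Mbp, at a flat **0.5 cM/Mbp** — a realistic mouse autosomal
  ratio and a single unambiguous bp↔cM conversion. No published marker
  panel exists for this fixture; these values are declared, not inferred.
* **Cross**: n = 600 (the scale of a typical N2 mapping cohort), additive
  effect 0.4 SD at the QTL, residual SD 1; glucose rises and
  insulin/body weight fall in N/N carriers, the diabetogenic direction of
  NZO alleles at this locus. The QTL is
  simulated as a hidden locus; marker genotypes never expose it directly.
* **SNP catalog**: windows inside declared blocks receive strictly more
  discordant SNPs than the declared density (150/window in the preset),
  windows outside strictly fewer than the background (40/window), plus
  concordant SNPs (80/window) so total ≠ discordant. Block edges must
  align to the window grid, which makes the downstream polymorphic calls
  deterministic at any seed.
* **Preset geometry**: 644 genes (208 coding / 377 gene models / 8 miRNAs
  / 51 Riken) tiled at 65 838 bp spacing; three polymorphic blocks
  (80.5–83.0, 93.0–95.75, 111.5–113.5 Mbp) chosen once so that exactly
  38 + 42 + 31 = 111 genes overlap them, the third block spanning the
  112.5 Mbp peak and carrying the candidate slots.
* **Expression**: intensities are generated as 2^(7 ± effect/2 + ε) − 1 so
  that log2(x+1) recovers the planted effect exactly in expectation;
  within-group SD 0.1 on the log2 scale, n = 5 per group. Planted |log2
  effects| ∈ [1.5, 3] for the 8 parental genes (the five candidates plus
  three gene-model fillers), the 5 candidates in the congenic contrast,
  and all but Acot12 in the ob/ob contrast. With an LFC standard error of
  ≈ 0.063, the strict |LFC| > 1 filter recovers the planted truth with
  overwhelming margin at any seed.
* **Single cell**: negative binomial with dispersion 0.5 (size 2), 50
  cells per cluster; hormone genes mark the cell types and Mki67, S100z,
  Iqgap2 peak in BetaP by construction.

What a green test establishes: the algorithms implement their definitions
and recover planted truth under the stated noise. What it does not: realism
of array normalization, ambient RNA, batch effects, linkage-map error, or
any biology beyond the planted structure.

# Localization limits of the scan

With effect 0.4 SD and n = 600 on a 0.5 cM/Mbp map, the
Darvasi–Soller approximation 530/(N·a²) cM puts the 95% confidence width of
the peak position near 5.5 cM ≈ 11 Mbp, and LOD profiles are near-flat over
several Mbp around the optimum. The scan therefore identifies the region
reliably but the argmax scatters megabases around the planted position —
a property of the stated world, not of the implementation (which is exact
against the regression closed form at typed markers). The recovery test
asserts what is attainable: a tight median error, a majority of replicates
within 3 Mbp, and that no peak beats the LOD at the true position by a
meaningful margin.

# Known limitations

Single-QTL model only (no epistasis, covariates, composite mapping, or
X-dosage handling); no genotyping-error HMM; indels/CNVs/de-novo variants
outside the SNP filter; no RMA/quantile normalization or count-model DE;
clustering of cells is taken as given. These are deliberate scope limits,
not oversights.
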