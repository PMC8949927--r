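# qtlcascade

Prioritizing candidate genes under a diabetes QTL in a two-strain mouse
backcross.

A quantitative trait locus (QTL) detected in an (NZOxB6)N2 backcross — a
hyperglycemia locus on chromosome 13 introduced by New Zealand Obese (NZO)
alleles — spans tens of megabases and hundreds of genes. `qtlcascade`
implements the computational cascade that narrows such an interval to a
handful of testable candidates, plus seeded synthetic-data generators that
emulate every input, for geneticists working with inbred mouse crosses:

1. **Linkage scan** — single-QTL interval mapping by the EM normal-mixture
   algorithm with permutation-based genome-wide significance.
2. **Haplotype filter** — strain-vs-strain SNP density in 250 kb windows;
   only genes overlapping polymorphic windows can carry a causal variant
   that differs between the strains.
3. **Expression filter** — log2 fold change (LFC) across bulk islet
   contrasts (parental B6 vs NZO, congenic B/B vs N/N, B6-*ob/ob* vs NZO).
4. **Single-cell profiling** — dot-plot statistics per islet cluster and
   marker-based labeling of the proliferating β-cell cluster (BetaP, high
   *Mki67*).

## The model

At each pseudomarker position the phenotype of individual *i* is a
two-component normal mixture over the backcross genotype classes
*g* ∈ {N/N, N/B}:

    y_i ~ Σ_g  p_ig · N(μ_g, σ²),

where *p_ig* = P(g | flanking markers) under the Haldane (no-interference)
map function, r(d) = (1 − e^(−2d))/2. The EM algorithm maximizes the mixture
likelihood L₁; evidence is LOD = log₁₀ L₁ − log₁₀ L₀ with L₀ the
single-normal fit. Genome-wide significance comes from permuting phenotypes
against genotype rows and taking the empirical (1 − α) quantile of the
per-permutation maximum LOD (α = 0.01, 1000 permutations by convention).

Downstream, a 250 kb window is *polymorphic* when its strain-discordant SNP
count strictly exceeds 100; a gene survives the haplotype filter when its
body overlaps a polymorphic window, and the expression filter keeps genes
with |LFC| > 1 per contrast. Final candidates are the intersection:
interval ∩ polymorphic ∩ DE-parental ∩ DE-congenic.

## Worked example

```r
library(qtlcascade)

# linkage: simulate an N2 cohort with a QTL at the rs4222065 position and scan
map   <- chr13_map()
sim   <- simulate_backcross(map, cross_spec(n = 600, qtl_bp = 112.5e6,
                                            effect = 0.4, seed = 11))
curve <- em_scan(sim$geno, sim$pheno$glucose, map)
pk    <- peak_position(curve)
sprintf("peak: %.1f Mbp, LOD %.2f", pk$pos_bp / 1e6, pk$lod)
#> peak: 120.0 Mbp, LOD 4.04

# candidate cascade on the seeded fixture
fix    <- make_cascade_fixture(seed = 7)
prof   <- window_counts(fix$catalog, "13", 78e6, 120.4e6)
kept   <- filter_genes(fix$annotation, call_polymorphic(prof, 100))
de_par <- intersect(de_filter(compute_lfc(fix$expr$parental)), kept$gene_id)
de_con <- intersect(de_filter(compute_lfc(fix$expr$congenic)), de_par)
cat("genes:", nrow(fix$annotation), "->", nrow(kept), "->",
    length(de_par), "->", length(de_con), "\n")
#> genes: 644 -> 111 -> 8 -> 5
sort(de_con)
#> "Acot12" "Ankrd55" "Iqgap2" "Rnf180" "S100z"

# single-cell annotation of the candidates
stats <- dotplot_stats(normalize_cells(fix$sc), c("Mki67", "S100z", "Iqgap2"))
label_proliferating(stats)          # cluster with maximal Mki67
#> "BetaP"
```

The scan peak (120.0 Mbp at this seed) identifies the planted QTL region:
LOD tops in a backcross of this size and effect (0.4 SD) are flat over
several Mbp, so the argmax scatters around the true position (112.5 Mbp)
within the classical Darvasi–Soller confidence width. The cascade counts
644 → 111 → 8 → 5 reproduce the fixture's planted truth, and the five
final candidates are annotated with their top-expressing islet cluster —
*S100z* and *Iqgap2* peak in the proliferating BetaP cluster.

A command-line interface wraps the same steps
(`inst/cli/qtlcascade simulate|scan|haplomap|deg|sc|prioritize|report`),
and `run_pipeline()` executes them end to end with deterministic outputs.

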