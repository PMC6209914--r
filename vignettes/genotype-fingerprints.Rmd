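---
title: "Genotype fingerprints: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype fingerprints: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofp)
```

## The model

A SNP-array genotype is a list of observed alleles at a few hundred
thousand biallelic SNPs, each identified by a stable dbSNP rsid. `genofp`
summarizes such a genotype as a **genotype fingerprint**: a 4 × L real
matrix (rows A, C, G, T) into which every retained SNP contributes at
column `rsid mod L`. This is a locality-sensitive hash: many rsids share a
column, so individual marker states cannot be recovered from the
fingerprint, yet two fingerprints of the same genome — or of close
relatives — remain highly correlated.

For each autosomal biallelic SNP with both alleles in {A, C, G, T}, the
observed nucleotide counts $n_A, n_C, n_G, n_T$ (with
$n_N = n_A + n_C + n_G + n_T = 2$) are compared with expected counts
$E[n_X] = n_N f_X$ and the differences $n_X - E[n_X]$ accumulated into the
SNP's column. Two sources of the expected frequencies $f_X$ are supported:

* **per-SNP-frequency mode** (`raw_fingerprint_freq()`): $f_X$ comes from
  an external per-rsid table, e.g. population frequencies;
* **cohort mode** (`raw_fingerprints_cohort()`, the default in the CLI):
  allele counts are tallied per individual into 4 × L matrices $N_X$ with
  column totals $N_N = 2k$; pooling them across the cohort yields expected
  column frequencies $E[f_X]$ and fingerprint entries
  $t_X = N_X - N_N\,E[f_X]$. No external data are needed, and when every
  individual reports the same SNP set this is algebraically identical to
  per-SNP mode with pooled frequencies (a test asserts the equivalence).

Because observed and expected counts have the same total, every raw
fingerprint column sums to zero, and cohort-mode fingerprints sum to the
zero matrix across the cohort.

**Normalization** (`normalize_fingerprint()`) applies two z-scoring
passes: per column (4 entries), then per row (L entries). The column pass
removes differences in substitution-type composition between columns; the
row pass removes residual per-nucleotide effects of the assay. Both
passes reflect methodology, not biology, so they are applied universally.

**Comparison** (`fp_compare()`, `fp_compare_all()`) concatenates the four
rows into a 4L-vector and computes Spearman's rank correlation. Rho is
the method's only similarity measure: ≈1 for the same individual,
high for first-degree relatives, decaying with relationship degree,
near 0 for unrelated individuals after population adjustment. For
all-against-all screens each fingerprint is ranked once and pairs are
evaluated as dot products of standardized rank vectors, which is what
makes million-pair screens cheap.

**Population analysis.** A population fingerprint
(`population_fingerprint()`) is the element-wise mean of member normalized
fingerprints; subtracting it (`adjust_fingerprint()`) cancels the
correlation shared by a population so that relatives stand out.
`classify_fingerprint()` assigns an individual to the population whose
fingerprint correlates best, and `evaluate_loo()` scores that classifier
with each individual excluded from its own population mean via the exact
downdate `(mean * n − self)/(n − 1)`. Queries are normalized, not
population-adjusted, fingerprints: at classification time the query's
population is by definition unknown.

**Structure analysis.** `fingerprint_matrix()` stacks fingerprints into an
individuals × 4L matrix for PCA (`fp_pca()`, centered and unit-scaled, via
SVD). As a classical baseline, `maf_ld_prune()` implements the standard
genotype-matrix preparation: MAF filter, complete-LD pruning, random
thinning.

**Kinship baseline.** `king_robust()` implements the KING-robust
between-family estimator
$\hat\varphi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N^{(i)}_{Aa} + N^{(j)}_{Aa})$,
with expectations 0.5 (self), 0.25 (parent–offspring, full siblings),
0.125 (second degree), 0 (unrelated). It depends only on joint
heterozygosity and opposite homozygotes, so allele labeling cannot flip
it. It provides an independent scale against which fingerprint
correlations are validated: class means of population-adjusted rho are
linear in class means of $\hat\varphi$.

## Parameters that matter

* **L** (fingerprint length; default **1000**). Controls the
  resolution/speed trade-off. Small L (≈100) suffices for identity
  checks; L = 5000 is recommended for population-structure and
  relatedness work. Comparisons require equal L on both sides (rsids are
  binned differently otherwise), and every public function checks this.
  An important regime condition: the method assumes many SNPs per column
  (SNPs/L ≫ 1). When L approaches the SNP count, additional columns carry
  sampling noise rather than information and resolution stops improving;
  the test suite's study sizes respect this regime.
* **Mode** (`freq` vs `cohort`). Cohort mode is the default: it needs no
  external frequencies and measures each individual against the pooled
  cohort, which is what makes population structure visible to PCA and
  classification. Per-SNP mode with population-matched frequencies
  centers individuals on their own population instead.
* **Cross-panel scaling factor** (`scale_cross_panel()`, default 0.75).
  Fingerprints built on two different but overlapping array designs are
  depressed by a roughly design-pair-specific constant ratio; 0.75 is the
  value observed for the 23andMe V2/V3 pair. The scaling is opt-in and
  reported alongside the raw rho, never silently substituted, because the
  factor is an empirical property of the panel pair at hand.
* **`maf_ld_prune()`** defaults `maf_min = 0.05`, `keep_fraction = 0.05`,
  the conventional GWAS-preprocessing values; the thinning seed is
  mandatory and recorded in the output.

## Numerical choices

* **Standard deviations divide by n** (population convention) in both
  normalization passes. With 4-entry columns the n vs n−1 choice is
  material; both passes z-score a complete finite set, not a sample, so
  the population form is used consistently.
* **Degenerate columns/rows** (sd = 0) are centered but not divided, so an
  all-zero fingerprint normalizes to zeros instead of NaN.
* **Normalization is only nearly idempotent.** After the row pass, column
  means are O(1/√L) rather than exactly 0, so re-normalizing shifts
  entries by about that much (≈0.03 at L = 1000). Rank structure is
  essentially unchanged (Spearman rho between once- and twice-normalized
  fingerprints > 0.999), and the deviation shrinks with L; a property
  test pins this behavior down.
* **Ties in ranking use midranks**, the standard Spearman definition;
  ties are common at small L.
* **Calls with $n_N \ne 2$** (no-calls, half-calls) are excluded before
  tallying, and do not count toward a column's SNP total. Duplicate rsids
  within one file keep the first occurrence, with a warning.
* **Classification ties** are broken alphabetically by population name and
  flagged — ties are measure-zero but determinism matters for
  reproducibility.
* **Complete LD** in the pruning pass is operationalized as |r| = 1
  against the nearest retained SNP to the left on the same chromosome
  (adjacency, not a window).
* **PCA signs** are fixed by making each component's largest-magnitude
  loading positive; constant columns are dropped before scaling and
  counted.
* **Parsing is permissive, filtering centralized**: I/D (indel) and '-'
  symbols and non-rs identifiers survive parsing where possible and are
  removed (with counts) by `filter_calls()`, which is the single place the
  autosomal/biallelic/ACGT rules live.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates the statistical structure every other module
assumes:

* **Population differentiation** via the Balding–Nichols model: ancestral
  frequencies uniform on (0.05, 0.95), per-population frequencies
  Beta-distributed around them with parameter $F_{ST}$. This is the
  minimal standard model that produces PCA-recoverable structure.
* **Pedigrees** by Mendelian transmission: PO, FS, HS, AV (avuncular), CO
  (first cousins), C2 (second cousins) and UN pairs. Auxiliary relatives
  needed to construct a pair (e.g. the grandparents behind a cousin pair)
  are generated internally but not emitted, so the truth tables cover
  exactly the instantiated pairs. Founders are never shared between
  pairs, so a "founders vs individuals" conflict cannot arise.
* **Array-design evolution** via two rsid panels of configurable sizes
  and overlap; rsids are random integers in 1..2×10⁸ drawn independently
  of position, so the mod-L hash distributes as for real dbSNP
  identifiers.
* **Noise**: per-genotype no-calls and per-allele symmetric flips at
  configured rates.

It does **not** model linkage disequilibrium (the fingerprint itself
ignores linkage; the LD-pruning baseline is exercised with
duplicated-column constructions), real rsid-number clustering, admixture,
or batch effects. Consequently, passing tests demonstrate the method's
behavior under idealized population-genetic structure; they do not
certify performance on cohorts with strong admixture or assay artifacts,
which is where the underlying approach itself reports degraded
classification.

## Study sizes used by the test suite

Two simulated study cohorts back the heavier tests (sizes chosen once, as
the package's standing study conditions):

* **Structure cohort**: 3 populations at $F_{ST} = 0.1$, 50 individuals
  each, 100,000 SNPs. The SNP count is a scaled-down array panel chosen
  to preserve the many-SNPs-per-column regime at the largest fingerprint
  studied (100000/5000 = 20 per column). On it the suite verifies perfect
  leave-one-out population assignment at L = 5000, perfect k-means
  recovery on PC1–2, and monotone loss of separation as L shrinks through
  1000 to 500.
* **Pedigree cohort**: one population, 30 unrelated founders plus 10
  pairs each of PO/FS/HS/AV/CO/UN at 15,000 SNPs, with two panels of
  9,000 and 14,000 rsids sharing 95% of the smaller panel. On it the
  suite verifies the relationship ordering FS ≈ PO > AV/HS > CO >
  unrelated, that an individual's two cross-panel fingerprints correlate
  above every relative pair, that the cross-panel depression ratio is
  constant across relationship classes, and the linear relationship
  between adjusted-fingerprint rho and KING kinship.

## Known limitations

* Fingerprints are comparable only at equal L; there is no rebinning.
* The privacy property is many-to-one hashing, not anonymity: fingerprints
  still identify individuals (by design) and reveal coarse ancestry.
* Cross-panel correlations need the empirical depression factor for their
  scale to match same-panel ones; the package ships the V2/V3 value as a
  default but cannot derive the factor for arbitrary panel pairs without
  paired data.
* `extract_from_vcf()` reads entire VCFs into memory via vcfR; it is meant
  for panel-sized extractions, not whole-genome multi-sample files.
* No admixture modeling: misassignment between historically related
  populations is expected and is reported, not corrected.
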