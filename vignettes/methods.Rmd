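---
title: "Models and methods behind wgspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wgspop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wgspop analyses small whole-genome resequencing cohorts of the kind used in
conservation genomics: two or more groups (species or populations) of a few
to a few dozen diploid individuals each, genotyped at biallelic SNVs against
a scaffold-level assembly. This vignette explains the statistical models the
package implements, the choices made where a method's description left the
design open, and what the synthetic-data validation does and does not
demonstrate.

## The genotype substrate

Everything operates on a `geno_matrix`: alternate-allele dosages (0/1/2,
`NA` for missing) over sites sorted by scaffold and position, with the GATK
site annotations carried alongside. Internal coordinates are 0-based
half-open; VCF positions are converted at the I/O boundary, so a variant at
VCF position `p` occupies `[p-1, p)` and window tiling is unambiguous.
Multiallelic records and indels are excluded (and counted) on input: all
downstream statistics assume biallelic SNVs. Missing genotypes are dropped
site-wise from frequency denominators; sites with fewer than two called
diploids are skipped in pairwise statistics.

## Diversity statistics

**Nucleotide diversity.** Per site, the unbiased pairwise-difference
estimator `2 p̂ (1-p̂) · m/(m-1)` with `m` the number of called alleles;
per window, the site sum divided by the window span in bp. This equals the
mean Hamming distance over all haplotype pairs (the test suite checks it
against an explicit enumeration oracle). Windows default to non-overlapping
40-kb tiles; diversity profiling around sweep candidates uses 10-kb tiles
over the candidate ± 500 kb.

**Tajima's D.** The 1989 statistic `(π_abs - S/a1)/sqrt(e1 S + e2 S(S-1))`
with constants computed from the chromosome count `n`. Genotypes are
unphased, so `n` is twice the number of called diploids; across a window we
take the site-wise minimum. Windows need at least three segregating sites
and four chromosomes, otherwise `D` is `NA` rather than an error.

**Runs of homozygosity.** A deterministic run-growing scan over the sorted
site sequence: maximal runs containing at most `max_het = 0` heterozygotes
and `max_missing = 2` missing calls, trimmed to homozygous end sites, are
accepted when they span at least 40 kb and contain at least 10 SNPs. This
honors the three published thresholds directly instead of re-implementing
the original tool's sliding-window heuristic, whose internals are not
described; the two agree on unambiguous tracts but may differ at noisy
boundaries. `F_ROH` divides the summed tract length by the genome length
(by default the assembly length from the VCF header). Low-diversity windows
(`π < 1e-4`, strict) are flagged and merged into runs.

**LD decay.** `r²` is the squared correlation of dosage vectors (composite
LD — phase is not available), over all intra-scaffold pairs within 500 kb,
binned by distance; the summary "decay length" is the first distance at
which the binned mean crosses 0.3 from above, linearly interpolated between
bin midpoints. For `n` samples the finite-sample floor of `r²` is about
`1/n`, which the tests verify on independent sites.

**Inbreeding.** The method-of-moments coefficient
`F = (O_hom - E_hom)/(L - E_hom)` with `E_hom` the Hardy–Weinberg
expectation at the sample's group frequencies (small-sample corrected).
Negative values indicate heterozygosity excess and are reported as such.

## Kinship and gene flow

IBS classes come from dosage differences (`IBS = 2 - |d_a - d_b|`) and give
`DST = (IBS2 + 0.5 IBS1)/N`. IBD states are estimated by the PLINK-style
method of moments: expected IBS-class proportions under IBD 0/1/2 are
computed from cohort allele frequencies with the finite-sample correction
factors, summed over sites, and solved sequentially; estimates are clamped
to `[0,1]`, renormalized, and summarized as `PI_HAT = P2 + 0.5 P1`. Allele
frequencies include the pair itself (the common tool convention). The
moments assume a homogeneous population: across strongly diverged groups,
shared monomorphism mimics IBD, so the pipeline estimates kinship within
groups. Related-sample pruning iteratively removes the lower-quality member
of any pair above `PI_HAT > 0.2` (a configurable convention; the threshold
is exposed because published pipelines rarely state one).

Neighbour-joining trees are built from `1 - DST` distances by the
Saitou–Nei algorithm (via ape); negative branch lengths are clamped to zero
with a warning so downstream Newick consumers are safe.

Patterson's D uses frequency-weighted site patterns,
`ABBA = Σ(1-p1)p2p3(1-p4)` and `BABA = Σp1(1-p2)p3(1-p4)`, so
multi-sample populations work without pseudo-haploidization. The Z score is
a delete-one block jackknife over consecutive SNP blocks (5000 by default,
matching common practice for genome-scale data); on the ~20k-site synthetic
fixtures the tests use 1000-SNP blocks, because four jackknife blocks do
not estimate a stable standard error.

## The selective-sweep scan

Pooled heterozygosity per window is
`Hp = 2 Σn_MAJ Σn_MIN / (Σn_MAJ + Σn_MIN)²`, with `n_MAJ`/`n_MIN` the
major/minor allele *observation counts* at each SNP (counts, not
frequencies, following the statistic's original definition; the two differ
when call rates vary). Ties between alleles are broken toward the
alphabetically smaller base, which only affects labeling, never the value.
Windows with 10 or fewer SNPs are ineligible. `zHp` standardizes by the
genome-wide mean and sample (n−1) standard deviation of eligible windows.

Windowed `F_ST` is Weir–Cockerham (1984): per-site variance components
`a`, `b`, `c` from the two populations' sizes, frequencies and observed
heterozygosities, combined per window as the ratio of sums
`Σa / Σ(a+b+c)` — the "weighted" windowed estimator of the standard tools.
Small negative values are legitimate estimator behavior near zero
differentiation.

Sweep candidates are windows in the top `q` (default 1%) of `F_ST` *and*
the bottom `q` of `zHp`, with empirical quantiles interpolated between
order statistics and inclusive comparisons, so a window sitting exactly at
a threshold passes. Under independence the expected overlap fraction is
`q²`, which the null-genome calibration check measures. The contrast
population can be the pooled non-focal individuals (default) or any
explicit sample set, covering both readings of a multi-species contrast.

## Sex scaffolds and STR panels

Birds are female-heterogametic (males ZZ, females ZW), so scaffold origin
is readable from sexed read depth. Depths are normalized per sample in two
passes: first by the sample's 80th-percentile scaffold depth — autosomes
are the highest-copy class in both sexes, so an upper quantile is robust
even when sex scaffolds are a large fraction of the assembly — then, after
a provisional classification, by the median over provisionally autosomal
scaffolds. Classification thresholds follow copy-number arithmetic with
generous noise margins: W requires male ratio < 0.1 and female ratio in
[0.3, 0.7]; Z requires male ratio in [0.8, 1.2] and female ratio in
[0.3, 0.7]; autosomes have both in [0.8, 1.2]; anything else (and any
scaffold under 50 kb, when lengths are supplied) is ambiguous. These
margins are configurable; they are design choices, not published values.
Sample sex is then the W-scaffold mean ratio: < 0.1 male, > 0.3 female.

Kinship STR panels keep loci with a 4-bp unit, at least five distinct
alleles ("more than four" read strictly), and no missing genotype in the
cohort; marker usefulness is quantified by Botstein's
`PIC = 1 - Σp_i² - Σ_{i<j} 2 p_i² p_j²`. W-linked sex markers demand the
hemizygosity signature exactly: every female called with two equal allele
lengths, every male missing. Hemizygous calls are represented as
homozygous genotypes, which is how STR genotypers report single-copy loci.

## Deleterious load and mutation rate

Effect categories are consumed from an annotation table (computing them
requires transcript models and is out of scope); a synonym map normalizes
common annotator spellings. Frameshift, stop-gain, stop-loss and splicing
variants form the strong class, missense and synonymous the slight class.
Per sample and zygosity (dosage 2 vs 1), the load proportion divides the
class count by the sample's classified genotypes of that zygosity —
reference-homozygous and missing genotypes are excluded. Group contrasts
use the two-sided Wilcoxon rank-sum test (exact null for combined n ≤ 20
without ties), the standard distribution-free choice at these sample
sizes; a t-test is available as an option.

The mutation rate is `μ = d·g/(2T)`: divergence fraction times generation
time over twice the divergence time, in mutations per site per generation.

## The synthetic cohorts: what they emulate, and what they do not

`simulate_cohort()` draws, per group and scaffold, a Poisson
`θ·L·a_n` number of segregating sites with derived-allele counts from the
neutral equilibrium spectrum `P(i) ∝ 1/i`. For non-inbred groups the drawn
count is placed exactly on the `2n` chromosomes, which makes windowed π
unbiased for θ and Tajima's D centred at zero by construction — the
properties the estimator tests rely on. Inbred groups use per-sample
Hardy–Weinberg-with-`f` draws instead. Each group's polymorphism is
private; there is no shared standing variation, recombination structure,
or demographic history, so the cohorts validate estimator arithmetic and
planted-truth recovery, not population-genetic realism. Gene-flow checks
use a separate generator (`simulate_introgression()`): an ancestral `1/p`
frequency spectrum, Balding–Nichols drift per population, and an admixture
fraction pulling the recipient toward the donor.

Planted features are constructed to be identifiable:

* **Sweeps** scale the focal group's site density and residual frequencies
  by `diversity_scale` and fix the focal group for the alternate allele at
  a `divergence_shift` fraction of region sites. Both selections are
  deterministic and evenly spread along the region (every k-th site by the
  fractional-count rule), so each sub-window of a planted region carries
  the configured signal rather than a binomially noisy one. The planting
  is phenomenological — it produces the low-Hp/high-F_ST signature the
  scan consumes, not selection dynamics.
* **Homozygous tracts** force the carrier homozygous inside the interval
  and heterozygous at the single site flanking each end. Without the
  delimiters a planted boundary would not be identifiable from genotypes
  at all (runs would extend through chance homozygous sites), so exact
  boundary recovery is a property of the planting design.
* **Depth profiles** are truncated-normal with CV 0.1 around
  `coverage × copy ratio` (autosome 1/1, Z 1/0.5, W 0/0.5 for
  males/females), qualitatively matching ~20× resequencing variability.
  At that noise level the classification margins make scaffold and sex
  calls deterministic, which is why the recovery checks expect 100%.
* **STR tables** follow a stepwise model (lengths = unit × k). Planted
  kinship loci expose their full allele spectrum across the cohort;
  W-linked markers are emitted female-homozygous/male-missing, alongside
  decoy W loci violating one rule each.

One master seed expands into fixed per-stage child seeds, so identical
configurations give byte-identical outputs, stage by stage.

## Problem sizes and numerical conventions

The validation suite runs at desk scale, chosen to keep every check sharp:
sweep-scan replicates use a 50-Mb genome (five 10-Mb scaffolds, 1250
windows of 40 kb) with per-group `θ = 4e-4`/bp — comparable in SNP density
to a multi-million-variant call set on a ~1-Gb genome — so that every
40-kb window comfortably clears the scan's 10-SNP eligibility rule.
Pedigree recovery uses ≥ 10,000 sites; neutral Tajima's D uses 600 10-kb
windows; oracle agreements are checked to 1e-10–1e-12.

Other conventions: empirical quantiles are type-7 (linear interpolation);
window statistics return `NA`, never errors, for ineligible windows;
`zhp_standardize` refuses zero-variance input; LD pruning drops exact
duplicates even at `r2_max = 1`; degenerate inputs (no jointly called
sites, monomorphic-only cohorts, missing W scaffolds) raise informative
errors.

## Known limitations

* No haplotype phase: LD is composite, the D statistic is
  frequency-weighted, and haplotype-based sweep statistics (iHS, XP-EHH)
  are out of scope.
* The IBD moments assume population homogeneity; across diverged groups
  PI_HAT is biased upward, which is why the pipeline screens within
  groups.
* The generator's neutral-equilibrium assumptions make it an arithmetic
  and recovery testbed, not a coalescent simulator; conclusions about
  power on real data require simulations with recombination and
  demography.
* Effect annotation, read alignment, variant calling and STR discovery
  from sequence are consumed as inputs, never computed.
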