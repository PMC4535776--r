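---
title: "Methods: dating, networks, introgression and morphometrics for island mouse cohorts"
author: "islandmouse"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandmouse)
```

`islandmouse` implements the computational core of a molecular and
morphological characterization of a recently colonized island house mouse
population: a mutation-frequency molecular clock on complete mitochondrial
genomes, median-joining haplotype networks for the D-loop, segmentation of
local-ancestry probability tracks into introgressed blocks, microsatellite
diversity summaries, and landmark-based mandible morphometrics. This
vignette explains each model, its assumptions and tunable parameters, what
the synthetic-data generators emulate, and the numerical choices made where
the design was genuinely open.

## The mutation-frequency clock

### Model

Immediately after a colonization bottleneck, the mitochondrial genealogy of
the descendants of a single founding haplotype is star-like: every sampled
lineage coalesces directly onto the founder, so new mutations accumulate
independently per lineage, and the expected number of derived variants in a
cohort grows linearly with time since colonization. The observable is the
per-nucleotide mutation frequency

$$\hat f = \frac{M}{n \cdot L},$$

where $M$ is the number of positions carrying a counted new mutation, $n$
the number of genomes, and $L$ the number of counted positions per genome.
Because $\hat f$ is proportional to age under a shared mutation rate and
generation time, the age of one island cohort follows from another island
whose colonization date is historically documented:

$$\hat T = T_{\mathrm{cal}} \cdot \frac{\hat f}{f_{\mathrm{cal}}}.$$

### Counting rules

`call_new_mutations()` compares every alignment column against the cohort
consensus (strict majority; two-base IUPAC ambiguity codes, read as Sanger
double peaks, contribute half weight to each constituent base; ties are an
error, never a coin flip). A call enters $M$ only if:

* it lies outside the control region (D-loop). The D-loop is hypervariable
  and is excluded from numerator *and* denominator so frequencies are
  comparable across cohorts;
* at least one genome is fixed for the derived base. A variant observed
  only as a heteroplasmic double peak is treated as inherited rather than
  new — when the same base is fixed in another animal the double peak
  reflects shared ancestry, and a lone double peak is not counted either;
* the column contains no alignment gap (indels are not point mutations).

A position is counted once regardless of heteroplasmic co-carriers.
Recently immigrated animals identified by independent evidence are removed
explicitly with `exclude_genomes()`; the package never auto-detects
immigrants.

The control region interval is always an explicit argument. The default,
`c(15422, 16299)` in 0-based half-open coordinates, is the mouse reference
(NCBI37/mm9) chrM annotation: an 877 bp D-loop at the end of the 16,299 bp
molecule, leaving $L = 15{,}422$ counted positions. The source data for the
packaged cohort do not state the exact interval used originally; this
default reproduces the published frequency and is flagged as an assumption.

### Rounding the age

At realistic counts ($M \approx 10$) the clock's resolution is coarse, so
the default point estimate rounds the frequency *ratio* to the nearest
integer before multiplying by the calibration age ("about twice as old"),
rather than pretending to year-level precision. `rounding = "signif"`
(one significant figure on the years) and `rounding = "none"` are
available; the unrounded value is always returned alongside.

### Uncertainty

The dominant noise is Poisson variation in the small count $M$.
`age_uncertainty()` resamples $M^* \sim \mathrm{Poisson}(M)$, maps each
resample through the frequency and calibration arithmetic, and reports a
percentile interval (default 95%, 10,000 resamples). For the packaged
cohort ($M = 10$) the interval spans roughly 160–670 years around a point
estimate of 400 — the honest statement that the clock dates the
colonization to a few centuries, not to a decade. The interval ignores
calibration error and any generation-time difference between islands
(assumed equal, as in the source analysis).

### Validation conditions

The test suite validates the estimator on 1,000 simulated star-genealogy
cohorts of 11 genomes of 16,299 bp with the per-site rate chosen so the
expected counted count is exactly 10 — the regime of the real cohort. Under
these conditions the frequency estimator is unbiased (checked against two
standard errors of the simulation mean) and the exact coverage of the 95%
percentile interval, computable by summing Poisson tail masses, is 96.4%;
the suite requires at least 93%. Note that coverage is sensitive to where
the true age falls relative to the discrete count-to-age lattice: moving
the simulated rate off the expected-count-10 condition by rounding it to
two digits shifts the truth between lattice points and can drop coverage
to ~92.6% — a discreteness artifact, not an estimator defect.

## Median-joining haplotype networks

`collapse_haplotypes()` merges identical sequences over substitution sites.
Alignment columns containing gaps are treated as indel columns: maximal
runs of adjacent gap columns with identical gap pattern count as one indel
event (an 11 bp insertion is one event, not eleven), recorded as an
annotation but excluded from mutational-step counts — D-loop indels are
hypermutable and conventionally ignored in step counts.

`median_joining()` builds the network: it iterates a minimum-spanning
network (MSN) over the current node set and augments it with quasi-medians
(coordinatewise majority of triples; positions where all three states
differ expand combinatorially) of triples connected by at least two MSN
links, until closure; median vectors whose removal leaves the minimum
spanning cost unchanged are then pruned, so every retained median strictly
reduces the connection cost. Design choices:

* `epsilon = 0` by default (the default of the software tradition this
  follows); the MSN at `epsilon = 0` is the union of all minimum spanning
  trees.
* All new quasi-medians of connected triples are added each round, rather
  than only the cheapest candidates. On an exhaustive enumeration of all
  distinct 2–4-haplotype instances over up to six binary sites (1,354
  split-weight classes) this reaches the exact Steiner-minimal connection
  cost in every class, verified in the tests against an independent
  closed-form topology-enumeration oracle; restricting addition to
  minimum-cost candidates per round missed the optimum in 6 classes.
* Tie-breaks (median insertion order, node ids) are lexicographic on the
  state strings, so the network is invariant to input order.
* Characters are compared as opaque states: non-binary or ambiguous
  characters are distinct states, and weights are uniform.

The `cost` of a network is the total mutational steps of a minimum
spanning tree over the retained nodes. Networks are exported as GML (which
round-trips through `read_network()`) or DOT, with node attributes for
frequency, population and the median-vector flag.

## Introgression block calling

The module consumes per-SNP local-ancestry probabilities in the shape
emitted by haploid-mode HMM ancestry inference: one record per
(individual, haplotype, chromosome, position) giving the probability of
carrying one copy from the source population, or the literal code 9 for
unknown ancestry.

* `call_introgressed_snps()` thresholds at a certainty level (0.9 in the
  analyses this emulates). Code-9 SNPs become `NA`: neither introgressed
  nor background.
* `merge_blocks()` turns maximal runs of introgressed SNPs into blocks.
  Block ends extend to the last SNP position + 1 (half-open), not to the
  midpoint of the next SNP gap: lengths are resolution-honest and never
  extrapolate beyond observed SNPs. Unknown SNPs bridge runs by default
  (HMMs emit unknowns sporadically; breaking on them would shatter real
  blocks) but can never start or end a block; `gap_policy = "break"` is
  available since the original merging rule is not documented.
* `copy_count_profile()` computes, by sweep-line coverage, the number of
  haplotypes carrying the introgressed ancestry at every bp, with
  breakpoints exactly at block boundaries; `genome_fraction()` reports the
  fraction of the supplied chromosomes (pass autosomes only for
  autosome-wide figures) at or above each copy number, which is
  monotonically non-increasing in the threshold; `fixed_regions()` emits
  maximal intervals where all 2N haplotypes are introgressed, the
  candidate regions for downstream enrichment analysis.

Coordinates are 1-based with half-open ends inside the package and in TSV
reports, and 0-based half-open in BED/bedGraph output, following each
format's standard.

The underlying ancestry HMM itself (phasing, copying model, generations
since admixture, miscopying rate) is out of scope: this module begins at
its output format. Consequently the published genome-wide admixture
fraction (6.5%) is not recomputable here — the tests instead verify exact
recovery of noise-free synthetic tracks, bp-level agreement of the
sweep-line with brute-force counting, and recovery of a synthetic 6.5%
fraction to lattice resolution at noise levels well above what a
thresholded HMM posterior exhibits.

## Microsatellite diversity

Standard per-population summaries over a long-format genotype table (or a
GenePop file): observed heterozygosity (fraction of scored individuals
with two distinct alleles, per locus), expected heterozygosity from scored
allele frequencies, and mean number of distinct alleles per locus. Because
the program originally used for these statistics is named but its exact
estimator is not, both $1 - \sum p_i^2$ (`"plain"`) and Nei's small-sample
correction $\frac{2n}{2n-1}(1 - \sum p_i^2)$ (`"nei_unbiased"`, the
default and that program's convention) are reported. Missing genotypes are
excluded per locus, so frequency denominators use scored alleles only.
Bayesian population-assignment clustering is an external tool and out of
scope.

## Geometric morphometrics

Centroid size is $\sqrt{\sum_i \lVert x_i - \bar x \rVert^2}$ — invariant
to rotation and translation, linear under isotropic scaling — and is
computed on the raw digitized configurations, before any superimposition.

`gpa()` performs full generalized Procrustes superimposition: center each
configuration, scale to unit centroid size, rotate to the current mean by
the optimal orthogonal rotation (SVD-based), recompute and renormalize the
mean, and iterate until the mean moves less than `tol = 1e-10` (Procrustes
distance), with `max_iter = 1000` and an explicit `converged` flag.
Choices worth noting:

* **Full** Procrustes (all configurations at unit centroid size), matching
  the superimposition method of the morphometrics software this emulates.
* Reflections are disallowed (rotation determinant +1 enforced). Mandibles
  digitized on the other body side must be mirrored explicitly on input;
  silently reflecting would hide a data-handling error.
* No tangent-space projection by default: shape variation in these data is
  small relative to the curvature of shape space, and the reference
  software operates in Procrustes coordinates.
* When replicate digitizations are present they should be averaged after
  superimposing the replicates; the package treats each input row as one
  configuration and leaves replicate averaging to the caller's metadata.

`shape_pca()` eigendecomposes the covariance of the flattened aligned
coordinates (specimens × 28 variables for 14 landmarks). Component signs
are fixed by making each component's largest-magnitude loading positive,
so plots reproduce across platforms. `group_shape_difference()` returns
per-landmark displacement between group mean shapes (the wire-frame
deformation quantity), optionally projected onto selected components.
`centroid_size_report()` gives box-plot-ready summaries plus pairwise
two-sided Wilcoxon tests with Holm correction; groups of fewer than two
specimens are excluded from testing with a warning.

One documented oddity of the source description: centroid size is defined
there over three coordinates although the landmarks are digitized in 2-D;
the implementation is 2-D throughout and the discrepancy is recorded, not
resolved.

## Synthetic data: what it does and does not emulate

Every generator returns its ground truth so downstream stages are testable
without the original data, which were not released.

* `simulate_mito_cohort()`: star genealogy from one founder, Poisson
  per-genome mutation counts, uniform placement with within-genome
  collision re-draw (infinite-sites per lineage; at ~10 mutations over
  >100 kb recurrent hits are negligible), optional heteroplasmic emission
  as IUPAC double-peak codes. It does **not** model shared internal
  branches, mutation spectrum bias (transitions = transversions), rate
  heterogeneity along the molecule, or selection — so passing tests show
  the counting and calibration arithmetic is right under the clock's own
  assumptions, not that those assumptions hold in any particular cohort.
* `simulate_ancestry_tracks()`: SNPs on a regular grid, probabilities near
  1 inside truth blocks and near 0 outside with truncated Gaussian noise,
  plus a configurable fraction of unknown-ancestry records. Real HMM
  posteriors have spatially correlated errors and uneven SNP spacing;
  the generator's iid noise is a harder case for run-breaking (no
  smoothing) but an easier one for boundary placement.
* `simulate_microsat_genotypes()`: Hardy–Weinberg draws from stated allele
  frequencies; no linkage, null alleles or genotyping error.
* `simulate_landmarks()`: group mean shape + isotropic Gaussian landmark
  noise + nuisance similarity transform (rotation, translation,
  log-uniform scale), with the applied transform recorded. Real digitizing
  error is anisotropic and landmark-specific.

All generators are deterministic under a fixed seed.

## Problem sizes used in validation

The packaged checks run at sizes chosen to exercise the published regime
while completing in minutes: 1,000 clock cohorts of 11 × 16,299 bp; the
full 1,354-class enumeration for the network/Steiner comparison; 100
random instances for the sweep-line/brute-force agreement and 100 seeds
for noisy block recovery on a 1 Mb chromosome at 1 kb SNP spacing; tens of
specimens per group for the morphometric recovery properties.

## Known limitations

* The clock assumes equal mutation rates and generation times between the
  focal and calibration islands; no correction is implemented.
* The conservation screen treats "conserved" as strict identity of all
  comparator species with the cohort consensus at the position.
* The packaged mutation table is a reconstruction from a flattened
  rendering of the published table (see `?heligoland_mutation_table`); it
  reproduces the published summary counts but individual cell assignments
  are not guaranteed.
* `median_joining()` is exact on the small instance classes enumerated in
  the tests; like all median-joining variants it remains a heuristic for
  large haplotype sets.
* The genome-fraction denominator is whatever chromosome set the caller
  supplies; sex-chromosome exclusion is the caller's responsibility.
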