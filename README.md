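# islandmouse

Population-genomic and morphometric analyses for recently colonized island
house mouse (*Mus musculus*) populations. The package implements, as
tested and reusable functions, the computations behind a molecular
characterization of an isolated island population:

* **Mutation-frequency molecular clock** — call new mitochondrial
  mutations against a cohort consensus (with explicit heteroplasmy and
  control-region rules), estimate the per-nucleotide mutation frequency
  `f = M / (n · L)`, and date the colonization by calibration against a
  reference island of known age: `T = T_cal · f / f_cal`, with a Poisson
  resampling interval for the small mutation count.
* **Median-joining haplotype networks** — collapse aligned D-loop
  sequences into haplotypes (indels annotated, excluded from step counts)
  and build a median-joining network: iterated minimum-spanning networks
  augmented with quasi-median vectors where they reduce the connection
  cost.
* **Introgression block calling** — threshold per-SNP local-ancestry
  probabilities (unknown-ancestry code 9 supported), merge runs into
  blocks with honest SNP-resolution boundaries, compute cohort
  copy-number profiles by sweep-line coverage, genome fractions per copy
  number, and fixed regions (all 2N haplotypes introgressed) as BED.
* **Microsatellite diversity** — observed/expected heterozygosity (plain
  and Nei-unbiased) and mean alleles per locus, per population, from
  long-format tables or GenePop files.
* **Geometric morphometrics** — centroid size, full generalized
  Procrustes superimposition (no reflections), shape PCA with
  reproducible component signs, group mean-shape differences
  (wire-frame displacements), and centroid-size reports with rank-based
  group tests.
* **Synthetic data** — generators for every input type (star-genealogy
  mitogenome cohorts, ancestry tracks, Hardy–Weinberg microsatellites,
  landmark configurations) with recorded ground truth, so the whole
  pipeline is testable without access to the original specimens.

## Worked example: dating the colonization

The package ships the cohort mutation table (10 positions × 11 genomes,
with heteroplasmies and a six-species conservation panel; see
`?heligoland_mutation_table` for its provenance as a reconstruction).

```r
library(islandmouse)

tab   <- heligoland_mutation_table()
aln   <- mutation_table_alignment(tab)      # 11 genomes x 16,299 bp
calls <- call_new_mutations(aln, annotation = tab[c("position", "annotation")])

length(unique(calls$position[calls$counted]))
#> [1] 10

freq <- mutation_frequency(calls, n_genomes = 11,
                           counted_length = counted_length(aln))
signif(freq, 2)
#> [1] 5.9e-05

age <- estimate_age(freq, calibration_frequency = 3.0e-5,
                    calibration_age = 200)
round(age$ratio, 2); age$age
#> [1] 1.96
#> [1] 400

age_uncertainty(10, 11, 15422, 3.0e-5, 200, seed = 1)
#> [1] 157.2256 667.8022
#> ...
```

Reading: the 11 genomes carry 10 new mutations outside the control region,
a frequency of 5.9×10⁻⁵ per sequenced nucleotide — about twice the
calibration island's 3.0×10⁻⁵ accumulated over its 200 documented years —
so the colonizing lineage is dated to roughly 400 years ago, with a 95%
Poisson interval of about 160–670 years. Three of the ten mutations
(positions 5157, 5163, 15163) fall at sites conserved across all six
comparator species:

```r
cons <- conserved_positions(calls, mutation_table_conservation(tab))
cons$position
#> [1]  5157  5163 15163
```

## Command line

A thin CLI over the same functions is installed as `exec/islandmouse`:

```sh
islandmouse date-colonization --alignment cohort.fasta \
    --control-region 15422:16299 --calibration-freq 3.0e-5 \
    --calibration-age 200 --out report/
islandmouse call-blocks --track track.tsv --chrom-sizes mm9.sizes \
    --threshold 0.9 --out blocks/
islandmouse build-network --fasta dloop.fasta --out net.gml
```

Every run writes a `provenance.json` echoing the tool version, timestamp
and full parameter set (seeds included).

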