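# magtraits

Analysis toolkit for genome-resolved microbiome studies — catalogues of
metagenome-assembled genomes (MAGs) sampled across two environments with
replicated streams, as in host-associated field studies of amphibian gut
and skin microbiomes. The package answers four questions such studies pose:

1. **What can each genome do?** Per-genome pathway-completeness traits
   (GIFTs) in [0,1], community-weighted per-sample profiles, and the
   metabolic capacity index (MCI, the mean over function-level traits).
2. **How diverse are the communities?** Hill-number alpha diversity
   (richness `q=0`, neutral and phylogenetic `q=1`), Jaccard-type turnover
   beta diversity at `q=1`, PCoA, PERMANOVA with permutation or exhaustive
   p-values, and multivariate dispersion tests.
3. **Which genomes are core, endemic or marginal?** Prevalence-based
   partitioning (detected in all streams → core; confined to one
   environment, in all its streams, at ≥20% prevalence → endemic; the
   sparse remainder → marginal) with fraction summaries and fraction-wise
   functional comparisons.
4. **Do strains differ between environments?** Microdiversity `1 − ANI`
   from per-sample consensus-allele tables (population-ANI over shared
   covered sites), contrasted within and between environments.

A synthetic-data generator (`sim_config()`, `generate_dataset()`) produces
ground-truth-annotated bundles with the same statistical structure —
31 samples over 2×2 streams, a core fraction carrying ~87% of reads,
environment-exclusive endemics, planted functional and strain-level
environment effects — so the entire chain is testable without sequence
data. Genome recovery completeness is assessed by the domain-adjusted
mapping rate (DAMR): mapped-read fraction divided by the estimated
prokaryotic fraction of the sample.

## The core quantities

For relative abundances `p_i`, the Hill number of order `q` is
`(Σ p_i^q)^(1/(1−q))`, with `exp(−Σ p_i ln p_i)` at `q=1`. Phylogenetic
`q=1` diversity is `exp(−Σ_b (L_b a_b / T̄) ln a_b)` over branches with
length `L_b`, descendant abundance `a_b` and mean depth `T̄ = Σ L_b a_b`.
Pairwise turnover at `q=1` is `ln(γ/ᾱ)/ln 2 ∈ [0,1]`, with `γ` the pooled
half-weight diversity and `ᾱ` the effective within-community diversity.
PERMANOVA partitions `SS_total = (1/n) Σ_{i<j} d_ij²` sequentially among
model terms, with pseudo-F and a `(1+b)/(1+B)` permutation p-value.
A pathway step requiring two identifiers scores 1 with both present, 0.5
with one, 0 with neither; alternative routes score as the best route; a
pathway's GIFT is the mean of its step scores.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers
(`01_simulate.R` … `05_microdiversity.R`), each a thin script over the
package functions that writes its tables under `results/`. Stage 4, for
example:

```sh
$ Rscript analysis/04_partition.R
fraction labels recover the planted truth for 100.0% of genomes
 fraction n_genomes percent mean_cumulative_abundance mean_genome_size  mean_mci
     core        50    55.6                0.86914365          3303978 0.8439375
  endemic        30    33.3                0.10930598          2475582 0.6958333
 marginal       10     11.1                0.02155037          2698573 0.5684375
...
fraction-wise functional comparison between environments:
  core     R2 = 0.006, p = 0.999, 0/10 traits differ after Holm
  endemic  R2 = 0.871, p = 0.001, 10/10 traits differ after Holm
  marginal R2 = 0.197, p = 0.054, 0/10 traits differ after Holm
```

Reading: the classifier reproduces the planted core/endemic/marginal
labels exactly; core genomes carry 86.9% of relative abundance (target
0.87) and are larger and more metabolically capable than the other
fractions; and the planted endemic-only completion-probability gap surfaces
exactly where it should — the endemic fraction shows a large environmental
effect on community function (R² = 0.87) while the core fraction shows
none. Stage 5 recovers the planted strain-level contrast: core genomes'
within-environment microdiversity is 0.0399 in the high-divergence
environment vs 0.0100 in the low one (Wilcoxon p ≈ 7e-18), with
between-environment divergence (0.0728) exceeding both.

The same flow is available as a single call on a bundle or a data
directory: `run_pipeline(generate_dataset(sim_config(seed = 42)), "out/")`.

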