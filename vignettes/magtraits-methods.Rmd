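---
title: "Methods: functional traits, prevalence partitioning and microdiversity of genome-resolved microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional traits, prevalence partitioning and microdiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magtraits)
```

# Scope

`magtraits` implements the analysis chain of a genome-resolved (MAG-based)
microbiome study with a two-environment, replicated-stream design: per-genome
pathway-completeness traits and their community weighting; Hill-number alpha
and beta diversity with PERMANOVA and dispersion tests; prevalence-based
partitioning of the catalogue into core, endemic and marginal fractions with
fraction-wise comparisons; and strain-level microdiversity from
consensus-allele tables. A synthetic-data generator with recorded ground
truth emulates the statistical structure such a study produces, so every
stage is testable without sequence data. Upstream steps — read QC, assembly,
binning, dereplication, taxonomy and gene annotation — are out of scope; the
package consumes their tabular products.

# Genome-inferred functional traits

Each pathway element is an ordered list of steps; a step is an expression
over gene identifiers (KEGG-ortholog / EC style) built from three node
kinds. An `IDENT` scores 1 when the genome carries the identifier and 0
otherwise. An `ALL_OF` node scores the arithmetic mean of its children: a
step requiring two identifiers is complete with both present, half-complete
with one, empty with neither. An `ANY_OF` node scores the maximum of its
children — the best alternative route counts in full. The trait (GIFT) of a
pathway is the mean of its step scores, so it lies in $[0,1]$ and a
single-identifier pathway yields a binary trait.

These semantics were a genuine design choice: published distillation
pipelines differ in how they reward partial alternative routes. Mean for
conjunction and max for disjunction is the simplest scheme that (i)
preserves the half-complete convention, (ii) is monotone — adding an
identifier can never lower a trait — and (iii) keeps every score inside the
unit interval. The package ships no curated database; `synthetic_pathway_db()`
builds miniature databases (default 40 elements, 4 steps each) that exercise
the whole grammar, and `read_pathway_db()` ingests user databases written in
a small text grammar (`;` between steps, whitespace = ALL_OF, `,` = ANY_OF,
parentheses group; comma binds less tightly than whitespace).

Element traits aggregate upward by unweighted means (elements within a
function, functions within a domain). The metabolic capacity index (MCI) is
the mean over function-level traits, so a constant matrix aggregates to the
constant and the index is invariant to trait order.

Community-weighted profiles weight each genome's traits by its relative
abundance in the sample. Weights are renormalized over the genomes
*detected* in that sample (and, when a profile is restricted to one
fraction, within that fraction). The alternative — weighting over the full
catalogue — would conflate a fraction's internal trait composition with its
mass, making fraction profiles incomparable between samples with different
fraction loads; renormalization keeps each profile a proper convex
combination, so every community value is bounded by the contributing
genomes' trait values. A sample where no member of the restricted set is
detected yields `NA`, never a silent zero.

# Diversity

Alpha diversity uses Hill numbers: $^qD = (\sum_i p_i^q)^{1/(1-q)}$, with
the $q = 1$ limit $\exp(-\sum_i p_i \ln p_i)$ computed directly from the
entropy rather than by numerical continuation, and $q = 0$ the count of
detected taxa. Abundance vectors must sum to one within $10^{-9}$;
`renormalize = TRUE` permits drifted input explicitly rather than silently.

Phylogenetic diversity at $q = 1$ uses the branch-abundance form
$\exp\!\big(-\sum_b (L_b a_b / \bar T)\ln a_b\big)$ where $a_b$ is the
summed relative abundance under branch $b$, $L_b$ its length and
$\bar T = \sum_b L_b a_b$ the abundance-weighted mean depth. On a star tree
with unit branches this reduces exactly to the neutral $q=1$ number, which
the tests exploit.

Pairwise beta diversity is the Jaccard-type turnover at $q = 1$: for two
equally weighted communities, $\gamma$ is the $q=1$ diversity of the
half-weight pooled community, $\bar\alpha$ the effective within-community
diversity of the pair, and the dissimilarity is
$\ln(\gamma/\bar\alpha)/\ln 2 \in [0,1]$ (at $q=1$ the Jaccard- and
Sørensen-type overlap measures coincide). The phylogenetic version applies
the same decomposition to branch abundances with the pooled community's
$\bar T$. $\beta$ is clamped to $[1,2]$ to absorb floating-point drift at
the boundaries.

PERMANOVA partitions $SS_{\text{total}} = \frac1n\sum_{i<j} d_ij^2$
sequentially (Type I) via projections of the Gower-centred inner-product
matrix, so term order follows the user's model and each term's $SS$ is the
reduction after its predecessors. The permutation p-value uses the
$(1+b)/(1+B)$ estimator, which can never return 0 and matches the
conventional floor of 0.001 at 999 permutations; free permutation is the
default, with optional within-stratum restriction. For $n \le 8$ an
exhaustive mode enumerates all $n!$ label permutations and reports the
exact proportion (identity included); the tests compare this against an
independent enumeration oracle built from the group-sum formulas. The
dispersion test embeds samples by principal coordinates keeping
negative-eigenvalue axes, measures distances to group centroids as
$\sqrt{d^2_{\text{real}} - d^2_{\text{imag}}}$ (clamped at zero), and
permutes group labels over those distances. Distances agree with the
centroid-based dispersion analysis in `vegan` to numerical precision (the
spatial-median variant is deliberately not used).

Two-group alpha comparisons follow an explicit decision rule: Shapiro-Wilk
normality in both groups and an F-test of equal variances, each at
$\alpha = 0.05$, select a pooled-variance t-test; any failure selects the
Wilcoxon rank-sum test with mid-rank ties and the normal approximation. The
result records which branch fired and why, because the choice itself is a
reportable analysis decision. Degenerate inputs (a group with fewer than
three distinct values, or all values identical) route to the nonparametric
branch, with $p = 1$ when the pooled data carry no variance at all.

The domain-adjusted mapping rate (DAMR) is the mapped-read fraction divided
by the estimated prokaryotic fraction. Values above 1 arise from estimation
noise and are flagged, not clamped; a zero prokaryotic fraction yields a
flagged missing value rather than an infinity.

# Prevalence partitioning

Detection is abundance above a threshold (default: any positive abundance —
the data are assumed already depth-filtered upstream). The classifier
applies three rules in order: detected in all streams → core; detected in
only one environment, in *every* stream of that environment, with
within-environment prevalence at or above 20% → endemic; everything else →
marginal. Prevalence is computed over samples within the environment, not
over streams — a 20% minimum is only meaningful at sample granularity with
~15 samples per environment.

The three rules are not exhaustive: a genome can span both environments
without reaching all streams. Such genomes default to marginal — the
marginal fraction is defined as the patternless remainder — and the
provenance column `rule_fired` separates the sub-cases (single environment
at low prevalence, single stream, cross-environment partial, undetected).
A `cross_env_policy = "core"` switch is exposed for users who prefer to
read "present in both environments" inclusively. Catalogue percentages are
rounded at the caller's precision (default one decimal) and are reported as
computed from the counts.

Fraction-wise functional comparison builds the community-weighted
function-level profile restricted to each fraction, tests every trait
between environments with Kruskal-Wallis plus Holm adjustment, and
summarizes the overall effect with a PERMANOVA on Euclidean trait
distances. Constant-trait columns get $p = 1$ directly; a fraction whose
profile is constant across samples is flagged degenerate instead of being
pushed through a zero-variance PERMANOVA; a fraction absent from one
environment is reported not-comparable without failing the other fractions.

# Microdiversity

Strain-level dissimilarity uses a consensus-allele population-ANI: over the
sites covered in both samples, ANI is the fraction of matching consensus
alleles, and microdiversity is $1 - \text{ANI}$. Pairs sharing fewer than
50 covered sites (configurable) are missing, not zero — a guard against
noisy sparse genomes. Within-sample polymorphism is deliberately not
modelled: the downstream contrasts consume only genome-by-sample-pair
dissimilarities, so one consensus allele per covered site suffices. The
pairwise computation is vectorized through per-base indicator cross
products and verified in the tests against the direct per-pair definition.

Environment contrasts are computed twice — on per-genome means (one value
per genome, the primary unit, avoiding pseudo-replication across the
$\binom{n}{2}$ pairs) and on pooled sample pairs — because the two choices
answer slightly different questions and the appropriate unit is a judgement
call; both are reported side by side.

# The synthetic-data generator

`sim_config()` fixes the study conditions: 2 environments × 2 streams with
8+7 (subalpine) and 7+9 (montane) samples — 31 animals; 50 core genomes, 15
endemics per environment, 10 marginal; core mass target 0.87; endemic
within-environment prevalence 0.6 (safely above the 0.2 rule threshold);
marginal prevalence 0.08; pathway completion probabilities 0.8 (core), 0.75
vs 0.55 (montane vs subalpine endemics — the planted functional effect),
0.5 (marginal); 1000 allele sites with per-site divergence 0.02 (montane)
vs 0.005 (subalpine) and 5% ancestral divergence between environments; 5%
coverage dropout; prokaryotic fractions Beta(7,3) for the gut-like preset
and Beta(1,9) for the skin-like preset.

Mechanism choices:

* **Occupancy and magnitude are drawn independently** — presence first
  (Bernoulli with fraction-specific prevalence), then log-normal weights
  (`sdlog = 1`) for occupied cells — so prevalence and mass are tunable
  separately. Log-normal rather than Dirichlet weights give the long-tailed
  rank-abundance structure typical of gut communities with one knob.
* **Mass calibration is in expectation, not per sample**: core weights are
  scaled by the constant that makes the *expected* core share equal the
  target, then columns are renormalized. Realized shares therefore
  fluctuate sample to sample (observed mean within ±0.01 of the 0.87
  target over 1000 samples), as real data would.
* **Genome sizes** are log-normal with means 3.2 Mb (core) vs 2.4 Mb
  (endemic, marginal), `sdlog = 0.18` — a typical gut-MAG range — planting
  the larger-core-genomes contrast without asserting any particular
  published values.
* **Alleles** are drawn over A/C/G/T with one consensus per covered site:
  each genome has two environment ancestral sequences differing at 5% of
  sites; each sample mutates its environment's ancestor per site at the
  environment's rate (substituted base uniform over the other three), so
  the expected within-environment mismatch is $\approx 2d$ for small $d$
  and between-environment divergence strictly exceeds within.
* Detection is exact presence/absence; no read-depth censoring model is
  applied (no per-sample depth model is available to parameterize one), so
  detectability does not vary with sequencing effort.

What passing tests on this generator do **not** show about real data: the
generator has no compositional count noise, no depth-dependent detection,
no taxonomic correlation between trait profiles and the phylogeny, and its
environment effects are placed exactly where the analysis looks for them.
Recovery results are therefore statements about the correctness of the
analysis chain, not about its power on field data.

# Calibration and null behaviour

One subtlety is worth recording. Even with equal completion probabilities
everywhere, the endemic fractions of the two environments consist of
*different genomes*, so their community profiles differ by genome-identity
sampling and the environment labels are not exchangeable for the endemic
fraction — a real feature of endemic fractions, not a test artefact. Null
calibration of the per-trait tests and the PERMANOVA permutation p is
therefore checked on the **core** fraction, whose genome set is identical
in every sample and whose abundance draws are i.i.d. across samples: there
the environment labels are exchangeable and the tests must behave as exact
nulls. The 200-seed null suite confirms family-wise control of the
Holm-adjusted trait counts and an approximately uniform PERMANOVA p.

# Problem sizes and numerical conventions

The test suite runs its Monte-Carlo suites at 200 seeds under the default
31-sample, 90-genome conditions; permutation counts inside those loops are
reduced (19–99) because only the statistic, or p at a 0.05 granularity, is
consumed — single fits use 999 permutations. Mass conservation is enforced
at $10^{-9}$ per abundance column; PCoA drops axes below a relative
eigenvalue tolerance of $10^{-9}$; turnover clamps $\beta$ to $[1,2]$;
exhaustive PERMANOVA is limited to $n \le 8$ (40 320 permutations). All
generators take explicit seeds, derive component sub-seeds
deterministically, and restore the caller's RNG state, so identical
configurations give byte-identical bundles.

# Known limitations

* The pathway grammar has no negation or stoichiometry; steps are
  independent and unweighted.
* Sequential (Type I) PERMANOVA only; marginal (Type II/III) partitions are
  not implemented.
* The microdiversity model ignores within-sample heterogeneity and
  recombination; between-environment divergence is a two-ancestor
  approximation.
* The classifier presumes the two-environment, replicated-stream design;
  other designs need the user to map their factors onto `environment` and
  `stream`.
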