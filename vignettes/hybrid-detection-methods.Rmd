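---
title: "Detecting interspecific hybrids from dominant markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interspecific hybrids from dominant markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridband)
```

## The problem

When two closely related, normally allopatric plant species are planted side
by side in a botanical collection, spontaneous hybridization can produce
offspring that are hard to diagnose from morphology alone: F1 hybrids,
later-generation backcrosses, and introgressed individuals may all look like
slightly odd members of one parental species. `hybridband` implements the
molecular side of the classical diagnostic workflow for this situation,
built around dominant fingerprint markers (RAPD and AFLP bands scored
present/absent), nuclear sequence alignments of cloned PCR products, and
PCR-RFLP chlorotypes of plastid amplicons.

Dominant markers carry less information per locus than codominant ones — a
band is seen whenever at least one of the two allele copies is the
"presence" allele, so heterozygotes are invisible — but hundreds of loci are
cheap to score, and a modest panel of *species-diagnostic* bands (fixed
present in one parental species, fixed absent in the other) is enough to
place a specimen on the axis between the two species.

## Band classification

For a specimens × loci 0/1 matrix and specimen roles (`parent_A`,
`parent_B`, `query`, `outgroup`), `classify_bands()` applies the standard
category definitions:

* **monomorphic** — present in all scored specimens; **polymorphic** —
  present in at least one but not all. These two categories partition the
  scored loci.
* **unique to a taxon** — present in ≥ 1 specimen of one parental group and
  absent from all specimens of the other.
* **diagnostic (species-specific)** — the fixed subset of unique bands:
  present in *every* specimen of one parental group, absent from *every*
  specimen of the other.

Query specimens never influence unique/diagnostic calls, so adding putative
hybrids cannot disturb the marker panel. Loci seen only in excluded groups
(the outgroup, by default) are dropped before classification, mirroring the
usual removal of outgroup-only bands from such matrices. Both the unique
and diagnostic tallies are reported separately, since within-species
polymorphic unique bands are deliberately not used for the hybrid index.
A strictness knob (`max_violations`, default 0) can relax fixation by a
given number of specimens per group; the default is strict because the
diagnostic definition is a fixation statement.

Missing data are not modeled: dominant-marker scoring in this workflow
records every band as present or absent, and a third "unknown" state would
change every definition downstream. Cells must be 0/1.

## Distances, trees, ordination

Between two band profiles, similarity is Dice's coefficient
$S = 2a/(2a + b + c)$, with $a$ the shared presences and $b, c$ the
presences exclusive to each specimen; shared absences are ignored, the
standard convention for dominant data where a shared missing band is not
evidence of homology. Genetic distance is $D = 1 - S$.

Trees are built by UPGMA (average linkage; the result is rooted and
ultrametric, with merge heights half the mean inter-cluster distance) and
by neighbor-joining (unrooted; negative branch lengths, which can appear on
non-additive input, are clamped to zero and logged). Both are standard
constructions and are delegated to `stats::hclust()` and `ape::nj()` behind
the package's interface; NJ on an additive matrix reproduces the input
distances exactly, which the test suite checks against tree metrics
generated from random trees.

Node support comes from bootstrap resampling of loci (columns) with
replacement, rebuilding the tree per pseudo-replicate, and counting how
often each bipartition of the point-estimate tree recurs — rooted clades
for UPGMA, unrooted splits for NJ. A replicate that leaves a specimen with
no bands at all (Dice undefined) is redrawn, up to 100 attempts.
Resampling is over the columns of the combined matrix; resampling within
marker systems (RAPD vs AFLP strata) can be had by bootstrapping the
per-system matrices separately before merging, but combined-matrix
resampling is the default because the combined matrix is the analysis
object.

Principal coordinate analysis is classical metric scaling
(`stats::cmdscale`): double-centering of the squared distances and
eigendecomposition. Dice distances are mildly non-Euclidean, so a few
small negative eigenvalues are normal; no Cailliez or Lingoes correction
is applied, the variance proportions use only the positive eigenvalues,
and the total negative mass is reported so the distortion can be judged.
Distance matrices can be exported in PHYLIP square format for external
split-network software (Neighbor-Net is deliberately out of scope).

## The hybrid index

With $m_A$ diagnostic markers for parent A and $m_B$ for parent B (51 and
44 in the motivating dogwood system), a specimen is scored by
$c$ = the number of B-diagnostic bands it carries and $a$ = the number of
A-diagnostic bands it lacks. Two index variants are reported:

* **raw**: $(c + a) / (m_A + m_B)$ — the pooled proportion of index-moving
  observations over all diagnostic markers;
* **normalized**: $\tfrac12 (c/m_B + a/m_A)$ — the mean of the two
  per-parent proportions.

Both are 0 for a pure parent A and 1 for a pure parent B, and both are
monotone in each count. They differ in between whenever $m_A \ne m_B$: the
normalized variant is exactly 0.5 at full marker additivity (an F1 carrying
every marker of both parents), while the raw variant gives
$m_B/(m_A + m_B)$ there. Published index values in this literature
sometimes mix the two conventions — near-pure specimens are typically
quoted on the pooled (raw) scale while F1s are quoted as 0.5 — so the
package computes and reports both rather than pretending to a single
formula. Display rounding is half-up at 2 decimals; full precision is kept
internally.

Class calls are interval-based and configurable (`hybrid_thresholds()`),
because class boundaries in this literature are narrative rather than
formal: pure below 0.2 / above 0.8, F1-type within [0.4, 0.6] *and*
carrying at least one diagnostic marker from each parent, backcross in
between, ambiguous for a central index missing one parental set. A
specimen with a pure-range index that nevertheless carries opposite-parent
markers keeps its pure call but is flagged `introgressed` — the signature
of repeated backcrossing toward one parent. Under 1:1 Mendelian
segregation of the non-recurrent parent's dominant markers, a first
backcross to parent A is expected at a normalized index of 0.25, which the
simulation tests verify.

Likelihood-based genotype-class assignment (NewHybrids-style posteriors) is
out of scope; the index plus admixture memberships cover the study design
this package targets.

## The admixture model for dominant markers

The model is a simplified STRUCTURE: $K$ clusters, each with band-allele
frequencies $p_{kl}$ (Beta(1,1) priors), each individual with admixture
proportions $q_i$ (symmetric Dirichlet($\alpha$), $\alpha = 1$ fixed by
default), no correlated frequencies, no linkage. Dominance enters as the
recessive-null coding: the phenotype is

$$\Pr(\text{band absent}) = \Big(\sum_k q_{ik} (1 - p_{kl})\Big)^{\!2},$$

i.e. both allele copies must be null. The Gibbs sampler augments each
individual-locus with the two latent allele copies: given the phenotype,
the pair (cluster-of-origin, allele state) for both copies is drawn jointly
— for an absent band both copies are null and only origins are sampled;
for a present band the both-null combination is excluded — and then
$p_{kl}$ and $q_i$ are redrawn from their Beta/Dirichlet full conditionals.
$P$ is clamped to $[10^{-9}, 1 - 10^{-9}]$ to keep the likelihood finite.
The sampler is implemented in C++ (Rcpp) on R's RNG, so a `set.seed()` run
is bit-reproducible; reported `Q` and `P` are posterior means over retained
sweeps and the log-likelihood trace is the phenotype log-likelihood at the
current parameter values.

Cluster number selection follows the Evanno ΔK criterion on replicate
runs: $\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / s_L(K)$,
defined at interior $K$ with at least two replicates; a zero replicate
standard deviation makes ΔK undefined there (flagged and excluded from the
argmax). Replicate label switching is undone by exhaustive permutation
alignment against a reference replicate (all $K!$ permutations for
$K \le 8$, greedy matching beyond), minimizing the total absolute
membership difference; the full CLUMPP/CLUMPAK machinery is intentionally
not reimplemented.

Default run lengths are desk-scale — burn-in 2000, 10000 retained sweeps —
chosen so that a 25-specimen × 200-locus scan over $K = 1..4$ with 3
replicates completes in well under a minute while reproducing the expected
$K = 2$ selection; the classical settings (1e5/2e5, 10 replicates,
$K = 1..5$) are a parameter change away.

## Sequence diagnostics and PCR-RFLP

For pre-aligned parental groups (the package does not compute alignments),
`find_diagnostic_snps()` reports columns where each parental group is fixed
for a different non-gap state — the "unambiguous" marker notion made
explicit. The fixation fraction is exposed as a parameter (default 1.0,
strict) because published marker counts in this literature are produced by
an undocumented filter; strict fixation is the defensible default.
`find_diagnostic_indels()` reports maximal gap runs fixed (with identical
boundaries) in one group and absent in the other, with length and carrier
group. Coordinates are 1-based alignment columns in all reports; there is
no ungapped remapping.

Cloned query sequences are scored per diagnostic site as A-state, B-state
or novel; counts always sum to the number of sites. This supports the
typical readout for hybrid clones — e.g. a clone carrying 8 of 9
diagnostic SNPs from one parent and 1 from the other, plus occasional
bases absent from both parents.

In-silico PCR-RFLP uses a built-in panel of ten palindromic cutters (AluI,
DraI, HindIII, HinfI, MboI, MseI, MspI, PstI, TaqI, XbaI) with exact
forward-strand recognition matching (palindromes cover the reverse strand);
`N` in a recognition site (HinfI) matches any real base, but ambiguity
codes in the substrate never match — conservative digestion. Fragments of
a linear molecule are returned 5'→3' and always sum to the sequence
length. Specimens with identical multi-enzyme profiles (0 bp tolerance by
default) share a haplotype; the haplotype-by-group concordance table makes
the maternal-inheritance argument directly readable: a chlorotype shared
by one parental species and all hybrids identifies that species as the
seed parent.

## The synthetic-data generator

No raw marker matrix was deposited for the motivating study, so the
generator is a first-class module producing datasets with the statistical
structure the analysis assumes:

* diagnostic loci fixed homozygous-presence in the owning species and
  homozygous-null in the other (defaults 51 A-diagnostic, 44 B-diagnostic
  among 600 loci);
* background loci with independent per-species band-allele frequencies
  drawn from U(0.1, 0.9) and parental genotypes in Hardy–Weinberg
  proportions — the study reports no frequency spectrum, so neutrality and
  independence are assumed;
* F1 = one gamete per species; BC1 = F1 gamete × recurrent-parent gamete,
  so non-recurrent diagnostic presence alleles segregate 1:1;
* phenotypes by strict dominance; optional hybrid-only novel bands
  (phenomenological, not a heteroduplex mechanism) and symmetric scoring
  errors; everything seeded.

Default pool sizes are 10 + 10 parents with 5 F1s, matching the scale of a
botanical-collection survey. One caveat the tests make explicit: with
finite parental pools, a background locus can by sampling chance be present
in all specimens of one pool and absent in the other, and will then be
*called* diagnostic. At 10 + 10 specimens this happens to roughly one
locus in five hundred; every *planted* diagnostic locus is always
recovered (that part is probability-1 under zero error rates), and the
recovery tests assert exact set equality at 25 + 25 parents where the
false-positive probability is negligible. This is a property of real
surveys too, not an artifact: small parental samples overstate fixation.

What passing tests on these simulations do **not** show: robustness to
non-independent loci (AFLP bands can be size-homoplasious), to
reproducibility filtering at the bench, or to later-generation hybrid
classes (F2, BC2+ are an extension point, not covered).

## Pipeline and reproducibility

`run_pipeline()` chains the stages (input/simulate → band classification →
distance → tree → PCoA → hybrid index → admixture scan) with one global
seed; each stochastic stage derives its own seed by a stable string hash of
(global seed, stage name), so adding a stage never shifts the streams of
existing ones, and a fixed-seed run is byte-reproducible. The package's
interface is its R functions plus `scripts/acceptance.R`; no shell
subcommand wrapper is provided, as the intended users drive analyses from
R. Reports are written as JSON plus delimited text, with the documented
2-decimal half-up rounding applied only to display exports.

## Numerical choices, in one place

* Dice undefined for two all-absent profiles → error, not NaN; bootstrap
  replicates that create all-absent specimens are redrawn.
* NJ negative branch lengths clamped to 0 (message emitted).
* PCoA: no negative-eigenvalue correction; positive-eigenvalue denominator;
  negative mass reported.
* Admixture: `P` clamped at 1e-9 from the boundaries; Q rows renormalized
  exactly by construction (Dirichlet draw).
* ΔK undefined where the replicate sd is 0; such K are excluded from the
  argmax rather than treated as infinite.
* Display rounding half-up at 2 decimals (`round_half_up()`); all stored
  values full precision.
* Problem sizes used by the acceptance computations: 200 simulated F1s for
  index recovery; a 25-specimen × 200-locus dataset, K = 1..4 × 3
  replicates at 2000 + 10000 sweeps for ΔK selection.
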