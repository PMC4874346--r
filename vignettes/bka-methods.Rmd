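---
title: "Quantifying and comparing bacterial killing capacity from endpoint serial-dilution assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing bacterial killing capacity from endpoint serial-dilution assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bkassay)
library(dplyr)
```

## The assay and its measurement model

The bacterial killing assay (BKA) measures the strength of humoral
constitutive innate immunity: serum is serially diluted (here two-fold,
1:2 to 1:256), challenged with a fixed *E. coli* inoculum, and bacterial
growth is read as absorbance at the start of incubation and 12 h later.
Two control types anchor the plate: positive controls (inoculum in PBS,
no serum) define saturated growth, and negative controls (PBS only)
monitor the medium itself.

Freshly prepared growth medium can discolour during incubation, dropping
the negative-control absorbance by up to about 14%. The per-plate
correction term is

$$\delta C = \overline{A_{12h}^{neg}} - \overline{A_{0h}^{neg}},$$

estimated from each plate's own negative controls and never pooled across
plates. Each well's raw growth $\delta A = A_{12h} - A_{0h}$ is then
combined with $\delta C$; the duplicate wells at each dilution are averaged
($\bar D$), and the percent killing capacity is

$$\mathrm{capacity} = \left(1 - \bar D / \bar P\right) \times 100,$$

with $\bar P$ the positive-control mean growth. Capacities above 100%
(net absorbance loss) or below 0% (growth beyond the positive control)
are retained by default — clipping would destroy exactly the information
the classification bands need.

Two points in this arithmetic are genuinely ambiguous and are therefore
both implemented, selectable by configuration:

* **Sign of the correction.** The default *adds* $\delta C$ to each
  $\delta A$. The alternative *subtracts* it, which is the direction that
  cancels (rather than doubles) a drift shared by all wells. When the
  plate shows no drift the two coincide, and the package treats the
  additive form as the default with `sign_convention = "subtract"` as the
  escape hatch. Note that when the same convention is applied to the
  positive controls as to the sample wells, a plate-wide shift largely
  cancels in the capacity ratio either way.
* **Whether $\bar P$ is corrected.** `positive_mode = "corrected"`
  (default) applies the same drift correction to positive controls, so
  all bacteria-bearing wells are treated alike; `"raw_12h"` uses the raw
  12 h positive-control absorbance instead.

## Endpoint rank scoring

On carnivore serum the assay behaves as a threshold process: up to some
dilution the serum kills the entire inoculum (capacity near 100%), and
beyond it the bacteria grow to saturation (capacity near 0%) — there is no
intermediate "optimal working dilution". The natural summary is therefore
an endpoint rank: the highest dilution step still showing complete
killing, with 1:2 mapping to rank 1 through 1:256 at rank 8.

Because wells are run in duplicate, the two aliquots at an individual's
threshold dilution sometimes disagree — one kills completely, the other
not at all — giving a mean capacity near 50%. Such samples receive the
mean of the two adjacent ranks, producing half-integer scores. A sample
that fails to kill even at 1:2 scores 0; by the same averaging rule a
discordant 1:2 dilution with no complete kill anywhere scores 0.5.

Raw capacities are noisy, so the package discretises each dilution's mean
capacity into `FULL` / `HALF` / `NONE` calls before applying the rank
rule. The two cutoffs are the pipeline's main free parameters:

* `full_threshold = 95`: complete killing reads at or above ~95% in
  practice, so 95 separates "complete" from everything else;
* `none_threshold = 25`: saturated growth reads near 0% with a spread set
  by read noise relative to positive-control growth (roughly 10 percentage
  points of standard deviation under the default noise model), so 25 is
  about 2.5 noise SDs above 0 while staying far below the ~50% band that
  marks a discordant duplicate.

The original assay description gives no numeric cutoffs; these defaults
are this package's choice and are recorded in every scored output.
Sequences that violate the single-threshold assumption (a `FULL`
reappearing after the first `NONE`, or a `HALF` not adjacent to the last
`FULL`) are scored at the last `FULL` before the first `NONE` and flagged
with a warning rather than silently reinterpreted.

## The statistical layer

All inference is nonparametric, matching the ordinal, heavily tied nature
of the rank scale. Every Monte-Carlo p-value uses the add-one estimator
$(b+1)/(B+1)$, is seeded explicitly, and is bit-reproducible; its floor is
$1/(B+1)$.

* **Kruskal–Wallis** (tie-corrected H) compares rank distributions across
  species; the asymptotic $\chi^2_{k-1}$ p-value is the default, with a
  label-permutation option for small samples.
* **Dwass–Steel–Critchlow–Fligner** all-pairs posthoc comparisons use the
  standardized pairwise Wilcoxon statistic (mid-rank tie correction,
  $\sqrt 2$ Studentized-range scaling) with each pair's p-value obtained
  by re-splitting the pooled pair at the observed group sizes. With
  heavily tied data the attainable p-values are limited by the number of
  distinct re-splits — with two groups of four, complete separation
  yields $p \to 2/70$, not the Monte-Carlo floor.
* **Jonckheere–Terpstra** tests a monotone trend across ordered groups
  (storage years); ties count one half. The two-sided p doubles the
  smaller permutation tail, capped at 1, since the storage-effect
  hypothesis is non-directional.
* **Skillings–Mack** generalizes Friedman to incomplete blocks and is the
  repeated-measures test across sampling occasions (1st to 6th capture of
  an individual); on complete balanced data it equals the Friedman
  statistic exactly, which the tests verify. Its permutation null
  shuffles observations within blocks.
* **Fisher's exact test** on the 6×2 species-by-sex table goes through the
  network algorithm (Monte-Carlo fallback for large tables).
* The **Mantel test** correlates the lower triangles of the species
  profile-distance matrix and a phylogenetic distance matrix, aligned by
  label, with a one-sided (positive association) permutation p by
  default, since the question is whether related species have similar
  immune phenotypes. The default permutation count is 9,999.

The repeated-measures "treatment" is the occasion index of each capture,
the only level structure shared across individuals with different
capture years.

## Species profiles, clustering and congruence

Cross-species comparisons deduplicate to one randomly chosen sample per
individual (seeded) to avoid pseudo-replication. Species profiles are the
per-species means of the per-sample mean capacities at each of the eight
dilutions; pairwise Euclidean distances between these 8-vectors feed both
the Mantel test and hierarchical clustering.

Clustering uses centroid (UPGMC) linkage, computed on squared Euclidean
distances — the geometry in which centroids are defined — with merge
heights reported back on the Euclidean scale. Centroid linkage can invert
(a later merge below an earlier one); inversions are recorded in the tree
object rather than reordered away. Input labels are sorted before
clustering, so tied merges resolve toward the lexicographically smallest
pair and the result does not depend on row order. Trees serialize as
Newick with the ultrametric midpoint convention (a pair merging at height
$h$ gets two branches of $h/2$), and tree-to-tree comparison uses the
Robinson–Foulds distance on unrooted topologies.

The choice to cluster mean capacity profiles (rather than per-individual
ranks) mirrors the construction of the distance matrix used by the Mantel
test, keeping the two congruence analyses on the same object.

## The synthetic-data generator

The generator exists so the full pipeline is testable without laboratory
data. Its model is deliberately the same threshold process the scoring
assumes, plus the nuisance effects the quantification must absorb:

* each individual draws a latent threshold from a truncated normal on
  [0, 8] rounded to the integer grid — the simplest distribution with the
  observed half-integer rank support including the rank-0 floor;
* wells at or below the threshold show zero growth plus read noise; wells
  beyond it grow to the positive-control level (`growth_mean` 0.40 AU on
  an `abs_0h` baseline of 0.50 AU, read noise 0.01 AU);
* at the boundary dilution one duplicate flips to killing with
  probability `p_discordant` (0.15 by default), generating half ranks;
* negative controls drift down by a per-plate uniform fraction of up to
  14% of baseline; positive controls grow fully.

The default study configuration reproduces the sampling design of the
field study the package is built around: six species with 275 / 38 / 10 /
10 / 8 / 8 individuals, published sex ratios, and repeated sampling (30,
8, 4, 2, 1 cheetahs captured 2–6 times, one caracal twice), giving 421
samples from 349 individuals of which 46 are repeats. Species threshold
means (cheetah 6.0, caracal 6.5, leopard 4.5, lion 4.0, brown hyena 3.5,
black-backed jackal 0 with SD 0) encode the qualitative ordering the
assay showed — the cheetah's kill/no-kill drop concentrated between 1:64
and 1:128, caracals slightly above cheetahs, the three mid-ranked species
similar to one another, and jackal serum never fully killing even at 1:2.
Within-species SD is 0.8 ranks, a spread wide enough to put most species
across 3–4 adjacent ranks without collapsing the species ordering.
Repeated captures of an individual keep its threshold fixed, so the
storage-time and repeated-measures tests are true nulls under the
generator.

A companion `planted_phylo_distances()` builds a phylogeny-like distance
matrix as a convex mixture $s\,D_{signal} + (1-s)\,D_{noise}$ of the
expected-profile distances and a random Euclidean configuration, so
congruence can be dialled from absent ($s = 0$, Mantel p uniform) to
perfect ($s = 1$, Mantel r near 1). The default is $s = 0.8$, a strong
but imperfect congruence of the magnitude the assay study reported.

What the generator does *not* emulate: partial-kill continua (a sigmoid
transition width exists only as a robustness option in spirit; the model
is binary by construction because that is what the assay showed),
plate-position effects, batch effects between assay days, storage-driven
decay, or any mechanistic growth kinetics. Passing tests therefore
demonstrate that the pipeline recovers parameters *under the stated
threshold model*, not that the model is right for any particular
laboratory's data.

## Numerical choices and degenerate inputs

* A plate without negative or positive controls, or whose corrected
  positive-control mean growth is not positive, is rejected outright.
* Samples with a replicate count other than two at some dilution are used
  as-is with a warning (error in strict mode).
* The Skillings–Mack covariance is inverted with a Moore–Penrose
  generalized inverse (the matrix is singular by construction); blocks
  observing fewer than two levels are dropped with a warning.
* Monte-Carlo p-values never report 0; determinism is per-seed and
  per-pair (DSCF derives one stream per pair from the base seed).
* Within-block constant data gives a Skillings–Mack statistic of exactly
  0; identical groups give a tie-corrected H of exactly 0.

## Problem sizes used by the test-suite

The packaged checks run the generator at desk scale: the full 421-sample
default study for structural checks, six species at $n = 50$ for
threshold-recovery checks (recovered species means within 0.25 ranks of
the planted means), 1,000 replicates for the size calibration of each
test at $\alpha = 0.05$ with $B = 199$ permutations per replicate, and
exhaustive enumeration oracles on instances of up to 8 observations.
These sizes were chosen to keep each statistical check's own Monte-Carlo
error well below the tolerance it asserts.

## Known limitations

* The classification cutoffs (95 / 25) are defaults, not measurements;
  datasets with different noise regimes should recalibrate them and the
  scored output records them for exactly that reason.
* The DSCF p-values are per-pair permutation p-values; no family-wise
  envelope across the 15 pairs is imposed beyond the Studentized-range
  scaling of the statistic.
* Centroid-linkage inversions make dendrogram heights non-monotone; the
  package reports them but the Newick serialization of an inverted merge
  necessarily contains a negative internal branch.
* With only six taxa, the Mantel permutation null has 720 distinct
  relabellings; p-values below ~0.0014 are unattainable regardless of
  permutation count.
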