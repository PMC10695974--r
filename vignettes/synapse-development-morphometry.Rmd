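---
title: "Quantifying synaptic development on skeletonized EM reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic development on skeletonized EM reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isochron)
```

## The measurement problem

Volume electron microscopy resolves every synapse in a block of cortex, but
the quantities neuroscientists compare across ages and species are not the
raw voxels — they are cable-length-normalized summary statistics computed on
skeletonized reconstructions: spine and shaft synapse densities per
micrometre of dendrite, filopodia per micrometre, total synapses and
distinct innervating axons per soma, synapse and branch frequencies along
axons, bouton volumes, PSD areas, and mitochondria coverage. `isochron`
implements that measurement layer as a tested, reusable pipeline, together
with a synthetic annotation-data generator so the whole chain can be
exercised, end to end and deterministically, without any imaging data.

The package deliberately works at the skeleton-plus-annotation level of
description. A neurite is a rooted tree of 3D nodes with radii
(the standard SWC representation); a synapse is a row in a table linking a
presynaptic axon identifier to a postsynaptic cell, a nearest skeleton node
and a target class (`spine`, `shaft` or `soma`), with optional PSD area,
vesicle count and bouton radius; filopodia and mitochondria are analogous
tables. Segmentation, proofreading and mesh geometry are out of scope — the
package consumes the *outputs* of such pipelines.

## Units

Coordinates and radii are micrometres. PSD areas are nm², mitochondria
volumes nm³, and mitochondria *density* — total mitochondrial volume per
length of dendritic cable — is kept in nm² (nm³ per nm). The nm² density
unit is unusual but is retained verbatim so values are directly comparable
with the published per-age means the bundled profiles encode. Mixing unit
systems between figures is a classic source of silent error; every function
documents its units.

## Dendrite morphometry

Densities are estimated on *fragments*: a dendrite is traced for a target
length (default 10 µm) and the number of annotations assigned to nodes on
the traced path is divided by the actual path length. Fragments that hit a
tip early are flagged truncated and their true length is used as the
denominator, never the nominal target. `sample_fragments()` draws start
nodes without replacement and walks tipward; at branch points the default
rule follows the thicker daughter (`traverse_branch`), because a human
tracer following "the" dendrite naturally continues along the dominant
shaft. A `stop_at_branch` rule is also exposed; which convention the
original tracing used is not documented, so both are available and the
default is stated here.

Two numerical details matter:

* **Membership is by node assignment, not spatial proximity.** A synapse
  belongs to the fragment when its `post_node_id` lies on the path. This
  mirrors how annotators assign synapses to traced dendrites, and it makes
  the split-and-pool identity exact: cutting a fragment in two and pooling
  counts and lengths reproduces the whole-fragment density to the last
  digit. The cost is a half-edge edge effect: an interior fragment's first
  node also collects synapses from the half edge *before* the path, so very
  short interior fragments are biased upward by roughly
  `spacing / (2 × length)`. Whole-dendrite fragments (used by the pipeline,
  where each generated dendrite *is* one traced fragment) have no such
  bias, which is why the density estimator is exactly unbiased there.
* **Diameter is a proxy.** The published measurements callipered each
  dendrite in three orthogonal image planes and averaged. Skeletons carry
  one radius per node, so `fragment_diameter()` reports twice the mean node
  radius along the path. We measure the shaft only; whether the original
  calliper measurements excluded spines is not stated, and the assumption
  is recorded here rather than hidden.

`spine_branch_distance()` measures how far a spine-synapse head sits from
its parent shaft: the Euclidean distance (reported in nm) from the synapse
position to the nearest point of the dendritic polyline. It is exactly zero
on the cable, never negative, and invariant under rigid motions.

`bulk_2d_density()` implements the single-section counting rule used for
very young tissue: synapses per field of view (default 20 µm²) counting
only events with at least 5 presynaptic vesicles, so sub-threshold
distractors never change the estimate.

## Somatic innervation

`soma_profile()` tallies synapses with `target_class == "soma"` on one
cell and groups them by presynaptic axon id. Two invariants are enforced
and tested: the per-axon counts always sum to the total, and the axon count
is monotone under identity merges/splits. Only cells listed in the
dataset's `complete_somata` metadata are admissible — a soma partially
outside the volume undercounts, so the function refuses it rather than
returning a biased number. Perisomatic synapses (on the first stretch of
dendrite) are *not* folded into the soma count, keeping the per-soma metric
faithful to its definition.

Bouton geometry treats the bouton as the sphere fitted during annotation:
surface area `4πr²`, volume `(4/3)πr³`, hence `SA/V = 3/r`. PSD occupancy
divides the summed PSD areas of somatic synapses by the soma sphere
surface; it is a qualitative bound (published data place it under ~10%), so
values above 1 are clipped with a warning rather than treated as valid.

## Axon analysis

`axon_trace_stats()` reports synapses and branch points per micrometre of
axonal cable, with branch points counted as nodes with at least two
children. The excitatory-axon call follows the operational tracing rule:
from a seed bouton, the axon must offer at least `min_additional = 3`
further synapses; it is called *excitatory* if any of them contacts a
dendritic spine, and otherwise stays *unclassified* — the rule never
licenses an inhibitory call, and axons with too few synapses are flagged
insufficient instead of being guessed. Additional synapses are examined in
trace order (along-cable distance from the seed, nearest first, ties broken
toward the thicker daughter); since the decision is "any spine among those
examined", it is invariant to the ordering of non-spine synapses, which the
tests check. We examine all available additional synapses once the minimum
of three is met, matching the tracing protocol's "at least 3" phrasing.

`detect_retraction_bulbs()` operationalizes the qualitative anatomy of a
retraction bulb — a sudden terminal swelling densely packed with
mitochondria. A terminal is flagged when its radius is at least
`radius_factor = 2` times the median non-terminal radius *and* at least
`min_bulb_mitos = 3` mitochondria lie within `span_um = 2` µm of it along
the cable. These thresholds are declared detector parameters (the source
anatomy is qualitative); the synthetic generator places bulbs well above
threshold (factor 3, 5 mitochondria), so on synthetic data the detector's
sensitivity is 1 by construction and its false-positive rate on bulb-free
axons is tested to stay under 2%. Detection is branch-specific: other
branches of the same axon keep their synapses.

## Mitochondria

`mito_dendrite_record()` sums the volumes of mitochondria hosted on a
dendrite (membership by host-skeleton span; partial spans count their full
volume, since no apportioning rule is documented) and pairs the resulting
coverage density with the dendrite's spine-synapse density.
`coverage_synapse_correlation()` then reports the Pearson r across
dendrites, split by apical/basal compartment, with the two-sided p-value
from the t reference distribution.

## The statistics layer

The comparison statistics are implemented from first principles because
they *are* part of the method being reimplemented; the standard library
implementations (`wilcox.test`, `cor.test`) appear only as independent
cross-checks in the test suite.

* **Mann-Whitney U.** U is computed from midranks. In `auto` mode the
  exact permutation null is fully enumerated when `n1 + n2 ≤ 16` and the
  pooled sample is tie-free; otherwise the normal approximation with tie
  correction and a 0.5 continuity correction is used. Two-tailed p doubles
  the smaller one-sided tail, capped at 1 (the common Wilcoxon convention).
  A pooled sample of identical values is degenerate and returns p = 1 with
  a flag. Whether the original analysis used exact or approximate mode for
  small n is unstated; `auto` is the declared default. The test suite
  checks the exact branch against a brute-force enumeration oracle, the
  approximation against the exact branch (within 0.02), the realized
  type-I error (within [0.03, 0.07] at α = 0.05 over 2000 null pairs of
  n = 20), and power on density samples a factor ~2.4 apart.
* **Pearson r** with `t = r√((n−2)/(1−r²))`; log-normal fits by maximum
  likelihood on the logs (n-denominator), with a normality test on the
  logs as goodness of fit; `mean_sem()` uses the n−1 sample standard
  deviation, and `change_metrics()` provides the percent and fold changes
  used for headline comparisons.
* **No multiple-testing correction by default.** Pairwise p-values between
  adjacent ages are reported uncorrected, matching the source analysis;
  the CLI can emit Holm-adjusted values on request.

## What the synthetic generator emulates — and what it does not

Each bundled *age profile* (`list_profiles()`) names one
species/region/layer/postnatal-day condition and carries the measured
means: spine density for mouse V1 L2/3 rising 0.01 → 0.87 → 1.63 → 2.1/µm
from p6 to p105 and declining by p523, the primate p7/p75/p3000 arc,
somatic innervation (e.g. 72.2 synapses from 33 axons at mouse p105),
axonal synapse/branch frequencies, bouton volumes, vesicle counts, the
p14/p105 mitochondria densities and their basal-dendrite correlation with
synapse density. Values not printed anywhere (shaft densities per age, the
absolute PSD-area scale, mitochondria parameters for the primate) were
chosen once to be anatomically plausible and are fixed in the profile
JSONs; the PSD and vesicle-cloud log-normal scales are constrained so the
p14 → p105 mean increases are 66.5% and 14.8% respectively, and the p6
shaft rate follows from the reported 8 shaft synapses over ~125 µm of
dendrite.

The generator makes the simplest distributional choices compatible with
published summaries:

* **Homogeneous Poisson placement** of synapses and filopodia along cable.
  Only mean densities are reported, so no clustering model is assumed.
* **Somatic innervation**: axon count ~ Poisson; each axon contributes
  `1 + Poisson(m − 1)` synapses with `m` the ratio of the two profile
  means, so the expected total matches the soma mean exactly (Wald's
  identity). The joint distribution of per-axon counts is not published;
  this partition is declared, not inferred.
* **Axon growth** at fixed total cable: each Poisson branch event converts
  the current tip into a branch point with two daughters, so realized
  branch count over cable length estimates the branch rate without bias.
* **Sizes**: PSD areas and vesicle-cloud sizes log-normal (the published
  distribution family); bouton volumes log-normal around the profile mean
  with CV 0.4; vesicle counts shifted Poisson (support starts at 1 — an
  annotated bouton has at least one vesicle).
* **Mitochondria**: per-dendrite density is linear in spine density plus
  Gaussian noise, with slope and noise solved from the target Pearson r
  and a density CV of 0.3 (chosen once, close to the dispersion implied by
  the published p14 SEM); apical dendrites use target r = 0. Densities are
  truncated at 1% of the mean to keep volumes positive — at CV 0.3 the
  truncation probability is negligible, so moments are effectively
  unchanged.
* **Excitatory shaft inputs**: a shaft synapse is made by an excitatory
  axon with probability 0.24 across all profiles. In full axon-population
  simulations, excitatory and non-excitatory axons produce shaft synapses
  at the same per-axon rate, so the shaft-weighted excitatory fraction
  equals the mixing fraction and the tracing-based classifier recovers it.

Determinism is a contract: the same (profile, seed) produces a
byte-identical dataset, and composite generators derive per-component
sub-seeds from a dedicated RNG stream (`derive_seeds()`), so datasets of
any size are reproducible from one integer.

What passing tests on synthetic data do *not* show: real dendrites taper,
real synapse placement is clustered and depth-dependent, annotators make
correlated errors, and real axons leave the volume. Recovery of generator
parameters validates the estimators' arithmetic and statistical behaviour
under the stated model — it is not evidence about biology, and no claim
beyond estimator correctness should be read into it.

## Problem sizes and runtime choices

The recovery analyses use 200 ten-µm dendrite fragments, 500 somata, 300
axons of 100 µm and 500 boutons — sizes at which the 3-standard-error
acceptance bands are decisive for every bundled mean while a full run of
the test suite and the acceptance script completes in a couple of minutes
on a single core. Node spacing is 0.5 µm for dendrites and 1 µm for axons:
fine enough that node-assignment granularity is far below the densities
measured, coarse enough to keep trees small.

## Degenerate inputs and tie-breaks

Zero-length fragments, empty samples, non-positive radii, unknown target
classes, dangling parents, cycles, disconnected subsets, all-identical
pooled samples, zero-variance correlations and infeasible correlation
targets (|r| > 1) all raise immediate, specific errors or flagged
degenerate results — never silent NAs. Ties at branch points (equal
daughter radii) resolve to the first thicker-or-equal daughter
deterministically via `which.max`.

## Known limitations

* Fragments sampled from *within* long dendrites inherit the half-edge
  membership bias described above; for unbiased density estimation use
  whole traced fragments, as the pipeline does.
* The soma is modelled as a single sphere-node; PSD occupancy therefore
  ignores soma shape.
* Mitochondria membership is span-based and does not apportion volume for
  organelles crossing dendrite boundaries.
* The generator does not model dynamic turnover (only net counts),
  voxel-level imagery, or cross-dataset axon continuity.
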