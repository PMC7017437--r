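---
title: "Quantifying and analysing dermal shield vascularization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and analysing dermal shield vascularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermovasc)
```

## The scientific question

Dermal bone — crocodylian-line osteoderms and the turtle shell — is not
inert armour: its internal cavities house blood vessels implicated in
acidosis buffering during apnea, in heat transfer, and (in soft-shelled
turtles) in cutaneous respiration. The *vascular area fraction* of a bone
cross-section, here called porosity, is a practical proxy for that
vascular supply, measurable on fossils as well as extant material.

Two questions follow for a sample of plates spread across a clade's
history. Is porosity *phylogenetically structured* — do close relatives
resemble each other beyond what lifestyle predicts? And does porosity
*track lifestyle* (terrestrial, freshwater/semi-aquatic, marine) once
that phylogenetic structure is discounted? `dermovasc` implements the
full chain: porosity measurement from binary section images, descriptive
statistics by lifestyle, Blomberg's K, Pagel's λ, a phylogenetic ANOVA,
and squared-change parsimony ancestral states, together with
synthetic-data generators that provide known ground truth for every step.

## Porosity from binary sections

A section is a two-valued raster: bone matrix versus void. Porosity is

$$\text{porosity} = \frac{\text{enclosed void}}{\text{enclosed void} + \text{bone}},$$

where *enclosed* void is any void not connected to the raster border.
Void is traversed with 4-connectivity and bone is therefore implicitly
8-connected — the standard digital-topology pairing that avoids
connectivity paradoxes. Every enclosed cavity counts, with no minimum
size: in histological practice even small cavities are vessel-filled.

Ornamented dermal bone carries apical crests separated by pits, and the
pits are packed with vessels; excluding them would understate the
vascular supply. `measure_vascular_area(..., bridge = TRUE)` therefore
(1) extracts the surface elevation profile on the ornamented side,
(2) finds crest apices as local maxima, and (3) joins consecutive apices
with one-pixel digital straight segments of bone, enclosing the pit
space so it counts as vascular area. Joining *consecutive* apices is the
shortest total bridging over order-preserving pairings; skipping an apex
could only lengthen the chain and would bury a crest.

Tunable parameters, all in pixels:

* `min_prominence` (default 3): a candidate apex must rise at least this
  far above the saddle separating it from higher ground. This suppresses
  single-pixel surface noise; on unornamented sections nothing passes,
  so `bridge = TRUE` is then a no-op by construction.
* `min_separation` (default 5): minimum spacing between accepted apices;
  when two candidates are closer, the more prominent one wins.
* `connect_edges` (default `FALSE`): optionally join the outermost
  apices to the first/last bone-surface point along the axis. It is off
  by default because with ornament confined between the outermost crests
  the extra segments are at best a no-op and can spuriously enclose
  non-pit margin area; turn it on for sections whose pits run to the cut
  edge.

Numerical conventions: flat apex plateaus contribute their midpoint,
ties rounding toward the lower index; digital segments are 8-connected
with both endpoints included; re-bridging a bridged section changes
nothing (the bridged surface has at most one apex plateau).

```{r}
gen <- generate_section(200, 130, target_porosity = 0.18,
                        ornamented = TRUE, n_crests = 5, seed = 1)
measure_vascular_area(gen$section, bridge = TRUE, side = "top")
gen$porosity_true
```

## The specimen dataset

The package ships the transcribed sample tables of the two study groups:
31 turtle shell sections in three lifestyle categories (terrestrial,
freshwater, marine) and 32 crocodylian-line osteoderm sections in two
(terrestrial, semi-aquatic). Plates — not species — are the sampling
units, so conspecific plates are distinct records with suffixed ids.
*Yarasuchus deccanensis*, an avemetatarsalian figured and analysed with
the pseudosuchian sample, is retained in that dataset and tagged by its
`clade` so it can be excluded with `include_outgroup = FALSE`; both
modes are supported because the original analysis is ambiguous on this
point.

`group_stats()` reports per-lifestyle n, mean, median, sample standard
deviation (n − 1 denominator — the population form does not reproduce
the published values), min and max, at full precision; display rounds
half-up to two decimals. One documented discrepancy: the published
semi-aquatic median (0.19) is not the median of the published
semi-aquatic porosity values, whose midpoint-of-central-values median is
0.175. The package reports the computed value and flags the mismatch
rather than silently matching the printed cell.

## Chronograms and the 1-Myr split rule

Trees are time-scaled (branch lengths in Myr), rooted, possibly
non-ultrametric (fossil tips end early) and may contain polytomies. The
exact calibrations of the original study trees were never published, so
the package ships coarse *reconstructed* chronograms (topology from the
published relationships of the sampled taxa; stage-midpoint tip ages;
round node ages). Every statistic computed on them is tree-dependent and
is treated as illustrative, not as a reproduction target; all
tree-dependent validation in the test suite is property-based on
synthetic trees instead.

Conspecific plates mapped to one species tip are expanded by
`split_conspecific_tips()`: a k-plate group's tip is replaced by a
hypothetical ancestor 1 Myr before the tip age carrying k pendant
branches of 1 Myr. Against timescales of 180–250 Myr this distorts path
lengths by well under 1%. Between-group shared history is preserved
exactly.

The Brownian covariance C has entries equal to the shared root-to-MRCA
path length; it is computed directly from the tree, so polytomies need
no resolution anywhere in the package (the contrasts algorithm is never
used). Zero-length pendant branches, which duplicate rows of C, are
perturbed on the diagonal by 1e-8 Myr only when they actually make C
singular.

## Phylogenetic signal

**Blomberg's K** compares the phylogenetically corrected mean squared
error of the trait with its star-phylogeny counterpart and scales the
ratio by its Brownian-motion expectation, so K = 1 under Brownian
evolution (exactly 1 on an equal-depth star tree, for any trait). Its
significance is assessed by permuting trait values across tips
(999 by default) with the add-one p-value estimator
$(1 + \#\{MSE_{perm} \le MSE_{obs}\})/(n_{perm}+1)$, which cannot return
zero.

**Pagel's λ** multiplies the off-diagonals of C; the ML estimate
maximises the profile multivariate-normal log-likelihood (mean and rate
profiled analytically) over [0, 1]. The bound of 1 is deliberate:
non-ultrametric trees admit λ slightly above 1, but the interpretation
is fragile and the study trait does not require it. The optimiser is a
51-point grid scan followed by golden-section refinement in the
bracketing interval (tolerance 1e-8), which in testing lands within
1e-4 of a dense grid search. The p-value is a likelihood-ratio test
against λ = 0 (the convention of the software the field uses); the test
against λ = 1 is available via `null = "one"`. On a star phylogeny λ is
unidentifiable and the lower bound is returned with a warning.

Both statistics are invariant under affine transformation of the trait,
which the tests verify, and both are cross-checked against an
independent implementation (phytools) on binary trees.

## Phylogenetic ANOVA

The default mode (`bm_simulation`) is the standard simulation null: the
observed one-way F statistic for porosity across lifestyles is referred
to the distribution of F over `n_sim` Brownian trait vectors simulated
on the tree (rate estimated from the data by GLS; F is scale-free, so
the rate choice does not affect the p-value). Two GLS modes exist
because the original analysis states that the phylogeny entering its
ANOVA is "quantified" by either K or λ: `gls_lambda` whitens by
C(λ̂) and uses the exact GLS F test, and `gls_K_scaled` does the same
under the untransformed Brownian C — the covariance under which K is
defined — as a documented approximation, since K itself does not induce
a covariance transform. On a star tree the GLS test reduces to the
classical ANOVA and the simulation p converges to the classical p,
which the tests verify, along with type-I calibration (rejection rate
0.05 ± 0.02 under the Brownian null across 500 replicates).

## Ancestral states

`squared_change_parsimony()` minimises the branch-weighted sum of
squared changes — a strictly convex quadratic solved exactly as a linear
system, with no iterative tolerance. The branch-length-weighted solution
equals the Brownian ML ancestral states, and its root equals the GLS
phylogenetic mean; the unweighted variant is provided because the
original study's software default is ambiguous. Reconstructed states
always lie within the range of the tip values.

## What the synthetic generators emulate — and what they do not

* `simulate_tree()`: star, balanced, Yule-shaped (rescaled to a stated
  depth) and user-fixed topologies, sized like the study trees
  (~30–64 tips, depths of order 100 Myr).
* `simulate_traits()`: exact Brownian branch-increment simulation
  (λ = 1), dense factorised sampling for λ < 1, and additive
  lifestyle-style group mean shifts.
* `generate_section()`: a bone body with non-overlapping circular pores
  plus single-pixel adjustment pores that hit the target porosity
  exactly in pixels, and optional equal-height triangular crests whose
  bridging chords are horizontal — so the enclosed pit area is known
  exactly and the measurement round-trip is pixel-exact.

These generators reproduce the *statistical and geometric structure* the
pipeline assumes, not real data: real sections have irregular outlines,
anisotropic and size-structured cavities, segmentation noise, and crests
of unequal height (where rasterised bridging chords can differ from the
ideal by about a pixel per bridge, the tolerance used throughout);
real traits need not follow Brownian motion or any λ-blend of it; and
lifestyle categories are assigned by experts, not drawn at random.
Passing tests therefore demonstrate correctness of the computations
under the stated models, and calibration/power of the tests under those
models — not that the models are right for any particular dataset.

Every generator takes an explicit integer seed and is fully
deterministic under it. Simulation sizes used in the test suite (1000
Brownian replicates for the mean-K check, 200 replicates per λ recovery
arm on 64-tip trees, 500 replicates for ANOVA calibration with a
399-draw null each, 50 synthetic sections) were chosen so Monte-Carlo
error is comfortably below the property tolerances.

## Known limitations

* The reconstructed chronogram fixtures are coarse; use your own
  calibrated trees for substantive inference (`run_pipeline(tree = ...)`).
* Radial compactness profiles (sigmoid modelling of compactness from
  centre to cortex) are out of scope; only the global area ratio is
  computed.
* No confidence intervals on ancestral states, and no post-hoc pairwise
  lifestyle contrasts, mirroring the original analysis surface.
* Ornament-side detection is not automatic; the caller states which of
  the four cardinal sides carries the ornament.
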