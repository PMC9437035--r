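---
title: "Reconstructing olfactory receptor glomerular maps from serial-section RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing olfactory receptor glomerular maps from serial-section RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomap)
```

## The problem and the data

Each mouse olfactory sensory neuron expresses one olfactory receptor (OR)
or trace amine-associated receptor (TAAR), and the axons of all neurons
expressing the same receptor converge onto one or two glomeruli — 50–120 µm
spheres of neuropil on the olfactory bulb (OB) surface, typically one on
the lateral and one on the medial half, with the medial partner displaced
posteriorly. The data `glomap` consumes are receptor-by-section abundance
tables from consecutive 100 µm sections cut along three axes
(anteroposterior AP, dorsoventral DV, mediolateral ML) of separate
replicate animals, plus an OMP row per table (olfactory marker protein,
expressed by all mature sensory axons, proxying how much glomerular
material each section contains). Each axis series localizes every receptor
along one coordinate; the package's job is to merge replicates, locate
receptors along each axis, combine the axes into 3D glomerulus positions,
and relate receptor protein sequence to those positions.

## Section weighting and 1D positions

TPM-like abundances are per-section shares: a receptor whose glomerulus
sits in a sparsely innervated slab looks inflated, one in a crowded slab
deflated. The weight `w_s = l_s / p_s` (OMP share `p_s`, glomerular-layer
share `l_s` from the scaffold's shell voxel counts, rescaled to mean 1 over
sections with OMP; `w_s = 0` where OMP is absent) converts shares into
per-unit-glomerular-material abundances. Weighted profiles are min-max
normalized per receptor (flat rows are zeroed and reported, the four
receptors with suspected ectopic bulb expression are dropped by default),
replicates are merged by the cellwise median and renormalized, and each
receptor is summarized by its expression-weighted mean position, computed
on the weighted pre-normalization values because min-max rescaling destroys
the relative mass the mean depends on. Group-level contrasts (dorsal vs
ventral zone, Class I vs Class II, TAAR vs OR) use a two-tailed
Mann-Whitney U test — exact enumeration when both groups have at most eight
members, otherwise the continuity-corrected normal approximation — and
concordance with an external epithelium zone index uses Spearman
correlation.

A numerical note: across every achievable U at group sizes 8/8, exact
enumeration and the continuity-corrected normal path agree to within
0.0109, with 8 of 65 U values (near |U − µ| = 8) between 0.0102 and 0.0109;
the test suite asserts exactly this exhaustive bound.

## The 3D model

Counts of section *s* are multinomial over receptors; with the weak
symmetric prior `Dirichlet(0.65)` the posterior composition is
`Dirichlet(n_s + 0.65)`, sampled 1000 times per section by gamma
normalization. Weighted counts are summed across replicates and rounded
before the update (the count scale fed to the model is a package choice;
sums preserve total evidence). The scaffold discretizes the bulb surface
into one slab of 100 µm voxels per section along each axis and keeps the
shell — voxels within half a voxel of an ellipsoid surface spanning the
grid (an analytic stand-in for an imaging-derived surface; an ASCII
PLY/OBJ vertex cloud can be imported instead), one voxel (100 µm) thick by
default, split into hemispheres by the ML midplane with an optional tilt.
Per posterior draw, a voxel's composition is the renormalized average of
its three intersecting sections' compositions, each weighted by the
inverse of its shell voxel count so a section's signal is conserved when
spread over its voxels; the per-voxel, per-receptor median over draws is
the posterior field.

### Assigning mirror-symmetric pairs

Averaging three 1D series creates two artifacts the assignment must beat.
First, "tubes": a voxel matching two of a receptor's three true slab
coordinates carries about two-thirds of the full signal. Second, "ghosts":
for a mirror pair, the voxel combining the lateral AP slab with the medial
ML slab is in expectation exactly as bright as the true medial corner, so
no ranking of voxel brightness alone can resolve a pair. The sectioning
geometry does: the medial glomerulus is posterior, so the receptor's AP
composition profile is bimodal with the anterior mode belonging to the
lateral glomerulus and the posterior mode to the medial one.

The scan therefore works on per-axis profiles (per-section posterior
median compositions scaled by the section's OMP share, which restores an
absolute-mass scale and silences empty sections). Profiles are smoothed
with a (1,2,1)/4 kernel because replicate jitter splits a mode's mass
across neighboring sections; a secondary AP mode counts when the profile
reaches 30 % of the main peak at least two sections away (well above any
within-animal smear tail); the ML profile contributes one mode per
hemisphere; each coordinate is refined by the expression-weighted mean in
a ±2-section window clipped at the AP inter-mode midpoint, the DV
coordinate comes from the merged DV mean position; and each target is
mapped to the nearest shell voxel of its hemisphere, the medial pick
constrained not to lie anterior to the lateral one and required to reach
20 % of the lateral corner score (the minimum of the three axis
compositions at the voxel's slabs) so single-glomerulus receptors are not
forced into pairs. All ties break deterministically toward smaller AP,
then DV, then ML. Assignments are reported with their cluster — the
26-connected component of voxels above the receptor's 99th-percentile
median threshold containing the pick — and a receptor passes the
expression filter when the cluster peak median reaches `tau = 5e-4`.

We first implemented a literal ranking of connected components by peak
median; on synthetic data at the study's noise level it recovered only
about half the planted positions because of the tube and ghost
degeneracies above, which motivated the mode-anchored scan. The component
machinery remains for cluster reporting and the filter.

### Evaluation

`evaluate_assignments()` measures, per reference receptor, the minimum
pairwise 3D distance between assigned-cluster voxels and a reference voxel
region (0 on overlap), against a baseline of 50 receptors drawn without
replacement from the same DV zone and side; `replicate_variance()`
compares best voxels between models fitted on disjoint replicate subsets.

## Sequence–position analyses

Percent identity uses global affine-gap alignment (BLOSUM62, open 11,
extend 1) with identity pinned to matches over the full alignment length
(gap columns included; alternatives selectable), validated in the suite
against an independent exhaustive Gotoh aligner. Pairwise identity is
related to per-axis position distance within strata at the 40/60/80 %
family/subfamily cutoffs by Mann-Whitney tests. The residue association
test asks, per alignment column, whether a query set (e.g. the most
anterior 20–35 % of ventral Class II receptors, quantile cut configurable)
is more physicochemically conserved than chance: the statistic is the mean
pairwise Grantham distance among query residues; the null re-samples
subsets of half the query size from the background (query members
included — sampling from the superset is conservative because the larger
observed set has the smaller variance); the p-value is lower-tailed with
the +1 correction, BH-adjusted across retained columns (gap fraction
≤ 10 %). Grantham distances are served from the published integer table;
a round-trip unit test confirms the formula (α = 1.833, β = 0.1018,
γ = 0.000399, ρ = 50.723) reproduces the printed values within rounding
except for three entries that deviate in the original printing (N–E, D–W,
and the 215 table maximum W–C vs 214.4 by formula). Position regression
uses 1000 gradient-boosted trees on per-gapless-column
composition/polarity/volume features with a position-stratified 90/10
split and optional 10-fold cross-validated tuning; the reported metrics
are holdout R² and RMSE. The "90/10" split is implemented as train/test.

## What the generator emulates

`simulation_config()` defaults encode the study conditions: 100 receptors,
23/22/22 sections of 100 µm, 5 × 10⁴ reads per section, log-normal
abundances (geometric SD 2) so the `tau` filter has realistic casualties,
spherical glomeruli of 60 µm radius placed on the scaffold shell with DV
position monotone in the receptor's epithelial zone index, a 300 µm
posterior offset of the medial mirror partner (applied exactly by
re-solving the ML coordinate on the surface at the shifted AP), 10 %
single-glomerulus receptors, and between-animal jitter of SD 100 µm —
inside the 75–270 µm range reported for glomerular positional variability.
Six AP and three DV/ML replicate animals mirror the study's design. Two
parameters are the package's own calls where no value is stated: the
within-animal spread of one receptor's signal across neighboring sections
(SD 60 µm, matching the glomerular radius — a 0 µm point mass is
physically wrong and makes the median merge fragile) and a relative
ambient noise floor of 10⁻⁴ so that per-section multinomial totals are
defined even in slabs without glomerular mass. The OMP row is proportional
to the glomerular volume per slab. Planted signal columns in the synthetic
alignment draw residues near a target that walks along the first principal
coordinate of the Grantham matrix with AP rank (a path along which
neighboring residues are physicochemically similar; a polarity-ordered
path fails because polarity neighbors like Trp/Cys are Grantham-distant);
`effect = 0` recovers the exchangeable null exactly.

What the generator does not emulate: capture-probe efficiency, library
chemistry, read-level errors, non-orthogonal section planes beyond the
optional symmetry tilt, and biological correlation between sequence
similarity and position (sequences are planted independently of the map
except through the configured signal columns). Passing recovery tests
therefore demonstrates that the inference machinery is correct and
well-calibrated under the stated geometry and noise — not that real tissue
meets those assumptions.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at 100 receptors, 23/22/22
sections and 1000 posterior draws (about a minute), permutation tests at
1000 permutations over 25-column alignments (50 null and 20 signal
repetitions), regression checks at 100–200 receptors with 200–300 trees,
and oracle comparisons on 100 random ≤ 12-residue sequence pairs. Posterior
sampling, jitter, placement and permutation draws all derive from one
master seed through fixed stream offsets, so every stage — including the
command-line driver — is byte-reproducible. Degenerate inputs are handled
explicitly: empty-OMP vectors are fatal, zero-OMP sections are flagged and
zero-weighted, flat receptor rows are zeroed and recorded, receptors with
no posterior support are returned unassigned rather than dropped.

## Known limitations

Accuracy is voxel-limited (100 µm) and, with three replicates per axis,
jitter-limited at about 60 µm per axis even for an ideal estimator; pairs
whose true AP separation falls below two sections collapse to a single AP
mode and are assigned at or near the same AP slab. The ghost resolution
assumes the anterolateral/posteromedial arrangement; a receptor violating
it would be assigned its mirror image. The ellipsoid scaffold is a
geometric idealization of the bulb; the mesh-import path exists for higher
fidelity surfaces.
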