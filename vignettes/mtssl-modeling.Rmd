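---
title: "Modeling the MTSSL spin label: rotamers, ensembles, and distance distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the MTSSL spin label: rotamers, ensembles, and distance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsslr)
```

## The problem

Pulsed EPR (DEER) measures the distribution of distances between the
unpaired electrons of two nitroxide spin labels attached to a protein. For
the standard MTSSL label the electron sits at the midpoint of the N–O bond,
five rotatable bonds away from the backbone. Interpreting a measured
distribution therefore requires a model of where the label's nitroxide can
be relative to the backbone: a discrete rotamer library for sampling, an
environment-aware weighting of the rotamers at a given site, and summary
machinery for the resulting inter-label distance distributions. This
vignette records the models implemented here, their assumptions, the
parameters that matter, and the numerical choices made where the design was
genuinely open.

## Side-chain topology and geometry

The side chain is represented as an atom tree built by sequential
internal-coordinate placement (the NeRF construction): each atom is placed
from three previously placed atoms by a bond length, a bond angle, and a
torsion. The linker runs Cβ–Sγ–Sδ–Cε–C3 into the 3-pyrroline ring
(C3=C4–C5–N1–C2, nitroxide N1–O1, gem-dimethyls on C2 and C5). The five
torsions are

* χ1 = N–Cα–Cβ–Sγ (the backbone nitrogen anchors the first torsion),
* χ2 = Cα–Cβ–Sγ–Sδ,
* χ3 = Cβ–Sγ–Sδ–Cε (about the disulfide bond),
* χ4 = Sγ–Sδ–Cε–C3,
* χ5 = Sδ–Cε–C3–C4, with C4 the doubly bonded ring carbon.

All torsions follow the IUPAC sign convention (verified against `bio3d`)
and live on the canonical domain [−180°, 180°), with +180° mapping to
−180° so that every angle has one representative. Collinearity in any
frame is treated as a degenerate input and rejected (cross-product norm
below 1e-10 Å²).

Bond lengths start from standard values (Cβ–Sγ 1.81 Å, Sγ–Sδ 2.04 Å,
Sδ–Cε 1.81 Å, planar 3-pyrroline ring bonds with the C3=C4 double bond at
1.33 Å) and are then rescaled once by a single uniform factor so that the
fully extended (all-trans) conformer places the N–O midpoint exactly 8.5 Å
from Cβ — the tether length the implicit cone model is built on. Because
the scaling is uniform and angles are untouched, the calibration is exact,
not fitted. The ring is closed through ideal planar internal coordinates;
the residual closure error at the unbuilt N1–C2 bond is a few hundredths of
an Ångström and has no effect on the electron position or clash geometry.

## The rotamer library

Candidate rotamers are the Cartesian product of the correlated χ
preferences: five (χ1, χ2) classes — mm, mt, tp, tm, tt in the m/p/t
nomenclature with canonical values m = −60°, p = +60°, t = 180° — two χ3
states (±90°), and six correlated (χ4, χ5) pairs: (180°, ±77°),
(−75°, −8°), (−75°, +100°), (+75°, +8°), (+75°, −100°). That enumerates
5 × 2 × 3 × 2 = 60 candidates.

Internal clashes are detected with a hard-sphere criterion: a non-bonded
atom pair clashes when its distance falls below `scale × (r_i + r_j)` with
element vdW radii C 1.70, N 1.55, O 1.52, S 1.80 Å. Three choices needed
to be made here, and each is a deliberate design decision:

1. **Pair exclusions.** Pairs at bond-graph distance 1–2, 1–3 *and* 1–4
   are excluded. At ideal geometry several 1–4 contacts (e.g. ring methyl
   to the doubly bonded ring carbon) sit permanently below the vdW sum
   regardless of any torsion, so including them makes the criterion blind
   to conformation; excluding 1–4 contacts is also the common convention in
   molecular mechanics exclusion lists.
2. **Clash context.** The criterion sees the side chain plus its anchoring
   N, Cα, Cβ. The carbonyl C/O are omitted because their position relative
   to the side chain depends on ψ, which is a property of the backbone
   conformation, not of the rotamer.
3. **Scale calibration.** The scale factor is deliberately above 1
   (default 1.10): it acts as a strain detector that flags conformations
   with contacts modestly inside the vdW sum for rescue, rather than
   marking only hard overlaps. It was calibrated once against the
   enumerated candidates so that exactly six candidates are irrecoverable,
   and then frozen. On this geometry the six deepest clashers are well
   separated: their tightest contact ratio (distance over vdW sum) is at
   most 0.73 while every other candidate stays above 0.99, and any scale in
   (1.07, 1.14) selects the same six. Two candidates each fall from the
   mm, tp and tm classes, so all five (χ1, χ2) classes survive.

**Rescue minimization** relieves a flagged clash by searching perturbations
of the distal torsions χ4 and χ5 on a 5° grid, bounded at ±30° per angle
and ordered by increasing perturbation size; the first clash-free point
wins, and a spec already clash-free is returned unchanged. χ1–χ3 stay
fixed during rescue because they define the rotamer's class bin — a rescue
that moved them by up to 30° could migrate one library entry into another
bin and defeat the purpose of a discrete library. Candidates with no
clash-free point in the distal box are dropped. The result — 60 enumerated,
30 flagged at the calibrated scale, 24 rescued, 6 removed, 54 kept — ships
as `inst/extdata/mtssl_rotamer_library.json` with full provenance metadata,
and `build_library()` regenerates it from scratch.

Each library entry carries per-χ standard deviations (15° for χ1/χ2, 10°
elsewhere) used by off-rotamer sampling. These are order-of-magnitude
rotamer widths, overridable through the library file; the library format is
versioned JSON with a topology hash so a library cannot silently be paired
with a different atom tree.

## Site labeling

`attach_rotamer()` builds the side chain off a site's N/Cα/Cβ frame with
mutation semantics: the native side chain beyond Cβ is ignored, and glycine
receives an ideal Cβ (the same construction is validated against real
structures to ~0.1–0.25 Å). `sample_site_ensemble()` evaluates, per library
rotamer, the base conformer plus the eight (χ1, χ2) ± 1 SD variants and
optionally `n_perturb` random off-rotamer draws from a seeded RNG.

Conformers are scored against the rigid protein with a smooth, purely
repulsive soft-sphere energy: the sum over label-atom × protein-atom pairs
of `max(0, scale·(r_i + r_j) − d)²` (the labeled residue itself is
excluded). Conformers above `clash_cutoff` (default 5, in Å² units of
squared overlap) are discarded; survivors get Boltzmann weights
∝ exp(−E/kT) with kT = 1 by default. The defaults were chosen so that a
fully exposed helical site retains conformers from several (χ1, χ2)
classes while a tightly caged site retains none; an optional
`top_fraction` truncation (e.g. 0.1) mimics keeping only the best-scored
tenth of models before weighting. An ensemble in which nothing survives is
returned as an explicit empty value carrying the reason ("occluded site"),
not an error.

Two fidelity gaps versus full-scale structure refinement are intentional
and should be kept in mind: the backbone is rigid and neighboring side
chains are fixed, so mutual accommodation between the label and its
environment is not modeled; and there is no attractive or electrostatic
term, so surface interactions of the nitroxide are invisible to the
weighting. Both limit realism mostly at surface sites.

## Distance distributions and comparison statistics

For two site ensembles the inter-label distribution is formed over all
conformer pairs, each weighted by the product of conformer weights, on a
0–100 Å grid at 0.5 Å bin width (covering the practical DEER range; both
are parameters). μ and σ are computed from the *unbinned* weighted
distances so they carry no binning bias; a `paired` mode treats two
parallel model sets index-by-index instead of as a cross product, and a
`use_cb` flag substitutes Cβ positions for N–O midpoints to reproduce the
crude backbone-only approximation. Experimental distributions reported
only as (μ, σ) are represented as discretized Gaussians; σ = 0 yields a
delta at the nearest bin.

Model–experiment agreement is summarized by MAE, RMSD and Pearson R
(MAE ≤ RMSD always; R requires at least two pairs and nonzero variance,
otherwise an error — it is never silently NA). Measurements whose σ
exceeds half their μ are flagged "exclude" by the breadth rule: such
distributions likely extend beyond the usable measurement range.

## Fitting sub-ensembles to a measured distribution

Agreement between binned distributions is measured by the cumulative
Euclidean distance: `D_E = sqrt( Σ_u [Σ_{i≤u} (p_i − q_i)]² )`, i.e. the
Euclidean norm of the difference between running sums, normalized by the
number of bins N. On N bins the normalized value lies in [0, 1].

`fit_ensemble_mc()` selects a subset of candidate models (each contributing
its distance as a delta distribution, pooled with equal weight) by greedy
Monte-Carlo: propose adding a random non-member or removing a random
member, accept only strict improvements, reject ties. The start set is
empty, so the first move is necessarily an addition. A pass stops after
1,000 consecutive rejections; because a greedy pass can stall in a local
optimum, the search then restarts from the start set with a fresh proposal
stream until the proposal budget (`max_iter`, default 10,000) is spent, and
the best pass is returned. Equal pooling (rather than clash-weighted
members) matches the intended use: the candidates are alternative whole
models, not weighted conformers.

## χ-angle recovery scoring

Model conformations are scored against reference χ tables hierarchically:
a model matches a reference to depth d when χ1…χd all lie within ±30°
(circular, boundary inclusive) of that single reference; unresolved
reference angles (NA) terminate the usable depth of that reference, and a
model is correct at depth d if it matches *any* reference to that depth.
Percentages over a model set are therefore non-increasing with depth by
construction. The m/p/t classification assigns the nearest canonical value
(m = −60°, p = +60°, t = 180°) within a ±30° window, otherwise "outlier".
Models with unresolved angles are rejected — a built conformer always
resolves all five torsions, so an NA there indicates an input error.

## The implicit cone model

An explicit ensemble at a site is summarized by the effective spin-label
position SL_ef (unweighted mean of the N–O midpoints; a weighted variant is
available but the default matches the convention of averaging plain model
sets), the distance d = |Cβ → SL_ef|, the tilt angle ∠Cα–Cβ–SL_ef, and the
cone opening angle, defined as the maximum pairwise angle between conformer
midpoints seen from Cβ. The trigonometric identity connecting the tether
length L and the opening ω, d = L·cos(ω/2), reproduces the canonical
d ≈ 6 Å at L = 8.5 Å and ω = 90°.

The D_SL − D_Cβ difference simulator draws synthetic residue pairs: Cβ
separations uniform on 10–60 Å and, for each label, an isotropic random
direction for SL_ef at distance d from its Cβ. The fully random orientation
is the model's own assumption; how the original cones were oriented
relative to the inter-residue axis is not constrained by anything this
package models, so the maximally agnostic choice is used. The triangle
inequality bounds every difference by 2d, and the simulator asserts this on
every draw. Hα, needed for the backbone superposition atom set when
bringing external model sets into a common frame, is synthesized from ideal
geometry when absent.

This synthetic site-pair sampler is a distributional stand-in for
collecting residue pairs from a large survey of real structures: it
reproduces the geometry of the difference statistic but not the abundance
profile of real Cβ separations or any backbone-conditioned orientation
bias.

## Synthetic fixtures: what they do and do not show

The fixture generators supply the geometric situations the method assumes:
`make_ideal_helix()` builds mathematically ideal backbones from constant
φ/ψ (defaults −57°/−47°; measured torsions reproduce the inputs exactly
and the α-helical rise per residue comes out at ~1.5 Å),
`make_two_helix_pair()` places two parallel copies at an exact inter-axis
separation, `make_occluding_cage()` surrounds a site with a Fibonacci
shell of dummy atoms to create a fully occluded pocket, and
`make_synthetic_distribution()` mixes discretized Gaussians into uni- or
multi-modal "experimental" distributions.

Tests passing on these fixtures demonstrate the internal consistency of
the machinery — exact geometry, correct weighting and normalization,
correct selection behavior — on inputs whose ground truth is known by
construction. They do not demonstrate accuracy on real proteins: ideal
helices have no tertiary environment, the cage is an artificial hard
boundary, and Gaussian mixtures lack the noise and background-correction
artifacts of real regularized DEER data.

## Numerical choices and limitations

* Angle domain [−180°, 180°); the 180° boundary maps to −180°.
* Degeneracy tolerance for collinearity: 1e-10 Å² on cross-product norms.
* Internal-coordinate round trips hold to 1e-6 (degrees/Å); Kabsch
  superposition is exact to 1e-9 on rigid motions, with the SVD
  determinant correction so reflections are never returned.
* Distribution vectors are renormalized on construction and sum to 1
  within 1e-9; distances outside the binning range land in the closest end
  bin rather than being dropped.
* Monte-Carlo fitting is deterministic given `seed`; ties are rejected, so
  the accepted-move trace is strictly decreasing within a pass.
* Problem sizes used in the shipped test-suite (helices of 12–20 residues,
  ensembles of a few hundred conformers, 8–20 fitting candidates, a few
  thousand simulator draws) were chosen as the smallest sizes at which the
  properties under test are meaningful.
* The labeling model keeps the backbone and all other side chains rigid,
  has no attractive/electrostatic terms, and weights conformers by a
  single-site Boltzmann factor on clash energy — a construction of this
  package, since whole-structure refinement assigns no per-conformer
  weights at a site. Predictions at surface sites are correspondingly
  more uncertain than at sterically constrained sites.
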