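# mtsslr

Rotamer-based modeling of the MTSSL nitroxide spin label for DEER/EPR
distance analysis in R.

Double electron–electron resonance (DEER) measures nanometer distances
between unpaired electrons of nitroxide spin labels attached to a protein
by site-directed spin labeling. The most common label, MTSSL, has five
rotatable bonds (χ1–χ5) between the backbone Cα and the unpaired electron
at the midpoint of the nitroxide N–O bond, so the electron's position
relative to the backbone is unknown a priori — on an exposed site the label
samples a whole ensemble of conformations and the experiment returns a
broad distance distribution. `mtsslr` provides the modeling machinery
needed to bridge between backbone coordinates and measured distances:

* **Geometry core** — torsion measurement and internal-coordinate (NeRF)
  atom placement under the IUPAC sign convention, and Kabsch superposition.
* **Rotamer library** — the MTSSL side-chain topology with its correlated
  χ-angle preferences: five (χ1, χ2) classes (mm, mt, tp, tm, tt in the
  m/p/t nomenclature, m = −60°, p = +60°, t = 180°), χ3 = ±90°, and six
  correlated (χ4, χ5) pairs, enumerating 5 × 2 × 3 × 2 = 60 candidates. A
  calibrated hard-sphere filter with rescue minimization (≤ 30° per χ)
  removes internally clashing conformations, leaving the canonical
  54-rotamer library shipped in `inst/extdata/`.
* **Site labeling** — attaches rotamers to any residue of a PDB structure
  (mutation semantics; glycine gets an ideal Cβ), scores each conformer
  against the rigid environment with a soft-sphere repulsion, and returns a
  Boltzmann-weighted conformer ensemble per site.
* **Distance distributions** — inter-label distributions from two site
  ensembles (weighted over all conformer pairs), summarized as μ/σ from the
  unbinned distances, plus MAE / RMSD / Pearson R comparison statistics and
  the breadth exclusion rule (exclude when σ > 0.5 μ).
* **Ensemble fitting** — greedy Monte-Carlo selection (only favorable
  moves, with restarts) of a model sub-ensemble whose pooled distribution
  matches an experimental one, scored by the normalized cumulative
  Euclidean distance D_E/N between the binned distributions.
* **χ recovery** — hierarchical ±30° scoring of model conformations
  against reference (crystallographic) χ tables: an angle counts only if
  all preceding angles match the same reference.
* **Cone model** — derives the implicit-model parameters (d = |Cβ→SL_ef|,
  tilt = ∠Cα–Cβ–SL_ef, cone opening angle) from explicit ensembles, checks
  the trigonometric identity d = L·cos(ω/2) (8.5 Å · cos 45° ≈ 6 Å), and
  simulates D_SL − D_Cβ difference histograms.
* **Fixtures** — ideal poly-alanine helices, parallel helix pairs,
  occluding cages and synthetic multi-modal distance distributions, so
  every workflow runs without external data.

## Worked example

Label two facing sites on a pair of parallel ideal helices 25 Å apart and
predict their inter-label distance distribution:

```r
library(mtsslr)

lib <- mtssl_library()
lib
#> MTSSL rotamer library: 54 rotamers
#>   enumerated 60, 30 clashing, 24 rescued, 6 removed (scale 1.100)
#>   (chi1,chi2) classes: mm=10 mt=12 tm=10 tp=10 tt=12

pair <- make_two_helix_pair(separation = 25, n_residues = 20)
e1 <- sample_site_ensemble(pair, site_spec("A", 10), lib, seed = 1)
e2 <- sample_site_ensemble(pair, site_spec("B", 10), lib, seed = 2)
e1
#> MTSSL label ensemble at A:10: 402 conformer(s)
#>   clash energy range 0-4.68, seed 1

pair_distribution(e1, e2)
#> Distance distribution: 200 bins (0.25-99.75 A), mu = 26.36 A, sigma = 3.60 A

pair_distribution(e1, e2, use_cb = TRUE)   # crude Cbeta-only approximation
#> Distance distribution: 200 bins (0.25-99.75 A), mu = 25.00 A, sigma = 0.00 A
```

The labels project outward from the two helices, so the mean label–label
distance (26.4 Å) exceeds the Cβ–Cβ distance and, unlike the Cβ
approximation, carries a width (σ = 3.6 Å) reflecting the conformational
ensemble of both labels. Summarizing the first site's ensemble with the
implicit cone model:

```r
derive_cone_parameters(e1)
#> Implicit spin-label cone parameters
#>   d (CB -> SL_ef): 4.22 A
#>   tilt (CA-CB-SL_ef): 134.4 deg
#>   opening angle: 179.0 deg (tether 8.5 A)
```

On a bare, fully exposed helix the label sweeps almost the full hemisphere
(opening ≈ 180°), pulling the effective position to 4.2 Å from Cβ; real
protein surfaces restrict the cone and lengthen d toward the canonical
6 Å. Fitting a sub-ensemble of candidate models to a bimodal synthetic
"experimental" distribution:

```r
experiment <- make_synthetic_distribution(list(c(24, 2, 0.7), c(32, 2, 0.3)))
set.seed(3)
candidates <- round(runif(20, 18, 40), 1)   # one distance per model
fit <- fit_ensemble_mc(candidates, experiment, seed = 4)
summary(fit)
#> Monte-Carlo sub-ensemble fit
#>   selected members (9): 1, 3, 4, 7, 8, 10, 12, 18, 20
#>   final objective D_E/N: 0.00130926
#>   accepted moves: 15 of 10000 proposals
#>   fitted distribution: mu = 26.31 A, sigma = 4.05 A
```

The selected 9-member sub-ensemble reproduces the target mean (26.3 Å vs
the mixture mean 26.4 Å) with a normalized cumulative Euclidean distance of
about 0.0013 — close agreement on the 200-bin grid.

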