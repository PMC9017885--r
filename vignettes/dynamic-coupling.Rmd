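---
title: "Dynamic flexibility and coupling analysis with prsdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flexibility and coupling analysis with prsdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsdyn)
```

## The model

`prsdyn` analyses how mechanical perturbations propagate through a folded
protein. The protein is coarse-grained to one node per residue (the C-alpha
atom), and the nodes are connected by harmonic springs — an elastic network
model (ENM). Within linear response, a force **F** applied to the network
produces displacements

\[ \Delta R = H^{-1} F, \]

where \(H\) is the \(3N \times 3N\) network Hessian. Because rigid-body
translation and rotation cost no energy, \(H\) is singular with a
six-dimensional null space; `pseudo_inverse()` eigendecomposes \(H\),
discards the (expected six) near-null modes, and reconstructs the inverse
from the remaining spectrum. Any symmetric positive-semidefinite
\(3N \times 3N\) matrix can take the place of \(H^{-1}\): in particular the
positional covariance of a molecular-dynamics ensemble, which carries
anharmonicity, solvation and sequence specificity that the bare network
lacks. `windowed_covariance()` and `average_covariance()` turn an aligned
trajectory into that replacement.

**Perturbation response scanning (PRS)** pushes on each residue in turn with
unit forces along a fixed set of directions and records how every other
residue moves. The result is an \(N \times N\) response matrix \(A\), from
which two per-residue indices are derived:

- **DFI** (dynamic flexibility index): residue \(i\)'s total response to
  perturbations everywhere, normalised by the whole protein's total
  response; the profile sums to 1. Low-DFI residues are hinges — rigid
  positions that transmit rather than absorb perturbations.
- **DCI** (dynamic coupling index): residue \(i\)'s mean response to
  perturbations at a designated functional-site set (e.g. catalytic
  residues), relative to its mean response to perturbations anywhere.
  Values above 1 mark preferential coupling to the functional sites.

Both are reported as percentile ranks (%DFI, %DCI) within the protein:
\(\mathrm{rank}_i = |\{k : v_k \le v_i\}|/N\), with ties sharing the upper
count so the maximum rank is exactly 1.

A **DARC site** (dynamic allosteric residue coupling site) is a residue
farther than 10 Å from every functional residue yet with %DCI above 0.60 —
coupled without contact. **DCI asymmetry**,
\(\mathrm{DCI}_{ij} - \mathrm{DCI}_{ji}\), gives the coupling a direction:
a positive value means the perturbed partner dominates the communication.
Mutational effects are summarised by relative profile changes
\((\mathrm{DFI}^{mut} - \mathrm{DFI}^{wt})/\mathrm{DFI}^{wt}\)
(`delta_profile()`).

```{r example}
chain <- make_structure("random_compact", n = 60, seed = 11)
fit <- prs(chain, functional = functional_sites(c(15, 45)))
fit
head(as.data.frame(fit), 3)
```

## Parameters that matter

- **Spring law** (`spring_model()`): the default is the parameter-free
  distance-dependent form \(\gamma(d) = \gamma_0 / d^2\); a uniform spring
  with a 10 Å cutoff (the classic anisotropic network) is available. The
  flexibility and coupling indices are ratios, so the overall stiffness
  \(\gamma_0\) cancels exactly (this is asserted in the tests), and their
  percentile ranks are only moderately sensitive to the functional form.
- **Response magnitude**: the package reports the mean-square displacement
  per perturbed residue, averaged isotropically over force directions. The
  default direction set — the 10 antipodally-unique vertices of a regular
  dodecahedron — is a spherical 5-design, so for the mean-square response
  (a quadratic in the force direction) the 10-direction average equals the
  exact isotropic average to machine precision; the closed form is
  \(\mathrm{tr}(B^\top B)/3\) for each \(3\times3\) response block \(B\).
  A mean displacement-norm variant is available (`magnitude = "norm"`);
  for it the same quadrature is accurate to a few percent, since the norm
  is not polynomial in the direction. Random direction sampling
  (`scheme = "seeded_random"`) mimics stochastic Brownian kicks and is
  seeded for reproducibility.
- **DARC thresholds**: %DCI > 0.60 and distance > 10 Å, both strict, both
  configurable. The distance is C-alpha to C-alpha, consistent with the
  node model; an all-atom minimum distance would classify a handful of
  borderline residues differently.
- **Windowing** (`windowed_covariance()`): windows start at multiples of
  `window_length - overlap` and each uses its own window-local mean, so
  slow drifts between windows do not inflate the covariance. Averaging the
  per-window covariances before PRS is the default route; profiles from
  1.5x-longer windows agree (Spearman rho ~ 1 in the shipped checks),
  which is the practical test that the ensemble is equilibrated.
- **Superposition** (`superpose_frames()`): Kabsch alignment onto an
  iteratively refined mean structure (two refinement passes). Alignment is
  a linearisation: it cleanly separates rigid-body from internal motion
  only while fluctuations are small compared to the structure. The
  synthetic ensembles used in the checks are therefore scaled to a
  root-mean-square fluctuation of ~0.5 Å per coordinate — a typical folded
  protein's thermal amplitude; at several Å the decomposition itself
  becomes ill-defined and part of the internal motion is absorbed into the
  fitted rotations.

## Clustering variant flexibility profiles

Variant-by-site %DFI matrices (rows = protein variants, columns = typically
the DARC sites) are factorised by SVD; each variant is represented by its
scores on the top \(r = 3\) singular pairs (`reduced_representation()`),
and score-space Euclidean distances feed average-linkage (UPGMA)
hierarchical clustering. At full rank the score distances equal the raw
profile distances exactly; truncation can only shrink them. Component signs
are canonicalised (largest-magnitude loading positive) so scores do not
depend on the linear-algebra backend. The profile matrix is factorised
as-is — no column centering — because the percentile profiles share a
common scale; a `center` flag provides classical PCA for users who want it.

## The pathogenicity classifier

Four dynamics features summarise a variant site: its DFI, the %DCI of the
functional residues given the site (how strongly the active site listens to
the site), the site-functional coupling asymmetry, and the mean DFI within
7 Å of the site (the radius of direct interaction; the neighbourhood always
contains the site itself, so the average is never over an empty set). A
feed-forward network — two hidden layers of 80 rectified-linear units with
50% dropout, sigmoid output, cross-entropy loss, gradient descent with
momentum 0.9 at learning rate 0.001 for 1000 epochs — maps the features to
a disease probability. Hidden weights initialise uniformly on
\(\pm 1/\sqrt{\mathrm{fan~in}}\), the output layer Xavier-uniform; dropout
acts only during training, with activations rescaled by the keep
probability at prediction time. Evaluation uses repeated plain-random 90/10
splits (`cross_validate()`), reporting accuracy, precision, recall and
trapezoidal ROC AUC per split. Features are used raw by default — three of
the four are already ratio or percentile quantities — with an optional
z-scoring flag; on synthetic cohorts whose raw features span three orders
of magnitude, standardisation mainly improves probability calibration, not
ranking.

## What the synthetic generators emulate — and what they do not

`make_structure()` produces deterministic toy geometries (tetrahedron,
collinear and zigzag chains, an ideal helix) and a seeded compact
self-avoiding coil with 3.8 Å steps. `make_gaussian_ensemble()` draws
frames from a prescribed covariance, excluding rigid-body directions.
`make_variant_cohort()` samples variant sites and plants disease labels
with probability
\(s\,\sigma(a(\%\mathrm{DCI} - 0.6)) + (1 - s)/2\)
(steepness \(a = 20\) by default — strong but not degenerate enrichment;
\(s\) is the signal strength), reproducing at desk scale the enrichment of
pathogenic variants at sites highly coupled to the active site.

These fixtures validate the mathematics — normalisation, symmetry,
antisymmetry, spectral identities, recovery of planted structure — not the
biology. Real proteins have secondary structure, side-chain packing,
anharmonic and multi-basin dynamics, and disease labels shaped by far more
than coupling geometry; passing these checks says the machinery is
implemented correctly, not that its predictions transfer to any particular
protein.

## Numerical choices and problem sizes

- Dense symmetric eigendecomposition throughout (structures of interest
  are at most ~1000 residues; determinism is worth more than sparse
  speed). Null modes are those below `1e-10` of the largest eigenvalue; a
  count other than six triggers a warning rather than an error, since
  planar or collinear geometries legitimately have larger null spaces.
- Percentile ranks compare values after rounding to 12 significant
  digits, so ties forced by symmetric geometry survive floating-point
  round-off.
- The shipped convergence demonstration uses a 20-residue compact coil,
  a 20,000-frame Gaussian ensemble, and 2000-frame windows with 50%
  overlap — large enough that the averaged windowed covariance reproduces
  the generator's %DFI profile (Spearman rho > 0.95), small enough to run
  in seconds.
- Cross-validation checks pool ~330 variants from three 120-residue
  synthetic proteins; the chance-level (shuffled-label) check averages
  over three independent shuffles of ten splits each, pinning the
  Monte-Carlo mean AUC to within ~0.02 of its expectation.

## Known limitations

- The ENM spring law is a modelling choice; absolute DFI/DCI values are
  not comparable across spring models, only their percentile profiles are.
- MD-derived covariances are accepted as supplied; the package does not
  judge whether the underlying trajectory was equilibrated (the
  window-robustness comparison is the user's tool for that).
- Mutant structures are not generated: comparisons (`run_compare()`)
  require the user to provide mutant coordinates or covariances.
- The classifier is a small fully-connected network; with only four
  features it is close to a smooth nonlinear logistic fit, and no
  calibration beyond the raw sigmoid output is attempted.
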