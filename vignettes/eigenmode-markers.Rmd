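---
title: "Distributed eigenmode markers of arousal: models, parameters, and design choices"
author: "eigenmarkers authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed eigenmode markers of arousal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenmarkers)
```

## The scientific problem

Loss and recovery of consciousness — under anaesthesia, and under deep brain
stimulation (DBS) of the central thalamus that can restore arousal despite
continued anaesthetic infusion — reorganise *distributed* patterns of cortical
activity, not just the activity of individual regions. This package computes
three complementary families of whole-cortex markers from parcellated
resting-state fMRI and a weighted structural connectome, and relates them to a
behavioural arousal score:

1. **Harmonic-mode energy** — how strongly activity loads on
   high-spatial-frequency eigenmodes of the structural connectome.
2. **Functional-gradient geometry** — the range, dispersion, and eigenvalue
   ratio of diffusion-map embedding components of functional connectivity
   (FC).
3. **Hierarchical integration and segregation** — how total FC covariance is
   distributed across the nested modular hierarchy implied by the sign
   structure of FC eigenvectors.

The empirical regularities these markers are designed to detect are:
anaesthesia *increases* harmonic energy (activity becomes more constrained by
anatomy), *contracts* the principal functional gradient (shallower processing
hierarchy), and *reduces* hierarchical integration; effective central-thalamic
stimulation reverses all three together with behavioural arousal.

## Models and their assumptions

### Harmonic mode decomposition

Given a symmetric, connected, non-negative structural connectome $C$ with
strength (degree) matrix $D$, the symmetric normalised graph Laplacian is

$$\Delta_G = D^{-1/2} (D - C)\, D^{-1/2},$$

whose eigenvectors $\varphi_k$ (eigenvalues $0 = \lambda_1 < \lambda_2 \le
\dots \le \lambda_N$) are the *harmonic modes*: whole-cortex spatial patterns
ordered by spatial frequency, from the uniform mode to fine-grained patterns.
Each BOLD timepoint $F_t$ is decomposed exactly as $F_t = \sum_k
\omega_k(t)\varphi_k$ with $\omega_k(t) = \langle F_t, \varphi_k\rangle$; the
*power* of mode $k$ is $|\omega_k(t)|$ and its *energy*
$\omega_k(t)^2\lambda_k^2$. The scan-level summary is the energy summed over
modes and averaged over timepoints. Assumptions: region order is shared
between the connectome and the runs (enforced by strict label matching); the
connectome is undirected (directed variants would need complex eigenmodes and
are out of scope); timepoints enter as-is after preprocessing, with no
per-timepoint renormalisation, so the decomposition and Parseval's identity
are exact.

Because $\lambda_1 = 0$, the uniform mode carries no energy; the summary is
zero exactly when activity is spatially uniform. The scan summary "sum over
modes, mean over timepoints" is a convention of this package: a per-mode
time-averaged profile (`mode_energy_profile()`) is also exported for
spectrum-shape analyses, so no information is lost by the scalar reduction.

### Functional gradients

FC is the Pearson correlation of regional time series. Off-diagonal entries
are Fisher z-transformed (|r| clipped at $1-10^{-7}$ so the transform stays
finite; the diagonal is excluded), each row keeps its $k =
\mathrm{round}(\mathrm{density}\cdot(N-1))$ largest signed entries (10%
density by default, i.e. 8 of 81 for an 82-region parcellation; ties broken
by lower column index), and the affinity between regions is the
normalised-angle similarity $1 - \arccos(\cos \theta)/\pi$ between their
thresholded rows — restoring symmetry after the asymmetric row threshold,
as the reference gradient toolboxes do. Diffusion map embedding
$\alpha$-normalises the affinity ($\alpha = 0.5$ balances local and global
geometry), forms the Markov matrix, and diagonalises it through its symmetric
conjugate. The trivial stationary component is dropped, and components are
scaled by $\lambda/(1-\lambda)$ (multiscale convention, diffusion time 0).

Markers: the **range** (max − min) of a gradient, the **dispersion** (sum of
squared distances to the centroid over the first three gradients), and the
**principal eigenvalue ratio** $\lambda_1/\sum_k \lambda_k$ over the retained
components. All three are invariant to sign flips, to region relabelling,
and (dispersion) to rotations of the 3-space, which is why no cross-scan
gradient alignment (e.g. Procrustes) is performed: the markers do not depend
on topographic correspondence, and omitting alignment avoids introducing a
step the analysis does not need.

### Hierarchical integration and segregation

FC is decomposed as $FC = U\Lambda U^\top$ with eigenvalues sorted
descending. The nested sign partition starts from one whole-cortex module
(the first eigenvector of a correlation-like FC has a single sign) and, at
each level $i \ge 2$, splits every existing module into its non-negative and
negative subsets under eigenvector $i$, dropping empty subsets. With module
counts $M_i$, sizes $m_j$, and the size-heterogeneity correction
$p_i = \sum_j |m_j - N/M_i|/N$:

$$H_{In} = \Lambda_1^2 M_1 (1 - p_1) / N^2 = \Lambda_1^2/N^2, \qquad
  H_{Se} = \sum_{i=2}^{N} \Lambda_i^2 M_i (1 - p_i) / N^2.$$

$H_{In}$ is 1 for an all-ones FC and $1/N^2$ in the uncorrelated limit
(closed form $\Lambda_1 = 1 + (N-1)r$ for equicorrelation). Numerical
choices: eigenvalues within $10^{-12}$ of zero are clamped before squaring;
exactly-zero eigenvector entries count as non-negative (a fixed, documented
tie-break); levels past the all-singleton partition still contribute their
$\Lambda_i^2 M_i/N^2$ terms, following the literal sum to $N$. When
consecutive eigenvalues are numerically degenerate the partition is
solver-dependent and a warning is emitted; tests use non-degenerate fixtures.

### Behavioural arousal and the brain–behaviour model

The arousal composite sums six criteria (exploration 0–2, spontaneous
movements 0–2, shaking/prodding 0–2, toe pinch 0–2, eye opening 0–2, corneal
reflex 0–1; total 0–11). Condition-level scores (awake 11, high-amplitude
centro-median DBS 9, low-amplitude CT and light sevoflurane 3, light
propofol 4, everything else 0) ship as a JSON resource.

Dominance analysis fits ordinary least squares on all $2^p - 1$ non-empty
predictor subsets and attributes to predictor $j$ the average (over subset
sizes, then over subsets within a size) incremental $R^2$ of adding $j$.
With the (default) unadjusted $R^2$ metric, total dominances sum *exactly*
to the full-model $R^2$, which is the property that justifies reading them
as a variance partition; an adjusted-$R^2$ mode is provided for comparison
but is only approximately additive, and a McFadden pseudo-$R^2$ logistic
mode covers the dichotomised-arousal classification variant (cutoffs 9 and
3 reproduce the study's two groupings). Model significance uses a one-sided
permutation test with the add-one correction $p = (1 + \#\{R^2_{null} \ge
R^2_{obs}\})/(1 + n_{perm})$. Markers are min-max normalised within each
dataset before pooling, dividing the min-subtracted values by their maximum
so each marker spans $[0,1]$ per dataset (the alternative reading — dividing
by the unshifted maximum — would not give a common scale, so the post-shift
maximum is used).

### Preprocessing

Temporal filtering is implemented as brick-wall masking of each region's
discrete Fourier transform — the simplest exactly-zero-phase realisation,
and idempotent by construction. Defaults: pass band 0.0025–0.05 Hz with a
notch at 0.03 Hz removing an artefactual pure frequency, the notch spanning
one bin either side of the nearest DFT bin (width configurable; no
principled width is available, so the minimal one is the default). Runs too
short to resolve the high-pass cutoff trigger a warning and lose only the DC
bin. Global-signal regression (per-region OLS on the per-timepoint spatial
mean plus intercept) is available behind a flag and defaults to *after*
filtering when both are requested; the order is configurable because no
single convention is universal, and GSR is off by default because not every
dataset in this design used it.

## The synthetic-data generator

Real macaque data of this kind are not redistributable, so the generator
produces datasets with exactly the statistical structure the markers assume —
no more. A modular weighted connectome (82 regions, 4 modules by default;
within-module weights ~1, between ~0.1, 30% multiplicative jitter) provides
the harmonic basis. Runs are drawn directly in harmonic coordinates:
$\omega_k(t) \sim \mathcal{N}(0, \sigma_k^2)$ i.i.d. over time, reconstructed
as $F_t = \sum_k \omega_k(t)\varphi_k$, plus isotropic Gaussian noise. Each
condition preset sets three $\sigma$ levels — the uniform global mode, the
low-frequency "modular" modes (2–8), and the remaining fine-grained modes —
plus a noise SD, with defaults of 500 timepoints at TR 1.25 s per run and
82 regions, matching the study's acquisition dimensions.

The preset constants (a versioned JSON resource, not hard-coded) are
calibrated so the generated conditions reproduce the qualitative directions
the markers target: relative to awake, deep anaesthesia has a weaker global
and modular signal and relatively more fine-grained (high-$\lambda$) mass,
which simultaneously raises scan energy (the $\lambda_k^2$ weighting makes
fine-grained mass expensive), lowers $\Lambda_1$ and hence $H_{In}$, and
flattens the FC similarity structure so the principal gradient contracts.
Intermediate conditions interpolate: high-amplitude CT stimulation sits near
awake, low-amplitude CT near light anaesthesia, and ventro-lateral
stimulation is indistinguishable from unstimulated anaesthesia — mirroring
the behavioural scores attached to each preset.

What the generator does **not** emulate: haemodynamics and autocorrelated
BOLD spectra (coefficients are white in time), inter-animal variability
(animal labels are cycled bookkeeping only), head motion and physiological
artefacts, scanner differences between datasets, and any topographic realism
of the modes. Passing the marker-direction suites therefore shows that the
pipeline *detects the covariance structure it is designed to detect*, not
that real anaesthesia data would show effects of this size.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; per-run seeds are
derived from the study seed and recorded in run sidecars, and regenerating a
study with the same seed reproduces byte-identical files. The test suite
exercises the full 82-region, 500-timepoint geometry where it matters (mode
counts, direction suites at 50 seed pairs, energy recovery at $T = 10^4$)
and smaller geometries (20–30 regions, 100–300 timepoints) for closed-form
and oracle comparisons, chosen as the smallest sizes at which the properties
under test are non-trivial. The acceptance script runs an 8-condition,
32-run synthetic study at full geometry in a few seconds on one CPU.

## Known limitations

* Eigenvectors within degenerate eigenvalue subspaces (structural or
  functional) are non-unique; aggregate energies are unaffected but
  individual mode patterns and the sign partition are solver-dependent
  there. The package warns rather than resolving the ambiguity.
* The eigenvalue-ratio marker uses the retained embedding eigenvalues
  (default 10), not all $N-1$; with strongly decaying spectra the
  difference is small, and the choice is configurable via `n_components`.
* Group-level inference (mixed-effects modelling of condition contrasts with
  animal as a random effect) is deliberately not reimplemented: the marker
  table is tidy and can be handed to `lme4::lmer()` or any equivalent
  routine directly.
* Directed connectomes, vertex-resolution harmonics, and gradient topography
  statistics are out of scope.
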