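---
title: "Scoring MEG source reconstruction in millimetres of anatomical distortion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring MEG source reconstruction in millimetres of anatomical distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megdistort)
```

## The idea

MEG source reconstruction is ill-posed: infinitely many cortical current
distributions explain any sensor recording, so every algorithm imposes prior
assumptions about where and how current flows. Because the primary currents
are anchored to the cortical sheet, the true anatomy offers an objective
yardstick: if the data really arise from current flow on the true cortex, a
good algorithm-plus-metric pair should prefer the true surface over
*plausible but wrong* surrogate surfaces. `megdistort` operationalizes this.
It builds a one-parameter family of surrogate cortices at controlled
distances (in mm) from the true one, reconstructs the same data onto each,
and reports where the fit metric peaks. The figure of merit — the
**distortion score** — is the mean, over trajectory seeds, of the distortion
at which the metric peaks: zero means the pipeline always picks the true
anatomy.

## Latent shape space and distortion trajectories

Surrogate anatomy is generated from a linear latent shape model: `K = 100`
per-vertex displacement fields over the mesh, playing the role of principal
modes of population shape variation, with latent coordinates in z-score
units. A **trajectory** perturbs every free component simultaneously. A
seeded fair coin fixes a sign `s_i` in {−1, +1} per component (components
1–7 are clamped to zero; see below), and step `j` of `N` applies the offset

    dz[i, j] = 2 Z (j − (N+1)/2) s_i / N,     j = 1..N

with defaults `N = 17`, `Z = 3`. The midpoint step is exactly zero — the
true surface — and steps mirror about it, so each trajectory contains
`(N−1)/2` pairs of distinct surfaces at equal millimetre distortion. With
these defaults the endpoints sit at |dz| = Z(N−1)/N ≈ 2.82 z-scores. (The
ladder formula is implemented exactly as stated; if one prefers endpoints at
exactly ±Z the denominator would need to be N−1 instead, and we deliberately
do not make that change.)

Because the signs are drawn independently per seed in a 93-dimensional
space, different trajectories are nearly orthogonal: the mean squared
correlation between the latent directions of eight seeded trajectories is
about 0.01 in the packaged fixture, so the benchmark probes many independent
directions of "wrongness" at each distortion level.

### The clamped size components

The first seven components are constructed as global affine fields — three
axis scalings, three symmetric shears, and a rigid translation toward the
sensor cap. They are exactly the deformations that would move sources closer
to (or farther from) the sensors without changing local anatomy, which is a
confound rather than a test of anatomical selectivity. The trajectory
machinery therefore clamps them to zero, and the package's property tests
verify that total mesh volume changes by less than 2% along a default
trajectory.

### What is synthetic here, and what that implies

Training a population shape model — principal displacement fields learned
from hundreds of MRIs by diffeomorphic registration — is out of scope for
this package; `synthesize_basis()` provides a **synthetic** basis instead: smoothed
Gaussian random displacement fields, orthonormalized by two passes of
modified Gram–Schmidt under the vertex-displacement inner product. Three
consequences matter when interpreting results:

* Deformation is **linear** in the latent code. `dz = 0` is an exact
  identity (the package exploits this: the true surface is simply the
  trajectory midpoint), offsets add exactly, and mirrored steps give exactly
  mirrored displacements. A diffeomorphic model would only approximate these
  properties, and its reconstruction of the true surface would carry a
  nonzero residual.
* The random fields are smooth (neighbour-averaging with a 15 mm length
  scale) but not brain-like: they do not respect sulcal topology or
  population covariance. Passing benchmarks here demonstrates the
  *machinery* discriminates anatomy; it does not certify performance on real
  cortical shape statistics.
* The basis carries one calibration constant, `global_scale`, fixed so that
  the endpoint of the basis's own default trajectory displaces vertices by
  **3.5 mm on average** — anchoring the distortion axis to a realistic
  scale for cortical shape variation. Distortion is always *measured* (mean
  per-vertex Euclidean distance between corresponding vertices), never
  inferred from the latent code, so the calibration only sets the range of
  the sweep, not the reported millimetres.

## Forward model

Dipoles sit at every mesh vertex, oriented along the outward area-weighted
surface normal, and the sensor array is a Fibonacci cap of radial
magnetometers. Gains use the closed-form field of a current dipole in a
spherically symmetric conductor (the Sarvas solution), which requires only a
volume centre: we use the vertex centroid of the *undistorted* mesh and hold
it fixed across a trajectory, so that sweeping distortion changes the source
model only. (Refitting the sphere per surrogate is a one-line change —
`fit_sphere()` on each deformed mesh — but mixes conductor error into the
anatomy comparison, so it is not the default.) Units are mm, nAm and fT
throughout; the classic silent-source property (radial dipoles produce no
external field) is verified to 1e-10 against an independently coded
implementation.

The null model row-permutes the gain matrix with a seeded uniform
permutation: the data and their statistics are untouched, but the
biophysical mapping from anatomy to sensors is destroyed, which defines
chance behaviour for every score.

## Inversion and free energy

All schemes share one linear Gaussian generative model: data = lead field ×
currents + noise, with zero-mean Gaussian currents and noise whose
covariances are weighted sums of fixed components,
`Sigma = sum_k exp(lambda_k) Q_k`. The log-scale weights are optimized by
Fisher scoring with Levenberg–Marquardt damping on the negative variational
free energy

    F = −Nt/2 log|Sigma| − Nt/2 tr(SigmaY Sigma^{-1}) − Nt Nc/2 log 2pi
        − (lambda − v)' Pi (lambda − v)/2 − log|Sigma_lambda Pi|/2.

The first three terms are exactly the Gaussian log likelihood of the time
samples (tested against a direct log-density sum to 1e-8); the last two
penalize hyperparameter complexity. The sign of the final (Occam) term is
implemented exactly as written above; some variational-Laplace treatments
write `+ log|Sigma_lambda Pi|/2`, and since `|Sigma_lambda Pi| <= 1` at an
optimum the difference is a small positive offset that is constant in
spirit across the model comparisons the benchmark makes.

Numerical choices that the equations do not determine:

* hyperparameters live on the log scale with Gaussian priors `v = 0`,
  `Pi = (1/256) I` — weak shrinkage that keeps unidentified components from
  drifting to infinity;
* before optimization, data are rescaled to unit mean sensor power and each
  sensor-level component to unit mean diagonal, so `lambda = 0` starts every
  component at the data's scale (returned covariances and currents are
  unscaled back to fT/nAm units);
* Fisher scoring runs at most 128 iterations and stops when the objective
  moves by less than 0.01 nats; steps that would decrease it are retried
  with stronger damping; a non-positive-definite candidate covariance is
  treated the same way;
* `Sigma_lambda` is the inverse of expected curvature plus prior precision
  at the optimum;
* ties anywhere (greedy selection, peak finding) break toward the first
  index / smaller distortion, and every stochastic step takes an explicit
  seed.

The three schemes differ only in their source components. **IID** uses a
single identity source component (regularized minimum norm). **EBB** builds
a diagonal prior from beamformer power estimates,
`q_i = (l̃_i' SigmaY^{-1} l̃_i)^{-1}` with column-normalized lead fields,
ridge-stabilized (1e-6 of the mean diagonal) and rescaled to unit trace so
the free-energy optimization owns the overall scale. **GS** greedily mixes
rank-1 patch priors (64 patches by default, geodesic exponential profiles
with a 10 mm length scale, farthest-point-sampled seeds), adding whichever
patch raises F most until the gain drops below 0.01 or 8 patches are
active; this simple forward selection is deliberately modest — sparse patch
search is known to be sub-optimal without relevance-determination pruning,
and the benchmark treats it as one more assumption set to score, not as a
reference solver.

Temporal-mode projection (SVD to 99% variance) is available behind a config
switch but off by default: with it on, `Nt` becomes the retained mode count,
which changes F's absolute scale while leaving within-dataset comparisons
intact.

## Fit metrics

Four metrics score an inversion on a given anatomy: free energy (above);
variance explained `R² = (SST − SSR)/SST` on the Frobenius norms (the
residual-based definition, which differs from a squared correlation when
the prediction is biased — we implement the residual form); channel
hold-out cross-validation (10 runs, a seeded 10% of channels held out,
**full re-optimization** of the inversion on the retained channels per fold
— the honest generalization test — and the per-channel RMS error in fT
averaged over held-out channels and runs); and maximum normalized projected
power from LCMV unit-gain filters, data power over projected noise power,
maximized over sources. Only cross-validation error is lower-is-better.

## The benchmark and its statistics

`run_benchmark()` crosses simulated datasets × schemes × metrics ×
trajectory seeds. Each simulated dataset is a single-dipole evoked response:
a 20 Hz Hann-windowed sinusoid (100 samples at 250 Hz — a mid-band choice
for an evoked response filtered to 5–90 Hz), 336 trials, white sensor noise
scaled so the peak channel's single-trial SNR is −1.77 dB, trials averaged.
Realized peak and median SNRs are recomputed from the generated trials and
stored in the metadata. Per curve, the metric peak maps to a millimetre
distortion (ties toward zero); per seed-set, peaks average into the
distortion score; chance is the mean score under row-permuted lead fields
(fresh permutation per null run); and score sets are compared with paired
one-tailed t-tests (`df = n − 1`), with a zero-variance guard returning a
large finite statistic. The "chance level" construction — mean of null
scores, significance by paired comparison of veridical versus matched null
scores across datasets — is our own concrete choice where only "better than
chance, p < 0.05" is specified externally.

Because mirrored steps have equal distortion, peaks are reported in unsigned
millimetres; a peak at step 6 or step 12 of a 17-step ladder is the same
score.

## Problem sizes

The packaged fixtures are desk-scale by design: a folded-sphere cortex
(deterministic sinusoidal gyral modulation of an icosphere) with 642
vertices ("tiny") or 2562 vertices ("standard") versus the ~30,000 of a
FreeSurfer white-matter surface, and a 120-channel radial-magnetometer cap
versus a 275-channel gradiometer system. The test suite runs its
property-based checks and the eight-seed selectivity analysis on the tiny
preset; the calibration and field-map agreement checks use the standard
preset. Vertex counts, component counts, sensor counts and all experiment
sizes are configuration knobs.

## Known limitations

* The linear synthetic basis cannot create the topology-preserving but
  locally folded deformations of a trained diffeomorphic model; distortion
  realism is limited accordingly.
* The single-sphere conductor ignores skull shape; results comparing
  forward models are out of scope.
* GS is plain forward selection over a fixed patch dictionary.
* Simulations use white sensor noise; correlated (e.g. environmental or
  physiological) noise would stress the noise component model in ways the
  benchmark currently does not.
* The true surface is the exact trajectory midpoint here, so the benchmark
  cannot probe the regime where even the closest surrogate misses the true
  anatomy by a residual — a regime that exists whenever surfaces come from
  a lossy parameterization.
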