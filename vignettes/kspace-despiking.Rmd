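---
title: "Removing RF spike artifacts from MR k-space with robust PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing RF spike artifacts from MR k-space with robust PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(despikr)
```

## The problem

Brief bursts of radiofrequency noise during MR acquisition corrupt a handful
of k-space samples with very large outliers ("k-space spikes"). Because each
k-space sample contributes a plane wave to the image, a single spike overlays
the whole image with a stripe pattern; gradient-heavy sequences such as
diffusion imaging are particularly prone. Hardware faults should be fixed,
but data acquired while a fault was present can often only be salvaged in
postprocessing. despikr removes such spikes retrospectively from complex raw
data.

## The model

The measured k-space matrix $M$ is modelled as the sum of a low-rank matrix
$L$ (the artifact-free data) and a sparse matrix $S$ (the spikes), found by
solving the robust PCA program

$$\min_{L,S}\ \lVert L\rVert_* + \lambda_{\mathrm{eff}}\,
  \lVert S\rVert_1 \quad \text{s.t.}\quad M = L + S ,$$

with the nuclear norm $\lVert\cdot\rVert_*$ (sum of singular values) standing
in for rank and the entrywise $\ell_1$ norm for sparsity. For a dynamic
series the observation is the *Casorati* (k-t) matrix: each frame's k-space,
vectorised, is one column, so mutual redundancy between frames makes $M$
approximately low-rank plus spikes. Frame order is irrelevant to the
decomposition. For a single frame the $k_x$-$k_y$ matrix itself is used, and
$S$ then captures line-to-line structure not explained by a low-rank
representation of the frame.

Unlike a conventional truncated PCA, no rank is chosen by the user, and the
outliers may be arbitrarily large: they are absorbed by $S$ rather than
perturbing $L$.

### The solver

`rpca_decompose()` implements the inexact augmented Lagrange multiplier
(ALM) scheme, which alternates two proximal steps under a growing penalty
$\mu$:

* $S \leftarrow \mathcal{T}_{\lambda_{\mathrm{eff}}/\mu}(M - L + Y/\mu)$,
  where $\mathcal{T}_\tau$ shrinks each entry's *modulus* by $\tau$ and
  preserves its phase (`complex_soft_threshold()`); entries at or below the
  threshold become exact zeros, which downstream steps rely on;
* $L \leftarrow \mathcal{D}_{1/\mu}(M - S + Y/\mu)$, singular value
  thresholding with the complex SVD (`singular_value_threshold()`);
* dual update $Y \leftarrow Y + \mu (M - L - S)$, then
  $\mu \leftarrow \rho\mu$.

These complex-valued forms are the unique natural extension of the standard
real-valued solver: the $\ell_1$ norm of a complex matrix is the sum of
entry moduli, whose proximal operator is magnitude shrinkage with phase
preservation.

Numerical choices, matching the widely used reference implementation of this
solver: $Y_0 = M / \max(\lVert M\rVert_2, \lVert M\rVert_\infty /
\lambda_{\mathrm{eff}})$, $\mu_0 = 1.25/\lVert M\rVert_2$ (capped at $10^7
\mu_0$), $\rho = 1.5$, and the stopping rule is the relative constraint
residual $\lVert M - L - S\rVert_F / \lVert M\rVert_F < 10^{-7}$ with an
iteration cap of 1000. Non-convergence is reported through a flag rather
than raised: a partially despiked decomposition is still useful. The solver
is deterministic. We use the full economy SVD at every iteration rather than
the reference solver's truncated-SVD fast path: at desk scale (a
$16384 \times 50$ complex Casorati matrix) one economy SVD costs about a
quarter of a second and the prediction machinery is not worth its
complexity; no partial-SVD backend is required.

### The sparsity weight

The solver's conventional default weight is $\lambda = 1/\sqrt{m}$ with $m$
the row count of the observation matrix ($m = N_x N_y$ for the Casorati
arrangement, $m = \max(N_x, N_y)$ for a single frame). Because genuine
k-space is strongly peaked at its centre — a feature sparse enough to be
mistaken for spikes — despiking scales this default by a factor $\kappa$:
$\lambda_{\mathrm{eff}} = \kappa\lambda$ (`effective_lambda()`). Too small a
$\kappa$ sends a large central cluster into $S$; too large a $\kappa$ leaves
spike energy in $L$. $\kappa$ is the one non-automated parameter; validated
working points are 5 for Look-Locker T1 series, 6 for cine series, 3 for a
single static frame, and 5 (diffusion-weighted) versus 6–9 (low-b
reference) for DTI shells.

A note on the weight's form: one could imagine making $\lambda$ fall with
the number of frames as $1/\sqrt{N_v N_t}$. We verified empirically that
such a weight degenerates at realistic scale — with 50 frames the optimum
moves essentially all thermal noise into $S$, collapsing $L$ to the rank of
the noiseless signal (about 2) and defeating the centre-refill step —
whereas the row-count default keeps the full frame rank in $L$ and confines
$S$ to the spikes plus a small central cluster. The package therefore uses
the row-count default throughout.

### Centre refilling

Even with $\kappa$-scaling, some central samples land in $S$. Step two of
the pipeline undoes this: every nonzero entry of $S$ (exact zeros make
"nonzero" unambiguous) whose connected component — default 8-connectivity,
computed per frame, clipped (not wrapped) at grid edges — touches the
central `center_window` × `center_window` box (default 16, so 256 samples)
is refilled into $L$ (`refill_center()`). Components are moved whole, so a
central cluster leaking past the box boundary is still recovered entirely.
Refilled samples are restored to the *measured* values exactly; elsewhere
$L + S$ reproduces $M$ to solver tolerance. For an even window $w$ centred
at index $c$ the box spans $[c - w/2,\; c + w/2 - 1]$ on each axis — an
arbitrary but fixed convention, pinned by tests. The k-space centre location
is explicit (`center_index`) because partial-Fourier acquisitions place it
off the grid midpoint; connectivity is a within-frame notion here, and the
window is centred on the configured index, both deliberate choices where
conventions could differ.

The refill step is also the method's known failure mode: a spike *inside*
the central window is refilled along with the genuine peak and its
low-spatial-frequency stripe survives. The spike simulator therefore
excludes the central window by default, with a switch
(`exclude_center = FALSE`) to study the hard case.

The cleaned series is the refilled $L$, inverse Fourier transformed by
`reconstruct_images()` (DC moved from `center_index` to the first sample,
inverse DFT normalised by $1/(N_x N_y)$, magnitude returned).

## The synthetic world

All validation runs on analytic ellipse phantoms (`make_look_locker_series()`,
`make_cine_series()`, `make_dwi_set()`); piecewise-constant geometry with a
one-pixel soft edge keeps the ground truth exact while making frames at
different geometry genuinely distinct. Defaults state realistic acquisition
surrogates:

* **Look-Locker T1**: 128 × 128 matrix, 50 inversion times (10 ms start,
  120 ms spacing, spanning about five T1), torso/myocardium/blood at
  apparent $T_1^\ast$ = 0.8/1.2/1.6 s, signal
  $s(t) = A(1 - 2e^{-t/T_1^\ast})$. With perfect inversion ($B = 2A$) the
  Look-Locker-corrected $T_1 = T_1^\ast(B/A - 1)$ equals $T_1^\ast$.
* **Cine**: 128 × 128, 20 frames, blood-pool radius varying sinusoidally by
  ±25% (total intensity varies by under 2% frame to frame).
* **DWI**: 64 × 64, 2 low-b reference frames (b = 100 s/mm²) and 12
  diffusion-weighted frames (b = 1000 s/mm²) — a scaled-down brain
  protocol — with isotropic tissue (0.7 × 10⁻³ mm²/s), an anisotropic tract
  (eigenvalues 1.7/0.3/0.3 × 10⁻³, FA ≈ 0.80) and fast isotropic fluid
  (2.5 × 10⁻³).
* **Noise**: complex Gaussian, per-channel σ = 0.01 of the reference
  amplitude (SNR ≈ 100).
* **Spikes** (`spike_model()`, `add_spikes()`): a uniform random count of
  5–20 per dataset, locations uniform over k-space with the whole spike
  footprint (kernel reach plus one pixel of connectivity margin) kept clear
  of the central window by default, complex
  amplitude with uniform phase and magnitude log-uniform in 5–50 times the
  k-space 99th-percentile magnitude (large relative to high-frequency
  k-space, below the DC peak), spread along the readout axis by an
  exponential rise/decay kernel $w(d) = e^{-|d|/\tau}$ with
  $\tau = k/2$ truncated at ±k (default k = 2), emulating spike duration.
  Every modified sample and its added value are returned in a ledger, which
  is the oracle for all recovery tests.

What the phantoms do *not* emulate: anatomy, motion, EPI trajectory
distortions, eddy currents, coil sensitivity profiles, or spikes with
structure repeated across frames (which reduce the power of the
decomposition on real hardware-fault data). A green test therefore
establishes that the algorithm removes the *modelled* class of corruption
without touching clean data — not that every real-world spike pattern is
recoverable. Multi-coil data should be despiked per channel as independent
series; the package takes no position on coil combination.

## Validation metrics

`fit_t1_look_locker()` fits $|A - B e^{-t/T_1^\ast}|$ by variable
projection (amplitudes linear, $T_1^\ast$ by golden-section search),
restoring the polarity lost in magnitude data by trying sign flips of the
samples up to just past the signal minimum and keeping the best residual;
the corrected $T_1 = T_1^\ast(B/A - 1)$ is the standard small-flip-angle
Look-Locker result. `background_noise_std()` measures the standard
deviation over four corner squares (each 10% of the matrix side; the
corners avoid object support in all phantoms) — spike stripes raise it,
so it serves as the artifact-level metric. `fit_diffusion_tensor()` and
`fa_md_maps()` estimate the tensor by ordinary log-linear least squares,
with eigenvalues floored at a small positive value before FA so that FA
stays in [0, 1]. Cohort statistics are left descriptive; no inferential
testing is re-implemented.

Spike corruption perturbs FA far more than MD: MD is an average over
directions, so random outliers tend to cancel, while FA is a dispersion
measure that a single outlier can inflate, especially near isotropy. The
acceptance suite checks exactly this signature: despiking moves the FA
distribution back toward the artifact-free one (1-D earth-mover distance,
`emd_1d()`) while mean MD stays within 2%.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
ph  <- make_look_locker_series(phantom_spec())        # artifact-free truth
sim <- add_spikes(ph$kspace, spike_model())           # seeded corruption
res <- despike(sim$corrupted, despike_config(kappa = 5))
res

led <- sim$ledger                                     # ground-truth support
idx <- cbind(led$sample_kx, led$sample_ky, led$frame)
1 - sum(Mod(res$clean$data[idx] - ph$kspace$data[idx])^2) /
    sum(Mod(led$value)^2)                             # spike energy removed
```

## Known limitations

* Complex raw data are required; magnitude-only input is rejected. A
  pseudo-k-space mode for magnitude images is a possible extension but the
  spike energy then concentrates at the DC sample, where the refill step is
  blind.
* Spikes inside the central window survive as low-frequency stripes.
* Few-frame series (and the single-frame mode) misclassify more of the
  central peak, making the refill step work harder; many-frame series are
  preferred.
* $\kappa$ remains a per-protocol choice; the documented working points are
  starting values, to be confirmed visually on one dataset per protocol.
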