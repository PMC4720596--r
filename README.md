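# despikr

Retrospective removal of RF spike artifacts ("k-space spikes") from complex
MR raw data by robust principal component analysis.

Brief bursts of RF noise — from vibrating gradients, loose coil connections,
poor shielding — corrupt individual k-space samples with very large
outliers, each of which overlays the reconstructed image with a stripe. When
the fault is only noticed after the scan, the data can still be salvaged:
despikr decomposes the measured k-space matrix **M** into a low-rank
component **L** (the artifact-free data) and a sparse component **S** (the
spikes) by solving

    min ‖L‖* + λ_eff ‖S‖₁   subject to  M = L + S

with an inexact augmented Lagrange multiplier solver extended to complex
matrices. For a dynamic series, **M** is the Casorati (k-t) matrix — each
frame's k-space is one column — so frame redundancy makes **L** low-rank
while spikes of arbitrary magnitude are absorbed by **S**. The sparsity
weight is the solver default `1/sqrt(rows)` scaled by a per-protocol factor
κ (`λ_eff = κ/√(NxNy)` for series; validated working points: T1 mapping 5,
cine 6, static frame 3, DTI shells 5–9) to protect the peaked k-space
centre, and any central samples still misclassified as sparse are refilled
into **L** by an 8-connected component rule over the central 16 × 16 window
before inverse Fourier reconstruction.

The package also ships analytic phantom generators (Look-Locker T1
inversion recovery, cardiac cine, diffusion-weighted sets), a seeded RF
spike simulator with a complete ledger of every corrupted sample, and the
validation metrics used to judge despiking: corrected Look-Locker T1,
background-noise standard deviation, and diffusion tensor FA/MD. It is
aimed at preclinical and clinical MR physicists who keep raw (complex)
data and need a semi-automated rescue path for spike-corrupted series.

## Worked example

```r
library(despikr)
set.seed(1)
ph  <- make_look_locker_series(phantom_spec())   # 128 x 128, 50 inversion times
sim <- add_spikes(ph$kspace, spike_model())      # seeded RF spike corruption
res <- despike(sim$corrupted, despike_config(kappa = 5))
res
#> despiked 128 x 128 x 50 k-space (multiframe mode, kappa = 5)
#>   lambda_eff = 0.03906; rank(L) = 50; converged
#>   refilled pixels per frame: mean 21.4 (max 44)
```

The low-rank component keeps the full rank of the series (50 = number of
frames): despiking removes outliers, not signal. On average 21 of the 256
central-window samples per frame were initially misclassified as sparse and
refilled. The simulator's ledger gives the ground-truth spike support, so
the removal can be measured exactly:

```r
led <- sim$ledger
idx <- cbind(led$sample_kx, led$sample_ky, led$frame)
1 - sum(Mod(res$clean$data[idx] - ph$kspace$data[idx])^2) / sum(Mod(led$value)^2)
#> [1] 0.999766
```

99.98% of the injected spike energy is gone from the cleaned k-space. The
quantitative endpoints recover accordingly — myocardial T1 (truth 1.2 s) and
the background-noise level of the reconstructed magnitude images:

```
T1:        free 1.19974   corrupted 1.19968   despiked 1.19974   [s]
noise std: free 0.00654   corrupted 0.05421   despiked 0.00656
```

Corruption raised the background standard deviation eightfold; despiking
returns it to within 0.2% of the artifact-free value without moving T1.

For DTI-style data with mixed signal levels, despike per b-value shell:

```r
res <- despike_grouped(series, kappa_by_group = c("100" = 6, "1000" = 5))
```

A command-line wrapper with `despike`, `simulate` and `validate`
subcommands is installed at `system.file("cli/despikr.R", package =
"despikr")`; file I/O uses a documented complex k-space container plus
NIfTI-1 magnitude volumes and JSON reports.

## Acceptance script

`scripts/acceptance.R` regenerates the full-scale simulated-spike
experiment from scratch with the installed package — 10 seeded
artifact-free Look-Locker phantoms (128 × 128, 50 frames), RF spike
injection, despiking at κ = 5 — and reports the mean relative deviation of
the despiked background-noise standard deviation from its artifact-free
value:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runtime is about a minute on one CPU.

## Vignette

`vignettes/kspace-despiking.Rmd` documents the model and solver, the
κ-scaled sparsity weight, the centre-refill rule, what the synthetic
phantoms do and do not emulate, and the package's numerical conventions.
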