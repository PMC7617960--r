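# hrvrmc

Estimation of missing or artefact-corrupted regions of heart-rate-variability
(HRV) power spectra by low-rank matrix completion, with a model-driven
refinement that selects the most informative recording segments before
completing.

## Who this is for

Researchers doing frequency-domain HRV analysis on ECG (or PPG-derived)
beat series who need to salvage spectra whose LF (0.04–0.15 Hz,
Mayer-wave) or HF (0.15–0.4 Hz, respiratory sinus arrhythmia) region is
distorted by motion artefacts, beat-detection errors, or interpolation —
without discarding the whole segment. The package covers the full chain:
RR-interval cleaning, dual-detector quality gating, 4 Hz resampling,
zero-phase Butterworth band-pass, Welch spectra, spectrum-matrix assembly,
and the completion machinery itself, plus a seeded synthetic-data
generator so everything is testable at desk scale.

## The method

Stacked per-segment PSDs form a matrix `S` (rows = 5-minute segments,
columns = frequency bins) that is approximately low rank, because a few
latent spectral shapes explain most segments. With `Ω` the set of trusted
entries and `A_Ω` the operator zeroing everything else, corrupted bins are
estimated by the constrained approximation

```
min ‖A_Ω(X) − A_Ω(S)‖_F   s.t.   ‖X‖_* ≤ λ ,
```

solved for fixed λ by alternating an exact projection onto the
nuclear-norm ball (singular-value soft-thresholding) with restoration of
the known entries, and driven by bisection on λ ∈ [0, ‖A_Ω(S)‖_*] down to
the smallest bound whose fixed point matches the observations to
`e_tol = 1e-8` (`complete_matrix()`). The **refined** method
(`rmc_estimate()`) first fits a per-band Gaussian model
`A/(√(2π)σ)·exp(−(f−f₀)²/(2σ²))` to every row's known bins, ranks all
rows by the Pearson correlation of their modelled spectra with the target
row's model on its known bins, and completes only the small matrix of the
target plus its `K = 9` best-correlated donors. A classic singular value
thresholding baseline (`svt_complete()`) is included for comparison, and
estimates are scored with the normalised RMSE
`nrmse()` = RMSE(hidden bins) / SD(true hidden bins).

## Worked example

Simulate a 60-segment spectrum matrix from three latent prototypes, hide
30% of one row as a contiguous block over the HF band, and estimate it:

```r
library(hrvrmc)

sim  <- synth_spectrum_matrix(60, default_prototypes(3),
                              additive_noise_sd = 500, seed = 11)
S    <- restrict_matrix(sim$matrix)          # 60 segments x 92 bins, 0.04-0.4 Hz
mask <- apply_mask(S, target_row = 7, ratio = 0.3, pattern = "band")
hidden <- which(!mask$known[7, ])

fit  <- rmc_estimate(S, mask, target_row = 7, K = 9)
nrmse(fit$estimate, S$rows[7, ], hidden)     # 0.679
base <- svt_complete(S$rows, mask)
nrmse(base$X[7, ], S$rows[7, ], hidden)      # 6.556
```

The refined estimate reconstructs the hidden HF block at a fraction of
the truth's spread (NRMSE 0.679 — dominated by the additive noise floor
the completion correctly refuses to reproduce), while the SVT baseline,
soft-thresholding the full matrix, misses the contiguous block badly
(6.556). `fit$selection$selected` lists the nine donor segments chosen
from the LF region, and `fit$result` records λ, the residual history and
convergence of the bisection.

A command-line front end is installed with the package
(`system.file("cli", "hrvrmc.R", package = "hrvrmc")`) with subcommands
`simulate`, `preprocess`, `psd`, `estimate`, `evaluate`, all thin wrappers
over the functions above.

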