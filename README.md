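# epighost

Referenceless Nyquist ghost correction for single-shot 2D EPI of
hyperpolarized ¹³C metabolites, with a synthetic acquisition simulator and
quantitative image metrics.

## The problem

Dynamic imaging of hyperpolarized [1-¹³C]pyruvate and its conversion to
[1-¹³C]lactate must race a polarization that decays in tens of seconds, so
single-shot echo planar imaging (EPI) is the sequence of choice. EPI's
alternating (bipolar) readout gradients accumulate opposite phase errors on
odd and even k-space lines, which fold a replica of the object — the Nyquist
ghost — half a field of view away along the phase-encode direction. The
classical fix, a reference scan with phase-encoding off, costs a time point
from the precious dynamic series; integrated reference echoes avoid that but
prolong the echo time and pay an SNR penalty through T₂\* decay.

This package implements a referenceless workflow instead: the odd/even phase
error is modelled as

```
theta(x) = alpha + beta * x
```

with `x` the centred normalized readout coordinate, `alpha` the zero-order
term (B₀-shift-like eddy currents) and `beta` the first-order term (readout
eddy currents and group delays). Each line `j` carries `(-1)^j * theta(x)`,
which splits the ideal image `rho` into

```
rho_hat(x, y) = rho(x, y) cos(theta(x)) + i rho(x, y - N/2) sin(theta(x))
```

— a cosine-weighted image in place plus a sine-weighted ghost shifted by
`N/2`. The correction coefficients are found by an exhaustive 100 × 100 grid
search of `(alpha, beta)` over `(-pi/2, pi/2]` (the error is periodic in π)
that minimizes the mean magnitude in ghost-containing background bands —
phase-encode rows outside the object ROI — and the single searched pair is
then applied to every frame of every metabolite in the dynamic series. The
reference-based alternatives (¹³C reference scan with Ahn phase unwrapping
and per-line linear fits, integrated reference echoes, ¹H reference scan
with gyromagnetic-ratio scaling) are implemented as comparators, along with
a 2D search variant with an additional first-order phase-encode term.

Everything runs on simulated data: the `simulate` module generates phantoms,
corrupted partial-Fourier acquisitions (20 of 32 lines, 62.5% of k-space),
reference scans, integrated echoes, and two-metabolite dynamic series with
seeded complex Gaussian noise, so the whole workflow is testable without a
scanner.

## Worked example

```r
library(epighost)

# 1. Simulate a corrupted single-shot acquisition of a disk phantom
phantom <- make_phantom(default_phantom())        # 32 x 32, disk radius 0.5
truth   <- default_corruption()                   # alpha = 0.56, beta = 0.86 rad
params  <- acquisition_params(coeffs = truth, noise_sd = 0, t2star = NULL)
kspace  <- acquire_epi(phantom, params)           # 20 of 32 lines (62.5%)
print(kspace)
#> <epi_kspace> 32 x 32, 20/32 lines acquired (62.5%), C13, echo spacing 552 us

# 2. Quantify the ghost before correction
mask <- phantom_mask(default_phantom())
rois <- build_roi_set(mask)
ghosting_level(magnitude(reconstruct(kspace)), rois)
#> uncorrected ghosting: 62.6%

# 3. Referenceless 1D exhaustive search over the ghost bands
bands <- build_ghost_bands(mask)
fit <- search_1d(kspace, bands)
print(fit)
#> <search_result_1d> alpha = 0.5553, beta = 0.8727 (band mean 0.02132, step 0.0317)
ghosting_level(magnitude(fit$corrected), rois)
#> corrected ghosting: 4.64%
```

The search lands on the grid points nearest the true pair (within one step,
π/99 ≈ 0.032 rad) and cuts the ghosting level from 62.6% to 4.6%; the
remaining signal in the bands is zero-filling ringing from the partial
k-space, not ghost (on full k-space the same correction reaches numerical
zero). For a dynamic series, `apply_workflow()` searches once — by default on
the lactate frame with the highest object SNR — and applies the pair to all
frames of both metabolites; `run_pipeline()` wires simulation, search,
correction and metrics into one reproducible, seeded run.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/epighost.R simulate --frames 10 --seed 1 --out series.json
Rscript inst/cli/epighost.R correct  --input series.json --method search1d --out coeffs.json
Rscript inst/cli/epighost.R run      --seed 1 --out-dir run1
```

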