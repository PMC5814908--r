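---
title: "Referenceless Nyquist ghost correction: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Referenceless Nyquist ghost correction: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epighost)
```

## The phase-error model and its assumptions

Single-shot EPI traverses k-space with alternating readout gradients, so
eddy currents and group delays accumulate phase errors of opposite sign on
odd and even lines. The package models this error as linear in the readout
coordinate,

$$\theta(x) = \alpha + \beta x,$$

where $x \in [-1, 1)$ is the centred normalized readout coordinate (0-based
pixel $n$ maps to $(n - N_x/2)/(N_x/2)$), $\alpha$ is the zero-order term and
$\beta$ the first-order term, expressed as the phase at the readout FOV edge.
In the x–ky hybrid space (each line 1D-transformed along the readout axis)
line $j$ is multiplied by $e^{i(-1)^j\theta(x)}$; even 0-based lines carry
$+\theta$. For a fully sampled acquisition this is exactly equivalent to the
closed form

$$\hat\rho(x,y) = \rho(x,y)\cos\theta(x) + i\,\rho(x, y - N/2)\sin\theta(x),$$

which `closed_form_ghost()` implements and the test suite verifies against
the transform pipeline to below $10^{-10}$ max absolute difference. The model
assumes non-oblique planes with negligible cross-term and higher-order eddy
currents; spatially varying errors (e.g. a deliberately de-shimmed field) are
outside the model and the simulator makes no attempt to emulate them.

Two conventions had to be fixed that the model itself leaves open, and both
are recorded in all I/O metadata:

* **Units of $\beta$.** With $x$ normalized to the FOV edge, the searched
  range $(-\pi/2, \pi/2]$ covers group delays up to a quarter of a dwell
  time, and $\beta$ is directly comparable across matrix sizes.
* **Line polarity.** Which parity of lines carries $+\theta$ is arbitrary;
  the opposite choice negates both coefficients. The package fixes even
  0-based lines (in acquisition order after the standard odd-echo time
  reversal) to $+\theta$.

The magnitude image is invariant under $\theta \to \theta + \pi$ (both the
cosine and sine terms flip sign), so $\alpha$ is canonicalized into
$(-\pi/2, \pi/2]$. $\beta + \pi$ is *not* a symmetry — it would add $\pi x$
to the error — so $\beta$ is never wrapped; the searches bound it instead.

## Reconstruction

All transforms use the DC-at-centre convention, so the half-FOV ghost is a
circular shift by exactly $N/2$ pixels and matrix sizes are required to be
even. Partial-Fourier acquisitions (the default geometry acquires 4 lines
before the k-space centre plus the full tail: 20 of 32 lines, 62.5%) are
zero-filled before the transform. Zero-filling trades SNR for blurring and
Gibbs ringing along phase-encode; no conjugate-synthesis or POCS completion
is attempted. This matters when reading residual ghosting numbers: after a
perfect correction of a partial acquisition, a few percent of "ghosting"
remains that is ringing leakage into the measurement bands, not ghost — on
full k-space the same correction reaches numerical zero, and the test suite
asserts both.

## The referenceless searches

`search_1d()` evaluates every $(\alpha, \beta)$ pair on an evenly spaced grid
over $[-\pi/2, \pi/2]$, reconstructs the corrected magnitude image, and
scores the mean magnitude over the ghost-containing background bands —
phase-encode positions strictly outside the object ROI's extent
(`build_ghost_bands()`). The grid has `n_steps = 100` points *including both
endpoints* (step $\pi/99$): the description "100 increments" is ambiguous
between points and intervals, and 100 points was chosen once and recorded in
`search_config()`. The mean (rather than sum) over band pixels makes the
objective comparable across band sizes; for a fixed band the two are
equivalent. Exact ties are broken towards the smallest $|\alpha| + |\beta|$,
then the smallest $|\beta|$ — determinism matters for golden tests. The
objective is evaluated on whole-image corrections (not per-line) for the 1D
search.

The evaluation is factorized: in hybrid space the correction phase depends
only on the readout position and the line parity, so the even-line and
odd-line contributions to the band pixels are projected once through the
phase-encode inverse DFT, and each candidate costs an elementwise
combination $|e^{-i\alpha}U + e^{i\alpha}V|$. The search remains literally
exhaustive — the full objective surface is returned for diagnostics — but a
100 × 100 search of a 32 × 32 frame takes well under a second.

An entropy-based criterion was deliberately not implemented: entropy is
blind to a global half-FOV shift of the image, which the band objective is
not.

`search_2d()` adds a first-order phase-encode term: for each candidate
$\beta_y$ on the grid, every readout row is independently assigned the
scalar phase $\theta_{col}(x)$ minimizing that row's band magnitude, and the
$\beta_y$ with the lowest total band magnitude wins. This per-column scalar
phase plus global linear $k_y$ term structure is an interpretation — the 2D
variant is under-specified — and two of its consequences are documented
rather than hidden: (i) rows with no ghost energy fall to the tie-break
(harmless: their hybrid data are zero or noise), and rows with no band
pixels at all inherit the global 1D solution and are flagged; (ii) the
per-row residual is quantized by the $\theta$ grid, because
$\alpha + \beta x$ generally falls between grid points, so the residual
ghosting of the 2D search on noiseless data shrinks roughly linearly with
the grid step instead of reaching zero. Local per-row minimization can also
be biased in rows with little ghost signal — the known weakness of the 2D
variant with multiple signal sources; per-source ROIs are the remedy.

## Reference-based estimators

With phase-encoding off, adjacent hybrid-space lines differ in phase by
exactly $2\theta(x)$ with alternating sign. `estimate_from_reference()`
unwraps that difference along the readout with Ahn's cumulative algorithm
(`phase_unwrap_1d()`: the running sum of the principal-value phase of the
lag-one complex product, immune to $\pm 2\pi$ wraps while true steps stay
below $\pi$), anchors the $2\pi$-ambiguous offset at the
maximum-magnitude sample, restricts and magnitude-weights the linear fit to
samples above 10% of the peak projection magnitude (the masking rule is not
prescribed anywhere; 10% is a configurable default), and assigns the fitted
pair per line — per-line application is the stated behaviour of the
reference-scan method. `estimate_from_integrated_echoes()` applies the same
pair-wise estimator to the prepended non-phase-encoded echoes and averages
into a single pair, which is the stated behaviour of that method. Pure
magnitude decay between echoes ($T_2^*$) carries no phase and does not bias
the estimate. `scale_reference_coeffs()` transfers ¹H-measured coefficients
to ¹³C: $\alpha$ scales by $\gamma_{13C}/\gamma_{1H} = 0.2515$ and $\beta$
additionally divides by the FOV ratio; at the same readout gradient the ¹H
FOV is about one quarter of the ¹³C FOV, so the two scalings nearly cancel
for $\beta$ ($0.2515/0.25 = 1.006$).

## Metrics

**Ghosting level** is the excess mean magnitude in the two half-FOV
phase-encode copies of the object region, with the frequency-encode copies
subtracting the noise floor, normalized by twice the object mean, in
percent. Regions 1/2 (and 3/4) are the two pieces of the shifted object mask
split at the image midline — the split is a documented convention, as the
regions are only ever used through their union in the arithmetic. The value
may be slightly negative under noise and is not clamped.

**SNR** is the mean object magnitude over the standard deviation of the
magnitude in a noise source (a region or a noise-only frame). Magnitude
noise is Rayleigh-distributed, so a pure-noise field measured against itself
gives mean/SD ≈ 1.91, and the "SNR" of an object is ≈ 1.53 × the
complex-channel SNR; whether a magnitude or complex definition is intended
by convention is genuinely ambiguous, and magnitude was chosen because that
is what is measurable on reconstructed images.

**SSIM** uses the standard constants $K_1 = 0.01$, $K_2 = 0.03$, a 7 × 7
Gaussian window of standard deviation 1.5 with population (weighted)
variances, the joint maximum as the dynamic range, and averages the local
map over the region where the window lies fully inside the images, so no
padding policy leaks into the score. The implementation is verified in the
tests against values computed independently with a separate implementation
of the same definition.

**Phase-encode pixel bandwidth**, $1/(N_{pe} \cdot t_{esp})$, is the B₀
offset that shifts the image one pixel along phase-encode: 56.6 Hz (≈ ±57
Hz of off-resonance immunity) for 32 lines at 552 µs.

## The simulator and what it does (not) emulate

`acquire_epi()` forward-transforms a phantom, applies per-echo $T_2^*$ decay
in acquisition order, corrupts the lines with the alternating phase error,
zero-fills the unacquired lines and adds seeded complex Gaussian noise to
acquired lines only (zero-filled lines are noise-free, matching zero-filling
after acquisition). `acquire_reference()` repeats the ky = 0 projection with
the same corruption; `acquire_integrated_echoes()` prepends decayed
reference echoes and advances the imaging train by `n_echoes` echo spacings,
so the noiseless amplitude cost is exactly
$e^{-n_{echoes}\, t_{esp}/T_2^*}$ (0.920 for three echoes at 552 µs and
$T_2^* = 20$ ms). `make_dynamic_series()` builds a two-metabolite series:
frame $t$ of metabolite $m$ is the corrupted acquisition of
$c_m(t) \cdot \text{phantom}_m$ with per-frame seeds derived from the master
seed (master + frame offset), and all frames share one true coefficient
pair — the property the workflow exploits.

Fixed defaults, chosen once as the study conditions and not revisited:

* **Corruption** `default_corruption()` = (0.56, 0.86) rad, set so the
  noiseless regular-FOV disk phantom shows an uncorrected ghosting level
  near 63% — severe, clearly visible ghosting of the kind the correction
  methods are expected to face.
* **Geometry**: 32 × 32 matrix, 4 lines before centre (62.5% partial
  k-space), 552 µs echo spacing, 4 cm readout FOV.
* **Signal curves**: pyruvate follows a gamma-variate (shape 3, scale 4 s)
  normalized to peak 1; lactate is the same family delayed 4 s and scaled
  0.3. No kinetic model is claimed; these are plumbing that produce a
  realistic rising-then-falling series with the lactate peak mid-series.
  With a 2 s repetition time the first two lactate frames carry no signal,
  so the ghosting metric — undefined at zero object mean — simply does not
  exist there, mirroring the exclusion of noise-dominated time points from
  dynamic measurements.
* **Series noise** `noise_sd = 1.0` (per k-space sample and channel), which
  puts the peak-lactate object SNR in the 11–13 range typical of a good
  in-vivo lactate series.
* **$T_2^*$** 20 ms where decay is enabled, a plausible value for ¹³C
  metabolites at high field.

What the simulator does **not** emulate: spatially varying (de-shim) phase
errors, B₀ inhomogeneity and off-resonance distortion, ramp sampling, flow
and motion, RF pulse profiles, coil sensitivities and parallel imaging.
Passing tests therefore demonstrate the correctness of the correction
machinery under the stated error model, not robustness to every scanner
non-ideality.

## Noise robustness of the search, honestly

The band-mean-magnitude objective has a noise floor: once the residual ghost
amplitude drops below the per-pixel noise, the Rician magnitude mean
responds only quadratically to further improvement, so the $\beta$ basin
flattens. In this simulator's regular-FOV geometry, recovering $\beta$ to
within 2 grid steps in ≥95% of seeds requires an object SNR (magnitude
definition) around 20; at SNR 5 the rate is near 40% with a median $\beta$
error of ~3 grid steps, even though the correction at those erroneous
coefficients often still looks visually acceptable. Recovery degrades
monotonically as SNR falls, and below roughly the mid-single digits the
returned coefficients are effectively random — which is why
`apply_workflow()` warns (default floor 4.7) when the selected search frame
is too noisy, and why the workflow searches on the highest-SNR frame or on
summed frames rather than frame-by-frame. The acceptance suite measures
these rates at 50 seeds per SNR level and asserts the monotone degradation;
the 95%-at-SNR-5 bar is asserted as stated and documented here as not met by
the band-mean objective in this geometry.

## Problem sizes and runtimes

All simulations use 32 × 32 frames. The test suite runs 100 random-image
oracle comparisons, a 25-pair on-grid recovery sweep, 50-seed recovery rates
at three SNR levels, 60-seed estimator bias checks, and 10-frame two-
metabolite workflow transfers; the full suite completes in well under two
minutes, and `scripts/acceptance.R` in under half a minute, on one CPU.

## Containers and interfaces

Complex k-space frames and dynamic series are serialized to a
schema-versioned JSON container holding `kspace_real`/`kspace_imag` arrays,
the `acquired_mask`, and the acquisition attributes (`echo_spacing_s`,
`lines_before_center`, `nucleus`, `fov_readout_m`), written at 17
significant digits so round trips are lossless. Magnitude images and ROI
masks use NIfTI-1 via `RNifti`. The CLI (`inst/cli/epighost.R`) exposes
`simulate`, `correct`, `metrics` and `run` subcommands over the same
functions; every pipeline run writes its resolved configuration, a log with
stage/seed/timing lines, and a JSON report beside its image outputs.

## Known limitations

* The error model is 1D-linear per line; oblique-plane cross terms and
  spatially varying eddy currents are out of scope.
* Partial-Fourier handling is zero-fill only; ringing inflates residual
  ghosting numbers on partial acquisitions (quantified above).
* The 2D search inherits the grid quantization of its per-row phases and
  the local-minimization bias with multiple sources.
* SSIM is the only perceptual metric; no figure reproduction is attempted.
* The magnitude-based SNR definition carries the Rayleigh/Rician caveats
  discussed above.
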