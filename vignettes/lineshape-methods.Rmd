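---
title: "Lineshape models and analysis methods in lipidorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineshape models and analysis methods in lipidorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidorder)
```

# The measurement problem

Multilamellar lipid vesicles (MLVs) present every bilayer orientation to the
magnetic field, so wide-line solid-state NMR spectra of them are *powder
patterns*: orientational averages of the anisotropic spin interaction. Two
interactions carry the membrane physics here:

* **²H quadrupolar coupling** of a perdeuterated palmitoyl chain (POPC-²H₃₁
  as the reporter lipid). Each of the 15 inequivalent deuteron groups (CD₂ at
  chain positions k = 2…15, CD₃ at k = 16) produces a Pake doublet whose
  90°-edge splitting Δν_Q measures the C–D bond order parameter at that
  position.
* **³¹P chemical shielding anisotropy (CSA)** of every phosphate in the
  mixture. Fluid lamellar phases average the shielding tensor to axial
  symmetry; each phosphate environment contributes one axially symmetric
  powder pattern characterized by (Δσ, δ_iso, line width, abundance).
  Phosphoinositide-rich membranes superimpose up to seven such patterns
  (PIP₂ alone carries three: the glycerol-bound phosphodiester and the 4- and
  5-phosphates of the inositol ring).

The package provides the forward model for both pattern families, the
de-Pakeing inversion that sharpens powder spectra into oriented-like spectra,
the splitting → order-parameter mapping, and the iterative multi-component
³¹P fit — plus a seeded generator that emulates the study conditions
(MV1-, MV2- and NER-like nuclear-envelope precursor membrane models) so the
whole chain is testable without instrument data.

# Forward model

## Orientation distribution

For a spherical MLV the probability of the angle θ between bilayer normal and
field is sin θ. Large static fields elongate vesicles into prolate
ellipsoids, depleting membrane area with normals along the field and hence
the high-frequency (0°) edge of the pattern. The exact deformation weighting
used in the original analysis software is unpublished, so the package adopts
a minimal single-parameter family with the right limits and monotonicity:

$$ w(\theta) \propto \sin\theta \,\left[1 + \varepsilon\,
   \tfrac{1 - 3\cos^2\theta}{2}\right]_+ $$

ε = 0 recovers the sphere; ε > 0 strictly reduces the θ = 0 weight. ε is
dimensionless, defaults to 0, and can float in the ³¹P fit (bounded to
[0, 1]).

## Per-orientation frequencies and the pinned conventions

All numeric results hinge on two sign/edge conventions, fixed once:

* **Quadrupolar:** the doublet of a group with 90°-edge splitting `s₉₀` sits
  at ±s₉₀·P₂(cos θ), giving intense edges separated by s₉₀ and outer
  shoulders at ±s₉₀. The rigid bound is s₉₀ ≤ (3/4)·A_Q with A_Q = 167 kHz.
  The order parameter follows |S_CD| = (4/3)·Δν_Q(90°)/A_Q; because plateau
  C–D bonds average at 90° to the long molecular axis, 2|S_CD| is the
  headline quantity (0 = fluid, 1 = rigid). The terminal CD₃ rotates fast
  about the chain axis (|P₂(cos 109.47°)| = 1/3), so `methyl = TRUE`
  multiplies the mapped value by 3; the raw splitting is always reported
  alongside.
* **CSA:** δ(θ) = δ_iso + Δσ·(3cos²θ − 1)/3 with Δσ = σ∥ − σ⊥; the intense
  perpendicular edge is at δ_iso − Δσ/3, the weak parallel edge at
  δ_iso + 2Δσ/3, breadth |Δσ|, and the first moment of the unbroadened
  pattern equals δ_iso (the property the ³¹P initial-guess routine exploits).

These reproduce the four printed plateau anchors exactly
(29.4 → 0.47, 50.7 → 0.81, 43.2 → 0.69, 45.7 → 0.73 for 2|S_CD|):

```{r anchors}
splitting_to_order(c(29.4, 50.7, 43.2, 45.7))
```

## Numerical integration and broadening

Powder integration uses a midpoint rule over equal-θ bins (default 4096 for
simulation, 2048 inside the fit and the de-Pake kernel; at least 64 enforced)
with intensities accumulated onto the frequency grid by linear splitting
between the two bracketing grid points — this suppresses the staircase
artifacts a nearest-bin histogram shows at the singular 90° edges. Grids that
do not span a component's pattern raise an error instead of silently
truncating (the fit disables this check while the optimizer explores).
Line broadening (the 50–300 Hz Lorentzian applied to the experimental FIDs)
is a unit-area Lorentzian convolution by zero-padded FFT on the uniform
grid, which conserves the integral to well under 0.1%. Every composed
spectrum integrates to the sum of its component weights.

Correctness of the deterministic engine is cross-checked in the test suite
against an independent brute-force oracle: ≥10⁶ orientations sampled from
the orientation distribution, mapped to resonance positions and binned on a
matched grid, agree with normalized L1 distance below 1%.

# De-Pakeing

The deconvolution that converts a powder spectrum into an oriented-like
(90°) spectrum is implemented as a discretized linear inversion: the powder
operator K is assembled column-by-column (one unit-weight Pake pattern per
point of a 90°-edge-splitting grid, broadened to the expected line width,
default 200 Hz) and solved as a non-negative Tikhonov problem

$$ \min_{x \ge 0} \; \|Kx - y\|^2 + \lambda^2 \|D_2 x\|^2 $$

with a second-difference smoothing operator D₂ (plus a vanishing identity
term for conditioning). The published de-Pakeing variant used originally is
not identifiable from the methods description; a regularized non-negative
inversion satisfies the same contract (sharp line pairs at ±Δν_Q/2,
re-projection reproducing the input) and is robust to noise. λ is
`regularization × max column norm of K`; the default constant 0.01 was fixed
once against the single-doublet round-trip contract (splitting recovered
within 2% at ≤300 Hz broadening, re-projection L1 < 3%) and is recorded in
the output metadata together with the asymmetry score of the mandatory
²H symmetrization. Increasing λ only smooths: the detected-peak count is
non-increasing in λ.

²H spectra are symmetrized before inversion (they are theoretically even;
averaging halves suppresses phase roll). The same machinery with the
isotropic shift pinned at the spectral first moment gives a one-parameter
CSA deconvolution used to seed the ³¹P fit with candidate anisotropies.

## Splitting measurement and profile assembly

Peaks are parabolic-interpolated local maxima above a threshold (default 6%
of the maximum), paired across zero within max(0.5 kHz, 3 grid steps) — the
pairing tolerance is not stated in the source material and is fixed here for
determinism. Deconvolution side lobes (pairs below 25% of a taller pair
within max(1.5, 0.08·s) kHz) are discarded. Profile assembly merges
splittings within 8% of the largest into the plateau (intensity-weighted
mean; positions k = 2…10 are treated as one group, matching how "the
plateau" is measured as a single quantity), assigns the smallest splitting
to the methyl, and intermediate ones to k = 11… in descending order.
Degenerate inputs yield partial profiles flagged as such, never errors. The
thermal table propagates the ±1 kHz splitting accuracy linearly
(±0.016 on 2|S_CD|).

# Multi-component ³¹P fitting

`fit_p31()` is the package's central fitting function; it returns a classed
object with the standard modelling methods (`print`, `summary`, `coef`,
`predict`, `residuals`, `fitted`, `plot`, `simulate`, `deviance`). The
residual is the difference between the measured spectrum and the composed
forward model; minimization is damped least squares (Levenberg–Marquardt via
minpack.lm) with:

* **freeze masks** per component parameter — by default Δσ, δ_iso and line
  widths float while **weights are frozen to stoichiometry** (mol% × one per
  phosphate, from the composition table); a global amplitude always floats.
  Freeing weights is an explicit flag, and on stoichiometric data the frozen
  fit can only do better, which the tests assert.
* **tie groups** — the glycerol-bound phosphates of PI/PIP/PIP₂ are
  constrained to one common Δσ (and line width) by default in mixtures that
  contain several of them, mirroring the degeneracy of the recovered
  parameter tables, which report a single value for all three.
* **bounds** — |Δσ| ≤ 150 ppm, δ_iso within ±20 ppm, line widths in
  [5, 3000] Hz, ε in [0, 1].
* **convergence** — relative residual change < 1e−8 or 500 iterations
  (unstated originally; fixed for reproducibility). Optional multi-start
  refits from seeded ±10% jittered initial values. A fit whose residual ends
  above its starting value is flagged diverged and returned as a partial
  result.

Under the study conditions (each characterized composition simulated from
its recovered parameter set with 1% Gaussian noise, stoichiometric weights,
glycerol ties on) the fit recovers anisotropies within 10% for |Δσ| ≥ 30 ppm
and within 50% for the small inositol-ring phosphates — the accuracy bands
quoted for the original tables. Bootstrap uncertainties are
residual-resampling refits; how the original ± values were derived is
unstated, so the bootstrap is a declared substitute, not a reconstruction.

# The synthetic-data generator

`generate_scenario()` emulates the experimental series for the fourteen
built-in compositions. It contains no lineshape physics of its own — at zero
noise its output is identical to `compose_spectrum()` — and it emits
machine-readable ground truth beside every spectrum.

Scenario defaults (chosen once; the four printed anchors are data, the rest
are synthetic):

* **Plateau truths at 10 °C** (2|S_CD|): POPC 0.47, POPC/Chol 0.81,
  POPC/Chol/PI 0.69, NER 0.73 (printed values); POPC/PI 0.42 ≈ MV1 0.42
  (MV1-like membranes are as disordered as POPC/PI), MV2 0.62 (between MV1
  and NER), and intermediate values for the remaining mixtures, preserving
  the qualitative ordering of the thermal plateau curves. Linear temperature
  trends: −0.004/°C for cholesterol-free fluid phases, −0.0015/°C for
  liquid-ordered (cholesterol-rich) systems, −0.002/°C for MV2.
* **Mid-chain profile**: k = 11…15 at 0.96/0.88/0.76/0.62/0.46 of the
  plateau splitting and CD₃ at 0.125 — synthetic defaults shaped like a
  fluid-phase order profile; per-position truths are only shown graphically
  in the source and are never cited as measured values.
* **Gel/fluid coexistence** near T_m ≈ −5 °C (POPC-like systems): a convex
  combination in which the gel phase is approximated by a broad axially
  symmetric envelope of 120 kHz 90°-edge width (weight 28/31) plus a gel
  methyl doublet at 11.8 kHz (weight 3/31, 300 Hz wide), so that at equal
  phase fractions the two central doublets carry near-equal areas. The true
  gel-phase (L_β′) lineshape is axially *asymmetric*; this envelope is an
  admitted approximation — only the width is constrained by the source.
  The default gel fraction follows a sigmoid of width 1.5 °C centred on T_m.
* **Contaminant and noise**: a sharp isotropic line (zero-anisotropy
  component, default 2% weight, always < 5%) models the small vesicles seen
  in the samples; noise is i.i.d. Gaussian with σ relative to the maximum
  intensity (default 1% — unstated originally, fixed here). All randomness
  derives deterministically from the mandatory scenario seed; identical
  spec + seed reproduces output files byte for byte.

What passing the synthetic round trips does *not* show: the generator's
fluid-phase profile, temperature slopes and gel envelope are idealized, so
recovery of its truths demonstrates the correctness and calibration of the
analysis chain, not the biological contrasts themselves; those enter only
through the printed anchor values.

# Problem sizes and runtime choices

Default grids are 2048 points over ±150 kHz (²H) and 1024 points over
−70…+40 ppm (³¹P); the de-Pake splitting grid caps at 400 columns (about
0.3 kHz resolution, refined below the grid step by parabolic interpolation).
These sizes keep every stage interactive on a single core while leaving the
round-trip tolerances (2% on splittings, ±0.02 on plateau 2|S_CD|) limited
by the method, not the discretization. The Monte Carlo oracle in the tests
uses 4×10⁶ orientations on a 256-point comparison grid, where sampling noise
contributes ≈0.5% L1.

# Known limitations

* Only axially symmetric tensors: no η ≠ 0 gel-phase fitting, no
  hexagonal/cubic/micellar lineshapes (the characterized samples are
  lamellar + a small isotropic line).
* The deformation family and the de-Pakeing variant are contract-equivalent
  stand-ins for unpublished originals; recovered ε values are comparable
  within this package only.
* De-Pakeing assumes a powder (fully orientationally averaged) sample on a
  uniform grid; partially oriented samples are out of scope.
* Time-domain processing (phasing, FT, vendor formats) is out of scope;
  inputs are frequency-domain two-column text spectra with JSON sidecars.
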