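---
title: "Determining the effective point of measurement of plane-parallel chambers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the effective point of measurement of plane-parallel chambers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epomfit)
```

## The problem

Electron-beam dosimetry protocols place the measurement point of a
plane-parallel ionization chamber at the inner surface of its entrance
window.  In reality the depth at which the chamber's reading best
represents dose to water — its *effective point of measurement* (EPOM) —
sits a fraction of a millimetre deeper, inside the air cavity, because the
wall and replacement perturbations vary with depth.  Using the nominal
point therefore distorts measured percentage depth-dose (PDD) curves and
adds avoidable uncertainty near the reference depth.

`epomfit` estimates the EPOM shift $\Delta z$ experimentally: it compares
the chamber's depth-ionization scan against a reference PDD measured with
an (effectively) energy-independent detector such as a synthetic diamond,
and finds the shift that makes the two agree best.

## The estimator

The chamber curve $\bar D_{\mathrm{det}}(z)$ (corrected for recombination
and polarity, see below) is converted to dose through the water/air
Spencer–Attix stopping-power ratio $\bar s_{w,\mathrm{air}}(z, R_{50})$ and
compared with the reference PDD $D_w$ sampled at the shifted depth:

$$\mathrm{rms}(\Delta z)^2 \;=\; \frac{1}{n} \sum_{i=1}^{n}
  \Bigl[\, D_w(z_i + \Delta z) \;-\;
  \bar s_{w,\mathrm{air}}(z^{*}, R_{50}) \, \bar D_{\mathrm{det}}(z_i)
  \,\Bigr]^2 ,$$

minimized over a regular grid of candidate shifts (default $-0.10$ to
$+0.20$ cm in steps of $0.01$ cm, which brackets every published
plane-parallel shift).  A positive $\Delta z$ moves the EPOM from the
entrance window toward the cavity, i.e. deeper.  `fit_epom()` returns the
argmin together with the full $(\Delta z, \mathrm{rms})$ grid for
diagnostics.

Evaluation points are the chamber's nominal scan depths from 0.1 cm below
the surface down to $z/R_{50} = 1.2$; beyond that the bremsstrahlung tail
dominates and the stopping-power parameterization is no longer valid.

### Choices the printed equation leaves open

Two conventions are genuinely ambiguous in this class of analysis, so both
are implemented and switchable in `epom_config()`; the fitted object
records which was used.

* **Stopping-power depth argument** `sp_convention`: the ratio can be
  evaluated at the effective depth $z^{*} = z_i + \Delta z$ (`"shifted"`,
  the default — the ratio should reflect the electron spectrum at the
  point the reading actually represents) or at the nominal depth $z_i$
  (`"nominal"`, equivalent to converting the PDI once before fitting).
  The practical difference is tiny: the ratio changes by less than about
  0.4% over a 0.1 cm shift and renormalization absorbs most of that.  On
  a 0.001 cm probe grid the mismatch moves the optimum by 0 (at
  $R_{50} = 2.4$–5 cm) to about 0.001 cm (at $R_{50} = 8.8$ cm) — well
  below the 0.01 cm reporting resolution, but it grows with beam quality,
  which is why the convention is recorded rather than silently fixed.
* **Amplitude matching** `amplitude`: both curves normalized to 100 at
  their maximum (`"normalize_max"`, the standard relative-dosimetry
  convention and the default) or a per-shift least-squares scale factor
  (`"fit_scale"`), which avoids pinning the comparison to a single noisy
  point.

Two further numerical choices: the evaluation set is held fixed across the
whole shift grid (the intersection of the windows valid for every
candidate $\Delta z$), so $n$ is constant and the grid values are directly
comparable; and exact ties in the minimum break toward the smallest
$|\Delta z|$ — the null hypothesis of no shift.  No sub-grid refinement of
the minimum is performed: the method's resolution *is* the grid.

## Physics inputs

* **Stopping-power ratio.** The rational-function fit of
  $\bar s_{w,\mathrm{air}}$ in $\ln R_{50}$ and $z/R_{50}$
  (`burns_coefficients()`), strictly enforced on its validity window
  $0.02 \le z/R_{50} \le 1.2$.  Because transcription of eight published
  coefficients is typo-prone, the test suite gates them against an
  independently published closed-form fit of the ratio at the reference
  depth $z_{\mathrm{ref}} = 0.6 R_{50} - 0.1$ cm; the two agree to better
  than 0.25% over $R_{50} = 2.40$–$8.82$ cm.
* **Beam quality.** $R_{50}$ is taken from the reference dose curve by
  monotone-cubic interpolation and root finding (`compute_r50()`).  For
  ionization-only data, `r50_from_ionization()` iterates
  conversion → re-extraction from the protocol's $I_{50}$ starting value
  until the change is below 0.001 cm.
* **Ion recombination and polarity.** Depth-wise TRS-398-style
  corrections: $k_{\mathrm{pol}} = (|M_+| + |M_-|)/(2|M|)$ and the pulsed-beam
  two-voltage quadratic $k_s = a_0 + a_1 (M_1/M_2) + a_2 (M_1/M_2)^2$ with
  tabulated coefficients for $V_1/V_2 \in \{2, 2.5, 3, 3.5, 4, 5\}$ (each
  row sums to 1 within 0.001, asserted as a transcription gate).  Applied
  multiplicatively to the operating-voltage reading; a depth-*independent*
  correction provably never changes a normalized curve, hence never the
  fitted shift.

## Scan handling

Depth scans are resampled with monotone shape-preserving piecewise cubics
(Fritsch–Carlson), which are exact at the knots and cannot overshoot on
the steep distal falloff — an ordinary cubic spline rings there.
Extrapolation is always refused.  Multi-session curves are averaged
pointwise on the union of their grids restricted to the common depth
interval; how sessions on slightly different grids should be aligned is
not standardized, and this union-grid choice is flagged to users here.

## The synthetic generator

Because water-tank measurements cannot ship with a package, every stage is
validated against simulated scans with known truth.  The reference PDD is
a documented analytic family — smooth build-up from
`surface_frac`·100 at the surface to 100 at `zmax`, a gently rounded
quadratic shoulder, a logistic distal falloff calibrated to cross exactly
50 at `r50`, and a small tail beyond the practical range `rp` — *not* a
Monte Carlo surrogate: what the tests need is controllable truth, not
physical fidelity.  The chamber scan inverts the analysis chain exactly:
the ideal signal is $D_{\mathrm{ref}}(z + \Delta z_{\mathrm{true}}) /
\bar s_{w,\mathrm{air}}$, the raw two-voltage and polarity channels are
constructed so the corrections invert them identically, and 0.3%
multiplicative Gaussian noise per channel (a typical scanning-system
repeatability) is added under a recorded seed.

The default study design mirrors a full experimental campaign: three
chamber types × three serial numbers × four energies (6, 12, 18, 22 MeV
at $R_{50}$ = 2.40, 4.97, 7.37, 8.82 cm; the extremes anchor the validated
range, the middle two are typical clinical values) × three sessions,
scanned at the 0.1 cm tank step with the reference sampled at 0.02 cm.
The true type-level shifts default to the established experimental values
0.104, 0.040 and 0.012 cm for NACP-02, Roos and Advanced Markus, with
energy spreads 0.026/0.020/0.021 cm (minimum at 6 MeV, maximum at 18 MeV)
and serial-to-serial SD 0.005 cm — a realistic manufacturing-scale
variation.  The two-voltage ratio defaults to $V_1/V_2 = 2$; that value is
an assumption, not a measured setting.

What the generator does **not** emulate: setup/positioning depth offsets
between sessions (available as independent noise only), detector volume
averaging, beam-output drift, and the real low-energy shoulder curvature.
The last one matters for one derived quantity: real 6 MeV beams have the
steepest PDD around $z_{\mathrm{ref}}$, so the dose impact of the shift,
$|PDD(z_{\mathrm{ref}} + \Delta z) - PDD(z_{\mathrm{ref}})|$, peaks at the
lowest energy (published maximum ≈ 0.3 percentage points).  The analytic
family's shoulder curvature scales with $R_{50}$, so in the synthetic
study that impact peaks at the *highest* energy instead (≈ 0.17 points)
while still respecting the 0.3-point bound.  Passing tests therefore
demonstrate correct estimation machinery, not beam realism.

## What the tests establish

* The grid argmin equals an independent brute-force enumeration of the
  objective on randomized synthetic cases.
* Noise-free recovery of any true shift is exact up to grid quantization
  (≤ 0.005 cm); at 0.5% channel noise the mean absolute error stays below
  0.02 cm (about 0.005 cm in practice), consistent with the ≈ 0.015 cm
  uncertainty scale of experimental determinations.
* The correction step inverts the generator's raw-signal construction to
  1e-10 relative, and the full study pipeline recovers type-level mean
  shifts within 0.01 cm.

Problem sizes (a 12 MeV-like beam for recovery runs, 20 replicates per
noise point, 36 scan groups per study) keep the whole suite and the
acceptance run within a few seconds while leaving the statistics
comfortably clear of their tolerances.

## Worked example

```{r example}
beam <- synthetic_beam(r50 = 4.97)
ref  <- make_reference_pdd(beam, seq(0, round(1.3 * beam$rp, 2), by = 0.02))
truth <- synthetic_truth(dz_true = 0.10, noise_sigma = 0.003, seed = 42)
raw  <- make_chamber_scan(ref, truth, beam)
det  <- correct_scan(raw)$curve
fit  <- fit_epom(ref, det)
summary(fit)
```

```{r plot, fig.width = 5, fig.height = 4}
plot(fit)
```

## Known limitations

* Only the two shipped scan dialects are read; vendor binary formats are
  out of scope.
* The stopping-power parameterization is the package's single conversion
  model; alternative fits can be supplied via `sp_fun`, but no Monte Carlo
  stopping powers are computed.
* Chamber geometry (including the NACP-02 entrance-window variants in
  `nacp02_window_models()`) is reference data only — nothing is simulated
  from it, and the known uncertainty in that chamber's actual window build
  means type-level shifts for it should be applied with care.
* The uncertainty reported for a study is the dispersion of fitted shifts
  (sample SD); no full uncertainty budget is attempted.
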