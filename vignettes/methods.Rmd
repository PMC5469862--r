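---
title: "Quantifying transcellular ion transport from the Raman water band"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcellular ion transport from the Raman water band}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanion)
```

## The measurement model

Confocal Raman micro-spectroscopy of hydrated samples shows a strong,
structured O-H stretching envelope between roughly 2400 and 4200 cm⁻¹.
The envelope is modelled as a sum of five sub-bands, one per
hydrogen-bond cluster class of liquid water — DAA (3016 cm⁻¹),
DDAA (3221 cm⁻¹), DA (3429 cm⁻¹), DDA (3572 cm⁻¹) and free O-H
(3636 cm⁻¹), where D and A count donor and acceptor hydrogen bonds.
Dissolved ions shift population between the fully tetrahedral DDAA
cluster and the partially bonded DA cluster: structure-breaking solutes
(Cl⁻, HCO₃⁻, Hepes, glucose, proteins) raise the DA population,
structure makers (Mg²⁺, Ca²⁺) raise DDAA. The band-area ratio

$$r = \frac{I_{DA}}{I_{DDAA}}$$

is therefore an *ionic-activity index*: in the millimolar range it
varies linearly with solute concentration, $r(c) = r_0 + s\,c$, with a
per-solute slope $s$. Differencing $r$ between treated and untreated
cells at matched depth cancels $r_0$ and everything cellular that does
not change, so a depth profile $\Delta r(z)$ converts directly into a
concentration-change profile $\Delta[\mathrm{Na}^+](z) = \Delta r(z)/s_{\mathrm{NaCl}}$
(electroneutrality makes the chloride change equal).

Three derived quantities summarise transport across a cell of thickness
$t$:

1. mean concentration change
   $\overline{\Delta[\mathrm{Na}^+]} = \frac1t\int_0^t \Delta[\mathrm{Na}^+](z)\,dz$,
   evaluated analytically for the fitted line as intercept + slope·t/2;
2. Fick's-first-law flux
   $\Delta J_{\mathrm{Na}} = -D_{\mathrm{Na}}\,\mathrm{d}\Delta[\mathrm{Na}^+]/\mathrm{d}z$,
   with the derivative taken in a coordinate frame whose z axis points
   from the apical to the basolateral surface;
3. the equivalent short-circuit current
   $\Delta I_{sc} = \Delta J_{\mathrm{Na}} \times F$.

The package stores all depth data in *instrument* coordinates (z = 0 at
the permeable support, increasing toward the apical side, the order in
which a z-scan is acquired) and applies the sign flip of the flux
convention inside `sodium_flux()` only. With the slope in mM µm⁻¹ and
$D$ in cm² s⁻¹, the unit conversion is 1 mM µm⁻¹ = 10⁻² mol cm⁻⁴, so
`sodium_flux(g, D)` returns `D * g * 1e-2` in mol s⁻¹ cm⁻².

`transport_constants()` fixes $D_{\mathrm{Na}} = 1.33\times10^{-8}$
cm² s⁻¹ and $F = 96485.332$ C mol⁻¹. This $D_{\mathrm{Na}}$ is a few
orders of magnitude below free-water sodium diffusivities; it should be
read as an effective intracellular mobility, and both constants are
arguments wherever they are used.

## Spectral processing

Each spectrum passes through three stages.

**Linear baseline.** `subtract_baseline()` fits a straight line to the
anchor windows 2400–2500 and 4100–4200 cm⁻¹ (the flat tails of the
window) and subtracts it everywhere.

**Normalisation.** `normalize_total()` rescales to a total trapezoidal
integral of 100. The ratio r is invariant under any positive rescaling;
normalisation matters only for comparing band tables across spectra.

**Constrained pseudo-Voigt deconvolution.** Bands are pseudo-Voigt
profiles — a linear Gaussian–Lorentzian mix with Lorentzian fraction
η ∈ [0, 1] — parameterised by integrated area rather than peak height,
because the sub-bands overlap heavily and areas are far more robust to
shape uncertainty than amplitudes. In the `"cell"` context the five O-H
bands are joined by the C-H stretching bands of lipids and proteins
(2855, 2874, 2900, 2933 cm⁻¹) and the aromatic C-H bands of the
polycarbonate culture substrate (2980, 3000, 3072 cm⁻¹), all fitted
simultaneously so that substrate overlap near z = 0 is separated rather
than ignored. The solver is Levenberg–Marquardt (`minpack.lm`) with an
analytic Jacobian, box constraints (areas ≥ 0, centres within ±30 cm⁻¹
of their reference positions — tightened to 45% of the gap to the
nearest neighbour so crowded C-H bands cannot swap — widths within
20–400 cm⁻¹ for O-H and 10–120 cm⁻¹ for C-H bands), and up to three
seeded jittered restarts on non-convergence.

Two numerical choices deserve emphasis because they decide whether r is
measurable at all:

* **Free shapes are not identifiable.** With centres, widths and shape
  fractions of five strongly overlapping bands all free, the Fisher
  information matrix of the model is numerically singular at the
  generating parameters: there are near-flat parameter directions along
  which width/η/area trade off with almost no change in the spectrum.
  Empirically this shows up as replicate r scatter of ±0.1–0.2 at 0.5%
  noise, larger than every biological effect of interest, while the
  Cramér–Rao bound with *fixed* shapes is ≈0.001. `deconvolve()`
  therefore has two modes: `shape = "free"` for calibrating band shapes
  on high signal-to-noise reference spectra (at zero noise it recovers
  the generating parameter vector to machine precision), and
  `shape = "fixed"` — an areas-only fit with shapes held at the
  reference (or previously fitted) values — which is the default for
  every quantitative r estimate (`spectrum_r()`, `process_zscan()`,
  `series_r_values()`). The fixed-shape problem is almost linear, well
  conditioned, unbiased in simulation, and ~100× faster.
* **Residual baseline term.** The anchor windows inevitably contain
  Lorentzian band tails, so the subtracted "baseline" removes a little
  genuine signal. A free linear offset inside the fit model absorbs
  this; without it the non-negativity constraints force a shape
  distortion that biases r by up to −0.18 even on noiseless data.

Along a z-scan the fits are warm-started from the previous depth
(processed top-down, starting in near-pure buffer), which is both faster
and keeps the solver in the physically relevant basin.

## Calibration and mixtures

`fit_series()` regresses all replicate r values (not concentration
means) on concentration — with 20 replicates per concentration this uses
the full design and yields honest slope standard errors.
`compare_slopes()` tests slope equality of two solutes through the
interaction term of the pooled model `r ~ c * group`, the classical
ANCOVA formulation. `predict_mixture_r()` implements additivity as
*one* shared pure-water intercept plus the sum of slope × concentration
contributions; naively summing per-component r values would count the
water intercept once per solute. `delta_r_to_concentration()` inverts
the line for differences, where the intercept cancels.

Divalent chlorides can be calibrated against cation or chloride
concentration; the `axis` field records which, with cation the default.
Protein series are in mg/mL and the units never mix — slopes are always
"per unit of the axis the series was built on".

## Cell profiles, thickness and significance

`average_profiles()` averages per-cell r(z) profiles (5 cells per group
by default) pointwise. `estimate_thickness()` locates the apical
membrane as the smallest grid depth from which the mean profile stays
within 1% (relative) of the extracellular reference ratio 1.363 for all
larger depths. The pipeline takes the *control* group's estimate as the
cytosol bound for both groups: treatment raises r near the apical
membrane, and once blurred by the axial PSF that elevation delays the
apparent plateau by about one grid step, whereas the control crossing is
sharp; cell thickness itself is not altered by the treatment.

`delta_profile()` restricts to cytosolic depths (0 < z < t),
differences the group means, converts to mM, and attaches per-depth
two-sided unpaired t-tests (Student's pooled-variance form by default,
Welch via `var_equal = FALSE`) with significance marked at p ≤ 0.05.
P-values are reported raw across depths by default — `p_adjust` accepts
any `stats::p.adjust` method for readers who want, e.g.,
Benjamini–Hochberg — because the per-depth tests are descriptive
annotation of the profile, not a family of confirmatory claims.

`fit_gradient()` fits the least-squares line of mean Δ[Na⁺] against z
over 1 µm ≤ z ≤ t − 1 µm. The 1 µm margins (configurable) exclude the
depths where the substrate bands dominate (z ≈ 0) and where the axial
PSF mixes in extracellular buffer (z ≈ t); both contaminations
attenuate Δr and would bias the slope toward zero. A constant profile
has an undefined Pearson correlation; it is reported as 0 with
`degenerate = TRUE`.

## What the synthetic generator does and does not emulate

The generator exists so that every downstream stage can be validated
against known ground truth. It emulates:

* spectra on a 2400–4200 cm⁻¹ grid at 1 cm⁻¹ spacing, built from the
  twelve reference bands, with a linear instrument baseline and additive
  Gaussian noise whose SD is a fraction of the spectrum maximum
  (default 0.5%);
* calibration series per solute (the standard concentration ladders,
  20 replicates each) with generating slopes ordered like the measured
  chemistry: NaCl ≡ KCl; MgCl₂ ≡ CaCl₂ per cation (half per chloride);
  NaHCO₃ weakest; Hepes, glucose and protein strongest. The shared
  intercept is chosen so the isotonic buffer (120 mM NaCl, 3.5 mM KCl,
  1 mM CaCl₂, 1 mM MgCl₂, 5 mM glucose, 10 mM Hepes) lands at exactly
  r = 1.363, which doubles as the extracellular reference;
* 0–30 µm z-scans at 1 µm steps: a control cytosolic r ramp from 1.45
  (basolateral) to 1.38 (apical) across a 15 µm cell, the extracellular
  plateau above, polycarbonate bands visible within the PSF reach of
  z = 0, lipid/protein bands inside the cell, and — for treated cells —
  a superposed linear Δ[Na⁺](z) from −6.725 mM at the support to
  +15.3 mM at the apical membrane (slope +1.47 mM µm⁻¹ in instrument
  coordinates). Every ideal profile is convolved along z with a
  Gaussian PSF of 1.14 µm FWHM before spectra are synthesised.

Band widths, shape fractions and absolute areas are conventions chosen
to make a realistic-looking envelope (O-H widths 90–230 cm⁻¹, C-H
widths 30–45 cm⁻¹, η ≈ 0.2–0.25); no published values exist for them,
and the recovery tests are meaningful for any similar setting. The
generator is phenomenological: no Raman cross-sections, no light
transport, no lateral imaging, no cosmic rays or detector etaloning, no
fluorescence background beyond a straight line. Passing recovery tests
therefore demonstrate that the *pipeline* is correct and
well-conditioned under the stated noise model — not that real cellular
spectra meet that model.

## Problem sizes and reproducibility

The validation suite runs the full chain at the design sizes: 20
replicate in-silico experiments of 5 cells per group × 31 depths, 500
simulations for the type-I-error and p-value-uniformity checks, and
20-replicate calibration series for all six buffer solutes. All
randomness flows through explicit integer seeds (`with_seed` restores
the RNG state, so library calls never perturb a session), and identical
seeds reproduce spectra bit-for-bit. Under these conditions the
pipeline recovers thickness exactly on the 1 µm grid, and gradient and
mean concentration change to within a few percent on average (worst
single experiments ≈ ±11%).

## Known limitations

* The fixed-shape quantification inherits any error in the calibrated
  band shapes; on real instruments the shape calibration should be
  repeated per optical configuration.
* The thickness estimator assumes the scan reaches a genuine
  extracellular plateau; scans truncated inside the cell raise an error
  rather than extrapolating.
* A single linear baseline is supported, matching flat-tailed windows;
  strongly fluorescent samples would need a polynomial background model
  that the package deliberately does not provide.
* The flux conversion treats the fitted gradient as spatially constant
  and purely diffusive; $D_{\mathrm{Na}}$ is an effective parameter and
  the resulting current is an order-of-magnitude-faithful equivalent,
  not an electrophysiological measurement.
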