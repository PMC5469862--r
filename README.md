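# ramanion

Quantifies transcellular Na⁺ transport in epithelial cell monolayers from
confocal Raman micro-spectroscopy, for cell physiologists who want ion-flux
estimates without electrodes.

Raman spectra of hydrated samples carry a broad water O-H stretching
envelope (2400–4200 cm⁻¹) composed of sub-bands from the hydrogen-bond
cluster classes of liquid water: DAA, DDAA, DA, DDA and free O-H at 3016,
3221, 3429, 3572 and 3636 cm⁻¹. Dissolved ions repartition these clusters,
so the band-area ratio

    r = I_DA / I_DDAA

acts as an ionic-activity index that is linear in solute concentration in
the millimolar range, `r(c) = r₀ + s·c`. The package:

* deconvolves spectra into constrained pseudo-Voigt bands
  (`subtract_baseline()`, `normalize_total()`, `deconvolve()`,
  `compute_r()`), including the lipid/protein and polycarbonate-substrate
  C-H bands that overlap the water envelope in cell scans;
* calibrates r per solute and compares slopes via the ANCOVA interaction
  term (`fit_series()`, `compare_slopes()`), predicts multi-solute
  mixtures by slope additivity (`predict_mixture_r()`), and inverts Δr to
  concentration changes (`delta_r_to_concentration()`);
* builds depth profiles r(z) of treated vs. untreated cells, locates the
  apical membrane from the extracellular plateau, and differences the
  groups with per-depth unpaired t-tests (`process_zscan()`,
  `average_profiles()`, `estimate_thickness()`, `delta_profile()`);
* converts the fitted Δ[Na⁺](z) gradient (mM µm⁻¹) into a mean
  concentration change (`mean_concentration_change()`), a Fick's-law flux
  `ΔJ_Na = −D_Na · dΔ[Na⁺]/dz` (`sodium_flux()`) and an equivalent
  short-circuit current `ΔI_sc = ΔJ_Na · F` (`short_circuit_current()`);
* generates synthetic spectra, calibration series and cell z-scans with
  known ground truth (`make_water_spectrum()`, `make_calibration_series()`,
  `make_cell_zscan()`), including an axial Gaussian PSF of 1.14 µm FWHM,
  so the whole chain is testable end to end.

## Worked example

```r
library(ramanion)

# a noisy synthetic solution spectrum with known ratio 1.45
s   <- make_water_spectrum(1.45, synth_config(noise_sd = 0.005), seed = 42)
fit <- deconvolve(normalize_total(subtract_baseline(s)), "solution")
compute_r(fit)
#> r = I_DA/I_DDAA = 1.4512

# calibrate r against NaCl concentration (4 concentrations x 20 replicates)
vals <- series_r_values(make_calibration_series("NaCl", seed = 1))
fit_series(vals, solute = "NaCl")
#> Calibration NaCl: r = 1.2073 + 1.003e-03 * c  (slope SE 2.8e-06, R2 0.9994, n 80)
```

The fitted ratio reproduces the generating 1.45 to three decimals, and the
calibration recovers the generating slope 1.0e-03 per mM within its
standard error. A full treated-vs-control experiment runs through
`run_pipeline()` (or the `profile` subcommand of
`inst/scripts/ramanion-cli.R`), which reports cell thickness, the
intracellular Δ[Na⁺] gradient with its Pearson correlation, the mean
concentration change, ΔJ_Na and ΔI_sc.

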