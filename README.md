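# pcdpileup

Simulation and small-signal analysis of energy-resolving photon-counting
X-ray detectors (PCDs) under pile-up.

At clinical fluence rates (up to ~10⁹ mm⁻²s⁻¹) the pulses of a PCD
overlap and the registered counts per energy bin stop being proportional
to the incident fluence: the detector is a non-linear system, and
linear-system tools (PSF, MTF, DQE) no longer apply as-is. This package
analyzes a PCD the way electrical engineers analyze non-linear circuits:
it linearizes the response around an **operating point** — the incident
spectral fluence rate Φ̇_op — and characterizes the linearized system by
the **perturbation point spread function (pPSF)**

    d_k(n, Φ̇_op + ΔΦ̇ⁿ⁰) − d_k(Φ̇_op) = Σ_l h_kΔ(n − n₀, Φ̇_op, E_l) · ΔΦ̇_El · A,

the change in count rate of energy bin *k* at pixel offset *n − n₀* per
incident probe photon of energy *E_l* on pixel *n₀* (pixel area *A*).
Unlike an ordinary PSF, *h* can be **negative**: under pile-up an extra
photon removes counts from low bins while promoting them into bins above
the highest incident energy. From the pPSF the package derives the
contrast `C_k = Σ_l h·A·ΔΦ̇_l / d_k` and contrast-to-noise ratio of a
small lesion, exposing pile-up effects such as contrast cancellation and
inversion between energy bins.

It is intended for detector physicists and medical-imaging researchers
who want to study spectral/spatial PCD performance at realistic rates
without a full particle-transport stack.

## What is inside

* **Physics data** — bundled elemental cross-section tables (1–300 keV,
  photoelectric/incoherent/coherent, K edges, fluorescence yields and
  lines), mixture rules, Beer–Lambert transmission.
* **Spectra** — parametric tungsten-anode tube model with filtration, the
  RQA9 reference beam (120 kVp, HVL-calibrated), half-value layers,
  sensor thickness matching, lesion perturbations.
* **Detector models** — presets `"iDCD-CZT"` (2 mm CZT, Gaussian 14 ns
  pulse, 8.0% FWHM @ 59.5 keV) and `"iICD-LaBr3"` (2.8 mm LaBr3:Ce with
  PTFE reflector septa, bi-exponential 16/7 ns pulse, 22.3% FWHM), with
  timing windows derived from the pulse shape (51/11 ns and 24/13 ns).
* **Transport** — simplified Monte-Carlo energy deposition in the pixel
  array: absorption, K-fluorescence escape/crosstalk, Compton crosstalk,
  reflector dead area.
* **Pulse trains and counting** — 1 ns sampled waveforms with energy
  blurring; paralyzable-like (P) and non-paralyzable-like (NP) counting
  with trigger threshold and peak detection; 1 keV bins 20–250 keV.
* **pPSF estimation** — paired simulations with a common operating-beam
  realization (`estimate_ppsf()`, with `print`/`summary`/`plot`/
  `predict` methods), plus contrast/CNR metrics and a direct two-run
  cross-check.

## Worked example

Estimate the pPSF of the CZT detector at an operating point of
10⁷ mm⁻²s⁻¹ (RQA9 spectrum) and predict the contrast of a thin iodine
lesion (ρ·x = 7·10⁻⁴ g/cm²):

```r
library(pcdpileup)

det <- detector_preset("iDCD-CZT", behavior = "NP")
op  <- rqa9_spectrum(total_rate = 1e7)

pp <- estimate_ppsf(det, op, probe_energies = seq(20, 150, 10),
                    probe_rate = 5e5, duration = 2e7, seed = 1)
pp
#> <pPSF> iDCD-CZT ( NP counting )
#>   operating point: 1e+07 mm^-2 s^-1;  probe: 5e+05 mm^-2 s^-1 over 14 energies
#>   bins: 231  pixels: 5x5  duration: 2e+07 ns in 16 sections

ct <- predict(pp, lesion_perturbation(op, lesion_spec()))
ct <- cnr(ct, pp$baseline$sectioned)
```

Selected bins of the result:

```
  bin_keV  contrast      cnr
1      40 -0.001750 -0.00758
2      60 -0.002110 -0.01610
3      80 -0.000936 -0.00571
4     100 -0.000602 -0.00280
5     120 -0.000659 -0.00130
6     140 -0.002230 -0.00279
```

At this moderate rate every bin shows negative contrast (the lesion
removes fluence), and bins *above* the highest incident energy (140 keV >
120 kVp endpoint) respond more strongly per count than mid-spectrum bins
— they are fed exclusively by pile-up, which the lesion suppresses. At
10⁸ mm⁻²s⁻¹ and above, the contrast starts switching sign across bins;
`rebin_macro()` shows how realistic tens-of-keV bins then cancel or
invert contrast.

`run_pipeline()` drives the whole chain (spectrum → baseline → pPSF →
contrast/CNR) from one config list and persists every artifact with its
seeds.

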