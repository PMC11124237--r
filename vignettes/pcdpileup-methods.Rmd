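---
title: "Simulating photon-counting detectors under pile-up: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photon-counting detectors under pile-up: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdpileup)
```

# The problem

Energy-resolving photon-counting detectors (PCDs) sort individual X-ray
pulses into energy bins. At clinical fluence rates — up to around
$10^9\ \mathrm{mm^{-2}s^{-1}}$ — pulses overlap (*pile-up*) and the
registered counts are no longer proportional to the incident fluence: the
detector is a non-linear system, and classic linear-system measures (PSF,
MTF, DQE) do not apply directly.

`pcdpileup` treats the PCD as a non-linear system *linearized around an
operating point*. The operating point is the incident spectral fluence
rate $\dot\Phi_{op} = (\dot\Phi_{E_1},\dots,\dot\Phi_{E_L})$ (photons
mm$^{-2}$ s$^{-1}$ per 1 keV channel). A small perturbation
$\Delta\dot\Phi$ applied to one pixel $n_0$ changes the registered count
rate $d_k$ in bin $k$ of pixel $n$ by

$$ d_k(n, \dot\Phi_{op} + \Delta\dot\Phi^{n_0}) - d_k(\dot\Phi_{op})
   = \sum_l h_{k\Delta}(n - n_0, \dot\Phi_{op}, E_l)\,
     \Delta\dot\Phi_{E_l}\, A, $$

which defines the **perturbation point spread function (pPSF)**
$h_{k\Delta}$: counts added (or, under pile-up, *removed*) per incident
probe photon of energy $E_l$, per bin and pixel offset. At zero operating
rate the pPSF reduces to the ordinary detector response; at high rates it
acquires negative entries because an extra photon piles up with operating
beam pulses, promoting counts out of low bins into high ones.

The package estimates $h_{k\Delta}$ by simulation (`estimate_ppsf()`),
and uses it to predict the contrast $C_k = \sum_l h\, A\,
\Delta\dot\Phi_l / d_k$ and contrast-to-noise ratio of a thin lesion
(`contrast_smallsignal()`, `cnr()`), cross-checked against a direct
two-run simulation (`contrast_direct_mc()`).

# The simulation chain

The chain is the synthetic-data generator of the package; its defaults
*are* the study conditions.

**Operating spectrum.** A Kramers bremsstrahlung shape
$\dot\Phi_E \propto (E_{kVp}-E)/E$ with tungsten K lines (57.98, 59.32,
67.24, 69.07 keV; 8% of the self-filtered continuum fluence), hardened by
an aluminium-equivalent anode self-filtration and a filtration stack. The
RQA9 beam (`rqa9_spectrum()`) uses 120 kVp, 0.8 mm Be + 0.10 mm Cu
intrinsic filtration and 40 mm added Al. The self-filtration
(6.73 mm Al-equivalent) was calibrated once so the generated RQA9 beam
reproduces the nominal first half-value layer of 11.6 mm Al — the
criterion the RQA series is defined by; it is larger than a physical
tube's inherent filtration because the Kramers shape overestimates the
soft continuum. The resulting fluence-weighted mean energy is 78 keV.
(A value of 63 keV is sometimes quoted for this beam; that is
incompatible with the 11.6 mm Al HVL — a monoenergetic 63 keV beam has an
HVL near 9.6 mm Al — and a spectrum consistent with the nominal beam
quality necessarily has its mean near or above the ~73 keV effective
energy.)

**Cross sections.** Bundled per-element tables, 1–300 keV
(`inst/extdata/attenuation/`): photoelectric from Cromer–Liberman $f''$,
incoherent from the free-electron Klein–Nishina cross section, coherent
from the Thomson cross section weighted by the squared IT92 atomic form
factor (constant term damped hydrogenically). Totals agree with standard
reference tables to about 2% over 30–150 keV for the materials used here.
Interpolation is log–log, with the grid split at K edges. K-shell data
(edges, fluorescence yields, K$\alpha_{1,2}$/K$\beta_1$ lines, and the
K-shell photoelectric fraction from the edge jump ratio) are bundled
alongside.

**Transport.** A deliberately simplified Monte-Carlo keeps exactly the
effects the pPSF analysis relies on: exponential interaction depths from
the total attenuation coefficient; photoelectric absorption with single
K-fluorescence emission (the K photon makes one isotropic exponential
flight and deposits fully or escapes); Klein–Nishina Compton scattering,
recursed to depth 5, then forced to absorb or escape on one final flight.
Coherent scattering deposits no energy and is not tracked; its cross
section is effectively redistributed over the two depositing processes so
that the interacting fraction still follows the total Beer–Lambert law.
Electron range is zero (no charge sharing) and optical transport is
omitted (no light leakage between scintillator pixels), so pixel
crosstalk stems from fluorescence and scatter alone. For the
indirect-conversion preset, primaries entering the 60 μm PTFE reflector
footprint deposit nothing (reduced geometric efficiency); secondary
photons crossing septa are not attenuated. Deposits of one primary in one
pixel are merged before blurring — they are simultaneous at ns scale, and
merging first means the resolution blur acts once on the summed energy.

**Pulse train.** Each merged deposit of blurred energy $E_i$ at time
$t_i$ contributes $E_i\,p(t-t_i)$ on a 1 ns grid, with $p$ a unit-peak
pulse: Gaussian (14 ns FWHM) for the CZT preset, bi-exponential
$e^{-t/16\,\mathrm{ns}} - e^{-t/7\,\mathrm{ns}}$ for the LaBr3:Ce/SiPM
preset. The event time marks the pulse *onset*; pulses are evaluated
analytically at grid points (no FFT wrap-around) and truncated below
$10^{-6}$ of peak. Energy resolution is Gaussian with relative FWHM
$\propto E^{-1/2}$ (22.3% and 8.0% at 59.5 keV for the two presets); the
inverse-square-root reading of the energy dependence is the conventional
one for counting detectors.

**Counting.** Both behaviors trigger on upward crossings of a 20 keV
threshold (sample$[t-1]$ < thr ≤ sample$[t]$; ties count as above) and
register the maximum sample over the peak-detection time $\tau_{pd}$.
NP-like counting opens an analysis window $\tau_{np}$ per accepted
trigger (one count per window; crossings inside the window are ignored;
after it closes a fresh crossing — signal below threshold first — is
required). P-like counting yields one count per upward crossing, so a
sustained excursion paralyzes it. These retrigger semantics are fixed as
canonical here; they reproduce the one-count guarantee for an isolated
maximum-energy pulse and the classic limits $n/(1+n\tau)$ and
$n e^{-n\tau}$ on rectangular-pulse trains. Registered energies are
binned in 1 keV bins centered 20–250 keV; energies outside are
discarded.

**Timing windows.** $\tau_{np}$ is the time over threshold of the
largest pulse the beam can produce — amplitude $E_{max} +$ FWHM($E_{max}$)
to allow for upward blurring — and $\tau_{pd}$ the rising-crossing-to-peak
time, each rounded up to the next integer ns plus 1 ns ("slightly
larger"). For the two presets this yields (51, 11) ns and (24, 13) ns.
That margin rule reproduces all four published settings simultaneously,
which is why it is adopted as canonical.

# The pPSF estimator

For each probe energy (default 20–150 keV in 2 keV steps), the exposure
is simulated twice with a *bit-identical operating-beam realization* —
arrivals, energies, entry points, transport and blur draws all come from
named substreams of the master seed — once with and once without a
monoenergetic probe beam covering the full 500 μm pitch of the center
pixel. The pPSF follows from the paired difference divided by the
expected probe photon count. Common random numbers remove the shared
realization noise, so the estimator variance scales with the probe count,
not the (much larger) operating-beam count. Only pixels that receive
probe-related deposits are re-counted in the perturbed pass; the others
are provably unchanged. Standard errors come from section-wise
replication in time (default 16 sections).

The default probe rate is 5% of the operating rate, capped at
$10^6\ \mathrm{mm^{-2}s^{-1}}$ (floor $10^4$ at zero operating rate): the
probe must stay small against the operating beam for the linearization to
hold, while more probe photons mean smaller standard errors. The probe
can pile up with *itself* at a rate proportional to its own intensity,
which puts a floor on the estimator bias; at the default settings this is
below $10^{-3}$ per bin.

Independent-realization estimation (no pairing) is available by giving
the two runs different seeds; it is used in tests to confirm the paired
estimator is unbiased.

# Contrast, CNR and the direct cross-check

The lesion is an aqueous iodine solution (mass fractions I 0.2308,
O 0.6832, H 0.0861, normalized) with areal density
$\rho x = 7\times10^{-4}\ \mathrm{g/cm^2}$, chosen so the spectral change
$\Delta\dot\Phi_E = \dot\Phi_E (e^{-\mu(E)/\rho\,\cdot\,\rho x} - 1)$
stays below 1% in every channel that carries fluence — the small-signal
regime. Violations raise a warning and a flag rather than an error.

`contrast_smallsignal()` contracts the center-pixel pPSF with
$\Delta\dot\Phi$. The pPSF is linearly interpolated from the probe grid
onto the 1 keV spectrum grid; perturbation content below 20 keV is
truncated (below the trigger threshold, and the RQA9 beam carries
essentially nothing there). Bins with zero baseline are masked, not
dropped. Note the interpolation assumes $h$ varies smoothly in $E_l$ on
the probe-grid scale — true for the blurred presets, not for a
perfect-resolution detector, for which the probe grid must match the bin
grid.

`contrast_direct_mc()` estimates the same contrast without the
linearization: the baseline exposure is simulated once, and the lesion
exposure is obtained from the *same realization* by thinning — each
primary of energy $E$ survives with probability $e^{-\mu(E)/\rho\cdot\rho
x}$, which is exactly a Poisson process with the attenuated spectrum.
Agreement of the two estimators within combined Monte-Carlo error is the
framework's core validity check and is asserted in the test suite at
$10^6$ and $10^8\ \mathrm{mm^{-2}s^{-1}}$.

$\sigma(C_k)$ uses the per-section spread of the baseline counts,
$\sigma(C_k) = \mathrm{sd}(d_k)/\bar d_k$, the simplest reading of
"variance via the counts"; target-run variance is not added. Sections are
scaled inversely with fluence rate (`equal_dose_section()`) so CNR is
compared at equal dose. Macro-bin rebinning recomputes contrast from
summed numerators and denominators, which is what exposes cancellation
and inversion between micro-bins.

# Numerical and design choices

* Spectra live on a fixed 1 keV grid from 1 keV to the tube voltage;
  loaded tables are rebinned conservatively (nearest channel, total
  fluence preserved exactly).
* Bisection tolerances: $10^{-4}$ mm for half-value layers and thickness
  matching; sub-ns crossings in `derive_timing()` to $10^{-9}$ ns.
* Arrival times are continuous but rasterized to the 1 ns grid at
  synthesis (floor); the dead-time oracles therefore carry a ±1 ns
  slack per event in the tests.
* The paralyzable behavior at $10^9\ \mathrm{mm^{-2}s^{-1}}$ is not
  required to converge: the signal almost never falls below threshold,
  so P-like counts vanish and relative quantities become undefined.
* Probe photons keep their own primary ids offset by $10^9$ so that
  operating-beam and probe deposits can never merge into one event.
* All randomness derives from one master seed through named substreams;
  re-running any estimator with the same seed and arguments reproduces
  the result bit-identically.

# Problem sizes used by the test suite

The bundled tests run the full chain at reduced scale: exposures of
$2.4\times10^6$ ns at $10^8\ \mathrm{mm^{-2}s^{-1}}$ down to
$2\times10^8$ ns at $10^6$ (so each run sees roughly $1.5\times10^6$
operating-beam photons and 2000–3000 probe photons per probe energy), a
probe grid of 10 keV steps for contrast work, and 10–12 time sections.
These sizes were chosen so the statistical assertions have clear margins;
the estimators themselves accept arbitrary durations, grids and section
counts.

# What passing tests do and do not show

The generator emulates Poisson arrivals, energy-dependent absorption,
fluorescence escape and Compton crosstalk, finite energy resolution, and
two idealized counting chains. It does **not** emulate charge sharing or
charge summing, optical crosstalk, electronic noise, ADC quantization,
coherent-scatter crosstalk, or detector housing scatter. Passing tests
therefore validate the *framework* — the linearization, the estimator,
the counting semantics, the metrics — under a faithful but simplified
detector physics; they do not certify quantitative response predictions
for any physical detector. Deposit-spectrum agreement with full
particle-transport codes is likewise outside what the simplified
transport can promise, and quantities that depend on it (e.g. absolute
CNR ratios between the two presets) are deliberately not asserted.

# Known limitations

* Free-electron Klein–Nishina overestimates incoherent scattering below
  ~30 keV for high-Z sensors (no incoherent scattering function); the
  effect on totals is at the percent level where it matters here.
* The Kramers + Al-equivalent tube model reproduces the RQA9 beam
  quality (HVL) but not every spectral detail of a measured tube
  spectrum; quantities tied to fine spectral shape inherit that error.
* L-shell fluorescence and Doppler broadening are not modeled.
* Edge pixels of the 5×5 array lack incoming crosstalk from outside the
  array; baseline rates use the center pixel, and shift invariance
  across interior pixels is verified statistically in the tests.
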