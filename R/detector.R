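# Detector model configuration: geometry, energy resolution, pulse shapes,
# counting parameters, derived timing windows, and the geometric
# charge-sharing estimator.

#' Energy resolution model
#'
#' Relative FWHM follows an inverse-square-root law in energy:
#' `rel(E) = rel_ref * sqrt(E_ref / E)`.
#'
#' @param rel_fwhm relative FWHM (fraction) at the reference energy; 0 is
#'   allowed and means a perfect (noiseless) resolution.
#' @param ref_energy reference energy in keV (59.5, the Am-241 line).
#' @return an object of class `resolution_model`.
#' @export
resolution_model <- function(rel_fwhm, ref_energy = 59.5) {
  if (rel_fwhm < 0 || rel_fwhm >= 1) stop("rel_fwhm must be in [0, 1)")
  structure(list(rel_fwhm = rel_fwhm, ref_energy = ref_energy),
            class = "resolution_model")
}

#' FWHM of the energy response at a given energy
#'
#' @param resolution a `resolution_model`.
#' @param energy photon energy in keV (> 0, vectorized).
#' @param relative return the relative FWHM instead of keV.
#' @return absolute FWHM in keV (default) or relative FWHM.
#' @export
fwhm_at <- function(resolution, energy, relative = FALSE) {
  if (any(energy <= 0)) stop("energy must be positive")
  rel <- resolution$rel_fwhm * sqrt(resolution$ref_energy / energy)
  if (relative) rel else rel * energy
}

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # 2.3548

# -- pulse shapes ------------------------------------------------------------

# A pulse shape is unit-peak-normalized, defined for t >= 0 with t = 0 the
# pulse onset, and carries its sampled values on the 1 ns grid plus the
# analytic peak time. `support` is the first integer time beyond which the
# pulse stays below 1e-6 of its peak.

new_pulse_shape <- function(kind, params, fun, peak_time, support) {
  structure(list(kind = kind, params = params, fun = fun,
                 peak_time = peak_time, support = support,
                 samples = fun(seq(0, support))),
            class = "pulse_shape")
}

#' Gaussian pulse shape
#'
#' Centered so that the 1 ns sample grid hits the peak exactly; truncated
#' where below 1e-6 of the peak.
#'
#' @param fwhm_ns full width at half maximum in ns.
#' @return a `pulse_shape`.
#' @export
pulse_shape_gaussian <- function(fwhm_ns) {
  sigma <- fwhm_ns / FWHM_SIGMA
  half <- ceiling(sigma * sqrt(2 * log(1e6)))  # 1e-6 truncation half-width
  fun <- function(t) ifelse(t < 0 | t > 2 * half, 0,
                            exp(-(t - half)^2 / (2 * sigma^2)))
  new_pulse_shape("gaussian", list(fwhm_ns = fwhm_ns, sigma = sigma),
                  fun, peak_time = half, support = 2 * half)
}

#' Bi-exponential pulse shape
#'
#' `p(t) = exp(-t/tau_decay) - exp(-t/tau_recharge)` for `t >= 0`,
#' normalized to unit peak; models a scintillation decay read out through
#' an SiPM recharge.
#'
#' @param tau_decay_ns scintillation decay constant, ns.
#' @param tau_recharge_ns SiPM recharge constant, ns (must be smaller).
#' @return a `pulse_shape`.
#' @export
pulse_shape_biexponential <- function(tau_decay_ns, tau_recharge_ns) {
  ta <- tau_decay_ns; tb <- tau_recharge_ns
  if (tb >= ta) stop("recharge constant must be smaller than decay constant")
  tpeak <- log(ta / tb) / (1 / tb - 1 / ta)
  pmax_un <- exp(-tpeak / ta) - exp(-tpeak / tb)
  fun <- function(t) ifelse(t < 0, 0,
                            (exp(-t / ta) - exp(-t / tb)) / pmax_un)
  # tail is exp(-t/ta)/pmax_un; below 1e-6 after:
  support <- ceiling(-ta * log(1e-6 * pmax_un))
  new_pulse_shape("biexponential",
                  list(tau_decay_ns = ta, tau_recharge_ns = tb),
                  fun, peak_time = tpeak, support = support)
}

#' @export
print.pulse_shape <- function(x, ...) {
  cat("<pulse shape>", x$kind, " peak at", round(x$peak_time, 2),
      "ns, support", x$support, "ns\n")
  invisible(x)
}

#' Derive counting timing windows from the pulse shape
#'
#' The analysis-window length `tau_np` is chosen slightly larger than the
#' time over threshold (ToT) of the largest pulse the spectrum can produce:
#' amplitude `E* = E_max + FWHM(E_max)`, accounting for upward energy
#' blurring. The peak-detection time `tau_pd` is likewise slightly larger
#' than the interval from the rising threshold crossing to the pulse peak.
#' "Slightly larger" is fixed as: round up to the next integer ns, then add
#' 1 ns.
#'
#' @param shape a `pulse_shape`.
#' @param resolution a `resolution_model`.
#' @param max_energy highest incident photon energy, keV (120 for RQA9).
#' @param threshold trigger threshold, keV.
#' @return named numeric vector `c(tau_np, tau_pd)` in ns.
#' @export
derive_timing <- function(shape, resolution, max_energy = 120,
                          threshold = 20) {
  amp <- max_energy + fwhm_at(resolution, max_energy)
  if (threshold >= amp) stop("threshold above maximum pulse amplitude")
  thr <- threshold / amp  # on the unit-peak pulse
  grid <- seq(0, shape$support)
  v <- shape$fun(grid)
  above <- which(v >= thr)
  if (length(above) == 0) stop("threshold never crossed")
  cross <- function(lo, hi) {  # p crosses thr within [lo, hi]
    stats::uniroot(function(t) shape$fun(t) - thr, c(lo, hi),
                   tol = 1e-9)$root
  }
  i1 <- above[1]; i2 <- above[length(above)]
  t_rise <- if (i1 == 1) 0 else cross(grid[i1 - 1], grid[i1])
  t_fall <- if (i2 == length(grid)) grid[i2] else cross(grid[i2],
                                                        grid[i2 + 1])
  tau_np <- ceiling(t_fall - t_rise) + 1
  tau_pd <- ceiling(shape$peak_time - t_rise) + 1
  c(tau_np = tau_np, tau_pd = tau_pd)
}

#' Geometric charge-sharing fraction
#'
#' Probability that a charge cloud of diameter `d`, centered uniformly on
#' an `a` x `b` pixel, overlaps a pixel border:
#' `1 - (a - d)(b - d) / (a b)`.
#'
#' @param a,b pixel sides in um.
#' @param d charge-cloud diameter in um (`0 <= d < min(a, b)`).
#' @return fraction of events subject to charge sharing.
#' @export
charge_sharing_fraction <- function(a, b = a, d) {
  if (any(d < 0) || any(d >= pmin(a, b)))
    stop("cloud diameter must satisfy 0 <= d < min(a, b)")
  1 - (a - d) * (b - d) / (a * b)
}

# -- geometry / counting / model ---------------------------------------------

#' Detector pixel-array geometry
#'
#' @param pitch_um pixel pitch in um (x and y).
#' @param n_pixels array size, `c(nx, ny)`, odd in both axes.
#' @param thickness_mm sensor thickness in mm.
#' @param septum_um reflector septum thickness in um (0 for direct
#'   conversion); the active pixel size is `pitch - 2 * septum`.
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(pitch_um = 500, n_pixels = c(5, 5),
                              thickness_mm = 2, septum_um = 0) {
  if (any(n_pixels %% 2 != 1)) stop("array size must be odd in both axes")
  active <- pitch_um - 2 * septum_um
  if (active <= 0) stop("septum leaves no active pixel area")
  structure(list(pitch_um = pitch_um, n_pixels = as.integer(n_pixels),
                 thickness_mm = thickness_mm, septum_um = septum_um,
                 active_um = active,
                 pixel_area_mm2 = (pitch_um * 1e-3)^2),
            class = "detector_geometry")
}

#' Counting configuration
#'
#' @param behavior `"NP"` (non-paralyzable-like: one count per analysis
#'   window of length `tau_np`) or `"P"` (paralyzable-like: one count per
#'   upward threshold crossing).
#' @param threshold trigger threshold in keV.
#' @param tau_pd peak-detection time, ns.
#' @param tau_np analysis-window length, ns (NP only; `>= tau_pd`).
#' @param bin_centers registered-energy bin centers in keV (1 keV bins;
#'   energies outside the outermost bin edges are discarded).
#' @return an object of class `counting_config`.
#' @export
counting_config <- function(behavior = c("NP", "P"), threshold = 20,
                            tau_pd = 13, tau_np = 24,
                            bin_centers = 20:250) {
  behavior <- match.arg(behavior)
  if (threshold <= 0) stop("threshold must be positive")
  if (behavior == "NP" && tau_np < tau_pd)
    stop("tau_np must be at least tau_pd")
  if (any(diff(bin_centers) != 1)) stop("bin centers must step by 1 keV")
  structure(list(behavior = behavior, threshold = threshold,
                 tau_pd = as.integer(tau_pd), tau_np = as.integer(tau_np),
                 bin_centers = as.numeric(bin_centers)),
            class = "counting_config")
}

#' Assemble a detector model
#'
#' @param name model name.
#' @param material sensor material (`material_spec` or built-in name).
#' @param geometry a `detector_geometry`.
#' @param resolution a `resolution_model`.
#' @param pulse a `pulse_shape`.
#' @param counting a `counting_config`.
#' @param transport `"mc"` for the Monte-Carlo energy-deposition model or
#'   `"full-absorption"` for an idealized sensor that photo-absorbs every
#'   photon in its entry pixel (the linear-detector reference).
#' @return an object of class `detector_model`.
#' @export
detector_model <- function(name, material, geometry, resolution, pulse,
                           counting, transport = c("mc", "full-absorption")) {
  if (is.character(material)) material <- material(material)
  structure(list(name = name, material = material, geometry = geometry,
                 resolution = resolution, pulse = pulse, counting = counting,
                 transport = match.arg(transport)),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  g <- x$geometry
  cat("<detector model>", x$name, "\n")
  cat("  sensor:", x$material$name, g$thickness_mm, "mm;",
      g$n_pixels[1], "x", g$n_pixels[2], "pixels at", g$pitch_um, "um pitch",
      if (g$septum_um > 0) paste0("(", g$septum_um, " um septa)") else "",
      "\n")
  cat("  resolution:", 100 * x$resolution$rel_fwhm, "% FWHM at",
      x$resolution$ref_energy, "keV;  pulse:", x$pulse$kind, "\n")
  cat("  counting:", x$counting$behavior, " threshold",
      x$counting$threshold, "keV, tau_pd", x$counting$tau_pd,
      "ns, tau_np", x$counting$tau_np, "ns\n")
  invisible(x)
}

#' Built-in detector presets
#'
#' `"iDCD-CZT"`: idealized direct-conversion detector, 2 mm CZT, Gaussian
#' 14 ns pulse, 8.0% FWHM at 59.5 keV. `"iICD-LaBr3"`: idealized
#' indirect-conversion detector, 2.8 mm LaBr3:Ce with 60 um PTFE reflector
#' septa, bi-exponential 16/7 ns pulse, 22.3% FWHM at 59.5 keV. Timing
#' windows are derived from the pulse shape via [derive_timing()] for a
#' 120 kVp beam and a 20 keV threshold.
#'
#' @param name preset name.
#' @param behavior counting behavior, `"NP"` or `"P"`.
#' @param n_pixels array size (odd in both axes).
#' @return a `detector_model`.
#' @export
detector_preset <- function(name = c("iDCD-CZT", "iICD-LaBr3"),
                            behavior = "NP", n_pixels = c(5, 5)) {
  name <- match.arg(name)
  if (name == "iDCD-CZT") {
    res <- resolution_model(0.080)
    pulse <- pulse_shape_gaussian(14)
    geom <- detector_geometry(500, n_pixels, thickness_mm = 2, septum_um = 0)
    mat <- "CZT"
  } else {
    res <- resolution_model(0.223)
    pulse <- pulse_shape_biexponential(16, 7)
    geom <- detector_geometry(500, n_pixels, thickness_mm = 2.8,
                              septum_um = 60)
    mat <- "LaBr3:Ce"
  }
  tau <- derive_timing(pulse, res, max_energy = 120, threshold = 20)
  cfg <- counting_config(behavior, threshold = 20,
                         tau_pd = tau[["tau_pd"]], tau_np = tau[["tau_np"]])
  detector_model(name, mat, geom, res, pulse, cfg)
}
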