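# Estimation of the perturbation point spread function (pPSF)
# h_k(dn, op, E_l): the change in registered count rate per incident probe
# photon of energy E_l at pixel offset dn, with the detector held at an
# operating point (spectrum shape + total fluence rate). Estimated by
# paired simulations sharing the operating-beam realization (common random
# numbers), one per probe energy.

default_probe_rate <- function(op_total) {
  if (op_total <= 0) 1e4 else min(0.05 * op_total, 1e6)
}

# probe deposition events under their own substream family (tagged by
# probe energy) so different probe energies are independent
probe_events <- function(detector, energy, rate, duration, seed, tag,
                         pixel = NULL) {
  geom <- detector$geometry
  if (is.null(pixel)) pixel <- (geom$n_pixels - 1) %/% 2
  pre <- paste0("probe.", tag, ".")
  pt <- with_seed(substream_seed(seed, paste0(pre, "arrivals")),
                  sample_arrivals(rate, geom$pixel_area_mm2, duration))
  n <- length(pt)
  if (n == 0)
    return(structure(data.frame(primary = integer(0), px = integer(0),
                                py = integer(0), energy = numeric(0),
                                time = numeric(0), origin = character(0)),
                     n_probe_primaries = 0L))
  pxy <- with_seed(substream_seed(seed, paste0(pre, "positions")),
                   cbind(stats::runif(n, pixel[1] * geom$pitch_um,
                                      (pixel[1] + 1) * geom$pitch_um),
                         stats::runif(n, pixel[2] * geom$pitch_um,
                                      (pixel[2] + 1) * geom$pitch_um)))
  dep <- with_seed(substream_seed(seed, paste0(pre, "transport")),
                   interact_photons(detector, rep(energy, n), pxy[, 1],
                                    pxy[, 2], primary = seq_len(n)))
  dep$time <- pt[dep$primary]
  dep$primary <- dep$primary + 1e9L  # keep probe ids distinct from op ids
  dep$origin <- rep("probe", nrow(dep))
  structure(dep, n_probe_primaries = n)
}

#' Registered count rates at the operating point
#'
#' Runs the full chain (transport, pulse train, counting) for a homogeneous
#' irradiation with the operating spectrum. Under shift invariance the
#' center-pixel rates serve as the per-pixel baseline d_k.
#'
#' @param detector a `detector_model`.
#' @param spectrum operating `spectral_fluence` (absolute fluence rates).
#' @param duration exposure duration, ns.
#' @param seed master seed.
#' @param n_sections number of time sections for variance estimation.
#' @return a list with `rates` (`count_rates` over the array), `sectioned`
#'   (`sectioned_counts`), and `center` (numeric vector of center-pixel
#'   rates per bin, counts/s).
#' @export
baseline_rates <- function(detector, spectrum, duration, seed,
                           n_sections = 16) {
  ev <- simulate_exposure(detector, spectrum, duration, seed)
  recs <- count_exposure(ev, detector, seed)
  cr <- bin_counts(recs, detector$counting, duration,
                   detector$geometry$n_pixels)
  sec <- sectioned_counts(recs, detector$counting, duration,
                          duration / n_sections,
                          detector$geometry$n_pixels)
  np <- detector$geometry$n_pixels
  center <- (np[1] - 1) %/% 2 + np[1] * ((np[2] - 1) %/% 2) + 1
  list(rates = cr, sectioned = sec, center = cr$rates[, center])
}

#' Estimate the perturbation point spread function
#'
#' For each probe energy, the exposure is simulated twice with an identical
#' operating-beam realization — once with and once without a monoenergetic
#' probe beam on the center pixel — and the pPSF follows as
#' `h = (d_perturbed - d_baseline) / (probe fluence rate x pixel area)`,
#' per energy bin and pixel. Standard errors come from section-wise
#' replication in time.
#'
#' @param detector a `detector_model`.
#' @param op_spectrum operating `spectral_fluence` (absolute fluence
#'   rates); pass a zero-rescaled spectrum for the no-operating-beam edge
#'   case.
#' @param probe_energies probe energies in keV (default 20-150 keV in
#'   2 keV steps).
#' @param probe_rate probe fluence rate, mm^-2 s^-1; default 5% of the
#'   operating rate capped at 1e6, or 1e4 at zero operating rate. The
#'   probe must stay small against the operating beam for the small-signal
#'   picture to hold; larger rates reduce estimator variance.
#' @param duration exposure duration, ns.
#' @param seed master seed; the estimate is bit-reproducible given
#'   (seed, arguments).
#' @param n_sections time sections for the standard errors.
#' @return an object of class `ppsf`: list with `h` and `se` (arrays
#'   bins x nx x ny x probe energies, counts per incident probe photon),
#'   `bin_centers`, `probe_energies`, `offsets` (pixel offsets dn relative
#'   to the center pixel), `baseline` (as [baseline_rates()]), and
#'   estimation metadata.
#' @export
estimate_ppsf <- function(detector, op_spectrum,
                          probe_energies = seq(20, 150, by = 2),
                          probe_rate = NULL, duration = 1e6, seed = 1,
                          n_sections = 16) {
  op_total <- total_fluence(op_spectrum)
  if (is.null(probe_rate)) probe_rate <- default_probe_rate(op_total)
  if (probe_rate <= 0) stop("probe rate must be positive")
  geom <- detector$geometry
  cfg <- detector$counting
  a_mm2 <- geom$pixel_area_mm2
  op_ev <- simulate_exposure(detector, op_spectrum, duration, seed)
  # blur the operating-beam deposits once; every perturbed run reuses these
  # draws (common random numbers), so count differences stem from the probe
  op_blur <- with_seed(substream_seed(seed, "blur.op"),
                       blur_energy(op_ev$energy, detector$resolution))
  nx <- geom$n_pixels[1]
  op_pix <- op_ev$px + nx * op_ev$py
  base_recs <- count_blurred_events(op_ev$time, op_blur, op_pix, detector,
                                    duration)
  base_sec <- sectioned_counts(base_recs, cfg, duration,
                               duration / n_sections, geom$n_pixels)
  base_cr <- bin_counts(base_recs, cfg, duration, geom$n_pixels)
  nb <- length(cfg$bin_centers)
  ns <- base_sec$n_sections
  t_sec_s <- base_sec$section_length * 1e-9
  denom <- probe_rate * a_mm2 * t_sec_s  # expected probe photons / section
  ne <- length(probe_energies)
  h <- array(NA_real_, c(nb, geom$n_pixels[1], geom$n_pixels[2], ne))
  se <- array(NA_real_, c(nb, geom$n_pixels[1], geom$n_pixels[2], ne))
  n_probe <- integer(ne)
  for (ie in seq_len(ne)) {
    el <- probe_energies[ie]
    tag <- format(el)
    pev <- probe_events(detector, el, probe_rate, duration, seed,
                        tag = tag)
    n_probe[ie] <- attr(pev, "n_probe_primaries")
    p_blur <- with_seed(substream_seed(seed, paste0("blur.probe.", tag)),
                        blur_energy(pev$energy, detector$resolution))
    # only pixels receiving probe deposits can change; recount just those
    affected <- sort(unique(pev$px + nx * pev$py))
    pert_recs <- count_blurred_events(c(op_ev$time, pev$time),
                                      c(op_blur, p_blur),
                                      c(op_pix, pev$px + nx * pev$py),
                                      detector, duration, pixels = affected)
    pert_counts <- base_sec$counts
    aff_sec <- sectioned_counts(pert_recs, cfg, duration,
                                duration / n_sections, geom$n_pixels)
    pert_counts[, affected + 1, ] <- aff_sec$counts[, affected + 1, ]
    hs <- (pert_counts - base_sec$counts) / denom  # [nb, npx, ns]
    hbar <- apply(hs, c(1, 2), mean)
    hsd <- apply(hs, c(1, 2), stats::sd) / sqrt(ns)
    h[, , , ie] <- array(hbar, c(nb, geom$n_pixels))
    se[, , , ie] <- array(hsd, c(nb, geom$n_pixels))
  }
  center <- (geom$n_pixels - 1) %/% 2
  structure(list(
    h = h, se = se,
    bin_centers = cfg$bin_centers,
    probe_energies = probe_energies,
    offsets = list(x = seq_len(geom$n_pixels[1]) - 1 - center[1],
                   y = seq_len(geom$n_pixels[2]) - 1 - center[2]),
    baseline = list(rates = base_cr, sectioned = base_sec,
                    center = base_cr$rates[, center[1] + 1 +
                                             geom$n_pixels[1] * center[2]]),
    op_total = op_total, probe_rate = probe_rate,
    pixel_area_mm2 = a_mm2, duration = duration, seed = seed,
    n_sections = ns, n_probe = n_probe,
    detector = detector$name, behavior = cfg$behavior),
    class = "ppsf")
}

#' Extract a center-pixel slice of the pPSF
#'
#' @param x a `ppsf`.
#' @param probe_energy probe energy (must be on the probe grid).
#' @param dn pixel offset `c(dx, dy)` (default center, `c(0, 0)`).
#' @return data.frame with `bin`, `h`, `se`.
#' @export
ppsf_slice <- function(x, probe_energy, dn = c(0, 0)) {
  ie <- match(probe_energy, x$probe_energies)
  if (is.na(ie)) stop("probe energy not on the probe grid")
  ix <- match(dn[1], x$offsets$x)
  iy <- match(dn[2], x$offsets$y)
  if (is.na(ix) || is.na(iy)) stop("pixel offset outside the array")
  data.frame(bin = x$bin_centers, h = x$h[, ix, iy, ie],
             se = x$se[, ix, iy, ie])
}

#' @export
print.ppsf <- function(x, ...) {
  cat("<pPSF>", x$detector, "(", x$behavior, "counting )\n")
  cat("  operating point:", format(x$op_total, digits = 4),
      "mm^-2 s^-1;  probe:", format(x$probe_rate, digits = 4),
      "mm^-2 s^-1 over", length(x$probe_energies), "energies\n")
  cat("  bins:", length(x$bin_centers), " pixels:",
      paste(dim(x$h)[2:3], collapse = "x"),
      " duration:", x$duration, "ns in", x$n_sections, "sections\n")
  invisible(x)
}

#' @export
summary.ppsf <- function(object, ...) {
  sl <- lapply(object$probe_energies, function(e)
    ppsf_slice(object, e))
  peak <- vapply(sl, function(d) d$bin[which.max(d$h)], numeric(1))
  hmax <- vapply(sl, function(d) max(d$h), numeric(1))
  hmin <- vapply(sl, function(d) min(d$h), numeric(1))
  out <- data.frame(probe_energy = object$probe_energies,
                    photopeak_bin = peak, h_max = hmax, h_min = hmin,
                    n_probe = object$n_probe)
  cat("pPSF summary (center pixel):\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
plot.ppsf <- function(x, probe_energy = utils::tail(x$probe_energies, 1),
                      dn = c(0, 0), ...) {
  d <- ppsf_slice(x, probe_energy, dn)
  graphics::plot(d$bin, d$h, type = "s", xlab = "energy bin k [keV]",
                 ylab = "h [counts / probe photon]", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
coef.ppsf <- function(object, ...) object$h

#' Predict the contrast response to a spectral perturbation
#'
#' Applies the small-signal form: the linearized detector response at the
#' estimated operating point is contracted with the perturbation (see
#' [contrast_smallsignal()]).
#'
#' @param object a `ppsf`.
#' @param perturbation a `perturbation_spectrum`.
#' @param ... passed to [contrast_smallsignal()].
#' @return a `contrast_result`.
#' @export
predict.ppsf <- function(object, perturbation, ...) {
  contrast_smallsignal(object, perturbation, ...)
}

#' Linear shift-invariant detector response
#'
#' Reference model for the low-rate limit: the registered count rate is
#' the discrete convolution of the incident per-pixel spectral fluence
#' with a (non-negative) detector PSF, summed over incident energies and
#' scaled by the pixel area.
#'
#' @param psf list with `values` (array bins x dx x dy x incident
#'   energies, probability per incident photon), `bin_centers`,
#'   `offsets` (list `x`, `y` of pixel offsets), `energies`.
#' @param spectrum_map array nx x ny x energies: per-pixel fluence rate at
#'   `psf$energies`, mm^-2 s^-1.
#' @param area pixel area, mm^2.
#' @return rates array bins x nx x ny (counts/s).
#' @export
linear_response <- function(psf, spectrum_map, area) {
  dm <- dim(spectrum_map)
  nb <- length(psf$bin_centers)
  if (dm[3] != length(psf$energies)) stop("energy grid mismatch")
  out <- array(0, c(nb, dm[1], dm[2]))
  for (nx in seq_len(dm[1])) for (ny in seq_len(dm[2])) {
    for (sx in seq_len(dm[1])) for (sy in seq_len(dm[2])) {
      ix <- match(nx - sx, psf$offsets$x)
      iy <- match(ny - sy, psf$offsets$y)
      if (is.na(ix) || is.na(iy)) next
      for (ie in seq_along(psf$energies))
        out[, nx, ny] <- out[, nx, ny] +
          psf$values[, ix, iy, ie] * spectrum_map[sx, sy, ie] * area
    }
  }
  out
}
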