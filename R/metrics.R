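# Contrast and contrast-to-noise ratio per energy bin: the direct two-run
# definition, the small-signal (pPSF-based) form, the linear-detector
# reference curve, equal-dose sectioning for the variance, and macro-bin
# rebinning.

new_contrast_result <- function(bin_centers, num, den, se = NULL,
                                meta = list()) {
  masked <- !is.finite(num / den) | den <= 0
  contrast <- ifelse(masked, NA_real_, num / den)
  structure(list(bin_centers = bin_centers, contrast = contrast,
                 num = num, den = den, se = se, masked = masked,
                 cnr = NULL, meta = meta),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  ok <- !x$masked
  cat("<contrast>", sum(ok), "defined bins,", sum(x$masked), "masked\n")
  if (any(ok))
    cat("  range:", format(min(x$contrast[ok]), digits = 3), "..",
        format(max(x$contrast[ok]), digits = 3), "\n")
  if (!is.null(x$cnr))
    cat("  max |CNR|:", format(max(abs(x$cnr[ok & is.finite(x$cnr)])),
                               digits = 3), "\n")
  invisible(x)
}

#' @export
plot.contrast_result <- function(x, what = c("contrast", "cnr"), ...) {
  what <- match.arg(what)
  y <- if (what == "cnr") x$cnr else x$contrast
  graphics::plot(x$bin_centers, y, type = "p", pch = 20,
                 xlab = "energy bin k [keV]", ylab = what, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Contrast from two measured count-rate vectors
#'
#' `C_k = (d_k(target) - d_k(baseline)) / d_k(baseline)`; bins with zero
#' baseline are masked (recorded, not dropped).
#'
#' @param d_target,d_baseline numeric vectors of per-bin count rates on
#'   the same binning, or `count_rates` objects (single pixel column).
#' @param bin_centers bin centers (taken from the inputs when they are
#'   `count_rates`).
#' @return a `contrast_result`.
#' @export
contrast_direct <- function(d_target, d_baseline, bin_centers = NULL) {
  if (inherits(d_target, "count_rates")) {
    bin_centers <- d_target$bin_centers
    d_target <- rowSums(d_target$rates)
  }
  if (inherits(d_baseline, "count_rates")) {
    if (is.null(bin_centers)) bin_centers <- d_baseline$bin_centers
    d_baseline <- rowSums(d_baseline$rates)
  }
  if (length(d_target) != length(d_baseline))
    stop("binning mismatch between target and baseline")
  if (is.null(bin_centers)) bin_centers <- seq_along(d_target)
  new_contrast_result(bin_centers, d_target - d_baseline, d_baseline)
}

#' Small-signal contrast from the pPSF
#'
#' First-order sensitivity form: the count-rate change in bin k caused by
#' a spectral perturbation is the pPSF (center pixel) contracted with the
#' perturbation, `sum_l h(k, 0, E_l) * A * dPhi_l`, and the contrast is
#' that change divided by the baseline rate d_k. The pPSF is linearly
#' interpolated from its probe-energy grid onto the 1 keV spectrum grid;
#' perturbation content below 20 keV (below the trigger threshold and the
#' probe grid) is truncated.
#'
#' @param ppsf a `ppsf` (its stored baseline provides d_k).
#' @param perturbation a `perturbation_spectrum`.
#' @param baseline optional per-bin baseline rates to use instead of the
#'   pPSF's stored center-pixel baseline.
#' @return a `contrast_result` with propagated standard errors.
#' @export
contrast_smallsignal <- function(ppsf, perturbation, baseline = NULL) {
  if (isFALSE(attr(perturbation, "small_signal")))
    warning("perturbation exceeds the small-signal threshold; ",
            "the first-order contrast may be inaccurate")
  d_k <- if (is.null(baseline)) ppsf$baseline$center else baseline
  ix <- match(0, ppsf$offsets$x)
  iy <- match(0, ppsf$offsets$y)
  grid <- ppsf$probe_energies
  keep <- perturbation$energy >= min(grid)
  el <- perturbation$energy[keep]
  dphi <- perturbation$delta[keep]
  if (max(perturbation$energy) > max(grid) &&
      any(perturbation$delta[perturbation$energy > max(grid)] != 0))
    warning("perturbation extends above the probe grid; truncated")
  el <- el[el <= max(grid)]
  dphi <- dphi[seq_along(el)]
  nb <- length(ppsf$bin_centers)
  num <- numeric(nb)
  var <- numeric(nb)
  a <- ppsf$pixel_area_mm2
  for (k in seq_len(nb)) {
    hk <- stats::approx(grid, ppsf$h[k, ix, iy, ], xout = el)$y
    sk <- stats::approx(grid, ppsf$se[k, ix, iy, ], xout = el)$y
    num[k] <- sum(hk * a * dphi)
    var[k] <- sum((sk * a * dphi)^2)
  }
  se <- ifelse(d_k > 0, sqrt(var) / d_k, NA_real_)
  new_contrast_result(ppsf$bin_centers, num, d_k, se = se,
                      meta = list(kind = "small-signal",
                                  op_total = ppsf$op_total))
}

#' Contrast of an ideal linear detector
#'
#' For a perfectly linear counting detector the contrast in bin k = E
#' follows the lesion attenuation directly:
#' `exp(-(mu/rho)(E) * rho_x) - 1`, independent of the fluence rate.
#'
#' @param lesion a `lesion_spec`.
#' @param energies energies in keV.
#' @return numeric vector of per-energy contrast (signed).
#' @export
linear_reference_contrast <- function(lesion, energies) {
  exp(-mass_attenuation(lesion$material, energies) * lesion$rho_x) - 1
}

#' Direct two-run Monte-Carlo contrast for a lesion
#'
#' Simulates the baseline exposure once and derives the lesion ("target")
#' exposure from the same realization by thinning: each operating-beam
#' primary of energy E survives with probability
#' `exp(-(mu/rho)(E) * rho_x)`, which is exactly a Poisson process with
#' the lesion-attenuated spectrum. The coupling removes the shared
#' realization noise from the contrast difference.
#'
#' @param detector a `detector_model`.
#' @param op_spectrum operating `spectral_fluence`.
#' @param lesion a `lesion_spec`.
#' @param duration exposure duration, ns.
#' @param seed master seed.
#' @param n_sections sections for the variance of the contrast.
#' @return a `contrast_result` (center pixel) with standard errors from
#'   section-wise replication.
#' @export
contrast_direct_mc <- function(detector, op_spectrum, lesion, duration,
                               seed, n_sections = 16) {
  ev <- simulate_exposure(detector, op_spectrum, duration, seed)
  en <- attr(ev, "primary_energies")
  surv <- exp(-mass_attenuation(lesion$material, en) * lesion$rho_x)
  keep_primary <- with_seed(substream_seed(seed, "lesion.thinning"),
                            stats::runif(length(en)) < surv)
  np <- detector$geometry$n_pixels
  center <- (np[1] - 1) %/% 2 + np[1] * ((np[2] - 1) %/% 2) + 1
  cfg <- detector$counting
  # blur once; the thinned (target) run reuses the surviving draws, and
  # only the center pixel is evaluated
  blur <- with_seed(substream_seed(seed, "blur.op"),
                    blur_energy(ev$energy, detector$resolution))
  pix <- ev$px + np[1] * ev$py
  keep_ev <- keep_primary[ev$primary]
  rb <- count_blurred_events(ev$time, blur, pix, detector, duration,
                             pixels = center - 1)
  rt <- count_blurred_events(ev$time[keep_ev], blur[keep_ev],
                             pix[keep_ev], detector, duration,
                             pixels = center - 1)
  sb <- sectioned_counts(rb, cfg, duration, duration / n_sections, np)
  st <- sectioned_counts(rt, cfg, duration, duration / n_sections, np)
  cb <- apply(sb$counts[, center, , drop = FALSE], 1, sum)
  ct <- apply(st$counts[, center, , drop = FALSE], 1, sum)
  # per-section contrast spread -> SE of the pooled contrast
  ns <- sb$n_sections
  num_s <- st$counts[, center, ] - sb$counts[, center, ]
  den_s <- sb$counts[, center, ]
  cs <- num_s / ifelse(den_s > 0, den_s, NA_real_)
  se <- apply(cs, 1, stats::sd, na.rm = TRUE) /
    sqrt(pmax(1, apply(is.finite(cs), 1, sum)))
  res <- new_contrast_result(cfg$bin_centers, ct - cb, cb, se = se,
                             meta = list(kind = "direct-mc",
                                         op_total =
                                           total_fluence(op_spectrum)))
  res$sectioned_baseline <- sb
  res
}

#' Contrast-to-noise ratio with equal-dose sectioning
#'
#' The contrast noise is derived from the per-section spread of the
#' baseline counts: `sigma(C_k) = sd(d_k over sections) / mean(d_k)`, with
#' the section length chosen inversely proportional to the total fluence
#' rate so every section sees the same dose; `CNR_k = C_k / sigma(C_k)`.
#' Zero-variance bins are masked.
#'
#' @param contrast a `contrast_result`.
#' @param sectioned a `sectioned_counts` of the baseline run (center
#'   pixel is used), sectioned at the equal-dose length.
#' @param pixel 1-based pixel column in the sectioned array (default
#'   center).
#' @return the `contrast_result` with a `cnr` field and
#'   `sigma_c` in `meta`.
#' @export
cnr <- function(contrast, sectioned, pixel = NULL) {
  if (sectioned$n_sections < 2) stop("need at least 2 sections")
  np <- sectioned$n_pixels
  if (is.null(pixel))
    pixel <- (np[1] - 1) %/% 2 + np[1] * ((np[2] - 1) %/% 2) + 1
  d <- sectioned$counts[, pixel, ]  # bins x sections
  m <- rowMeans(d)
  s <- apply(d, 1, stats::sd)
  sigma_c <- ifelse(m > 0 & s > 0, s / m, NA_real_)
  contrast$cnr <- contrast$contrast / sigma_c
  contrast$meta$sigma_c <- sigma_c
  contrast$meta$section_length <- sectioned$section_length
  contrast
}

#' Equal-dose section length for a fluence rate
#'
#' Scales a reference section length inversely with the total fluence
#' rate, so each section sees the same dose at every rate.
#'
#' @param rate total fluence rate, mm^-2 s^-1.
#' @param ref_rate,ref_length reference rate and section length (ns).
#' @return section length in ns.
#' @export
equal_dose_section <- function(rate, ref_rate = 1e6, ref_length = 1e6) {
  if (rate <= 0) stop("rate must be positive")
  ref_length * ref_rate / rate
}

#' Rebin counts or contrast onto macro energy bins
#'
#' Counts are summed; contrast is recomputed from the summed numerator
#' and denominator (not averaged), which is what makes contrast
#' cancellation and inversion between micro-bins visible.
#'
#' @param x a `contrast_result` or `count_rates`.
#' @param edges macro bin edges in keV (increasing, within the micro-bin
#'   range).
#' @return an object of the same class on the macro binning.
#' @export
rebin_macro <- function(x, edges) {
  if (any(diff(edges) <= 0)) stop("macro edges must be increasing")
  if (inherits(x, "count_rates")) {
    centers <- x$bin_centers
    idx <- findInterval(centers, edges)
    ok <- idx >= 1 & idx < length(edges)
    nb <- length(edges) - 1
    counts <- matrix(0L, nb, ncol(x$counts))
    for (b in seq_len(nb)) {
      sel <- ok & idx == b
      counts[b, ] <- colSums(x$counts[sel, , drop = FALSE])
    }
    return(structure(list(counts = counts,
                          rates = counts / (x$duration * 1e-9),
                          bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                          duration = x$duration, n_pixels = x$n_pixels),
                     class = "count_rates"))
  }
  if (!inherits(x, "contrast_result")) stop("unsupported type")
  idx <- findInterval(x$bin_centers, edges)
  ok <- idx >= 1 & idx < length(edges)
  nb <- length(edges) - 1
  num <- den <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- ok & idx == b & !x$masked
    num[b] <- sum(x$num[sel])
    den[b] <- sum(x$den[sel])
  }
  new_contrast_result((edges[-1] + edges[-length(edges)]) / 2, num, den,
                      meta = c(x$meta, list(macro_edges = edges)))
}
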