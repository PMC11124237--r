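# Pulse-train synthesis: deposition events -> sampled waveforms at 1 ns
# resolution, with Gaussian energy blurring applied per merged deposition
# event before convolution with the pulse shape.

#' Blur deposited energies with the detector resolution
#'
#' Gaussian draw with mean `energy` and `sigma = FWHM(E)/2.3548`; negative
#' draws are clamped to zero. A zero-width resolution model returns the
#' energies unchanged. Uses the current RNG state.
#'
#' @param energy deposited energies, keV (vectorized).
#' @param resolution a `resolution_model`.
#' @return blurred energies, keV.
#' @export
blur_energy <- function(energy, resolution) {
  if (resolution$rel_fwhm == 0 || length(energy) == 0) return(energy)
  sigma <- fwhm_at(resolution, energy) / FWHM_SIGMA
  pmax(0, stats::rnorm(length(energy), energy, sigma))
}

# blur an event list reproducibly: operating-beam and probe events get
# independent substreams so the operating-beam draws do not depend on the
# presence of a probe
blur_events <- function(events, resolution, seed) {
  e <- events$energy
  is_op <- events$origin == "op"
  e[is_op] <- with_seed(substream_seed(seed, "blur.op"),
                        blur_energy(events$energy[is_op], resolution))
  if (any(!is_op))
    e[!is_op] <- with_seed(substream_seed(seed, "blur.probe"),
                           blur_energy(events$energy[!is_op], resolution))
  e
}

#' Synthesize a sampled pulse train from deposition events
#'
#' Per pixel, `signal(t) = sum_i E_i * p(t - t_i)` on the 1 ns grid, where
#' `E_i` are (optionally blurred) deposited energies and `p` the unit-peak
#' pulse shape with onset at the event time (rasterized to the grid). A pad
#' of one pulse support length is appended so tails are not cut off.
#'
#' @param events deposition event data.frame (`px`, `py`, `time`, `energy`).
#' @param shape a `pulse_shape`.
#' @param resolution a `resolution_model`, or `NULL` to skip blurring.
#' @param duration train duration in ns.
#' @param n_pixels array size `c(nx, ny)`.
#' @param seed seed for the blur draws (required when `resolution` given).
#' @return an object of class `pulse_train`: list with `signal` (matrix,
#'   samples x pixels, pixel order column-major in (px, py)), `duration`,
#'   `pad`, `n_pixels`.
#' @export
synthesize <- function(events, shape, resolution = NULL, duration,
                       n_pixels = c(1, 1), seed = 1) {
  if (nrow(events) > 0 && any(events$time < 0 | events$time >= duration))
    stop("event outside the train duration")
  energies <- events$energy
  if (!is.null(resolution)) {
    if (is.null(events$origin)) events$origin <- rep("op", nrow(events))
    energies <- blur_events(events, resolution, seed)
  }
  pad <- shape$support
  ns <- as.integer(duration + pad)
  sig <- matrix(0, ns, n_pixels[1] * n_pixels[2])
  if (nrow(events) > 0) {
    pix <- events$px + n_pixels[1] * events$py + 1
    for (p in unique(pix)) {
      sel <- pix == p
      sig[, p] <- cpp_synthesize(ns, events$time[sel], energies[sel],
                                 shape$samples)
    }
  }
  structure(list(signal = sig, duration = duration, pad = pad,
                 n_pixels = n_pixels), class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat("<pulse train>", nrow(x$signal), "samples at 1 ns x",
      ncol(x$signal), "pixel(s), duration", x$duration, "ns (pad",
      x$pad, "ns)\n")
  invisible(x)
}
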