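# P-like and NP-like counting on pulse trains, energy binning, sectioned
# counting for variance estimation, and the analytic dead-time oracles.

count_train <- function(train, cfg, paralyzable) {
  recs <- list()
  for (p in seq_len(ncol(train$signal))) {
    r <- cpp_count_signal(train$signal[, p], cfg$threshold, cfg$tau_pd,
                          if (paralyzable) 0L else cfg$tau_np, paralyzable)
    if (length(r$time) > 0)
      recs[[length(recs) + 1]] <-
        data.frame(pixel = p - 1L, time = r$time, energy = r$energy)
  }
  if (length(recs) == 0)
    return(data.frame(pixel = integer(0), time = numeric(0),
                      energy = numeric(0)))
  do.call(rbind, recs)
}

#' Non-paralyzable-like counting on a pulse train
#'
#' An upward threshold crossing with no active window opens an analysis
#' window of length `tau_np` and yields exactly one count; the registered
#' energy is the maximum sample over the first `tau_pd` of the window.
#' After the window closes a fresh upward crossing (signal below threshold
#' first) is required.
#'
#' @param train a `pulse_train`.
#' @param cfg a `counting_config` (its `tau_np` is used).
#' @return data.frame of count records: `pixel` (0-based, column-major),
#'   `time` (trigger time, ns), `energy` (registered, keV).
#' @export
count_np <- function(train, cfg) {
  if (cfg$tau_pd > cfg$tau_np) stop("tau_pd must not exceed tau_np")
  count_train(train, cfg, paralyzable = FALSE)
}

#' Paralyzable-like counting on a pulse train
#'
#' Every upward threshold crossing starts a `tau_pd` peak-detection window
#' and yields one count; a prolonged above-threshold excursion yields no
#' further counts.
#'
#' @inheritParams count_np
#' @return data.frame of count records, as [count_np()].
#' @export
count_p <- function(train, cfg) count_train(train, cfg, paralyzable = TRUE)

#' Bin registered energies into count rates
#'
#' 1 keV bins centered on `cfg$bin_centers` (edges at center +- 0.5 keV);
#' registered energies outside the outermost edges are discarded.
#'
#' @param records count records ([count_np()]/[count_p()] output).
#' @param cfg a `counting_config`.
#' @param duration counting duration in ns (for rates).
#' @param n_pixels array size `c(nx, ny)`.
#' @return an object of class `count_rates`: list with `counts` (matrix,
#'   bins x pixels), `rates` (counts/s), `bin_centers`, `duration`,
#'   `n_pixels`.
#' @export
bin_counts <- function(records, cfg, duration, n_pixels = c(1, 1)) {
  nb <- length(cfg$bin_centers)
  npx <- n_pixels[1] * n_pixels[2]
  counts <- matrix(0L, nb, npx)
  if (nrow(records) > 0) {
    bin <- round(records$energy - cfg$bin_centers[1]) + 1
    ok <- records$energy >= cfg$bin_centers[1] - 0.5 &
      records$energy < cfg$bin_centers[nb] + 0.5 &
      bin >= 1 & bin <= nb
    if (any(ok)) {
      tab <- table(factor(bin[ok], levels = seq_len(nb)),
                   factor(records$pixel[ok] + 1, levels = seq_len(npx)))
      counts <- matrix(as.integer(tab), nb, npx)
    }
  }
  structure(list(counts = counts, rates = counts / (duration * 1e-9),
                 bin_centers = cfg$bin_centers, duration = duration,
                 n_pixels = n_pixels), class = "count_rates")
}

#' @export
print.count_rates <- function(x, ...) {
  cat("<count rates>", nrow(x$counts), "bins x", ncol(x$counts),
      "pixel(s);", sum(x$counts), "counts in", x$duration * 1e-9, "s\n")
  invisible(x)
}

#' Split count records into equal time sections
#'
#' Counting is run once over the full record stream; records are assigned
#' to sections by trigger time, giving per-section count rates for
#' variance estimation.
#'
#' @param records count records.
#' @param cfg a `counting_config`.
#' @param duration total duration, ns.
#' @param section_length section length, ns (at least 2 sections must fit).
#' @param n_pixels array size.
#' @return an object of class `sectioned_counts`: list with `counts`
#'   (array bins x pixels x sections), `section_length`, `n_sections`,
#'   `bin_centers`.
#' @export
sectioned_counts <- function(records, cfg, duration, section_length,
                             n_pixels = c(1, 1)) {
  ns <- floor(duration / section_length)
  if (ns < 2) stop("fewer than 2 sections; shorten the section length")
  nb <- length(cfg$bin_centers)
  npx <- n_pixels[1] * n_pixels[2]
  arr <- array(0L, c(nb, npx, ns))
  if (nrow(records) > 0) {
    sec <- floor(records$time / section_length) + 1
    keep <- sec <= ns
    r <- records[keep, ]
    sec <- sec[keep]
    for (s in unique(sec)) {
      b <- bin_counts(r[sec == s, ], cfg, section_length, n_pixels)
      arr[, , s] <- b$counts
    }
  }
  structure(list(counts = arr, section_length = section_length,
                 n_sections = ns, bin_centers = cfg$bin_centers,
                 n_pixels = n_pixels), class = "sectioned_counts")
}

# event-driven counting of pre-blurred events; `pixels` (0-based linear
# indices) restricts counting to a pixel subset — a pixel's waveform
# depends only on its own deposits, so counts in untouched pixels are
# unchanged and need not be recomputed
count_blurred_events <- function(times, blurred, pix, detector, duration,
                                 pixels = NULL) {
  cfg <- detector$counting
  paralyzable <- cfg$behavior == "P"
  if (is.null(pixels)) pixels <- sort(unique(pix))
  recs <- list()
  for (p in pixels) {
    sel <- which(pix == p)
    if (length(sel) == 0) next
    ord <- sel[order(times[sel])]
    r <- cpp_count_events(times[ord], blurred[ord],
                          detector$pulse$samples, cfg$threshold,
                          cfg$tau_pd,
                          if (paralyzable) 0L else cfg$tau_np,
                          paralyzable, duration)
    if (length(r$time) > 0)
      recs[[length(recs) + 1]] <-
        data.frame(pixel = p, time = r$time, energy = r$energy)
  }
  if (length(recs) == 0)
    return(data.frame(pixel = integer(0), time = numeric(0),
                      energy = numeric(0)))
  do.call(rbind, recs)
}

#' Event-driven counting of a simulated exposure
#'
#' Blurs deposited energies, synthesizes the waveform cluster by cluster
#' per pixel and applies the configured counting behavior. Equivalent to
#' [synthesize()] + [count_np()]/[count_p()], but with cost proportional
#' to the number of events instead of the exposure duration.
#'
#' @param events deposition events from [simulate_exposure()].
#' @param detector a `detector_model`.
#' @param seed master seed (for the blur substreams).
#' @return count records data.frame (`pixel`, `time`, `energy`).
#' @export
count_exposure <- function(events, detector, seed) {
  duration <- attr(events, "duration")
  energies <- blur_events(events, detector$resolution, seed)
  nx <- detector$geometry$n_pixels[1]
  count_blurred_events(events$time, energies, events$px + nx * events$py,
                       detector, duration)
}

#' Analytic dead-time count-rate models
#'
#' Classic loss formulas: non-paralyzable `n / (1 + n tau)`, paralyzable
#' `n exp(-n tau)`; validation oracles for the counting implementations.
#'
#' @param behavior `"NP"` or `"P"`.
#' @param rate true event rate, counts/s.
#' @param dead_time dead time, s.
#' @return registered count rate, counts/s.
#' @export
analytic_rate <- function(behavior = c("NP", "P"), rate, dead_time) {
  behavior <- match.arg(behavior)
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(dead_time < 0)) stop("negative dead time")
  if (behavior == "NP") rate / (1 + rate * dead_time)
  else rate * exp(-rate * dead_time)
}
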