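# shared test fixtures built in code

# rectangular unit pulse of width w ns: the analytic dead-time oracles
# n/(1+n*tau) and n*exp(-n*tau) hold exactly for this shape
rect_pulse <- function(w) {
  structure(list(kind = "rect", params = list(w = w),
                 fun = function(t) ifelse(t >= 0 & t < w, 1, 0),
                 peak_time = 0, support = w,
                 samples = c(rep(1, w), 0)),
            class = "pulse_shape")
}

# deposition event data.frame in one pixel with a duration attribute
event_df <- function(times, energies, duration, px = 0L, py = 0L) {
  n <- length(times)
  ev <- data.frame(primary = seq_len(n), px = rep(px, n), py = rep(py, n),
                   energy = energies, time = times,
                   origin = rep("op", n))
  attr(ev, "duration") <- duration
  ev
}

# single-pixel counting configuration around a rectangular pulse
rect_config <- function(behavior, w, tau_np = w, threshold = 0.5) {
  counting_config(behavior, threshold = threshold,
                  tau_pd = min(w, tau_np), tau_np = tau_np)
}

# count a monoenergetic Poisson pulse train with a rectangular pulse and
# return the registered total count rate (counts/s)
rect_count_rate <- function(behavior, rate_per_ns, w, tau_np, duration,
                            seed) {
  set.seed(seed)
  times <- sample_arrivals(rate_per_ns * 1e9, 1, duration)
  r <- pcdpileup:::cpp_count_events(times, rep(1, length(times)),
                                    rect_pulse(w)$samples, 0.5,
                                    min(w, tau_np),
                                    if (behavior == "P") 0L else tau_np,
                                    behavior == "P", duration)
  length(r$time) / (duration * 1e-9)
}
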