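test_that("counting trivial cases: empty train, isolated pulse", {
  det <- detector_preset("iDCD-CZT")
  cfg <- det$counting
  zero <- synthesize(event_df(numeric(0), numeric(0), 1000),
                     det$pulse, NULL, 1000)
  expect_equal(nrow(count_np(zero, cfg)), 0)
  expect_equal(nrow(count_p(zero, cfg)), 0)
  # one isolated maximum-energy pulse gives exactly one count, for both
  # behaviors, with the full amplitude registered
  amp <- 120 + fwhm_at(det$resolution, 120)
  tr <- synthesize(event_df(200, amp, 1000), det$pulse, NULL, 1000)
  for (f in list(count_np, count_p)) {
    r <- f(tr, cfg)
    expect_equal(nrow(r), 1)
    expect_equal(r$energy, amp, tolerance = 1e-9)
  }
})

test_that("pile-up within the peak-detection window registers one summed count", {
  det <- detector_preset("iDCD-CZT")
  cfg <- det$counting
  tr <- synthesize(event_df(c(100, 105), c(60, 60), 1000), det$pulse,
                   NULL, 1000)
  r <- count_np(tr, cfg)
  expect_equal(nrow(r), 1)
  expect_equal(r$energy, max(tr$signal), tolerance = 1e-12)
  expect_gt(r$energy, 60)  # summed waveform peaks above a single pulse
})

test_that("a sustained plateau above threshold yields exactly one P-like count", {
  cfg <- counting_config("P", threshold = 20, tau_pd = 10, tau_np = 10)
  sig <- c(rep(0, 5), rep(50, 10 * cfg$tau_pd), rep(0, 5))
  r <- pcdpileup:::cpp_count_signal(sig, 20, cfg$tau_pd, 0L, TRUE)
  expect_length(r$time, 1)
  # NP-like on the same plateau: one count per elapsed analysis window
  # would be wrong — a fresh crossing is required, so also exactly one
  r2 <- pcdpileup:::cpp_count_signal(sig, 20, 10L, 24L, FALSE)
  expect_length(r2$time, 1)
})

test_that("binning centers, discards and section bookkeeping", {
  cfg <- counting_config("NP")
  recs <- data.frame(pixel = 0L, time = c(10, 20, 30, 40),
                     energy = c(20.2, 300, 19.2, 250.4))
  b <- bin_counts(recs, cfg, 1000)
  expect_equal(sum(b$counts), 2)  # 300 and 19.2 discarded
  expect_equal(b$counts[b$bin_centers == 20], 1)
  expect_equal(b$counts[b$bin_centers == 250], 1)
  expect_lte(sum(b$counts), nrow(recs))
  expect_error(sectioned_counts(recs, cfg, 1000, 1000), "sections")
})

test_that("sectioned counts are stationary and Poisson at low rate", {
  det <- make_fixture("ideal-detector")
  spec <- rescale_total(make_fixture("toy-spectrum"), 4e6)
  ev <- simulate_exposure(det, spec, 4e6, seed = 13)
  recs <- count_exposure(ev, det, seed = 13)
  sec <- sectioned_counts(recs, det$counting, 4e6, 4e6 / 400,
                          det$geometry$n_pixels)
  tot <- apply(sec$counts, 3, sum)  # counts per section, whole array
  # stationarity: section means consistent with the overall mean
  expect_lt(abs(mean(tot) - sum(recs$time >= 0) / 400),
            3 * sd(tot) / sqrt(400))
  # Poisson: variance-to-mean ratio near 1 (3 sigma on 400 sections)
  vm <- var(tot) / mean(tot)
  expect_lt(abs(vm - 1), 3 * sqrt(2 / 399))
})

test_that("analytic dead-time formulas", {
  expect_equal(analytic_rate("NP", 1e6, 1e-7), 1e6 / 1.1)
  expect_equal(analytic_rate("P", 1e6, 1e-7), 1e6 * exp(-0.1))
  expect_equal(analytic_rate("NP", 1e6, 0), 1e6)
  expect_equal(analytic_rate("P", 1e6, 0), 1e6)
  expect_error(analytic_rate("P", 1e6, -1), "negative")
})

test_that("NP count rate saturates monotonically; P-like peaks", {
  # rectangular-pulse monoenergetic trains across the decade rate sweep
  # map the decade fluence-rate sweep to per-pixel event rates of the
  # 500 um pixel (2.5e-5 .. 0.25 events/ns) with detector-like windows
  rates <- 2.5e-5 * 10^(0:4) * 1e9  # events/s on one pixel
  durs <- c(4e8, 4e7, 4e6, 1.5e6, 1e6)
  np <- vapply(seq_along(rates), function(i)
    rect_count_rate("NP", rates[i] * 1e-9, 5, 24, durs[i], 17),
    numeric(1))
  expect_true(all(diff(np) > 0))
  p <- vapply(seq_along(rates), function(i)
    rect_count_rate("P", rates[i] * 1e-9, 100, 100, durs[i], 18),
    numeric(1))
  expect_gt(max(p), p[length(p)])  # a maximum strictly inside the sweep
  # NP bound: at most floor(duration / tau_np) + 1 counts
  r <- rect_count_rate("NP", 1, 5, 500, 1e5, 19)
  expect_lte(r * 1e5 * 1e-9, floor(1e5 / 500) + 1)
  # vanishing rate: P and NP totals agree exactly on the same train
  set.seed(20)
  times <- sample_arrivals(1e3, 1, 1e7)
  pulse <- rect_pulse(5)$samples
  rn <- pcdpileup:::cpp_count_events(times, rep(1, length(times)), pulse,
                                     0.5, 5L, 500L, FALSE, 1e7)
  rp <- pcdpileup:::cpp_count_events(times, rep(1, length(times)), pulse,
                                     0.5, 5L, 0L, TRUE, 1e7)
  expect_identical(rn$time, rp$time)
})
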