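test_that("pPSF of the ideal linear detector is the identity", {
  det <- make_fixture("ideal-detector")
  zero <- rescale_total(rqa9_spectrum(), 0)
  pp <- estimate_ppsf(det, zero, probe_energies = c(60, 120),
                      probe_rate = 1e5, duration = 2e7, seed = 7,
                      n_sections = 10)
  for (e in c(60, 120)) {
    d <- ppsf_slice(pp, e)
    expect_lt(abs(d$h[d$bin == e] - 1),
              4 * max(d$se[d$bin == e], 0.02))
    # elsewhere only the probe's own (rare) self-pile-up contributes
    expect_lt(sum(abs(d$h[d$bin != e])), 0.02)
  }
  # off-center pixels see nothing (full absorption in the entry pixel)
  expect_equal(sum(abs(pp$h[, 1, 1, ])), 0)
})

test_that("pPSF estimation is bit-reproducible under the same seed", {
  det <- detector_preset("iDCD-CZT")
  op <- rqa9_spectrum(5e6)
  a <- estimate_ppsf(det, op, probe_energies = 80, probe_rate = 1e6,
                     duration = 2e5, seed = 33, n_sections = 4)
  b <- estimate_ppsf(det, op, probe_energies = 80, probe_rate = 1e6,
                     duration = 2e5, seed = 33, n_sections = 4)
  expect_identical(a$h, b$h)
  expect_identical(a$se, b$se)
  c <- estimate_ppsf(det, op, probe_energies = 80, probe_rate = 1e6,
                     duration = 2e5, seed = 34, n_sections = 4)
  expect_false(identical(a$h, c$h))
})

test_that("at zero operating rate the center-pixel pPSF is a sub-probability", {
  det <- detector_preset("iDCD-CZT")
  zero <- rescale_total(rqa9_spectrum(), 0)
  pp <- estimate_ppsf(det, zero, probe_energies = c(40, 80, 120),
                      probe_rate = 1e5, duration = 2e7, seed = 9,
                      n_sections = 10)
  ix <- match(0, pp$offsets$x); iy <- match(0, pp$offsets$y)
  for (ie in seq_along(pp$probe_energies)) {
    tot <- sum(pp$h[, ix, iy, ie])
    se <- sqrt(sum(pp$se[, ix, iy, ie]^2))
    # NP counting: at most one center-pixel count per probe photon
    expect_lte(tot, 1 + 3 * se)
    # non-negative up to estimator noise
    expect_gte(min(pp$h[, ix, iy, ie]), -2 * max(pp$se[, ix, iy, ie]))
  }
  # crosstalk locality: |h| beyond the nearest neighbours is negligible
  far <- abs(outer(pp$offsets$x, rep(1, 5)) ) > 1 |
    abs(outer(rep(1, 5), pp$offsets$y)) > 1
  h120 <- pp$h[, , , 3]
  center_mass <- sum(abs(h120[, ix, iy]))
  far_mass <- sum(abs(aperm(h120, c(2, 3, 1))[far]))
  expect_lt(far_mass, 0.05 * center_mass)
})

test_that("linear response reproduces a brute-force convolution", {
  # toy: 3 bins, 3x1 pixels, 2 energies, hand-checkable psf
  psf <- list(values = array(0, c(3, 3, 1, 2)),
              bin_centers = 1:3,
              offsets = list(x = -1:1, y = 0),
              energies = c(10, 20))
  psf$values[1, 2, 1, 1] <- 0.8   # on-pixel response, E=10 -> bin 1
  psf$values[1, 3, 1, 1] <- 0.1   # crosstalk to the dn = +1 neighbour
  psf$values[3, 2, 1, 2] <- 0.5   # E=20 -> bin 3
  phi <- array(0, c(3, 1, 2))
  phi[1, 1, 1] <- 2; phi[2, 1, 2] <- 4
  out <- linear_response(psf, phi, area = 0.25)
  # brute force by hand:
  # pixel 1, bin 1: on-pixel response to the E=10 beam on pixel 1
  expect_equal(out[1, 1, 1], 0.8 * 2 * 0.25)
  # pixel 2, bin 1: dn = +1 crosstalk from pixel 1
  expect_equal(out[1, 2, 1], 0.1 * 2 * 0.25)
  expect_equal(out[3, 2, 1], 0.5 * 4 * 0.25)
  expect_equal(sum(out), (0.8 * 2 + 0.1 * 2 + 0.5 * 4) * 0.25)
  # all-zero spectrum -> zero rates
  expect_true(all(linear_response(psf, array(0, c(3, 1, 2)), 0.25) == 0))
})

test_that("identity psf turns the spectrum into rates d_k = Phi_k * A", {
  psf <- list(values = array(0, c(2, 1, 1, 2)),
              bin_centers = c(10, 20), offsets = list(x = 0, y = 0),
              energies = c(10, 20))
  psf$values[1, 1, 1, 1] <- 1
  psf$values[2, 1, 1, 2] <- 1
  phi <- array(c(5, 7), c(1, 1, 2))
  out <- linear_response(psf, phi, area = 0.25)
  expect_equal(as.numeric(out), c(5, 7) * 0.25)
})

test_that("baseline rates are shift-invariant across interior pixels", {
  det <- detector_preset("iDCD-CZT")
  op <- rqa9_spectrum(1e6)
  br <- baseline_rates(det, op, duration = 4e6, seed = 15, n_sections = 8)
  tot <- colSums(br$rates$counts)
  m <- mean(tot)
  expect_true(all(abs(tot - m) < 4 * sqrt(m)))
  # low-rate sanity: total rate matches the interacting, above-threshold
  # photon rate within Monte-Carlo error
  p_int <- sum(op$fluence * (1 - transmission("CZT", 2, op$energy))) /
    total_fluence(op)
  expected <- total_fluence(op) * 25 * det$geometry$pixel_area_mm2 *
    p_int * 4e6 * 1e-9  # counts over the 4 ms exposure
  observed <- sum(tot)
  expect_lt(abs(observed - expected) / expected, 0.1)
})
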