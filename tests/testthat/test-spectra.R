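test_that("tube spectrum has the right support and hardens under filtration", {
  s <- generate_tube_spectrum(120)
  expect_equal(s$energy, 1:120)
  # positive across the interior; the Kramers shape vanishes exactly at kVp
  expect_true(all(s$fluence[s$energy > 15 & s$energy < 120] > 0))
  expect_equal(s$fluence[s$energy == 120], 0)
  expect_error(generate_tube_spectrum(30), "kVp")
  # deterministic
  expect_identical(s$fluence, generate_tube_spectrum(120)$fluence)
  # adding a filter reduces fluence and does not soften the beam
  f <- filter_spectrum(s, "aluminium", 5)
  expect_lt(total_fluence(f), total_fluence(s))
  expect_true(all(f$fluence <= s$fluence))
  expect_gte(mean_energy(f), mean_energy(s))
  expect_identical(filter_spectrum(s, "copper", 0)$fluence, s$fluence)
  # filtering twice equals filtering once with the summed thickness
  expect_equal(filter_spectrum(filter_spectrum(s, "aluminium", 2),
                               "aluminium", 3)$fluence,
               filter_spectrum(s, "aluminium", 5)$fluence,
               tolerance = 1e-12)
})

test_that("mean energy and rescaling behave as defined", {
  mono <- spectral_fluence(1:100, c(rep(0, 69), 1e6, rep(0, 30)))
  expect_equal(mean_energy(mono), 70)
  two <- spectral_fluence(1:100, replace(rep(0, 100), c(60, 80), 1))
  expect_equal(mean_energy(two), 70)
  r <- rescale_total(two, 1e8)
  expect_equal(total_fluence(r), 1e8)
  expect_equal(r$fluence[60] / r$fluence[80], 1)
  expect_equal(total_fluence(rescale_total(two, 0)), 0)
  expect_error(rescale_total(rescale_total(two, 0), 5), "all-zero")
  expect_error(mean_energy(rescale_total(two, 0)), "empty")
})

test_that("half-value layer: closed form and beam-hardening direction", {
  mono <- spectral_fluence(1:100, replace(rep(0, 100), 60, 1e6))
  mu <- mass_attenuation("aluminium", 60) * material("aluminium")$density
  expect_equal(half_value_layer(mono), 10 * log(2) / mu, tolerance = 1e-3)
  s <- generate_tube_spectrum(120)
  hvl1 <- half_value_layer(s)
  # harder beam (more Cu) has a larger HVL
  expect_gt(half_value_layer(filter_spectrum(s, "copper", 0.5)), hvl1)
  # second HVL is at least the first (beam hardening)
  halved <- filter_spectrum(s, "aluminium", hvl1)
  expect_gte(half_value_layer(halved), hvl1 * (1 - 1e-6))
})

test_that("thickness matching: identity and density scaling", {
  s <- rqa9_spectrum()
  expect_equal(match_thickness(s, list("CZT", 2), "CZT"), 2,
               tolerance = 1e-3)
  czt <- material("CZT")
  dense <- mixture(stats::setNames(czt$fractions, czt$elements),
                   density = 2 * czt$density, name = "dense-CZT")
  expect_equal(match_thickness(s, list("CZT", 2), dense), 1,
               tolerance = 1e-3)
})

test_that("spectrum file round trip conserves fluence", {
  path <- tempfile(fileext = ".txt")
  s <- make_fixture("toy-spectrum")
  write_spectrum(s, path)
  r <- load_spectrum(path)
  expect_equal(r$fluence, s$fluence, tolerance = 1e-9)
  # 2 keV grid: total conserved under rebinning
  path2 <- tempfile(fileext = ".txt")
  writeLines(c("# test", paste(seq(10, 80, 2), 100)), path2)
  r2 <- load_spectrum(path2)
  expect_equal(total_fluence(r2), 36 * 100, tolerance = 1e-9)
  # single line -> monoenergetic
  path3 <- tempfile(fileext = ".txt")
  writeLines("59.5 123", path3)
  r3 <- load_spectrum(path3)
  expect_equal(sum(r3$fluence > 0), 1)
  expect_equal(total_fluence(r3), 123)
  writeLines(c("10 5", "8 5"), path3)
  expect_error(load_spectrum(path3), "increasing")
})

test_that("lesion perturbation follows the attenuation formula", {
  op <- rqa9_spectrum(1e8)
  expect_equal(lesion_perturbation(op, lesion_spec(rho_x = 0))$delta,
               rep(0, length(op$energy)))
  p <- lesion_perturbation(op, lesion_spec())
  expect_true(all(p$delta <= 0))
  expect_true(attr(p, "small_signal"))
  carry <- op$fluence > 1e-9 * max(op$fluence)
  expect_lte(max(abs(p$delta[carry] / op$fluence[carry])), 0.01)
  # relative change is independent of the total fluence
  p2 <- lesion_perturbation(rescale_total(op, 1e5), lesion_spec())
  expect_equal(p$relative, p2$relative, tolerance = 1e-12)
  mu <- mass_attenuation("iodine_lesion", 60)
  expect_equal(p$relative[op$energy == 60], exp(-mu * 7e-4) - 1,
               tolerance = 1e-12)
  # perturbation magnitude grows with rho_x at every energy (the doubled
  # lesion sits right at the 1% boundary, so silence the flag here)
  p3 <- suppressWarnings(lesion_perturbation(op, lesion_spec(rho_x = 14e-4)))
  expect_true(all(abs(p3$delta) >= abs(p$delta)))
  # an implausibly thick lesion trips the small-signal flag
  expect_warning(pbad <- lesion_perturbation(op, lesion_spec(rho_x = 0.1)),
                 "small-signal")
  expect_false(attr(pbad, "small_signal"))
})
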