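test_that("Poisson arrivals have the right count and spacing statistics", {
  expect_length(sample_arrivals(0, 1, 1e6), 0)
  set.seed(4)
  # expectation: rate 1e6 mm^-2 s^-1 over 0.25 mm^2 for 1 ms -> mean 250
  counts <- replicate(200, length(sample_arrivals(1e6, 0.25, 1e6)))
  expect_lt(abs(mean(counts) - 250), 3 * sqrt(250 / 200))
  # inter-arrival exponentiality (KS at alpha = 0.01)
  t <- sample_arrivals(4e8, 0.25, 1e5)
  gaps <- diff(t)
  # suppress the tie warning: runif's 32-bit grid can collide once in 1e4
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp",
                                        rate = 1 / mean(gaps)))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_arrivals(-1, 1, 1), "non-negative")
})

test_that("photoelectric below all K edges deposits fully in the entry pixel", {
  det <- detector_preset("iDCD-CZT")
  set.seed(11)
  n <- 2000
  x <- runif(n, 600, 900)  # inside pixel (1, 1)
  y <- runif(n, 600, 900)
  dep <- interact_photons(det, rep(9, n), x, y)
  full <- dep$energy > 8.999 & dep$px == 1 & dep$py == 1
  expect_gt(mean(full), 0.99)
})

test_that("interaction fraction matches Beer-Lambert", {
  det <- detector_preset("iDCD-CZT")
  set.seed(21)
  n <- 2e4
  dep <- interact_photons(det, rep(100, n), runif(n, 0, 2500),
                          runif(n, 0, 2500))
  p <- 1 - transmission("CZT", 2, 100)
  frac <- length(unique(dep$primary)) / n
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("energy is conserved per primary and K-escape shifts deposits", {
  det <- detector_preset("iDCD-CZT")
  set.seed(31)
  n <- 3e4
  dep <- interact_photons(det, rep(120, n), runif(n, 0, 2500),
                          runif(n, 0, 2500))
  tot <- tapply(dep$energy, dep$primary, sum)
  expect_lte(max(tot), 120 + 1e-9)
  # Te K-escape: full-absorption-minus-line deposits in [89, 93] keV
  esc_te <- sum(dep$energy >= 120 - 31 & dep$energy <= 120 - 27)
  esc_cd <- sum(dep$energy >= 120 - 26 & dep$energy <= 120 - 23)
  flank <- sum(dep$energy >= 100 & dep$energy <= 104)
  expect_gt(esc_te, flank * 2)
  expect_gt(esc_cd, flank * 2)
})

test_that("reflector septa reduce the geometric acceptance", {
  iicd <- detector_preset("iICD-LaBr3")
  geom0 <- detector_geometry(500, c(5, 5), thickness_mm = 2.8,
                             septum_um = 0)
  open_det <- detector_model("iICD-open", "LaBr3:Ce", geom0,
                             iicd$resolution, iicd$pulse, iicd$counting)
  set.seed(41)
  n <- 2e4
  x <- runif(n, 0, 2500); y <- runif(n, 0, 2500)
  set.seed(42); d1 <- interact_photons(iicd, rep(60, n), x, y)
  set.seed(42); d0 <- interact_photons(open_det, rep(60, n), x, y)
  active_frac <- (380 / 500)^2
  f1 <- length(unique(d1$primary)) / n
  f0 <- length(unique(d0$primary)) / n
  expect_lt(abs(f1 / f0 - active_frac), 0.03)
  # with septa set to 0 the acceptance equals the direct-conversion layout
  expect_gt(f0, 0.9)  # 2.8 mm LaBr3 at 60 keV is nearly opaque
})

test_that("operating-beam realization is invariant to the probe (CRN)", {
  det <- detector_preset("iDCD-CZT")
  spec <- rqa9_spectrum(5e6)
  ev1 <- simulate_exposure(det, spec, 1e5, seed = 7)
  ev2 <- simulate_exposure(det, spec, 1e5, seed = 7,
                           probe = list(energy = 120, rate = 1e6))
  op2 <- ev2[ev2$origin == "op", ]
  for (cn in c("primary", "px", "py", "energy", "time"))
    expect_identical(ev1[[cn]], op2[[cn]])
  expect_gt(sum(ev2$origin == "probe"), 0)
  # probe photons enter only the target pixel footprint
  probe_dep <- ev2[ev2$origin == "probe", ]
  expect_true(all(abs(probe_dep$px - 2) <= 2))
  # zero-rate spectrum + probe only
  ev3 <- simulate_exposure(det, rescale_total(spec, 0), 1e5, seed = 7,
                           probe = list(energy = 80, rate = 1e6))
  expect_true(all(ev3$origin == "probe"))
  expect_error(simulate_exposure(det, spec, 1e5, seed = 1,
                                 probe = list(energy = 80, rate = 1e5,
                                              pixel = c(9, 9))),
               "outside")
})
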