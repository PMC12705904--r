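test_that("peak height and position recover a single band, with deterministic tie-breaks", {
  s <- make_spectrum(gaussian_band(std_grid, 1667, 12, 3.5))
  pk <- peak_height(s, "amide1")
  expect_equal(pk$height, 3.5, tolerance = 1e-6)
  expect_equal(pk$position, 1667)

  # flat zero window: height 0, position at the nominal center (tie rule)
  pk0 <- peak_height(flat_spectrum(0), "amide1")
  expect_identical(pk0$height, 0)
  expect_identical(pk0$position, 1667)

  # two equal maxima equidistant from the center: lower wavenumber wins
  y <- rep(0, 701)
  y[std_grid %in% c(1657, 1677)] <- 2
  pk2 <- peak_height(make_spectrum(y), "amide1")
  expect_identical(pk2$position, 1657)
})

test_that("FWHM matches closed forms for Gaussian and Lorentzian bands", {
  sg <- make_spectrum(gaussian_band(std_grid, 1667, 10, 1))
  expect_equal(fwhm(sg, "amide1"), 2 * sqrt(2 * log(2)) * 10, tolerance = 0.1 / 23.5)

  sl <- make_spectrum(lorentzian_band(std_grid, 1243, 10, 1))
  expect_equal(fwhm(sl, "amide3"), 20, tolerance = 0.1 / 20)

  # band truncated by the window edge: crossing not reached inside the window
  wide <- make_spectrum(gaussian_band(std_grid, 1667, 80, 1))
  expect_error(fwhm(wide, "amide1"), class = "dentinemap_fwhm_error")
})

test_that("integrated area matches trapezoid and closed-form oracles", {
  expect_identical(integrated_area(flat_spectrum(0), "amide1"), 0)

  # triangle of height 1 spanning exactly the amide1 window: area = base / 2
  w <- band_window("amide1")
  y <- pmax(0, 1 - abs(std_grid - 1667) / 52)
  expect_equal(integrated_area(make_spectrum(y), "amide1"), 52, tolerance = 0.01)

  # Gaussian fully inside the window: A * sigma * sqrt(2*pi) within 1%
  A <- 2.4; sig <- 9
  s <- make_spectrum(gaussian_band(std_grid, 1667, sig, A))
  expect_equal(integrated_area(s, "amide1"), A * sig * sqrt(2 * pi),
               tolerance = 0.01)

  # without chord subtraction the integral is additive over shared endpoints
  s2 <- make_spectrum(gaussian_band(std_grid, 1660, 25, 3) + 1)
  wa <- data.frame(name = "a", center = 1640, lo = 1615, hi = 1660)
  wb <- data.frame(name = "b", center = 1690, lo = 1660, hi = 1719)
  whole <- data.frame(name = "w", center = 1667, lo = 1615, hi = 1719)
  expect_equal(integrated_area(s2, wa, chord = FALSE) +
                 integrated_area(s2, wb, chord = FALSE),
               integrated_area(s2, whole, chord = FALSE), tolerance = 1e-12)
})

test_that("doublet detection flags resolved pairs and rejects merged or single bands", {
  two <- make_spectrum(gaussian_band(std_grid, 1243, 7, 1) +
                         gaussian_band(std_grid, 1270, 7, 0.9))
  d2 <- doublet_status(two)
  expect_true(d2$flag)
  expect_gt(d2$contrast, 0.5)

  one <- make_spectrum(gaussian_band(std_grid, 1243, 10, 1))
  d1 <- doublet_status(one)
  expect_false(d1$flag)
  expect_identical(d1$contrast, 0)

  # separation below min_sep: merged pair is not a doublet
  merged <- make_spectrum(gaussian_band(std_grid, 1243, 3, 1) +
                            gaussian_band(std_grid, 1249, 3, 0.95))
  expect_false(doublet_status(merged)$flag)
})

test_that("SNR follows the printed truncate-to-one-decimal convention", {
  pairs <- list(c(28, 8), c(62, 7), c(50, 5), c(50, 3), c(39, 2))
  printed <- vapply(pairs, function(p) snr(p[1], p[2])$printed, numeric(1))
  expect_equal(printed, c(3.5, 8.8, 10, 16.6, 19.5))
  expect_equal(snr(62, 7)$value, 62 / 7)
  expect_identical(snr(0, 5)$value, 0)
  expect_error(snr(10, 0), "positive")
})

test_that("estimated SNR grows with acquisition time on synthetic replicates", {
  set.seed(21)
  acq <- c(6, 12, 24, 48)
  n_rep <- 30
  res <- expand.grid(acq = acq, rep = seq_len(n_rep))
  res$snr <- vapply(seq_len(nrow(res)), function(i) {
    s <- generate_spectrum(spectrum_spec("T1", "A", 800, acq_min = res$acq[i]))
    estimate_snr(baseline_correct(s))$value
  }, numeric(1))
  rho <- cor(res$acq, res$snr, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("extract_features returns the full descriptor row", {
  s <- generate_spectrum(spectrum_spec("T3", "D", 700, seed = 9))
  f <- extract_features(s)
  expect_named(f, c("h_amide1", "h_amide3", "h_1450", "h_carbonate",
                    "fwhm_amide1", "fwhm_amide3", "area_amide1", "area_amide3",
                    "doublet_flag", "doublet_contrast", "snr"))
  expect_true(all(c(f$h_amide1, f$h_amide3, f$area_amide1, f$area_amide3) >= 0))
  expect_true(f$doublet_flag)
})
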