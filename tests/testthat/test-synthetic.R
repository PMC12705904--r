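test_that("identical seeds and parameters give bit-identical spectra", {
  m <- degradation_model()
  sp <- spectrum_spec("T1", "A", 300, seed = 99)
  s1 <- generate_spectrum(sp, m)
  s2 <- generate_spectrum(sp, m)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- generate_spectrum(spectrum_spec("T1", "A", 300, seed = 100), m)
  expect_false(identical(s1$intensity, s3$intensity))

  tr1 <- generate_transect("T1", "B", n_points = 4, seed = 7)
  tr2 <- generate_transect("T1", "B", n_points = 4, seed = 7)
  expect_identical(lapply(tr1$spectra, `[[`, "intensity"),
                   lapply(tr2$spectra, `[[`, "intensity"))

  i1 <- generate_indentation("T1", "test", c(50, 150, 250), seed = 5)
  i2 <- generate_indentation("T1", "test", c(50, 150, 250), seed = 5)
  expect_identical(i1$depth_um, i2$depth_um)
})

test_that("degradation factor has the stated shape and Amide I heights follow it", {
  m <- degradation_model(d_scale = 250, amide1_floor = 0.35)
  d <- seq(0, 2000, by = 50)
  f <- degradation_factor(m, d, m$amide1_floor)
  expect_true(all(diff(f) >= 0))
  expect_equal(f[1], 0.35)
  expect_lt(abs(f[length(f)] - 1), 1e-3)

  # control spectra: Amide I peak height constant across distances (zero noise)
  h_ctrl <- vapply(c(50, 400, 900, 1500), function(d)
    max(noiseless_spectrum(d, "control", bg_coefs = c(0, 0, 0))$intensity[
      std_grid >= 1615 & std_grid <= 1719]), numeric(1))
  expect_equal(diff(range(h_ctrl)), 0, tolerance = 1e-12)

  # naocl height ratio at 50 vs 1500 um equals f(50)/f(1500), evaluated by hand
  h50 <- max(noiseless_spectrum(50, bg_coefs = c(0, 0, 0))$intensity[
    std_grid >= 1615 & std_grid <= 1719])
  h1500 <- max(noiseless_spectrum(1500, bg_coefs = c(0, 0, 0))$intensity[
    std_grid >= 1615 & std_grid <= 1719])
  f_hand <- function(d) 0.35 + (1 - 0.35) * (1 - exp(-d / 250))
  expect_equal(h50 / h1500, f_hand(50) / f_hand(1500), tolerance = 1e-10)
})

test_that("noise standard deviation scales as 1/sqrt(acquisition time)", {
  set.seed(404)
  n_rep <- 100
  resid_sd <- function(acq) {
    clean <- generate_spectrum(
      spectrum_spec("T1", "A", 500, acq_min = acq), sigma0 = 0)
    res <- replicate(n_rep, {
      s <- generate_spectrum(spectrum_spec("T1", "A", 500, acq_min = acq))
      s$intensity - clean$intensity
    })
    sd(as.numeric(res))
  }
  ratio <- resid_sd(12) / resid_sd(24)
  expect_equal(ratio, sqrt(2), tolerance = 0.03)
})

test_that("transect distances follow the sampling designs", {
  tr <- generate_transect("T5", "A", n_points = 18, spacing_um = 50, seed = 1)
  expect_equal(tr$manifest$distance_um, seq(50, 900, by = 50))

  trc <- generate_transect("T12", "A", n_points = 6, spacing_um = 150,
                           treatment = "control", seed = 2)
  expect_equal(trc$manifest$distance_um, seq(150, 900, by = 150))

  tr1 <- generate_transect("T5", "C", n_points = 1, spacing_um = 75, seed = 3)
  expect_equal(tr1$manifest$distance_um, 75)

  # optional extra point at a stated offset inside the CDJ
  tr_cdj <- generate_transect("T5", "D", n_points = 3, spacing_um = 50,
                              cdj_um = 1700, cdj_offset_um = 50, seed = 4)
  expect_equal(tr_cdj$manifest$distance_um, c(50, 100, 150, 1650))
  expect_error(generate_transect("T5", "D", n_points = 0, seed = 1))
})

test_that("monotone degradation: noiseless heights and areas non-decreasing with distance", {
  m <- degradation_model()
  d <- seq(50, 900, by = 50)
  feats <- do.call(rbind, lapply(d, function(di)
    extract_features(noiseless_spectrum(di, model = m))))
  tol <- 1e-6
  expect_true(all(diff(feats$h_amide1) > -tol))
  expect_true(all(diff(feats$h_amide3) > -tol))
  expect_true(all(diff(feats$area_amide1) > -tol))
  expect_true(all(diff(feats$area_amide3) > -tol))
  # doublet contrast recovers with distance and the near-lumen doublet is lost
  expect_false(feats$doublet_flag[1])
  expect_true(feats$doublet_flag[length(d)])
})

test_that("inter-tubular spectra fail the QI filter nearly always", {
  set.seed(77)
  rejected <- vapply(1:40, function(i) {
    s <- generate_spectrum(
      spectrum_spec("T1", "A", 600, locus = "inter_tubular", seed = 1000 + i))
    !score_spectrum(s)$accepted
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("indentation depths follow a - b*ln(d + c) with the stated edge cases", {
  # sigma = 0 and distance + c = 1: depth equals a exactly
  r0 <- generate_indentation("T1", "test", 0,
                             params = list(a = 70, b = 5, c = 1, sigma = 0))
  expect_identical(r0$depth_um, 70)

  # exact hand evaluation at three distances
  p <- list(a = 80, b = 6, c = 2, sigma = 0)
  r <- generate_indentation("T1", "test", c(10, 100, 500), params = p)
  expect_equal(r$depth_um, 80 - 6 * log(c(10, 100, 500) + 2), tolerance = 1e-12)

  # near-lumen depths exceed far depths in expectation (test defaults)
  set.seed(12)
  near <- generate_indentation("T1", "test", rep(50, 1000))$depth_um
  far <- generate_indentation("T1", "test", rep(850, 1000))$depth_um
  expect_gt(mean(near), mean(far))

  # control defaults are shallower and flatter than test defaults
  pt <- indentation_defaults("test"); pc <- indentation_defaults("control")
  expect_gt(pt$b, pc$b)
  expect_gt(pt$a - pt$b * log(51), pc$a - pc$b * log(51))

  expect_error(generate_indentation("T1", "test", 50,
                                    params = list(a = 1, b = 1, c = 0, sigma = 0)),
               "c must be > 0")
  expect_error(generate_indentation("T1", "test", -5))
})

test_that("morphometry generator produces valid, maturity-faithful tables", {
  m <- generate_morphometry(c("T1", "T2", "T3"), mi = c(2.5, 4.2, 6.1), seed = 8)
  expect_identical(nrow(m), 3L)
  mt <- morphometry_table(m)
  expect_true(all(mt$mass_v2 >= mt$mass_v1))
  expect_true(all(mt$vol_instrumented_cm3 > 0))
  expect_equal(mt$mi, c(2.5, 4.2, 6.1), tolerance = 0.15)
  m2 <- generate_morphometry(c("T1", "T2", "T3"), mi = c(2.5, 4.2, 6.1), seed = 8)
  expect_identical(m2, m)
})
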