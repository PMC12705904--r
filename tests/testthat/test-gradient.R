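test_that("distance bins are half-open with Table-style labels", {
  bins <- distance_bins()
  expect_identical(nrow(bins), 9L)
  expect_identical(bins$label[1], "Up to 100 um")
  expect_identical(bins$label[9], "> 800-900 um")
  b <- assign_bin(c(50, 100, 100.5, 900, 950))
  expect_identical(as.character(b),
                   c("Up to 100 um", "Up to 100 um", "> 100-200 um",
                     "> 800-900 um", NA))
})

test_that("binned OLS matches the normal-equations oracle and handles exact lines", {
  # exact line: area = 2 + 0.05 * distance -> 5 per 100 um, zero-width CI
  d <- data.frame(distance_um = seq(50, 900, by = 50),
                  area_amide1 = 2 + 0.05 * seq(50, 900, by = 50),
                  accepted = TRUE)
  fit <- suppressWarnings(binned_linear_models(d, bands = "area_amide1", strata = NULL))
  ent <- fit[fit$bin == "Entire thickness", ]
  expect_equal(ent$coefficient, 5, tolerance = 1e-6)
  expect_lt(ent$ci_hi - ent$ci_lo, 1e-8)

  # noisy fixture vs closed-form normal equations, to 1e-8
  set.seed(42)
  d2 <- data.frame(distance_um = rep(seq(100, 900, by = 100), 3),
                   accepted = TRUE)
  d2$area_amide1 <- 10 + 0.02 * d2$distance_um + rnorm(nrow(d2))
  fit2 <- binned_linear_models(d2, bands = "area_amide1", strata = NULL)
  ent2 <- fit2[fit2$bin == "Entire thickness", ]
  X <- cbind(1, d2$distance_um / 100)
  beta <- solve(t(X) %*% X, t(X) %*% d2$area_amide1)
  expect_equal(ent2$coefficient, beta[2], tolerance = 1e-8)

  # covariate adjustment: ei enters when it varies
  d2$ei_mm <- rep(c(0.03, 0.05, 0.07), each = 9)
  d2$area_amide1 <- d2$area_amide1 + 50 * d2$ei_mm
  fit3 <- binned_linear_models(d2, bands = "area_amide1", strata = NULL)
  ent3 <- fit3[fit3$bin == "Entire thickness", ]
  X3 <- cbind(1, d2$distance_um / 100, d2$ei_mm)
  beta3 <- solve(t(X3) %*% X3, t(X3) %*% d2$area_amide1)
  expect_equal(ent3$coefficient, beta3[2], tolerance = 1e-8)
})

test_that("sparse or degenerate bins are flagged instead of fitted", {
  d <- data.frame(distance_um = c(50, 100, 350, 350, 350, 420),
                  area_amide1 = c(1, 2, 3, 4, 5, 6), accepted = TRUE)
  fit <- binned_linear_models(d, bands = "area_amide1", strata = NULL)
  expect_identical(fit$status[fit$bin == "Up to 100 um"], "insufficient data")
  expect_identical(fit$status[fit$bin == "> 300-400 um"], "collinear")
  expect_identical(fit$status[fit$bin == "> 500-600 um"], "insufficient data")
  expect_error(binned_linear_models(d[0, ]), "empty")
  expect_error(binned_linear_models(transform(d, accepted = FALSE)), "accepted")
})

test_that("decay fit recovers noiseless parameters and the analytic boundary", {
  d <- seq(50, 900, by = 50)
  y <- 1.0 - (1.0 - 0.2) * exp(-d / 250)
  fit <- fit_decay(d, y)
  expect_equal(fit$y0, 0.2, tolerance = 1e-4)
  expect_equal(fit$y_inf, 1.0, tolerance = 1e-4)
  expect_equal(fit$lambda, 250, tolerance = 1e-4)
  expect_equal(fit$boundary_um, fit$lambda * log(20), tolerance = 1e-10)
  expect_equal(fit$boundary_um, 250 * log(20), tolerance = 1e-3)
  expect_true(fit$lambda_identifiable)
  expect_gt(fit$r2, 0.999)

  # exactly constant data: unidentifiable flag, no lambda
  flat <- fit_decay(d, rep(0.7, length(d)))
  expect_false(flat$lambda_identifiable)
  expect_true(is.na(flat$lambda))

  # noisy flat data: flagged unidentifiable in most replicates
  set.seed(31)
  flags <- replicate(40, fit_decay(d, 0.7 + rnorm(length(d), 0, 0.05))$lambda_identifiable)
  expect_lt(mean(flags), 0.3)

  expect_error(fit_decay(d[1:4], y[1:4]), "5 points")
  expect_error(fit_decay(rep(c(100, 200), 4), rep(1, 8)), "distinct")
})

test_that("quality trend reports r2 with a caution flag for weak trends", {
  d <- seq(50, 900, by = 50)
  qi_clean <- 20 - (20 - 4) * (1 - exp(-d / 200))
  qt <- quality_trend(data.frame(distance_um = d, qi = qi_clean))
  expect_gt(qt$r2, 0.99)
  expect_false(qt$caution)

  set.seed(8)
  qi_noise <- sample(c(3, 4, 6, 10, 27), length(d), replace = TRUE)
  qt2 <- quality_trend(data.frame(distance_um = d, qi = qi_noise))
  expect_true(qt2$caution)

  expect_error(quality_trend(data.frame(distance_um = numeric(0), qi = numeric(0))),
               "empty")
})
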