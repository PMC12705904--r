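test_that("depth binning reproduces hand statistics and flags empty bins", {
  rec <- data.frame(distance_um = c(60, 70, 150, 450),
                    depth_um = c(60, 70, 66, 58))
  b <- bin_depths(rec)
  up100 <- b[b$bin == "Up to 100 um", ]
  expect_equal(up100$mean, 65)
  expect_equal(up100$sd, sd(c(60, 70)))
  expect_identical(up100$n, 2L)

  one <- b[b$bin == "> 100-200 um", ]
  expect_equal(one$mean, 66)
  expect_identical(one$sd, 0)

  expect_identical(b$status[b$bin == "> 300-400 um"], "No data")
  expect_true(is.na(b$mean[b$bin == "> 300-400 um"]))
  expect_error(bin_depths(rec[0, ]), "no indentation")
})

test_that("one-way ANOVA agrees with a brute-force sums-of-squares oracle", {
  set.seed(9)
  rec <- data.frame(
    distance_um = rep(c(50, 150, 250, 450), each = 6),
    depth_um = rnorm(24, rep(c(70, 66, 62, 60), each = 6), 4))
  av <- anova_bins(rec)

  # brute-force oracle
  g <- as.character(assign_bin(rec$distance_um))
  grand <- mean(rec$depth_um)
  ssb <- sum(tapply(rec$depth_um, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(rec$depth_um, g, function(x) sum((x - mean(x))^2)))
  k <- length(unique(g)); n <- nrow(rec)
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(av$f, f_oracle, tolerance = 1e-8)
  expect_equal(av$p, pf(f_oracle, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_identical(av$df, c(k - 1, n - k))

  # Bonferroni adjustment is exactly min(1, m * p_raw)
  m <- nrow(av$pairwise)
  expect_equal(m, choose(k, 2))
  expect_equal(av$pairwise$p_adj, pmin(1, m * av$pairwise$p_raw))

  # pairwise t against a hand-computed pooled-variance t test
  pw <- av$pairwise[1, ]
  x1 <- rec$depth_um[g == pw$bin1]; x2 <- rec$depth_um[g == pw$bin2]
  msw <- ssw / (n - k)
  t_hand <- (mean(x1) - mean(x2)) / sqrt(msw * (1 / length(x1) + 1 / length(x2)))
  expect_equal(pw$p_raw, 2 * pt(abs(t_hand), n - k, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA edge cases: identical bins give F = 0; thin data errors", {
  rec0 <- data.frame(distance_um = rep(c(50, 150), each = 3),
                     depth_um = rep(c(60, 62, 64), 2))
  av0 <- anova_bins(rec0)
  expect_equal(av0$f, 0, tolerance = 1e-12)
  expect_false(av0$degenerate)

  # zero within-bin variance everywhere: flagged degenerate
  recd <- data.frame(distance_um = rep(c(50, 150), each = 2),
                     depth_um = rep(c(60, 70), each = 2))
  expect_true(anova_bins(recd)$degenerate)

  expect_error(anova_bins(data.frame(distance_um = c(50, 150), depth_um = c(1, 2))),
               ">= 2")
})

test_that("near-lumen group comparison is a Welch test on the cutoff subset", {
  set.seed(14)
  tst <- generate_indentation("T1", "test", rep(seq(50, 900, 50), 4), seed = 2)
  ctl <- generate_indentation("C1", "control", rep(seq(50, 900, 50), 4), seed = 3)
  cmp <- compare_near_lumen(tst, ctl)
  xt <- tst$depth_um[tst$distance_um <= 200]
  xc <- ctl$depth_um[ctl$distance_um <= 200]
  ref <- t.test(xt, xc)
  expect_equal(cmp$p, ref$p.value)
  expect_equal(cmp$difference, mean(xt) - mean(xc))
  expect_identical(cmp$n_test, length(xt))

  # identical samples: zero difference
  same <- compare_near_lumen(tst, transform(tst, group = "control"))
  expect_equal(same$difference, 0)
  expect_error(compare_near_lumen(tst, ctl[0, ]), ">= 2")
})

test_that("logarithmic trend fit recovers exact parameters and flat data", {
  d <- c(10, 50, 100, 300, 600, 900)
  rec <- data.frame(distance_um = d, depth_um = 90 - 7 * log(d + 1))
  fit <- fit_log_trend(rec)
  expect_equal(fit$a, 90, tolerance = 1e-8)
  expect_equal(fit$b, 7, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)

  # with c estimated, the generating offset is recovered
  rec2 <- data.frame(distance_um = d, depth_um = 90 - 7 * log(d + 25))
  fit2 <- fit_log_trend(rec2, fit_c = TRUE)
  expect_equal(fit2$c, 25, tolerance = 1e-3)
  expect_equal(fit2$b, 7, tolerance = 1e-4)

  flat <- fit_log_trend(data.frame(distance_um = d, depth_um = rep(60, 6)))
  expect_equal(flat$b, 0, tolerance = 1e-10)

  expect_error(fit_log_trend(rec[1:2, ]), "3 records")
  expect_error(fit_log_trend(rec, c_offset = 0), "> 0")
})

test_that("synthetic defaults keep the test trend above the control trend to 900 um", {
  pt <- indentation_defaults("test"); pc <- indentation_defaults("control")
  d <- seq(0, 900, by = 10)
  mu_t <- pt$a - pt$b * log(d + pt$c)
  mu_c <- pc$a - pc$b * log(d + pc$c)
  expect_true(all(mu_t > mu_c))

  # binned test means decrease from the lumen outward in expectation
  set.seed(6)
  recs <- do.call(rbind, lapply(1:50, function(i)
    generate_indentation("T1", "test", seq(50, 900, 50), seed = i)))
  b <- bin_depths(recs)
  expect_gt(mean(b$mean[1:2]), mean(b$mean[8:9]))
})
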