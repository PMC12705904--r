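#' Bin indentation depths by distance from the lumen
#'
#' Mean, standard deviation and count of the total indentation distance in
#' half-open 100 um bins `(lo, hi]` from the canal lumen. Empty bins are
#' reported with status `"No data"`.
#'
#' @param records Indentation data.frame with columns `distance_um`,
#'   `depth_um` (see [read_indentation()]).
#' @param bin_width Bin width (um), default 100.
#' @param max_um Upper edge of the last bin; defaults to cover the data.
#' @return data.frame with `bin`, `mean`, `sd`, `n`, `status`.
#' @export
bin_depths <- function(records, bin_width = 100, max_um = NULL) {
  if (!nrow(records)) stop("no indentation records")
  if (is.null(max_um))
    max_um <- max(900, ceiling(max(records$distance_um) / bin_width) * bin_width)
  bins <- distance_bins(bin_width = bin_width, max_um = max_um)
  b <- assign_bin(records$distance_um, bins)
  out <- data.frame(bin = bins$label, mean = NA_real_, sd = NA_real_,
                    n = 0L, status = "No data", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bins))) {
    x <- records$depth_um[!is.na(b) & b == bins$label[i]]
    if (length(x)) {
      out$mean[i] <- mean(x)
      out$sd[i] <- if (length(x) > 1L) stats::sd(x) else 0
      out$n[i] <- length(x)
      out$status[i] <- "ok"
    }
  }
  out
}

#' One-way ANOVA of depth across distance bins with Bonferroni post hoc
#'
#' Tests whether mean indentation depth differs among the distance bins,
#' followed by all pairwise comparisons of non-empty bins with
#' Bonferroni-adjusted p-values (`p_adj = min(1, m * p_raw)`, `m` = number
#' of pairs; pooled-variance t tests, as in a classical post hoc).
#'
#' @param records Indentation data.frame with `distance_um`, `depth_um`.
#' @param bin_width Bin width (um), default 100.
#' @return List with `f` (F statistic), `p`, `df` (c(between, within)),
#'   `pairwise` (data.frame `bin1`, `bin2`, `diff`, `p_raw`, `p_adj`),
#'   and `degenerate` (TRUE when the within-bin variance is zero
#'   everywhere, leaving the F statistic undefined).
#' @export
anova_bins <- function(records, bin_width = 100) {
  if (!nrow(records)) stop("no indentation records")
  b <- assign_bin(records$distance_um,
                  distance_bins(bin_width = bin_width,
                                max_um = max(900, ceiling(max(records$distance_um) /
                                                            bin_width) * bin_width)))
  keep <- !is.na(b)
  depth <- records$depth_um[keep]
  bin <- droplevels(b[keep])
  counts <- table(bin)
  if (sum(counts >= 2L) < 2L || length(counts) < 2L)
    stop("ANOVA needs >= 2 non-empty bins with >= 2 records each")
  if (any(counts < 2L)) {
    keep2 <- bin %in% names(counts)[counts >= 2L]
    depth <- depth[keep2]; bin <- droplevels(bin[keep2])
  }
  fit <- stats::aov(depth ~ bin)
  tab <- summary(fit)[[1L]]
  msw <- tab["Residuals", "Mean Sq"]
  degenerate <- !is.finite(msw) || msw <= .Machine$double.eps * mean(depth^2 + 1)
  fstat <- if (degenerate && tab[1L, "Sum Sq"] <= .Machine$double.eps) 0
           else tab[1L, "F value"]
  pval <- tab[1L, "Pr(>F)"]
  lev <- levels(bin)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  pw <- data.frame(bin1 = pairs[1L, ], bin2 = pairs[2L, ],
                   diff = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  if (!degenerate) {
    dfw <- tab["Residuals", "Df"]
    for (j in seq_len(m)) {
      x1 <- depth[bin == pw$bin1[j]]; x2 <- depth[bin == pw$bin2[j]]
      se <- sqrt(msw * (1 / length(x1) + 1 / length(x2)))
      tstat <- (mean(x1) - mean(x2)) / se
      pw$diff[j] <- mean(x1) - mean(x2)
      pw$p_raw[j] <- 2 * stats::pt(abs(tstat), dfw, lower.tail = FALSE)
      pw$p_adj[j] <- min(1, m * pw$p_raw[j])
    }
  }
  list(f = unname(fstat), p = unname(pval),
       df = unname(c(tab[1L, "Df"], tab["Residuals", "Df"])),
       pairwise = pw, degenerate = degenerate)
}

#' Near-lumen comparison of indentation depth between groups
#'
#' Welch (unequal-variance) two-sample comparison of depths at distances
#' within `cutoff` um of the canal lumen, test versus control group.
#'
#' @param test,control Indentation data.frames with `distance_um`,
#'   `depth_um`.
#' @param cutoff Distance cutoff (um), default 200.
#' @return List with `difference` (mean test - mean control), `ci` (95%),
#'   `p`, `n_test`, `n_control`.
#' @export
compare_near_lumen <- function(test, control, cutoff = 200) {
  x <- test$depth_um[test$distance_um <= cutoff]
  y <- control$depth_um[control$distance_um <= cutoff]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 records within the cutoff in each group")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(difference = unname(mean(x) - mean(y)),
       ci = unname(tt$conf.int), p = unname(tt$p.value),
       n_test = length(x), n_control = length(y))
}

#' Logarithmic trend of indentation depth versus distance
#'
#' Least-squares fit of `depth = a - b * log(distance + c)`. The offset `c`
#' is fixed at 1 um by default so that a distance of 0 is admissible; set
#' `fit_c = TRUE` to estimate it by non-linear least squares.
#'
#' @param records Indentation data.frame with `distance_um`, `depth_um`.
#' @param c_offset Fixed offset c (um), > 0.
#' @param fit_c Estimate `c` instead of fixing it.
#' @return List with `a`, `b`, `c`, `r2`, `n`.
#' @export
fit_log_trend <- function(records, c_offset = 1, fit_c = FALSE) {
  if (nrow(records) < 3L) stop("log trend fit needs at least 3 records")
  if (c_offset <= 0) stop("c_offset must be > 0")
  d <- records$distance_um; y <- records$depth_um
  if (fit_c) {
    fit <- minpack.lm::nlsLM(y ~ a - b * log(d + cc),
                             start = list(a = max(y), b = 1, cc = c_offset),
                             lower = c(-Inf, 0, 1e-6))
    p <- stats::coef(fit)
    res <- stats::residuals(fit)
    a <- unname(p["a"]); bb <- unname(p["b"]); cc <- unname(p["cc"])
  } else {
    lf <- stats::lm(y ~ log(d + c_offset))
    a <- unname(stats::coef(lf)[1L]); bb <- -unname(stats::coef(lf)[2L])
    cc <- c_offset
    res <- stats::residuals(lf)
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  list(a = a, b = bb, c = cc, r2 = r2, n = length(y))
}
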