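#' Distance bin definitions along the lumen-to-CDJ transect
#'
#' Nine half-open 100 um bins `(lo, hi]` from the canal lumen ("Up to 100
#' um", "> 100-200 um", ..., "> 800-900 um"): a point at exactly 100 um
#' belongs to "Up to 100 um".
#'
#' @param bin_width Bin width (um), default 100.
#' @param max_um Upper edge of the last bin (um), default 900.
#' @return data.frame with `lo`, `hi`, `label`.
#' @export
distance_bins <- function(bin_width = 100, max_um = 900) {
  lo <- seq(0, max_um - bin_width, by = bin_width)
  hi <- lo + bin_width
  label <- ifelse(lo == 0, sprintf("Up to %g um", hi),
                  sprintf("> %g-%g um", lo, hi))
  data.frame(lo = lo, hi = hi, label = label, stringsAsFactors = FALSE)
}

#' Assign distances to bins
#' @param d Distances (um).
#' @param bins Bin table from [distance_bins()].
#' @return Factor of bin labels (`NA` outside all bins).
#' @export
assign_bin <- function(d, bins = distance_bins()) {
  cut(d, breaks = c(bins$lo[1L], bins$hi), labels = bins$label, right = TRUE)
}

#' Distance-binned linear models of band area
#'
#' For each stratum (maturity group, plus a pooled `"all"` stratum), each
#' distance bin (plus an `"Entire thickness"` pseudo-bin over all
#' distances) and each band, fits ordinary least squares of integrated band
#' area on distance (expressed per 100 um) with the per-quadrant extent of
#' canal instrumentation as covariate. Only accepted spectra (QI <= 6)
#' enter. Bins with fewer than 3 accepted sites are flagged
#' `"insufficient data"`; bins whose sites share one distance are flagged
#' `"collinear"`. Confidence intervals are plain OLS 95% intervals;
#' within-tooth clustering of sites is not modelled (set
#' `cluster = "tooth_id"` for cluster-robust intervals by tooth).
#'
#' @param data data.frame with columns `distance_um`, `accepted`, the band
#'   area columns, `maturity_group`, and (optionally) `ei_mm` and
#'   `tooth_id`.
#' @param bands Names of the dependent-variable columns.
#' @param bins Bin table from [distance_bins()].
#' @param strata `"maturity_group"` for stratified fits plus pooled, or
#'   `NULL` for pooled only.
#' @param cluster Optional column name for cluster-robust standard errors
#'   (simple cluster bootstrap-free CR0 sandwich).
#' @return data.frame with columns `stratum`, `bin`, `band`, `coefficient`
#'   (area units per 100 um), `ci_lo`, `ci_hi`, `n_sites`, `status`.
#' @export
binned_linear_models <- function(data, bands = c("area_amide1", "area_amide3"),
                                 bins = distance_bins(),
                                 strata = "maturity_group", cluster = NULL) {
  if (!nrow(data)) stop("empty input table")
  if ("accepted" %in% names(data)) data <- data[data$accepted, , drop = FALSE]
  if (!nrow(data)) stop("no accepted spectra in input table")
  data$.bin <- as.character(assign_bin(data$distance_um, bins))
  strata_values <- list(all = rep(TRUE, nrow(data)))
  if (!is.null(strata) && strata %in% names(data)) {
    for (g in sort(unique(data[[strata]])))
      strata_values[[as.character(g)]] <- data[[strata]] == g
  }
  bin_sets <- c(list(`Entire thickness` = rep(TRUE, nrow(data))),
                stats::setNames(lapply(bins$label, function(b)
                  !is.na(data$.bin) & data$.bin == b), bins$label))
  out <- list()
  for (sname in names(strata_values)) {
    for (bname in names(bin_sets)) {
      sel <- strata_values[[sname]] & bin_sets[[bname]]
      for (band in bands) {
        d <- data[sel, , drop = FALSE]
        row <- fit_bin_model(d, band, cluster)
        out[[length(out) + 1L]] <- cbind(
          data.frame(stratum = sname, bin = bname, band = band,
                     stringsAsFactors = FALSE), row)
      }
    }
  }
  do.call(rbind, out)
}

fit_bin_model <- function(d, band, cluster = NULL) {
  empty <- data.frame(coefficient = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, n_sites = nrow(d),
                      status = "insufficient data", stringsAsFactors = FALSE)
  if (nrow(d) < 3L) return(empty)
  if (length(unique(d$distance_um)) < 2L) {
    empty$status <- "collinear"
    return(empty)
  }
  d$.dist100 <- d$distance_um / 100
  use_ei <- "ei_mm" %in% names(d) && length(unique(d$ei_mm)) > 1L
  fml <- if (use_ei) stats::as.formula(paste(band, "~ .dist100 + ei_mm"))
         else stats::as.formula(paste(band, "~ .dist100"))
  fit <- stats::lm(fml, data = d)
  co <- stats::coef(fit)[".dist100"]
  se <- cluster_se(fit, d, cluster)
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  data.frame(coefficient = unname(co),
             ci_lo = unname(co - tcrit * se),
             ci_hi = unname(co + tcrit * se),
             n_sites = nrow(d), status = "ok", stringsAsFactors = FALSE)
}

# standard error of the distance coefficient: plain OLS, or CR0 sandwich
# clustered on the given column
cluster_se <- function(fit, d, cluster = NULL) {
  X <- stats::model.matrix(fit)
  j <- match(".dist100", colnames(X))
  if (is.null(cluster) || !cluster %in% names(d)) {
    return(sqrt(diag(stats::vcov(fit)))[j])
  }
  u <- stats::residuals(fit)
  XtXinv <- chol2inv(qr.R(fit$qr))
  cl <- d[[cluster]]
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cl)) {
    idx <- which(cl == g)
    sg <- crossprod(X[idx, , drop = FALSE], u[idx])
    meat <- meat + sg %*% t(sg)
  }
  V <- XtXinv %*% meat %*% XtXinv
  sqrt(diag(V))[j]
}

#' Saturating-exponential decay fit of band amplitude versus distance
#'
#' Fits `y(d) = y_inf - (y_inf - y0) * exp(-d / lambda)` by non-linear
#' least squares with multi-start initialization over a grid of decay
#' lengths. `y0` is the amplitude at the lumen, `y_inf` the asymptotic
#' (intact) amplitude and `lambda` the decay length (um). The boundary of
#' effect is defined as the distance at which the fitted amplitude reaches
#' 95% of the lumen-to-asymptote recovery: `boundary_um = lambda * ln 20`.
#'
#' For flat input (controls) the decay amplitude is not distinguishable
#' from a constant: the fit is compared against the constant model with an
#' F-test, and `lambda_identifiable` is set to `FALSE` when the decay term
#' does not improve the fit at the 5% level (exactly constant data are
#' flagged immediately).
#'
#' @param distance Distances from the lumen (um).
#' @param y Band amplitudes at those distances.
#' @param lambda_init Decay-length starting values (um) for multi-start.
#' @return A `decay_fit` list: `y0`, `y_inf`, `lambda`, `boundary_um`,
#'   `rss`, `r2`, `lambda_identifiable`, `n`.
#' @export
fit_decay <- function(distance, y,
                      lambda_init = c(50, 100, 250, 500, 1000)) {
  if (length(distance) != length(y)) stop("distance and y lengths differ")
  keep <- is.finite(distance) & is.finite(y)
  distance <- distance[keep]; y <- y[keep]
  if (length(y) < 5L) stop("decay fit needs at least 5 points")
  if (length(unique(distance)) < 3L) stop("decay fit needs >= 3 distinct distances")
  tss <- sum((y - mean(y))^2)
  if (tss < .Machine$double.eps * max(1, mean(y)^2)) {
    out <- list(y0 = mean(y), y_inf = mean(y), lambda = NA_real_,
                boundary_um = NA_real_, rss = 0, r2 = NA_real_,
                lambda_identifiable = FALSE, n = length(y))
    class(out) <- "decay_fit"
    return(out)
  }
  ord <- order(distance)
  y0_start <- mean(y[ord][seq_len(max(1L, length(y) %/% 5L))])
  yinf_start <- mean(y[ord][seq(length(y) - max(1L, length(y) %/% 5L) + 1L, length(y))])
  best <- NULL
  for (l0 in lambda_init) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y_inf - (y_inf - y0) * exp(-distance / lambda),
        start = list(y0 = y0_start, y_inf = yinf_start, lambda = l0),
        lower = c(-Inf, -Inf, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("decay fit did not converge from any starting value")
  p <- stats::coef(best$fit)
  rss <- best$rss
  n <- length(y)
  # F-test of the 3-parameter decay against the 1-parameter constant
  rss0 <- tss
  fstat <- ((rss0 - rss) / 2) / (rss / max(1L, n - 3L))
  pval <- stats::pf(fstat, 2, max(1L, n - 3L), lower.tail = FALSE)
  identifiable <- is.finite(pval) && pval < 0.05
  out <- list(y0 = unname(p["y0"]), y_inf = unname(p["y_inf"]),
              lambda = unname(p["lambda"]),
              boundary_um = unname(p["lambda"]) * log(20),
              rss = rss, r2 = 1 - rss / tss,
              lambda_identifiable = identifiable, n = n)
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> y(d) = y_inf - (y_inf - y0) exp(-d/lambda)\n")
  cat(sprintf("  y0 = %.4g, y_inf = %.4g, lambda = %.4g um, boundary = %.4g um\n",
              x$y0, x$y_inf, x$lambda, x$boundary_um))
  cat(sprintf("  r2 = %.3f, n = %d, lambda %s\n", x$r2, x$n,
              if (x$lambda_identifiable) "identifiable" else "NOT identifiable (flat data)"))
  invisible(x)
}

#' Trend of spectral quality versus distance
#'
#' Fits the same saturating-exponential form to the quality index (QI)
#' against distance from the lumen. QI is high (poor) near the lumen and
#' decays outward, so `y0 > y_inf` for degraded dentine. When the fit
#' explains little variance (`r2 < r2_caution`) a caution flag is set: the
#' estimated trend should then be read qualitatively only.
#'
#' @param quality data.frame with columns `distance_um` and `qi`.
#' @param r2_caution Caution threshold on r-squared, default 0.2.
#' @return List with the `decay_fit`, `r2` and logical `caution`.
#' @export
quality_trend <- function(quality, r2_caution = 0.2) {
  if (!nrow(quality)) stop("empty quality table")
  fit <- fit_decay(quality$distance_um, quality$qi)
  r2 <- fit$r2
  list(fit = fit, r2 = r2, caution = !is.finite(r2) || r2 < r2_caution)
}
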