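#' Peak height and position within a band window
#'
#' The band height is the maximum intensity over the closed window
#' `[lo, hi]`; the position is the wavenumber of that maximum. Ties are
#' broken toward the window's nominal center, and if two tied maxima are
#' equidistant from the center the lower wavenumber is taken (deterministic
#' tie-break).
#'
#' @param s A preprocessed `raman_spectrum`.
#' @param w One-row band window (see [band_window()]), or a window name.
#' @return List with `height` and `position` (cm^-1). A flat all-equal
#'   window returns the window's nominal center as position.
#' @export
peak_height <- function(s, w) {
  w <- as_window(w)
  idx <- window_idx(s, w$lo, w$hi)
  y <- s$intensity[idx]; x <- s$wavenumber[idx]
  h <- max(y)
  cand <- which(y == h)
  if (length(cand) > 1L) {
    ord <- order(abs(x[cand] - w$center), x[cand])
    cand <- cand[ord[1L]]
  }
  list(height = h, position = x[cand])
}

#' Full width at half maximum of a band
#'
#' Locates the two half-maximum crossings nearest the band peak, each by
#' linear interpolation between grid points, and returns their distance.
#' The search is confined to the band window; if either crossing falls
#' outside the window (truncated band) an error of class
#' `dentinemap_fwhm_error` is signalled.
#'
#' @inheritParams peak_height
#' @return FWHM in cm^-1.
#' @export
fwhm <- function(s, w) {
  w <- as_window(w)
  idx <- window_idx(s, w$lo, w$hi)
  y <- s$intensity[idx]; x <- s$wavenumber[idx]
  pk <- peak_height(s, w)
  if (pk$height <= 0) stop("fwhm undefined: peak height is not positive")
  i0 <- which.min(abs(x - pk$position))
  half <- pk$height / 2
  left <- NA_real_; right <- NA_real_
  # walk left from the peak to the first crossing below half maximum
  for (i in rev(seq_len(i0 - 1L))) {
    if (y[i] < half) {
      left <- x[i] + (x[i + 1L] - x[i]) * (half - y[i]) / (y[i + 1L] - y[i])
      break
    }
  }
  if (i0 < length(y)) {
    for (i in (i0 + 1L):length(y)) {
      if (y[i] < half) {
        right <- x[i - 1L] + (x[i] - x[i - 1L]) * (y[i - 1L] - half) / (y[i - 1L] - y[i])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    cond <- structure(
      class = c("dentinemap_fwhm_error", "error", "condition"),
      list(message = sprintf(
        "half-maximum not crossed within window [%g, %g]: width undefined",
        w$lo, w$hi), call = sys.call(-1)))
    stop(cond)
  }
  right - left
}

#' Integrated band area
#'
#' Trapezoidal integral of the intensity over the closed window `[lo, hi]`.
#' By default a local linear chord between the window endpoint intensities is
#' subtracted first, which makes window areas robust to residual background;
#' a negative result is floored at 0 with a warning. Set `chord = FALSE` for
#' the plain trapezoidal integral (which is exactly additive over adjacent
#' sub-windows sharing an endpoint).
#'
#' @inheritParams peak_height
#' @param chord Subtract the endpoint chord first (default `TRUE`).
#' @return Integrated area (intensity units x cm^-1).
#' @export
integrated_area <- function(s, w, chord = TRUE) {
  w <- as_window(w)
  idx <- window_idx(s, w$lo, w$hi)
  y <- s$intensity[idx]; x <- s$wavenumber[idx]
  if (length(idx) < 2L) stop("window contains fewer than 2 grid points")
  if (chord) {
    n <- length(y)
    y <- y - (y[1L] + (y[n] - y[1L]) * (x - x[1L]) / (x[n] - x[1L]))
  }
  a <- sum(diff(x) * (y[-1L] + y[-length(y)])) / 2
  if (a < 0) {
    warning("negative integrated area floored at 0")
    a <- 0
  }
  a
}

#' Amide III doublet detection
#'
#' Detects the two highest local maxima within the Amide III window and
#' quantifies the valley between them. The doublet contrast is
#' `1 - valley / lower peak`; the doublet flag is set when the two maxima
#' are separated by at least `min_sep` cm^-1 and the contrast is at least
#' `min_contrast`. The doublet reports the collagen triple helix: its
#' flattening (loss of contrast) indicates denaturation.
#'
#' @inheritParams peak_height
#' @param min_sep Minimum separation of the two maxima (cm^-1), default 10.
#' @param min_contrast Minimum contrast for a doublet call, default 0.05.
#' @return List with `flag` (logical) and `contrast` (in [0, 1]).
#'   Single-peak windows return `flag = FALSE`, `contrast = 0`.
#' @export
doublet_status <- function(s, w = band_window("amide3"),
                           min_sep = 10, min_contrast = 0.05) {
  w <- as_window(w)
  idx <- window_idx(s, w$lo, w$hi)
  y <- s$intensity[idx]; x <- s$wavenumber[idx]
  lm_idx <- local_maxima(y)
  if (length(lm_idx) < 2L) return(list(flag = FALSE, contrast = 0))
  ord <- order(y[lm_idx], decreasing = TRUE)
  i1 <- lm_idx[ord[1L]]; i2 <- lm_idx[ord[2L]]
  lo <- min(i1, i2); hi <- max(i1, i2)
  valley <- min(y[lo:hi])
  lower_peak <- min(y[i1], y[i2])
  contrast <- if (lower_peak <= 0) 0 else max(0, min(1, 1 - valley / lower_peak))
  sep <- abs(x[i1] - x[i2])
  list(flag = sep >= min_sep && contrast >= min_contrast, contrast = contrast)
}

#' Signal-to-noise ratio
#'
#' `snr()` is the plain amplitude ratio; the `printed` element applies the
#' reporting convention of truncating toward zero at one decimal (so
#' 62/7 prints as 8.8 and 50/3 as 16.6).
#'
#' @param signal_amplitude Band peak amplitude (> = 0).
#' @param noise_amplitude Noise amplitude (> 0).
#' @return List with `value` (full precision) and `printed` (truncated to
#'   one decimal).
#' @export
snr <- function(signal_amplitude, noise_amplitude) {
  if (!is.finite(noise_amplitude) || noise_amplitude <= 0)
    stop("noise amplitude must be positive")
  v <- signal_amplitude / noise_amplitude
  list(value = v, printed = trunc(v * 10) / 10)
}

#' Estimate the signal-to-noise ratio of a band
#'
#' Signal is the band peak height; noise is the peak-to-peak amplitude of the
#' quiet-window residual after removing a linear trend. The quiet window
#' (default 1500-1580 cm^-1) carries no band, so its detrended residual is a
#' direct read of the noise amplitude. For acquisition-time comparisons the
#' conventional input is the baseline-corrected, unsmoothed spectrum, since
#' smoothing suppresses the very noise the ratio reports; applied to a fully
#' preprocessed spectrum the value describes the processed signal instead.
#'
#' @inheritParams peak_height
#' @param quiet Quiet window `c(lo, hi)` in cm^-1.
#' @return List with `value`, `printed`, `signal`, `noise`.
#' @export
estimate_snr <- function(s, w = band_window("amide1"), quiet = quiet_window()) {
  w <- as_window(w)
  sig <- peak_height(s, w)$height
  idx <- window_idx(s, quiet[1L], quiet[2L])
  x <- s$wavenumber[idx]; y <- s$intensity[idx]
  res <- stats::.lm.fit(cbind(1, x), y)$residuals
  noise <- diff(range(res))
  if (noise <= 0) stop("quiet window has zero residual amplitude")
  r <- snr(sig, noise)
  c(r, list(signal = sig, noise = noise))
}

#' Extract all band descriptors from one spectrum
#'
#' Runs the full descriptor set over the four default band windows:
#' peak heights, Amide I/III FWHM and integrated areas, Amide III doublet
#' flag and contrast, and the estimated SNR of the Amide I band. Undefined
#' widths (half maximum not crossed inside the window) are reported as `NA`.
#'
#' @param s A preprocessed `raman_spectrum` (see [preprocess_spectrum()]);
#'   raw spectra are preprocessed first when `preprocess = TRUE`.
#' @param preprocess Preprocess `s` first if it is not flagged as such.
#' @param ... Passed to [preprocess_spectrum()].
#' @return One-row data.frame with columns `h_amide1`, `h_amide3`, `h_1450`,
#'   `h_carbonate`, `fwhm_amide1`, `fwhm_amide3`, `area_amide1`,
#'   `area_amide3`, `doublet_flag`, `doublet_contrast`, `snr`.
#' @export
extract_features <- function(s, preprocess = TRUE, ...) {
  if (preprocess && !isTRUE(s$meta$preprocessed)) s <- preprocess_spectrum(s, ...)
  safe_fwhm <- function(w) tryCatch(fwhm(s, w), error = function(e) NA_real_)
  dbl <- doublet_status(s)
  data.frame(
    h_amide1    = peak_height(s, "amide1")$height,
    h_amide3    = peak_height(s, "amide3")$height,
    h_1450      = peak_height(s, "ch_1450")$height,
    h_carbonate = peak_height(s, "carbonate")$height,
    fwhm_amide1 = safe_fwhm("amide1"),
    fwhm_amide3 = safe_fwhm("amide3"),
    area_amide1 = integrated_area(s, "amide1"),
    area_amide3 = integrated_area(s, "amide3"),
    doublet_flag = dbl$flag,
    doublet_contrast = dbl$contrast,
    snr = tryCatch(estimate_snr(s)$value, error = function(e) NA_real_)
  )
}

as_window <- function(w) {
  if (is.character(w)) return(band_window(w))
  stopifnot(is.data.frame(w), nrow(w) == 1L,
            all(c("center", "lo", "hi") %in% names(w)))
  w
}
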