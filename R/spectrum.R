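#' Construct a Raman spectrum object
#'
#' A `raman_spectrum` is a light-weight container for a single point spectrum:
#' a strictly ascending wavenumber grid (cm^-1), an intensity vector of equal
#' length (arbitrary counts; no absolute calibration is attempted), and a list
#' of acquisition metadata (tooth, quadrant, distance from the canal lumen,
#' acquisition time, tubule locus, treatment group).
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly ascending.
#' @param intensity Numeric vector of intensities, same length as `wavenumber`.
#' @param meta Named list of acquisition metadata (may be empty).
#' @param validate Check the grid invariants (default `TRUE`).
#'
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list(), validate = TRUE) {
  s <- structure(
    list(wavenumber = as.numeric(wavenumber),
         intensity = as.numeric(intensity),
         meta = meta),
    class = "raman_spectrum"
  )
  if (validate) validate_spectrum(s)
  s
}

#' Validate a Raman spectrum
#'
#' Checks that wavenumbers are strictly ascending with no duplicates, that
#' the two vectors have equal length, that all values are finite, and that the
#' grid covers the analysis range (all band windows must lie inside the grid).
#'
#' @param s A `raman_spectrum`.
#' @param range_lo,range_hi Minimal coverage required of the grid (cm^-1).
#'   Defaults cover every default band window (carbonate lower edge to the
#'   Amide I upper edge plus margin).
#' @return `s`, invisibly; errors on violation.
#' @export
validate_spectrum <- function(s, range_lo = 1052, range_hi = 1729) {
  if (!inherits(s, "raman_spectrum")) stop("not a raman_spectrum")
  w <- s$wavenumber; y <- s$intensity
  if (length(w) != length(y)) stop("wavenumber and intensity lengths differ")
  if (length(w) < 2L) stop("spectrum must contain at least 2 points")
  if (anyNA(w) || anyNA(y) || !all(is.finite(w)) || !all(is.finite(y)))
    stop("non-finite values in spectrum")
  if (anyDuplicated(w)) stop("duplicate wavenumbers in spectrum")
  if (any(diff(w) <= 0)) stop("wavenumbers are not strictly ascending")
  if (w[1L] > range_lo || w[length(w)] < range_hi)
    stop(sprintf("spectrum covers [%.1f, %.1f] cm^-1 but must cover [%.1f, %.1f]",
                 w[1L], w[length(w)], range_lo, range_hi))
  invisible(s)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  m <- x$meta
  if (length(m)) {
    keep <- intersect(c("tooth_id", "quadrant", "distance_um", "acq_min",
                        "locus", "treatment"), names(m))
    if (length(keep))
      cat("  ", paste(sprintf("%s=%s", keep, unlist(m[keep])), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber_cm1 = x$wavenumber, intensity = x$intensity)
}

#' Default analysis band windows
#'
#' The four closed band windows used throughout the analysis: carbonate
#' (mineral reference, 1072 cm^-1), Amide III (collagen tertiary structure,
#' 1243 cm^-1, window 1215-1302 cm^-1), the CH2 deformation band
#' (1450 cm^-1), and Amide I (collagen secondary structure, 1667 cm^-1,
#' window 1615-1719 cm^-1). Windows are closed intervals `[lo, hi]`; grid
#' points exactly at a bound are included. One window definition is shared by
#' feature extraction and quality rating.
#'
#' @return A data.frame with columns `name`, `center`, `lo`, `hi` (cm^-1).
#' @export
band_windows <- function() {
  data.frame(
    name   = c("carbonate", "amide3", "ch_1450", "amide1"),
    center = c(1072, 1243, 1450, 1667),
    lo     = c(1052, 1215, 1400, 1615),
    hi     = c(1092, 1302, 1500, 1719),
    stringsAsFactors = FALSE
  )
}

#' Look up one band window by name
#' @param name One of `"carbonate"`, `"amide3"`, `"ch_1450"`, `"amide1"`.
#' @return One-row data.frame with `name`, `center`, `lo`, `hi`.
#' @export
band_window <- function(name) {
  bw <- band_windows()
  i <- match(name, bw$name)
  if (is.na(i)) stop("unknown band window: ", name)
  bw[i, , drop = FALSE]
}

#' Quiet (band-free) window used for noise estimation
#'
#' The 1500-1580 cm^-1 region carries no collagen or mineral band and is used
#' to estimate the noise amplitude for signal-to-noise calculations.
#' @return Numeric length-2 vector `c(lo, hi)` in cm^-1.
#' @export
quiet_window <- function() c(1500, 1580)

# indices of grid points falling inside a closed window [lo, hi]
window_idx <- function(s, lo, hi) {
  idx <- which(s$wavenumber >= lo & s$wavenumber <= hi)
  if (!length(idx)) stop(sprintf("window [%g, %g] outside the spectral grid", lo, hi))
  idx
}

# topographic prominence of each peak index: height above the higher of the
# two lowest points separating the peak from higher ground (or the window edge)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(i) {
    h <- y[i]
    left <- if (i > 1L) {
      seg <- y[seq_len(i - 1L)]
      higher <- which(seg > h)
      if (!length(higher)) min(seg)
      else if (max(higher) + 1L > i - 1L) h
      else min(y[(max(higher) + 1L):(i - 1L)])
    } else h
    right <- if (i < length(y)) {
      seg <- y[(i + 1L):length(y)]
      higher <- which(seg > h)
      if (!length(higher)) min(seg)
      else if (min(higher) == 1L) h
      else min(seg[seq_len(min(higher) - 1L)])
    } else h
    h - max(left, right)
  }, numeric(1))
}

# run-length based local maxima: returns indices (first grid point of a
# plateau) of interior points strictly higher than both neighbouring runs
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  r <- rle(y)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in 2:(k - 1L)) {
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
      out <- c(out, starts[j])
  }
  out
}
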