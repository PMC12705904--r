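#' Rate one spectral region for quality
#'
#' Operationalization of the three-level rating applied to each of the
#' Amide III, Amide I, and 1450 cm^-1 regions of a carbonate-normalized
#' spectrum. Let `H` be the main peak height (the local maximum nearest the
#' window's nominal center) and `A` the tallest accessory peak (any other
#' local maximum in the window; 0 if none), both relative to the carbonate
#' peak height:
#'
#' * rating 3 if `A > H`, or `H < 0.25`, or `H > 0.75` (unacceptable);
#' * otherwise rating 2 if `0.25 <= A <= 0.75` (accessory band present);
#' * otherwise rating 1 (clean band between 25% and 75% of carbonate).
#'
#' Thresholds are closed intervals: `H = 0.25` exactly rates 1. Degenerate
#' flat windows have no local maximum, hence `H = 0` and rating 3. In the
#' Amide III window the doublet partner (the second-highest maximum when a
#' doublet is resolved) is an expected feature of intact collagen, not an
#' abnormal accessory band, and is excluded from `A`; set
#' `n_expected = 1` to disable this. Candidate peaks must have a
#' topographic prominence of at least `min_prominence` times the carbonate
#' height, so noise ripples riding on a band flank do not count as
#' accessory bands.
#'
#' @param s A preprocessed `raman_spectrum`.
#' @param w Band window (name or one-row data.frame).
#' @param carbonate_height Carbonate reference height of `s` (1 after
#'   normalization; measured from the spectrum if `NULL`).
#' @param n_expected Number of expected peaks in the window (2 for the
#'   Amide III doublet, else 1).
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   carbonate height, default 0.05.
#' @return Integer rating 1, 2 or 3.
#' @export
rate_region <- function(s, w, carbonate_height = NULL, n_expected = NULL,
                        min_prominence = 0.05) {
  w <- as_window(w)
  if (is.null(n_expected))
    n_expected <- if (identical(w$name, "amide3")) 2L else 1L
  if (is.null(carbonate_height))
    carbonate_height <- peak_height(s, "carbonate")$height
  idx <- window_idx(s, w$lo, w$hi)
  y <- s$intensity[idx]; x <- s$wavenumber[idx]
  lm_idx <- local_maxima(y)
  if (length(lm_idx)) {
    prom <- peak_prominence(y, lm_idx)
    lm_idx <- lm_idx[prom >= min_prominence * carbonate_height]
  }
  if (!length(lm_idx)) return(3L)
  main <- lm_idx[which.min(abs(x[lm_idx] - w$center))]
  expected <- main
  if (n_expected > 1L) {
    # doublet partner(s): the tallest remaining maxima are expected features
    rest <- setdiff(lm_idx, main)
    if (length(rest)) {
      rest <- rest[order(y[rest], decreasing = TRUE)]
      expected <- c(main, rest[seq_len(min(n_expected - 1L, length(rest)))])
    }
  }
  H <- y[main] / carbonate_height
  accessory <- setdiff(lm_idx, expected)
  A <- if (length(accessory)) max(y[accessory]) / carbonate_height else 0
  if (A > H || H < 0.25 || H > 0.75) return(3L)
  if (A >= 0.25 && A <= 0.75) return(2L)
  1L
}

#' Overall general quality of a spectrum
#'
#' 1 if no region is rated 3; 2 if at least one (but not all) regions are
#' rated 3; 3 if all three regions are rated 3 (the spectrum does not
#' resemble a collagen spectrum in any part).
#'
#' @param ratings Integer vector of the three region ratings (each in 1:3).
#' @return Integer general quality in 1:3.
#' @export
general_quality <- function(ratings) {
  ratings <- as.integer(ratings)
  if (length(ratings) != 3L || !all(ratings %in% 1:3))
    stop("ratings must be three values in 1:3")
  n3 <- sum(ratings == 3L)
  if (n3 == 0L) 1L else if (n3 == 3L) 3L else 2L
}

#' Quality index (QI) and inclusion decision
#'
#' `QI = (r_amide3 + r_amide1 + r_1450) x general`; a spectrum is accepted
#' for the integrated-area analysis iff `QI <= 6`. The operator precedence
#' (sum first, then multiply) follows the published worked examples
#' `(3 + 1 + 1) x 2 = 10` (rejected) and `(2 + 2 + 2) x 1 = 6` (accepted).
#'
#' @param r_amide3,r_amide1,r_1450 Region ratings in 1:3.
#' @param general Overall general quality in 1:3.
#' @return List with integer `qi` and logical `accepted`.
#' @export
compute_qi <- function(r_amide3, r_amide1, r_1450, general) {
  r <- as.integer(c(r_amide3, r_amide1, r_1450)); g <- as.integer(general)
  if (!all(r %in% 1:3) || !g %in% 1:3) stop("ratings and general must be in 1:3")
  qi <- sum(r) * g
  list(qi = qi, accepted = qi <= 6L)
}

#' Score a spectrum for quality
#'
#' Applies [rate_region()] to the Amide III, Amide I and 1450 cm^-1 windows,
#' derives the general quality and the QI, and returns the inclusion
#' decision. Spectra that fail carbonate normalization (fluorescence-masked,
#' typically inter-tubular sites) are assigned ratings (3, 3, 3), general
#' quality 3 and QI 27.
#'
#' @param s A `raman_spectrum`; preprocessed internally when needed.
#' @param ... Passed to [preprocess_spectrum()].
#' @return A `quality_score` list: `r_amide3`, `r_amide1`, `r_1450`,
#'   `general`, `qi`, `accepted`.
#' @export
score_spectrum <- function(s, ...) {
  sp <- if (isTRUE(s$meta$preprocessed)) s else
    tryCatch(preprocess_spectrum(s, ...),
             dentinemap_normalization_error = function(e) NULL)
  if (is.null(sp)) {
    out <- list(r_amide3 = 3L, r_amide1 = 3L, r_1450 = 3L,
                general = 3L, qi = 27L, accepted = FALSE)
    class(out) <- "quality_score"
    return(out)
  }
  carb <- peak_height(sp, "carbonate")$height
  r3 <- rate_region(sp, "amide3", carbonate_height = carb)
  r1 <- rate_region(sp, "amide1", carbonate_height = carb)
  r1450 <- rate_region(sp, "ch_1450", carbonate_height = carb)
  g <- general_quality(c(r3, r1, r1450))
  qi <- compute_qi(r3, r1, r1450, g)
  out <- list(r_amide3 = r3, r_amide1 = r1, r_1450 = r1450,
              general = g, qi = qi$qi, accepted = qi$accepted)
  class(out) <- "quality_score"
  out
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("<quality_score> ratings (amide3, amide1, 1450) = (%d, %d, %d), general = %d\n",
              x$r_amide3, x$r_amide1, x$r_1450, x$general))
  cat(sprintf("  QI = %d -> %s\n", x$qi, if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}
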