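#' Degradation model for hypochlorite-exposed dentine collagen
#'
#' Parametrizes how collagen band features recover with distance `d` (um)
#' from the canal lumen. The degradation factor is
#' `f(d) = floor + (1 - floor) * (1 - exp(-d / d_scale))`:
#' monotone non-decreasing in `d`, equal to `floor` at the lumen and
#' approaching 1 (intact collagen) far from it. Separate floors govern the
#' Amide I amplitude, the Amide III amplitude and the Amide III doublet
#' contrast; `broaden_max` is the maximal fractional width increase of the
#' Amide III sub-bands at the lumen (band broadening accompanies
#' denaturation). The default decay length of 250 um confines pronounced
#' change to roughly the first 300-500 um from the lumen.
#'
#' @param d_scale Decay length lambda (um), > 0. Default 250.
#' @param amide1_floor,amide3_floor,doublet_floor Fraction of the intact
#'   value retained at the lumen, in [0, 1]. Default 0.35.
#' @param broaden_max Maximal fractional width increase at the lumen, >= 0.
#'   Default 1.0 (width doubles at the lumen at full degradation), chosen so
#'   the modelled doublet contrast falls below the
#'   detection threshold at the lumen while the doublet stays resolved
#'   beyond roughly 200 um.
#' @return A `degradation_model` list.
#' @export
degradation_model <- function(d_scale = 250, amide1_floor = 0.35,
                              amide3_floor = 0.35, doublet_floor = 0.35,
                              broaden_max = 1.0) {
  stopifnot(d_scale > 0, broaden_max >= 0)
  floors <- c(amide1_floor, amide3_floor, doublet_floor)
  if (any(floors < 0 | floors > 1)) stop("floors must lie in [0, 1]")
  structure(list(d_scale = d_scale, amide1_floor = amide1_floor,
                 amide3_floor = amide3_floor, doublet_floor = doublet_floor,
                 broaden_max = broaden_max),
            class = "degradation_model")
}

#' Degradation factor at a distance
#' @param model A [degradation_model()].
#' @param d Distance from the canal lumen (um), >= 0.
#' @param floor Which floor to use: value in [0, 1].
#' @return `floor + (1 - floor) * (1 - exp(-d / d_scale))`.
#' @export
degradation_factor <- function(model, d, floor) {
  stopifnot(all(d >= 0))
  floor + (1 - floor) * (1 - exp(-d / model$d_scale))
}

#' Acquisition specification for one synthetic spectrum
#'
#' @param tooth_id Tooth label.
#' @param quadrant One of `"A"` (buccal), `"B"` (mesial), `"C"`
#'   (lingual/palatal), `"D"` (distal).
#' @param distance_um Distance from the canal lumen (um), >= 0.
#' @param acq_min Acquisition time (minutes), > 0. Default 24.
#' @param locus `"intra_tubular"` or `"inter_tubular"`.
#' @param treatment `"naocl"` or `"control"`.
#' @param seed Integer RNG seed, or `NULL` to draw from the current stream.
#' @return A `spectrum_spec` list.
#' @export
spectrum_spec <- function(tooth_id, quadrant, distance_um, acq_min = 24,
                          locus = c("intra_tubular", "inter_tubular"),
                          treatment = c("naocl", "control"), seed = NULL) {
  locus <- match.arg(locus)
  treatment <- match.arg(treatment)
  if (!quadrant %in% c("A", "B", "C", "D"))
    stop("quadrant must be one of A (buccal), B (mesial), C (lingual/palatal), D (distal)")
  if (distance_um < 0) stop("distance_um must be >= 0")
  if (acq_min <= 0) stop("acq_min must be > 0")
  structure(list(tooth_id = as.character(tooth_id), quadrant = quadrant,
                 distance_um = distance_um, acq_min = acq_min,
                 locus = locus, treatment = treatment, seed = seed),
            class = "spectrum_spec")
}

#' Default band model of intact intra-tubular dentine
#'
#' Five Gaussian components: carbonate 1072 cm^-1 (mineral reference),
#' the Amide III doublet as sub-bands at 1243 and 1270 cm^-1 (the second
#' center chosen inside the 1215-1302 cm^-1 Amide III window), the CH2
#' deformation band at 1450 cm^-1, and Amide I at 1667 cm^-1. Amplitudes
#' are chosen so that after carbonate normalization the intact Amide and CH
#' band heights fall between 25% and 75% of the carbonate height (rating 1
#' territory), and the sub-band widths resolve the doublet in intact
#' collagen. `shape` may be `"gaussian"` or `"lorentzian"` per band.
#'
#' @return data.frame with columns `name`, `center`, `fwhm`, `amplitude`,
#'   `shape`.
#' @export
default_bands <- function() {
  data.frame(
    name      = c("carbonate", "amide3", "amide3b", "ch_1450", "amide1"),
    center    = c(1072, 1243, 1270, 1450, 1667),
    fwhm      = c(15, 18, 18, 30, 55),
    amplitude = c(100, 45, 40, 55, 60),
    shape     = "gaussian",
    stringsAsFactors = FALSE
  )
}

band_profile <- function(x, center, fwhm, amplitude, shape) {
  if (shape == "lorentzian") {
    amplitude / (1 + (2 * (x - center) / fwhm)^2)
  } else {
    amplitude * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
  }
}

#' Generate one synthetic Raman spectrum
#'
#' Intensity = quadratic fluorescence background + band mixture + zero-mean
#' Gaussian noise, on a regular grid covering 1050-1750 cm^-1 at 1 cm^-1
#' spacing. The noise standard deviation is `sigma0 / sqrt(acq_min)`,
#' emulating photon averaging over the acquisition time; for inter-tubular
#' sites it additionally scales with the square root of the fluorescence
#' scale factor (shot-noise-like behaviour of the stronger background).
#'
#' For `treatment = "naocl"` the Amide amplitudes are multiplied by the
#' degradation factor at the site's distance, and the Amide III sub-band
#' widths broaden as the doublet contrast factor drops toward the lumen,
#' flattening the doublet. Controls have degradation factor 1 everywhere.
#' For `locus = "inter_tubular"` the fluorescence background is scaled by
#' `bg_scale_inter` and all band amplitudes attenuated by `mask_atten`,
#' emulating fluorescence-masked spectra devoid of collagen and carbonate
#' bands; the carbonate peak is then far below 25% of the background range.
#'
#' Identical `(spec, model, seed)` give bit-identical output.
#'
#' @param spec A [spectrum_spec()].
#' @param model A [degradation_model()].
#' @param bands Band table as in [default_bands()].
#' @param sigma0 Noise scale (counts x sqrt(min)). Default 4.5.
#' @param bg_coefs Quadratic background coefficients `c(b0, b1, b2)` in
#'   `x = wavenumber - 1050`.
#' @param bg_scale_inter Background scale factor for inter-tubular sites.
#' @param mask_atten Band attenuation factor for inter-tubular sites.
#' @param grid Wavenumber grid (cm^-1).
#' @return A `raman_spectrum` with the spec fields in `meta`.
#' @export
generate_spectrum <- function(spec, model = degradation_model(),
                              bands = default_bands(), sigma0 = 4.5,
                              bg_coefs = c(100, 0.3, -3e-4),
                              bg_scale_inter = 20, mask_atten = 0.01,
                              grid = seq(1050, 1750, by = 1)) {
  stopifnot(inherits(spec, "spectrum_spec"))
  d <- spec$distance_um
  naocl <- spec$treatment == "naocl"
  f1 <- if (naocl) degradation_factor(model, d, model$amide1_floor) else 1
  f3 <- if (naocl) degradation_factor(model, d, model$amide3_floor) else 1
  fd <- if (naocl) degradation_factor(model, d, model$doublet_floor) else 1
  width_mult <- 1 + model$broaden_max * (1 - fd)

  b <- bands
  amp <- b$amplitude
  wid <- b$fwhm
  amp[b$name == "amide1"] <- amp[b$name == "amide1"] * f1
  is_a3 <- b$name %in% c("amide3", "amide3b")
  amp[is_a3] <- amp[is_a3] * f3
  wid[is_a3] <- wid[is_a3] * width_mult

  inter <- spec$locus == "inter_tubular"
  bg_scale <- if (inter) bg_scale_inter else 1
  if (inter) amp <- amp * mask_atten

  x <- grid - 1050
  bg <- bg_scale * (bg_coefs[1] + bg_coefs[2] * x + bg_coefs[3] * x^2)
  sig <- bg
  for (i in seq_len(nrow(b)))
    sig <- sig + band_profile(grid, b$center[i], wid[i], amp[i], b$shape[i])

  sd_noise <- sigma0 * sqrt(bg_scale) / sqrt(spec$acq_min)
  noise <- if (sd_noise > 0) with_seed(spec$seed, stats::rnorm(length(grid), 0, sd_noise))
           else rep(0, length(grid))

  meta <- unclass(spec)[c("tooth_id", "quadrant", "distance_um", "acq_min",
                          "locus", "treatment")]
  raman_spectrum(grid, sig + noise, meta = meta)
}

# run code under a seed without disturbing the caller's RNG stream;
# seed = NULL draws from the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a sampling transect of synthetic spectra
#'
#' Point `k` (1-based) lies at distance `k * spacing_um` from the canal
#' lumen; the test design uses 18 equidistant 50 um points per quadrant and
#' the control design 6 equidistant 150 um points. Optionally one extra
#' point is placed at a stated offset inside the cemento-dentinal junction
#' (CDJ).
#'
#' @param tooth_id,quadrant Labels for the transect.
#' @param n_points Number of equidistant points (>= 1).
#' @param spacing_um Spacing between points (um), > 0.
#' @param model A [degradation_model()].
#' @param treatment `"naocl"` or `"control"`.
#' @param seed Integer seed; point-level seeds are derived from it.
#' @param acq_min Acquisition time (minutes).
#' @param locus Tubule locus for all points.
#' @param cdj_um Distance of the CDJ from the lumen (um), or `NULL` for no
#'   extra point.
#' @param cdj_offset_um Offset of the extra point inside the CDJ (um).
#' @param ... Passed to [generate_spectrum()].
#' @return List with `spectra` (list of `raman_spectrum`) and `manifest`
#'   (data.frame with columns `tooth_id`, `quadrant`, `distance_um`,
#'   `acq_min`, `locus`, `treatment`, `seed`).
#' @export
generate_transect <- function(tooth_id, quadrant, n_points = 18L,
                              spacing_um = 50, model = degradation_model(),
                              treatment = "naocl", seed = 1L, acq_min = 24,
                              locus = "intra_tubular", cdj_um = NULL,
                              cdj_offset_um = 50, ...) {
  stopifnot(n_points >= 1L, spacing_um > 0)
  dists <- seq_len(n_points) * spacing_um
  if (!is.null(cdj_um)) dists <- c(dists, cdj_um - cdj_offset_um)
  point_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(dists)))
  spectra <- vector("list", length(dists))
  for (k in seq_along(dists)) {
    sp <- spectrum_spec(tooth_id, quadrant, dists[k], acq_min = acq_min,
                        locus = locus, treatment = treatment,
                        seed = point_seeds[k])
    spectra[[k]] <- generate_spectrum(sp, model = model, ...)
  }
  manifest <- data.frame(
    tooth_id = as.character(tooth_id), quadrant = quadrant,
    distance_um = dists, acq_min = acq_min, locus = locus,
    treatment = treatment, seed = point_seeds, stringsAsFactors = FALSE)
  list(spectra = spectra, manifest = manifest)
}

#' Default logarithmic indentation parameters
#'
#' Depth (um) follows `a - b * log(distance + c)`. The test-group defaults
#' were obtained once by least squares on the published per-bin mean depths
#' of hypochlorite-treated dentine (nine 100 um bins, bin-center distances)
#' with `c` fixed at 1 um, and likewise for the saline control group (seven
#' non-empty bins); they are frozen here as the package's study conditions.
#' `sigma` defaults approximate the typical within-bin standard deviations
#' (test ~6 um, control ~3 um).
#'
#' @param group `"test"` or `"control"`.
#' @return List with `a`, `b`, `c`, `sigma`.
#' @export
indentation_defaults <- function(group = c("test", "control")) {
  group <- match.arg(group)
  if (group == "test") list(a = 97.3366, b = 5.8380, c = 1, sigma = 6)
  else list(a = 81.5332, b = 3.6353, c = 1, sigma = 3)
}

#' Generate synthetic indentation records
#'
#' Total indentation distance (depth, um) at distance `d` from the lumen is
#' `a - b * log(d + c)` plus Gaussian noise, floored at 0. The control
#' defaults are shallower (smaller `a`) and flatter (smaller `b`) than the
#' test defaults, reproducing the deeper near-lumen indentation of
#' hypochlorite-softened dentine.
#'
#' @param tooth_id Tooth label.
#' @param group `"test"` or `"control"`.
#' @param distances Distances from the lumen (um), >= 0.
#' @param params List `a`, `b`, `c`, `sigma` (defaults per group from
#'   [indentation_defaults()]); requires `b >= 0`, `c > 0`, `sigma >= 0`.
#' @param seed Integer seed or `NULL`.
#' @param quadrant Quadrant labels recycled over the records.
#' @return data.frame with columns `tooth_id`, `quadrant`, `distance_um`,
#'   `depth_um`, `group`.
#' @export
generate_indentation <- function(tooth_id, group = c("test", "control"),
                                 distances, params = NULL, seed = NULL,
                                 quadrant = c("A", "B", "C", "D")) {
  group <- match.arg(group)
  if (is.null(params)) params <- indentation_defaults(group)
  stopifnot(all(distances >= 0), params$b >= 0, params$sigma >= 0)
  if (params$c <= 0) stop("offset c must be > 0")
  mu <- params$a - params$b * log(distances + params$c)
  noise <- if (params$sigma > 0)
    with_seed(seed, stats::rnorm(length(distances), 0, params$sigma))
  else rep(0, length(distances))
  data.frame(
    tooth_id = as.character(tooth_id),
    quadrant = rep_len(quadrant, length(distances)),
    distance_um = distances,
    depth_um = pmax(0, mu + noise),
    group = group,
    stringsAsFactors = FALSE)
}

#' Generate synthetic tooth morphometry
#'
#' One row per tooth: apical root thickness and canal width at the four
#' reference levels (0.25/0.5/0.75/1.0 mm from the foramen), canal
#' impression masses before and after instrumentation, the impression
#' material density, and the extent-of-instrumentation distance in each
#' quadrant. Canal widths are drawn around 1 mm, root thicknesses follow
#' the requested maturity index (thickness = MI x width, with measurement
#' noise); instrumented volumes are drawn around 0.049 cm^3 and
#' per-quadrant extents around 0.048 mm, matching the study-scale summary
#' values. The per-quadrant spread of the extent is a modelling choice (the
#' true between-quadrant variance structure is not known).
#'
#' @param tooth_ids Character vector of tooth labels.
#' @param mi Target maturity indices (recycled); default draws uniformly
#'   in [2, 7].
#' @param density Impression material density (g/cm^3), default 1.15
#'   (light-body silicone).
#' @param seed Integer seed or `NULL`.
#' @return data.frame with columns `tooth_id`, `rt1..rt4`, `cw1..cw4`,
#'   `mass_v1`, `mass_v2`, `density`, `ei_a..ei_d` (mm and g).
#' @export
generate_morphometry <- function(tooth_ids, mi = NULL, density = 1.15,
                                 seed = NULL) {
  n <- length(tooth_ids)
  with_seed(seed, {
    if (is.null(mi)) mi <- stats::runif(n, 2, 7)
    mi <- rep_len(mi, n)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      cw <- pmax(0.2, stats::rnorm(4, 1.0, 0.08))
      rt <- pmax(cw, mi[i] * cw + stats::rnorm(4, 0, 0.1))
      vol <- pmax(0.01, stats::rnorm(1, 0.049, 0.002))
      m1 <- pmax(0.05, stats::rnorm(1, 0.30, 0.02))
      ei <- pmax(0.005, stats::rnorm(4, 0.048, 0.012))
      out[[i]] <- data.frame(
        tooth_id = as.character(tooth_ids[i]),
        rt1 = rt[1], rt2 = rt[2], rt3 = rt[3], rt4 = rt[4],
        cw1 = cw[1], cw2 = cw[2], cw3 = cw[3], cw4 = cw[4],
        mass_v1 = m1, mass_v2 = m1 + vol * density, density = density,
        ei_a = ei[1], ei_b = ei[2], ei_c = ei[3], ei_d = ei[4],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
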