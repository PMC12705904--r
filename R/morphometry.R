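#' Maturity index and maturity group
#'
#' The maturity index is the mean apical root thickness divided by the mean
#' apical canal width, both measured at 0.25, 0.5, 0.75 and 1.0 mm from the
#' foramen: `MI = mean(rt) / mean(cw)`. Teeth are grouped by the integer
#' floor of MI (bins of width 1), the grouping used for stratified gradient
#' models. MI is scale-invariant: multiplying all measurements by a common
#' factor leaves it unchanged.
#'
#' @param rt Root thickness measurements (mm), > 0.
#' @param cw Canal width measurements (mm), > 0, same length as `rt`.
#' @return List with `mi` (dimensionless) and `maturity_group` (integer).
#' @export
maturity_index <- function(rt, cw) {
  if (any(rt <= 0) || any(cw <= 0)) stop("measurements must be > 0")
  if (length(rt) != length(cw)) stop("rt and cw must have the same length")
  mi <- mean(rt) / mean(cw)
  list(mi = mi, maturity_group = as.integer(floor(mi)))
}

#' Instrumented canal volume by Archimedes' principle
#'
#' The dentine volume removed by canal preparation is the difference of the
#' canal impression masses before (`mass_v1`) and after (`mass_v2`)
#' instrumentation, divided by the impression material density.
#'
#' @param mass_v1,mass_v2 Impression masses (g); `mass_v2 >= mass_v1`.
#' @param density Impression material density (g/cm^3), > 0.
#' @return Volume in cm^3.
#' @export
instrumented_volume <- function(mass_v1, mass_v2, density) {
  if (density <= 0) stop("density must be > 0")
  if (mass_v2 < mass_v1) stop("mass_v2 must be >= mass_v1")
  (mass_v2 - mass_v1) / density
}

#' Mean extent of canal instrumentation
#'
#' Mean of the per-quadrant linear distances from the impression margin to
#' the canal wall (mm). Supplying fewer than four quadrants triggers a
#' warning; negative distances are errors.
#'
#' @param ei Per-quadrant extent-of-instrumentation distances (mm).
#' @return Mean extent (mm).
#' @export
mean_extent_instrumentation <- function(ei) {
  if (!length(ei)) stop("no extent measurements supplied")
  if (any(ei < 0)) stop("extent of instrumentation cannot be negative")
  if (length(ei) < 4L)
    warning(sprintf("only %d quadrant(s) supplied; mean over available quadrants",
                    length(ei)))
  mean(ei)
}

#' Derive morphometry summary columns for a table of teeth
#'
#' Takes a morphometry table (one row per tooth, columns `rt1..rt4`,
#' `cw1..cw4`, `mass_v1`, `mass_v2`, `density`, `ei_a..ei_d` as written by
#' [generate_morphometry()]) and appends the derived columns `mi`,
#' `maturity_group`, `vol_instrumented_cm3`, `ei_mean_mm`.
#'
#' @param m Morphometry data.frame.
#' @return `m` with the four derived columns appended.
#' @export
morphometry_table <- function(m) {
  req <- c(paste0("rt", 1:4), paste0("cw", 1:4), "mass_v1", "mass_v2",
           "density", paste0("ei_", c("a", "b", "c", "d")))
  missing <- setdiff(req, names(m))
  if (length(missing))
    stop("morphometry table is missing column(s): ", paste(missing, collapse = ", "))
  n <- nrow(m)
  m$mi <- NA_real_; m$maturity_group <- NA_integer_
  m$vol_instrumented_cm3 <- NA_real_; m$ei_mean_mm <- NA_real_
  for (i in seq_len(n)) {
    mi <- maturity_index(as.numeric(m[i, paste0("rt", 1:4)]),
                         as.numeric(m[i, paste0("cw", 1:4)]))
    m$mi[i] <- mi$mi
    m$maturity_group[i] <- mi$maturity_group
    m$vol_instrumented_cm3[i] <- instrumented_volume(m$mass_v1[i], m$mass_v2[i],
                                                     m$density[i])
    m$ei_mean_mm[i] <- mean(as.numeric(m[i, paste0("ei_", c("a", "b", "c", "d"))]))
  }
  m
}
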