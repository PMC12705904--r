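# fixtures built in code: analytic spectra on the standard 1 cm^-1 grid

std_grid <- seq(1050, 1750, by = 1)

gaussian_band <- function(x, center, sigma, amplitude = 1) {
  amplitude * exp(-(x - center)^2 / (2 * sigma^2))
}

lorentzian_band <- function(x, center, gamma, amplitude = 1) {
  amplitude / (1 + ((x - center) / gamma)^2)
}

# spectrum made of explicit components on the standard grid
make_spectrum <- function(intensity, grid = std_grid, meta = list()) {
  raman_spectrum(grid, intensity, meta = meta)
}

flat_spectrum <- function(value = 0, grid = std_grid) {
  make_spectrum(rep(value, length(grid)), grid)
}

# a realistic preprocessed-like spectrum: carbonate reference + one band
two_band_spectrum <- function(main_center, main_h, acc_center = NULL, acc_h = 0,
                              carb_h = 1, sigma = 8) {
  y <- gaussian_band(std_grid, 1072, 6, carb_h) +
    gaussian_band(std_grid, main_center, sigma, main_h)
  if (!is.null(acc_center)) y <- y + gaussian_band(std_grid, acc_center, sigma, acc_h)
  make_spectrum(y)
}

# noiseless generator shortcut
noiseless_spectrum <- function(d, treatment = "naocl", model = degradation_model(),
                               ...) {
  generate_spectrum(spectrum_spec("T1", "A", d, treatment = treatment, seed = 1L),
                    model = model, sigma0 = 0, ...)
}
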