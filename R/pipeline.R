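#' Extract features and quality scores for a set of spectra
#'
#' Preprocesses each spectrum once and computes both the band descriptors
#' and the quality score from the same processed spectrum. Spectra failing
#' carbonate normalization (fluorescence-masked) get `NA` features, ratings
#' (3, 3, 3) and QI 27.
#'
#' @param spectra List of raw `raman_spectrum` objects.
#' @param manifest Optional data.frame of per-spectrum metadata
#'   (one row per spectrum) prepended to the output columns.
#' @param ... Passed to [preprocess_spectrum()].
#' @return data.frame: manifest columns + feature columns + `r_amide3`,
#'   `r_amide1`, `r_1450`, `general`, `qi`, `accepted`.
#' @export
analyze_spectra <- function(spectra, manifest = NULL, ...) {
  if (!is.null(manifest) && nrow(manifest) != length(spectra))
    stop("manifest rows and spectra count differ")
  feat_na <- data.frame(
    h_amide1 = NA_real_, h_amide3 = NA_real_, h_1450 = NA_real_,
    h_carbonate = NA_real_, fwhm_amide1 = NA_real_, fwhm_amide3 = NA_real_,
    area_amide1 = NA_real_, area_amide3 = NA_real_,
    doublet_flag = NA, doublet_contrast = NA_real_, snr = NA_real_)
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- tryCatch(preprocess_spectrum(spectra[[i]], ...),
                   dentinemap_normalization_error = function(e) NULL)
    if (is.null(sp)) {
      q <- data.frame(r_amide3 = 3L, r_amide1 = 3L, r_1450 = 3L,
                      general = 3L, qi = 27L, accepted = FALSE)
      rows[[i]] <- cbind(feat_na, q)
    } else {
      f <- suppressWarnings(extract_features(sp, preprocess = FALSE))
      qs <- score_spectrum(sp)
      q <- data.frame(r_amide3 = qs$r_amide3, r_amide1 = qs$r_amide1,
                      r_1450 = qs$r_1450, general = qs$general,
                      qi = qs$qi, accepted = qs$accepted)
      rows[[i]] <- cbind(f, q)
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(manifest)) res <- cbind(manifest, res, row.names = NULL)
  res
}

#' Default pipeline configuration
#'
#' Synthetic study conditions: `n_test` hypochlorite-irrigated teeth sampled
#' at 18 equidistant 50 um points in each of the four quadrants, and
#' `n_control` saline controls sampled at 6 equidistant 150 um points in
#' the buccal quadrant; 24 min acquisitions; indentation along each
#' quadrant at 50 um steps to 900 um.
#'
#' @param seed Global seed.
#' @param n_test,n_control Numbers of test and control teeth.
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_test = 7L, n_control = 1L) {
  list(
    seed = seed,
    model = list(d_scale = 250, amide1_floor = 0.35, amide3_floor = 0.35,
                 doublet_floor = 0.35, broaden_max = 1.0),
    spectra = list(n_test = n_test, n_control = n_control,
                   n_points = 18L, spacing_um = 50,
                   control_n_points = 6L, control_spacing_um = 150,
                   acq_min = 24,
                   quadrants = c("A", "B", "C", "D"),
                   control_quadrants = "A"),
    indentation = list(distances = seq(50, 900, by = 50))
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> features -> quality ->
#' gradient -> indentation into one reproducible run. Stage outputs are
#' flat CSVs with stable column names so any stage can be re-run in
#' isolation; a `report.txt` summarizes accepted-spectrum counts, the
#' per-bin gradient coefficients, the decay fit with its boundary estimate
#' and the indentation summary. Deterministic under the configured seed.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file holding one. Alternatively to synthetic generation, the
#'   config may name existing inputs: `paths$manifest` (with spectrum files
#'   alongside), `paths$indentation`, `paths$morphometry`.
#' @param out_dir Output directory for stage CSVs and the report.
#' @return Invisible list with the stage tables: `features`, `gradient`,
#'   `decay`, `indent_bins`, `anova`, `near_lumen`, `log_trend`, and the
#'   output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  config <- utils::modifyList(base, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  # --- stage: inputs (synthetic generation or load) -------------------------
  if (!is.null(config$paths)) {
    p <- config$paths
    for (nm in c("manifest", "indentation")) {
      if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
        stop("stage simulate/load: missing input path for '", nm, "': ",
             if (is.null(p[[nm]])) "<unset>" else p[[nm]])
    }
    manifest <- read_manifest(p$manifest)
    spectra <- lapply(file.path(dirname(p$manifest), manifest$file), read_spectrum)
    indent <- read_indentation(p$indentation)
    morph <- if (!is.null(p$morphometry)) morphometry_table(
      utils::read.csv(p$morphometry, stringsAsFactors = FALSE)) else NULL
  } else {
    sim <- simulate_study(config)
    spectra <- sim$spectra; manifest <- sim$manifest
    indent <- sim$indentation; morph <- sim$morphometry
    utils::write.csv(indent, file.path(out_dir, "indentation.csv"), row.names = FALSE)
    utils::write.csv(morph, file.path(out_dir, "morphometry.csv"), row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }

  # --- stage: preprocess + features + quality -------------------------------
  features <- analyze_spectra(spectra, manifest)
  if (!is.null(morph)) {
    qcols <- c(A = "ei_a", B = "ei_b", C = "ei_c", D = "ei_d")
    mrow <- match(features$tooth_id, morph$tooth_id)
    features$maturity_group <- morph$maturity_group[mrow]
    features$ei_mm <- vapply(seq_len(nrow(features)), function(i) {
      if (is.na(mrow[i])) return(NA_real_)
      as.numeric(morph[mrow[i], qcols[[features$quadrant[i]]]])
    }, numeric(1))
  }
  utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

  # --- stage: gradient ------------------------------------------------------
  naocl <- features[features$treatment == "naocl", , drop = FALSE]
  gradient <- if (any(naocl$accepted))
    binned_linear_models(naocl) else NULL
  if (!is.null(gradient))
    utils::write.csv(gradient, file.path(out_dir, "gradient.csv"), row.names = FALSE)
  decay_data <- if (nrow(naocl)) naocl else features
  decay <- tryCatch(fit_decay(decay_data$distance_um, decay_data$h_amide1),
                    error = function(e) NULL)
  qtrend <- tryCatch(quality_trend(features[, c("distance_um", "qi")]),
                     error = function(e) NULL)

  # --- stage: indentation ---------------------------------------------------
  tst <- indent[indent$group == "test", , drop = FALSE]
  ctl <- indent[indent$group == "control", , drop = FALSE]
  indent_bins <- rbind(
    if (nrow(tst)) cbind(group = "test", bin_depths(tst)),
    if (nrow(ctl)) cbind(group = "control", bin_depths(ctl)))
  utils::write.csv(indent_bins, file.path(out_dir, "indent_summary.csv"),
                   row.names = FALSE)
  av <- if (nrow(tst)) tryCatch(anova_bins(tst), error = function(e) NULL) else NULL
  nl <- if (nrow(tst) && nrow(ctl))
    tryCatch(compare_near_lumen(tst, ctl), error = function(e) NULL) else NULL
  lt <- if (nrow(tst)) tryCatch(fit_log_trend(tst), error = function(e) NULL) else NULL

  # --- report ---------------------------------------------------------------
  rep_path <- file.path(out_dir, "report.txt")
  con <- file(rep_path, "w"); on.exit(close(con), add = TRUE)
  wline <- function(...) writeLines(sprintf(...), con)
  wline("dentinemap pipeline report (seed %d)", seed)
  wline("spectra: %d total, %d accepted (QI <= 6)",
        nrow(features), sum(features$accepted))
  if (!is.null(decay)) {
    if (decay$lambda_identifiable)
      wline("Amide I decay: lambda = %.1f um, boundary (95%% recovery) = %.1f um, r2 = %.3f",
            decay$lambda, decay$boundary_um, decay$r2)
    else
      wline("Amide I decay: lambda unidentifiable (flat amplitude profile)")
  }
  if (!is.null(qtrend))
    wline("quality trend: r2 = %.3f%s", qtrend$r2,
          if (qtrend$caution) " (caution: weak trend)" else "")
  if (!is.null(gradient)) {
    ok <- gradient[gradient$status == "ok" & gradient$stratum == "all", ]
    wline("gradient coefficients (area units / 100 um), pooled stratum:")
    for (i in seq_len(nrow(ok)))
      wline("  %-18s %-12s %8.2f [%6.2f, %6.2f] (n = %d)", ok$bin[i], ok$band[i],
            ok$coefficient[i], ok$ci_lo[i], ok$ci_hi[i], ok$n_sites[i])
  }
  if (!is.null(av))
    wline("indentation ANOVA across bins: F = %.2f, p = %.3g", av$f, av$p)
  if (!is.null(nl))
    wline("near-lumen (<= 200 um) test - control depth: %.2f um (p = %.3g)",
          nl$difference, nl$p)
  if (!is.null(lt))
    wline("test-group log trend: depth = %.2f - %.2f ln(d + %g), r2 = %.3f",
          lt$a, lt$b, lt$c, lt$r2)

  invisible(list(features = features, gradient = gradient, decay = decay,
                 quality_trend = qtrend, indent_bins = indent_bins,
                 anova = av, near_lumen = nl, log_trend = lt,
                 out_dir = out_dir))
}

#' Simulate a full synthetic study
#'
#' Generates, under one seed: morphometry for all teeth, Raman transects
#' (test design: every quadrant, 18 x 50 um; control design: 6 x 150 um in
#' the buccal quadrant), and indentation records along each quadrant.
#'
#' @param config Configuration list (see [default_config()]).
#' @return List with `spectra`, `manifest`, `indentation`, `morphometry`.
#' @export
simulate_study <- function(config = default_config()) {
  seed <- as.integer(config$seed)
  model <- do.call(degradation_model, config$model)
  sc <- config$spectra
  test_ids <- sprintf("T%02d", seq_len(sc$n_test))
  ctrl_ids <- if (sc$n_control > 0) sprintf("C%02d", seq_len(sc$n_control)) else character(0)
  morph <- generate_morphometry(c(test_ids, ctrl_ids), seed = seed)
  morph <- morphometry_table(morph)

  seeds <- with_seed(seed, sample.int(2^30, 4L))
  spectra <- list(); manifest <- NULL
  tseed <- seeds[1L]
  for (tid in test_ids) {
    for (q in sc$quadrants) {
      tseed <- tseed + 1L
      tr <- generate_transect(tid, q, n_points = sc$n_points,
                              spacing_um = sc$spacing_um, model = model,
                              treatment = "naocl", seed = tseed,
                              acq_min = sc$acq_min)
      spectra <- c(spectra, tr$spectra)
      manifest <- rbind(manifest, tr$manifest)
    }
  }
  cseed <- seeds[2L]
  for (tid in ctrl_ids) {
    for (q in sc$control_quadrants) {
      cseed <- cseed + 1L
      tr <- generate_transect(tid, q, n_points = sc$control_n_points,
                              spacing_um = sc$control_spacing_um, model = model,
                              treatment = "control", seed = cseed,
                              acq_min = sc$acq_min)
      spectra <- c(spectra, tr$spectra)
      manifest <- rbind(manifest, tr$manifest)
    }
  }
  manifest$file <- sprintf("%s_%s_%03d.csv", manifest$tooth_id,
                           manifest$quadrant, seq_len(nrow(manifest)))
  manifest <- manifest[, c("file", setdiff(names(manifest), "file"))]

  indent <- NULL
  iseed <- seeds[3L]
  for (tid in test_ids) {
    for (q in c("A", "B", "C", "D")) {
      iseed <- iseed + 1L
      indent <- rbind(indent, generate_indentation(
        tid, "test", config$indentation$distances, seed = iseed, quadrant = q))
    }
  }
  for (tid in ctrl_ids) {
    for (q in c("A", "B", "C", "D")) {
      iseed <- iseed + 1L
      indent <- rbind(indent, generate_indentation(
        tid, "control", config$indentation$distances, seed = iseed, quadrant = q))
    }
  }
  list(spectra = spectra, manifest = manifest, indentation = indent,
       morphometry = morph)
}
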