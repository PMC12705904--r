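#' Write a spectrum to a two-column delimited text file
#'
#' Header line `wavenumber_cm1,intensity` (or tab-separated), one row per
#' grid point, 10 significant digits so write-then-read round-trips preserve
#' values beyond the 6-significant-digit contract.
#'
#' @param s A `raman_spectrum`.
#' @param path Output file path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",") {
  validate_spectrum(s)
  df <- data.frame(wavenumber_cm1 = format(s$wavenumber, digits = 10, trim = TRUE),
                   intensity = format(s$intensity, digits = 10, trim = TRUE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from a delimited text file
#'
#' Accepts comma- or tab-delimited two-column files (delimiter sniffed from
#' the first data line), with or without a header. Descending wavenumber
#' order is reversed with a notice; duplicate wavenumbers and non-numeric
#' rows are errors (the offending line is named). The grid must cover the
#' analysis range (see [validate_spectrum()]).
#'
#' @param path File path.
#' @param meta Optional metadata list attached to the spectrum.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, meta = list()) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  has_header <- suppressWarnings(anyNA(as.numeric(first[1:2])))
  data_lines <- if (has_header) lines[-1L] else lines
  offset <- if (has_header) 1L else 0L
  parts <- strsplit(data_lines, sep, fixed = TRUE)
  ncol_ok <- vapply(parts, length, 1L) >= 2L
  if (!all(ncol_ok))
    stop(sprintf("line %d of %s has fewer than 2 columns",
                 which(!ncol_ok)[1L] + offset, path))
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(w) | !is.finite(y))
  if (length(bad))
    stop(sprintf("non-numeric value on line %d of %s", bad[1L] + offset, path))
  if (anyDuplicated(w)) stop("duplicate wavenumbers in ", path)
  if (all(diff(w) < 0)) {
    message("descending wavenumber order in ", path, ": reversing")
    w <- rev(w); y <- rev(y)
  }
  raman_spectrum(w, y, meta = meta)
}

manifest_required_cols <- c("file", "tooth_id", "quadrant", "distance_um",
                            "acq_min", "locus", "treatment")

#' Write a spectrum manifest CSV
#'
#' @param manifest data.frame with at least the columns `file`, `tooth_id`,
#'   `quadrant`, `distance_um`, `acq_min`, `locus`, `treatment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(manifest_required_cols, names(manifest))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a spectrum manifest CSV
#'
#' Required columns: `file`, `tooth_id`, `quadrant`, `distance_um`,
#' `acq_min`, `locus`, `treatment`. Unknown columns are preserved. Quadrant
#' labels must be A-D; distances must be >= 0 and acquisition times > 0.
#' An empty manifest (header only) is returned as an empty table.
#'
#' @param path File path.
#' @return data.frame of per-spectrum metadata.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_required_cols, names(m))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(m) == 0L) return(m)
  if (!all(m$quadrant %in% c("A", "B", "C", "D")))
    stop("invalid quadrant label(s): ",
         paste(unique(setdiff(m$quadrant, c("A", "B", "C", "D"))), collapse = ", "))
  if (any(m$distance_um < 0)) stop("negative distance_um in manifest")
  if (any(m$acq_min <= 0)) stop("non-positive acq_min in manifest")
  if (!all(m$locus %in% c("intra_tubular", "inter_tubular")))
    stop("invalid locus value(s) in manifest")
  if (!all(m$treatment %in% c("naocl", "control")))
    stop("invalid treatment value(s) in manifest")
  m
}

#' Read indentation records from CSV
#'
#' Required columns: `tooth_id`, `quadrant`, `distance_um`, `depth_um`,
#' `group` (`"test"` or `"control"`).
#'
#' @param path File path.
#' @return data.frame of indentation records.
#' @export
read_indentation <- function(path) {
  if (!file.exists(path)) stop("indentation file not found: ", path)
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("tooth_id", "quadrant", "distance_um", "depth_um", "group")
  missing <- setdiff(req, names(r))
  if (length(missing))
    stop("indentation table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(r) && (any(r$depth_um < 0) || any(r$distance_um < 0)))
    stop("negative depth_um or distance_um in indentation table")
  if (nrow(r) && !all(r$group %in% c("test", "control")))
    stop("invalid group value(s) in indentation table")
  r
}

#' Write a set of spectra with a manifest
#'
#' One delimited text file per spectrum (named `<tooth>_<quadrant>_<k>.csv`)
#' plus `manifest.csv` in `dir`.
#'
#' @param spectra List of `raman_spectrum` objects.
#' @param manifest data.frame as produced by [generate_transect()] (without
#'   the `file` column, which is added).
#' @param dir Output directory (created if needed).
#' @return The manifest with its `file` column, invisibly.
#' @export
write_spectra <- function(spectra, manifest, dir) {
  stopifnot(length(spectra) == nrow(manifest))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%s_%03d.csv", manifest$tooth_id, manifest$quadrant,
                   seq_len(nrow(manifest)))
  for (i in seq_along(spectra))
    write_spectrum(spectra[[i]], file.path(dir, files[i]))
  manifest$file <- files
  manifest <- manifest[, c("file", setdiff(names(manifest), "file"))]
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
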