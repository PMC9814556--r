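#' Construct a full-spectrum chromatogram
#'
#' A full-spectrum chromatogram is an absorbance surface A(t, lambda): a
#' numeric matrix with one row per elution time point (minutes) and one column
#' per detector wavelength (nm). It is the central object of the pipeline.
#'
#' @param time Numeric vector of elution times in minutes, strictly increasing.
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param absorbance Numeric matrix, `length(time)` rows by
#'   `length(wavelength)` columns, in absorbance units (AU).
#' @param meta Named list of free-form provenance (source path, simulation
#'   settings, ...).
#'
#' @return An object of class `spectral_chromatogram`.
#' @examples
#' chrom <- spectral_chromatogram(0:2, c(200, 201, 202), matrix(0, 3, 3))
#' dim(chrom$absorbance)
#' @export
spectral_chromatogram <- function(time, wavelength, absorbance, meta = list()) {
  assert_numeric_vector(time, "time")
  assert_numeric_vector(wavelength, "wavelength")
  assert_strictly_increasing(time, "time")
  assert_strictly_increasing(wavelength, "wavelength")
  if (!is.matrix(absorbance) || !is.numeric(absorbance)) {
    abort("`absorbance` must be a numeric matrix")
  }
  if (nrow(absorbance) != length(time) ||
      ncol(absorbance) != length(wavelength)) {
    abort(sprintf(
      "absorbance matrix is %d x %d but axes imply %d x %d",
      nrow(absorbance), ncol(absorbance), length(time), length(wavelength)))
  }
  if (any(!is.finite(absorbance))) {
    abort("absorbance contains non-finite values")
  }
  dimnames(absorbance) <- NULL
  structure(
    list(time = as.numeric(time), wavelength = as.numeric(wavelength),
         absorbance = absorbance, meta = meta),
    class = "spectral_chromatogram")
}

#' @export
print.spectral_chromatogram <- function(x, ...) {
  cat(sprintf(
    "<spectral_chromatogram> %d time points (%.3f-%.3f min) x %d wavelengths (%.1f-%.1f nm)\n",
    length(x$time), min(x$time), max(x$time),
    length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as_tibble.spectral_chromatogram <- function(x, ...) {
  tibble(
    time = rep(x$time, times = length(x$wavelength)),
    wavelength = rep(x$wavelength, each = length(x$time)),
    absorbance = as.vector(x$absorbance))
}

#' Construct a reference absorption spectrum
#'
#' @param species Species label (non-empty string).
#' @param wavelength Wavelengths in nm, strictly increasing, length >= 16.
#' @param absorbance Absorbance values (arbitrary scale), same length.
#' @param source Provenance: `"literature"`, `"measured"` or `"synthetic"`.
#'
#' @return An object of class `ref_spectrum`.
#' @export
ref_spectrum <- function(species, wavelength, absorbance,
                         source = "synthetic") {
  if (!is.character(species) || length(species) != 1 || !nzchar(species)) {
    abort("`species` must be a non-empty string")
  }
  assert_numeric_vector(wavelength, "wavelength")
  assert_strictly_increasing(wavelength, "wavelength")
  if (length(wavelength) < 16) {
    abort("a reference spectrum needs at least 16 wavelength samples")
  }
  if (length(absorbance) != length(wavelength)) {
    abort("`wavelength` and `absorbance` must have equal length")
  }
  structure(
    list(species = species, wavelength = as.numeric(wavelength),
         absorbance = as.numeric(absorbance), source = source),
    class = "ref_spectrum")
}

#' @export
print.ref_spectrum <- function(x, ...) {
  cat(sprintf("<ref_spectrum> %s [%s], %d points, %.1f-%.1f nm\n",
              x$species, x$source, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as_tibble.ref_spectrum <- function(x, ...) {
  tibble(species = x$species, wavelength = x$wavelength,
         absorbance = x$absorbance, source = x$source)
}

#' Construct a spectral reference library
#'
#' A library is a collection of [ref_spectrum()] entries with a manifest
#' tibble. Duplicate species are allowed (multiple reference spectra per
#' species); classifier training requires at least two distinct species.
#'
#' @param entries List of `ref_spectrum` objects.
#' @param manifest Optional tibble with columns `species`, `file`, `source`;
#'   rebuilt from the entries when omitted.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(entries, manifest = NULL) {
  if (!length(entries) ||
      !all(vapply(entries, inherits, logical(1), "ref_spectrum"))) {
    abort("`entries` must be a non-empty list of ref_spectrum objects")
  }
  species <- vapply(entries, `[[`, character(1), "species")
  if (is.null(manifest)) {
    manifest <- tibble(
      species = species,
      file = sprintf("%s_%03d.csv", gsub("[^A-Za-z0-9]+", "_", species),
                     seq_along(entries)),
      source = vapply(entries, `[[`, character(1), "source"))
  }
  trainable <- length(unique(species)) >= 2
  if (!trainable) {
    warn("library has fewer than 2 distinct species; unfit for classifier training")
  }
  structure(list(entries = entries, manifest = as_tibble(manifest),
                 trainable = trainable),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d spectra, %d species\n",
              length(x$entries), length(unique(x$manifest$species))))
  invisible(x)
}

#' @export
as_tibble.spectral_library <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$entries, as_tibble))
}

#' @rdname spectral_library
#' @param x An object.
#' @export
species_labels <- function(x) unique(x$manifest$species)

#' Read / write a full-spectrum chromatogram CSV
#'
#' The on-disk dialect is a wide CSV: first column `time_min`, remaining
#' column headers the numeric wavelengths in nm (at most 6 significant
#' digits). Axes are sorted ascending on load and validated.
#'
#' @param path File path.
#' @return `read_chromatogram()` returns a validated
#'   [spectral_chromatogram()]; `write_chromatogram()` returns `path`
#'   invisibly.
#' @export
read_chromatogram <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "time_min") {
    abort("first column header must be 'time_min'")
  }
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(wl))) {
    abort(sprintf("non-numeric wavelength header(s): %s",
                  paste(names(df)[-1][is.na(wl)], collapse = ", ")))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    abort(sprintf("non-numeric cell in row %d", badrow))
  }
  if (anyNA(mat) || anyNA(df$time_min)) {
    abort(sprintf("missing/non-numeric cell in row %d",
                  which(rowSums(is.na(mat)) > 0 | is.na(df$time_min))[1]))
  }
  tm <- df$time_min
  ot <- order(tm); ow <- order(wl)
  if (anyDuplicated(tm)) abort("non-monotone time axis")
  if (anyDuplicated(wl)) abort("non-monotone wavelength axis")
  spectral_chromatogram(tm[ot], wl[ow], mat[ot, ow, drop = FALSE],
                        meta = list(source = path))
}

#' @rdname read_chromatogram
#' @param chrom A [spectral_chromatogram()].
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "spectral_chromatogram"))
  if (length(chrom$time) == 0 || length(chrom$wavelength) == 0) {
    abort("refusing to write an empty chromatogram")
  }
  df <- as.data.frame(chrom$absorbance)
  names(df) <- formatC(chrom$wavelength, digits = 6, format = "g")
  df <- cbind(time_min = chrom$time, df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a reference spectrum CSV (two columns:
#' `wavelength_nm`, `absorbance`)
#'
#' @param path File path.
#' @param species,source Metadata attached on read.
#' @return A [ref_spectrum()].
#' @export
read_spectrum <- function(path, species = NULL, source = "measured") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df))) {
    abort("spectrum CSV needs columns 'wavelength_nm' and 'absorbance'")
  }
  o <- order(df$wavelength_nm)
  ref_spectrum(species %||% sub("\\.[^.]*$", "", basename(path)),
               df$wavelength_nm[o], df$absorbance[o], source = source)
}

#' @rdname read_spectrum
#' @param spectrum A [ref_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ref_spectrum"))
  readr::write_csv(
    tibble(wavelength_nm = spectrum$wavelength,
           absorbance = spectrum$absorbance),
    path, progress = FALSE)
  invisible(path)
}

#' Read / write a spectral library via its manifest
#'
#' The manifest is a TSV with columns `species`, `file`, `source`; `file`
#' paths are resolved relative to the manifest's directory and point to
#' two-column spectrum CSVs.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return A [spectral_library()].
#' @export
read_library <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path))
  }
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("species", "file", "source") %in% names(man))) {
    abort("manifest needs columns 'species', 'file', 'source'")
  }
  base <- dirname(manifest_path)
  entries <- purrr::pmap(man, function(species, file, source, ...) {
    fp <- file.path(base, file)
    if (!file.exists(fp)) {
      abort(sprintf("library entry '%s': file not found: %s", species, file))
    }
    read_spectrum(fp, species = species, source = source)
  })
  spectral_library(entries, manifest = man)
}

#' @rdname read_library
#' @param library A [spectral_library()].
#' @param dir Directory to write the manifest (`manifest.tsv`) and one CSV per
#'   entry into; created if absent.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "spectral_library"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- library$manifest
  purrr::walk2(library$entries, man$file,
               ~ write_spectrum(.x, file.path(dir, .y)))
  readr::write_tsv(man, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

peak_table_cols <- c("peak_id", "retention_time", "apex_absorbance",
                     "start", "end", "species", "posterior", "r2",
                     "frechet", "deconvolved")

#' Read / write an annotated peak table TSV
#'
#' Fixed column order: peak_id, retention_time, apex_absorbance, start, end,
#' species, posterior, r2, frechet, deconvolved.
#'
#' @param table A tibble with the peak-table columns.
#' @param path File path.
#' @export
write_peak_table <- function(table, path) {
  missing_cols <- setdiff(peak_table_cols, names(table))
  if (length(missing_cols)) {
    abort(sprintf("peak table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(table[peak_table_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    peak_id = "i", species = "c", deconvolved = "l",
                    .default = "d"))
}
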