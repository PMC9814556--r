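#' Convert detector intensities to absorbance
#'
#' Standard dual-beam absorbance: `A = -log10((I - dark) / (I0 - dark))`.
#' Channels where the dark-corrected sample intensity is non-positive are
#' clipped to `a_max` (detector floor reached).
#'
#' @param sample_intensity,reference_intensity,dark Equal-length numeric
#'   vectors of detector counts; `dark` may be a scalar.
#' @param a_max Clip value for saturated channels, AU.
#' @return Absorbance vector in AU.
#' @examples
#' compute_absorbance(190, 1000, 100)  # -log10(90/900) = 1
#' @export
compute_absorbance <- function(sample_intensity, reference_intensity,
                               dark = 0, a_max = 4) {
  n <- length(sample_intensity)
  if (length(dark) == 1) dark <- rep(dark, n)
  if (length(reference_intensity) != n || length(dark) != n) {
    abort("intensity vectors must have equal length")
  }
  blank <- reference_intensity - dark
  if (any(blank <= 0)) {
    abort("invalid blank: reference intensity must exceed dark everywhere")
  }
  sig <- sample_intensity - dark
  a <- ifelse(sig <= 0, a_max, -log10(pmax(sig, .Machine$double.xmin) / blank))
  pmin(a, a_max)
}

#' Resample a reference spectrum onto a wavelength grid
#'
#' Linear interpolation inside the spectrum's support; grid points outside
#' the support are returned as `NA` (missing) and are excluded pairwise from
#' downstream similarity computations rather than zero-filled.
#'
#' @param spectrum A [ref_spectrum()].
#' @param grid Target wavelength grid, nm, strictly increasing.
#' @return A `ref_spectrum` on `grid`; `absorbance` is `NA` outside the
#'   original support.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "ref_spectrum"))
  assert_strictly_increasing(grid, "grid")
  inside <- grid >= min(spectrum$wavelength) & grid <= max(spectrum$wavelength)
  if (!any(inside)) abort("grid does not overlap the spectrum's support")
  y <- rep(NA_real_, length(grid))
  y[inside] <- approx(spectrum$wavelength, spectrum$absorbance,
                      xout = grid[inside])$y
  out <- spectrum
  out$wavelength <- as.numeric(grid)
  out$absorbance <- y
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with the window expressed in nm.
#' The window length in samples is `2 * round(half_window_nm / grid_step) + 1`
#' and must exceed the polynomial order. An order-5 filter reproduces
#' polynomials up to degree 5 exactly, so genuine band structure is
#' preserved while digitisation noise is suppressed.
#'
#' @param values Numeric vector to smooth (NA runs at the ends, as produced
#'   by [resample_to_grid()], are preserved; the finite segment is smoothed).
#' @param grid_step Sample spacing in nm.
#' @param poly_order Polynomial order (default 5).
#' @param half_window_nm Half window in nm (default 4.5).
#' @return Smoothed vector, same length.
#' @export
savgol_smooth <- function(values, grid_step, poly_order = 5,
                          half_window_nm = 4.5) {
  n_win <- 2 * round(half_window_nm / grid_step) + 1
  if (n_win <= poly_order) {
    abort(sprintf(
      "window of %d samples too small for order %d; need half_window_nm > %.3g",
      n_win, poly_order, (poly_order / 2) * grid_step))
  }
  fin <- which(is.finite(values))
  if (!length(fin)) return(values)
  i0 <- min(fin); i1 <- max(fin)
  seg <- values[i0:i1]
  if (any(!is.finite(seg))) abort("interior NA in values; cannot smooth")
  if (length(seg) < n_win) {
    abort(sprintf("need at least %d finite samples (have %d)", n_win,
                  length(seg)))
  }
  out <- values
  out[i0:i1] <- as.numeric(signal::sgolayfilt(seg, p = poly_order, n = n_win))
  out
}

#' First derivative by central differences
#'
#' Central differences at interior points, one-sided at the ends; units
#' AU/nm. Differentiation removes any constant baseline offset between
#' spectra recorded on different instruments.
#'
#' @param values Numeric vector.
#' @param grid Strictly increasing sample positions (nm).
#' @return Derivative vector, same length.
#' @export
first_derivative <- function(values, grid) {
  if (length(values) < 3) abort("need at least 3 samples to differentiate")
  assert_strictly_increasing(grid, "grid")
  n <- length(values)
  d <- numeric(n)
  d[1] <- (values[2] - values[1]) / (grid[2] - grid[1])
  d[n] <- (values[n] - values[n - 1]) / (grid[n] - grid[n - 1])
  i <- 2:(n - 1)
  d[i] <- (values[i + 1] - values[i - 1]) / (grid[i + 1] - grid[i - 1])
  d
}

#' Extract a single-wavelength detection channel
#'
#' Averages the absorbance surface over wavelengths within `center_nm +/-
#' half_window_nm`, emulating a conventional single-wavelength detector
#' trace (e.g. monitoring at 230 +/- 2 nm). The mean (not sum) keeps the
#' trace scale-free across window widths.
#'
#' @param chrom A [spectral_chromatogram()].
#' @param center_nm Channel centre, nm.
#' @param half_window_nm Half window, nm (default 2).
#' @return A `channel_chromatogram`: list with `time`, `absorbance`,
#'   `center_wavelength`, `half_window`.
#' @export
extract_channel <- function(chrom, center_nm, half_window_nm = 2) {
  stopifnot(inherits(chrom, "spectral_chromatogram"))
  if (half_window_nm < 0) abort("`half_window_nm` must be >= 0")
  idx <- which(chrom$wavelength >= center_nm - half_window_nm &
                 chrom$wavelength <= center_nm + half_window_nm)
  if (!length(idx)) {
    abort(sprintf("no wavelengths in %.6g +/- %.6g nm", center_nm,
                  half_window_nm))
  }
  structure(
    list(time = chrom$time,
         absorbance = rowMeans(chrom$absorbance[, idx, drop = FALSE]),
         center_wavelength = center_nm, half_window = half_window_nm),
    class = "channel_chromatogram")
}

#' @export
print.channel_chromatogram <- function(x, ...) {
  cat(sprintf("<channel_chromatogram> %.6g +/- %.6g nm, %d points\n",
              x$center_wavelength, x$half_window, length(x$time)))
  invisible(x)
}

#' @export
as_tibble.channel_chromatogram <- function(x, ...) {
  tibble(time = x$time, absorbance = x$absorbance)
}

#' Detect chromatographic peaks on a single channel
#'
#' The trace is baseline-subtracted (baseline = median of its lowest
#' decile), lightly smoothed in time (cubic Savitzky-Golay over a
#' `min_separation_min` window, skipped when the window is too short), and
#' scanned for local maxima. A maximum is kept when its height and its
#' topographic prominence both exceed `min_snr` times a robust noise
#' estimate (1.4826 x median absolute deviation of the first-difference
#' detrended raw trace) - the prominence requirement rejects noise ripples
#' riding on a broad peak flank. The tallest apex wins within any
#' `min_separation_min` span. Each peak carries the times at which the
#' baseline-subtracted absorbance first falls to 10% of its apex height on
#' the rising and trailing sides, found by walking outward from the apex
#' with linear interpolation between samples (clamped and flagged at the
#' trace edges).
#'
#' @param channel A `channel_chromatogram` from [extract_channel()].
#' @param min_snr Minimum apex signal-to-noise (and prominence-to-noise)
#'   ratio.
#' @param min_separation_min Minimum apex separation, minutes.
#' @return Tibble with columns `apex_time`, `apex_absorbance` (raw),
#'   `height` (baseline-subtracted), `snr`, `rise_time_10pct`,
#'   `trail_time_10pct`, `edge_clipped`; the baseline and noise sd are
#'   attached as attributes.
#' @export
detect_peaks <- function(channel, min_snr = 5, min_separation_min = 0.05) {
  stopifnot(inherits(channel, "channel_chromatogram"))
  tm <- channel$time
  if (length(tm) < 10) abort("need at least 10 time points")
  base <- baseline_level(channel$absorbance)
  y_raw <- channel$absorbance - base
  noise <- robust_noise_sd(y_raw)
  dt <- grid_step(tm)
  n_sm <- 2 * floor(round(min_separation_min / dt) / 2) + 1
  y <- if (n_sm >= 7 && n_sm < length(y_raw)) {
    as.numeric(signal::sgolayfilt(y_raw, p = 3, n = n_sm))
  } else {
    y_raw
  }
  n <- length(y)
  i <- 2:(n - 1)
  cand <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > 0]
  if (noise > 0) cand <- cand[y[cand] / noise >= min_snr]
  # topographic prominence: drop ripples on the flank of a taller peak
  prominence <- function(p) {
    taller_l <- which(y[seq_len(p - 1)] > y[p])
    taller_r <- which(y[(p + 1):n] > y[p]) + p
    v_l <- if (length(taller_l)) min(y[max(taller_l):p]) else min(y[1:p])
    v_r <- if (length(taller_r)) min(y[p:min(taller_r)]) else min(y[p:n])
    y[p] - max(v_l, v_r)
  }
  if (noise > 0 && length(cand)) {
    cand <- cand[vapply(cand, prominence, numeric(1)) / noise >= min_snr]
  }
  empty <- tibble(apex_time = numeric(), apex_absorbance = numeric(),
                  height = numeric(), snr = numeric(),
                  rise_time_10pct = numeric(), trail_time_10pct = numeric(),
                  edge_clipped = logical())
  if (!length(cand)) return(structure(empty, baseline = base, noise_sd = noise))
  # tallest-first greedy separation
  cand <- cand[order(-y[cand])]
  keep <- integer()
  for (ci in cand) {
    if (!length(keep) || all(abs(tm[ci] - tm[keep]) >= min_separation_min)) {
      keep <- c(keep, ci)
    }
  }
  keep <- sort(keep)
  cross10 <- function(apex, dir) {
    thr <- 0.1 * y[apex]
    j <- apex
    repeat {
      nxt <- j + dir
      if (nxt < 1 || nxt > n) return(list(t = tm[j], clipped = TRUE))
      if (y[nxt] <= thr) {
        frac <- (y[j] - thr) / (y[j] - y[nxt])
        return(list(t = tm[j] + frac * (tm[nxt] - tm[j]), clipped = FALSE))
      }
      j <- nxt
    }
  }
  rows <- purrr::map(keep, function(a) {
    lo <- cross10(a, -1L); hi <- cross10(a, +1L)
    tibble(apex_time = tm[a], apex_absorbance = channel$absorbance[a],
           height = y[a], snr = if (noise > 0) y[a] / noise else Inf,
           rise_time_10pct = lo$t, trail_time_10pct = hi$t,
           edge_clipped = lo$clipped || hi$clipped)
  })
  structure(dplyr::bind_rows(rows), baseline = base, noise_sd = noise)
}
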