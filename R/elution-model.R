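#' Crop a chromatogram to a time window
#'
#' @param chrom A [spectral_chromatogram()].
#' @param t_start,t_end Window bounds, minutes.
#' @return A [spectral_chromatogram()] restricted to the window.
#' @export
crop_time <- function(chrom, t_start, t_end) {
  sel <- which(chrom$time >= t_start & chrom$time <= t_end)
  if (length(sel) < 2) abort("window outside the time axis")
  spectral_chromatogram(chrom$time[sel], chrom$wavelength,
                        chrom$absorbance[sel, , drop = FALSE],
                        meta = chrom$meta)
}

gaussian_sum_model <- function(t, rt, sigma, amp) {
  G <- vapply(seq_along(rt),
              function(j) exp(-(t - rt[j])^2 / (2 * sigma[j]^2)),
              numeric(length(t)))
  as.numeric(G %*% amp)
}

# default initial guesses from the k tallest local maxima of the trace;
# extra components (hidden species) are seeded at quantiles of the signal
# mass, and the initial width comes from the tallest peak's half-height
# width so broad windows do not seed degenerately broad components
init_from_maxima <- function(tm, y, k) {
  n <- length(y)
  i <- 2:(n - 1)
  cand <- i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
  cand <- cand[order(-y[cand])]
  span <- diff(range(tm))
  rt0 <- tm[cand]
  if (length(rt0) >= k) {
    rt0 <- sort(rt0[seq_len(k)])
  } else {
    mass <- cumsum(pmax(y, 0))
    mass <- mass / mass[n]
    q <- seq_len(k - length(rt0)) / (k - length(rt0) + 1)
    extra <- tm[vapply(q, function(p) which.max(mass >= p), integer(1))]
    rt0 <- sort(c(rt0, extra))
  }
  amp0 <- pmax(approx(tm, y, xout = rt0)$y, 0.1 * max(y))
  apex <- which.max(y)
  above <- which(y >= 0.5 * y[apex])
  fwhm <- tm[max(above)] - tm[min(above)]
  sigma0 <- rep(max(min(fwhm / 2.355, span / (4 * k)), 2 * grid_step(tm)), k)
  list(rt = rt0, sigma = sigma0, amp = amp0)
}

#' Fit a sum of Gaussian elution peaks to a single channel
#'
#' Penalised nonlinear least squares of `b + sum_j a_j exp(-(t - Rt_j)^2 /
#' (2 sigma_j^2))` to the trace, with `a_j >= 0` and `sigma_j` bounded
#' between the sampling step and half the window; the constant baseline `b`
#' is a free parameter (initialised at the lowest-decile median, which by
#' itself sits below the true baseline by about 1.6 noise-sd and would bias
#' the peak parameters if subtracted and frozen). Although often called a
#' Gaussian mixture in chromatography, the data are a curve, not draws from
#' a density, so this is curve fitting, not expectation-maximisation.
#'
#' With more components than visible apexes the least-squares surface is
#' multimodal, so when no explicit `init` is given the optimiser is run
#' from a small set of starting layouts (detected maxima plus signal-mass
#' quantiles, and even spacings across the central signal mass at two
#' widths) and the best converged fit wins.
#'
#' @param channel A `channel_chromatogram`.
#' @param k Number of components (>= 1).
#' @param init Optional list with numeric vectors `rt`, `sigma`, `amp` of
#'   length k; when supplied, only that start is used.
#' @param max_iter Optimiser iteration cap (per start).
#' @return A `gmm_fit`: list with `components` tibble (`rt`, `sigma`,
#'   `amplitude`, sorted by rt), `residual_rms`, `converged`, `baseline`,
#'   plus the fitted trace. Non-convergence is flagged, not an error.
#' @export
fit_gaussian_sum <- function(channel, k, init = NULL, max_iter = 200) {
  stopifnot(inherits(channel, "channel_chromatogram"), k >= 1)
  tm <- channel$time
  if (length(tm) < 5 * k) abort("need at least 5k time points")
  base0 <- baseline_level(channel$absorbance)
  y_raw <- channel$absorbance
  dt <- grid_step(tm)
  span <- diff(range(tm))
  inits <- if (!is.null(init)) {
    stopifnot(length(init$rt) == k)
    list(init)
  } else {
    y0 <- y_raw - base0
    starts <- list(init_from_maxima(tm, y0, k))
    if (k > 1) {
      # even spacings across the central 90% of the signal mass, at two
      # candidate widths (hidden components make the surface multimodal)
      mass <- cumsum(pmax(y0, 0))
      mass <- mass / mass[length(mass)]
      lo <- tm[which.max(mass >= 0.05)]
      hi <- tm[which.max(mass >= 0.95)]
      if (hi - lo > 2 * dt) {
        rt_even <- seq(lo, hi, length.out = k)
        amp_even <- pmax(approx(tm, y0, xout = rt_even)$y, 0.1 * max(y0))
        for (sg in c((hi - lo) / (2 * k), (hi - lo) / (6 * k))) {
          starts <- c(starts, list(list(rt = rt_even,
                                        sigma = rep(max(sg, 2 * dt), k),
                                        amp = amp_even)))
        }
      }
    }
    starts
  }
  lower <- c(rep(min(tm), k), rep(dt, k), rep(0, k), -Inf)
  upper <- c(rep(max(tm), k), rep(span / 2, k), rep(Inf, k), Inf)
  run_one <- function(ini) {
    p0 <- c(ini$rt, pmin(pmax(ini$sigma, dt), span / 2), pmax(ini$amp, 0),
            base0)
    tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) {
          y_raw - p[3 * k + 1] -
            gaussian_sum_model(tm, p[1:k], p[(k + 1):(2 * k)],
                               p[(2 * k + 1):(3 * k)])
        },
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      error = function(e) NULL)
  }
  fits <- purrr::compact(purrr::map(inits, run_one))
  if (!length(fits)) {
    p <- c(inits[[1]]$rt, inits[[1]]$sigma, inits[[1]]$amp, base0)
    converged <- FALSE
  } else {
    fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "deviance"))]]
    p <- fit$par
    converged <- fit$info %in% 1:4
  }
  o <- order(p[1:k])
  base <- p[3 * k + 1]
  comp <- tibble(rt = p[1:k][o], sigma = p[(k + 1):(2 * k)][o],
                 amplitude = p[(2 * k + 1):(3 * k)][o])
  fitted <- gaussian_sum_model(tm, comp$rt, comp$sigma, comp$amplitude)
  structure(
    list(components = comp,
         residual_rms = sqrt(mean((y_raw - base - fitted)^2)),
         converged = converged, baseline = base, time = tm, fitted = fitted,
         observed = y_raw - base, shared_rt = FALSE),
    class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> %d component(s), residual RMS %.3g AU%s%s\n",
              nrow(x$components), x$residual_rms,
              if (x$shared_rt) ", shared Rt" else "",
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$components)
  invisible(x)
}

#' @export
tidy.gmm_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = 1)
}

#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(k = nrow(x$components), residual_rms = x$residual_rms,
         converged = x$converged, shared_rt = x$shared_rt)
}

#' Retention-time consistency diagnostic across wavelength channels
#'
#' Fits an independent k-component Gaussian sum to each listed channel and
#' compares the fitted retention times component-by-component. For a true
#' k-species window the Rt of each component is a physical property and must
#' not depend on the detection wavelength; a spread above `tol_factor` times
#' the median fitted peak width signals an under-specified k - a hidden
#' species whose varying spectral contribution drags the fit around.
#'
#' @param chrom A [spectral_chromatogram()].
#' @param window `c(t_start, t_end)`, minutes.
#' @param k Components per channel fit.
#' @param channel_centers Channel centres in nm (>= 3).
#' @param half_window_nm Channel half window.
#' @param tol_factor Spread tolerance as a fraction of the median fitted
#'   sigma (default 0.05; on clean single-species data the spread across
#'   usable channels is two orders of magnitude below this, while an
#'   unmodelled species shifts it by a sizeable fraction of sigma).
#' @param min_channel_snr Channels whose baseline-subtracted maximum is
#'   below this multiple of the channel noise carry too little
#'   retention-time information (a species need not absorb at every
#'   wavelength, and weak channels fit Rt imprecisely) and are excluded
#'   (default 20).
#' @return List with `table` (tibble: channel, component, rt, sigma),
#'   `spread` (per-component max - min Rt, minutes), `sigma_hat`, `tol`,
#'   `flagged`, and `excluded` (channels skipped, failed or degenerate).
#'   With fewer than 3 usable channels the diagnostic is inconclusive and
#'   reports `flagged = FALSE`.
#' @export
rt_consistency_diagnostic <- function(chrom, window, k,
                                      channel_centers = seq(240, 400, by = 20),
                                      half_window_nm = 2, tol_factor = 0.05,
                                      min_channel_snr = 20) {
  if (length(channel_centers) < 3) abort("need at least 3 channels")
  sub <- crop_time(chrom, window[1], window[2])
  span <- diff(range(sub$time))
  edge <- 0.02 * span
  rows <- purrr::map(channel_centers, function(cw) {
    ch <- extract_channel(sub, cw, half_window_nm)
    y <- ch$absorbance - baseline_level(ch$absorbance)
    noise <- robust_noise_sd(ch$absorbance)
    if (noise > 0 && max(y) / noise < min_channel_snr) return(NULL)
    f <- fit_gaussian_sum(ch, k)
    if (!f$converged) return(NULL)
    # a component stuck at the window edge or blown up to the width bound
    # is a failed fit, not retention-time evidence; the remaining
    # components still carry it (an underspecified k typically parks one
    # junk component at the edge while the real peak's Rt drifts)
    comp <- dplyr::filter(f$components,
                          .data$rt >= min(sub$time) + edge,
                          .data$rt <= max(sub$time) - edge,
                          .data$sigma <= 0.45 * span)
    if (!nrow(comp)) return(NULL)
    dplyr::mutate(comp, component = dplyr::row_number(), channel = cw,
                  .before = 1)
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (sum(ok) < 3) {
    return(list(table = tibble(), spread = rep(NA_real_, k),
                sigma_hat = NA_real_, tol = NA_real_, flagged = FALSE,
                excluded = channel_centers[!ok]))
  }
  table <- dplyr::bind_rows(rows[ok])
  spread <- table |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(spread = max(.data$rt) - min(.data$rt)) |>
    dplyr::pull(.data$spread)
  sigma_hat <- median(table$sigma)
  tol <- tol_factor * sigma_hat
  list(table = table, spread = spread, sigma_hat = sigma_hat, tol = tol,
       flagged = any(spread > tol), excluded = channel_centers[!ok])
}

#' Joint Gaussian fit with retention times shared across channels
#'
#' Two-stage elution-model fit for a congested window. First, `Rt_j` and
#' `sigma_j` are fitted jointly over a small set of wavelength channels with
#' per-channel free amplitudes (physical elution positions and widths do not
#' depend on wavelength). Second, with `Rt` and `sigma` frozen, amplitudes
#' are refit at every wavelength by non-negative least squares, yielding
#' unit-area concentration profiles `C` and a full per-wavelength amplitude
#' spectrum per component. Channels default to centres every 20 nm across
#' 240-400 nm - the region where species-specific band structure lives (the
#' short-wavelength absorption below ~245 nm is common to all aromatics and
#' carries no discriminating information); channels without signal are
#' harmless here since their amplitudes simply fit to ~0, and spectral
#' regions where only a subset of species absorb pin down those species'
#' Rt best.
#'
#' @param chrom A [spectral_chromatogram()].
#' @param window `c(t_start, t_end)`, minutes.
#' @param k Number of species (e.g. from [estimate_k_elbow()]).
#' @param rt_init Numeric vector of length k: initial retention times.
#' @param sigma_init Optional initial widths (scalar or length k).
#' @param channels Channel centres for stage one, nm.
#' @param half_window_nm Channel half window.
#' @param max_iter Optimiser iteration cap.
#' @return A `gmm_fit` with `shared_rt = TRUE` carrying `C` (time x k,
#'   scaled unit-area Gaussians), `S` (wavelength x k, unit-max amplitude
#'   spectra), `time`, `wavelength` and per-channel residual RMS.
#' @export
fit_shared_rt <- function(chrom, window, k, rt_init, sigma_init = NULL,
                          channels = NULL, half_window_nm = 2,
                          max_iter = 300) {
  if (length(rt_init) != k) abort("`rt_init` must have length k")
  sub <- crop_time(chrom, window[1], window[2])
  tm <- sub$time
  dt <- grid_step(tm)
  span <- diff(range(tm))
  if (is.null(sigma_init)) sigma_init <- span / (4 * k)
  sigma_init <- rep_len(sigma_init, k)
  if (is.null(channels)) channels <- seq(240, 400, by = 20)
  channels <- channels[channels - half_window_nm >= min(sub$wavelength) &
                         channels + half_window_nm <= max(sub$wavelength)]
  traces <- purrr::map(channels, function(cw) {
    ch <- extract_channel(sub, cw, half_window_nm)
    ch$absorbance - baseline_level(ch$absorbance)
  })
  m <- length(traces)
  gmat <- function(rt, sigma) {
    vapply(seq_len(k), function(j) exp(-(tm - rt[j])^2 / (2 * sigma[j]^2)),
           numeric(length(tm)))
  }
  # initial amplitudes: per-channel NNLS against the initial Gaussians
  G0 <- gmat(rt_init, sigma_init)
  A0 <- vapply(traces, function(y) nnls_multi(G0, cbind(y))[, 1],
               numeric(k))                       # k x m
  p0 <- c(sort(rt_init), pmin(pmax(sigma_init, dt), span / 2),
          pmax(as.numeric(A0), 0))
  lower <- c(rep(min(tm), k), rep(dt, k), rep(0, k * m))
  upper <- c(rep(max(tm), k), rep(span / 2, k), rep(Inf, k * m))
  resid_fn <- function(p) {
    G <- gmat(p[1:k], p[(k + 1):(2 * k)])
    A <- matrix(p[-(1:(2 * k))], nrow = k)
    unlist(purrr::map(seq_len(m), function(c) traces[[c]] - G %*% A[, c]))
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  p <- fit$par
  o <- order(p[1:k])
  rt <- p[1:k][o]
  sigma <- p[(k + 1):(2 * k)][o]
  # optional channel augmentation: channels dominated by one component
  A1 <- matrix(p[-(1:(2 * k))], nrow = k)[o, , drop = FALSE]
  # stage two: freeze Rt/sigma, refit amplitudes at every wavelength by NNLS
  # against unit-area profiles
  Gu <- vapply(seq_len(k), function(j) dnorm(tm, rt[j], sigma[j]),
               numeric(length(tm)))
  amp <- t(nnls_multi(Gu, sub$absorbance))        # wavelength x k
  smax <- pmax(apply(amp, 2, max), .Machine$double.eps)
  S <- sweep(amp, 2, smax, "/")
  C <- sweep(Gu, 2, smax, "*")
  resid_rms <- vapply(seq_len(m), function(c) {
    sqrt(mean((traces[[c]] - gmat(rt, sigma) %*% A1[, c])^2))
  }, numeric(1))
  structure(
    list(components = tibble(rt = rt, sigma = sigma,
                             amplitude = apply(amp, 2, max)),
         C = C, S = S, amplitudes = amp, time = tm,
         wavelength = sub$wavelength, window = c(window[1], window[2]),
         channels = channels, channel_amplitudes = A1,
         residual_rms = mean(resid_rms), residual_rms_per_channel = resid_rms,
         converged = fit$info %in% 1:4, shared_rt = TRUE),
    class = "gmm_fit")
}

#' Initial spectra from peak flanks (the 10%-of-apex rule)
#'
#' Builds the initial spectra set for curve resolution from the chromatogram
#' itself: the first (earliest) component's estimate is the measured
#' spectrum at its rising 10%-of-apex time, the last component's at its
#' trailing 10% time - time points chosen to maximise that species'
#' signal-to-noise while minimising interference from neighbours. Interior
#' (hidden) components, which have no uncontaminated flank, are estimated by
#' the spectrum at their fitted retention time. Each sampled spectrum is the
#' mean of `2 * half_rows + 1` consecutive rows centred on the target time
#' (a fraction of a second - negligible against the peak width - that
#' matters at the 10% flank, where the signal is a tenth of the apex).
#' Columns are unit-max normalised. 10% times falling outside the window
#' are clamped to the edge and flagged.
#'
#' @param chrom A [spectral_chromatogram()] (may be wider than the fit
#'   window).
#' @param fit A `gmm_fit` from [fit_shared_rt()] or [fit_gaussian_sum()].
#' @param half_rows Rows averaged on each side of the target time
#'   (default 3; about +/- 0.6 s, negligible against peak widths of several
#'   seconds).
#' @return List with `S0` (wavelength x k matrix, unit-max columns), `times`
#'   (sampled time per component, monotone increasing), `clipped` (logical
#'   per component).
#' @export
flank_spectra <- function(chrom, fit, half_rows = 3) {
  stopifnot(inherits(fit, "gmm_fit"))
  comp <- fit$components
  k <- nrow(comp)
  if (k < 1) abort("fit has no components")
  tm <- chrom$time
  win <- if (!is.null(fit$window)) fit$window else range(fit$time)
  target <- comp$rt
  target[1] <- comp$rt[1] - comp$sigma[1] * TEN_PCT_HALF_WIDTH
  if (k > 1) target[k] <- comp$rt[k] + comp$sigma[k] * TEN_PCT_HALF_WIDTH
  clipped <- target < win[1] | target > win[2]
  target <- pmin(pmax(target, win[1]), win[2])
  idx <- vapply(target, function(t0) which.min(abs(tm - t0)), integer(1))
  S0 <- vapply(idx, function(i) {
    rows <- max(1, i - half_rows):min(length(tm), i + half_rows)
    colMeans(chrom$absorbance[rows, , drop = FALSE])
  }, numeric(length(chrom$wavelength)))
  # light wavelength smoothing: flank rows sit at a tenth of the apex
  # signal, and the initial spectra set the basin MCR refines within
  wl_step <- grid_step(chrom$wavelength)
  S0 <- apply(S0, 2, function(s) {
    tryCatch(savgol_smooth(s, wl_step), error = function(e) s)
  })
  S0 <- apply(S0, 2, unit_max)
  list(S0 = S0, times = tm[idx], clipped = clipped)
}
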