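#' Pipeline configuration
#'
#' Settings for the end-to-end unsupervised analysis. The detection channel
#' defaults to 230 +/- 2 nm, where aromatic analytes absorb strongly.
#'
#' @param channel_center,channel_hw Detection channel, nm.
#' @param min_snr,min_separation Peak detection thresholds (see
#'   [detect_peaks()]).
#' @param k_max,n_restarts Species-count scan settings (see
#'   [estimate_k_elbow()]).
#' @param rt_channels Channel centres for the Rt-consistency diagnostic and
#'   the shared-Rt fit, nm.
#' @param rt_tol_factor Rt-spread tolerance as a fraction of the fitted
#'   width.
#' @param mcr_tol,mcr_max_iter Curve-resolution convergence settings.
#' @param window_pad Padding added around each congested region, minutes.
#' @param seed Master seed; all stochastic steps (K-means restarts) derive
#'   from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(channel_center = 230, channel_hw = 2,
                            min_snr = 5, min_separation = 0.05,
                            k_max = 8, n_restarts = 10,
                            rt_channels = seq(240, 400, by = 20),
                            rt_tol_factor = 0.05,
                            mcr_tol = 1e-8, mcr_max_iter = 500,
                            window_pad = 0.15, seed = 1L) {
  cfg <- as.list(environment())
  if (any(vapply(cfg[c("channel_hw", "min_snr", "min_separation", "k_max",
                       "n_restarts", "rt_tol_factor", "mcr_tol",
                       "mcr_max_iter")], function(v) any(v <= 0),
                 logical(1)))) {
    abort("all pipeline thresholds must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

# group detected peaks into congestion regions: peaks share a region when
# their [10%-rise, 10%-trail] intervals overlap
group_peak_regions <- function(peaks) {
  if (!nrow(peaks)) return(list())
  o <- order(peaks$apex_time)
  peaks <- peaks[o, ]
  groups <- list()
  cur <- 1L
  cur_end <- peaks$trail_time_10pct[1]
  idx <- 1L
  for (i in seq_len(nrow(peaks))[-1]) {
    if (peaks$rise_time_10pct[i] <= cur_end) {
      idx <- c(idx, i)
      cur_end <- max(cur_end, peaks$trail_time_10pct[i])
    } else {
      groups[[cur]] <- peaks[idx, ]
      cur <- cur + 1L
      idx <- i
      cur_end <- peaks$trail_time_10pct[i]
    }
  }
  groups[[cur]] <- peaks[idx, ]
  groups
}

chrom_row_spectrum <- function(chrom, t0, label = "query") {
  i <- which.min(abs(chrom$time - t0))
  ref_spectrum(label, chrom$wavelength,
               unit_max(pmax(chrom$absorbance[i, ], 0)), source = "measured")
}

unresolved_rows <- function(region_peaks, reason) {
  tibble(retention_time = region_peaks$apex_time,
         apex_absorbance = region_peaks$apex_absorbance,
         start = region_peaks$rise_time_10pct,
         end = region_peaks$trail_time_10pct,
         species = "unresolved", posterior = NA_real_, r2 = NA_real_,
         frechet = NA_real_, deconvolved = FALSE, note = reason)
}

#' Deconvolve a congested elution window
#'
#' Runs the full hidden-peak procedure on one window: shared-Rt Gaussian
#' elution fit, flank-spectrum initialisation (10%-of-apex rule, interior
#' species at their fitted Rt) and curve resolution by alternating
#' non-negative regression with the unimodality constraint on the
#' concentration profiles (elution profiles are single peaks; without the
#' constraint, rotational ambiguity lets a hidden component absorb
#' neighbouring features for unfavourable spectral geometries). Components
#' are returned in elution order.
#'
#' @param chrom A [spectral_chromatogram()].
#' @param t_start,t_end Window bounds, minutes.
#' @param k Number of species in the window.
#' @param rt_init,sigma_init,channels Passed to [fit_shared_rt()];
#'   `rt_init` defaults to the k tallest local maxima of the 230 nm channel
#'   (extra components seeded across the window when fewer are visible).
#' @param mcr_tol,mcr_max_iter,unimodal Passed to [mcr_ar()]; the
#'   unimodality constraint is on by default here.
#' @param detect_channel Channel centre used for the default `rt_init`, nm.
#' @return List with `fit` (the shared-Rt `gmm_fit`), `flanks` (see
#'   [flank_spectra()]) and `mcr` (the `mcr_result`; its `S` columns are
#'   the recovered spectra on the chromatogram's wavelength grid, ordered
#'   by retention time).
#' @export
deconvolve_window <- function(chrom, t_start, t_end, k, rt_init = NULL,
                              sigma_init = NULL, channels = NULL,
                              mcr_tol = 1e-8, mcr_max_iter = 500,
                              unimodal = TRUE, detect_channel = 230) {
  sub <- crop_time(chrom, t_start, t_end)
  if (is.null(rt_init)) {
    ch <- extract_channel(sub, detect_channel, 2)
    rt_init <- init_from_maxima(ch$time,
                                ch$absorbance - baseline_level(ch$absorbance),
                                k)$rt
  }
  sfit <- fit_shared_rt(chrom, c(t_start, t_end), k, rt_init = rt_init,
                        sigma_init = sigma_init, channels = channels)
  fl <- flank_spectra(sub, sfit)
  mcr <- mcr_ar(sub$absorbance, fl$S0, tol = mcr_tol,
                max_iter = mcr_max_iter, unimodal = unimodal,
                order = "elution")
  list(fit = sfit, flanks = fl, mcr = mcr, window = c(t_start, t_end),
       wavelength = sub$wavelength)
}

resolve_region <- function(chrom, channel, region_peaks, model, library,
                           config, region_id) {
  n_apex <- nrow(region_peaks)
  win <- c(max(min(region_peaks$rise_time_10pct) - config$window_pad,
               min(chrom$time)),
           min(max(region_peaks$trail_time_10pct) + config$window_pad,
               max(chrom$time)))
  diag <- tryCatch(
    rt_consistency_diagnostic(chrom, win, n_apex,
                              channel_centers = config$rt_channels,
                              tol_factor = config$rt_tol_factor),
    error = function(e) list(flagged = FALSE))
  congested <- n_apex > 1 || isTRUE(diag$flagged)
  log <- sprintf("region %d: %.2f-%.2f min, %d apex(es), rt-flag=%s",
                 region_id, win[1], win[2], n_apex, isTRUE(diag$flagged))
  if (!congested) {
    sp <- chrom_row_spectrum(chrom, region_peaks$apex_time[1])
    cls <- classify_spectrum(model, sp, tiebreak_library = library)
    return(list(
      rows = tibble(retention_time = region_peaks$apex_time,
                    apex_absorbance = region_peaks$apex_absorbance,
                    start = region_peaks$rise_time_10pct,
                    end = region_peaks$trail_time_10pct,
                    species = cls$final_label,
                    posterior = cls$candidates$posterior[1],
                    r2 = cls$r2_to_final, frechet = cls$frechet_to_final,
                    deconvolved = FALSE, note = ""),
      spectra = list(sp), log = log))
  }
  # congested region: count species, fit the shared-Rt elution model,
  # initialise from the flanks, deconvolve by MCR, classify each component
  kres <- count_species(chrom, win[1], win[2], k_max = config$k_max,
                        n_restarts = config$n_restarts,
                        seed = derive_seed(config$seed, region_id))
  k <- max(kres$k, n_apex)
  if (isTRUE(diag$flagged) && k <= n_apex) k <- n_apex + 1L
  sigma0 <- median((region_peaks$trail_time_10pct -
                      region_peaks$rise_time_10pct) / (2 * TEN_PCT_HALF_WIDTH))
  # initial Rts from the cluster time centroids: each cluster of window
  # spectra dwells around one species' elution
  rt0 <- if (length(kres$cluster_times) == k) {
    as.numeric(kres$cluster_times)
  } else {
    NULL
  }
  dec <- deconvolve_window(chrom, win[1], win[2], k, rt_init = rt0,
                           sigma_init = sigma0,
                           channels = config$rt_channels,
                           mcr_tol = config$mcr_tol,
                           mcr_max_iter = config$mcr_max_iter,
                           detect_channel = config$channel_center)
  sfit <- dec$fit
  mcr <- dec$mcr
  sub <- crop_time(chrom, win[1], win[2])
  log <- c(log, sprintf(
    "region %d: k_elbow=%d -> k=%d, shared Rt [%s], MCR lof %.3g%% (%d it)",
    region_id, kres$k, k,
    paste(sprintf("%.3f", sfit$components$rt), collapse = ", "),
    tail(mcr$residual_history, 1), mcr$iterations))
  rows <- list()
  spectra <- list()
  for (j in seq_len(k)) {
    sp <- ref_spectrum(sprintf("region%d_component%d", region_id, j),
                       sub$wavelength, pmax(mcr$S[, j], 0),
                       source = "measured")
    cls <- classify_spectrum(model, sp, tiebreak_library = library)
    rt_j <- sfit$components$rt[j]
    sg_j <- sfit$components$sigma[j]
    rows[[j]] <- tibble(
      retention_time = rt_j,
      apex_absorbance = approx(channel$time, channel$absorbance,
                               xout = rt_j, rule = 2)$y,
      start = rt_j - sg_j * TEN_PCT_HALF_WIDTH,
      end = rt_j + sg_j * TEN_PCT_HALF_WIDTH,
      species = cls$final_label, posterior = cls$candidates$posterior[1],
      r2 = cls$r2_to_final, frechet = cls$frechet_to_final,
      deconvolved = TRUE, note = "")
    spectra[[j]] <- sp
  }
  list(rows = dplyr::bind_rows(rows), spectra = spectra, log = log)
}

#' Run the full unsupervised pipeline
#'
#' End-to-end analysis of a full-spectrum chromatogram: (1) detect peaks on
#' the configured detection channel; (2) group peaks whose 10%-of-apex
#' extents overlap into regions; (3) for each region, run the
#' retention-time-consistency diagnostic and, when the region is congested
#' (multiple overlapping apexes, or a single apex whose fitted Rt drifts
#' with wavelength), estimate the species count by PCA + K-means elbow, fit
#' the shared-Rt Gaussian elution model, initialise spectra from the peak
#' flanks and deconvolve by MCR-AR; otherwise take the apex-time spectrum
#' directly; (4) classify every recovered spectrum with the fingerprint
#' model. A failed region is marked `"unresolved"`; the pipeline always
#' completes.
#'
#' @param chrom A [spectral_chromatogram()].
#' @param model A `fingerprint_model`.
#' @param library Reference library for the tiebreak (defaults to the
#'   model's training library).
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list with `peak_table` (tibble, one row per
#'   resolved species), `spectra` (list of recovered [ref_spectrum()]s,
#'   aligned with the rows), `log` (character).
#' @export
run_pipeline <- function(chrom, model, library = model$library,
                         config = pipeline_config()) {
  stopifnot(inherits(chrom, "spectral_chromatogram"),
            inherits(model, "fingerprint_model"))
  channel <- extract_channel(chrom, config$channel_center, config$channel_hw)
  peaks <- detect_peaks(channel, config$min_snr, config$min_separation)
  regions <- group_peak_regions(peaks)
  log <- sprintf("detected %d peak(s) in %d region(s) at %g +/- %g nm",
                 nrow(peaks), length(regions), config$channel_center,
                 config$channel_hw)
  out_rows <- list()
  out_spectra <- list()
  for (g in seq_along(regions)) {
    res <- tryCatch(
      resolve_region(chrom, channel, regions[[g]], model, library, config, g),
      error = function(e) {
        list(rows = unresolved_rows(regions[[g]], conditionMessage(e)),
             spectra = rep(list(NULL), nrow(regions[[g]])),
             log = sprintf("region %d: FAILED (%s)", g, conditionMessage(e)))
      })
    out_rows[[g]] <- res$rows
    out_spectra <- c(out_spectra, res$spectra)
    log <- c(log, res$log)
  }
  tab <- dplyr::bind_rows(out_rows)
  if (nrow(tab)) {
    o <- order(tab$retention_time)
    tab <- tab[o, ]
    out_spectra <- out_spectra[o]
    tab <- dplyr::mutate(tab, peak_id = dplyr::row_number(), .before = 1)
  } else {
    tab <- dplyr::mutate(tab, peak_id = integer(), .before = 1)
  }
  structure(list(peak_table = tab, spectra = out_spectra, log = log,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d annotated peak(s), %d deconvolved\n",
              nrow(x$peak_table), sum(x$peak_table$deconvolved)))
  print(x$peak_table)
  invisible(x)
}

#' @export
tidy.pipeline_result <- function(x, ...) x$peak_table

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(n_peaks = nrow(x$peak_table),
         n_deconvolved = sum(x$peak_table$deconvolved),
         n_unresolved = sum(x$peak_table$species == "unresolved"))
}
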