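# fixtures and independent oracles used across the suite

# brute-force discrete Fréchet distance: direct recursion over all monotone
# couplings (exponential; curves of length <= 10 only)
frechet_bruteforce <- function(x1, y1, x2, y2) {
  d <- function(i, j) sqrt((x1[i] - x2[j])^2 + (y1[i] - y2[j])^2)
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 1 && j == 1) {
      d(1, 1)
    } else if (i == 1) {
      max(rec(1, j - 1), d(1, j))
    } else if (j == 1) {
      max(rec(i - 1, 1), d(i, 1))
    } else {
      max(min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1)), d(i, j))
    }
    memo[[key]] <- v
    v
  }
  rec(length(x1), length(x2))
}

# single noise-free Gaussian channel trace
gaussian_channel <- function(rt = 5, sigma = 0.1, amp = 1,
                             t = seq(4, 6, by = 0.002)) {
  chrom <- spectral_chromatogram(
    t, c(229, 230, 231),
    matrix(rep(amp * exp(-(t - rt)^2 / (2 * sigma^2)), 3), ncol = 3))
  extract_channel(chrom, 230, 1)
}

# tiny deterministic chromatogram for I/O tests
tiny_chrom <- function(seed = 42, n_t = 6, n_wl = 5) {
  withr::with_seed(seed, {
    spectral_chromatogram(
      time = sort(runif(n_t, 0, 10)),
      wavelength = sort(runif(n_wl, 200, 450)),
      absorbance = matrix(runif(n_t * n_wl), n_t, n_wl))
  })
}

# library with replicate spectra built from a scenario's base species, so a
# fingerprint model can be trained for the simulated runs
scenario_training_library <- function(scn, replicates = 3, noise_sd = 0.01,
                                      seed = 1000) {
  entries <- withr::with_seed(seed, {
    unlist(lapply(scn$library$entries, function(b) {
      lapply(seq_len(replicates), function(r) {
        ref_spectrum(b$species, b$wavelength,
                     b$absorbance + rnorm(length(b$absorbance), 0, noise_sd),
                     source = "synthetic")
      })
    }), recursive = FALSE)
  })
  spectral_library(entries)
}

# run the hidden-peak deconvolution chain on a three-species scenario and
# report recovery statistics for the middle (hidden) species
recover_hidden <- function(scn) {
  dec <- deconvolve_window(scn$chrom, 5, 7, 3, sigma_init = 0.1)
  sub <- crop_time(scn$chrom, 5, 7)
  i_rt <- which.min(abs(sub$time - dec$fit$components$rt[2]))
  list(S = dec$mcr$S,
       post_r2 = cor(dec$mcr$S[, 2], scn$truth$S[, 2])^2,
       pre_r2 = cor(sub$absorbance[i_rt, ], scn$truth$S[, 2])^2,
       fit = dec$fit)
}
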