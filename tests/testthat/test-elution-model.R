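test_that("a single Gaussian peak is recovered to machine-level accuracy", {
  ch <- gaussian_channel(rt = 5.2, sigma = 0.08, amp = 0.7)
  fit <- fit_gaussian_sum(ch, 1)
  expect_true(fit$converged)
  expect_equal(fit$components$rt, 5.2, tolerance = 1e-6)
  expect_equal(fit$components$sigma, 0.08, tolerance = 1e-6)
  expect_equal(fit$components$amplitude, 0.7, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-9)
})

test_that("single-peak fits agree with a brute-force grid-search oracle", {
  ch <- gaussian_channel(rt = 4.73, sigma = 0.11, amp = 0.5)
  y <- ch$absorbance
  rt_grid <- seq(4.5, 5.0, by = 0.01)
  sg_grid <- seq(0.05, 0.2, by = 0.005)
  sse <- outer(rt_grid, sg_grid, Vectorize(function(rt, sg) {
    g <- exp(-(ch$time - rt)^2 / (2 * sg^2))
    a <- sum(g * y) / sum(g * g)   # amplitude solved in closed form
    sum((y - a * g)^2)
  }))
  best <- which(sse == min(sse), arr.ind = TRUE)
  fit <- fit_gaussian_sum(ch, 1)
  expect_lt(abs(fit$components$rt - rt_grid[best[1]]), 0.01)
  expect_lt(abs(fit$components$sigma - sg_grid[best[2]]), 0.005)
})

test_that("two overlapping Gaussians are resolved at 1% apex noise", {
  t <- seq(3, 7, by = 0.005)
  errs <- vapply(1:20, function(r) {
    y <- withr::with_seed(100 + r, {
      exp(-(t - 4.8)^2 / (2 * 0.1^2)) + exp(-(t - 5.0)^2 / (2 * 0.1^2)) +
        rnorm(length(t), 0, 0.01)
    })
    chrom <- spectral_chromatogram(t, c(229, 230, 231),
                                   matrix(rep(y, 3), ncol = 3))
    fit <- fit_gaussian_sum(extract_channel(chrom, 230, 1), 2)
    max(abs(fit$components$rt - c(4.8, 5.0)))
  }, numeric(1))
  # mean error within 0.02 sigma; single-replicate extremes sit at the
  # information-limited floor for this sampling density
  expect_lt(mean(errs), 0.02 * 0.1)
  expect_lt(max(errs), 0.06 * 0.1)
})

test_that("single-channel goodness of fit cannot expose the hidden peak", {
  # at 1.2-sigma spacing an underspecified k = 2 fit matches one channel
  # to within the noise - residual inspection alone cannot reject it,
  # which is precisely why the multi-wavelength Rt-consistency diagnostic
  # exists (tested below)
  scn <- hidden_peak_scenario(1, "three")
  ch <- extract_channel(crop_time(scn$chrom, 5, 7), 230, 2)
  noise <- attr(detect_peaks(ch), "noise_sd")
  fit2 <- fit_gaussian_sum(ch, 2)
  expect_lt(fit2$residual_rms, 2 * noise)
  # nested models: adding a component never increases the residual
  fit3 <- fit_gaussian_sum(ch, 3)
  expect_lte(fit3$residual_rms, fit2$residual_rms + 1e-12)
})

test_that("rt consistency flags hidden species and spares clean windows", {
  scn <- hidden_peak_scenario(1, "three")
  # window as the pipeline would set it: the composite peak's 10% extent
  d2 <- rt_consistency_diagnostic(scn$chrom, c(5.4, 6.6), 2)
  expect_true(d2$flagged)  # leading-peak Rt drifts with wavelength at k = 2
  # noise-free single species at true k: negligible spread
  lib <- make_library(2, 1, noise_sd = 0, seed = 3)
  spec1 <- tibble::tibble(label = species_labels(lib)[1], rt = 2,
                          sigma = 0.1, amount = 1)
  chrom <- simulate_chromatogram(
    sim_config(c(210, 460, 2), c(1, 3, 0.005), spec1, noise_sd = 0), lib)
  d1 <- rt_consistency_diagnostic(chrom, c(1.5, 2.5), 1)
  expect_false(d1$flagged)
  expect_lt(max(d1$spread), 1e-6)
  # spread is invariant to rescaling the channel amplitudes
  chrom5 <- chrom
  chrom5$absorbance <- chrom5$absorbance * 5
  d5 <- rt_consistency_diagnostic(chrom5, c(1.5, 2.5), 1)
  expect_equal(d5$spread, d1$spread, tolerance = 1e-8)
})

test_that("shared-Rt fitting recovers the elution model and spectra", {
  scn0 <- hidden_peak_scenario(1, "three")
  layout <- scn0$truth$species
  quiet <- simulate_chromatogram(
    sim_config(c(190, 500, 1), c(4.5, 7.5, 0.2 / 60), layout, noise_sd = 0),
    scn0$library)
  fit <- fit_shared_rt(quiet, c(5, 7), 3, rt_init = c(5.7, 6.0, 6.3),
                       sigma_init = 0.12)
  expect_equal(fit$components$rt, layout$rt, tolerance = 0.01 * 0.15)
  expect_equal(fit$components$sigma, rep(0.15, 3), tolerance = 0.01)
  # unit-area concentration columns: C_j / max-amplitude integrates to 1
  for (j in 1:3) {
    expect_equal(pracma::trapz(fit$time, fit$C[, j] /
                                 fit$components$amplitude[j]), 1,
                 tolerance = 1e-6)
  }
  expect_error(fit_shared_rt(quiet, c(5, 7), 3, rt_init = c(5.7, 6.0)),
               "length")
})

test_that("amplitude spectra of an isolated species match its true spectrum", {
  lib <- make_library(2, 1, noise_sd = 0, seed = 21)
  layout <- tibble::tibble(label = species_labels(lib), rt = c(2, 3),
                           sigma = 0.1, amount = 1)
  chrom <- simulate_chromatogram(
    sim_config(c(190, 500, 1), c(1.5, 3.5, 0.005), layout, noise_sd = 0), lib)
  fit <- fit_shared_rt(chrom, c(1.6, 3.4), 2, rt_init = c(2, 3),
                       sigma_init = 0.1)
  truth <- chrom$meta$truth
  for (j in 1:2) expect_gte(cor(fit$S[, j], truth$S[, j])^2, 0.999)
  # freezing Rt/sigma and refitting amplitudes by NNLS never loses to the
  # stage-one amplitudes on the fitting channels
  for (ci in seq_along(fit$channels)) {
    ch <- extract_channel(crop_time(chrom, 1.6, 3.4), fit$channels[ci], 2)
    y <- ch$absorbance - chromaspec:::baseline_level(ch$absorbance)
    G <- vapply(1:2, function(j) {
      exp(-(fit$time - fit$components$rt[j])^2 /
            (2 * fit$components$sigma[j]^2))
    }, numeric(length(fit$time)))
    stage1 <- sum((y - G %*% fit$channel_amplitudes[, ci])^2)
    refit <- nnls_multi(G, cbind(y))
    expect_lte(sum((y - G %*% refit)^2), stage1 + 1e-10)
  }
})

test_that("flank spectra follow the 10% rule and bracket the interior", {
  scn <- hidden_peak_scenario(2, "three")
  dec <- deconvolve_window(scn$chrom, 5, 7, 3, sigma_init = 0.1)
  fl <- dec$flanks
  expect_true(all(diff(fl$times) > 0))  # rising < interior Rt < trailing
  comp <- dec$fit$components
  expect_equal(fl$times[1],
               comp$rt[1] - comp$sigma[1] * sqrt(2 * log(10)),
               tolerance = 0.01)
  # rising-flank spectrum matches the first species best
  r2 <- vapply(1:3, function(j) cor(fl$S0[, 1], scn$truth$S[, j])^2,
               numeric(1))
  expect_identical(which.max(r2), 1L)
  # single species: both flank spectra match the species at 1% noise
  lib <- make_library(2, 1, noise_sd = 0, seed = 31)
  layout <- tibble::tibble(label = species_labels(lib)[1], rt = 2,
                           sigma = 0.1, amount = 1)
  quiet <- simulate_chromatogram(
    sim_config(c(190, 500, 1), c(1.5, 2.5, 0.005), layout, noise_sd = 0),
    lib)
  noisy <- simulate_chromatogram(
    sim_config(c(190, 500, 1), c(1.5, 2.5, 0.005), layout,
               noise_sd = 0.01 * max(quiet$absorbance), seed = 5), lib)
  fit1 <- fit_gaussian_sum(extract_channel(noisy, 230, 2), 1)
  fit1$window <- c(1.5, 2.5)
  fl1 <- flank_spectra(noisy, fit1)
  truth_s <- quiet$meta$truth$S[, 1]
  expect_gte(cor(fl1$S0[, 1], truth_s)^2, 0.99)
})
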