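test_that("synthetic spectra are deterministic, banded and distinct", {
  a <- make_synthetic_spectrum("x", n_bands = 1, seed = 5)
  b <- make_synthetic_spectrum("x", n_bands = 1, seed = 5)
  expect_identical(a$absorbance, b$absorbance)
  expect_equal(max(a$absorbance), 1)
  expect_true(all(a$absorbance >= 0))
  # single band: exactly one interior local maximum
  y <- a$absorbance
  n_max <- sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] > y[3:length(y)])
  expect_identical(n_max, 1L)
  expect_error(make_synthetic_spectrum("x", n_bands = 0, seed = 1), "n_bands")
  # 24 distinct seeds give mutually dissimilar fingerprints
  S <- vapply(0:23, function(s) {
    make_synthetic_spectrum(paste0("s", s), 3, seed = s)$absorbance
  }, numeric(length(a$absorbance)))
  r2 <- cor(S)^2
  expect_gte(mean(r2[upper.tri(r2)] < 0.95), 0.95)
})

test_that("library generation is structured and reproducible", {
  lib <- make_library(n_species = 24, replicates_per_species = 3, seed = 2)
  expect_length(lib$entries, 72)
  expect_length(species_labels(lib), 24)
  lib2 <- make_library(n_species = 24, replicates_per_species = 3, seed = 2)
  expect_equal(lib$entries[[10]]$absorbance, lib2$entries[[10]]$absorbance)
  # zero noise: replicates equal the base up to the small wavelength shift
  quiet <- make_library(n_species = 3, replicates_per_species = 2,
                        noise_sd = 0, seed = 7)
  r1 <- quiet$entries[[1]]$absorbance
  r2 <- quiet$entries[[2]]$absorbance
  expect_gt(cor(r1, r2), 0.99)
  # changing only replicate_seed keeps the species spectra
  q <- make_library(n_species = 3, replicates_per_species = 1,
                    noise_sd = 0.01, seed = 7, replicate_seed = 99)
  expect_gt(cor(q$entries[[1]]$absorbance, r1), 0.98)
})

test_that("simulated chromatograms follow the bilinear mixing model", {
  lib <- make_library(n_species = 3, replicates_per_species = 1,
                      noise_sd = 0, seed = 11)
  species <- tibble::tibble(label = species_labels(lib),
                            rt = c(2, 3, 4), sigma = 0.1,
                            amount = c(1, 0.5, 2))
  grid <- list(wl = c(200, 460, 2), t = c(1, 5, 0.005))
  cfg <- sim_config(grid$wl, grid$t, species, noise_sd = 0, seed = 1)
  chrom <- simulate_chromatogram(cfg, lib)
  truth <- chrom$meta$truth
  expect_equal(chrom$absorbance, truth$C %*% t(truth$S), tolerance = 1e-12)
  # all-zero amounts give the zero matrix
  cfg0 <- sim_config(grid$wl, grid$t,
                     dplyr::mutate(species, amount = 0), noise_sd = 0,
                     seed = 1)
  expect_equal(max(abs(simulate_chromatogram(cfg0, lib)$absorbance)), 0)
  # bilinearity: doubling one amount doubles that contribution exactly
  cfg2 <- sim_config(grid$wl, grid$t,
                     dplyr::mutate(species,
                                   amount = amount * c(2, 1, 1)),
                     noise_sd = 0, seed = 1)
  chrom2 <- simulate_chromatogram(cfg2, lib)
  delta <- chrom2$absorbance - chrom$absorbance
  expect_equal(delta, truth$C[, 1, drop = FALSE] %*%
                 t(truth$S[, 1, drop = FALSE]), tolerance = 1e-12)
  # channel peak areas are proportional to amounts (trapezoid)
  area <- function(ch) pracma::trapz(ch$time, ch$absorbance)
  # pick a wavelength where all three species absorb
  wl_all <- chrom$wavelength[which.max(apply(truth$S > 0.05, 1, sum))]
  a1 <- area(extract_channel(chrom, wl_all, 0))
  a2 <- area(extract_channel(chrom2, wl_all, 0))
  s1 <- truth$S[which.min(abs(chrom$wavelength - wl_all)), 1]
  expect_equal(a2 - a1, species$amount[1] * s1, tolerance = 1e-6)
  expect_error(simulate_chromatogram(
    sim_config(grid$wl, grid$t,
               dplyr::mutate(species, label = c("nope", label[2:3]))),
    lib), "nope")
})

test_that("single-species channels are Gaussians at the configured Rt", {
  lib <- make_library(n_species = 2, replicates_per_species = 1,
                      noise_sd = 0, seed = 13)
  species <- tibble::tibble(label = species_labels(lib)[1], rt = 3,
                            sigma = 0.12, amount = 1)
  chrom <- simulate_chromatogram(
    sim_config(c(210, 400, 5), c(2, 4, 0.005), species, noise_sd = 0), lib)
  rts <- vapply(seq(220, 380, by = 40), function(cw) {
    ch <- extract_channel(chrom, cw, 2)
    if (max(ch$absorbance) < 1e-6) return(NA_real_)
    fit_gaussian_sum(ch, 1)$components$rt
  }, numeric(1))
  rts <- rts[!is.na(rts)]
  expect_gte(length(rts), 3)
  expect_lt(max(rts) - min(rts), 1e-6)
  expect_lt(max(abs(rts - 3)), 1e-6)
})

test_that("hidden-peak scenarios match their stated geometry", {
  scn <- hidden_peak_scenario(1, "three")
  expect_identical(length(scn$truth$labels), 3L)
  frac_mid <- scn$truth$C[, 2] / rowSums(scn$truth$C)
  expect_lt(max(frac_mid, na.rm = TRUE), 0.9)
  scn5 <- hidden_peak_scenario(1, "five")
  expect_identical(length(scn5$truth$labels), 5L)
  # replicate runs share the truth but not the noise
  rep2 <- hidden_peak_scenario(1, "three", noise_seed = 2)
  expect_equal(rep2$truth$S, scn$truth$S)
  expect_false(identical(rep2$chrom$absorbance, scn$chrom$absorbance))
})
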