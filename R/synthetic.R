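#' Simulation configuration for synthetic chromatograms
#'
#' Defines the grids and species layout for [simulate_chromatogram()]. The
#' full detector grid spans 180-890 nm at 0.217 nm optical resolution; the
#' analysis functions are grid-agnostic, and coarser desk-scale grids
#' (delta-lambda 1 nm, delta-t 0.2 s) are used throughout the examples and
#' tests for speed.
#'
#' @param wavelength `c(start, stop, step)` in nm.
#' @param time `c(start, stop, step)` in minutes.
#' @param species Tibble with columns `label`, `rt` (min), `sigma` (min),
#'   `amount` (AU * min). Elution profiles are unit-area Gaussians so `amount`
#'   is the integrated peak area at each species' strongest wavelength.
#' @param noise_sd Additive iid Gaussian noise sd in AU.
#' @param baseline_drift Linear baseline drift in AU per minute, constant
#'   across wavelength.
#' @param seed Integer seed controlling the noise draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(wavelength = c(180, 890, 0.217),
                       time = c(0, 10, 0.2 / 60),
                       species = tibble(label = character(), rt = numeric(),
                                        sigma = numeric(), amount = numeric()),
                       noise_sd = 0, baseline_drift = 0, seed = 1L) {
  stopifnot(length(wavelength) == 3, length(time) == 3)
  if (wavelength[3] <= 0 || time[3] <= 0) abort("grid steps must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  species <- as_tibble(species)
  if (nrow(species) && any(species$sigma <= 0)) abort("`sigma` must be > 0")
  structure(list(wavelength = wavelength, time = time, species = species,
                 noise_sd = noise_sd, baseline_drift = baseline_drift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_axis <- function(g) seq(g[1], g[2], by = g[3])

#' Generate a synthetic reference spectrum
#'
#' Builds a non-negative absorption spectrum as a sum of Gaussian bands with
#' centres drawn in 200-450 nm (the region where polycyclic aromatics
#' absorb most strongly) and widths in 3-20 nm, unit-max normalised. The
#' first band is a broad short-wavelength transition (centre 215-245 nm,
#' width 8-15 nm, relative height 0.3-0.7): every aromatic chromophore
#' carries one, which is what makes a 230 nm detection channel universal,
#' while the narrower long-wavelength bands carry the species-specific
#' fingerprint. Deterministic for a fixed seed.
#'
#' @param label Species label.
#' @param n_bands Number of absorption bands (>= 1).
#' @param seed Integer seed.
#' @param wavelength Wavelength grid in nm for the stored curve.
#' @return A [ref_spectrum()] with `source = "synthetic"`.
#' @examples
#' sp <- make_synthetic_spectrum("chrysene-like", n_bands = 3, seed = 7)
#' max(sp$absorbance)
#' @export
make_synthetic_spectrum <- function(label, n_bands = 3L, seed = 1L,
                                    wavelength = seq(190, 500, by = 0.5)) {
  if (n_bands < 1) abort("`n_bands` must be >= 1")
  withr::with_seed(as.integer(seed), {
    centre <- c(runif(1, 215, 245),
                if (n_bands > 1) runif(n_bands - 1, 200, 450))
    width <- c(runif(1, 8, 15),
               if (n_bands > 1) runif(n_bands - 1, 3, 20))
    height <- c(runif(1, 0.3, 0.7),
                if (n_bands > 1) runif(n_bands - 1, 0.3, 1))
    y <- rowSums(vapply(seq_len(n_bands), function(j) {
      height[j] * exp(-(wavelength - centre[j])^2 / (2 * width[j]^2))
    }, numeric(length(wavelength))))
    ref_spectrum(label, wavelength, y / max(y), source = "synthetic")
  })
}

# shared per-species base spectra; make_library replicates these and the
# chromatogram scenarios elute them, so a model trained on the library
# applies to the simulated runs
base_spectra <- function(n_species, seed, n_bands_range = c(2L, 5L),
                         wavelength = seq(190, 500, by = 0.5)) {
  purrr::map(seq_len(n_species), function(i) {
    nb <- withr::with_seed(derive_seed(seed, i), {
      sample(seq(n_bands_range[1], n_bands_range[2]), 1)
    })
    make_synthetic_spectrum(sprintf("sp%02d", i), n_bands = nb,
                            seed = derive_seed(seed, i),
                            wavelength = wavelength)
  })
}

#' Generate a synthetic reference library
#'
#' Emulates a multi-source library: each species has a base synthetic
#' spectrum and `replicates_per_species` noisy copies with small random
#' wavelength shifts (at most `shift_max` nm), as arises when reference
#' spectra are digitised from different instruments.
#'
#' @param n_species Number of distinct species (>= 2).
#' @param replicates_per_species Spectra per species.
#' @param noise_sd Additive noise sd on the unit-max spectra.
#' @param seed Integer seed for the per-species base spectra.
#' @param replicate_seed Integer seed for the replicate noise and shifts
#'   (defaults to `seed`); fresh query spectra of the *same* species are
#'   obtained by changing `replicate_seed` only.
#' @param shift_max Maximum absolute wavelength shift per replicate, nm.
#' @param n_bands_range Range of per-species band counts.
#' @param wavelength Stored wavelength grid.
#' @return A [spectral_library()] with `n_species * replicates_per_species`
#'   entries.
#' @export
make_library <- function(n_species = 24L, replicates_per_species = 3L,
                         noise_sd = 0.01, seed = 1L, replicate_seed = seed,
                         shift_max = 0.5, n_bands_range = c(2L, 5L),
                         wavelength = seq(190, 500, by = 0.5)) {
  if (n_species < 2) abort("`n_species` must be >= 2")
  bases <- base_spectra(n_species, seed, n_bands_range, wavelength)
  entries <- withr::with_seed(as.integer(replicate_seed), {
    purrr::flatten(purrr::map(bases, function(b) {
      purrr::map(seq_len(replicates_per_species), function(r) {
        shift <- runif(1, -shift_max, shift_max)
        y <- approx(b$wavelength + shift, b$absorbance, xout = b$wavelength,
                    rule = 2)$y
        if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
        ref_spectrum(b$species, b$wavelength, y, source = "synthetic")
      })
    }))
  })
  spectral_library(entries)
}

#' Simulate a full-spectrum chromatogram
#'
#' Implements the bilinear Beer-Lambert mixing model `A = C S^T + baseline +
#' noise`: column j of C is `amount_j` times a unit-area Gaussian elution
#' profile centred at `rt_j` with width `sigma_j`, and column j of S is that
#' species' library spectrum resampled onto the configured wavelength grid
#' (zero outside its support).
#'
#' @param config A [sim_config()].
#' @param library A [spectral_library()] containing every configured label.
#' @return A [spectral_chromatogram()]; the generating C and S matrices are
#'   attached in `meta$truth`.
#' @export
simulate_chromatogram <- function(config, library) {
  stopifnot(inherits(config, "sim_config"),
            inherits(library, "spectral_library"))
  tm <- sim_axis(config$time)
  wl <- sim_axis(config$wavelength)
  sp <- config$species
  lib_labels <- vapply(library$entries, `[[`, character(1), "species")
  unknown <- setdiff(sp$label, lib_labels)
  if (length(unknown)) {
    abort(sprintf("species not in library: %s", paste(unknown, collapse = ", ")))
  }
  k <- nrow(sp)
  C <- matrix(0, length(tm), max(k, 1))
  S <- matrix(0, length(wl), max(k, 1))
  for (j in seq_len(k)) {
    C[, j] <- sp$amount[j] * dnorm(tm, sp$rt[j], sp$sigma[j])
    entry <- library$entries[[match(sp$label[j], lib_labels)]]
    S[, j] <- approx(entry$wavelength, entry$absorbance, xout = wl,
                     yleft = 0, yright = 0)$y
  }
  A <- C %*% t(S)
  A <- A + config$baseline_drift * (tm - tm[1])  # recycled down columns
  if (config$noise_sd > 0) {
    A <- A + withr::with_seed(config$seed,
      matrix(rnorm(length(A), 0, config$noise_sd), nrow(A)))
  }
  spectral_chromatogram(tm, wl, A,
    meta = list(simulated = TRUE, config = config,
                truth = list(C = C[, seq_len(k), drop = FALSE],
                             S = S[, seq_len(k), drop = FALSE],
                             labels = sp$label)))
}

#' Canonical hidden-peak test scenarios
#'
#' Generates the two congested-elution study conditions used throughout the
#' package, together with their ground truth:
#'
#' * `"three"` - three species whose retention times are spaced at 1.2 sigma
#'   so the middle species never produces an apex of its own nor a spectrally
#'   pure time point (a fully hidden peak flanked by two neighbours).
#' * `"five"` - five species in a 2.2 min window, two of them nearly
#'   coincident (delta-Rt = 0.05 min = 0.5 sigma, an unresolvable single
#'   apex) and three further peaks overlapping at the few-percent level.
#'
#' Noise is 1% of the noiseless surface maximum; grids are desk-scale
#' (delta-lambda 1 nm, delta-t 0.2 s).
#'
#' @param seed Integer seed for the species spectra.
#' @param variant `"three"` or `"five"`.
#' @param noise_seed Integer seed for the measurement noise (defaults to
#'   `seed`); replicate chromatographic runs of the same mixture are
#'   obtained by changing `noise_seed` only.
#' @return A list with elements `chrom` ([spectral_chromatogram()]), `truth`
#'   (list with `C`, `S`, `labels`, `species` layout tibble) and `library`
#'   (the generating [spectral_library()]).
#' @export
hidden_peak_scenario <- function(seed = 1L, variant = c("three", "five"),
                                 noise_seed = seed) {
  variant <- match.arg(variant)
  layout <- if (variant == "three") {
    tibble(label = c("flankA", "hiddenB", "flankC"),
           rt = c(5.82, 6.0, 6.18), sigma = 0.15,
           amount = c(1.0, 0.65, 1.0))
  } else {
    tibble(label = sprintf("pk%d", 1:5),
           rt = c(8.2, 8.695, 8.745, 9.3, 9.95), sigma = 0.10,
           amount = c(1.0, 1.0, 1.0, 1.0, 1.0))
  }
  time <- if (variant == "three") c(4.5, 7.5, 0.2 / 60) else c(7.5, 10.7, 0.2 / 60)
  entries <- purrr::imap(layout$label, function(lab, i) {
    make_synthetic_spectrum(lab, n_bands = 3 + (i %% 3),
                            seed = derive_seed(seed, 17 + i))
  })
  lib <- spectral_library(entries)
  cfg0 <- sim_config(wavelength = c(190, 500, 1), time = time,
                     species = layout, noise_sd = 0, seed = seed)
  noiseless <- simulate_chromatogram(cfg0, lib)
  cfg <- sim_config(wavelength = c(190, 500, 1), time = time,
                    species = layout,
                    noise_sd = 0.01 * max(noiseless$absorbance),
                    seed = noise_seed)
  chrom <- simulate_chromatogram(cfg, lib)
  truth <- chrom$meta$truth
  truth$species <- layout
  list(chrom = chrom, truth = truth, library = lib)
}

#' Full multi-species separation scenario
#'
#' Simulates a complete 24-component separation emulating a priority-
#' pollutant panel run: `n_species - 5` well-resolved single peaks, one
#' hidden triplet (spacing 1.2 sigma, middle species with no apex of its
#' own) and one nearly coincident pair (gap 0.05 min = 0.5 sigma, a single
#' apex), with 1% noise. The species' base spectra are shared with
#' [make_library()] at the same seed, so a fingerprint model trained on
#' that library applies directly to the simulated run.
#'
#' @param seed Integer seed.
#' @param n_species Panel size (default 24; must be >= 6).
#' @return A list with `chrom`, `truth` (including the layout tibble) and
#'   `library` (the base spectra as a [spectral_library()]).
#' @export
multi_species_scenario <- function(seed = 1L, n_species = 24L) {
  if (n_species < 6) abort("`n_species` must be >= 6")
  n_single <- n_species - 5L
  layout <- tibble(
    label = sprintf("sp%02d", seq_len(n_species)),
    rt = c(seq(1.0, by = 0.5, length.out = n_single),          # singles
           11.0, 11.18, 11.36,                                  # hidden triplet
           12.2, 12.25),                                        # coincident pair
    sigma = c(rep(0.08, n_single), rep(0.15, 3), rep(0.10, 2)),
    amount = c(rep(1.0, n_single), 1.0, 0.65, 1.0, 1.0, 1.0))
  bases <- base_spectra(n_species, seed)
  lib <- spectral_library(bases)
  time <- c(0.5, 12.9, 0.2 / 60)
  cfg0 <- sim_config(wavelength = c(190, 500, 1), time = time,
                     species = layout, noise_sd = 0, seed = seed)
  noiseless <- simulate_chromatogram(cfg0, lib)
  cfg <- sim_config(wavelength = c(190, 500, 1), time = time,
                    species = layout,
                    noise_sd = 0.01 * max(noiseless$absorbance), seed = seed)
  chrom <- simulate_chromatogram(cfg, lib)
  truth <- chrom$meta$truth
  truth$species <- layout
  list(chrom = chrom, truth = truth, library = lib)
}
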