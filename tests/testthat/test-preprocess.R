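test_that("absorbance conversion matches Beer-Lambert arithmetic", {
  expect_equal(compute_absorbance(c(100, 50), c(100, 50)), c(0, 0))
  expect_equal(compute_absorbance(10, 100), 1)
  expect_equal(compute_absorbance(190, 1000, 100), 1)  # -log10(90/900)
  expect_equal(compute_absorbance(50, 1000, 100, a_max = 3), 3,
               tolerance = 1e-12, ignore_attr = TRUE)
  # saturated channel clips to a_max
  expect_equal(compute_absorbance(c(100, 0), c(1000, 1000), 10, a_max = 4)[2],
               4)
  expect_error(compute_absorbance(1, 5, 10), "blank")
})

test_that("grid resampling is linear inside support, missing outside", {
  sp <- ref_spectrum("ramp", seq(200, 450, by = 10),
                     seq(0, 2.5, length.out = 26))
  on_grid <- resample_to_grid(sp, sp$wavelength)
  expect_equal(on_grid$absorbance, sp$absorbance)
  fine <- resample_to_grid(sp, seq(205, 445, by = 1))
  expect_equal(fine$absorbance, (fine$wavelength - 200) / 100,
               tolerance = 1e-12)
  wide <- resample_to_grid(sp, seq(180, 890, by = 5))
  outside <- wide$wavelength < 200 | wide$wavelength > 450
  expect_true(all(is.na(wide$absorbance[outside])))
  expect_true(all(is.finite(wide$absorbance[!outside])))
  expect_error(resample_to_grid(sp, seq(500, 600, by = 1)), "overlap")
})

test_that("Savitzky-Golay smoothing is exact on low-degree polynomials", {
  x <- seq(200, 300, by = 0.5)
  for (deg in c(0, 2, 4, 5)) {
    y <- (x / 250 - 1)^deg
    expect_equal(savgol_smooth(y, grid_step = 0.5), y, tolerance = 1e-9)
  }
  # white noise is attenuated
  noise <- withr::with_seed(1, rnorm(length(x)))
  expect_lt(sd(savgol_smooth(noise, 0.5)), sd(noise))
  expect_error(savgol_smooth(rnorm(50), grid_step = 10), "too small")
  # NA run at the edges (missing support) is preserved
  y2 <- c(rep(NA, 20), (x / 250 - 1)^2, rep(NA, 10))
  sm <- savgol_smooth(y2, 0.5)
  expect_true(all(is.na(sm[1:20])))
  expect_equal(sm[21:(20 + length(x))], (x / 250 - 1)^2, tolerance = 1e-9)
})

test_that("first derivative cancels offsets and matches closed forms", {
  g <- seq(0, 10, by = 1)
  expect_equal(first_derivative(rep(3, 11), g), rep(0, 11))
  s <- sin(g)
  expect_equal(first_derivative(s, g), first_derivative(s + 0.3, g))
  q <- g^2
  d <- first_derivative(q, g)
  expect_equal(d[2:10], 2 * g[2:10], tolerance = 1e-9)
  expect_error(first_derivative(c(1, 2), c(0, 1)), "3")
  # smoothing then differentiating a degree-4 polynomial is analytic at
  # interior points
  x <- seq(200, 300, by = 0.5)
  p <- 2 + 0.01 * (x - 250) + 1e-4 * (x - 250)^3
  dp <- first_derivative(savgol_smooth(p, 0.5), x)
  # central differences carry O(h^2) truncation (~2.5e-5 here)
  expect_lt(max(abs(dp[10:190] - (0.01 + 3e-4 * (x[10:190] - 250)^2))),
            5e-5)
})

test_that("channel extraction averages the window and commutes with crops", {
  chrom <- tiny_chrom(9, n_t = 20, n_wl = 12)
  wl <- chrom$wavelength
  single <- extract_channel(chrom, wl[4], 0)
  expect_equal(single$absorbance, chrom$absorbance[, 4])
  # constant in wavelength -> channel equals the constant
  flat <- spectral_chromatogram(1:10, c(200, 210, 220),
                                matrix(2.5, 10, 3))
  expect_equal(extract_channel(flat, 210, 10)$absorbance, rep(2.5, 10))
  expect_error(extract_channel(chrom, 900, 1), "900")
  # commutes with time cropping
  cropped <- crop_time(chrom, chrom$time[5], chrom$time[15])
  a <- extract_channel(cropped, wl[6], 30)$absorbance
  b <- extract_channel(chrom, wl[6], 30)$absorbance[5:15]
  expect_equal(a, b)
})

test_that("peak detection matches the Gaussian 10% closed form", {
  ch <- gaussian_channel(rt = 5, sigma = 0.1)
  pk <- detect_peaks(ch)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$apex_time, 5, tolerance = 1e-3)
  half <- 0.1 * sqrt(2 * log(10))  # 0.2146 min
  expect_equal(pk$rise_time_10pct, 5 - half, tolerance = 2e-3)
  expect_equal(pk$trail_time_10pct, 5 + half, tolerance = 2e-3)
  expect_false(pk$edge_clipped)
  # flat trace -> nothing
  flat <- gaussian_channel(amp = 0)
  expect_identical(nrow(detect_peaks(flat)), 0L)
  # two Gaussians 10 sigma apart -> two peaks (brute-force maxima count)
  t <- seq(0, 4, by = 0.002)
  y <- exp(-(t - 1)^2 / (2 * 0.1^2)) + exp(-(t - 2)^2 / (2 * 0.1^2))
  chrom <- spectral_chromatogram(t, c(229, 230, 231),
                                 matrix(rep(y, 3), ncol = 3))
  pk2 <- detect_peaks(extract_channel(chrom, 230, 1))
  expect_identical(nrow(pk2), 2L)
  expect_equal(pk2$apex_time, c(1, 2), tolerance = 1e-3)
})

test_that("peak detection is invariant to a constant offset", {
  base <- gaussian_channel(rt = 5, sigma = 0.1)
  shifted <- base
  shifted$absorbance <- shifted$absorbance + 0.7
  p1 <- detect_peaks(base)
  p2 <- detect_peaks(shifted)
  expect_equal(p1$apex_time, p2$apex_time, tolerance = 1e-9)
  expect_equal(p1$rise_time_10pct, p2$rise_time_10pct, tolerance = 1e-6)
  expect_equal(p1$height, p2$height, tolerance = 1e-6)
})
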