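test_that("multi-RHS NNLS agrees with the reference single-RHS solver", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      A <- matrix(rnorm(10 * 4), 10, 4)
      B <- matrix(rnorm(10 * 6), 10, 6)
      X <- nnls_multi(A, B)
      expect_true(all(X >= 0))
      for (j in seq_len(ncol(B))) {
        ref <- pracma::lsqnonneg(A, B[, j])$x
        expect_equal(sum((A %*% X[, j] - B[, j])^2),
                     sum((A %*% ref - B[, j])^2), tolerance = 1e-8)
      }
    }
  })
})

test_that("curve resolution has a noise-free fixed point", {
  withr::with_seed(11, {
    t <- seq(0, 1, length.out = 60)
    C <- cbind(dnorm(t, 0.4, 0.1), dnorm(t, 0.6, 0.1))
    S <- cbind(exp(-(1:80 - 20)^2 / 50), exp(-(1:80 - 55)^2 / 80))
  })
  D <- C %*% t(S)
  res <- mcr_ar(D, S)
  expect_true(res$converged)
  expect_lte(res$iterations, 3)
  expect_lt(tail(res$residual_history, 1), 1e-6)
  expect_true(all(res$C >= 0) && all(res$S >= 0))
  expect_equal(unname(apply(res$S, 2, max)), c(1, 1))
  # permuting the initial spectra permutes the output identically
  res_p <- mcr_ar(D, S[, 2:1])
  expect_equal(res_p$S, res$S[, 2:1], tolerance = 1e-9)
  tinyD <- D[1:3, 1:5]
  expect_error(mcr_ar(tinyD, matrix(1, 5, 4)), "rank")
})

test_that("lack-of-fit decreases monotonically from rough starts", {
  withr::with_seed(13, {
    for (rep in 1:3) {
      t <- seq(0, 1, length.out = 50)
      C <- cbind(dnorm(t, 0.3, 0.12), dnorm(t, 0.55, 0.1),
                 dnorm(t, 0.7, 0.15))
      S <- matrix(runif(60 * 3), 60, 3)
      D <- C %*% t(S) + matrix(rnorm(50 * 60, 0, 0.02), 50, 60)
      S0 <- pmax(S + matrix(rnorm(60 * 3, 0, 0.3), 60, 3), 0)
      res <- mcr_ar(D, S0, max_iter = 100)
      expect_true(all(diff(res$residual_history) <= 1e-9))
    }
  })
})

test_that("the hidden species' spectrum is recovered from flank starts", {
  scn <- hidden_peak_scenario(1, "three")
  rec <- recover_hidden(scn)
  expect_gte(rec$post_r2, 0.96)
  expect_lt(rec$pre_r2, rec$post_r2)  # convolved apex spectrum is worse
})

test_that("unimodality projection clips secondary bumps and is idempotent", {
  v <- c(0, 2, 1, 3, 1, 2, 0)
  p <- unimodality_constraint(v)
  a <- which.max(p)
  expect_true(all(diff(p[1:a]) >= 0))          # exhaustive monotonicity
  expect_true(all(diff(p[a:length(p)]) <= 0))
  expect_identical(unimodality_constraint(p), p)
  mono <- c(0, 1, 3, 2, 0.5)
  expect_identical(unimodality_constraint(mono), mono)
})

test_that("discrete Fréchet distance equals the brute-force oracle", {
  expect_equal(frechet_distance(c(0, 0.5, 1), c(0, 1, 0),
                                c(0, 0.5, 1), c(0, 0.8, 0)), 0.2)
  withr::with_seed(17, {
    for (rep in 1:20) {
      n <- sample(2:10, 1); m <- sample(2:10, 1)
      x1 <- sort(runif(n)); y1 <- rnorm(n)
      x2 <- sort(runif(m)); y2 <- rnorm(m)
      expect_equal(frechet_distance(x1, y1, x2, y2),
                   frechet_bruteforce(x1, y1, x2, y2), tolerance = 1e-12)
    }
  })
})

test_that("discrete Fréchet satisfies the metric axioms", {
  withr::with_seed(19, {
    curves <- replicate(12, {
      n <- sample(3:8, 1)
      list(x = sort(runif(n)), y = rnorm(n))
    }, simplify = FALSE)
  })
  dist_ij <- function(a, b) frechet_distance(a$x, a$y, b$x, b$y)
  for (rep in 1:20) {
    ijk <- withr::with_seed(19 + rep, sample(12, 3))
    a <- curves[[ijk[1]]]; b <- curves[[ijk[2]]]; c3 <- curves[[ijk[3]]]
    expect_equal(dist_ij(a, b), dist_ij(b, a), tolerance = 1e-12)
    expect_lte(dist_ij(a, c3), dist_ij(a, b) + dist_ij(b, c3) + 1e-12)
  }
  a <- curves[[1]]
  expect_identical(dist_ij(a, a), 0)
  expect_gt(dist_ij(curves[[1]], curves[[2]]), 0)
})

test_that("spectrum comparison reports scale-free r2 and normalised shape", {
  sp <- make_synthetic_spectrum("a", 3, seed = 23)
  same <- compare_spectra(sp, sp)
  expect_equal(same$r2, 1)
  expect_equal(same$frechet, 0)
  doubled <- ref_spectrum("b", sp$wavelength, 2 * sp$absorbance)
  offset <- ref_spectrum("c", sp$wavelength, 2 * sp$absorbance + 0.1)
  expect_equal(compare_spectra(sp, doubled)$r2, 1)
  # pure rescaling vanishes under per-curve unit-max normalisation ...
  expect_equal(compare_spectra(sp, doubled)$frechet, 0, tolerance = 1e-12)
  # ... but a constant offset survives it (the baseline lifts)
  expect_equal(compare_spectra(sp, offset)$r2, 1)
  expect_gt(compare_spectra(sp, offset)$frechet, 0)
  short <- ref_spectrum("d", seq(200, 204, by = 0.25), rep(1, 17))
  expect_error(compare_spectra(sp, short), "overlap")
})
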