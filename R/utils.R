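# internal helpers shared across modules

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               .Machine$integer.max)
}

assert_numeric_vector <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0) {
    abort(sprintf("`%s` must be a non-empty numeric vector", name))
  }
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values", name))
  }
  invisible(x)
}

assert_strictly_increasing <- function(x, name) {
  if (any(diff(x) <= 0)) {
    abort(sprintf("non-monotone %s axis: `%s` must be strictly increasing",
                  sub("_.*", "", name), name))
  }
  invisible(x)
}

# median grid step, used where a scalar step is needed on a near-uniform axis
grid_step <- function(x) median(diff(x))

# half-width of a Gaussian at 10% of its apex: sigma * sqrt(2 ln 10)
TEN_PCT_HALF_WIDTH <- sqrt(2 * log(10))

# baseline level of a trace: median of its lowest decile
baseline_level <- function(y) {
  q <- stats::quantile(y, 0.1, names = FALSE, na.rm = TRUE)
  median(y[y <= q], na.rm = TRUE)
}

# robust noise sd of a trace: 1.4826 * MAD of the first-difference detrended
# signal (differences of iid noise have variance 2 * sigma^2)
robust_noise_sd <- function(y) {
  d <- diff(y)
  1.4826 * median(abs(d - median(d))) / sqrt(2)
}

unit_max <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else x / m
}

unit_norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}
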