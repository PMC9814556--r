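#' Multi-right-hand-side non-negative least squares
#'
#' Solves `min ||A x - b||` subject to `x >= 0` for every column `b` of `B`,
#' exactly, by enumerating all candidate active sets: the unconstrained
#' least-squares solution restricted to the optimal support equals the NNLS
#' optimum (KKT), so taking the feasible candidate with smallest residual
#' over all supports is exact. Enumeration is `2^k - 1` supports, so this is
#' intended for the small component counts (k <= 12) of curve resolution,
#' where it vectorises over thousands of right-hand sides at once.
#'
#' @param A Numeric matrix (m x k), k <= 12.
#' @param B Numeric matrix (m x n) of right-hand sides.
#' @return Matrix (k x n) of non-negative solutions.
#' @export
nnls_multi <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  k <- ncol(A); n <- ncol(B)
  if (k > 12) abort("nnls_multi enumerates active sets; k must be <= 12")
  X <- matrix(0, k, n)
  best <- colSums(B^2)                       # all-zero candidate
  AtB <- crossprod(A, B)
  AtA <- crossprod(A)
  for (bits in seq_len(2^k - 1)) {
    s <- which(bitwAnd(bits, bitwShiftL(1L, 0:(k - 1))) != 0)
    sol <- tryCatch(
      solve(AtA[s, s, drop = FALSE], AtB[s, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(sol)) next
    feas <- colSums(sol < -1e-10) == 0
    if (!any(feas)) next
    sol[sol < 0] <- 0
    # residuals computed directly: the quadratic-form shortcut cancels
    # catastrophically near exact fits and then mis-ranks candidate
    # supports
    r2 <- colSums((B - A[, s, drop = FALSE] %*% sol)^2)
    upd <- feas & r2 < best
    if (any(upd)) {
      best[upd] <- r2[upd]
      X[, upd] <- 0
      X[s, upd] <- sol[, upd, drop = FALSE]
    }
  }
  X
}

#' Multivariate curve resolution by alternating non-negative regression
#'
#' Factors a window's absorbance matrix `D` (time x wavelength) into
#' non-negative concentration profiles `C` (time x k) and spectra `S`
#' (wavelength x k), `D ~ C S^T`, by alternating exact non-negative least
#' squares: solve for `C` given `S`, then for `S` given `C`, until the
#' relative change in lack-of-fit drops below `tol`. The intrinsic scale
#' ambiguity is fixed by unit-max spectra columns (with `C` absorbing the
#' scale) and the permutation ambiguity by matching components to the
#' initial spectra `S0` by maximal correlation.
#'
#' Lack-of-fit is `100 * sqrt(sum(residual^2) / sum(D^2))` (percent) and is
#' non-increasing across iterations because each half-step is an exact
#' constrained minimisation.
#'
#' @param D Window absorbance matrix, time x wavelength.
#' @param S0 Initial spectra, wavelength x k (e.g. from [flank_spectra()]).
#' @param tol Relative lack-of-fit change for convergence (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @param unimodal Apply [unimodality_constraint()] to each concentration
#'   profile after the C half-step (off by default; the hidden-peak
#'   procedure in [deconvolve_window()] turns it on, elution profiles
#'   being single peaks).
#' @param order `"init"` (default) matches output components to the `S0`
#'   columns by maximal correlation, so permuting `S0` permutes the result
#'   identically; `"elution"` orders components by the apex time of their
#'   concentration profiles, which is the robust choice when `S0` columns
#'   are known to be elution-ordered but spectrally convolved (a hidden
#'   peak's initial spectrum can resemble a neighbour more than itself).
#' @return An `mcr_result`: list with `C`, `S` (unit-max columns),
#'   `residual_history` (lack-of-fit per iteration, %), `converged`,
#'   `iterations`.
#' @export
mcr_ar <- function(D, S0, tol = 1e-8, max_iter = 500, unimodal = FALSE,
                   order = c("init", "elution")) {
  order <- match.arg(order)
  D <- as.matrix(D)
  S <- as.matrix(S0)
  if (nrow(S) != ncol(D)) abort("S0 must live on D's wavelength grid")
  k <- ncol(S)
  if (k > min(dim(D))) abort("k exceeds the rank bound min(dim(D))")
  S <- pmax(S, 0)
  S <- apply(S, 2, unit_max)
  ssD <- sum(D^2)
  lof <- numeric(0)
  C <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- t(nnls_multi(S, t(D)))
    if (unimodal) C <- apply(C, 2, unimodality_constraint)
    S_new <- t(nnls_multi(C, D))
    dead <- apply(S_new, 2, max) <= 0
    S_new[, dead] <- S[, dead]               # keep a collapsed component alive
    smax <- apply(S_new, 2, max)
    S <- sweep(S_new, 2, smax, "/")
    C <- sweep(C, 2, smax, "*")
    lof <- c(lof, 100 * sqrt(sum((D - C %*% t(S))^2) / ssD))
    # an exact factorisation leaves only rounding jitter; 1e-9% of the data
    # norm is far below any measurement
    if (lof[it] < 1e-9 ||
        (it > 1 && abs(lof[it - 1] - lof[it]) <
           tol * max(lof[it - 1], .Machine$double.eps))) {
      converged <- TRUE
      break
    }
  }
  # final C consistent with the converged S
  C <- t(nnls_multi(S, t(D)))
  if (unimodal) C <- apply(C, 2, unimodality_constraint)
  # permutation ambiguity
  perm <- if (order == "elution") {
    base::order(apply(C, 2, which.max))
  } else {
    S0n <- apply(as.matrix(S0), 2, unit_max)
    cors <- abs(suppressWarnings(cor(S0n, S)))
    cors[!is.finite(cors)] <- -1
    p <- integer(k)
    avail <- seq_len(k)
    for (j in base::order(-apply(cors, 1, max, na.rm = TRUE))) {
      pick <- avail[which.max(cors[j, avail])]
      p[j] <- pick
      avail <- setdiff(avail, pick)
    }
    p
  }
  structure(
    list(C = C[, perm, drop = FALSE], S = S[, perm, drop = FALSE],
         residual_history = lof, converged = converged, iterations = length(lof)),
    class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("<mcr_result> %d components, lack-of-fit %.4g%% after %d iterations%s\n",
              ncol(x$S), tail(x$residual_history, 1), x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
tidy.mcr_result <- function(x, ...) {
  tibble(iteration = seq_along(x$residual_history),
         lack_of_fit = x$residual_history)
}

#' @export
glance.mcr_result <- function(x, ...) {
  tibble(k = ncol(x$S), lack_of_fit = tail(x$residual_history, 1),
         iterations = x$iterations, converged = x$converged)
}

#' Unimodality projection for a concentration profile
#'
#' Enforces a single maximum by clipping the profile to a monotone envelope
#' on each side of its apex (values may only decrease walking away from the
#' apex). Idempotent; consistent with Gaussian elution profiles. Off by
#' default in [mcr_ar()].
#'
#' @param x Numeric vector (one concentration profile).
#' @return Projected vector of the same length.
#' @export
unimodality_constraint <- function(x) {
  n <- length(x)
  a <- which.max(x)
  if (a > 1) for (i in (a - 1):1) x[i] <- min(x[i], x[i + 1])
  if (a < n) for (i in (a + 1):n) x[i] <- min(x[i], x[i - 1])
  x
}

#' Discrete Fréchet distance between two point sequences
#'
#' The minimum over monotone couplings of the maximum pointwise Euclidean
#' distance - the classic "dog-leash" curve metric, computed by dynamic
#' programming in O(nm).
#'
#' @param x1,y1 Coordinates of the first curve.
#' @param x2,y2 Coordinates of the second curve.
#' @return Non-negative scalar distance.
#' @examples
#' frechet_distance(c(0, 0.5, 1), c(0, 1, 0), c(0, 0.5, 1), c(0, 0.8, 0))
#' @export
frechet_distance <- function(x1, y1, x2, y2) {
  n <- length(x1); m <- length(x2)
  stopifnot(n == length(y1), m == length(y2), n >= 1, m >= 1)
  d <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (i in seq_len(n)[-1]) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(m)[-1]) {
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                      d[i, j])
    }
  }
  ca[n, m]
}

#' Compare two absorption spectra
#'
#' Aligns both spectra on a common wavelength grid (the first spectrum's
#' samples within the overlapping support; pairwise-complete, missing points
#' dropped) and reports
#'
#' * `r2` - the squared Pearson correlation of the absorbance values
#'   (invariant to scale and offset), and
#' * `frechet` - the discrete Fréchet distance after normalising wavelength
#'   to `[0, 1]` over the common support and each curve's absorbance to unit
#'   maximum. Absolute Fréchet values depend on this normalisation
#'   convention; they are comparable within it only.
#'
#' @param a,b [ref_spectrum()] objects, or lists/tibbles with `wavelength`
#'   and `absorbance`.
#' @param min_overlap Minimum number of common samples (default 50).
#' @return Tibble with columns `r2`, `frechet`, `n_overlap`.
#' @export
compare_spectra <- function(a, b, min_overlap = 50) {
  wa <- a$wavelength; ya <- a$absorbance
  wb <- b$wavelength; yb <- b$absorbance
  lo <- max(min(wa), min(wb))
  hi <- min(max(wa), max(wb))
  keep <- which(wa >= lo & wa <= hi & is.finite(ya))
  if (length(keep) < 2) abort("insufficient overlap between spectra")
  g <- wa[keep]
  va <- ya[keep]
  vb <- approx(wb[is.finite(yb)], yb[is.finite(yb)], xout = g)$y
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < min_overlap) {
    abort(sprintf("insufficient overlap: %d common samples (need >= %d)",
                  sum(ok), min_overlap))
  }
  g <- g[ok]; va <- va[ok]; vb <- vb[ok]
  r2 <- suppressWarnings(cor(va, vb))^2
  gx <- (g - min(g)) / max(diff(range(g)), .Machine$double.eps)
  tibble(r2 = r2,
         frechet = frechet_distance(gx, unit_max(va), gx, unit_max(vb)),
         n_overlap = length(g))
}
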