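#' Collect unit-norm spectra from an elution window
#'
#' Extracts the per-timepoint spectra within `[t_start, t_end]`, drops
#' baseline-only rows (total absorbance below `min_absorbance`, by default 5%
#' of the largest row total in the window) and scales each surviving row to
#' unit Euclidean norm so that clustering reflects spectral shape, not
#' concentration.
#'
#' @param chrom A [spectral_chromatogram()].
#' @param t_start,t_end Window bounds, minutes.
#' @param min_absorbance Minimum row total (AU summed over wavelengths);
#'   `NULL` for the 5% default.
#' @return Matrix (surviving timepoints x wavelengths) with attributes
#'   `times` and `wavelength`.
#' @export
collect_window_spectra <- function(chrom, t_start, t_end,
                                   min_absorbance = NULL) {
  stopifnot(inherits(chrom, "spectral_chromatogram"))
  sel <- which(chrom$time >= t_start & chrom$time <= t_end)
  if (!length(sel)) abort("window outside the time axis")
  M <- chrom$absorbance[sel, , drop = FALSE]
  tot <- rowSums(M)
  if (is.null(min_absorbance)) {
    # 5% of the strongest row, but never below the noise floor of the
    # row-total series - a signal-free window must not pass baseline rows
    min_absorbance <- max(0.05 * max(tot), 10 * robust_noise_sd(tot))
  }
  keep <- tot >= min_absorbance
  if (sum(keep) < 5) abort("window too sparse: fewer than 5 signal-bearing spectra")
  M <- M[keep, , drop = FALSE]
  M <- M / sqrt(rowSums(M^2))
  structure(M, times = chrom$time[sel][keep], wavelength = chrom$wavelength)
}

#' PCA embedding of window spectra
#'
#' Mean-centred projection onto the leading principal components with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param spectra_matrix Rows are spectra (e.g. from
#'   [collect_window_spectra()]).
#' @param n_components Number of components retained (default 2).
#' @return Scores matrix (rows x `n_components`) with attribute
#'   `explained_variance` (per-component variance ratios) and `rotation`.
#' @export
pca_embed <- function(spectra_matrix, n_components = 2) {
  if (nrow(spectra_matrix) < n_components + 1) {
    abort("need at least n_components + 1 rows")
  }
  tot_var <- sum(apply(spectra_matrix, 2, stats::var))
  if (tot_var < .Machine$double.eps) abort("degenerate input: zero variance")
  p <- prcomp(spectra_matrix, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(nc), drop = FALSE]
  scores <- p$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(scores,
            explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(nc)],
            rotation = rot)
}

#' Estimate the number of species by K-means with the elbow criterion
#'
#' Runs K-means for k = 1..`k_max` (best of `n_restarts` starts each) on the
#' PCA scores and selects the elbow of the within-cluster sum-of-squares
#' curve as the k maximising the vertical distance between `log wcss(k)` and
#' the chord joining the endpoints of the log curve - the point of maximal
#' curvature of the elbow plot on its natural (relative-improvement) scale.
#' The log scale makes the choice invariant to global rescaling of the
#' scores, and measuring curvature against the chord balances the initial
#' drop against the flat tail (a raw second difference is dominated by the
#' k = 1 to 2 drop on any convex curve). Ties break toward smaller k
#' (parsimony). If `wcss(1)` is already below `noise_floor_frac` per row the
#' window is treated as a single species and k = 1 is returned.
#'
#' @param scores Scores matrix from [pca_embed()].
#' @param k_max Largest k scanned (default 8).
#' @param n_restarts K-means restarts per k (default 10).
#' @param seed Integer seed making the restarts reproducible.
#' @param noise_floor_frac Per-row wcss(1) floor below which the window is
#'   declared single-species (default 1e-3; unit-norm rows make this scale
#'   meaningful).
#' @return A `clustering_result`: list with `k`, `labels`, `centers`,
#'   `wcss_curve`, `elbow_objective` (chord distance per k), `scores`.
#' @export
estimate_k_elbow <- function(scores, k_max = 8, n_restarts = 10, seed = 1L,
                             noise_floor_frac = 1e-3) {
  if (nrow(scores) < k_max) abort("need at least `k_max` rows")
  fits <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(k_max), function(k) {
      kmeans(scores, centers = k, nstart = n_restarts, iter.max = 200)
    })
  })
  wcss <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  # k clusters can always reproduce a (k-1)-cluster solution; enforce the
  # theoretical monotonicity against restart shortfalls
  wcss <- cummin(wcss)
  if (wcss[1] / nrow(scores) < noise_floor_frac) {
    k <- 1L
    obj <- rep(NA_real_, k_max)
  } else {
    lw <- log(pmax(wcss, .Machine$double.xmin))
    ks <- seq_len(k_max)
    chord <- lw[1] + (lw[k_max] - lw[1]) * (ks - 1) / (k_max - 1)
    obj <- chord - lw
    k <- which.max(obj)  # which.max takes the first (smallest k) tie
  }
  structure(
    list(k = as.integer(k), labels = fits[[k]]$cluster,
         centers = fits[[k]]$centers, wcss_curve = wcss,
         elbow_objective = obj, scores = scores),
    class = "clustering_result")
}

#' Count the species in a congested elution window
#'
#' Convenience wrapper for the full species-counting procedure: collect
#' unit-norm spectra from the window, embed with PCA keeping every component
#' above an explained-variance floor (at least 2, at most `max_components`;
#' five species directions cannot generically embed in two dimensions),
#' select k by K-means with the elbow criterion, and cap the choice at the
#' spectral rank of the window plus one. Unit-norm spectra of k mixing
#' species span k - 1 independent contrast directions after centring, so
#' the number of structured eigenvalues bounds the species count; the rank
#' is taken as the last eigenvalue followed by a drop of at least
#' `drop_ratio` (the noise tail decays by factors of ~1.1-1.5 per
#' component, structured eigenvalues sit far above it). The cap reins in
#' the elbow's tendency to over-segment a smooth mixture arc, as produced
#' by two nearly coincident species.
#'
#' @inheritParams collect_window_spectra
#' @inheritParams estimate_k_elbow
#' @param ev_floor Explained-variance ratio below which trailing components
#'   are considered noise (default 0.005).
#' @param max_components Cap on retained components (default 6).
#' @param drop_ratio Eigenvalue drop marking the structure/noise boundary
#'   (default 3).
#' @return A `clustering_result` (see [estimate_k_elbow()]) with attributes
#'   `n_components` (PCA dimensions used) and `k_rank` (the rank-based
#'   bound).
#' @export
count_species <- function(chrom, t_start, t_end, min_absorbance = NULL,
                          ev_floor = 0.005, max_components = 6,
                          k_max = 8, n_restarts = 10, seed = 1L,
                          drop_ratio = 3) {
  M <- collect_window_spectra(chrom, t_start, t_end, min_absorbance)
  ev <- prcomp(M)$sdev^2
  ev <- ev / sum(ev)
  nc <- max(2, min(max_components, sum(ev >= ev_floor)))
  scores <- pca_embed(M, n_components = nc)
  res <- estimate_k_elbow(scores, k_max = min(k_max, nrow(M) - 1),
                          n_restarts = n_restarts, seed = seed)
  ratios <- head(ev, k_max) / ev[2:(k_max + 1)]
  drops <- which(ratios >= drop_ratio)
  k_rank <- if (length(drops)) max(drops) + 1L else 1L
  if (res$k > k_rank) {
    res$k <- as.integer(k_rank)
    res$labels <- withr::with_seed(as.integer(seed), {
      km <- kmeans(scores, centers = k_rank, nstart = n_restarts,
                   iter.max = 200)
      res$centers <- km$centers
      km$cluster
    })
  }
  attr(res, "n_components") <- nc
  attr(res, "k_rank") <- k_rank
  times <- attr(M, "times")
  res$cluster_times <- sort(vapply(split(times, res$labels), median,
                                   numeric(1)))
  res
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d (of %d scanned)\n", x$k,
              length(x$wcss_curve)))
  invisible(x)
}

#' @export
tidy.clustering_result <- function(x, ...) {
  tibble(k = seq_along(x$wcss_curve), wcss = x$wcss_curve,
         elbow_objective = x$elbow_objective)
}

#' @export
glance.clustering_result <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$scores), wcss = x$wcss_curve[x$k])
}
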