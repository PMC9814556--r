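default_fingerprint_grid <- function() seq(200, 450, by = 0.217)

# resample + Savitzky-Golay smooth a spectrum on the model grid; NA outside
# support
smooth_on_grid <- function(spectrum, grid, poly_order = 5,
                           half_window_nm = 4.5) {
  rs <- resample_to_grid(spectrum, grid)
  savgol_smooth(rs$absorbance, grid_step(grid), poly_order, half_window_nm)
}

#' Turn a spectrum into a fingerprint feature vector
#'
#' The fingerprint pipeline: linear resampling onto the common wavelength
#' grid, Savitzky-Golay smoothing (order 5, +/- 4.5 nm window), first
#' derivative (cancels any constant baseline offset between instruments),
#' unit-norm scaling (cancels concentration/path-length scale). Grid points
#' outside the spectrum's support are imputed as zero only after the
#' derivative, so no artificial spectral structure is introduced; spectra
#' covering less than half the grid are rejected.
#'
#' @param spectrum A [ref_spectrum()].
#' @param grid Common wavelength grid, nm (default 200-450 at 0.217 nm).
#' @param poly_order,half_window_nm Savitzky-Golay settings.
#' @return Numeric feature vector of `length(grid)`, unit Euclidean norm.
#' @export
featurize <- function(spectrum, grid = default_fingerprint_grid(),
                      poly_order = 5, half_window_nm = 4.5) {
  sm <- smooth_on_grid(spectrum, grid, poly_order, half_window_nm)
  cover <- mean(is.finite(sm))
  if (cover < 0.5) {
    abort(sprintf("spectrum covers only %.0f%% of the %g-%g nm window",
                  100 * cover, min(grid), max(grid)))
  }
  d <- rep(0, length(grid))
  fin <- which(is.finite(sm))
  i0 <- min(fin); i1 <- max(fin)
  d[i0:i1] <- first_derivative(sm[i0:i1], grid[i0:i1])
  unit_norm(d)
}

fit_projected_lda <- function(X, labels, max_components = NULL,
                              ev_floor = 0.005) {
  n <- nrow(X)
  classes <- unique(labels)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / sum(sv$d^2)
  r <- min(max_components %||% Inf, n - length(classes),
           sum(ev >= ev_floor), sum(sv$d > 1e-8 * sv$d[1]))
  r <- max(r, 1)
  shrunk <- FALSE
  repeat {
    rot <- sv$v[, seq_len(r), drop = FALSE]
    colnames(rot) <- paste0("PC", seq_len(r))
    scores <- Xc %*% rot
    ld <- tryCatch(
      withCallingHandlers(
        MASS::lda(scores, grouping = factor(labels)),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    if (!is.null(ld)) break
    if (r <= 1) {
      # within-class scatter exactly singular (e.g. identical replicates):
      # regularise with a deterministic jitter far below any real signal
      scores <- scores + withr::with_seed(0, {
        matrix(rnorm(length(scores), 0, 1e-3 * max(sd(scores), 1e-12)),
               nrow(scores))
      })
      ld <- tryCatch(MASS::lda(scores, grouping = factor(labels)),
                     error = function(e) NULL)
      if (is.null(ld)) abort("discriminant fit failed even at 1 component")
      shrunk <- TRUE
      break
    }
    r <- max(1, floor(r * 0.7))
    shrunk <- TRUE
  }
  if (shrunk) warn("singular within-class scatter; projection shrunk")
  list(center = center, rotation = rot, lda = ld, r = r)
}

#' Train the spectral fingerprint classifier
#'
#' Features (first-derivative fingerprints, see [featurize()]) are projected
#' onto the principal variance components carrying at least 0.5% of the
#' training variance each (never more than `n_samples - n_classes`) before
#' a linear discriminant is fitted with shared covariance - with thousands
#' of wavelength features and tens of reference spectra, raw LDA would be
#' singular, and discriminating in the full `n - k` dimensional span
#' overfits the sample-poor classes. Classes with a single reference spectrum are kept (the pooled
#' covariance covers them). When every class has at least two spectra a
#' leave-one-out accuracy (full pipeline, tiebreak included) is reported.
#'
#' @param library A [spectral_library()] with >= 2 distinct species.
#' @param grid Common wavelength grid.
#' @param p_conf Posterior above which the top candidate is accepted
#'   outright (default 0.95).
#' @param margin Minimum top-two posterior margin (default 0.25); below
#'   either threshold the r-squared tiebreak engages.
#' @param loo Compute leave-one-out accuracy (default TRUE when every class
#'   has >= 2 spectra).
#' @return A `fingerprint_model`.
#' @export
train_fingerprint_model <- function(library, grid = default_fingerprint_grid(),
                                    p_conf = 0.95, margin = 0.25, loo = NULL) {
  stopifnot(inherits(library, "spectral_library"))
  labels <- vapply(library$entries, `[[`, character(1), "species")
  if (length(unique(labels)) < 2) abort("need at least 2 distinct species")
  X <- t(vapply(library$entries, featurize, numeric(length(grid)),
                grid = grid))
  fit <- fit_projected_lda(X, labels)
  n_per_class <- table(labels)
  model <- structure(
    list(grid = grid, center = fit$center, rotation = fit$rotation,
         lda = fit$lda, classes = sort(unique(labels)),
         n_per_class = tibble(species = names(n_per_class),
                              n = as.integer(n_per_class)),
         p_conf = p_conf, margin = margin, library = library,
         features = X, feature_labels = labels, loo_accuracy = NA_real_),
    class = "fingerprint_model")
  if (is.null(loo)) loo <- all(n_per_class >= 2)
  if (loo) {
    hits <- vapply(seq_along(library$entries), function(i) {
      sub <- spectral_library(library$entries[-i],
                              manifest = library$manifest[-i, ])
      m_i <- train_fingerprint_model(sub, grid = grid, p_conf = p_conf,
                                     margin = margin, loo = FALSE)
      res <- classify_spectrum(m_i, library$entries[[i]])
      res$final_label == labels[i]
    }, logical(1))
    model$loo_accuracy <- mean(hits)
  }
  model
}

#' @export
print.fingerprint_model <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_model> %d classes, %d training spectra, %d components%s\n",
    length(x$classes), nrow(x$features), ncol(x$rotation),
    if (is.na(x$loo_accuracy)) ""
    else sprintf(", LOO accuracy %.1f%%", 100 * x$loo_accuracy)))
  invisible(x)
}

#' @export
tidy.fingerprint_model <- function(x, ...) x$n_per_class

#' @export
glance.fingerprint_model <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_spectra = nrow(x$features),
         n_components = ncol(x$rotation), loo_accuracy = x$loo_accuracy)
}

#' Classify a spectrum against the fingerprint model
#'
#' Ranks species by discriminant posterior. The decision is deemed
#' inconclusive - and the tiebreak engages - when the top posterior is below
#' `p_conf`, the top-two margin is below `margin`, or the query sits far
#' from every class in discriminant space (squared distance to the nearest
#' class mean above `outlier_factor` times the 99.9% chi-square quantile;
#' shared-covariance posteriors saturate even for out-of-distribution
#' queries such as convolved mixture spectra, so a distance check is needed
#' to catch them). In the tiebreak the top `n_tiebreak` candidates are
#' compared to the query by squared Pearson correlation on the smoothed
#' (zeroth-derivative) spectra, averaged over each candidate's reference
#' spectra, and the highest mean r-squared wins. Classification is entirely
#' retention-time-free.
#'
#' @param model A `fingerprint_model`.
#' @param spectrum A [ref_spectrum()].
#' @param tiebreak_library Library providing candidate reference spectra
#'   (defaults to the training library).
#' @param n_tiebreak Number of top candidates entering the tiebreak
#'   (default 3).
#' @param outlier_factor Inflation of the chi-square distance threshold
#'   (default 25; generous so that clean single-species queries at the
#'   percent noise level never trigger it).
#' @return A `classification_result`: list with `candidates` tibble
#'   (`species`, `posterior`, ranked), `final_label`, `tiebreak_used`,
#'   `r2_to_final`, `frechet_to_final`.
#' @export
classify_spectrum <- function(model, spectrum,
                              tiebreak_library = model$library,
                              n_tiebreak = 3, outlier_factor = 25) {
  stopifnot(inherits(model, "fingerprint_model"))
  f <- featurize(spectrum, grid = model$grid)
  z <- (f - model$center) %*% model$rotation
  pred <- predict(model$lda, newdata = z)
  post <- pred$posterior[1, ]
  cand <- tibble(species = colnames(pred$posterior),
                 posterior = as.numeric(post)) |>
    dplyr::arrange(dplyr::desc(.data$posterior))
  # distance to the nearest class mean in discriminant coordinates, where
  # the pooled within-class covariance is the identity
  mu <- predict(model$lda, newdata = model$lda$means)$x
  d2_best <- min(colSums((t(mu) - as.numeric(pred$x))^2))
  df <- ncol(pred$x)
  tiebreak <- cand$posterior[1] < model$p_conf ||
    (nrow(cand) > 1 && cand$posterior[1] - cand$posterior[2] < model$margin) ||
    d2_best > outlier_factor * stats::qchisq(0.999, df)
  final <- cand$species[1]
  if (tiebreak) {
    top <- head(cand$species, n_tiebreak)
    qs <- smooth_on_grid(spectrum, model$grid)
    lib_labels <- vapply(tiebreak_library$entries, `[[`, character(1),
                         "species")
    mean_r2 <- vapply(top, function(sp) {
      refs <- tiebreak_library$entries[lib_labels == sp]
      if (!length(refs)) return(NA_real_)
      mean(vapply(refs, function(ref) {
        rs <- smooth_on_grid(ref, model$grid)
        ok <- is.finite(qs) & is.finite(rs)
        if (sum(ok) < 50) return(NA_real_)
        suppressWarnings(cor(qs[ok], rs[ok]))^2
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    if (any(is.finite(mean_r2))) final <- top[which.max(mean_r2)]
  }
  lib_labels <- vapply(tiebreak_library$entries, `[[`, character(1), "species")
  refs <- tiebreak_library$entries[lib_labels == final]
  sim <- if (length(refs)) {
    sims <- purrr::map(refs, function(ref) {
      tryCatch(compare_spectra(spectrum, ref), error = function(e) NULL)
    })
    sims <- purrr::compact(sims)
    if (length(sims)) dplyr::slice_max(dplyr::bind_rows(sims), .data$r2,
                                       n = 1, with_ties = FALSE) else NULL
  } else NULL
  structure(
    list(candidates = cand, final_label = final, tiebreak_used = tiebreak,
         r2_to_final = if (is.null(sim)) NA_real_ else sim$r2,
         frechet_to_final = if (is.null(sim)) NA_real_ else sim$frechet),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s (posterior %.3f%s, r2 %.3f)\n",
              x$final_label, x$candidates$posterior[1],
              if (x$tiebreak_used) ", tiebreak" else "",
              x$r2_to_final))
  invisible(x)
}

#' @export
tidy.classification_result <- function(x, ...) {
  dplyr::mutate(x$candidates, final = .data$species == x$final_label)
}

#' @export
glance.classification_result <- function(x, ...) {
  tibble(final_label = x$final_label, posterior = x$candidates$posterior[1],
         tiebreak_used = x$tiebreak_used, r2 = x$r2_to_final,
         frechet = x$frechet_to_final)
}

#' Save / load a fingerprint model as a portable JSON archive
#'
#' Text metadata plus full-precision numeric arrays; a loaded model gives
#' identical predictions to the original.
#'
#' @param model A `fingerprint_model`.
#' @param path File path (`.json`).
#' @export
save_fingerprint_model <- function(model, path) {
  stopifnot(inherits(model, "fingerprint_model"))
  ld <- model$lda
  payload <- list(
    format = "chromaspec_fingerprint_model", version = 1L,
    grid = model$grid, center = model$center,
    rotation = model$rotation, rotation_names = colnames(model$rotation),
    classes = model$classes, p_conf = model$p_conf, margin = model$margin,
    loo_accuracy = model$loo_accuracy,
    n_per_class = model$n_per_class,
    lda = list(prior = as.numeric(ld$prior), counts = as.numeric(ld$counts),
               means = ld$means, scaling = ld$scaling, lev = ld$lev,
               svd = ld$svd, N = ld$N,
               means_colnames = colnames(ld$means)),
    library = purrr::map(model$library$entries, function(e) {
      list(species = e$species, source = e$source,
           wavelength = e$wavelength, absorbance = e$absorbance)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_fingerprint_model
#' @export
load_fingerprint_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "chromaspec_fingerprint_model")) {
    abort("not a chromaspec fingerprint model archive")
  }
  rot <- as.matrix(p$rotation)
  colnames(rot) <- p$rotation_names
  means <- as.matrix(p$lda$means)
  colnames(means) <- p$lda$means_colnames
  rownames(means) <- p$lda$lev
  scaling <- as.matrix(p$lda$scaling)
  rownames(scaling) <- p$lda$means_colnames
  colnames(scaling) <- paste0("LD", seq_len(ncol(scaling)))
  ld <- structure(
    list(prior = setNames(p$lda$prior, p$lda$lev),
         counts = setNames(p$lda$counts, p$lda$lev),
         means = means, scaling = scaling, lev = p$lda$lev,
         svd = p$lda$svd, N = p$lda$N, call = quote(lda())),
    class = "lda")
  entries <- purrr::map(seq_len(nrow(p$library)), function(i) {
    ref_spectrum(p$library$species[i], p$library$wavelength[[i]],
                 p$library$absorbance[[i]], source = p$library$source[i])
  })
  lib <- spectral_library(entries)
  labels <- vapply(entries, `[[`, character(1), "species")
  structure(
    list(grid = p$grid, center = p$center, rotation = rot, lda = ld,
         classes = p$classes, n_per_class = as_tibble(p$n_per_class),
         p_conf = p$p_conf, margin = p$margin, library = lib,
         features = NULL, feature_labels = labels,
         loo_accuracy = p$loo_accuracy %||% NA_real_),
    class = "fingerprint_model")
}
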