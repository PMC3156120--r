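#' Fit a principal component decomposition of normalized time-point vectors
#'
#' Eigendecomposition of the covariance of the mean-centered log-ratio
#' vectors (one per time point), computed via singular values. Values are
#' already on a common natural-log scale, so no unit-variance scaling is
#' applied. Component signs are fixed by making each component's
#' largest-magnitude loading positive; downstream angles are computed within
#' one projection and are sign-insensitive.
#'
#' @param norm Normalized tibble from [normalize_samples()] (or any tibble
#'   with the four metadata columns followed by numeric features).
#' @return A `mir_pca` object: `rotation` (miRs x components, orthonormal),
#'   `center` (per-miR mean), `variance_fractions` (non-increasing, summing
#'   to 1), `sdev`, and `fitted_sample_ids`.
#' @export
fit_pca <- function(norm) {
  m <- mir_matrix(norm)
  if (nrow(m) < 2) abort("PCA needs at least 2 time-point vectors")
  total_var <- sum(apply(m, 2, stats::var))
  if (!is.finite(total_var) || total_var < 1e-12) {
    abort(paste0("degenerate variance: the time-point vectors are ",
                 "(numerically) identical; PCA is undefined"))
  }
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-magnitude loading of each component positive
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  ev <- p$sdev^2
  structure(
    list(
      rotation = p$rotation,
      center = p$center,
      sdev = p$sdev,
      variance_fractions = ev / sum(ev),
      fitted_sample_ids = norm$sample_id
    ),
    class = "mir_pca"
  )
}

#' @export
print.mir_pca <- function(x, ...) {
  k <- min(3, length(x$variance_fractions))
  cat("<mir_pca> ", length(x$fitted_sample_ids), " time points, ",
      nrow(x$rotation), " miRs\n", sep = "")
  cat("  first ", k, " PCs explain ",
      sprintf("%.1f%%", 100 * sum(x$variance_fractions[seq_len(k)])),
      " of variance\n", sep = "")
  invisible(x)
}

#' Cumulative fraction of variance explained by the first k components
#'
#' @param model A `mir_pca` object.
#' @param k Number of leading components.
#' @return Fraction in (0, 1].
#' @export
cumulative_variance <- function(model, k) {
  nf <- length(model$variance_fractions)
  if (k < 1 || k > nf) {
    abort(paste0("k must be between 1 and ", nf))
  }
  sum(model$variance_fractions[seq_len(k)])
}

#' Project a normalized series onto the first k principal components
#'
#' Coordinates are inner products of the mean-centered vectors with the
#' leading component directions.
#'
#' @param model A `mir_pca` object.
#' @param series Normalized tibble (a series or the full sample table).
#' @param k Number of components to keep (default 3).
#' @return A tibble `sample_id`, `strain`, `treatment`, `day`, `pc1`..`pck`.
#' @export
project_series <- function(model, series, k = 3) {
  m <- mir_matrix(series)
  if (ncol(m) != nrow(model$rotation) ||
      !identical(colnames(m), rownames(model$rotation))) {
    abort("series miRs do not match the fitted model")
  }
  nc <- ncol(model$rotation)
  if (k < 1 || k > nc) abort(paste0("k must be between 1 and ", nc))
  co <- sweep(m, 2, model$center) %*% model$rotation[, seq_len(k), drop = FALSE]
  colnames(co) <- paste0("pc", seq_len(k))
  dplyr::bind_cols(
    dplyr::select(series, dplyr::all_of(META_COLS)),
    tibble::as_tibble(co)
  )
}

#' @export
#' @rdname fit_pca
#' @param x A `mir_pca` object.
#' @param ... Unused.
tidy.mir_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$variance_fractions),
    std_dev = x$sdev,
    variance_fraction = x$variance_fractions,
    cumulative = cumsum(x$variance_fractions)
  )
}

#' @export
#' @rdname fit_pca
glance.mir_pca <- function(x, ...) {
  cum <- cumsum(x$variance_fractions)
  tibble::tibble(
    n_points = length(x$fitted_sample_ids),
    n_mirs = nrow(x$rotation),
    var_pc3 = sum(x$variance_fractions[seq_len(min(3, length(cum)))]),
    k_for_90 = which(cum >= 0.9)[1]
  )
}

#' Scree plot of a fitted PCA
#'
#' @param object A `mir_pca` object.
#' @param n_components Number of components to show (default 9).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mir_pca <- function(object, n_components = 9, ...) {
  td <- tidy(object)
  td <- td[seq_len(min(n_components, nrow(td))), ]
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$component),
                                   y = .data$variance_fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative),
                        colour = "steelblue") +
    ggplot2::labs(x = "principal component", y = "fraction of variance",
                  title = "Variance explained") +
    ggplot2::theme_minimal()
}

#' Plot PCA trajectories of one or more series
#'
#' Draws the day-ordered path of each series in a plane of two principal
#' components, labelling the time points in days.
#'
#' @param proj Projection tibble from [project_series()] (possibly several
#'   series bound together).
#' @param dims Which two PCs to draw (default `c(1, 2)`).
#' @return A ggplot.
#' @export
plot_trajectories <- function(proj, dims = c(1, 2)) {
  xs <- paste0("pc", dims[1])
  ys <- paste0("pc", dims[2])
  proj <- dplyr::mutate(proj,
                        series = paste(.data$strain, .data$treatment)) %>%
    dplyr::arrange(.data$series, .data$day)
  ggplot2::ggplot(proj, ggplot2::aes(x = .data[[xs]], y = .data[[ys]],
                                     colour = .data$series)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$day),
                       vjust = -0.7, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = toupper(xs), y = toupper(ys)) +
    ggplot2::theme_minimal()
}
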