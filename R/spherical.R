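#' Unit direction from one point to another
#'
#' @param a,b Numeric vectors of equal length; the direction is
#'   `(b - a) / ||b - a||`.
#' @return A unit vector.
#' @export
direction <- function(a, b) {
  if (length(a) != length(b)) abort("points have different dimensions")
  v <- b - a
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("undefined direction: the two points coincide")
  v / n
}

#' Angular distance between two unit vectors, in degrees
#'
#' The distance on the sphere is the angle between the vectors,
#' `acos(u . v)`, reported in degrees; symmetric and in \[0, 180\].
#'
#' @param u,v Unit vectors of equal length.
#' @param tol Allowed deviation of the input norms from 1.
#' @return Angle in degrees.
#' @export
angular_distance <- function(u, v, tol = 1e-6) {
  if (length(u) != length(v)) abort("vectors have different dimensions")
  if (abs(sqrt(sum(u^2)) - 1) > tol || abs(sqrt(sum(v^2)) - 1) > tol) {
    abort("inputs must be unit vectors")
  }
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Center-projected directions of a trajectory
#'
#' Places one time point of a projected series at the center of a sphere and
#' takes the unit direction from it through each subsequent time point — for
#' an n-point series with the earliest point as center, this gives n-1 points
#' on the sphere whose spread measures how well-defined the trajectory's
#' direction is.
#'
#' @param proj Coordinate tibble with a `day` column and numeric coordinate
#'   columns (`pc*` from [project_series()], or raw miR columns for a
#'   full-dimension analysis); one series only.
#' @param center_day The day whose coordinates become the projection center.
#' @param coord_cols Optional character vector naming the coordinate columns;
#'   default: `pc*` columns if present, else all columns after the metadata.
#' @return A `direction_set`: list with `directions` (rows = unit vectors),
#'   `days`, `center_day`, `ambient_dim`.
#' @export
center_projected_directions <- function(proj, center_day, coord_cols = NULL) {
  if (is.null(coord_cols)) {
    coord_cols <- grep("^pc[0-9]+$", names(proj), value = TRUE)
    if (length(coord_cols) == 0) coord_cols <- mir_cols(proj)
  }
  if (anyDuplicated(proj$day)) abort("series has repeated days")
  if (!center_day %in% proj$day) {
    abort(paste0("center day ", center_day, " not present in the series"))
  }
  m <- as.matrix(proj[coord_cols])
  ctr <- m[proj$day == center_day, ]
  later <- which(proj$day > center_day)
  if (length(later) == 0) {
    abort("no time points after the center day")
  }
  dirs <- t(vapply(later, function(i) {
    v <- m[i, ] - ctr
    n <- sqrt(sum(v^2))
    if (n < 1e-12) {
      abort(paste0("undefined direction: day ", proj$day[i],
                   " coincides with the center point"))
    }
    v / n
  }, numeric(ncol(m))))
  new_direction_set(dirs, days = proj$day[later], center_day = center_day)
}

new_direction_set <- function(directions, days = NULL, center_day = NA) {
  directions <- rbind(directions)
  structure(
    list(directions = directions,
         days = days %||% seq_len(nrow(directions)),
         center_day = center_day,
         ambient_dim = ncol(directions)),
    class = "direction_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.direction_set <- function(x, ...) {
  cat("<direction_set> ", nrow(x$directions), " directions on S^",
      x$ambient_dim - 1, ", center day ", x$center_day, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.direction_set <- function(x, ...) {
  d <- tibble::as_tibble(x$directions, .name_repair = ~ paste0("e", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(day = x$days), d)
}

as_direction_matrix <- function(x) {
  m <- if (inherits(x, "direction_set")) x$directions else rbind(x)
  if (nrow(m) == 0) abort("empty direction set")
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-6)) abort("directions must be unit vectors")
  m / nrm
}

# start policy: for S^2 the 8 octant points plus the normalized mean plus
# seeded random unit vectors; in higher dimension octants are infeasible, so
# the mean, every input direction and 32 random unit vectors are used
make_starts <- function(m, n_random = NULL) {
  d <- ncol(m)
  n_random <- n_random %||% if (d == 3) 8 else 32
  s <- list()
  mn <- colMeans(m)
  if (sqrt(sum(mn^2)) > 1e-12) s <- c(s, list(mn / sqrt(sum(mn^2))))
  if (d == 3) {
    oct <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
    s <- c(s, split(oct, row(oct)[, 1]))
  } else {
    s <- c(s, split(m, row(m)[, 1]))
  }
  if (n_random > 0) {
    z <- matrix(rnorm(n_random * d), n_random)
    z <- z / sqrt(rowSums(z^2))
    s <- c(s, split(z, row(z)[, 1]))
  }
  do.call(rbind, s)
}

#' Smallest enclosing spherical circle of a direction set
#'
#' Finds the center on the unit sphere minimizing the maximum angular
#' distance to the directions; the minimized maximum is the cap radius. A
#' small radius means the trajectory keeps to a well-defined direction. The
#' minimization is multi-start (see [make_starts()] policy in the package
#' vignette); for symmetric configurations the optimal center need not be
#' unique, in which case one optimum is returned.
#'
#' @param x A `direction_set` or a numeric matrix of unit row vectors.
#' @param n_random_starts Extra seeded random starts (default 8 on S^2, 32
#'   in higher dimension). Uses the session RNG.
#' @return An `enclosing_circle`: list with unit `center` and `radius_deg`
#'   in \[0, 180\].
#' @export
min_enclosing_circle <- function(x, n_random_starts = NULL) {
  m <- as_direction_matrix(x)
  if (nrow(m) == 1) {
    return(structure(list(center = m[1, ], radius_deg = 0),
                     class = "enclosing_circle"))
  }
  fit <- cpp_cap(m, make_starts(m, n_random_starts))
  structure(list(center = as.numeric(fit$center),
                 radius_deg = fit$radius_rad * 180 / pi),
            class = "enclosing_circle")
}

#' @export
print.enclosing_circle <- function(x, ...) {
  cat(sprintf("<enclosing_circle> radius %.2f deg\n", x$radius_deg))
  invisible(x)
}

#' Spherical standard deviation of a direction set
#'
#' Finds the center on the sphere minimizing the root mean square of the
#' angular distances to the directions; that minimized RMS (in degrees) is
#' the spherical standard deviation — a spread measure more robust to
#' outliers than the enclosing-cap radius, and never larger than it.
#'
#' @inheritParams min_enclosing_circle
#' @return A `spherical_spread`: list with unit `sd_center` and `sd_deg`.
#' @export
spherical_sd <- function(x, n_random_starts = NULL) {
  m <- as_direction_matrix(x)
  if (nrow(m) == 1) {
    return(structure(list(sd_center = m[1, ], sd_deg = 0),
                     class = "spherical_spread"))
  }
  fit <- cpp_sd(m, make_starts(m, n_random_starts))
  structure(list(sd_center = as.numeric(fit$center),
                 sd_deg = fit$rms_rad * 180 / pi),
            class = "spherical_spread")
}

#' @export
print.spherical_spread <- function(x, ...) {
  cat(sprintf("<spherical_spread> sd %.2f deg\n", x$sd_deg))
  invisible(x)
}

#' Discrimination between two direction sets
#'
#' The angular separation between the two spherical-SD-optimal centers
#' divided by the larger of the two spherical standard deviations; a
#' dimensionless ratio, large when the groups point in clearly different
#' directions relative to their own spread.
#'
#' @param a,b `direction_set`s (or unit-row matrices) of equal ambient
#'   dimension.
#' @inheritParams min_enclosing_circle
#' @return A single number.
#' @export
discrimination <- function(a, b, n_random_starts = NULL) {
  ma <- as_direction_matrix(a)
  mb <- as_direction_matrix(b)
  if (ncol(ma) != ncol(mb)) abort("direction sets differ in dimension")
  sa <- spherical_sd(ma, n_random_starts)
  sb <- spherical_sd(mb, n_random_starts)
  mx <- max(sa$sd_deg, sb$sd_deg)
  if (mx < 1e-9) {
    abort("both spherical standard deviations are zero; discrimination is undefined")
  }
  angular_distance(sa$sd_center, sb$sd_center) / mx
}

#' Azimuthal plot of a direction set with its enclosing circle
#'
#' Rotates the sphere so the enclosing-cap center sits at the pole and shows
#' the directions in an azimuthal equidistant projection (radial distance =
#' angle from the center, in degrees), with the enclosing circle dashed and
#' the spherical standard deviation dotted.
#'
#' @param ds A `direction_set` on S^2.
#' @return A ggplot.
#' @export
plot_direction_set <- function(ds) {
  m <- as_direction_matrix(ds)
  if (ncol(m) != 3) abort("plotting is defined on S^2 only")
  circ <- min_enclosing_circle(ds)
  sd <- spherical_sd(ds)
  c0 <- circ$center
  # angles and azimuths about the cap center
  ang <- acos(pmax(-1, pmin(1, m %*% c0))) * 180 / pi
  ref <- if (abs(c0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * c0) * c0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
          c0[3] * e1[1] - c0[1] * e1[3],
          c0[1] * e1[2] - c0[2] * e1[1])
  az <- atan2(m %*% e2, m %*% e1)
  pts <- tibble::tibble(x = ang * cos(az), y = ang * sin(az),
                        day = ds$days)
  th <- seq(0, 2 * pi, length.out = 181)
  ring <- function(r, what) tibble::tibble(x = r * cos(th), y = r * sin(th),
                                           what = what)
  rings <- dplyr::bind_rows(ring(circ$radius_deg, "enclosing circle"),
                            ring(sd$sd_deg, "spherical sd"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(linetype = .data$what), colour = "grey40") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$day), vjust = -0.8,
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "degrees from cap center", y = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
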