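#' Uniform random unit vector
#'
#' Draws each coordinate from a standard normal and normalizes, giving the
#' uniform distribution on the sphere S^(d-1). Uses the session RNG, so
#' results are reproducible under `set.seed()`.
#'
#' @param d Ambient dimension (>= 2).
#' @param n Number of vectors.
#' @return For `n = 1` a unit vector; otherwise an `n` x `d` matrix of unit
#'   rows.
#' @export
random_unit_vector <- function(d, n = 1) {
  if (d < 2) abort("dimension must be at least 2")
  z <- matrix(rnorm(n * d), n)
  z <- z / sqrt(rowSums(z^2))
  if (n == 1) z[1, ] else z
}

#' Random walk with unit-length uniform-direction steps
#'
#' The null model for trajectory directionality: starting from the origin,
#' each displacement is an independent unit vector uniform on the sphere.
#'
#' @param n_points Number of points including the origin (>= 2).
#' @param d Ambient dimension.
#' @return An `n_points` x `d` matrix; row 1 is the origin.
#' @export
random_walk <- function(n_points, d = 3) {
  if (n_points < 2) abort("a walk needs at least 2 points")
  steps <- random_unit_vector(d, n_points - 1)
  rbind(0, apply(rbind(steps), 2, cumsum))
}

walk_direction_set <- function(n_directions, d) {
  w <- random_walk(n_directions + 1, d)
  dirs <- t(apply(w[-1, , drop = FALSE], 1, function(p) p / sqrt(sum(p^2))))
  new_direction_set(dirs)
}

new_null_distribution <- function(statistic, samples, n_directions, d, seed) {
  structure(
    list(statistic = statistic, samples = as.numeric(samples),
         n_reps = length(samples), n_directions = n_directions,
         ambient_dim = d, seed = seed),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$statistic, ", ", x$n_reps, " reps, ",
      paste(x$n_directions, collapse = "+"), " directions on S^",
      x$ambient_dim - 1, "\n", sep = "")
  print(quantile(x$samples, c(0.01, 0.05, 0.5, 0.95)))
  invisible(x)
}

#' Null distribution of the enclosing-cap radius under a random walk
#'
#' For each replicate, a random walk of `n_directions + 1` points is
#' generated, the directions from its first point through each subsequent
#' point are taken, and the radius of their smallest enclosing spherical
#' circle is recorded.
#'
#' @param n_directions Number of directions (series length minus one).
#' @param d Ambient dimension (3 for a first-three-PCs analysis).
#' @param n_reps Number of Monte-Carlo replicates (default 10000).
#' @param seed Optional integer seed applied before simulation and recorded
#'   in the result.
#' @param n_random_starts Random starts per enclosing-circle solve.
#' @return A `null_distribution` with `statistic = "radius"`, samples in
#'   degrees.
#' @export
null_radius_distribution <- function(n_directions, d = 3, n_reps = 10000,
                                     seed = NULL, n_random_starts = NULL) {
  if (n_directions < 1) abort("need at least one direction")
  if (!is.null(seed)) set.seed(seed)
  nrs <- n_random_starts %||% if (d == 3) 8 else 32
  samples <- cpp_null_radius(n_directions, d, n_reps, nrs)
  new_null_distribution("radius", samples, n_directions, d, seed)
}

#' Null distribution of the discrimination between two random walks
#'
#' Both groups are replaced by independent random walks of the observed
#' sizes; the discrimination (separation of spherical-SD centers over the
#' larger spherical SD) is recorded per replicate.
#'
#' @param n_directions_a,n_directions_b Direction counts of the two groups.
#' @inheritParams null_radius_distribution
#' @return A `null_distribution` with `statistic = "discrimination"`.
#' @export
null_discrimination_distribution <- function(n_directions_a, n_directions_b,
                                             d = 3, n_reps = 10000,
                                             seed = NULL,
                                             n_random_starts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nrs <- n_random_starts %||% if (d == 3) 8 else 32
  samples <- cpp_null_discrimination(n_directions_a, n_directions_b, d,
                                     n_reps, nrs)
  new_null_distribution("discrimination", samples,
                        c(n_directions_a, n_directions_b), d, seed)
}

#' Null distribution of the angle between a random-walk center and a fixed
#' reference direction
#'
#' Only the test group is randomized: each replicate replaces it by a random
#' walk, and the angle between the walk's spherical-SD center and the fixed
#' reference center is recorded.
#'
#' @param n_directions Direction count of the randomized test group.
#' @param reference_center Unit vector held fixed.
#' @inheritParams null_radius_distribution
#' @return A `null_distribution` with `statistic = "proximity_angle"`,
#'   samples in degrees.
#' @export
null_proximity_distribution <- function(n_directions, d, reference_center,
                                        n_reps = 10000, seed = NULL,
                                        n_random_starts = NULL) {
  if (length(reference_center) != d) {
    abort("reference center does not match the ambient dimension")
  }
  if (!is.null(seed)) set.seed(seed)
  nrs <- n_random_starts %||% if (d == 3) 8 else 32
  samples <- cpp_null_proximity(n_directions, d, reference_center, n_reps, nrs)
  new_null_distribution("proximity_angle", samples, n_directions, d, seed)
}

#' Monte-Carlo P-value for trajectory directionality
#'
#' The fraction of null enclosing radii that are equal to or smaller than the
#' observed radius: the probability that a random walk produces directions at
#' least as tightly enclosed.
#'
#' @param observed_radius_deg Observed enclosing-cap radius in degrees.
#' @param null A `null_distribution` with `statistic = "radius"`.
#' @return P-value in \[0, 1\].
#' @export
p_value_directionality <- function(observed_radius_deg, null) {
  check_null(null, "radius")
  mean(null$samples <= observed_radius_deg)
}

#' Monte-Carlo P-value for group discrimination
#'
#' One-sided on large discrimination: the fraction of replicate
#' discriminations at least as large as observed.
#'
#' @param observed Observed discrimination ratio.
#' @param null A `null_distribution` with `statistic = "discrimination"`.
#' @return P-value in \[0, 1\].
#' @export
p_value_discrimination <- function(observed, null) {
  check_null(null, "discrimination")
  mean(null$samples >= observed)
}

#' Monte-Carlo P-value for cross-group proximity
#'
#' One-sided on small angles: the fraction of replicates in which a random
#' walk's center lands at least as close to the reference direction as the
#' observed test group did.
#'
#' @param observed_angle_deg Observed separation angle in degrees.
#' @param null A `null_distribution` with `statistic = "proximity_angle"`.
#' @return P-value in \[0, 1\].
#' @export
p_value_proximity <- function(observed_angle_deg, null) {
  check_null(null, "proximity_angle")
  mean(null$samples <= observed_angle_deg)
}

check_null <- function(null, statistic) {
  if (!inherits(null, "null_distribution")) {
    abort("'null' must be a null_distribution")
  }
  if (null$statistic != statistic) {
    abort(paste0("null distribution holds '", null$statistic,
                 "', not '", statistic, "'"))
  }
  invisible(null)
}
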