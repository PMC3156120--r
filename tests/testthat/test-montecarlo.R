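test_that("random unit vectors are unit, uniform-centered and seed-stable", {
  set.seed(30)
  m <- random_unit_vector(3, n = 1000)
  expect_equal(sqrt(rowSums(m^2)), rep(1, 1000), tolerance = 1e-12)

  set.seed(31)
  big <- random_unit_vector(3, n = 100000)
  expect_true(all(abs(colMeans(big)) < 0.02))

  set.seed(99)
  a <- random_unit_vector(5, n = 10)
  set.seed(99)
  b <- random_unit_vector(5, n = 10)
  expect_identical(a, b)
  expect_error(random_unit_vector(1), "at least 2")
})

test_that("random walks take unit steps with the expected diffusion", {
  set.seed(32)
  w <- random_walk(8, 3)
  expect_equal(dim(w), c(8L, 3L))
  expect_equal(w[1, ], c(0, 0, 0))
  steps <- diff(w)
  expect_equal(sqrt(rowSums(steps^2)), rep(1, 7), tolerance = 1e-12)

  # E ||end||^2 = number of steps (independent unit steps)
  set.seed(33)
  ends <- replicate(10000, sum(random_walk(8, 3)[8, ]^2))
  se <- sqrt(28 / 10000) # Var(||S||^2) = 4 * C(7,2) * Var(u.v) = 84/3
  expect_lt(abs(mean(ends) - 7), 3 * se)
  expect_error(random_walk(1), "at least 2")
})

test_that("null radius distributions are seeded, bounded and monotone in size", {
  n1 <- null_radius_distribution(1, 3, n_reps = 50, seed = 1)
  expect_true(all(n1$samples == 0))

  a <- null_radius_distribution(5, 3, n_reps = 120, seed = 7)
  b <- null_radius_distribution(5, 3, n_reps = 120, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_equal(a$n_reps, 120L)
  expect_equal(a$seed, 7)
  expect_true(all(a$samples >= 0 & a$samples <= 180))

  # more directions from a walk are harder to enclose
  few <- null_radius_distribution(2, 3, n_reps = 800, seed = 8)
  many <- null_radius_distribution(7, 3, n_reps = 800, seed = 9)
  expect_gt(median(many$samples), median(few$samples))
})

test_that("p-value tail conventions follow their definitions", {
  null <- null_radius_distribution(4, 3, n_reps = 400, seed = 10)
  expect_equal(p_value_directionality(180, null), 1)
  expect_equal(p_value_directionality(min(null$samples) - 1e-9, null), 0)
  # monotone non-decreasing in the observed radius
  obs <- quantile(null$samples, c(0.2, 0.5, 0.8))
  ps <- vapply(obs, p_value_directionality, numeric(1), null = null)
  expect_true(all(diff(ps) >= 0))
  # plain fractions, no continuity correction
  expect_equal(p_value_directionality(median(null$samples), null),
               mean(null$samples <= median(null$samples)))

  dn <- null_discrimination_distribution(3, 3, 3, n_reps = 200, seed = 11)
  expect_equal(p_value_discrimination(0, dn), 1)
  expect_equal(p_value_discrimination(max(dn$samples) + 1, dn), 0)

  pn <- null_proximity_distribution(3, 3, c(0, 0, 1), n_reps = 200, seed = 12)
  expect_equal(p_value_proximity(180, pn), 1)
  expect_equal(p_value_proximity(-1e-9, pn), 0)

  expect_error(p_value_directionality(10, dn), "discrimination")
  expect_error(p_value_proximity(10, null), "radius")
})

test_that("single-direction proximity null matches the spherical cap area", {
  # one direction: its sd center is itself, uniform on the sphere, so
  # P(angle <= theta) = (1 - cos theta) / 2; at 60 degrees that is 0.25
  pn <- null_proximity_distribution(1, 3, c(0, 0, 1), n_reps = 2000, seed = 13)
  p <- p_value_proximity(60, pn)
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(p - 0.25), 3 * se)
})

test_that("discrimination null is self-consistent across seeds", {
  a <- null_discrimination_distribution(7, 6, 3, n_reps = 4000, seed = 14)
  b <- null_discrimination_distribution(7, 6, 3, n_reps = 4000, seed = 15)
  expect_true(all(is.finite(a$samples)) && all(a$samples >= 0))
  ks <- suppressWarnings(stats::ks.test(a$samples, b$samples))
  expect_gt(ks$p.value, 0.01)
})
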