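test_that("direction and angular distance follow their closed forms", {
  expect_equal(direction(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  expect_equal(direction(c(1, 1, 1), c(1, 1, 2)), c(0, 0, 1))
  expect_error(direction(c(1, 2), c(1, 2)), "coincide")
  expect_error(direction(c(1, 2), c(1, 2, 3)), "dimensions")

  u <- c(1, 0, 0)
  expect_equal(angular_distance(u, u), 0)
  expect_equal(angular_distance(u, c(0, 1, 0)), 90)
  expect_equal(angular_distance(u, -u), 180)
  expect_equal(angular_distance(u, c(0, 1, 0)),
               angular_distance(c(0, 1, 0), u))
  expect_error(angular_distance(u, c(2, 0, 0)), "unit")
})

test_that("center-projected direction counts follow the series design", {
  proj <- tibble::tibble(day = c(0, 1, 3, 5, 7, 14, 21, 30),
                         pc1 = cos(1:8), pc2 = sin(1:8), pc3 = (1:8) / 4)
  # sham-style: center at day 0 -> 7 directions through days 1..30
  ds0 <- center_projected_directions(proj, 0)
  expect_equal(nrow(ds0$directions), 7L)
  expect_equal(ds0$days, c(1, 3, 5, 7, 14, 21, 30))
  # IRI-style: center at day 1 -> 6 directions through days 3..30
  ds1 <- center_projected_directions(proj, 1)
  expect_equal(nrow(ds1$directions), 6L)
  expect_equal(sqrt(rowSums(ds1$directions^2)), rep(1, 6))
  # two-point series -> a single direction
  two <- proj[1:2, ]
  expect_equal(nrow(center_projected_directions(two, 0)$directions), 1L)
  expect_error(center_projected_directions(proj, 2), "not present")
  dup <- proj
  dup$day[2] <- 0
  expect_error(center_projected_directions(dup, 0), "repeated")
  coincident <- proj
  coincident[2, c("pc1", "pc2", "pc3")] <- coincident[1, c("pc1", "pc2", "pc3")]
  expect_error(center_projected_directions(coincident, 0), "day 1")
})

test_that("smallest enclosing circle matches symmetry cases and the oracle", {
  one <- min_enclosing_circle(rbind(c(0, 1, 0)))
  expect_equal(one$radius_deg, 0)
  expect_equal(one$center, c(0, 1, 0))

  pair <- min_enclosing_circle(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(pair$radius_deg, 45, tolerance = 1e-8)
  expect_equal(pair$center, c(1, 1, 0) / sqrt(2), tolerance = 1e-8)

  set.seed(20)
  for (i in 1:60) {
    D <- random_directions(sample(2:8, 1))
    fit <- min_enclosing_circle(D)
    expect_equal(fit$radius_deg, oracle_cap(D)$radius_deg, tolerance = 1e-6)
    # every direction is inside the cap
    ang <- acos(pmax(-1, pmin(1, D %*% fit$center))) * 180 / pi
    expect_true(all(ang <= fit$radius_deg + 1e-6))
    expect_true(fit$radius_deg >= 0 && fit$radius_deg <= 180)
  }
  expect_error(min_enclosing_circle(matrix(numeric(0), 0, 3)), "empty")
})

test_that("spherical sd matches symmetry cases and the lattice oracle", {
  same <- spherical_sd(rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(same$sd_deg, 0, tolerance = 1e-6)

  # two directions theta apart: optimal center at the geodesic midpoint,
  # sd = theta / 2
  theta <- 40
  D <- rbind(c(1, 0, 0),
             c(cos(theta * pi / 180), sin(theta * pi / 180), 0))
  sp <- spherical_sd(D)
  expect_equal(sp$sd_deg, theta / 2, tolerance = 1e-6)
  mid <- D[1, ] + D[2, ]
  expect_equal(abs(sum(sp$sd_center * mid / sqrt(sum(mid^2)))), 1,
               tolerance = 1e-8)

  set.seed(21)
  lattice <- sphere_lattice()
  for (i in 1:8) {
    D <- random_directions(7)
    expect_equal(spherical_sd(D)$sd_deg, oracle_sd(D, lattice),
                 tolerance = 0.1)
  }
})

test_that("spherical sd never exceeds the enclosing radius", {
  set.seed(22)
  for (i in 1:50) {
    D <- random_directions(sample(2:9, 1))
    expect_lte(spherical_sd(D)$sd_deg,
               min_enclosing_circle(D)$radius_deg + 1e-6)
  }
})

test_that("discrimination composes separation and spread", {
  # two 2-point clusters, each +-5 degrees about centers 90 degrees apart
  d5 <- 5 * pi / 180
  A <- rbind(c(cos(d5), sin(d5), 0), c(cos(d5), -sin(d5), 0))
  B <- rbind(c(sin(d5), cos(d5), 0), c(-sin(d5), cos(d5), 0))
  expect_equal(discrimination(A, B), 90 / 5, tolerance = 1e-6)
  expect_equal(discrimination(A, A), 0, tolerance = 1e-9)

  set.seed(23)
  a <- random_directions(6)
  b <- random_directions(5)
  sa <- spherical_sd(a)
  sb <- spherical_sd(b)
  manual <- angular_distance(sa$sd_center, sb$sd_center) /
    max(sa$sd_deg, sb$sd_deg)
  expect_equal(discrimination(a, b), manual, tolerance = 1e-6)

  same <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(discrimination(same, same), "undefined")
  expect_error(discrimination(a, random_directions(4, d = 4)), "dimension")
})

test_that("cap, sd and discrimination are rotation invariant", {
  set.seed(24)
  A <- random_directions(7)
  B <- random_directions(6)
  r0 <- min_enclosing_circle(A)$radius_deg
  s0 <- spherical_sd(A)$sd_deg
  d0 <- discrimination(A, B)
  for (i in 1:3) {
    q <- random_rotation(3)
    expect_equal(min_enclosing_circle(A %*% q)$radius_deg, r0,
                 tolerance = 1e-8)
    expect_equal(spherical_sd(A %*% q)$sd_deg, s0, tolerance = 1e-8)
    expect_equal(discrimination(A %*% q, B %*% q), d0, tolerance = 1e-6)
  }
})

test_that("non-unit rows are rejected", {
  expect_error(min_enclosing_circle(rbind(c(2, 0, 0), c(0, 1, 0))), "unit")
  expect_error(spherical_sd(rbind(c(0.5, 0, 0))), "unit")
})
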