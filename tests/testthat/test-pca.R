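make_norm_tbl <- function(m, days = seq_len(nrow(m))) {
  colnames(m) <- sprintf("m%02d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", seq_len(nrow(m))),
                   strain = "B6", treatment = "IRI", day = as.integer(days)),
    tibble::as_tibble(m)
  )
}

test_that("variance fractions match an independent eigendecomposition", {
  set.seed(10)
  m <- matrix(rnorm(8 * 20), 8)
  fit <- fit_pca(make_norm_tbl(m))
  ev <- eigen(stats::cov(m), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(fit$variance_fractions[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-9)
  # invariants: fractions sum to one, non-increasing; loadings orthonormal
  expect_equal(sum(fit$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$variance_fractions) <= 1e-12))
  k <- sum(fit$sdev > 1e-8)
  rot <- fit$rotation[, seq_len(k)]
  expect_equal(crossprod(rot), diag(k), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("rank and degeneracy are detected", {
  set.seed(11)
  basis <- qr.Q(qr(matrix(rnorm(10 * 2), 10)))
  m <- matrix(rnorm(6 * 2), 6) %*% t(basis) # points on a 2-plane in R^10
  fit <- fit_pca(make_norm_tbl(m))
  expect_equal(sum(fit$variance_fractions > 1e-10), 2L)

  const <- matrix(1, 4, 5)
  expect_error(fit_pca(make_norm_tbl(const)), "degenerate")
  expect_error(fit_pca(make_norm_tbl(matrix(1, 1, 5))), "at least 2")
})

test_that("projection preserves geometry and recovers constructed coordinates", {
  set.seed(12)
  m <- matrix(rnorm(7 * 12), 7)
  tbl <- make_norm_tbl(m)
  fit <- fit_pca(tbl)
  # 7 centered points span at most 6 dimensions; all components carry them
  k_full <- length(fit$sdev)
  pr <- project_series(fit, tbl, k = k_full)
  co <- as.matrix(pr[grep("^pc", names(pr))])
  # full-dimension projection preserves pairwise distances
  expect_equal(as.matrix(dist(co)), as.matrix(dist(m)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # projecting the model's center gives the zero vector
  ctr <- make_norm_tbl(rbind(fit$center), days = 1)
  expect_equal(unname(as.matrix(project_series(fit, ctr, 3)[, 5:7])),
               matrix(0, 1, 3), tolerance = 1e-10)
  # a point displaced from the center along PC1 by t projects to (t, 0, 0)
  t_len <- 1.7
  disp <- make_norm_tbl(rbind(fit$center + t_len * fit$rotation[, 1]), 1)
  expect_equal(unname(as.matrix(project_series(fit, disp, 3)[, 5:7])),
               matrix(c(t_len, 0, 0), 1), tolerance = 1e-8)
  expect_error(project_series(fit, tbl, k = 99), "between 1 and")

  back <- co %*% t(fit$rotation[, seq_len(k_full)]) +
    rep(1, nrow(m)) %o% fit$center
  expect_equal(back, m, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("downstream angles are invariant under rotation when k is full", {
  set.seed(13)
  m <- matrix(rnorm(6 * 5), 6)
  ang_between <- function(mm) {
    tbl <- make_norm_tbl(mm)
    fit <- fit_pca(tbl)
    pr <- project_series(fit, tbl, k = ncol(mm))
    ds <- center_projected_directions(pr, 1,
                                      coord_cols = grep("^pc", names(pr),
                                                        value = TRUE))
    angular_distance(ds$directions[1, ], ds$directions[4, ])
  }
  a0 <- ang_between(m)
  for (i in 1:3) {
    r <- random_rotation(5)
    expect_equal(ang_between(m %*% r), a0, tolerance = 1e-8)
  }
})

test_that("cumulative variance and tidiers are consistent", {
  set.seed(14)
  m <- matrix(rnorm(9 * 6), 9)
  fit <- fit_pca(make_norm_tbl(m))
  expect_equal(cumulative_variance(fit, length(fit$variance_fractions)), 1,
               tolerance = 1e-9)
  expect_error(cumulative_variance(fit, 0), "between")
  td <- tidy(fit)
  expect_equal(td$cumulative, cumsum(td$variance_fraction))
  expect_equal(glance(fit)$var_pc3, cumulative_variance(fit, 3))
  # two points span a single direction
  two <- fit_pca(make_norm_tbl(matrix(rnorm(2 * 4), 2)))
  expect_equal(cumulative_variance(two, 1), 1, tolerance = 1e-9)
})
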