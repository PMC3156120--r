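# Small programmatic fixtures shared across test files.

# a tiny raw-intensity matrix: 4 miRs x (naive + 2 sham + 2 IRI) for one strain
tiny_experiment <- function() {
  expr <- tibble::tibble(
    mir_id = c("miR-a", "miR-b", "miR-c", "miR-d"),
    n0 = c(400, 400, 100, 1000),
    s1 = c(200, 800, 150, 1000),
    s2 = c(400, 400, 120, 2000),
    i1 = c(800, 200, 90, 1000),
    i2 = c(1600, 100, 60, 500)
  )
  sheet <- tibble::tibble(
    sample_id = c("n0", "s1", "s2", "i1", "i2"),
    strain = "B6",
    treatment = c("naive", "sham", "sham", "IRI", "IRI"),
    day = c(0L, 1L, 3L, 1L, 3L)
  )
  list(expression = expr, samples = sheet)
}

# normalized log-ratio vectors lying exactly in a 3-dimensional subspace of
# miR space, exported as raw intensities (reference 400, all above floor)
rank3_experiment <- function(n_mirs = 30, seed = 42) {
  set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(n_mirs * 3), n_mirs)))[, 1:3]
  days <- c(1, 3, 5, 7, 14)
  series <- list(sham = 0.25 * cbind(cos(days / 4), sin(days / 4), days / 30),
                 IRI = 0.25 * cbind(days / 15, -cos(days / 5), sin(days / 6)))
  cols <- list(n0 = rep(400, n_mirs))
  sheet <- list(tibble::tibble(sample_id = "n0", strain = "B6",
                               treatment = "naive", day = 0L))
  for (trt in names(series)) {
    w <- series[[trt]] %*% t(basis) # days x miRs, in the 3-space
    for (i in seq_along(days)) {
      id <- paste0(trt, "_d", days[i])
      cols[[id]] <- 400 * exp(w[i, ])
      sheet[[id]] <- tibble::tibble(sample_id = id, strain = "B6",
                                    treatment = trt, day = as.integer(days[i]))
    }
  }
  expr <- dplyr::bind_cols(
    tibble::tibble(mir_id = sprintf("m%02d", seq_len(n_mirs))),
    tibble::as_tibble(cols)
  )
  list(expression = expr, samples = dplyr::bind_rows(sheet))
}

# drifted experiment whose injury signal lives entirely in a named miR set
signal_in_subset_experiment <- function(seed = 5, n_mirs = 40, n_signal = 5) {
  set.seed(seed)
  ids <- sprintf("m%02d", seq_len(n_mirs))
  signal <- ids[seq_len(n_signal)]
  days <- c(1, 3, 5, 7, 14)
  base <- rep(log(1000), n_mirs)
  v <- rep(0, n_mirs)
  v[seq_len(n_signal)] <- 1 / sqrt(n_signal)
  cols <- list(n0 = exp(base))
  sheet <- list(tibble::tibble(sample_id = "n0", strain = "B6",
                               treatment = "naive", day = 0L))
  for (trt in c("sham", "IRI")) {
    for (t in days) {
      mu <- base + rnorm(n_mirs, 0, 0.02)
      if (trt == "IRI") mu <- mu + 0.5 * t * v
      id <- paste0(trt, "_d", t)
      cols[[id]] <- exp(mu)
      sheet[[id]] <- tibble::tibble(sample_id = id, strain = "B6",
                                    treatment = trt, day = as.integer(t))
    }
  }
  expr <- dplyr::bind_cols(tibble::tibble(mir_id = ids),
                           tibble::as_tibble(cols))
  list(expression = expr, samples = dplyr::bind_rows(sheet),
       signal_mirs = signal)
}

# run the standard 3-PC directionality test on one series of a generated
# experiment and return the enclosing radius (degrees)
observed_radius_3pc <- function(sim, strain, treatment, center_day,
                                co_series = NULL) {
  sheet <- sim$samples
  kept <- filter_by_mean(sim$expression, 200,
                         sheet$sample_id[sheet$strain == strain])
  norm <- normalize_samples(kept, sheet)
  sr <- extract_series(norm, strain, treatment)
  fit <- if (is.null(co_series)) {
    sr
  } else {
    dplyr::distinct(dplyr::bind_rows(
      sr, extract_series(norm, strain, co_series)
    ))
  }
  model <- fit_pca(fit)
  proj <- project_series(model, sr, k = 3)
  ds <- center_projected_directions(proj, center_day)
  min_enclosing_circle(ds)$radius_deg
}
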