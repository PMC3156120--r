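test_that("configuration is validated", {
  expect_error(simulation_config(injury_drift_magnitude = -1), "magnitude")
  expect_error(simulation_config(fraction_expressed = 0), "fraction_expressed")
  expect_error(simulation_config(fraction_expressed = 1.2),
               "fraction_expressed")
  cfg <- simulation_config(day_grids = list("B6" = list(sham = c(1, 3))))
  expect_error(generate_experiment(cfg, seed = 1), "day grid missing")
})

test_that("generated experiments validate and are seed-reproducible", {
  cfg <- simulation_config()
  sim <- generate_experiment(cfg, seed = 101)
  # validators run inside the generator; re-run them explicitly
  expect_silent(mirtraj:::validate_expression_matrix(sim$expression))
  expect_silent(mirtraj:::validate_sample_sheet(sim$samples))
  expect_equal(nrow(sim$expression), 571L)
  # 6 series over 3 strains, one naive per strain
  expect_equal(sum(sim$samples$treatment == "naive"), 3L)
  expect_equal(sqrt(sum(sim$truth$injury_direction^2)), 1, tolerance = 1e-12)

  # byte-identical files under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(generate_experiment(cfg, seed = 101)$expression, f1)
  write_expression_matrix(generate_experiment(cfg, seed = 101)$expression, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the default configuration retains 20-30% of miRs", {
  for (s in c(201, 202, 203)) {
    sim <- generate_experiment(simulation_config(), seed = s)
    kept <- filter_by_mean(
      sim$expression, 200,
      sim$samples$sample_id[sim$samples$strain == "C57BL/6"]
    )
    frac <- nrow(kept) / nrow(sim$expression)
    expect_gte(frac, 0.20)
    expect_lte(frac, 0.30)
  }
})

test_that("noise-free limits give degenerate geometry as constructed", {
  cfg <- simulation_config(injury_drift_magnitude = 0,
                          sham_fluctuation_sd = 0,
                          measurement_noise_sd = 0)
  sim <- generate_experiment(cfg, seed = 55)
  kept <- filter_by_mean(sim$expression, 200,
                         sim$samples$sample_id[sim$samples$strain == "C57BL/6"])
  norm <- normalize_samples(kept, sim$samples)
  sh <- extract_series(norm, "C57BL/6", "sham")
  # all post-day-1 vectors identical (jump only)
  vals <- as.matrix(sh[sh$day >= 1, mirtraj:::mir_cols(sh)])
  expect_equal(max(abs(sweep(vals, 2, vals[1, ]))), 0)
  # directions from day 0 all coincide -> enclosing radius 0
  ds <- center_projected_directions(sh, 0)
  expect_lt(min_enclosing_circle(ds)$radius_deg, 1e-6)
  # IRI with zero drift: later points coincide with the day-1 center
  ir <- extract_series(norm, "C57BL/6", "IRI")
  expect_error(center_projected_directions(ir, 1), "day 3")
})

test_that("injury-direction recovery responds to the injected signal", {
  sim <- generate_experiment(simulation_config(), seed = 77)
  kept <- filter_by_mean(sim$expression, 200,
                         sim$samples$sample_id[sim$samples$strain == "C57BL/6"])
  norm <- normalize_samples(kept, sim$samples)
  ir <- extract_series(norm, "C57BL/6", "IRI")
  sp <- spherical_sd(center_projected_directions(ir, 1))
  ctr <- setNames(sp$sd_center, mirtraj:::mir_cols(ir))
  expect_lt(recover_injury_direction(sim$truth, ctr), 30)
  expect_error(recover_injury_direction(sim$truth,
                                        setNames(c(1, 0), c("x", "y"))),
               "retained miR ids")
})
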