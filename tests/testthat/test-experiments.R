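test_that("sim_config wires supply factors into all three source modes", {
  cfg <- sim_config(production_factor = 2)
  expect_equal(cfg$kinetics$mu_p, 2 * 8.25e-5)
  expect_equal(cfg$source$mu_j0, 2 * 0.033 / 20)
  expect_equal(cfg$source$mu_C0, 2)
  cfg_flux <- sim_config(bc = "flux")
  expect_equal(cfg_flux$Ls, 0)
  expect_error(sim_config(x_targets_cells = 300),
               class = "morphosim_invalid_parameter")
})

test_that("update_config rebuilds a consistent configuration", {
  cfg <- sim_config(n = 1, Lp_cells = 100)
  cfg2 <- update_config(cfg, n = 4, mu_delta = 2.5)
  expect_equal(cfg2$kinetics$n, 4)
  expect_equal(cfg2$area$mu_delta, 2.5)
  expect_equal(cfg2$Lp, 100 * 2.5)
})

test_that("sweeps validate their axes", {
  cfg <- sim_config(Lp_cells = 40, x_targets_cells = 5)
  expect_error(run_sweep(cfg, sweep = list()),
               class = "morphosim_config_error")
  expect_error(run_sweep(cfg, sweep = list(n = numeric(0))),
               class = "morphosim_config_error")
  expect_error(run_sweep(cfg, sweep = list(bogus = 1)),
               class = "morphosim_config_error")
})

test_that("sweep tables are reproducible and tidy", {
  cfg <- sim_config(Lp_cells = 40, x_targets_cells = c(5, 20))
  s1 <- run_sweep(cfg, sweep = list(n = c(1, 2)), n_replicates = 10, seed = 4)
  s2 <- run_sweep(cfg, sweep = list(n = c(1, 2)), n_replicates = 10, seed = 4)
  expect_equal(s1, s2)
  expect_equal(nrow(s1), 4) # 2 exponents x 2 targets
  expect_true(all(c("n", "cv_p", "bc_mode", "x_target_cells", "sigma_x_cells",
                    "sigma_x_se_cells", "point_seed") %in% names(s1)))
  expect_true(all(s1$sigma_x >= 0))
})

test_that("decay-order comparison pairs rows and propagates errors", {
  res <- tibble::tibble(
    n = c(1, 2), cv_p = 0.3, cv_d = 0.3, cv_D = 0.3, cv_A = 0.5,
    bc_mode = "source", production_factor = 1, mu_delta = 5, Lp_cells = 200,
    x_target_cells = 5,
    sigma_x_cells = c(0.8, 0.6), sigma_x_se_cells = c(0.03, 0.04)
  )
  cmp <- compare_decay_orders(res)
  expect_equal(cmp$delta_sigma_cells, -0.2)
  expect_equal(cmp$delta_se_cells, sqrt(0.03^2 + 0.04^2))
  # identical precision gives zero difference
  res0 <- dplyr::mutate(res, sigma_x_cells = 0.7)
  expect_equal(compare_decay_orders(res0)$delta_sigma_cells, 0)
  # a missing baseline is an error
  expect_error(compare_decay_orders(dplyr::filter(res, n > 1)),
               class = "morphosim_pairing_error")
  expect_error(compare_decay_orders(dplyr::mutate(res, x_target_cells = c(5, 10))),
               class = "morphosim_pairing_error")
})

test_that("presets cover the standard designs with valid axes", {
  names <- c("cell_area_cv", "cell_size_scaling", "decay_order_profile",
             "production_only", "domain_length", "source_cv_flux",
             "source_strength_near", "source_strength_far")
  for (nm in names) {
    ps <- preset_sweep(nm)
    expect_s3_class(ps$config, "sim_config")
    expect_true(length(ps$sweep) >= 1)
    expect_true(all(lengths(ps$sweep) >= 1))
  }
  expect_equal(preset_sweep("cell_size_scaling")$config$args$Lp_cells, 100)
  expect_error(preset_sweep("nope"))
})
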