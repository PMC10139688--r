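test_that("readout returns the source-facing border of the first subceeding cell", {
  real <- fake_realization(x_left = c(0, 5, 10), C_avg = c(1.0, 0.5, 0.2))
  expect_equal(read_position(real, 0.4), 10)
  expect_equal(read_position(real, 2), 0)    # every cell subceeds
  expect_true(is.na(read_position(real, 0))) # nothing subceeds: censored
  # strictly the first subceeding cell, even if the profile rises again
  real2 <- fake_realization(x_left = c(0, 5, 10, 15),
                            C_avg = c(1.0, 0.3, 0.8, 0.1))
  expect_equal(read_position(real2, 0.5), 5)
})

test_that("thresholds map monotonically from the deterministic reference", {
  ref <- deterministic_reference(default_kinetics(), Ls = 25, Lp = 500,
                                 mu_delta = 5)
  xs <- c(0, 20, 100, 250)
  th <- threshold_from_reference(ref, xs)
  expect_true(all(diff(th) < 0))
  # one decay length from the source: about e^-1 of the amplitude, up to a
  # cell-averaging correction of order mu_delta / lambda
  expect_equal(th[2] / th[1], exp(-1), tolerance = 0.15)
  expect_error(threshold_from_reference(ref, 600),
               class = "morphosim_range_error")
  expect_error(threshold_from_reference(ref, -5),
               class = "morphosim_range_error")
})

test_that("positional error is the ensemble standard deviation", {
  ens <- fake_ensemble(c(0, 10))
  prec <- positional_error(ens, n_bootstrap = 50)
  expect_equal(prec$sigma_x, sqrt(50))
  expect_equal(prec$mu_x, 5)
  ens2 <- fake_ensemble(rep(10, 4))
  prec2 <- positional_error(ens2, n_bootstrap = 50)
  expect_equal(prec2$sigma_x, 0)
  expect_equal(prec2$sigma_x_se, 0)
  expect_equal(prec2$sigma_x_cells, 0)
})

test_that("positional error ignores replicate order and censored replicates", {
  set.seed(2)
  pos <- rnorm(200, 100, 8)
  s1 <- positional_error(fake_ensemble(pos), n_bootstrap = 10)$sigma_x
  s2 <- positional_error(fake_ensemble(sample(pos)), n_bootstrap = 10)$sigma_x
  s3 <- positional_error(fake_ensemble(c(pos, NA)), n_bootstrap = 10)
  expect_equal(s1, s2)
  expect_equal(s3$sigma_x, s1)
  expect_equal(s3$n_censored, 1)
  expect_error(positional_error(fake_ensemble(c(5, NA, NA))),
               class = "morphosim_undefined_precision")
})

test_that("bootstrap standard error agrees with normal theory", {
  set.seed(8)
  n <- 1000
  pos <- rnorm(n, 100, 5)
  prec <- positional_error(fake_ensemble(pos), n_bootstrap = 1000)
  theory <- prec$sigma_x / sqrt(2 * (n - 1))
  expect_equal(prec$sigma_x_se, theory, tolerance = 0.2)
})

test_that("noise-free ensembles have zero positional error", {
  cfg <- sim_config(cv_p = 0, cv_d = 0, cv_D = 0, cv_A = 0,
                    Lp_cells = 50, x_targets_cells = 10)
  ens <- run_ensemble(cfg, n_replicates = 3, seed = 1)
  prec <- positional_error(ens, n_bootstrap = 20)
  expect_equal(prec$sigma_x, 0)
  expect_equal(prec$n_used, 3)
})

test_that("ensembles are bit-reproducible under the master seed", {
  cfg <- sim_config(Lp_cells = 40, x_targets_cells = c(5, 20))
  e1 <- run_ensemble(cfg, n_replicates = 5, seed = 99)
  e2 <- run_ensemble(cfg, n_replicates = 5, seed = 99)
  e3 <- run_ensemble(cfg, n_replicates = 5, seed = 100)
  expect_identical(e1$position, e2$position)
  expect_false(identical(e1$position, e3$position))
  # single replicates can be re-simulated in isolation from their sub-seed
  sub <- attr(e1, "sub_seeds")
  real <- simulate_replicate(cfg, sub[3])
  th <- unique(e1$threshold)[1]
  expect_equal(read_position(real, th),
               e1$position[e1$replicate == 3 & e1$threshold == th])
})

test_that("first-order error prediction matches simulation for small noise", {
  # noise must be small for the linearisation yet large enough that the
  # cell-border quantisation of the readout (5 um steps) does not dominate
  cfg <- sim_config(cv_p = 0.1, cv_d = 0.1, cv_D = 0.1, cv_A = 0,
                    Lp_cells = 100, x_targets_cells = 10)
  x_t <- 50
  ens <- run_ensemble(cfg, n_replicates = 300, seed = 5, record_at = x_t)
  prec <- positional_error(ens, n_bootstrap = 100)
  ref <- attr(ens, "reference")
  pred <- eq_first_order_sigma_x(sensed_sd(ens, x_t),
                                 profile_slope_at(ref, x_t))
  expect_gt(pred / prec$sigma_x, 0.5)
  expect_lt(pred / prec$sigma_x, 2)
  expect_warning(res <- eq_first_order_sigma_x(0.1, 0), "diverges")
  expect_identical(res, Inf)
  expect_equal(eq_first_order_sigma_x(0, 2), 0)
})

test_that("glance summarises an ensemble", {
  cfg <- sim_config(Lp_cells = 40, x_targets_cells = 5)
  ens <- run_ensemble(cfg, n_replicates = 3, seed = 2)
  g <- glance(ens)
  expect_equal(g$n_replicates, 3)
  expect_equal(g$n_failed, 0)
  expect_false(g$unreliable)
})
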