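kin0 <- kinetic_spec(cv_p = 0, cv_d = 0, cv_D = 0)

test_that("uniform linear-decay solution matches the cosh closed form", {
  ref <- deterministic_reference(kin0, Ls = 25, Lp = 500, mu_delta = 5,
                                 points_per_cell = 80)
  exact <- oracle_cosh_profile(ref$x, p = kin0$mu_p, d = kin0$mu_d,
                               D = kin0$mu_D, Ls = 25, Lp = 500)
  expect_lt(max(abs(ref$C - exact) / exact), 2e-5)
  # cell averages match the analytic per-cell integral
  pat <- ref$cells[!ref$cells$is_source, ]
  exact_avg <- oracle_cosh_cell_average(pat$x_left, pat$x_right,
                                        p = kin0$mu_p, d = kin0$mu_d,
                                        D = kin0$mu_D, Ls = 25, Lp = 500)
  expect_lt(max(abs(pat$C_avg - exact_avg) / exact_avg), 2e-5)
})

test_that("piecewise coefficients are handled exactly at cell interfaces", {
  # source-free linear problem with strong cell-to-cell jumps in d and D,
  # checked against an exact right-to-left transfer-matrix propagation
  set.seed(21)
  dom <- uniform_domain(5, Ls = 0, Lp = 50)
  fld <- sample_kinetic_field(kinetic_spec(cv_p = 0, cv_d = 0.8, cv_D = 0.8),
                              dom)
  sol <- solve_steady_state(dom, fld,
                            source = source_spec("dirichlet", mu_C0 = 1,
                                                 cv_C0 = 0),
                            points_per_cell = 80)
  orc <- oracle_transfer_linear(dom, fld, C0 = 1)
  C_orc <- orc(sol$x)
  expect_lt(max(abs(sol$C - C_orc) / C_orc), 1e-5)
})

test_that("nonlinear noisy solves are mesh-converged", {
  set.seed(31)
  dom <- sample_domain(area_spec(5, 0.5), Ls = 25, Lp = 250)
  fld <- sample_kinetic_field(kinetic_spec(n = 4), dom)
  s1 <- solve_steady_state(dom, fld, points_per_cell = 8)
  s2 <- solve_steady_state(dom, fld, points_per_cell = 32)
  a1 <- s1$cells$C_avg
  a2 <- s2$cells$C_avg
  expect_lt(max(abs(a1 - a2) / a2), 1e-3)
})

test_that("uniform non-linear solves reproduce the shifted power law", {
  kin2 <- kinetic_spec(n = 2, cv_p = 0, cv_d = 0, cv_D = 0)
  sol <- deterministic_reference(kin2,
                                 source = source_spec("dirichlet",
                                                      mu_C0 = 1, cv_C0 = 0),
                                 Lp = 4000, mu_delta = 5,
                                 points_per_cell = 10)
  keep <- sol$x <= 1000
  exact <- analytic_power_law(sol$x[keep], C0 = 1, D = kin2$mu_D,
                              d = kin2$mu_d, n = 2)
  expect_lt(max(abs(sol$C[keep] - exact) / exact), 0.01)
})

test_that("zero production gives the zero solution", {
  dom <- uniform_domain(5, 25, 100)
  fld <- sample_kinetic_field(kin0, dom)
  fld$p <- rep(0, nrow(fld))
  sol <- solve_steady_state(dom, fld)
  expect_equal(max(abs(sol$C)), 0)
  fld2 <- sample_kinetic_field(kinetic_spec(n = 2, cv_p = 0, cv_d = 0,
                                            cv_D = 0),
                               uniform_domain(5, 0, 100))
  sol2 <- solve_steady_state(uniform_domain(5, 0, 100), fld2,
                             source = source_spec("flux"), bc_value = 0)
  expect_equal(max(abs(sol2$C)), 0)
})

test_that("deterministic profiles are positive, monotone and flat at the far end", {
  for (n in c(1, 2)) {
    kin <- kinetic_spec(n = n, cv_p = 0, cv_d = 0, cv_D = 0)
    ref <- deterministic_reference(kin, Ls = 25, Lp = 1000, mu_delta = 5)
    pat <- ref$C[ref$x >= 0]
    expect_true(all(pat > 0))
    expect_true(all(diff(pat) < 0))
    # zero-flux distal boundary: relative drop across the last sub-interval
    # is second order in the mesh spacing
    last2 <- utils::tail(ref$C, 2)
    expect_lt((last2[1] - last2[2]) / last2[2], 1e-3)
  }
})

test_that("steady-state production balances degradation on noisy tissues", {
  set.seed(17)
  for (n in c(1, 2)) {
    cfg_kin <- kinetic_spec(n = n)
    dom <- sample_domain(area_spec(5, 0.5), Ls = 25, Lp = 1000)
    fld <- sample_kinetic_field(cfg_kin, dom)
    sol <- solve_steady_state(dom, fld)
    expect_lt(abs(flux_balance(sol)$relative_imbalance), 1e-6)
  }
})

test_that("mismatched field and domain are rejected", {
  dom <- uniform_domain(5, 25, 100)
  fld <- sample_kinetic_field(kin0, uniform_domain(5, 25, 50))
  expect_error(solve_steady_state(dom, fld),
               class = "morphosim_invalid_parameter")
  # flux mode demands a source-free domain
  fld2 <- sample_kinetic_field(kin0, dom)
  expect_error(solve_steady_state(dom, fld2, source = source_spec("flux")),
               class = "morphosim_invalid_parameter")
})

test_that("reference log-slope recovers the decay length", {
  ref <- deterministic_reference(kin0, Ls = 25, Lp = 1000, mu_delta = 5,
                                 points_per_cell = 40)
  keep <- ref$x > 0 & ref$x < 1000 - 3 * 20
  fit <- lm(log(ref$C[keep]) ~ ref$x[keep])
  expect_equal(-1 / coef(fit)[[2]], 20, tolerance = 0.005)
})

test_that("non-linear decay yields shallower tails at matched amplitude", {
  x <- c(100, 200, 400)
  e1 <- analytic_exponential(x, 1, 0.033, 8.25e-5)
  e2 <- analytic_power_law(x, 1, 0.033, 8.25e-5, 2)
  expect_true(all(e2 > e1))
})
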