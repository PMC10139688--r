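test_that("mean cell area formula inflates the circle area by (1+CV^2)^(1/4)", {
  expect_equal(mean_area_from_diameter(5, 0), pi * 6.25)
  expect_equal(mean_area_from_diameter(5, 0.5), pi * 6.25 * 1.25^0.25)
  expect_equal(mean_area_from_diameter(5, 0.5), 20.761436, tolerance = 1e-6)
  expect_error(mean_area_from_diameter(0, 0.5),
               class = "morphosim_invalid_parameter")
  expect_error(mean_area_from_diameter(5, -0.1),
               class = "morphosim_invalid_parameter")
})

test_that("zero area variance gives a deterministic uniform tissue", {
  dom <- sample_domain(area_spec(5, 0), Ls = 25, Lp = 1000)
  expect_equal(sum(dom$cells$is_source), 5)
  expect_equal(sum(!dom$cells$is_source), 200)
  expect_equal(dom$cells$diameter, rep(5, 205))
})

test_that("sampled domains cover exactly [-Ls, Lp] for any seed and CV", {
  for (seed in 1:10) {
    set.seed(seed)
    cv <- sample(c(0.1, 0.5, 0.9), 1)
    dom <- sample_domain(area_spec(5, cv), Ls = 25, Lp = 300)
    b <- c(dom$cells$x_left, dom$cells$x_right[nrow(dom$cells)])
    expect_true(all(diff(b) > 0))
    expect_equal(b[1], -25)
    expect_equal(b[length(b)], 300)
    expect_equal(sum(dom$cells$diameter), 325, tolerance = 1e-10)
    expect_equal(sum(dom$cells$diameter[dom$cells$is_source]), 25,
                 tolerance = 1e-10)
    expect_true(all(dom$cells$diameter > 0))
    # no cell straddles the source boundary
    expect_true(any(dom$cells$x_left == 0))
  }
})

test_that("a source-free domain is valid for boundary-condition source modes", {
  set.seed(3)
  dom <- sample_domain(area_spec(5, 0.5), Ls = 0, Lp = 1000)
  expect_equal(sum(dom$cells$is_source), 0)
  expect_equal(dom$cells$x_left[1], 0)
})

test_that("pooled mean cell diameter converges to mu_delta", {
  set.seed(42)
  diams <- unlist(lapply(1:50, function(i) {
    dom <- sample_domain(area_spec(5, 0.5), Ls = 0, Lp = 1000)
    # drop the truncated final cell of the region
    utils::head(dom$cells$diameter, -1)
  }))
  expect_gt(length(diams), 5e3)
  expect_equal(mean(diams), 5, tolerance = 0.01)
})

test_that("sampled areas follow the specified log-normal law", {
  set.seed(7)
  mu_A <- mean_area_from_diameter(5, 0.5)
  a <- rlnorm_mean_cv(1e4, mu_A, 0.5)
  pars <- lnorm_params(mu_A, 0.5)
  ks <- suppressWarnings(
    stats::ks.test(a, "plnorm", meanlog = pars$meanlog, sdlog = pars$sdlog)
  )
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(a), mu_A, tolerance = 0.02)
  expect_equal(sd(a) / mean(a), 0.5, tolerance = 0.03)
})

test_that("domains round-trip through JSON", {
  set.seed(11)
  dom <- sample_domain(area_spec(5, 0.5), Ls = 25, Lp = 200)
  dom2 <- domain_from_json(domain_to_json(dom))
  expect_equal(dom2$cells$x_left, dom$cells$x_left)
  expect_equal(dom2$cells$is_source, dom$cells$is_source)
  expect_equal(dom2$Lp, dom$Lp)
})

test_that("tidy() exposes the cell table", {
  dom <- uniform_domain(5, 25, 100)
  td <- tidy(dom)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("cell", "x_left", "x_right", "diameter", "is_source"))
})
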