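#' Configure one simulation condition
#'
#' Bundles tissue geometry, cell-area variability, morphogen kinetics, the
#' source representation and the readout targets into a single object.
#' Defaults encode the reference condition used throughout: mean cell
#' diameter a quarter of the gradient length (`mu_delta = mu_lambda / 4`),
#' a patterning domain of 200 cells and a source domain of 5 cells, cell-area
#' CV 0.5 and kinetic CVs 0.3.
#'
#' @param n Decay exponent (>= 1).
#' @param cv_p,cv_d,cv_D Kinetic coefficients of variation.
#' @param cv_A Cell-area coefficient of variation.
#' @param mu_delta Mean cell diameter, micrometres.
#' @param mu_lambda Mean gradient length, micrometres.
#' @param mu_D Mean diffusivity, square micrometres per second.
#' @param C_ref Reference concentration (arbitrary units).
#' @param production_factor Multiplier on the mean morphogen supply: scales
#'   `mu_p` (source mode), `mu_j0` (flux mode) or `mu_C0` (Dirichlet mode)
#'   relative to the defaults `mu_d * C_ref`, `mu_D * C_ref / mu_lambda` and
#'   `C_ref`. Equals the dimensionless supply ratio `p / (d C_ref)` in
#'   source mode.
#' @param bc Source representation: `"source"` (explicit secreting cells),
#'   `"flux"` or `"dirichlet"`.
#' @param cv_j0,cv_C0 CVs of the boundary draw in flux/Dirichlet modes.
#' @param Ls_cells,Lp_cells Region lengths in numbers of mean cell
#'   diameters. `Ls_cells` is forced to 0 in flux/Dirichlet modes.
#' @param x_targets_cells Nominal readout positions, in mean cell diameters.
#' @param x_targets_um Optional readout positions in micrometres; overrides
#'   `x_targets_cells`.
#' @param points_per_cell Solver mesh resolution.
#' @param n_replicates Default ensemble size.
#' @param seed Default master seed.
#' @return A `sim_config` object.
#' @examples
#' sim_config(n = 2, x_targets_cells = c(5, 75))
#' @export
sim_config <- function(n = 1, cv_p = 0.3, cv_d = 0.3, cv_D = 0.3,
                       cv_A = 0.5, mu_delta = mu_lambda / 4, mu_lambda = 20,
                       mu_D = 0.033, C_ref = 1, production_factor = 1,
                       bc = c("source", "flux", "dirichlet"),
                       cv_j0 = 0.3, cv_C0 = 0.3,
                       Ls_cells = 5, Lp_cells = 200,
                       x_targets_cells = c(5, 75), x_targets_um = NULL,
                       points_per_cell = 8, n_replicates = 1000, seed = 1) {
  bc <- match.arg(bc)
  check_positive_scalar(production_factor, "production_factor")
  mu_d <- mu_D / mu_lambda^2
  kinetics <- kinetic_spec(mu_D = mu_D, mu_lambda = mu_lambda,
                           mu_p = production_factor * mu_d * C_ref,
                           cv_p = cv_p, cv_d = cv_d, cv_D = cv_D,
                           n = n, C_ref = C_ref)
  source <- source_spec(bc,
                        mu_j0 = production_factor * mu_D * C_ref / mu_lambda,
                        mu_C0 = production_factor * C_ref,
                        cv_j0 = cv_j0, cv_C0 = cv_C0)
  area <- area_spec(mu_delta = mu_delta, cv_A = cv_A)
  Ls <- if (bc == "source") Ls_cells * mu_delta else 0
  Lp <- Lp_cells * mu_delta
  x_targets <- x_targets_um %||% (x_targets_cells * mu_delta)
  if (length(x_targets) < 1 || any(x_targets < 0) || any(x_targets > Lp)) {
    abort("Readout targets must lie within the patterning domain.",
          class = "morphosim_invalid_parameter")
  }
  args <- list(n = n, cv_p = cv_p, cv_d = cv_d, cv_D = cv_D, cv_A = cv_A,
               mu_delta = mu_delta, mu_lambda = mu_lambda, mu_D = mu_D,
               C_ref = C_ref, production_factor = production_factor, bc = bc,
               cv_j0 = cv_j0, cv_C0 = cv_C0, Ls_cells = Ls_cells,
               Lp_cells = Lp_cells, x_targets_cells = x_targets_cells,
               x_targets_um = x_targets_um,
               points_per_cell = points_per_cell,
               n_replicates = n_replicates, seed = seed)
  structure(
    list(kinetics = kinetics, area = area, source = source,
         Ls = Ls, Lp = Lp, x_targets = x_targets,
         points_per_cell = points_per_cell,
         n_replicates = n_replicates, seed = seed, args = args),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n = %g, bc = %s | mu_delta = %g um, Ls = %g um, Lp = %g um\n",
    x$kinetics$n, x$source$mode, x$area$mu_delta, x$Ls, x$Lp
  ))
  cat(sprintf(
    "  CVs: p %g, d %g, D %g, A %g | supply factor %g | targets (um): %s\n",
    x$kinetics$cv_p, x$kinetics$cv_d, x$kinetics$cv_D, x$area$cv_A,
    x$args$production_factor, paste(signif(x$x_targets, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Modify a simulation configuration
#'
#' Rebuilds a [sim_config()] with some arguments replaced.
#'
#' @param config A `sim_config`.
#' @param ... Named [sim_config()] arguments to override.
#' @return A new `sim_config`.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  dots <- list(...)
  args <- config$args
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' Run a parameter sweep of positional-error measurements
#'
#' Expands the sweep axes into a grid of conditions, runs one Monte-Carlo
#' ensemble per condition and returns a tidy table with one row per
#' condition and readout target. Each sweep point runs on an independently
#' derived sub-seed of the master seed, so the table is reproducible and
#' independent of execution order.
#'
#' @param config Base [sim_config()].
#' @param sweep Named list of [sim_config()] arguments to sweep; each entry
#'   is a vector of values (e.g. `list(n = c(1, 2, 4))`). Must be non-empty
#'   with non-empty axes.
#' @param n_replicates Ensemble size per sweep point (overrides the config;
#'   use a few hundred for scaled-down runs).
#' @param seed Master seed for the whole sweep.
#' @return A tibble with the swept arguments, the noise settings, and per
#'   target: `x_target`, `x_target_cells`, `mu_x`, `sigma_x`, `sigma_x_se`,
#'   `sigma_x_cells`, `sigma_x_se_cells`, `n_used`, `n_censored`,
#'   `n_failed`, `n_replicates`, `point_seed`.
#' @examples
#' \donttest{
#' cfg <- sim_config(Lp_cells = 40, x_targets_cells = 10)
#' run_sweep(cfg, sweep = list(n = c(1, 2)), n_replicates = 20, seed = 1)
#' }
#' @export
run_sweep <- function(config, sweep, n_replicates = config$n_replicates,
                      seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(sweep) || length(sweep) == 0 ||
      any(lengths(sweep) == 0) || is.null(names(sweep)) ||
      any(names(sweep) == "")) {
    abort("`sweep` must be a non-empty named list of non-empty axes.",
          class = "morphosim_config_error")
  }
  unknown <- setdiff(names(sweep), names(config$args))
  if (length(unknown)) {
    abort(paste0("Unknown sweep axes: ", paste(unknown, collapse = ", ")),
          class = "morphosim_config_error")
  }
  sweep <- lapply(sweep, function(v) if (is.list(v)) unlist(v) else v)
  grid <- tidyr::expand_grid(!!!sweep)
  point_seeds <- derive_seeds(seed, nrow(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    overrides <- as.list(grid[i, , drop = FALSE])
    cfg_i <- do.call(update_config, c(list(config), overrides))
    ens <- run_ensemble(cfg_i, n_replicates = n_replicates,
                        seed = point_seeds[i])
    prec <- positional_error(ens)
    meta <- tibble::tibble(
      n = cfg_i$kinetics$n,
      cv_p = cfg_i$kinetics$cv_p, cv_d = cfg_i$kinetics$cv_d,
      cv_D = cfg_i$kinetics$cv_D, cv_A = cfg_i$area$cv_A,
      bc_mode = cfg_i$source$mode,
      production_factor = cfg_i$args$production_factor,
      mu_delta = cfg_i$area$mu_delta,
      Lp_cells = cfg_i$args$Lp_cells,
      cv_j0 = cfg_i$source$cv_j0, cv_C0 = cfg_i$source$cv_C0,
      n_replicates = n_replicates,
      point_seed = point_seeds[i]
    )
    dplyr::bind_cols(meta[rep(1L, nrow(prec)), ], tibble::as_tibble(prec))
  })
  dplyr::bind_rows(rows)
}

#' Positional-error difference between non-linear and linear decay
#'
#' Pairs each `n > 1` row of a sweep table with the matching `n = 1` row at
#' the same readout target (and same other sweep settings) and reports the
#' difference of the positional errors in units of the mean cell diameter,
#' with standard errors propagated in quadrature.
#'
#' @param results Sweep table from [run_sweep()] containing `n = 1` rows.
#' @param x_targets Optional subset of `x_target_cells` to compare.
#' @return Tibble with the pairing keys, `n`, `delta_sigma_cells`
#'   (`sigma_x[n] - sigma_x[1]`, in cell diameters) and `delta_se_cells`.
#' @export
compare_decay_orders <- function(results, x_targets = NULL) {
  needed <- c("n", "x_target_cells", "sigma_x_cells", "sigma_x_se_cells")
  if (!all(needed %in% names(results))) {
    abort("`results` must come from run_sweep() (missing columns).",
          class = "morphosim_pairing_error")
  }
  if (!is.null(x_targets)) {
    results <- dplyr::filter(results,
                             .data$x_target_cells %in% x_targets)
  }
  keys <- intersect(
    c("cv_p", "cv_d", "cv_D", "cv_A", "bc_mode", "production_factor",
      "mu_delta", "Lp_cells", "x_target_cells"),
    names(results)
  )
  base <- dplyr::filter(results, .data$n == 1)
  if (nrow(base) == 0) {
    abort("No n = 1 baseline rows to compare against.",
          class = "morphosim_pairing_error")
  }
  base <- dplyr::select(base, dplyr::all_of(keys),
                        sigma_base = "sigma_x_cells",
                        se_base = "sigma_x_se_cells")
  nonlin <- dplyr::filter(results, .data$n > 1)
  out <- dplyr::inner_join(nonlin, base, by = keys)
  if (nrow(out) != nrow(nonlin)) {
    abort("Some n > 1 rows have no matching n = 1 baseline.",
          class = "morphosim_pairing_error")
  }
  out <- dplyr::mutate(out,
    delta_sigma_cells = .data$sigma_x_cells - .data$sigma_base,
    delta_se_cells = sqrt(.data$sigma_x_se_cells^2 + .data$se_base^2)
  )
  dplyr::select(out, dplyr::all_of(c(keys, "n", "delta_sigma_cells",
                                     "delta_se_cells")))
}

#' Pre-configured sweep designs
#'
#' Returns the base configuration and sweep axes of the package's standard
#' experiment designs, covering cell-area variability, cell-size scaling,
#' decay non-linearity along the domain, production-only noise, the three
#' source representations with increasing source variability, and
#' source-strength sweeps near and far from the source.
#'
#' @param name One of `"cell_area_cv"`, `"cell_size_scaling"`,
#'   `"decay_order_profile"`, `"production_only"`, `"domain_length"`,
#'   `"source_cv_source"`, `"source_cv_flux"`, `"source_cv_dirichlet"`,
#'   `"source_strength_near"`, `"source_strength_far"`.
#' @return List with elements `config` (a [sim_config()]) and `sweep` (axes
#'   for [run_sweep()]).
#' @export
preset_sweep <- function(name = c("cell_area_cv", "cell_size_scaling",
                                  "decay_order_profile", "production_only",
                                  "domain_length", "source_cv_source",
                                  "source_cv_flux", "source_cv_dirichlet",
                                  "source_strength_near",
                                  "source_strength_far")) {
  name <- match.arg(name)
  along_domain <- c(2, 5, 10, 25, 50, 75, 100, 125, 150, 175, 190)
  switch(name,
    cell_area_cv = list(
      config = sim_config(x_targets_cells = c(5, 75, 150)),
      sweep = list(cv_A = c(0, 0.3, 0.5, 0.9), n = c(1, 2, 4))
    ),
    cell_size_scaling = list(
      config = sim_config(Lp_cells = 100, x_targets_cells = 15),
      sweep = list(mu_delta = 20 / c(16, 8, 4, 2), n = c(1, 2))
    ),
    decay_order_profile = list(
      config = sim_config(x_targets_cells = along_domain),
      sweep = list(n = 1:4)
    ),
    production_only = list(
      config = sim_config(cv_d = 0, cv_D = 0, x_targets_cells = along_domain),
      sweep = list(n = 1:4)
    ),
    domain_length = list(
      config = sim_config(x_targets_cells = c(5, 25, 45)),
      sweep = list(Lp_cells = c(50, 100, 150, 200), n = c(1, 2))
    ),
    source_cv_source = list(
      config = sim_config(x_targets_cells = c(5, 150)),
      sweep = list(cv_p = c(0.01, 0.05, 0.1, 0.3, 0.5, 1), n = c(1, 2, 4))
    ),
    source_cv_flux = list(
      config = sim_config(bc = "flux", x_targets_cells = c(5, 150)),
      sweep = list(cv_j0 = c(0.01, 0.05, 0.1, 0.3, 0.5, 1), n = c(1, 2, 4))
    ),
    source_cv_dirichlet = list(
      config = sim_config(bc = "dirichlet", x_targets_cells = c(5, 150)),
      sweep = list(cv_C0 = c(0.01, 0.05, 0.1, 0.3, 0.5, 1), n = c(1, 2, 4))
    ),
    source_strength_near = list(
      config = sim_config(x_targets_cells = 5),
      sweep = list(production_factor = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                   n = c(1, 2, 4))
    ),
    source_strength_far = list(
      config = sim_config(x_targets_cells = 150),
      sweep = list(production_factor = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                   n = c(1, 2, 4))
    )
  )
}

#' Run a pre-configured sweep
#'
#' @inheritParams preset_sweep
#' @param n_replicates Ensemble size per sweep point; the scaled-down
#'   default of 300 reproduces the qualitative orderings of full-size runs.
#' @param seed Master seed.
#' @return Tidy sweep table (see [run_sweep()]).
#' @export
run_preset <- function(name, n_replicates = 300, seed = 1) {
  ps <- preset_sweep(name)
  run_sweep(ps$config, ps$sweep, n_replicates = n_replicates, seed = seed)
}

#' Quick solver validation against the closed-form gradients
#'
#' Compares the numerical steady state with the exponential and shifted
#' power-law closed forms on noise-free domains and checks the
#' production/degradation flux balance.
#'
#' @param points_per_cell Mesh resolution for the exponential check; the
#'   default resolves the closed form to about 1e-6 relative error.
#' @return Tibble of checks with measured errors and pass flags.
#' @export
validate_solver <- function(points_per_cell = 400) {
  kin <- kinetic_spec(cv_p = 0, cv_d = 0, cv_D = 0)
  ref <- deterministic_reference(kin, Ls = 25, Lp = 1000, mu_delta = 5,
                                 points_per_cell = points_per_cell)
  exact <- cosh_closed_form(ref$x, p = kin$mu_p, d = kin$mu_d, D = kin$mu_D,
                            Ls = 25, Lp = 1000)
  err_cosh <- max(abs(ref$C - exact) / exact)

  # The power-law comparison must stay clear of the distal no-flux boundary:
  # with non-linear decay the gradient flattens over a range comparable to
  # half the domain, so compare only over the proximal quarter of a long
  # domain, where the semi-infinite closed form applies.
  kin2 <- kinetic_spec(n = 2, cv_p = 0, cv_d = 0, cv_D = 0)
  src <- source_spec("dirichlet", mu_C0 = 1, cv_C0 = 0)
  ref2 <- deterministic_reference(kin2, source = src, Lp = 4000, mu_delta = 5,
                                  points_per_cell = 20)
  keep <- ref2$x <= 1000
  exact2 <- analytic_power_law(ref2$x[keep], C0 = 1, D = kin2$mu_D,
                               d = kin2$mu_d, n = 2)
  err_pl <- max(abs(ref2$C[keep] - exact2) / exact2)

  bal <- abs(flux_balance(ref)$relative_imbalance)
  tibble::tibble(
    check = c("exponential_closed_form", "power_law_closed_form",
              "flux_balance"),
    error = c(err_cosh, err_pl, bal),
    tolerance = c(1e-6, 0.01, 1e-3),
    pass = .data$error <= .data$tolerance
  )
}

# internal: piecewise cosh steady state for n = 1, uniform parameters,
# zero-flux at both outer ends. a*cosh((x+Ls)/lambda) + p/d in the source,
# b*cosh((Lp-x)/lambda) in the patterning region, matched at x = 0.
cosh_closed_form <- function(x, p, d, D, Ls, Lp) {
  lam <- sqrt(D / d)
  b <- (p / d) / (cosh(Lp / lam) + sinh(Lp / lam) / tanh(Ls / lam))
  a <- -b * sinh(Lp / lam) / sinh(Ls / lam)
  ifelse(x < 0,
         p / d + a * cosh((x + Ls) / lam),
         b * cosh((Lp - x) / lam))
}
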