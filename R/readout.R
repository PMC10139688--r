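#' Map a nominal readout position to a threshold concentration
#'
#' Returns the cell-averaged concentration of the reference cell containing
#' `x_target`. Thresholds defined this way are noise-independent and
#' reproducible: the same deterministic reference maps every target position
#' to its concentration threshold before any noisy ensemble is run.
#'
#' @param reference A noise-free `gradient_realization`, typically from
#'   [deterministic_reference()].
#' @param x_target Nominal readout position in micrometres, in `[0, Lp]`.
#' @return Threshold concentration \eqn{C_\theta}.
#' @export
threshold_from_reference <- function(reference, x_target) {
  stopifnot(inherits(reference, "gradient_realization"))
  if (!is.numeric(x_target) || any(x_target < 0) ||
      any(x_target > reference$domain$Lp)) {
    abort("`x_target` must lie within the patterning domain [0, Lp].",
          class = "morphosim_range_error")
  }
  pat <- dplyr::filter(reference$cells, !.data$is_source)
  idx <- findInterval(x_target, pat$x_left, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(pat))
  pat$C_avg[idx]
}

#' Threshold readout position on one noisy gradient
#'
#' Scans the patterning cells in order of increasing `x` and returns the
#' source-facing border of the first cell whose averaged concentration falls
#' below the threshold — the position where the fate boundary forms. If no
#' cell subceeds the threshold the readout is censored (`NA`).
#'
#' @param realization A `gradient_realization`.
#' @param C_theta Threshold concentration (>= 0; a zero threshold is always
#'   censored since concentrations are positive).
#' @return Position in micrometres, or `NA_real_` if censored.
#' @examples
#' dom <- uniform_domain(5, 25, 250)
#' fld <- sample_kinetic_field(kinetic_spec(cv_p = 0, cv_d = 0, cv_D = 0), dom)
#' sol <- solve_steady_state(dom, fld)
#' read_position(sol, threshold_from_reference(sol, 100))
#' @export
read_position <- function(realization, C_theta) {
  stopifnot(inherits(realization, "gradient_realization"))
  check_positive_scalar(C_theta, "C_theta", allow_zero = TRUE)
  pat <- realization$cells[!realization$cells$is_source, ]
  hit <- which(pat$C_avg < C_theta)
  if (length(hit) == 0L) {
    return(NA_real_)
  }
  pat$x_left[hit[1L]]
}

#' Simulate one gradient realisation of a configuration
#'
#' Draws a fresh cellular domain, kinetic field and (if applicable) source
#' boundary value under the given seed and solves the steady state. Exposed
#' so that any single replicate of an ensemble can be re-simulated in
#' isolation from its sub-seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this replicate.
#' @return A `gradient_realization`.
#' @export
simulate_replicate <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  dom <- sample_domain(config$area, Ls = config$Ls, Lp = config$Lp)
  fld <- sample_kinetic_field(config$kinetics, dom)
  bc_value <- if (config$source$mode == "source") NULL else
    sample_source_boundary(config$source)
  solve_steady_state(dom, fld, source = config$source, bc_value = bc_value,
                     points_per_cell = config$points_per_cell)
}

#' Run a Monte-Carlo ensemble of noisy gradients and read them out
#'
#' Repeats the full generative pipeline — sample a cellular domain, sample
#' per-cell kinetics (and the source boundary draw where applicable), solve
#' the steady state, read out the threshold positions — for `n_replicates`
#' statistically independent tissues. Thresholds for the configured target
#' positions are mapped once from the noise-free reference gradient of the
#' same configuration. Replicates where the solver fails are recorded and
#' excluded; replicates where no cell subceeds a threshold are censored for
#' that threshold.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of independent realisations (>= 2).
#' @param seed Master seed; each replicate runs on an independently derived
#'   sub-seed, so results do not depend on execution order.
#' @param record_at Optional positions (micrometres) at which the sensed
#'   (cell-averaged) concentration of the containing cell is recorded per
#'   replicate, for local concentration-noise estimates.
#' @return A `readout_ensemble`: tibble with one row per replicate x target
#'   (`replicate`, `x_target`, `threshold`, `position`), with the
#'   configuration, sub-seeds, failure count, recorded concentrations and
#'   reference gradient attached as attributes. If more than 20% of
#'   replicates fail or are censored at any target, the ensemble is flagged
#'   unreliable with a warning.
#' @examples
#' cfg <- sim_config(Lp_cells = 50, x_targets_cells = 10, n_replicates = 2)
#' ens <- run_ensemble(cfg, n_replicates = 5, seed = 1)
#' positional_error(ens, n_bootstrap = 100)
#' @export
run_ensemble <- function(config, n_replicates = config$n_replicates,
                         seed = config$seed, record_at = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_replicates < 2) {
    abort("`n_replicates` must be >= 2.", class = "morphosim_invalid_parameter")
  }
  reference <- deterministic_reference(
    config$kinetics, source = config$source, Ls = config$Ls, Lp = config$Lp,
    mu_delta = config$area$mu_delta, points_per_cell = config$points_per_cell
  )
  x_targets <- config$x_targets
  thresholds <- threshold_from_reference(reference, x_targets)
  seeds <- derive_seeds(seed, n_replicates)

  one <- function(j) {
    real <- tryCatch(simulate_replicate(config, seeds[j]),
                     morphosim_solver_failure = function(e) NULL)
    if (is.null(real)) {
      return(list(pos = rep(NA_real_, length(x_targets)), failed = TRUE,
                  sensed = rep(NA_real_, length(record_at))))
    }
    pos <- vapply(thresholds, function(ct) read_position(real, ct), 0)
    sensed <- if (length(record_at)) {
      pat <- real$cells[!real$cells$is_source, ]
      ii <- findInterval(record_at, pat$x_left, rightmost.closed = TRUE)
      pat$C_avg[pmin(pmax(ii, 1L), nrow(pat))]
    } else {
      numeric(0)
    }
    list(pos = pos, failed = FALSE, sensed = sensed)
  }
  runs <- purrr::map(seq_len(n_replicates), one)
  failed <- purrr::map_lgl(runs, "failed")
  pos_mat <- do.call(rbind, purrr::map(runs, "pos"))
  out <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                            target = seq_along(x_targets))
  out <- dplyr::mutate(out,
                       x_target = x_targets[.data$target],
                       threshold = thresholds[.data$target],
                       position = pos_mat[cbind(.data$replicate, .data$target)],
                       failed = failed[.data$replicate])
  out <- dplyr::select(out, -"target")
  bad_share <- dplyr::summarise(
    dplyr::group_by(out, .data$x_target),
    share = mean(.data$failed | is.na(.data$position))
  )
  unreliable <- any(bad_share$share > 0.2)
  if (unreliable) {
    warn(paste0(
      "More than 20% of replicates failed or were censored at some target; ",
      "the positional error may not be reliably determined in this regime."
    ))
  }
  sensed <- if (length(record_at)) {
    do.call(rbind, purrr::map(runs, "sensed"))
  } else {
    NULL
  }
  structure(out,
            config = config, seed = seed, sub_seeds = seeds,
            n_replicates = n_replicates, n_failed = sum(failed),
            record_at = record_at, sensed = sensed,
            reference = reference, unreliable = unreliable,
            mu_delta = config$area$mu_delta,
            class = c("readout_ensemble", class(out)))
}

#' @rdname tidy-morphosim
#' @export
tidy.readout_ensemble <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Positional error of a readout ensemble
#'
#' The positional error is the standard deviation of the readout positions
#' across gradient realisations, \eqn{\sigma_x = stddev[x_\theta]}; its
#' standard error is estimated by bootstrapping the replicate positions.
#' Censored and failed replicates are excluded (not imputed), and their
#' counts are reported.
#'
#' @param ensemble A `readout_ensemble` from [run_ensemble()].
#' @param n_bootstrap Bootstrap resamples for the standard error.
#' @return A `precision_summary` tibble, one row per target position:
#'   `x_target`, `threshold`, `n_used`, `n_censored`, `n_failed`, `mu_x`,
#'   `sigma_x`, `sigma_x_se`, and the same positions/errors in units of the
#'   mean cell diameter (`x_target_cells`, `sigma_x_cells`,
#'   `sigma_x_se_cells`).
#' @export
positional_error <- function(ensemble, n_bootstrap = 1000) {
  stopifnot(inherits(ensemble, "readout_ensemble"))
  mu_delta <- attr(ensemble, "mu_delta")
  n_failed_total <- attr(ensemble, "n_failed")
  summarise_one <- function(df) {
    pos <- df$position[!df$failed & !is.na(df$position)]
    if (length(pos) < 2) {
      abort("Fewer than 2 uncensored readout positions: positional error undefined.",
            class = "morphosim_undefined_precision")
    }
    boots <- vapply(seq_len(n_bootstrap), function(b) {
      sd(sample(pos, replace = TRUE))
    }, 0)
    tibble::tibble(
      n_used = length(pos),
      n_censored = sum(!df$failed & is.na(df$position)),
      n_failed = sum(df$failed),
      mu_x = mean(pos),
      sigma_x = sd(pos),
      sigma_x_se = sd(boots)
    )
  }
  out <- dplyr::reframe(
    dplyr::group_by(ensemble, .data$x_target, .data$threshold),
    summarise_one(dplyr::pick(dplyr::everything()))
  )
  out <- dplyr::mutate(dplyr::ungroup(out),
                       x_target_cells = .data$x_target / mu_delta,
                       sigma_x_cells = .data$sigma_x / mu_delta,
                       sigma_x_se_cells = .data$sigma_x_se / mu_delta)
  structure(out, mu_delta = mu_delta,
            class = c("precision_summary", class(out)))
}

#' @rdname glance-morphosim
#' @export
glance.readout_ensemble <- function(x, ...) {
  tibble::tibble(
    n_replicates = attr(x, "n_replicates"),
    n_targets = length(unique(x$x_target)),
    n_failed = attr(x, "n_failed"),
    n_censored = sum(!x$failed & is.na(x$position)),
    unreliable = attr(x, "unreliable"),
    seed = attr(x, "seed")
  )
}

#' Standard deviation of the sensed concentration at a recorded position
#'
#' Requires the ensemble to have been run with `record_at` covering `x`.
#'
#' @param ensemble A `readout_ensemble` run with `record_at`.
#' @param x One of the recorded positions.
#' @return Standard deviation of the cell-averaged concentration across
#'   replicates at `x`.
#' @export
sensed_sd <- function(ensemble, x) {
  record_at <- attr(ensemble, "record_at")
  sensed <- attr(ensemble, "sensed")
  if (is.null(sensed)) {
    abort("Ensemble was run without `record_at`; no concentrations recorded.",
          class = "morphosim_invalid_parameter")
  }
  j <- which(abs(record_at - x) < 1e-9)
  if (length(j) != 1L) {
    abort("`x` is not one of the recorded positions.",
          class = "morphosim_range_error")
  }
  sd(sensed[, j], na.rm = TRUE)
}

#' First-order prediction of the positional error
#'
#' To first order the positional error follows from the local concentration
#' noise and the gradient steepness:
#' \eqn{\sigma_x \approx |\partial C/\partial x|^{-1} \sigma_C}. Where the
#' deterministic slope vanishes — as it must at a distal zero-flux boundary —
#' the prediction diverges, which is the mechanism behind the loss of
#' precision near an impermeable tissue end.
#'
#' @param sigma_C Local standard deviation of the sensed concentration.
#' @param slope Local slope \eqn{\partial C/\partial x} of the reference
#'   gradient.
#' @return Predicted positional error in micrometres (`Inf`, with a warning,
#'   for zero slope).
#' @export
eq_first_order_sigma_x <- function(sigma_C, slope) {
  stopifnot(is.numeric(sigma_C), is.numeric(slope), sigma_C >= 0)
  if (slope == 0) {
    warn("Reference slope is zero: first-order positional error diverges.")
    return(Inf)
  }
  sigma_C / abs(slope)
}
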