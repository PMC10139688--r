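#' Closed-form exponential gradient for linear decay
#'
#' On a semi-infinite domain, linear decay (`n = 1`) gives
#' \eqn{C(x) = C_0 e^{-x/\lambda}} with decay length
#' \eqn{\lambda = \sqrt{D/d}}.
#'
#' @param x Position(s) in micrometres.
#' @param C0 Amplitude at `x = 0`.
#' @param D Diffusivity, square micrometres per second.
#' @param d Degradation rate, per second.
#' @return Concentration at `x` (vectorised over `x`).
#' @examples
#' analytic_exponential(20, C0 = 1, D = 0.033, d = 8.25e-5)  # = exp(-1)
#' @export
analytic_exponential <- function(x, C0, D, d) {
  check_positive_scalar(C0, "C0")
  check_positive_scalar(D, "D")
  check_positive_scalar(d, "d")
  C0 * exp(-x / sqrt(D / d))
}

#' Power-law exponent for non-linear decay
#'
#' Decay of order `n > 1` produces shifted power-law gradients with exponent
#' `m = 2 / (n - 1)`.
#'
#' @param n Decay exponent (> 1).
#' @return The power-law exponent `m`.
#' @export
power_law_exponent <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 1) {
    abort("`n` must be > 1 for a power-law gradient.",
          class = "morphosim_invalid_parameter")
  }
  2 / (n - 1)
}

#' Length scale of the shifted power-law gradient
#'
#' Substituting \eqn{C(x) = C_0 (1 + x/(m\lambda_m))^{-m}} into the
#' steady-state equation \eqn{0 = D C'' - d C^n / C_{ref}^{n-1}} on a
#' semi-infinite domain forces `m = 2/(n-1)` and fixes the length scale to
#' \deqn{\lambda_m = \sqrt{\frac{m+1}{m}\,\frac{D}{d}
#'   \left(\frac{C_{ref}}{C_0}\right)^{n-1}}.}
#' Unlike the exponential decay length, \eqn{\lambda_m} depends on the
#' amplitude `C0`: higher amplitudes steepen the gradient near the source.
#'
#' @inheritParams analytic_exponential
#' @param n Decay exponent (> 1).
#' @param C_ref Reference concentration.
#' @return The length scale in micrometres.
#' @examples
#' power_law_length(D = 0.033, d = 8.25e-5, n = 2)  # sqrt(1.5 * 400)
#' @export
power_law_length <- function(D, d, n, C0 = 1, C_ref = 1) {
  m <- power_law_exponent(n)
  check_positive_scalar(D, "D")
  check_positive_scalar(d, "d")
  check_positive_scalar(C0, "C0")
  check_positive_scalar(C_ref, "C_ref")
  sqrt((m + 1) / m * (D / d) * (C_ref / C0)^(n - 1))
}

#' Closed-form shifted power-law gradient for non-linear decay
#'
#' \eqn{C(x) = C_0 (1 + x/(m\lambda_m))^{-m}} with `m` from
#' [power_law_exponent()] and `lambda_m` from [power_law_length()]; an exact
#' steady state of the reaction-diffusion equation on a semi-infinite domain.
#'
#' @inheritParams power_law_length
#' @param x Position(s) in micrometres.
#' @return Concentration at `x` (vectorised over `x`).
#' @export
analytic_power_law <- function(x, C0, D, d, n, C_ref = 1) {
  m <- power_law_exponent(n)
  lm_ <- power_law_length(D, d, n, C0 = C0, C_ref = C_ref)
  C0 * (1 + x / (m * lm_))^(-m)
}

#' Construct an analytic reference gradient
#'
#' Bundles the closed-form exponential (`n = 1`) or shifted power-law
#' (`n > 1`) steady-state profile with its parameters, for threshold readout
#' and shift analysis.
#'
#' @inheritParams power_law_length
#' @param n Decay exponent (>= 1); 1 selects the exponential form.
#' @return An `analytic_gradient` object with an `eval` function and, for the
#'   exponential form, `lambda`, or, for the power-law form, `m` and
#'   `lambda_m`.
#' @examples
#' g <- analytic_gradient(C0 = 1, D = 0.033, d = 8.25e-5, n = 1)
#' readout_position(g, C_theta = exp(-1))  # 20 um
#' @export
analytic_gradient <- function(C0, D, d, n = 1, C_ref = 1) {
  check_positive_scalar(C0, "C0")
  if (n == 1) {
    g <- list(form = "exponential", C0 = C0, D = D, d = d, n = 1,
              C_ref = C_ref, lambda = sqrt(D / d))
  } else {
    g <- list(form = "power_law", C0 = C0, D = D, d = d, n = n,
              C_ref = C_ref, m = power_law_exponent(n),
              lambda_m = power_law_length(D, d, n, C0 = C0, C_ref = C_ref))
  }
  structure(g, class = "analytic_gradient")
}

#' Threshold readout position of an analytic gradient
#'
#' Inverts the closed-form profile: for the exponential,
#' \eqn{x_\theta = \lambda \log(C_0/C_\theta)}; for the power law,
#' \eqn{x_\theta = m\lambda_m ((C_0/C_\theta)^{1/m} - 1)}.
#'
#' @param gradient An [analytic_gradient()].
#' @param C_theta Readout threshold concentration (> 0, below the amplitude).
#' @return Position in micrometres.
#' @export
readout_position <- function(gradient, C_theta) {
  stopifnot(inherits(gradient, "analytic_gradient"))
  check_positive_scalar(C_theta, "C_theta")
  if (C_theta > gradient$C0) {
    abort("Threshold lies above the gradient amplitude: no readout position.",
          class = "morphosim_no_readout")
  }
  if (gradient$form == "exponential") {
    gradient$lambda * log(gradient$C0 / C_theta)
  } else {
    gradient$m * gradient$lambda_m *
      ((gradient$C0 / C_theta)^(1 / gradient$m) - 1)
  }
}

#' Shift of a readout position under an amplitude change
#'
#' Computes \eqn{\Delta x = x_\theta(\rho C_0) - x_\theta(C_0)} for a fixed
#' threshold when the gradient amplitude is scaled by `amplitude_factor`
#' \eqn{\rho}. For exponential gradients the shift is
#' \eqn{\lambda \log \rho}, independent of the absolute amplitude. For
#' shifted power-law gradients the length scale is recomputed at the scaled
#' amplitude, so the shift shrinks as the absolute amplitude grows — the
#' higher the morphogen supply, the more rigid the power-law profile.
#'
#' @param gradient An [analytic_gradient()].
#' @param C_theta Readout threshold (> 0), below the amplitude both before
#'   and after scaling.
#' @param amplitude_factor Fold change \eqn{\rho > 0} of the amplitude.
#' @return Shift in micrometres (positive for `amplitude_factor > 1`).
#' @examples
#' g <- analytic_gradient(C0 = 1, D = 0.033, d = 8.25e-5, n = 1)
#' readout_shift(g, C_theta = 0.1, amplitude_factor = 2)  # 20 * log(2)
#' @export
readout_shift <- function(gradient, C_theta, amplitude_factor) {
  stopifnot(inherits(gradient, "analytic_gradient"))
  check_positive_scalar(amplitude_factor, "amplitude_factor")
  scaled <- analytic_gradient(C0 = amplitude_factor * gradient$C0,
                              D = gradient$D, d = gradient$d,
                              n = gradient$n, C_ref = gradient$C_ref)
  readout_position(scaled, C_theta) - readout_position(gradient, C_theta)
}
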