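#' Specify mean morphogen kinetics and their cell-to-cell variability
#'
#' Defaults follow measurements of the Hedgehog gradient in the Drosophila
#' wing disc and the mouse neural tube: mean diffusivity
#' \eqn{\mu_D = 0.033\ \mu m^2/s} and mean exponential gradient length
#' \eqn{\mu_\lambda = 20\ \mu m}, from which the mean degradation rate is
#' \eqn{\mu_d = \mu_D/\mu_\lambda^2} and the mean production rate
#' \eqn{\mu_p = \mu_d C_{ref}}. Physiological noise in production, decay and
#' transport is around CV = 0.3. Concentrations are reported in arbitrary
#' units with \eqn{C_{ref} = 1}; only the ratio \eqn{D/d} matters at steady
#' state, so these choices fix length scales without loss of generality.
#'
#' @param mu_D Mean diffusivity, square micrometres per second.
#' @param mu_lambda Mean gradient decay length, micrometres; sets
#'   `mu_d = mu_D / mu_lambda^2` when `mu_d` is not given.
#' @param mu_d Mean degradation rate, per second.
#' @param mu_p Mean production rate, concentration per second; default
#'   `mu_d * C_ref`.
#' @param cv_p,cv_d,cv_D Coefficients of variation of the per-cell kinetic
#'   parameters (>= 0).
#' @param n Decay exponent (>= 1): 1 for linear decay, > 1 for self-enhanced
#'   (non-linear) decay.
#' @param C_ref Reference concentration that renders units independent of
#'   `n`; 1 arbitrary unit by default.
#' @return A `kinetic_spec` object.
#' @examples
#' default_kinetics()
#' kinetic_spec(n = 2, cv_p = 0)
#' @export
kinetic_spec <- function(mu_D = 0.033, mu_lambda = 20,
                         mu_d = mu_D / mu_lambda^2, mu_p = mu_d * C_ref,
                         cv_p = 0.3, cv_d = 0.3, cv_D = 0.3,
                         n = 1, C_ref = 1) {
  check_positive_scalar(mu_D, "mu_D")
  check_positive_scalar(mu_d, "mu_d")
  check_positive_scalar(mu_p, "mu_p")
  check_positive_scalar(C_ref, "C_ref")
  for (nm in c("cv_p", "cv_d", "cv_D")) {
    check_positive_scalar(get(nm), nm, allow_zero = TRUE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a decay exponent >= 1.",
          class = "morphosim_invalid_parameter")
  }
  structure(
    list(mu_p = mu_p, mu_d = mu_d, mu_D = mu_D,
         cv_p = cv_p, cv_d = cv_d, cv_D = cv_D,
         n = n, C_ref = C_ref),
    class = "kinetic_spec"
  )
}

#' @rdname kinetic_spec
#' @export
default_kinetics <- function() {
  kinetic_spec()
}

#' @export
print.kinetic_spec <- function(x, ...) {
  cat(sprintf(
    "<kinetic_spec> n = %g | mu_p = %.3g, mu_d = %.3g, mu_D = %.3g | CVs = (%g, %g, %g) | C_ref = %g\n",
    x$n, x$mu_p, x$mu_d, x$mu_D, x$cv_p, x$cv_d, x$cv_D, x$C_ref
  ))
  invisible(x)
}

#' Draw per-cell kinetic parameters for one tissue realisation
#'
#' Each cell receives an independent log-normal draw of its production rate
#' `p`, degradation rate `d` and diffusivity `D`. Parameters are constant
#' within a cell and jump at cell borders; production only acts in source
#' cells (the solver masks `p` outside the source).
#'
#' @param spec A [kinetic_spec()].
#' @param domain A `cell_domain` from [sample_domain()].
#' @return A `kinetic_field`: tibble (`cell`, `p`, `d`, `D`) with the decay
#'   exponent `n` and `C_ref` carried as attributes.
#' @examples
#' set.seed(1)
#' dom <- sample_domain(area_spec(), Ls = 25, Lp = 100)
#' sample_kinetic_field(default_kinetics(), dom)
#' @export
sample_kinetic_field <- function(spec, domain) {
  stopifnot(inherits(spec, "kinetic_spec"), inherits(domain, "cell_domain"))
  nc <- nrow(domain$cells)
  field <- tibble::tibble(
    cell = domain$cells$cell,
    p = rlnorm_mean_cv(nc, spec$mu_p, spec$cv_p),
    d = rlnorm_mean_cv(nc, spec$mu_d, spec$cv_d),
    D = rlnorm_mean_cv(nc, spec$mu_D, spec$cv_D)
  )
  structure(field, n = spec$n, C_ref = spec$C_ref,
            class = c("kinetic_field", class(field)))
}

#' Specify how the morphogen source is represented
#'
#' Three source models are supported: an explicit source domain of
#' morphogen-secreting cells on `x < 0` (`"source"`), a flux boundary
#' condition \eqn{-D\,\partial C/\partial x|_{x=0} = j_0} (`"flux"`), and a
#' Dirichlet boundary condition \eqn{C(0) = C_0} (`"dirichlet"`). In the two
#' boundary-condition modes the influx or amplitude is itself a log-normal
#' draw per realisation, standing in for production noise. Default means are
#' \eqn{\mu_{j0} = \mu_D C_{ref}/\mu_\lambda} and \eqn{\mu_{C0} = C_{ref}},
#' chosen so all three modes produce comparable noise-free gradients.
#'
#' @param mode One of `"source"`, `"flux"`, `"dirichlet"`.
#' @param mu_j0 Mean influx (concentration x um / s), flux mode.
#' @param mu_C0 Mean amplitude (concentration), Dirichlet mode.
#' @param cv_j0,cv_C0 Coefficients of variation of the respective draws.
#' @return A `source_spec` object.
#' @export
source_spec <- function(mode = c("source", "flux", "dirichlet"),
                        mu_j0 = 0.033 * 1 / 20, mu_C0 = 1,
                        cv_j0 = 0, cv_C0 = 0) {
  mode <- match.arg(mode)
  check_positive_scalar(mu_j0, "mu_j0")
  check_positive_scalar(mu_C0, "mu_C0")
  check_positive_scalar(cv_j0, "cv_j0", allow_zero = TRUE)
  check_positive_scalar(cv_C0, "cv_C0", allow_zero = TRUE)
  structure(list(mode = mode, mu_j0 = mu_j0, mu_C0 = mu_C0,
                 cv_j0 = cv_j0, cv_C0 = cv_C0),
            class = "source_spec")
}

#' Draw the source boundary value for one realisation
#'
#' @param spec A [source_spec()] in `"flux"` or `"dirichlet"` mode.
#' @return A single positive draw of `j0` (flux mode) or `C0` (Dirichlet
#'   mode).
#' @export
sample_source_boundary <- function(spec) {
  stopifnot(inherits(spec, "source_spec"))
  switch(spec$mode,
    flux = rlnorm_mean_cv(1L, spec$mu_j0, spec$cv_j0),
    dirichlet = rlnorm_mean_cv(1L, spec$mu_C0, spec$cv_C0),
    abort(
      "Source-domain mode has no boundary draw; production is sampled per cell.",
      class = "morphosim_invalid_mode"
    )
  )
}
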