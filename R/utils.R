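#' @importFrom rlang abort warn %||%
#' @importFrom stats rlnorm sd quantile approx coef lm
NULL

# internal: validate a single positive finite scalar
check_positive_scalar <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name),
          class = "morphosim_invalid_parameter")
  }
  if (allow_zero && x < 0) {
    abort(sprintf("`%s` must be >= 0.", name),
          class = "morphosim_invalid_parameter")
  }
  if (!allow_zero && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name),
          class = "morphosim_invalid_parameter")
  }
  invisible(x)
}

#' Draw log-normal variates with a given mean and coefficient of variation
#'
#' Parameterises the log-normal by its arithmetic mean `mean` and coefficient
#' of variation `cv` via moment matching: `sdlog^2 = log(1 + cv^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`. With `cv = 0` the draw degenerates to
#' the constant `mean`, which keeps noise-free configurations on the same code
#' path as noisy ones.
#'
#' @param n Number of draws.
#' @param mean Arithmetic mean of the distribution (> 0).
#' @param cv Coefficient of variation (>= 0).
#' @return Numeric vector of length `n`, strictly positive.
#' @examples
#' set.seed(1)
#' mean(rlnorm_mean_cv(1e4, 5, 0.5))
#' @export
rlnorm_mean_cv <- function(n, mean, cv) {
  check_positive_scalar(mean, "mean")
  check_positive_scalar(cv, "cv", allow_zero = TRUE)
  if (cv == 0) {
    return(rep(mean, n))
  }
  sdlog2 <- log1p(cv^2)
  rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Moment-matched log-normal parameters for a mean/CV pair
#'
#' @param mean Arithmetic mean (> 0).
#' @param cv Coefficient of variation (>= 0).
#' @return List with `meanlog` and `sdlog`.
#' @keywords internal
#' @export
lnorm_params <- function(mean, cv) {
  sdlog2 <- log1p(cv^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# internal: derive independent sub-seeds from one master seed so that any
# replicate or sweep point can be re-simulated in isolation.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
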