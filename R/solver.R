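#' @useDynLib morphosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# internal: build the computational mesh for a cellular domain.
# Every cell border is a mesh node; each cell is subdivided into
# `points_per_cell` equal sub-intervals. Returns node positions, per-face
# cell index and per-face width.
build_mesh <- function(domain, points_per_cell) {
  cells <- domain$cells
  k <- as.integer(points_per_cell)
  stopifnot(k >= 2)
  nc <- nrow(cells)
  frac <- seq_len(k) / k
  x <- c(cells$x_left[1],
         as.vector(t(outer(cells$diameter, frac) + cells$x_left)))
  # pin borders exactly (outer() re-adds rounding at each border)
  x[1 + k * seq_len(nc)] <- cells$x_right
  list(x = x,
       face_cell = rep(seq_len(nc), each = k),
       face_h = rep(cells$diameter / k, each = k),
       k = k)
}

# internal: one damped-Newton solve on a fixed mesh.
# Returns list(C, converged, iterations, residual_norm).
newton_solve <- function(mesh, field, domain, n, C_ref, bc,
                         C_init, max_iter = 50L, rtol = 1e-9, atol = NULL) {
  atol <- atol %||% (1e-12 * C_ref)
  cells <- domain$cells
  a <- field$D[mesh$face_cell] / mesh$face_h
  w <- mesh$face_h / 2
  np <- length(mesh$x)
  dvol <- numeric(np)
  pvol <- numeric(np)
  d_f <- field$d[mesh$face_cell] * w
  p_f <- ifelse(cells$is_source[mesh$face_cell], field$p[mesh$face_cell], 0) * w
  idx <- seq_len(np - 1L)
  dvol[idx] <- dvol[idx] + d_f
  dvol[idx + 1L] <- dvol[idx + 1L] + d_f
  pvol[idx] <- pvol[idx] + p_f
  pvol[idx + 1L] <- pvol[idx + 1L] + p_f

  dirichlet <- identical(bc$mode, "dirichlet")
  BL <- if (identical(bc$mode, "flux")) bc$value else 0
  crefp <- C_ref^(n - 1)

  residual <- function(C) {
    flux <- a * (C[idx] - C[idx + 1L])
    R <- c(flux, 0) - c(BL, flux) + dvol * C^n / crefp - pvol
    if (dirichlet) R[1L] <- C[1L] - bc$value
    R
  }

  C <- pmax(C_init, 0)
  R <- residual(C)
  res_scale <- max(pvol, dvol * C_ref, a * C_ref, 1e-300)
  rnorm0 <- max(abs(R))
  if (!is.finite(rnorm0)) {
    return(list(C = C, converged = FALSE, iterations = 0L,
                residual_norm = rnorm0 / res_scale))
  }
  converged <- FALSE
  iter <- 0L
  rnorm <- rnorm0
  while (iter < max_iter) {
    if (rnorm <= 1e-12 * res_scale) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    diag <- c(a, 0) + c(0, a) + n * dvol * pmax(C, 0)^(n - 1) / crefp
    upper <- -a
    lower <- -a
    if (dirichlet) {
      diag[1L] <- 1
      upper[1L] <- 0
    }
    delta <- solve_tridiag(lower, diag, upper, -R)
    if (!all(is.finite(delta))) break
    # damped step with positivity clamp
    t <- 1
    repeat {
      C_new <- pmax(C + t * delta, 0)
      R_new <- residual(C_new)
      rn <- max(abs(R_new))
      if (is.finite(rn) && (rn < rnorm || t <= 1 / 4096)) break
      t <- t / 2
    }
    step <- max(abs(C_new - C))
    C <- C_new
    R <- R_new
    rnorm <- rn
    if (step <= rtol * max(abs(C)) + atol && rnorm <= 1e-8 * res_scale) {
      converged <- TRUE
      break
    }
  }
  list(C = C, converged = converged, iterations = iter,
       residual_norm = rnorm / res_scale)
}

# internal: initial guess on a mesh. For n = 1 the problem is linear and the
# first Newton step from zero is the exact direct solve, which avoids
# catastrophic cancellation in the deep gradient tail (an analytic warm start
# there is correct only to a few digits, and guess + delta would subtract
# nearly equal numbers where C underflows dozens of orders of magnitude).
# For n > 1 the closed-form gradient with the field's mean parameters is
# used; power-law tails are fat, so no cancellation arises.
initial_guess <- function(mesh, field, domain, n, C_ref, bc) {
  if (n == 1) {
    return(numeric(length(mesh$x)))
  }
  d_bar <- mean(field$d)
  D_bar <- mean(field$D)
  lam <- sqrt(D_bar / d_bar)
  src <- domain$cells$is_source
  C0g <- switch(bc$mode,
    source = {
      if (!any(src) || all(field$p[src] == 0)) 0 else {
        p_bar <- mean(field$p[src])
        t <- tanh(domain$Ls / lam)
        (p_bar / d_bar) * t / (1 + t)
      }
    },
    flux = {
      if (bc$value <= 0) 0 else {
        C0 <- C_ref
        for (i in 1:30) {
          C0 <- bc$value * power_law_length(D_bar, d_bar, n, C0 = max(C0, 1e-12),
                                            C_ref = C_ref) / D_bar
        }
        C0
      }
    },
    dirichlet = bc$value
  )
  if (C0g <= 0) {
    return(numeric(length(mesh$x)))
  }
  x <- mesh$x
  g <- numeric(length(x))
  pat <- x >= 0
  g[pat] <- analytic_power_law(x[pat], C0 = C0g, D = D_bar, d = d_bar,
                               n = n, C_ref = C_ref)
  g[!pat] <- C0g
  pmax(g, 0)
}

# internal: per-cell averaged concentration (length-normalised integral of
# the piecewise-linear mesh solution over each cell).
cell_average_concentration <- function(mesh, C, domain) {
  k <- mesh$k
  nc <- nrow(domain$cells)
  # trapezoid over each cell's k sub-intervals
  seg <- (C[-length(C)] + C[-1L]) / 2 * mesh$face_h
  as.vector(tapply(seg, mesh$face_cell, sum)) / domain$cells$diameter
}

#' Solve the steady-state reaction-diffusion equation on a cellular domain
#'
#' Solves \eqn{0 = D C'' - d C^n / C_{ref}^{n-1} + p\,H(-x)} with per-cell
#' constant coefficients, zero-flux conditions at both outer tissue ends
#' (source mode), or an influx/Dirichlet condition at `x = 0` when the
#' source is represented by a boundary condition. The discretisation is a
#' conservative finite-volume scheme whose nodes include every cell border,
#' so continuity of concentration and of the flux \eqn{-D C'} at cell
#' interfaces holds by construction; the non-linear system is solved by
#' damped Newton iteration started from the closed-form gradient with mean
#' parameters. On non-convergence the solver falls back to continuation in
#' the decay exponent and then to mesh refinement before failing.
#'
#' @param domain A `cell_domain`.
#' @param field A `kinetic_field` aligned with `domain` (same cells).
#' @param source A [source_spec()]; `"source"` mode uses the per-cell
#'   production rates on `x < 0`, the other modes impose the condition at
#'   `x = 0` (the domain may then have `Ls = 0`).
#' @param bc_value Influx `j0` (flux mode) or amplitude `C0` (Dirichlet
#'   mode) for this realisation; defaults to the mode's mean. Ignored in
#'   source mode.
#' @param points_per_cell Mesh sub-intervals per cell (default 8). Increase
#'   for high-accuracy reference solves.
#' @param max_iter Newton iteration cap per attempt.
#' @return A `gradient_realization`: mesh positions `x`, concentrations `C`,
#'   a `cells` tibble with per-cell averaged concentrations `C_avg`, the
#'   `field` used, and `diagnostics` (convergence flag, iterations, scaled
#'   residual norm, node count, refinements).
#' @examples
#' dom <- uniform_domain(5, Ls = 25, Lp = 250)
#' fld <- sample_kinetic_field(kinetic_spec(cv_p = 0, cv_d = 0, cv_D = 0), dom)
#' sol <- solve_steady_state(dom, fld)
#' head(tidy(sol))
#' @export
solve_steady_state <- function(domain, field, source = source_spec("source"),
                               bc_value = NULL, points_per_cell = 8,
                               max_iter = 50L) {
  stopifnot(inherits(domain, "cell_domain"), inherits(field, "kinetic_field"),
            inherits(source, "source_spec"))
  if (nrow(field) != nrow(domain$cells)) {
    abort("`field` and `domain` must have the same number of cells.",
          class = "morphosim_invalid_parameter")
  }
  if (source$mode != "source" && domain$Ls > 0) {
    abort("Flux/Dirichlet source modes require a domain without source cells (Ls = 0).",
          class = "morphosim_invalid_parameter")
  }
  n <- attr(field, "n")
  C_ref <- attr(field, "C_ref")
  bc <- list(
    mode = source$mode,
    value = switch(source$mode,
                   source = NA_real_,
                   flux = bc_value %||% source$mu_j0,
                   dirichlet = bc_value %||% source$mu_C0)
  )

  attempt <- function(ppc, use_continuation) {
    mesh <- build_mesh(domain, ppc)
    guess <- initial_guess(mesh, field, domain, n, C_ref, bc)
    if (use_continuation && n > 1) {
      exps <- unique(c(seq(1, n, length.out = 4L)[-1L], n))
      C <- newton_solve(mesh, field, domain, 1, C_ref, bc, guess,
                        max_iter = max_iter)$C
      fit <- NULL
      for (ni in exps) {
        fit <- newton_solve(mesh, field, domain, ni, C_ref, bc, C,
                            max_iter = max_iter)
        C <- fit$C
      }
      list(mesh = mesh, fit = fit)
    } else {
      list(mesh = mesh, fit = newton_solve(mesh, field, domain, n, C_ref, bc,
                                           guess, max_iter = max_iter))
    }
  }

  plan <- list(c(points_per_cell, FALSE), c(points_per_cell, TRUE),
               c(2 * points_per_cell, TRUE), c(4 * points_per_cell, TRUE))
  res <- NULL
  refinements <- 0L
  for (i in seq_along(plan)) {
    res <- attempt(plan[[i]][1], as.logical(plan[[i]][2]))
    refinements <- i - 1L
    if (res$fit$converged) break
  }
  if (!res$fit$converged) {
    abort(
      sprintf("Steady-state solver failed to converge (scaled residual %.3g after %d attempts).",
              res$fit$residual_norm, length(plan)),
      class = "morphosim_solver_failure",
      diagnostics = res$fit[c("iterations", "residual_norm")]
    )
  }
  C <- res$fit$C
  if (min(C) < -1e-8 * max(C, C_ref)) {
    abort("Solver produced negative concentrations beyond tolerance.",
          class = "morphosim_solver_failure")
  }
  cells <- domain$cells
  cells$C_avg <- cell_average_concentration(res$mesh, C, domain)
  structure(
    list(x = res$mesh$x, C = C, cells = cells, domain = domain, field = field,
         n = n, C_ref = C_ref, k = res$mesh$k,
         diagnostics = list(converged = TRUE,
                            iterations = res$fit$iterations,
                            residual_norm = res$fit$residual_norm,
                            n_nodes = length(C),
                            refinements = refinements)),
    class = "gradient_realization"
  )
}

#' @export
print.gradient_realization <- function(x, ...) {
  cat(sprintf(
    "<gradient_realization> n = %g, %d cells, %d nodes | amplitude C(0) = %.4g | residual %.2g\n",
    x$n, nrow(x$cells), length(x$C), profile_at(x, 0),
    x$diagnostics$residual_norm
  ))
  invisible(x)
}

#' @rdname tidy-morphosim
#' @export
tidy.gradient_realization <- function(x, ...) {
  dplyr::select(x$cells, "cell", "x_left", "x_right", "is_source", "C_avg")
}

#' Evaluate a solved concentration profile at arbitrary positions
#'
#' Linear interpolation of the finite-volume solution between mesh nodes.
#'
#' @param realization A `gradient_realization`.
#' @param x Positions in micrometres within `[-Ls, Lp]`.
#' @return Concentrations at `x`.
#' @export
profile_at <- function(realization, x) {
  stopifnot(inherits(realization, "gradient_realization"))
  approx(realization$x, realization$C, xout = x, rule = 2)$y
}

#' Local slope of a solved concentration profile
#'
#' Central-difference derivative of the mesh solution, interpolated to `x`.
#' Used for first-order positional-error predictions.
#'
#' @inheritParams profile_at
#' @return \eqn{\partial C/\partial x} at `x`.
#' @export
profile_slope_at <- function(realization, x) {
  stopifnot(inherits(realization, "gradient_realization"))
  xm <- realization$x
  dC <- diff(realization$C) / diff(xm)
  mid <- (xm[-1] + xm[-length(xm)]) / 2
  approx(mid, dC, xout = x, rule = 2)$y
}

#' Noise-free reference gradient for a parameter set
#'
#' Solves the steady state with all coefficients of variation set to zero on
#' a uniform-cell domain. Used to map nominal readout positions to threshold
#' concentrations and as the slope reference for first-order error
#' estimates.
#'
#' @param kinetics A [kinetic_spec()]; its CVs are ignored (treated as 0).
#' @param source A [source_spec()]; boundary draws use the means.
#' @param Ls,Lp Region lengths in micrometres.
#' @param mu_delta Cell diameter in micrometres.
#' @param points_per_cell Mesh resolution per cell.
#' @return A `gradient_realization`.
#' @examples
#' ref <- deterministic_reference(default_kinetics(), Ls = 25, Lp = 250,
#'                                mu_delta = 5)
#' profile_at(ref, c(0, 20, 40))
#' @export
deterministic_reference <- function(kinetics, source = source_spec("source"),
                                    Ls = 5 * mu_delta, Lp = 200 * mu_delta,
                                    mu_delta = 5, points_per_cell = 8) {
  stopifnot(inherits(kinetics, "kinetic_spec"))
  spec0 <- kinetics
  spec0$cv_p <- spec0$cv_d <- spec0$cv_D <- 0
  dom <- uniform_domain(mu_delta, Ls = if (source$mode == "source") Ls else 0,
                        Lp = Lp)
  fld <- sample_kinetic_field(spec0, dom)
  bc_value <- switch(source$mode, source = NULL, flux = source$mu_j0,
                     dirichlet = source$mu_C0)
  solve_steady_state(dom, fld, source = source, bc_value = bc_value,
                     points_per_cell = points_per_cell)
}

#' Production/degradation flux balance of a realisation
#'
#' At steady state with zero-flux outer boundaries, total production in the
#' source must equal total degradation over the tissue:
#' \eqn{\int_{source} p\,dx = \int d\,C^n/C_{ref}^{n-1}\,dx}. Returns both
#' integrals (trapezoidal quadrature of the mesh solution) and their
#' relative imbalance.
#'
#' @param realization A `gradient_realization` solved in source mode.
#' @return A tibble with `production`, `degradation` and
#'   `relative_imbalance`.
#' @export
flux_balance <- function(realization) {
  stopifnot(inherits(realization, "gradient_realization"))
  dom <- realization$domain
  fld <- realization$field
  mesh <- build_mesh(dom, realization$k)
  C <- realization$C
  idx <- seq_len(length(C) - 1L)
  seg_deg <- fld$d[mesh$face_cell] *
    (C[idx]^realization$n + C[idx + 1L]^realization$n) / 2 * mesh$face_h /
    realization$C_ref^(realization$n - 1)
  production <- sum(fld$p[dom$cells$is_source] *
                      dom$cells$diameter[dom$cells$is_source])
  degradation <- sum(seg_deg)
  tibble::tibble(
    production = production,
    degradation = degradation,
    relative_imbalance = (degradation - production) /
      max(production, .Machine$double.xmin)
  )
}
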