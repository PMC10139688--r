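# Independent reference solutions and fixture builders used across tests.

# Closed-form steady state for linear decay with uniform parameters on
# [-Ls, Lp], production p in the source, zero flux at both outer ends.
# Derived by matching value and flux of the homogeneous cosh branches at
# x = 0: C = p/d + a*cosh((x+Ls)/l) for x < 0, C = b*cosh((Lp-x)/l) for
# x > 0, with l = sqrt(D/d).
oracle_cosh_profile <- function(x, p, d, D, Ls, Lp) {
  l <- sqrt(D / d)
  b <- (p / d) / (cosh(Lp / l) + sinh(Lp / l) / tanh(Ls / l))
  a <- -b * sinh(Lp / l) / sinh(Ls / l)
  ifelse(x < 0, p / d + a * cosh((x + Ls) / l), b * cosh((Lp - x) / l))
}

# Cell average of the cosh closed form over [x0, x1] in the patterning
# region (antiderivative of cosh is sinh).
oracle_cosh_cell_average <- function(x0, x1, p, d, D, Ls, Lp) {
  l <- sqrt(D / d)
  b <- (p / d) / (cosh(Lp / l) + sinh(Lp / l) / tanh(Ls / l))
  b * l * (sinh((Lp - x0) / l) - sinh((Lp - x1) / l)) / (x1 - x0)
}

# Exact transfer-matrix oracle for n = 1 with per-cell piecewise-constant
# (d, D) on a source-free domain [0, Lp], Dirichlet C(0) = C0, no flux at
# Lp. Within each cell the solution is a cosh/sinh combination with local
# decay length sqrt(D_i/d_i); the state (C, F = D C') is continuous at cell
# borders, so propagating it exactly right-to-left from (1, 0) and rescaling
# by linearity gives the solution to machine precision. Returns a function
# of x.
oracle_transfer_linear <- function(domain, field, C0) {
  cells <- domain$cells
  nc <- nrow(cells)
  lam <- sqrt(field$D / field$d)
  # state at the right border of each cell, before rescaling
  Cr <- numeric(nc)
  Fr <- numeric(nc)
  Cv <- 1
  Fv <- 0
  for (i in rev(seq_len(nc))) {
    Cr[i] <- Cv
    Fr[i] <- Fv
    u <- cells$diameter[i] / lam[i]
    Cl <- Cv * cosh(u) - lam[i] * Fv / field$D[i] * sinh(u)
    Fl <- -field$D[i] / lam[i] * Cv * sinh(u) + Fv * cosh(u)
    Cv <- Cl
    Fv <- Fl
  }
  scale <- C0 / Cv
  function(x) {
    i <- findInterval(x, cells$x_left, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), nc)
    u <- (cells$x_right[i] - x) / lam[i]
    scale * (Cr[i] * cosh(u) - lam[i] * Fr[i] / field$D[i] * sinh(u))
  }
}

# Minimal hand-built gradient realization for unit-testing the readout,
# bypassing the solver.
fake_realization <- function(x_left, C_avg, is_source = NULL) {
  n <- length(C_avg)
  is_source <- is_source %||% rep(FALSE, n)
  width <- diff(c(x_left, x_left[n] + (x_left[n] - x_left[n - 1])))
  structure(
    list(cells = tibble::tibble(
      cell = seq_len(n), x_left = x_left, x_right = x_left + width,
      diameter = width, is_source = is_source, C_avg = C_avg
    )),
    class = "gradient_realization"
  )
}

# Minimal readout ensemble carrying a given vector of positions (NA =
# censored) at a single target, for unit-testing positional_error().
fake_ensemble <- function(positions, mu_delta = 5, x_target = 50) {
  tbl <- tibble::tibble(
    replicate = seq_along(positions),
    x_target = x_target,
    threshold = 0.1,
    position = positions,
    failed = FALSE
  )
  structure(tbl, mu_delta = mu_delta, n_failed = 0L,
            n_replicates = length(positions), seed = 0L,
            class = c("readout_ensemble", class(tbl)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
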