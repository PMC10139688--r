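#' Mean cell area that yields a target mean cell diameter
#'
#' Cells are generated by drawing cross-sectional areas \eqn{A_i} from a
#' log-normal distribution and converting them to diameters
#' \eqn{\delta_i = 2\sqrt{A_i/\pi}}. Because the square root is concave, the
#' mean of the diameters is not the diameter of the mean area; the log-normal
#' area mean must be inflated to
#' \deqn{\mu_A = \pi (\mu_\delta/2)^2 (1 + CV_A^2)^{1/4}}
#' so that the resulting diameters have mean \eqn{\mu_\delta} exactly.
#'
#' @param mu_delta Target mean cell diameter in micrometres (> 0).
#' @param cv_A Coefficient of variation of the cell areas (>= 0).
#' @return Mean cell area in square micrometres.
#' @examples
#' mean_area_from_diameter(5, 0)    # area of a circle of diameter 5
#' mean_area_from_diameter(5, 0.5)
#' @export
mean_area_from_diameter <- function(mu_delta, cv_A) {
  check_positive_scalar(mu_delta, "mu_delta")
  check_positive_scalar(cv_A, "cv_A", allow_zero = TRUE)
  pi * (mu_delta / 2)^2 * (1 + cv_A^2)^(1 / 4)
}

#' Specify the cell-area distribution of a tissue
#'
#' @param mu_delta Mean cell diameter in micrometres (> 0).
#' @param cv_A Coefficient of variation of cell areas (>= 0). The default 0.5
#'   is a typical apical-area CV for epithelia; values up to about 0.9 have
#'   been reported in the vertebrate neural tube.
#' @return An `area_spec` object.
#' @export
area_spec <- function(mu_delta = 5, cv_A = 0.5) {
  check_positive_scalar(mu_delta, "mu_delta")
  check_positive_scalar(cv_A, "cv_A", allow_zero = TRUE)
  structure(list(mu_delta = mu_delta, cv_A = cv_A), class = "area_spec")
}

# internal: draw cell diameters until they cover length L, truncating the
# final cell so the region length is met exactly. Returns numeric(0) if L = 0.
fill_region <- function(L, mu_delta, cv_A) {
  if (L == 0) {
    return(numeric(0))
  }
  mu_A <- mean_area_from_diameter(mu_delta, cv_A)
  diams <- numeric(0)
  total <- 0
  while (total < L) {
    k <- max(16L, ceiling(1.5 * (L - total) / mu_delta))
    a <- rlnorm_mean_cv(k, mu_A, cv_A)
    d <- 2 * sqrt(a / pi)
    diams <- c(diams, d)
    total <- total + sum(d)
  }
  cum <- cumsum(diams)
  n_cells <- which(cum >= L)[1L]
  diams <- diams[seq_len(n_cells)]
  # truncate the last cell so the region has length exactly L
  diams[n_cells] <- diams[n_cells] - (cum[n_cells] - L)
  if (diams[n_cells] <= 0) {
    # pathological truncation to zero width: merge into the previous cell
    diams <- diams[-n_cells]
    diams[length(diams)] <- L - sum(diams[-length(diams)])
  }
  diams
}

#' Sample a one-dimensional cellular tissue domain
#'
#' Builds the tissue cell by cell: areas are drawn from a log-normal
#' distribution with mean [mean_area_from_diameter()] and CV `cv_A`, converted
#' to diameters, and appended until the source region `[-Ls, 0)` and the
#' patterning region `[0, Lp]` are each covered. The last cell of each region
#' is truncated so the region lengths are met exactly; no cell straddles
#' `x = 0`, so morphogen production can switch off exactly at the source
#' boundary.
#'
#' @param spec An [area_spec()].
#' @param Ls Source region length in micrometres (>= 0; 0 gives a source-free
#'   domain for flux or Dirichlet boundary modes).
#' @param Lp Patterning region length in micrometres (> 0).
#' @return A `cell_domain` object: a list with a `cells` tibble
#'   (`cell`, `x_left`, `x_right`, `diameter`, `is_source`) plus `Ls`, `Lp`
#'   and `mu_delta`.
#' @examples
#' set.seed(1)
#' dom <- sample_domain(area_spec(5, 0.5), Ls = 25, Lp = 1000)
#' dom
#' @export
sample_domain <- function(spec, Ls, Lp) {
  stopifnot(inherits(spec, "area_spec"))
  check_positive_scalar(Ls, "Ls", allow_zero = TRUE)
  check_positive_scalar(Lp, "Lp")
  d_src <- fill_region(Ls, spec$mu_delta, spec$cv_A)
  d_pat <- fill_region(Lp, spec$mu_delta, spec$cv_A)
  diams <- c(d_src, d_pat)
  is_source <- c(rep(TRUE, length(d_src)), rep(FALSE, length(d_pat)))
  bounds <- -Ls + cumsum(c(0, diams))
  # pin region edges against accumulated rounding
  bounds[length(d_src) + 1L] <- 0
  bounds[length(bounds)] <- Lp
  cells <- tibble::tibble(
    cell = seq_along(diams),
    x_left = bounds[-length(bounds)],
    x_right = bounds[-1L],
    diameter = diff(bounds),
    is_source = is_source
  )
  new_cell_domain(cells, Ls = Ls, Lp = Lp, mu_delta = spec$mu_delta)
}

#' Build a noise-free uniform cellular domain
#'
#' All cells have diameter exactly `mu_delta`; region lengths are rounded to
#' whole numbers of cells.
#'
#' @param mu_delta Cell diameter in micrometres.
#' @param Ls,Lp Region lengths in micrometres.
#' @return A `cell_domain`.
#' @export
uniform_domain <- function(mu_delta, Ls, Lp) {
  check_positive_scalar(mu_delta, "mu_delta")
  n_src <- round(Ls / mu_delta)
  n_pat <- round(Lp / mu_delta)
  stopifnot(n_pat >= 1, abs(n_src * mu_delta - Ls) < 1e-9 * mu_delta,
            abs(n_pat * mu_delta - Lp) < 1e-9 * mu_delta)
  bounds <- seq(-Ls, Lp, by = mu_delta)
  cells <- tibble::tibble(
    cell = seq_len(n_src + n_pat),
    x_left = bounds[-length(bounds)],
    x_right = bounds[-1L],
    diameter = diff(bounds),
    is_source = c(rep(TRUE, n_src), rep(FALSE, n_pat))
  )
  new_cell_domain(cells, Ls = Ls, Lp = Lp, mu_delta = mu_delta)
}

new_cell_domain <- function(cells, Ls, Lp, mu_delta) {
  dom <- structure(list(cells = cells, Ls = Ls, Lp = Lp, mu_delta = mu_delta),
                   class = "cell_domain")
  validate_cell_domain(dom)
  dom
}

validate_cell_domain <- function(dom) {
  cells <- dom$cells
  stopifnot(all(cells$diameter > 0),
            all(diff(c(cells$x_left, dom$Lp)) > 0))
  tol <- 1e-8 * max(dom$Ls + dom$Lp, 1)
  stopifnot(abs(cells$x_left[1] + dom$Ls) <= tol,
            abs(cells$x_right[nrow(cells)] - dom$Lp) <= tol,
            abs(sum(cells$diameter[cells$is_source]) - dom$Ls) <= tol,
            abs(sum(cells$diameter[!cells$is_source]) - dom$Lp) <= tol)
  invisible(dom)
}

#' @export
print.cell_domain <- function(x, ...) {
  cat(sprintf(
    "<cell_domain> %d source + %d patterning cells on [%g, %g] um (mu_delta = %g um)\n",
    sum(x$cells$is_source), sum(!x$cells$is_source), -x$Ls, x$Lp, x$mu_delta
  ))
  invisible(x)
}

#' @rdname tidy-morphosim
#' @export
tidy.cell_domain <- function(x, ...) {
  x$cells
}

#' Serialise a cellular domain to JSON
#'
#' Round-trips through [domain_from_json()] for replaying single tissues.
#'
#' @param dom A `cell_domain`.
#' @return A JSON string.
#' @export
domain_to_json <- function(dom) {
  stopifnot(inherits(dom, "cell_domain"))
  jsonlite::toJSON(
    list(
      boundaries = c(dom$cells$x_left, dom$Lp),
      is_source = dom$cells$is_source,
      Ls = dom$Ls, Lp = dom$Lp, mu_delta = dom$mu_delta
    ),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname domain_to_json
#' @param json A JSON string produced by [domain_to_json()].
#' @export
domain_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  bounds <- rec$boundaries
  cells <- tibble::tibble(
    cell = seq_len(length(bounds) - 1L),
    x_left = bounds[-length(bounds)],
    x_right = bounds[-1L],
    diameter = diff(bounds),
    is_source = as.logical(rec$is_source)
  )
  new_cell_domain(cells, Ls = rec$Ls, Lp = rec$Lp, mu_delta = rec$mu_delta)
}
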