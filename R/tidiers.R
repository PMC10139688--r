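#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy morphosim objects
#'
#' `tidy()` returns the per-cell or per-replicate content of a morphosim
#' object as a tibble: the cell table of a `cell_domain`, the cell-averaged
#' concentrations of a `gradient_realization`, or the replicate-level
#' readout positions of a `readout_ensemble`.
#'
#' @param x A morphosim object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-morphosim
NULL

#' Glance at morphosim objects
#'
#' `glance()` returns a one-row summary of an ensemble: replicate, failure
#' and censoring counts, the reliability flag and the master seed.
#'
#' @param x A morphosim object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance-morphosim
NULL
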