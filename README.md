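# morphosim

Cell-based stochastic simulation of morphogen gradient precision in R.

During tissue patterning, a morphogen secreted by a localised source spreads
and decays, forming a concentration gradient that cells read out against
thresholds (the French flag principle): the position where the local
concentration falls below a threshold `C_θ` sets a cell-fate boundary.
Real gradients are noisy — every cell has its own production, degradation
and transport kinetics, and its own size — so the readout position `x_θ`
varies between embryos. `morphosim` quantifies that variability with the
**positional error**

σ<sub>x</sub> = stddev<sub>j</sub>[x<sub>θ,j</sub>],

the standard deviation of the readout position across independent gradient
realisations, and asks how it depends on the *order* of morphogen decay.

The steady-state model on a 1D cellular domain (source `[-L_s, 0)`,
patterning region `[0, L_p]`) is

0 = D ∂²C/∂x² − d Cⁿ / C<sub>ref</sub>ⁿ⁻¹ + p H(−x),

with zero-flux outer boundaries (or, alternatively, an influx `j₀` or fixed
amplitude `C₀` imposed at `x = 0` instead of an explicit source domain).
Linear decay (n = 1) gives exponential gradients `C = C₀ exp(−x/λ)` with
`λ = √(D/d)`; non-linear, self-enhanced decay (n > 1) gives shifted
power-law gradients `C = C₀ (1 + x/(m λ_m))^(−m)` with `m = 2/(n−1)`.
Each cell carries independent log-normal draws of `(p, d, D)` and of its
cross-sectional area; the resulting piecewise-coefficient boundary-value
problem is solved by a conservative finite-volume scheme with damped Newton
iteration, cells sense their diameter-averaged concentration, and
Monte-Carlo ensembles of tissues yield `σ_x` with bootstrap standard
errors.

The package is written for quantitative developmental biologists and
modellers who want to measure — rather than assume — how decay
non-linearity, noise amplitudes, cell size, boundary conditions and source
strength shape patterning precision.

## Worked example

Positional error under reference conditions (mean gradient length
`μ_λ = 20 µm`, mean cell diameter `μ_δ = μ_λ/4 = 5 µm`, kinetic CVs 0.3,
cell-area CV 0.5, 200-cell patterning domain, 5-cell source), read out 5
and 75 cell diameters from the source:

```r
library(morphosim)

cfg <- sim_config(n = 1, x_targets_cells = c(5, 75))
ens <- run_ensemble(cfg, n_replicates = 300, seed = 101)
positional_error(ens)
#> # A tibble: 2 × 11
#>   x_target     threshold n_used n_censored n_failed  mu_x sigma_x sigma_x_se
#>      <dbl>         <dbl>  <int>      <int>    <int> <dbl>   <dbl>      <dbl>
#> 1       25 0.116            300          0        0  26.4    4.19      0.147
#> 2      375 0.00000000292    300          0        0 364.    10.3       0.418
#>   x_target_cells sigma_x_cells sigma_x_se_cells
#>            <dbl>         <dbl>            <dbl>
#> 1              5         0.838           0.0294
#> 2             75         2.06            0.0836
```

Each row is one readout target: the threshold mapped from the noise-free
reference gradient, the mean readout position `mu_x` (µm), the positional
error `sigma_x` (µm) with its bootstrap standard error, and the same
quantities in units of the mean cell diameter. Here patterning is
sub-cellular near the source (`σ_x/μ_δ ≈ 0.84`) and about two cell
diameters at 75 cells (`σ_x/μ_δ ≈ 2.1`).

Closed-form gradients expose the classic shift argument — for exponential
gradients a doubling of the amplitude shifts every boundary by
`λ ln 2 ≈ 13.9 µm` regardless of the absolute level:

```r
g <- analytic_gradient(C0 = 1, D = 0.033, d = 8.25e-5, n = 1)
readout_shift(g, C_theta = 0.1, amplitude_factor = 2)
#> [1] 13.86294
```

Sweeps over decay exponents, noise levels, cell sizes, boundary conditions
and source strengths are run with `run_sweep()` / `run_preset()` and return
tidy tibbles ready for `plot_positional_error()`; `compare_decay_orders()`
differences non-linear against linear decay at matched readout positions.
A command-line front end (`inst/cli/morphosim`) wraps `simulate`, `sweep`,
`diff-decay` and `validate` for shell use.

## Documentation

The methods vignette (`vignettes/gradient-precision.Rmd`) describes the
model, the numerical scheme, the noise model, the readout definition and
the package's design choices in detail.
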