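# shared fixtures: parameter sets and grids used across test files
np_high <- neuron_params("high")
np_low <- neuron_params("low")
hp_high <- hazard_params(np_high)
hp_low <- hazard_params(np_low)

# coarse grid for cheap renewal checks, fine grid for membrane integration
grid_coarse <- function(t_max = 1, dt = 1e-3) time_grid(dt = dt, t_max = t_max)
grid_sim <- function(t_max = 0.5) time_grid(dt = 5e-5, t_max = t_max)

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# a smooth random nonnegative hazard for property-style loops
random_hazard <- function(grid, seed, base = 10) {
  tt <- grid_times(grid)
  set.seed(seed)
  f <- stats::runif(3, 1, 20)
  ph <- stats::runif(3, 0, 2 * pi)
  v <- base * exp(0.5 * (sin(2 * pi * f[1] * tt + ph[1]) +
                           sin(2 * pi * f[2] * tt + ph[2]) +
                           sin(2 * pi * f[3] * tt + ph[3])) / 3)
  sampled_fun(v, grid, "1/s")
}
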