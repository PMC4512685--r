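#' Modulation specification
#'
#' Parameters of the random log-modulation used to build target ISI
#' distributions: a superposition of unit-amplitude sinusoids with random
#' phases at equidistant frequencies, mapped so the multiplicative
#' modulation Dp_in spans exactly [1 - r_dp, 1 + r_dp] on the window.
#' Presets: low-frequency band = 60 sinusoids on [10, 100] Hz,
#' high-frequency band = 60 sinusoids on [100, 200] Hz.
#'
#' @param n_sinusoids number of sinusoids (>= 1).
#' @param f_lo,f_hi band edges in Hz (`f_lo <= f_hi`); with a single
#'   sinusoid the frequency is `f_lo`.
#' @param r_dp probability fluctuation ratio in [0, 1): the peak deviation of
#'   Dp_in from 1.
#' @param seed integer seed for the random phases.
#' @return object of class `"modulation_spec"`.
#' @examples
#' modulation_spec_band("low", r_dp = 0.44, seed = 1)
#' @export
modulation_spec <- function(n_sinusoids, f_lo, f_hi, r_dp, seed = 1L) {
  if (r_dp < 0 || r_dp >= 1)
    stop("r_dp must lie in [0, 1): Dp_in must stay positive")
  if (n_sinusoids < 1) stop("need at least one sinusoid")
  if (f_lo > f_hi) stop("require f_lo <= f_hi")
  if (n_sinusoids > 1 && f_lo == f_hi)
    stop("a degenerate band needs n_sinusoids = 1")
  structure(list(n_sinusoids = as.integer(n_sinusoids),
                 f_lo = f_lo, f_hi = f_hi, r_dp = r_dp,
                 seed = as.integer(seed)),
            class = "modulation_spec")
}

#' @rdname modulation_spec
#' @param band `"low"` ([10, 100] Hz) or `"high"` ([100, 200] Hz).
#' @export
modulation_spec_band <- function(band = c("low", "high"), r_dp, seed = 1L) {
  band <- match.arg(band)
  if (band == "low") modulation_spec(60L, 10, 100, r_dp, seed)
  else modulation_spec(60L, 100, 200, r_dp, seed)
}

#' @export
print.modulation_spec <- function(x, ...) {
  cat(sprintf(
    "log-modulation: %d sinusoid(s) on [%g, %g] Hz, r_dp = %g, seed = %d\n",
    x$n_sinusoids, x$f_lo, x$f_hi, x$r_dp, x$seed))
  invisible(x)
}

mod_frequencies <- function(spec) {
  n <- spec$n_sinusoids
  if (n == 1L) spec$f_lo
  else spec$f_lo + (seq_len(n) - 1L) * (spec$f_hi - spec$f_lo) / (n - 1L)
}

#' Generate the log-modulation signal
#'
#' Sums `n_sinusoids` unit-amplitude sinusoids at equidistant frequencies
#' (endpoints included) with phases uniform on [0, 2 pi) drawn from the
#' spec's seed, then affinely maps the sum in log space so that
#' exp(min) = 1 - r_dp and exp(max) = 1 + r_dp exactly on the window.  The
#' affine coefficients and sinusoid parameters are attached for analytic
#' differentiation downstream.
#'
#' @param spec a [modulation_spec()].
#' @param grid a [time_grid()] spanning at least one period of `f_lo`.
#' @return ln Dp_in as a dimensionless [sampled_fun()] with attribute
#'   `"mod_params"` (frequencies in Hz, phases, affine `alpha`, `beta`).
#' @export
make_log_modulation <- function(spec, grid) {
  stopifnot(inherits(spec, "modulation_spec"), inherits(grid, "time_grid"))
  T_win <- (grid$n - 1L) * grid$dt
  if (spec$f_lo > 0 && T_win < 1 / spec$f_lo)
    warning("window shorter than one period of the lowest frequency")
  tt <- grid_times(grid)
  freqs <- mod_frequencies(spec)
  phases <- withr_seed(spec$seed, stats::runif(spec$n_sinusoids, 0, 2 * pi))
  s <- rowSums(vapply(seq_along(freqs),
                      function(k) sin(2 * pi * freqs[k] * tt + phases[k]),
                      numeric(length(tt))))
  if (spec$r_dp == 0) {
    alpha <- 0; beta <- 0
  } else {
    lo <- log(1 - spec$r_dp); hi <- log(1 + spec$r_dp)
    rng <- range(s)
    alpha <- (hi - lo) / (rng[2L] - rng[1L])
    beta <- lo - alpha * rng[1L]
  }
  out <- sampled_fun(alpha * s + beta, grid, "1")
  attr(out, "mod_params") <- list(freqs = freqs, phases = phases,
                                  alpha = alpha, beta = beta)
  out
}

# run expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# analytic d/dt ln Dp_in from stored sinusoid parameters, with a central
# finite-difference fallback (O(dt^2)) for tabulated signals
logmod_derivative <- function(ln_dp, grid) {
  mp <- attr(ln_dp, "mod_params")
  if (!is.null(mp)) {
    if (mp$alpha == 0) return(numeric(grid$n))
    tt <- grid_times(grid)
    d <- rowSums(vapply(seq_along(mp$freqs), function(k) {
      w <- 2 * pi * mp$freqs[k]
      w * cos(w * tt + mp$phases[k])
    }, numeric(length(tt))))
    return(mp$alpha * d)
  }
  v <- ln_dp$values
  n <- length(v)
  dt <- grid$dt
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  d
}

#' Build a target ISI distribution
#'
#' Constructs p_in(t) = p_0(t) Dp_in(t): an exponential baseline with hazard
#' h0 = [baseline_hazard()] at `V0`, multiplied by the random log-modulation
#' of `spec`, renormalized to unit mass on the window.  The unnormalized
#' ln Dp_in is kept — the current encoder only uses its derivative, so the
#' normalization constant never enters the neuron's input.
#'
#' @param spec a [modulation_spec()].
#' @param V0 baseline voltage (mV).
#' @param neuron a [neuron_params()].
#' @param hazard a [hazard_params()].
#' @param grid a [time_grid()]; the evaluation window.
#' @return object of class `"isi_target"` with fields `grid`, `V0`, `h0`,
#'   `ln_dp_in` (unnormalized log-modulation), `p_in` (window-normalized
#'   [isi_distribution()]), `modulation`, `spec`.
#' @export
build_target <- function(spec, V0, neuron, hazard, grid) {
  stopifnot(inherits(grid, "time_grid"))
  h0 <- baseline_hazard(V0, neuron, hazard)
  tt <- grid_times(grid)
  p0 <- h0 * exp(-h0 * tt)
  mass0 <- trapz_uniform(p0, grid$dt)
  if (mass0 < 0.99)
    warning(sprintf(
      "window captures only %.1f%% of the baseline mass (h0 = %.3g Hz)",
      100 * mass0, h0))
  ln_dp <- make_log_modulation(spec, grid)
  p_raw <- p0 * exp(ln_dp$values)
  Z <- trapz_uniform(p_raw, grid$dt)
  p_in <- p_raw / Z
  S_in <- pmax(1 - cumtrapz_uniform(p_in, grid$dt), 0)
  structure(list(grid = grid, V0 = V0, h0 = h0,
                 ln_dp_in = ln_dp,
                 p_in = isi_distribution(p_in, S_in, grid),
                 modulation = ln_dp, spec = spec),
            class = "isi_target")
}

#' @export
print.isi_target <- function(x, ...) {
  cat(sprintf("target ISI distribution: V0 = %g mV, h0 = %.4g Hz\n",
              x$V0, x$h0))
  print(x$spec)
  invisible(x)
}
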