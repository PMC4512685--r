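#' EIF/LIF membrane parameters
#'
#' Physiological parameters of the exponential integrate-and-fire neuron.
#' Defaults are the UP-state parameter set used throughout the package:
#' C_m = 0.281 nF, E_L = -70.6 mV, V_T = -50.4 mV, Delta_T = 3 mV,
#' V_p = -40.4 mV, with the leak conductance selecting the regime —
#' g_L = 150 nS in the high-conductance (UP-state) regime, 30 nS in the low.
#' The membrane time constant tau_m = C_m / g_L comes out as ~1.9 ms (high)
#' or ~9.4 ms (low).  The LIF is the Delta_T -> 0 limit with spike detection
#' at V_T; model selection happens in the dynamics functions, not here.
#'
#' @param regime `"high"` or `"low"` conductance; sets the default `g_L`.
#' @param C_m membrane capacitance (nF).
#' @param g_L leak conductance (nS); overrides the regime default.
#' @param E_L leak reversal potential (mV).
#' @param V_T threshold potential (mV).
#' @param Delta_T slope factor of the exponential spike-initiation current
#'   (mV); the LIF dynamics use 0.
#' @param V_p peak (spike-detection) potential (mV).
#' @return object of class `"neuron_params"`; `tau_m` (seconds) is derived.
#' @examples
#' np <- neuron_params("high")
#' np$tau_m * 1e3   # ~1.87 ms
#' @export
neuron_params <- function(regime = c("high", "low"), C_m = 0.281,
                          g_L = NULL, E_L = -70.6, V_T = -50.4,
                          Delta_T = 3, V_p = -40.4) {
  regime <- match.arg(regime)
  if (is.null(g_L)) g_L <- if (regime == "high") 150 else 30
  if (C_m <= 0 || g_L <= 0) stop("C_m and g_L must be positive")
  if (Delta_T < 0) stop("Delta_T must be nonnegative")
  if (!(V_p >= V_T && V_T > E_L))
    stop("require V_p >= V_T > E_L")
  structure(list(C_m = C_m, g_L = g_L, E_L = E_L, V_T = V_T,
                 Delta_T = Delta_T, V_p = V_p,
                 tau_m = C_m / g_L,        # nF / nS = seconds
                 regime = regime),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "EIF/LIF neuron (%s conductance): C_m = %g nF, g_L = %g nS, tau_m = %.3g ms\n",
    x$regime, x$C_m, x$g_L, x$tau_m * 1e3))
  cat(sprintf("  E_L = %g mV, V_T = %g mV, Delta_T = %g mV, V_p = %g mV\n",
              x$E_L, x$V_T, x$Delta_T, x$V_p))
  invisible(x)
}

#' Escape-noise hazard parameters
#'
#' The stochastic firing criterion: the hazard depends exponentially on the
#' (optionally filtered) distance of the membrane potential from threshold,
#' \deqn{h(t) = \frac{1}{K\tau_m}\exp\!\big((\mathcal{K}*(V-V_T))(t)/\Delta_T\big),}
#' with a spiking-determinism parameter fixed at 3 mV for both EIF and LIF so
#' the two models differ only in their membrane dynamics.  The scaling K is
#' chosen so the hazard at V = V_T equals `rate_at_threshold` (default 10 Hz,
#' the low UP-state firing rate), giving K ~ 53.4 (high conductance) or
#' ~ 10.7 (low).
#'
#' @param neuron a [neuron_params()] (supplies tau_m for the default K).
#' @param K dimensionless hazard scaling; default `1/(rate_at_threshold * tau_m)`.
#' @param Delta_T_det spiking determinism (mV); 3 mV for both models.
#' @param rate_at_threshold hazard at V = V_T (1/s) used to set the default K.
#' @param kernel optional causal filter kernel as a [sampled_fun()];
#'   `NULL` means the Dirac delta (pure escape noise).  A supplied kernel is
#'   renormalized to unit discrete integral.
#' @return object of class `"hazard_params"`.
#' @export
hazard_params <- function(neuron, K = NULL, Delta_T_det = 3,
                          rate_at_threshold = 10, kernel = NULL) {
  stopifnot(inherits(neuron, "neuron_params"))
  if (is.null(K)) K <- 1 / (rate_at_threshold * neuron$tau_m)
  if (K <= 0) stop("K must be positive")
  if (Delta_T_det <= 0) stop("Delta_T_det must be positive")
  if (!is.null(kernel)) {
    stopifnot(inherits(kernel, "sampled_fun"))
    mass <- sum(kernel$values) * kernel$grid$dt
    if (mass <= 0) stop("kernel must have positive integral")
    kernel$values <- kernel$values / mass
  }
  structure(list(K = K, Delta_T_det = Delta_T_det, kernel = kernel),
            class = "hazard_params")
}

#' @export
print.hazard_params <- function(x, ...) {
  cat(sprintf("escape-noise hazard: K = %.4g, Delta_T_det = %g mV, kernel: %s\n",
              x$K, x$Delta_T_det,
              if (is.null(x$kernel)) "delta" else "sampled"))
  invisible(x)
}

#' Read a neuron/hazard parameter block from a YAML config
#'
#' Field names mirror the standard parameter table: `C_m`, `g_L`, `E_L`,
#' `V_T`, `Delta_T`, `V_p`, `dt`, `K`, `Delta_T_det`, `regime`.
#'
#' @param path YAML file path.
#' @return list with elements `neuron`, `hazard`, and `dt` (seconds).
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params_from_list(cfg)
}

params_from_list <- function(cfg) {
  regime <- cfg$regime %||% "high"
  np <- neuron_params(regime = regime,
                      C_m = cfg$C_m %||% 0.281,
                      g_L = cfg$g_L,
                      E_L = cfg$E_L %||% -70.6,
                      V_T = cfg$V_T %||% -50.4,
                      Delta_T = cfg$Delta_T %||% 3,
                      V_p = cfg$V_p %||% -40.4)
  hp <- hazard_params(np, K = cfg$K,
                      Delta_T_det = cfg$Delta_T_det %||% 3,
                      rate_at_threshold = cfg$rate_at_threshold %||% 10)
  list(neuron = np, hazard = hp, dt = cfg$dt %||% 5e-5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
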