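#' Holding current for a constant voltage baseline
#'
#' The constant current density I*_0 (in mV/s, i.e. current divided by C_m)
#' that keeps the membrane at V0: the membrane equation with dV/dt = 0 gives
#' \deqn{I^*_0 = (V_0 - E_L)/\tau_m - (\Delta_T/\tau_m)\exp((V_0-V_T)/\Delta_T),}
#' the exponential term being absent for the LIF.
#'
#' @param V0 baseline voltage (mV), below V_p.
#' @param neuron a [neuron_params()].
#' @param model `"eif"` or `"lif"`.
#' @return current density in mV/s.
#' @export
holding_current <- function(V0, neuron, model = c("eif", "lif")) {
  model <- match.arg(model)
  stopifnot(inherits(neuron, "neuron_params"))
  if (any(V0 >= neuron$V_p)) stop("V0 must be below the peak potential")
  leak <- (V0 - neuron$E_L) / neuron$tau_m
  if (model == "lif" || neuron$Delta_T == 0) return(leak)
  leak - (neuron$Delta_T / neuron$tau_m) *
    exp((V0 - neuron$V_T) / neuron$Delta_T)
}

#' Baseline hazard at a constant voltage
#'
#' h0 = (1/(K tau_m)) exp((V0 - V_T)/Delta_T_det); equals the calibrated
#' threshold rate (10 Hz by default) at V0 = V_T.  Identical for EIF and LIF
#' since both share the 3 mV spiking determinism.
#'
#' @inheritParams holding_current
#' @param hazard a [hazard_params()].
#' @return hazard in 1/s (Hz).
#' @examples
#' np <- neuron_params("high"); hp <- hazard_params(np)
#' baseline_hazard(np$V_T, np, hp)        # 10 Hz
#' baseline_hazard(-51.4, np, hp)         # ~7.2 Hz
#' @export
baseline_hazard <- function(V0, neuron, hazard) {
  stopifnot(inherits(neuron, "neuron_params"), inherits(hazard, "hazard_params"))
  (1 / (hazard$K * neuron$tau_m)) *
    exp((V0 - neuron$V_T) / hazard$Delta_T_det)
}

# causal discrete convolution of a signal with a kernel on the same dt;
# the signal's past (t < 0) is zero-padded
causal_convolve <- function(values, kernel_values, dt) {
  n <- length(values)
  # 'open' convolution with rev(): element k collects sum_{i+j=k+1} v[i]*k[j]
  full <- stats::convolve(values, rev(kernel_values), type = "open")
  full[seq_len(n)] * dt
}

#' Escape-noise hazard from a voltage trajectory
#'
#' Evaluates h(t) = (1/(K tau_m)) exp((K * (V - V_T))(t) / Delta_T_det).
#' With the default delta kernel this is the instantaneous exponential
#' escape-noise hazard; with a sampled causal kernel the distance to
#' threshold is low-pass filtered first (past zero-padded).
#'
#' @param traj a `voltage_trajectory` (from [integrate_membrane()]) or a
#'   [sampled_fun()] of membrane voltage in mV.
#' @inheritParams baseline_hazard
#' @return hazard as a [sampled_fun()] in 1/s.
#' @export
hazard_from_voltage <- function(traj, neuron, hazard) {
  V <- if (inherits(traj, "voltage_trajectory")) traj$V else traj
  stopifnot(inherits(V, "sampled_fun"))
  dist <- V$values - neuron$V_T
  if (!is.null(hazard$kernel)) {
    if (!isTRUE(all.equal(hazard$kernel$grid$dt, V$grid$dt)))
      stop("kernel and voltage must share the same time step")
    dist <- causal_convolve(dist, hazard$kernel$values, V$grid$dt)
  }
  h <- (1 / (hazard$K * neuron$tau_m)) * exp(dist / hazard$Delta_T_det)
  sampled_fun(h, V$grid, "1/s")
}

#' Encode a target ISI distribution as an input current
#'
#' Inverts the small-signal mapping between current and ISI density: the
#' input current density is set linear in d/dt ln p_in(t),
#' \deqn{I^*(t) = (V_0-E_L)/\tau_m + \Delta_T\,[-(K-1)h_0 + \tfrac{d}{dt}\ln p_\mathrm{in}(t)]}
#' for the EIF; for the LIF the bracket's intercept -(K-1)h0 is replaced by
#' +h0.  With d/dt ln p_in = -h0 + d/dt ln Dp_in, zero modulation reduces both
#' to the respective [holding_current()].  The derivative of the
#' log-modulation is taken analytically from the target's sinusoid
#' parameters when available, otherwise by central finite differences.
#'
#' @param target an [build_target()] object.
#' @param neuron a [neuron_params()].
#' @param hazard a [hazard_params()] with the delta kernel (the encoding
#'   fixes the filtered current; only the delta kernel makes it the current
#'   itself).
#' @param model `"eif"` or `"lif"`.
#' @return input current density as a [sampled_fun()] in mV/s.
#' @export
encode_target_current <- function(target, neuron, hazard,
                                  model = c("eif", "lif")) {
  model <- match.arg(model)
  stopifnot(inherits(target, "isi_target"))
  if (!is.null(hazard$kernel))
    stop("current encoding requires the delta hazard kernel")
  dln <- logmod_derivative(target$modulation, target$grid)
  if (any(!is.finite(dln)))
    stop("non-finite derivative of the log-modulation")
  h0 <- target$h0
  dlnp <- -h0 + dln                      # d/dt ln p_in
  intercept <- if (model == "eif") -(hazard$K - 1) * h0 else h0
  I <- (target$V0 - neuron$E_L) / neuron$tau_m +
    hazard$Delta_T_det * (intercept + dlnp)
  sampled_fun(I, target$grid, "mV/s")
}

#' Integrate the EIF/LIF membrane equation
#'
#' Deterministic third-order Runge-Kutta integration of
#' \deqn{\dot V = -(V-E_L)/\tau_m + (\Delta_T/\tau_m)\exp((V-V_T)/\Delta_T) + I^*(t)}
#' at the grid step (the exponential term is dropped for the LIF).  There is
#' no stochastic firing: a reset to `V_r` happens only when V crosses the
#' peak potential V_p (EIF) or the threshold V_T (LIF); crossing is detected
#' at the first grid point at or above the criterion, without sub-step
#' interpolation.  Integration continues under the ongoing, clock-aligned
#' current profile after a reset.
#'
#' @param I input current density as a [sampled_fun()] in mV/s.
#' @param neuron a [neuron_params()].
#' @param V_init initial voltage (mV).
#' @param model `"eif"` or `"lif"`.
#' @param V_r reset potential (mV); defaults to `V_init` (the baseline), the
#'   convention used for every voltage baseline here.
#' @return object of class `"voltage_trajectory"`: `V` (a [sampled_fun()],
#'   mV) and `reset_times` (seconds).
#' @export
integrate_membrane <- function(I, neuron, V_init, model = c("eif", "lif"),
                               V_r = V_init) {
  model <- match.arg(model)
  stopifnot(inherits(I, "sampled_fun"), inherits(neuron, "neuron_params"))
  dt <- I$grid$dt
  n <- I$grid$n
  tau <- neuron$tau_m
  E_L <- neuron$E_L
  V_T <- neuron$V_T
  DT <- if (model == "eif") neuron$Delta_T else 0
  V_thr <- if (model == "eif") neuron$V_p else neuron$V_T

  deriv <- if (DT > 0) {
    function(V, Iv) -(V - E_L) / tau + (DT / tau) * exp((V - V_T) / DT) + Iv
  } else {
    function(V, Iv) -(V - E_L) / tau + Iv
  }

  Iv <- I$values
  V <- numeric(n)
  V[1L] <- V_init
  resets <- numeric(0)
  for (i in seq_len(n - 1L)) {
    I0 <- Iv[i]; I1 <- Iv[i + 1L]; Im <- 0.5 * (I0 + I1)
    v <- V[i]
    k1 <- deriv(v, I0)
    k2 <- deriv(v + 0.5 * dt * k1, Im)
    k3 <- deriv(v - dt * k1 + 2 * dt * k2, I1)
    v_next <- v + dt * (k1 + 4 * k2 + k3) / 6
    if (!is.finite(v_next))
      stop(sprintf("membrane integration diverged at t = %.6g s; reduce dt",
                   i * dt))
    if (v_next >= V_thr) {
      resets <- c(resets, i * dt)
      v_next <- V_r
    }
    V[i + 1L] <- v_next
  }
  structure(list(V = sampled_fun(V, I$grid, "mV"), reset_times = resets),
            class = "voltage_trajectory")
}

#' @export
print.voltage_trajectory <- function(x, ...) {
  cat("voltage trajectory on ")
  print(x$V$grid)
  cat(sprintf("  range [%.3f, %.3f] mV, %d reset(s)\n",
              min(x$V$values), max(x$V$values), length(x$reset_times)))
  invisible(x)
}
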