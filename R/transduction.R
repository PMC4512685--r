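#' Transduce a target ISI distribution through an EIF/LIF neuron
#'
#' The package's central computation.  Given a target ISI distribution
#' p_in = p_0 Dp_in, the pipeline (i) encodes the target as an input current
#' ([encode_target_current()]), (ii) integrates the deterministic membrane
#' equation from V(0) = V0 with reset to V_r = V0
#' ([integrate_membrane()]), (iii) converts the voltage trajectory to an
#' escape-noise hazard ([hazard_from_voltage()]) and (iv) recovers the
#' neuron's output ISI density p_out = S h ([isi_from_hazard()]).  The
#' output log-modulation is read directly off the density,
#' ln Dp_out = ln p_out - ln p_0 (no window renormalization: the modulation
#' of a renewal density is defined relative to the exponential baseline,
#' and renormalizing on a finite window would smear any local trajectory
#' error, such as an erroneous threshold crossing, into a global offset);
#' the normalized L1 distance between ln Dp_in and ln Dp_out scores the
#' approximation.
#'
#' @param target an [build_target()] target.
#' @param neuron a [neuron_params()]; defaults to the high-conductance set.
#' @param hazard a [hazard_params()]; defaults to `hazard_params(neuron)`.
#' @param model `"eif"` or `"lif"`.
#' @return object of class `"isi_transduction"` with components `target`,
#'   `model`, `neuron`, `hazard`, `current`, `trajectory`, `hazard_out`,
#'   `p_out` (the raw output [isi_distribution()] on the window),
#'   `ln_dp_out`, `ln_dp_in` (the target's log-modulation), `constants`
#'   ([transfer_constants()]) and `l1` (normalized L1 score).
#' @examples
#' np <- neuron_params("high"); hp <- hazard_params(np)
#' g <- time_grid(dt = 5e-5, t_max = 0.5)
#' tg <- build_target(modulation_spec(60, 10, 200, 0.44, seed = 1),
#'                    V0 = -51.4, np, hp, g)
#' fit <- isi_transduction(tg, np, hp, model = "eif")
#' fit$l1
#' @export
isi_transduction <- function(target, neuron = neuron_params(),
                             hazard = hazard_params(neuron),
                             model = c("eif", "lif")) {
  model <- match.arg(model)
  stopifnot(inherits(target, "isi_target"))
  grid <- target$grid
  I <- encode_target_current(target, neuron, hazard, model)
  traj <- integrate_membrane(I, neuron, V_init = target$V0, model = model,
                             V_r = target$V0)
  h <- hazard_from_voltage(traj, neuron, hazard)
  p_raw <- isi_from_hazard(h)

  tt <- grid_times(grid)
  p0 <- target$h0 * exp(-target$h0 * tt)
  ln_dp_out <- sampled_fun(log(p_raw$p) - log(p0), grid, "1")
  ln_dp_in <- target$ln_dp_in

  structure(list(
    target = target, model = model, neuron = neuron, hazard = hazard,
    current = I, trajectory = traj, hazard_out = h,
    p_out = p_raw,
    ln_dp_out = ln_dp_out, ln_dp_in = ln_dp_in,
    constants = transfer_constants(target$V0, neuron, hazard),
    l1 = l1_distance(ln_dp_in, ln_dp_out)),
    class = "isi_transduction")
}

#' @export
print.isi_transduction <- function(x, ...) {
  cat(sprintf("ISI transduction (%s, %s conductance)\n",
              toupper(x$model), x$neuron$regime))
  cat(sprintf("  V0 = %g mV, h0 = %.4g Hz, r_dp = %g\n",
              x$target$V0, x$target$h0, x$target$spec$r_dp))
  cat(sprintf("  normalized L1(ln Dp_in, ln Dp_out) = %.4f\n", x$l1))
  invisible(x)
}

#' @export
summary.isi_transduction <- function(object, ...) {
  dV <- object$trajectory$V$values - object$target$V0
  out <- list(model = object$model,
              V0 = object$target$V0,
              h0 = object$target$h0,
              r_dp = object$target$spec$r_dp,
              l1 = object$l1,
              n_resets = length(object$trajectory$reset_times),
              max_abs_dV = max(abs(dV)),
              Delta_T_det = object$hazard$Delta_T_det,
              constants = object$constants)
  class(out) <- "summary.isi_transduction"
  out
}

#' @export
print.summary.isi_transduction <- function(x, ...) {
  cat(sprintf("ISI transduction summary (%s)\n", toupper(x$model)))
  cat(sprintf("  baseline: V0 = %g mV, h0 = %.4g Hz\n", x$V0, x$h0))
  cat(sprintf("  modulation depth r_dp = %g\n", x$r_dp))
  cat(sprintf("  normalized L1 error   = %.4f\n", x$l1))
  cat(sprintf("  voltage excursion max|V - V0| = %.3f mV (Delta_T_det = %g mV)\n",
              x$max_abs_dV, x$Delta_T_det))
  cat(sprintf("  erroneous threshold crossings: %d\n", x$n_resets))
  print(x$constants)
  invisible(x)
}

#' @export
coef.isi_transduction <- function(object, ...) {
  tc <- object$constants
  c(h0 = tc$h0, c0 = tc$c0,
    Kconst = if (object$model == "eif") tc$K_EIF0 else tc$K_LIF0,
    K = object$hazard$K)
}

#' Analytic prediction of the output log-modulation
#'
#' The small-signal transfer-function prediction of ln Dp_out for the
#' fitted configuration (see [predict_logmod()]).  Both the prediction and
#' the simulated `ln_dp_out` are anchored at ln Dp_out(0) = 0 (the hazard
#' starts unperturbed at a spike), so they are directly comparable.
#'
#' @param object an [isi_transduction()] fit.
#' @param ... passed to [predict_logmod()] (e.g. `transient = FALSE`).
#' @return predicted ln Dp_out as a [sampled_fun()].
#' @export
predict.isi_transduction <- function(object, ...) {
  predict_logmod(object$target$ln_dp_in, object$constants,
                 object$model, ...)
}

#' Draw ISI samples from the fitted output distribution
#'
#' @param object an [isi_transduction()] fit.
#' @param nsim number of ISIs to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return numeric vector of ISIs (seconds).
#' @export
simulate.isi_transduction <- function(object, nsim = 1, seed = NULL, ...) {
  sample_isis(object$p_out, nsim, seed = seed)
}

#' @export
residuals.isi_transduction <- function(object, ...) {
  sampled_fun(object$ln_dp_out$values - object$ln_dp_in$values,
              object$target$grid, "1")
}

#' @export
plot.isi_transduction <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tt <- grid_times(x$target$grid)
  ylim <- range(x$ln_dp_in$values, x$ln_dp_out$values)
  plot(tt, x$ln_dp_in$values, type = "l", col = "red", ylim = ylim,
       xlab = "t (s)", ylab = "ln Dp(t)",
       main = sprintf("log-modulation (%s)", toupper(x$model)), ...)
  graphics::lines(tt, x$ln_dp_out$values, col = "blue")
  graphics::legend("topright", c("target", "output"), lty = 1,
                   col = c("red", "blue"), bty = "n")
  plot(tt, x$target$p_in$p, type = "l", col = "red",
       xlab = "t (s)", ylab = "p(t) (1/s)", main = "ISI densities")
  graphics::lines(tt, x$p_out$p, col = "blue")
  invisible(x)
}
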