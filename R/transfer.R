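#' Small-signal transfer constants
#'
#' The coefficients of the linearized hazard dynamics around a voltage
#' baseline V0: c0 = exp((V_T - V0)/Delta_T_det) and the hazard-feedback
#' weights
#' \deqn{K_{EIF,0} = -K c_0 + K - 1,\qquad K_{LIF,0} = -K c_0 - 1.}
#' As V0 approaches threshold, |K_EIF,0| collapses to 1 while |K_LIF,0|
#' converges to K + 1 — the analytic root of the EIF's advantage.
#'
#' @inheritParams baseline_hazard
#' @return object of class `"transfer_constants"` with `c0`, `K_EIF0`,
#'   `K_LIF0`, `h0` (1/s) and `V0`.
#' @export
transfer_constants <- function(V0, neuron, hazard) {
  c0 <- exp((neuron$V_T - V0) / hazard$Delta_T_det)
  K <- hazard$K
  structure(list(V0 = V0, c0 = c0,
                 K_EIF0 = -K * c0 + K - 1,
                 K_LIF0 = -K * c0 - 1,
                 h0 = baseline_hazard(V0, neuron, hazard)),
            class = "transfer_constants")
}

#' @export
print.transfer_constants <- function(x, ...) {
  cat(sprintf(
    "transfer constants at V0 = %g mV: c0 = %.4g, K_EIF0 = %.4g, K_LIF0 = %.4g, h0 = %.4g Hz\n",
    x$V0, x$c0, x$K_EIF0, x$K_LIF0, x$h0))
  invisible(x)
}

#' Probability-modulation transfer function
#'
#' \deqn{T(s) = \frac{s - h_0}{s - h_0 - K' h_0},\qquad s = i 2\pi f,}
#' the small-signal ratio of output to input log-modulation.  K' = 0 gives
#' the identity transducer; for any K' the gain tends to 1 and the phase to
#' 0 at high frequencies.
#'
#' @param f frequency (Hz), vectorized, nonnegative.
#' @param h0 baseline hazard (1/s).
#' @param Kconst hazard-feedback weight (K_EIF0 or K_LIF0).
#' @return complex response T(i 2 pi f).
#' @export
transfer_function <- function(f, h0, Kconst) {
  if (any(f < 0)) stop("frequencies must be nonnegative")
  s <- 1i * 2 * pi * f
  den <- s - h0 - Kconst * h0
  if (any(Mod(den) == 0))
    stop("transfer function evaluated at its singular pole")
  (s - h0) / den
}

#' Bode curves for the EIF and LIF transducers
#'
#' Gain and unwrapped phase of T(i 2 pi f) for both models across a set of
#' voltage baselines.  Phase is in degrees, negative meaning lag.
#'
#' @param frequencies positive, sorted frequencies in Hz; default 200
#'   log-spaced points on [1, 300] Hz.
#' @param V0_values baseline voltages (mV); default 8 equidistant values from
#'   -65 mV to V_T - 1 mV.
#' @inheritParams baseline_hazard
#' @return a `data.frame` of class `"bode_result"` with columns
#'   `frequency_hz`, `model`, `V0_mV`, `gain`, `phase_deg`.
#' @export
bode <- function(frequencies = NULL, V0_values = NULL, neuron, hazard) {
  if (is.null(frequencies))
    frequencies <- exp(seq(log(1), log(300), length.out = 200L))
  if (is.unsorted(frequencies) || any(frequencies <= 0))
    stop("frequencies must be positive and sorted")
  if (is.null(V0_values))
    V0_values <- seq(-65, neuron$V_T - 1, length.out = 8L)
  rows <- lapply(V0_values, function(V0) {
    tc <- transfer_constants(V0, neuron, hazard)
    lapply(c(eif = "eif", lif = "lif"), function(m) {
      Kc <- if (m == "eif") tc$K_EIF0 else tc$K_LIF0
      Tf <- transfer_function(frequencies, tc$h0, Kc)
      data.frame(frequency_hz = frequencies, model = m, V0_mV = V0,
                 gain = Mod(Tf),
                 phase_deg = signal::unwrap(Arg(Tf)) * 180 / pi)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  class(out) <- c("bode_result", "data.frame")
  out
}

#' @export
plot.bode_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  v0s <- sort(unique(x$V0_mV))
  cols <- grDevices::hcl.colors(length(v0s), "Zissou 1")
  panels <- expand.grid(what = c("phase_deg", "gain"),
                        model = c("eif", "lif"),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(panels))) {
    m <- panels$model[r]; w <- panels$what[r]
    sub <- x[x$model == m, ]
    ylab <- if (w == "gain") "amplitude gain" else "phase shift (deg)"
    plot(NA, xlim = range(sub$frequency_hz), ylim = range(sub[[w]]),
         log = "x", xlab = "frequency (Hz)", ylab = ylab,
         main = toupper(m), ...)
    for (j in seq_along(v0s)) {
      s <- sub[sub$V0_mV == v0s[j], ]
      graphics::lines(s$frequency_hz, s[[w]], col = cols[j])
    }
    if (w == "gain") graphics::abline(h = 1, lty = 3)
    else graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Spectral prediction of the output log-modulation
#'
#' Applies the transfer function componentwise to the input log-modulation:
#' each sinusoid is scaled by |T(i 2 pi f)| and shifted by arg T, the
#' constant offset by the real T(0).  Because the analysis assumes zero
#' initial conditions (the hazard starts unperturbed at a spike), the exact
#' inverse of T(s) U(s) also carries a start-up transient decaying at the
#' system pole h0 (1 + K'); it is included by default and dropped with
#' `transient = FALSE` for the pure steady-state Bode reading.  For
#' tabulated signals without sinusoid parameters the filtering is done on
#' the FFT (periodic, hence transient-free).
#'
#' @param ln_dp_in input log-modulation as a [sampled_fun()] (with the
#'   `"mod_params"` attribute from [make_log_modulation()] when available).
#' @param constants a [transfer_constants()].
#' @param model `"eif"` or `"lif"`.
#' @param transient include the zero-initial-condition start-up term.
#' @return predicted ln Dp_out as a [sampled_fun()].
#' @export
predict_logmod <- function(ln_dp_in, constants, model = c("eif", "lif"),
                           transient = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(ln_dp_in, "sampled_fun"),
            inherits(constants, "transfer_constants"))
  Kc <- if (model == "eif") constants$K_EIF0 else constants$K_LIF0
  h0 <- constants$h0
  grid <- ln_dp_in$grid
  mp <- attr(ln_dp_in, "mod_params")
  if (!is.null(mp)) {
    tt <- grid_times(grid)
    pole <- h0 * (1 + Kc)            # < 0 whenever c0 > 1 - 1/K
    out <- numeric(grid$n)
    # a constant input component never perturbs the hazard (Dh(0) = 0 and
    # nothing drives it), so the DC offset beta is not transduced at all
    if (mp$alpha != 0) {
      for (k in seq_along(mp$freqs)) {
        w <- 2 * pi * mp$freqs[k]
        phi <- mp$phases[k]
        Tf <- transfer_function(mp$freqs[k], h0, Kc)
        steady <- Mod(Tf) * sin(w * tt + phi + Arg(Tf))
        if (transient && pole != 0) {
          # exact solution of y'' - pole*y' = u'' - h0 u' with
          # y(0) = 0, y'(0) = u'(0): steady state + C e^{pole t} + D
          Ck <- (w * cos(phi) - Mod(Tf) * w * cos(phi + Arg(Tf))) / pole
          Dk <- -Mod(Tf) * sin(phi + Arg(Tf)) - Ck
          steady <- steady + Ck * exp(pole * tt) + Dk
        }
        out <- out + mp$alpha * steady
      }
    }
    return(sampled_fun(out, grid, "1"))
  }
  # FFT route: filter each discrete frequency bin
  v <- ln_dp_in$values
  n <- grid$n
  fbin <- (seq_len(n) - 1L) / (n * grid$dt)
  fbin[fbin > 1 / (2 * grid$dt)] <- fbin[fbin > 1 / (2 * grid$dt)] - 1 / grid$dt
  Tf <- transfer_function(abs(fbin), h0, Kc)
  Tf[fbin < 0] <- Conj(Tf[fbin < 0])
  out <- Re(stats::fft(stats::fft(v) * Tf, inverse = TRUE)) / n
  sampled_fun(out, grid, "1")
}
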