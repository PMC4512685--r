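#' Log-normal parameters from the probability fluctuation ratio
#'
#' For a log-normally distributed modulation Dp with unit mean and
#' coefficient of variation r_dp, the log-variance and log-mean are
#' \deqn{\sigma^2 = \ln(r_{\Delta p}^2 + 1),\qquad \mu = -\sigma^2/2.}
#'
#' @param r_dp probability fluctuation ratio (>= 0), read as the CV of Dp.
#' @return list with `sigma2` and `mu`.
#' @export
lognormal_params <- function(r_dp) {
  if (r_dp < 0) stop("r_dp must be nonnegative")
  sigma2 <- log(r_dp^2 + 1)
  list(sigma2 = sigma2, mu = -sigma2 / 2)
}

#' Range model for realizable ISI distributions
#'
#' Models the per-time marginal of the ISI density under stationary
#' log-normal modulation: at each t, p(t) = p_0(t) Dp(t) is log-normal with
#' log-mean mu + ln h0 - h0 t and log-variance sigma^2, so its mean is the
#' exponential baseline p_0(t) = h0 exp(-h0 t) exactly.
#'
#' @param h0 baseline hazard (1/s).
#' @param r_dp probability fluctuation ratio (CV of Dp).
#' @return object of class `"range_model"`.
#' @export
range_model <- function(h0, r_dp) {
  stopifnot(h0 > 0)
  lp <- lognormal_params(r_dp)
  structure(list(h0 = h0, r_dp = r_dp, sigma2 = lp$sigma2, mu = lp$mu),
            class = "range_model")
}

#' @export
print.range_model <- function(x, ...) {
  cat(sprintf(
    "log-normal range model: h0 = %.4g Hz, r_dp = %g (sigma2 = %.4g, mu = %.4g)\n",
    x$h0, x$r_dp, x$sigma2, x$mu))
  invisible(x)
}

#' Per-time distribution of realizable density values
#'
#' The log-normal distribution of p(t) at a fixed time t.
#'
#' @param t time since the last spike (s), vectorized, >= 0.
#' @param model a [range_model()].
#' @return data.frame with `t_s`, `meanlog`, `sdlog`, the closed-form `mean`
#'   (equal to h0 exp(-h0 t)) and a `density` function attribute is not
#'   stored; use `stats::dlnorm(p, meanlog, sdlog)` rowwise.
#' @export
value_density <- function(t, model) {
  stopifnot(inherits(model, "range_model"), all(t >= 0))
  meanlog <- model$mu + log(model$h0) - model$h0 * t
  sdlog <- sqrt(model$sigma2)
  data.frame(t_s = t, meanlog = meanlog, sdlog = sdlog,
             mean = exp(meanlog + model$sigma2 / 2))
}

#' Quantile band of realizable ISI-density values over time
#'
#' Closed-form log-normal quantiles of p(t) per time point, with the
#' exponential baseline p_0(t) overlay.  With r_dp = 0 every quantile
#' collapses onto p_0.
#'
#' @param model a [range_model()].
#' @param grid a [time_grid()].
#' @param quantiles probabilities in (0, 1);
#'   default `c(0.025, 0.25, 0.5, 0.75, 0.975)`.
#' @return object of class `"range_summary"`: long data.frame `table`
#'   (`t_s`, `quantile`, `p_value`), baseline `p0`, and the model.
#' @export
range_summary <- function(model, grid,
                          quantiles = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(model, "range_model"), inherits(grid, "time_grid"),
            all(quantiles > 0 & quantiles < 1))
  tt <- grid_times(grid)
  vd <- value_density(tt, model)
  tab <- do.call(rbind, lapply(quantiles, function(q) {
    data.frame(t_s = tt, quantile = q,
               p_value = stats::qlnorm(q, vd$meanlog, vd$sdlog))
  }))
  structure(list(table = tab,
                 p0 = sampled_fun(model$h0 * exp(-model$h0 * tt), grid, "1/s"),
                 model = model),
            class = "range_summary")
}

#' @export
print.range_summary <- function(x, ...) {
  cat("realizable-range summary for ")
  print(x$model)
  cat(sprintf("  %d time points x %d quantiles\n",
              length(unique(x$table$t_s)), length(unique(x$table$quantile))))
  invisible(x)
}

#' @export
plot.range_summary <- function(x, ...) {
  qs <- sort(unique(x$table$quantile))
  tt <- unique(x$table$t_s)
  mat <- sapply(qs, function(q) x$table$p_value[x$table$quantile == q])
  graphics::matplot(tt, mat, type = "l", lty = 2, col = "grey40",
                    xlab = "t (s)", ylab = "p(t) (1/s)",
                    main = sprintf("realizable range, r_dp = %g, h0 = %.3g Hz",
                                   x$model$r_dp, x$model$h0), ...)
  graphics::lines(tt, x$p0$values, col = "blue", lwd = 2)
  invisible(x)
}
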