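#' @title Renewal-theory transforms between hazard, survivor and ISI density
#'
#' @description
#' For a renewal spike train the time since the last spike fully determines
#' the firing statistics.  The hazard h(t) (conditional instantaneous firing
#' rate), the survivor function S(t) (probability of no spike up to t) and
#' the ISI density p(t) are linked by
#' \deqn{S(t) = \exp(-\int_0^t h),\qquad p(t) = S(t)\,h(t),\qquad h = p/S.}
#' These functions implement the three transforms on a uniform grid using
#' cumulative trapezoid integration, plus inverse-transform ISI sampling.
#'
#' @name renewal
NULL

# survivor values below this are clamped to 0 and flagged
.S_UNDERFLOW <- 1e-300

#' Survivor function from a hazard
#'
#' @param h nonnegative hazard as a [sampled_fun()] in 1/s.
#' @return survivor function S(t) as a dimensionless [sampled_fun()];
#'   `attr(, "underflow")` is TRUE where S fell below 1e-300 and was clamped.
#' @examples
#' g <- time_grid(dt = 1e-3, t_max = 1)
#' S <- survivor_from_hazard(sampled_fun(rep(10, g$n), g, "1/s"))
#' all.equal(S$values, exp(-10 * grid_times(g)))
#' @export
survivor_from_hazard <- function(h) {
  stopifnot(inherits(h, "sampled_fun"))
  if (any(h$values < 0))
    stop("hazard must be nonnegative everywhere")
  H <- cumtrapz_uniform(h$values, h$grid$dt)
  S <- exp(-H)
  under <- S < .S_UNDERFLOW
  S[under] <- 0
  out <- sampled_fun(S, h$grid, "1")
  attr(out, "underflow") <- under
  out
}

#' ISI distribution (density + survivor)
#'
#' @param p density values (1/s) per grid point.
#' @param S survivor values per grid point.
#' @param grid a [time_grid()].
#' @return object of class `"isi_distribution"` with fields `grid`, `p`, `S`.
#' @export
isi_distribution <- function(p, S, grid) {
  stopifnot(inherits(grid, "time_grid"),
            length(p) == grid$n, length(S) == grid$n)
  if (any(p < 0)) stop("ISI density must be nonnegative")
  structure(list(grid = grid, p = as.numeric(p), S = as.numeric(S)),
            class = "isi_distribution")
}

#' @export
print.isi_distribution <- function(x, ...) {
  mass <- trapz_uniform(x$p, x$grid$dt)
  cat("ISI distribution on ")
  print(x$grid)
  cat(sprintf("  mass on window: %.4f, S(T) = %.4g\n",
              mass, x$S[length(x$S)]))
  invisible(x)
}

#' ISI density from a hazard
#'
#' Computes p(t) = S(t) h(t) with S from [survivor_from_hazard()].  On any
#' finite window the mass budget \eqn{\int_0^T p + S(T) = 1} holds up to
#' integration error.
#'
#' @inheritParams survivor_from_hazard
#' @return an [isi_distribution()].
#' @export
isi_from_hazard <- function(h) {
  S <- survivor_from_hazard(h)
  isi_distribution(S$values * h$values, S$values, h$grid)
}

#' Hazard from an ISI density
#'
#' Recovers h = p / S, recomputing the survivor from the density alone as
#' S(t) = 1 - \eqn{\int_0^t p} (so the transform is a genuine inverse of
#' [isi_from_hazard()] rather than a lookup of a stored survivor).
#'
#' @param p an [isi_distribution()].
#' @return hazard as a [sampled_fun()] in 1/s.
#' @export
hazard_from_isi <- function(p) {
  stopifnot(inherits(p, "isi_distribution"))
  S <- 1 - cumtrapz_uniform(p$p, p$grid$dt)
  bad <- which(S <= .S_UNDERFLOW)
  if (length(bad)) {
    t_bad <- grid_times(p$grid)[bad[1L]]
    stop(sprintf(
      "survivor function exhausted (S <= 0) at t = %.6g s; shorten the window",
      t_bad))
  }
  sampled_fun(p$p / S, p$grid, "1/s")
}

#' Inverse-transform sampling of ISIs
#'
#' Draws `count` interspike intervals from an ISI distribution by inverting
#' its CDF F(t) = 1 - S(t) with linear interpolation on the grid.  The window
#' must cover at least 99\% of the probability mass; the residual tail is
#' folded back by scaling the uniforms to F(T).
#'
#' @param p an [isi_distribution()] whose window holds >= 0.99 probability mass.
#' @param count number of samples.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of ISIs in seconds.
#' @export
sample_isis <- function(p, count, seed = NULL) {
  stopifnot(inherits(p, "isi_distribution"), count >= 1)
  tt <- grid_times(p$grid)
  F <- cumtrapz_uniform(p$p, p$grid$dt)
  F_T <- F[length(F)]
  if (F_T < 0.99)
    stop(sprintf(
      "window holds only %.3f of the probability mass; use a longer window (see recommend_window())",
      F_T))
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(count) * F_T
  # F is non-decreasing; ties = "ordered" tolerates flat (p = 0) stretches
  stats::approx(F, tt, xout = u, ties = "ordered", rule = 2)$y
}

#' Recommended ISI window for a baseline hazard
#'
#' Window length T such that the exponential baseline survivor falls below
#' `tail`, i.e. T = -log(tail) / h0.
#'
#' @param h0 baseline hazard (1/s).
#' @param tail survivor mass allowed beyond the window (default 0.01).
#' @return window length in seconds.
#' @export
recommend_window <- function(h0, tail = 0.01) {
  stopifnot(h0 > 0, tail > 0, tail < 1)
  -log(tail) / h0
}
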