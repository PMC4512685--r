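#' Uniform time grid
#'
#' A uniform time axis starting at t = 0, the common carrier for voltage
#' traces, currents, hazards and ISI densities.  All times are in seconds.
#'
#' @param dt time step in seconds (default 5e-5 s, i.e. 0.05 ms).
#' @param n number of grid points (>= 2).
#' @param t_max alternative to `n`: total window length in seconds; the grid
#'   then has `floor(t_max / dt) + 1` points.
#' @return An object of class `"time_grid"` with fields `dt` and `n`.
#' @examples
#' g <- time_grid(dt = 1e-3, t_max = 0.5)
#' range(grid_times(g))
#' @export
time_grid <- function(dt = 5e-5, n = NULL, t_max = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive number (seconds)")
  if (is.null(n)) {
    if (is.null(t_max)) stop("supply either 'n' or 't_max'")
    n <- floor(t_max / dt) + 1L
  }
  n <- as.integer(n)
  if (n < 2L) stop("a time grid needs at least 2 points")
  structure(list(dt = dt, n = n), class = "time_grid")
}

#' Times of a grid
#' @param grid a [time_grid()].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  (seq_len(grid$n) - 1L) * grid$dt
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid: %d points, dt = %g ms, window = %g s\n",
              x$n, x$dt * 1e3, (x$n - 1L) * x$dt))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-12) {
  a$n == b$n && abs(a$dt - b$dt) < tol * max(a$dt, b$dt)
}

#' Real-valued signal on a time grid
#'
#' @param values numeric vector, one value per grid point.
#' @param grid a [time_grid()].
#' @param unit unit label, e.g. `"1/s"`, `"mV"`, `"mV/s"`.
#' @return An object of class `"sampled_fun"`.
#' @export
sampled_fun <- function(values, grid, unit = "") {
  stopifnot(inherits(grid, "time_grid"))
  if (length(values) != grid$n)
    stop("length(values) must equal the number of grid points")
  structure(list(grid = grid, values = as.numeric(values), unit = unit),
            class = "sampled_fun")
}

#' @export
print.sampled_fun <- function(x, ...) {
  cat(sprintf("sampled function [%s] on ", x$unit))
  print(x$grid)
  cat(sprintf("  range: [%.6g, %.6g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.sampled_fun <- function(x, ...) {
  data.frame(time_s = grid_times(x$grid), value = x$values)
}

#' Write a signal to CSV with a JSON metadata sidecar
#'
#' Two-column CSV `(time_s, value)` plus `<path>.json` holding the unit and
#' time step, so a written trace is self-describing.
#'
#' @param x a [sampled_fun()] or [isi_distribution()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  if (inherits(x, "isi_distribution")) {
    df <- data.frame(time_s = grid_times(x$grid), p = x$p, S = x$S)
    meta <- list(kind = "isi_distribution", dt_s = x$grid$dt, n = x$grid$n,
                 units = list(p = "1/s", S = "1"))
  } else {
    stopifnot(inherits(x, "sampled_fun"))
    df <- as.data.frame(x)
    meta <- list(kind = "sampled_fun", dt_s = x$grid$dt, n = x$grid$n,
                 unit = x$unit)
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# cumulative trapezoid on a uniform grid; first element is 0
cumtrapz_uniform <- function(values, dt) {
  as.numeric(pracma::cumtrapz(values)) * dt
}

trapz_uniform <- function(values, dt) {
  pracma::trapz(values) * dt
}
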