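#' Run configuration for the command-style experiments
#'
#' Validates and normalizes a configuration list (typically read from YAML)
#' shared by the experiment runners.  Recognized fields: the parameter block
#' of [read_params_config()] (`C_m`, `g_L`, `E_L`, `V_T`, `Delta_T`, `V_p`,
#' `dt`, `K`, `Delta_T_det`, `regime`), a modulation block (`n_sinusoids`,
#' `f_lo`, `f_hi`, `r_dp`, `band`), `V0`, `model` (`"eif"`, `"lif"` or
#' `"both"`), `seed`, `quick`, `window_s`.
#'
#' @param config list or YAML path.
#' @return validated config list of class `"run_config"`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  pb <- params_from_list(config)
  V0 <- config$V0 %||% -51.4
  if (V0 < pb$neuron$E_L || V0 >= pb$neuron$V_p)
    stop("invalid config field 'V0': must lie in [E_L, V_p)")
  model <- config$model %||% "both"
  if (!model %in% c("eif", "lif", "both"))
    stop("invalid config field 'model': use eif, lif or both")
  seed <- as.integer(config$seed %||% 1L)
  r_dp <- config$r_dp %||% 0.44
  if (r_dp < 0 || r_dp >= 1) stop("invalid config field 'r_dp'")
  spec <- if (!is.null(config$band) && is.null(config$f_lo)) {
    modulation_spec_band(config$band, r_dp = r_dp, seed = seed)
  } else {
    modulation_spec(config$n_sinusoids %||% 60L,
                    config$f_lo %||% 10, config$f_hi %||% 200,
                    r_dp = r_dp, seed = seed)
  }
  structure(list(neuron = pb$neuron, hazard = pb$hazard, dt = pb$dt,
                 V0 = V0, model = model, seed = seed, spec = spec,
                 band = config$band %||% "low",
                 quick = isTRUE(config$quick),
                 window_s = config$window_s %||% (5 / spec$f_lo),
                 raw = config),
            class = "run_config")
}

#' Fig-5-style preset configuration
#'
#' The broadband showcase: 60 sinusoids on [10, 200] Hz, V0 = -51.4 mV
#' (one mV below threshold, h0 = 7.2 Hz), r_dp = 0.44, high conductance.
#'
#' @param seed modulation seed.
#' @return a [run_config()].
#' @export
showcase_config <- function(seed = 1L) {
  run_config(list(n_sinusoids = 60L, f_lo = 10, f_hi = 200, r_dp = 0.44,
                  V0 = -51.4, regime = "high", seed = seed))
}

write_manifest <- function(outdir, cfg, extra = list()) {
  manifest <- c(list(
    package = "isisampler",
    version = as.character(utils::packageVersion("isisampler")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg$raw), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the transduction experiment and write its artifacts
#'
#' Builds the target from the config, transduces it through the requested
#' model(s), and writes target/current/voltage/hazard/output traces as CSV,
#' a `summary.json` with the L1 scores, and a `manifest.json` sufficient to
#' re-run the experiment identically.
#'
#' @param config a [run_config()], list, or YAML path.
#' @param outdir output directory (created if needed).
#' @param plot if TRUE also write a PDF figure.
#' @return the per-model list of [isi_transduction()] fits, invisibly.
#' @export
run_simulation_experiment <- function(config = showcase_config(),
                                      outdir, plot = FALSE) {
  cfg <- as_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  grid <- time_grid(dt = cfg$dt, t_max = cfg$window_s)
  target <- suppressWarnings(
    build_target(cfg$spec, cfg$V0, cfg$neuron, cfg$hazard, grid))
  models <- if (cfg$model == "both") c("eif", "lif") else cfg$model
  fits <- lapply(stats::setNames(models, models), function(m)
    isi_transduction(target, cfg$neuron, cfg$hazard, model = m))

  write_signal_csv(target$ln_dp_in, file.path(outdir, "ln_dp_in.csv"))
  write_signal_csv(target$p_in, file.path(outdir, "p_in.csv"))
  for (m in models) {
    f <- fits[[m]]
    write_signal_csv(f$current, file.path(outdir, sprintf("current_%s.csv", m)))
    write_signal_csv(f$trajectory$V, file.path(outdir, sprintf("voltage_%s.csv", m)))
    write_signal_csv(f$hazard_out, file.path(outdir, sprintf("hazard_%s.csv", m)))
    write_signal_csv(f$p_out, file.path(outdir, sprintf("p_out_%s.csv", m)))
    write_signal_csv(f$ln_dp_out, file.path(outdir, sprintf("ln_dp_out_%s.csv", m)))
  }
  jsonlite::write_json(
    list(L1 = lapply(fits, `[[`, "l1"),
         h0_hz = target$h0, V0_mV = cfg$V0, r_dp = cfg$spec$r_dp),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, cfg, list(experiment = "simulate",
                                   window_s = cfg$window_s))
  if (plot) {
    grDevices::pdf(file.path(outdir, "simulate.pdf"), width = 7, height = 7)
    for (m in models) plot(fits[[m]])
    grDevices::dev.off()
  }
  invisible(fits)
}

#' Run the Bode experiment
#'
#' Gain/phase tables for both models across voltage baselines for one or
#' both conductance regimes, written as `bode_<regime>.csv`.
#'
#' @inheritParams run_simulation_experiment
#' @param regimes character vector of conductance regimes to cover.
#' @return named list of [bode()] tables, invisibly.
#' @export
run_bode_experiment <- function(config = list(), outdir,
                                regimes = c("high", "low"), plot = FALSE) {
  cfg <- as_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- lapply(stats::setNames(regimes, regimes), function(rg) {
    np <- neuron_params(rg)
    b <- bode(neuron = np, hazard = hazard_params(np))
    utils::write.csv(b, file.path(outdir, sprintf("bode_%s.csv", rg)),
                     row.names = FALSE)
    b
  })
  write_manifest(outdir, cfg, list(experiment = "bode", regimes = regimes))
  if (plot) {
    grDevices::pdf(file.path(outdir, "bode.pdf"), width = 8, height = 6)
    for (b in out) plot(b)
    grDevices::dev.off()
  }
  invisible(out)
}

#' Run the (V0 x r_dp) sweep experiment
#'
#' @inheritParams run_simulation_experiment
#' @param band frequency band, `"low"` or `"high"`.
#' @return the [run_sweep()] result, invisibly.
#' @export
run_sweep_experiment <- function(config = list(), outdir,
                                 band = NULL, plot = FALSE) {
  cfg <- as_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  band <- band %||% cfg$band
  sw <- run_sweep(band, cfg$neuron, cfg$hazard, quick = cfg$quick,
                  seed = cfg$seed, dt = cfg$dt)
  utils::write.csv(as.data.frame(sw),
                   file.path(outdir, sprintf("sweep_%s.csv", band)),
                   row.names = FALSE)
  write_manifest(outdir, cfg, list(experiment = "sweep", band = band,
                                   window_s = sw$window_s,
                                   quick = cfg$quick))
  if (plot) {
    grDevices::pdf(file.path(outdir, "sweep.pdf"), width = 8, height = 4)
    plot(sw)
    grDevices::dev.off()
  }
  invisible(sw)
}

#' Run the realizable-range experiment
#'
#' Quantile tables of the log-normal range model over a grid of r_dp and h0
#' values, written as `range.csv`.
#'
#' @inheritParams run_simulation_experiment
#' @param r_dp_values,h0_values grids for the model parameters.
#' @return long data.frame of quantile tables, invisibly.
#' @export
run_range_experiment <- function(config = list(), outdir,
                                 r_dp_values = c(0.2, 0.5, 0.8),
                                 h0_values = c(1, 5, 10), plot = FALSE) {
  cfg <- as_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (r in r_dp_values) for (h0 in h0_values) {
    grid <- time_grid(dt = recommend_window(h0) / 200, n = 201L)
    rs <- range_summary(range_model(h0, r), grid)
    rows[[length(rows) + 1L]] <-
      cbind(r_dp = r, h0 = h0, rs$table)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(outdir, "range.csv"), row.names = FALSE)
  write_manifest(outdir, cfg, list(experiment = "range",
                                   r_dp_values = r_dp_values,
                                   h0_values = h0_values))
  if (plot) {
    grDevices::pdf(file.path(outdir, "range.pdf"), width = 6, height = 4)
    plot(range_summary(range_model(h0_values[1L], r_dp_values[1L]),
                       time_grid(dt = recommend_window(h0_values[1L]) / 200,
                                 n = 201L)))
    grDevices::dev.off()
  }
  invisible(tab)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else run_config(config)
}
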