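#' Root-mean-square error between paired series
#'
#' `sqrt(mean((yL - yB)^2))`, the per-sample RMSE between a mapped
#' fixed-point trace and its continuous reference, in the units of the
#' series (mV for membrane potential).
#'
#' @param yB Reference series.
#' @param yL Mapped (inverse-transformed) series of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(yB, yL) {
  if (length(yB) != length(yL)) stop("series lengths differ")
  if (length(yB) < 1) stop("need at least one sample")
  sqrt(mean((yL - yB)^2))
}

#' Pearson product-moment correlation between paired series
#'
#' Written out explicitly (sum of co-deviations over the root product of
#' sums of squared deviations) rather than delegated, so the statistic
#' under test is the one defined by the validation procedure; it agrees
#' with `stats::cor` to machine precision.
#'
#' @inheritParams rmse
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(yB, yL) {
  if (length(yB) != length(yL)) stop("series lengths differ")
  if (length(yB) < 2) stop("need at least two samples")
  dB <- yB - mean(yB); dL <- yL - mean(yL)
  den <- sqrt(sum(dL^2) * sum(dB^2))
  if (den == 0) stop("undefined correlation: a series has zero variance")
  sum(dL * dB) / den
}

# Shared-bin histogram densities for a pair of series.
.paired_histogram <- function(a, b, bins) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  list(breaks = breaks,
       density_ref = graphics::hist(a, breaks = breaks, plot = FALSE)$density,
       density_emu = graphics::hist(b, breaks = breaks, plot = FALSE)$density)
}

.series_report <- function(ref, emu, n_samples) {
  fit <- stats::lm.fit(cbind(1, ref), emu)
  list(rmse = rmse(ref, emu),
       rmse_per_ms = rmse(ref, emu) / n_samples,
       pearson = pearson(ref, emu),
       trend = c(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2])))
}

#' Compare a reference trace with an inverse-mapped emulator run
#'
#' Inverse-maps the fixed-point states to physical units (`V = v*Vs + Vr`
#' for voltage; `I = u*C*Vs/dt` for current), aligns the two runs on the
#' shared step grid, and computes the validation statistics per state
#' variable: per-sample RMSE (mV / pA), the run-normalized RMSE
#' `rmse / n` on which run-level errors are reported (mV per ms of
#' simulated time at the default 1-ms step; see the methods vignette),
#' Pearson correlation, a least-squares trend over the paired samples,
#' shared-bin histogram densities, and the spike rasters of both sides.
#'
#' @param ref A `state_trace` from [simulate_reference()].
#' @param emu An `emulator_run` from [simulate_emulator()].
#' @param params A [neuron_params()] (for the inverse transforms); defaults
#'   to the compartment's originating parameters.
#' @param cfg A [mapping_config()]; defaults to the compartment's.
#' @param bins Number of shared histogram bins.
#' @return An object of class `validation_report` with elements `n`, `v`
#'   and `i` (each: `rmse`, `rmse_per_ms`, `pearson`, `trend`),
#'   `histogram_v`, `paired_v` (data frame of aligned samples), and
#'   `raster` (reference spike times and emulator spike steps).
#' @examples
#' pair <- simulate_pair(lif_table1()[["1"]], NULL, T = 500)
#' compare_runs(pair$ref, pair$emu)
#' @export
compare_runs <- function(ref, emu, params = emu$comp$params,
                         cfg = emu$comp$cfg, bins = 60) {
  n <- length(ref$V)
  if (n != emu$n_steps)
    stop("grid mismatch: reference has ", n, " samples, emulator ",
         emu$n_steps, " steps")
  if (abs(ref$h - cfg$dt) > 1e-12)
    stop("grid mismatch: reference h != mapping dt")
  V_emu <- voltage_from_loihi(emu$v_trace, params, cfg)
  I_emu <- current_from_levels(emu$u_trace, params, cfg)
  rep_v <- .series_report(ref$V, V_emu, n)
  rep_i <- if (stats::var(ref$I) > 0 || stats::var(I_emu) > 0)
    list(rmse = rmse(ref$I, I_emu),
         rmse_per_ms = rmse(ref$I, I_emu) / n,
         pearson = if (stats::var(ref$I) > 0 && stats::var(I_emu) > 0)
           pearson(ref$I, I_emu) else NA_real_,
         trend = NULL)
  else NULL
  structure(list(n = n,
                 v = rep_v, i = rep_i,
                 histogram_v = .paired_histogram(ref$V, V_emu, bins),
                 paired_v = data.frame(ref = ref$V, emu = V_emu),
                 raster = list(ref_spike_times = ref$spikes,
                               emu_spike_steps = emu$spike_steps),
                 cfg = cfg),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation report over %d samples (dt = %g ms)\n",
              x$n, x$cfg$dt))
  cat(sprintf("  membrane potential: r = %.6f, RMSE = %.4g mV (%.4g mV/ms)\n",
              x$v$pearson, x$v$rmse, x$v$rmse_per_ms))
  if (!is.null(x$i))
    cat(sprintf("  synaptic current:   r = %s, RMSE = %.4g pA\n",
                if (is.na(x$i$pearson)) "NA" else sprintf("%.6f", x$i$pearson),
                x$i$rmse))
  invisible(x)
}

#' Temporal-precision sweep
#'
#' Re-runs the paired simulation at each requested step size and tabulates
#' the per-state errors. The emulator executes `T / dt` steps per row
#' (5000 at dt = 0.1 ms, 50 at dt = 10 ms for a 500 ms run). Step sizes at
#' which the neuron's time constants are not representable are flagged in
#' the output rather than raised.
#'
#' @param params A [neuron_params()].
#' @param stimulus A stimulus object or `NULL`.
#' @param dts Step sizes to test, ms/step.
#' @param T Duration, ms.
#' @param cfg Base [mapping_config()]; each row overrides `dt`.
#' @param threshold Passed to [simulate_pair()] (default `FALSE`:
#'   subthreshold state fidelity).
#' @return A data frame with one row per `dt`: `dt`, `n_steps`, `ok`,
#'   `rmse_v`, `rmse_v_per_ms`, `r_v`, `rmse_u`, `note`.
#' @export
sweep_dt <- function(params, stimulus = NULL, dts = c(0.1, 1, 10), T = 500,
                     cfg = mapping_config(), threshold = FALSE) {
  rows <- lapply(dts, function(dt) {
    cfg_i <- mapping_config(Vs = cfg$Vs, dt = dt, rounding = cfg$rounding)
    .sweep_row(params, stimulus, T, cfg_i, threshold,
               data.frame(dt = dt, n_steps = round(T / dt)))
  })
  do.call(rbind, rows)
}

#' Voltage-precision sweep
#'
#' As [sweep_dt()], but varying the voltage scale `Vs`. Scales at which
#' the threshold overflows the 23-bit state register are flagged per row.
#'
#' @inheritParams sweep_dt
#' @param vs_list Voltage scales to test, mV/level.
#' @return A data frame with one row per `Vs`: `Vs`, `n_steps`, `ok`,
#'   `rmse_v`, `rmse_v_per_ms`, `r_v`, `rmse_u`, `note`.
#' @export
sweep_vs <- function(params, stimulus = NULL,
                     vs_list = c(1e-3, 1e-4, 1e-5), T = 500,
                     cfg = mapping_config(), threshold = FALSE) {
  rows <- lapply(vs_list, function(vs) {
    cfg_i <- mapping_config(Vs = vs, dt = cfg$dt, rounding = cfg$rounding)
    .sweep_row(params, stimulus, T, cfg_i, threshold,
               data.frame(Vs = vs, n_steps = round(T / cfg$dt)))
  })
  do.call(rbind, rows)
}

.sweep_row <- function(params, stimulus, T, cfg_i, threshold, head) {
  res <- tryCatch({
    pair <- simulate_pair(params, stimulus, T = T, cfg = cfg_i,
                          threshold = threshold)
    rep <- compare_runs(pair$ref, pair$emu)
    cbind(head, ok = TRUE, rmse_v = rep$v$rmse,
          rmse_v_per_ms = rep$v$rmse_per_ms, r_v = rep$v$pearson,
          rmse_u = if (is.null(rep$i)) NA_real_ else rep$i$rmse,
          note = "")
  }, error = function(e) {
    cbind(head, ok = FALSE, rmse_v = NA_real_, rmse_v_per_ms = NA_real_,
          r_v = NA_real_, rmse_u = NA_real_, note = conditionMessage(e))
  })
  res
}
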