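#' @title Physical-to-fixed-point parameter mapping
#' @description Functions translating LIF parameters and states between
#'   physical units and the unit-less fixed-point representation of the
#'   hardware compartment model.
#' @name core-mapping
NULL

# Fixed-point geometry of the compartment model: 12-bit decay words,
# +/-23-bit state registers, 17-high-bit threshold (granularity 2^6).
.LEVELS <- 4096          # 2^12, decay word denominator
.STATE_MAX <- 2^23 - 1   # saturation bound on |v|, |u|
.THETA_GRAIN <- 64       # 2^6, threshold mantissa granularity
.BIAS_MANT_MAX <- 4096   # 2^12, |bias mantissa| bound
.BIAS_EXP_MAX <- 7

#' Mapping configuration
#'
#' The two bridge constants between the physical model and the fixed-point
#' compartment, plus the rounding policy applied at quantization points.
#'
#' @param Vs Voltage scale: millivolts per unit-less state level. The
#'   default, 1e-4 mV/level (10,000 levels per mV), is the precision at
#'   which membrane-potential error plateaus in the voltage-precision sweep.
#' @param dt Temporal scale: milliseconds of physical time per discrete
#'   step. The default 1 ms/step minimizes the discretization error in the
#'   temporal-precision sweep.
#' @param rounding Rounding policy at quantization points: `"nearest"`
#'   (ties away from zero, the default) or `"floor"` for sensitivity checks.
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(Vs = 1e-4, dt = 1,
                           rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(Vs) || Vs <= 0) stop("Vs must be positive (mV/level)")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive (ms/step)")
  structure(list(Vs = Vs, dt = dt, rounding = rounding),
            class = "mapping_config")
}

#' @export
print.mapping_config <- function(x, ...) {
  cat(sprintf("mapping config: Vs = %g mV/level, dt = %g ms/step, %s rounding\n",
              x$Vs, x$dt, x$rounding))
  invisible(x)
}

# round-to-nearest, ties away from zero; or floor
.quantize <- function(x, rounding) {
  if (rounding == "floor") floor(x) else trunc(x + 0.5 * sign(x))
}

#' Forward voltage transform: millivolts to state levels
#'
#' `v = (V - Vr) / Vs`: shifts the physical membrane potential so the reset
#' maps to the fixed-point origin, then rescales to state levels. Returns a
#' real number; quantization happens only where integer state is required.
#'
#' @param V Membrane potential(s), mV.
#' @param params A [neuron_params()] object (supplies `Vr`).
#' @param cfg A [mapping_config()] (supplies `Vs`).
#' @return State level value(s), real.
#' @export
voltage_to_loihi <- function(V, params, cfg = mapping_config()) {
  (V - params$Vr) / cfg$Vs
}

#' Inverse voltage transform: state levels to millivolts
#'
#' `V = v * Vs + Vr`, the exact inverse of [voltage_to_loihi()].
#'
#' @param v State level value(s).
#' @inheritParams voltage_to_loihi
#' @return Membrane potential(s), mV.
#' @export
voltage_from_loihi <- function(v, params, cfg = mapping_config()) {
  v * cfg$Vs + params$Vr
}

#' Membrane-potential decay word
#'
#' Computes the 12-bit voltage decay word from the membrane time constant
#' via the linear-Euler correspondence `delta_v = (dt / tau_v) * 2^12`,
#' quantized under the configured rounding. The stored word uses the
#' hardware convention that 0 denotes full decay (`delta_v = 4096`).
#'
#' A time constant is representable only when `tau_v` lies in
#' `[dt, 4096 * dt]`; outside that range the decay word would leave
#' `[1, 4096]` and an error is raised (see [max_representable_tau()]).
#'
#' @param tau_v Time constant, ms (membrane or, for the current path via
#'   [compute_current_decay()], synaptic).
#' @param cfg A [mapping_config()].
#' @return A list with `delta` (integer decay in `[1, 4096]`) and `stored`
#'   (the 12-bit stored word, 0 meaning 4096).
#' @export
compute_voltage_decay <- function(tau_v, cfg = mapping_config()) {
  if (tau_v <= 0) stop("tau_v must be positive")
  if (tau_v < cfg$dt)
    stop(sprintf(
      "tau_v = %g ms not representable: below one step (dt = %g ms)",
      tau_v, cfg$dt))
  if (tau_v > .LEVELS * cfg$dt)
    stop(sprintf(
      "tau_v = %g ms not representable at dt = %g ms: exceeds 2^12 * dt = %g ms",
      tau_v, cfg$dt, .LEVELS * cfg$dt))
  delta <- .quantize(cfg$dt / tau_v * .LEVELS, cfg$rounding)
  delta <- max(1, min(.LEVELS, delta))
  list(delta = delta, stored = if (delta == .LEVELS) 0L else as.integer(delta))
}

#' Synaptic-current decay word
#'
#' Computes the 12-bit current decay word from the synaptic time constant.
#' Unlike the voltage path, whose decay word is pinned by the hardware's
#' published linear-Euler correspondence, the current-decay encoding is
#' free; it is calibrated so the per-step multiplier `(4096 - delta_u)/4096`
#' matches the exponential kernel `exp(-dt / tau_syn)` as closely as the
#' 12-bit word allows: `delta_u = round(4096 * (1 - exp(-dt / tau_syn)))`.
#' This keeps the emulated postsynaptic current shape aligned with the
#' continuous reference even when `tau_syn` is comparable to `dt` (see the
#' methods vignette for the rationale and its effect on trace fidelity).
#'
#' @param tau_syn Synaptic current time constant, ms.
#' @inheritParams compute_voltage_decay
#' @return A list with `delta` and `stored` as in [compute_voltage_decay()].
#' @export
compute_current_decay <- function(tau_syn, cfg = mapping_config()) {
  if (tau_syn <= 0) stop("tau_syn must be positive")
  delta <- .quantize(.LEVELS * (1 - exp(-cfg$dt / tau_syn)), cfg$rounding)
  if (delta < 1)
    stop(sprintf(
      "tau_syn = %g ms not representable at dt = %g ms: decay word underflows",
      tau_syn, cfg$dt))
  delta <- min(.LEVELS, delta)
  list(delta = delta, stored = if (delta == .LEVELS) 0L else as.integer(delta))
}

#' Largest representable membrane time constant
#'
#' The decay word must stay at or above 1, so the largest representable
#' time constant at step `dt` is `2^12 * dt` (about 4,100 ms at the default
#' 1 ms step; about 41 ms at a 0.01 ms step).
#'
#' @param cfg A [mapping_config()].
#' @return Upper bound on `tau_v`, ms.
#' @export
max_representable_tau <- function(cfg = mapping_config()) {
  .LEVELS * cfg$dt
}

#' Threshold mapping
#'
#' Maps the physical firing threshold through the voltage transform,
#' `theta = (Theta - Vr) / Vs`, then quantizes to the 17-high-bit
#' representation: `theta_mant = round(theta / 2^6)`, effective threshold
#' `theta_mant * 2^6`. Errors if the effective threshold would reach the
#' 23-bit state bound.
#'
#' @param params A [neuron_params()].
#' @param cfg A [mapping_config()].
#' @return A list with `theta_mant` and `theta_eff` (state levels).
#' @export
map_threshold <- function(params, cfg = mapping_config()) {
  theta <- (params$Theta - params$Vr) / cfg$Vs
  mant <- .quantize(theta / .THETA_GRAIN, cfg$rounding)
  eff <- mant * .THETA_GRAIN
  if (eff >= 2^23)
    stop(sprintf(
      "threshold overflow: effective theta %g >= 2^23 at Vs = %g; use a coarser Vs",
      eff, cfg$Vs))
  list(theta_mant = mant, theta_eff = eff)
}

#' Bias mapping: constant per-step drive as mantissa * 2^exponent
#'
#' The constant part of the unit-less synaptic drive --- injected bias
#' current plus the leak offset toward the resting potential --- folded
#' into one per-step increment:
#' `b* = dt * (Ie / C + (EL - Vr) / tau_v) / Vs` (state levels per step).
#' The encoder picks the smallest exponent in `[0, 7]` such that
#' `|b* / 2^exp| <= 2^12`, minimizing quantization error, and rounds the
#' mantissa under the configured policy. The absolute encoding error is at
#' most `2^(exp - 1)` under nearest rounding.
#'
#' @inheritParams map_threshold
#' @return A list with `bias_mant`, `bias_exp`, `bias_eff`
#'   (`= bias_mant * 2^bias_exp`) and `target` (the unquantized `b*`).
#' @export
map_bias <- function(params, cfg = mapping_config()) {
  bstar <- cfg$dt * (params$Ie / params$C +
                     (params$EL - params$Vr) / params$tau_v) / cfg$Vs
  if (abs(bstar) > .BIAS_MANT_MAX * 2^.BIAS_EXP_MAX)
    stop(sprintf(
      "bias overflow: |b*| = %g exceeds 2^12 * 2^7 levels/step at Vs = %g",
      abs(bstar), cfg$Vs))
  bexp <- 0
  while (abs(bstar) / 2^bexp > .BIAS_MANT_MAX && bexp < .BIAS_EXP_MAX)
    bexp <- bexp + 1
  mant <- .quantize(bstar / 2^bexp, cfg$rounding)
  list(bias_mant = mant, bias_exp = as.integer(bexp),
       bias_eff = mant * 2^bexp, target = bstar)
}

#' Synaptic weight in integer state levels
#'
#' A presynaptic spike of physical weight `w` pA deposits
#' `round(w * dt / (C * Vs))` levels onto the fixed-point current state,
#' the same per-step scaling used by the bias path.
#'
#' @param w Synaptic weight(s), pA.
#' @inheritParams map_threshold
#' @return Integer level increment(s).
#' @export
weight_to_levels <- function(w, params, cfg = mapping_config()) {
  .quantize(w * cfg$dt / (params$C * cfg$Vs), cfg$rounding)
}

#' Inverse current transform: state levels to picoamperes
#'
#' Inverse of the [weight_to_levels()] scaling: `I = u * C * Vs / dt`.
#'
#' @param u Current state level(s).
#' @inheritParams map_threshold
#' @return Current, pA.
#' @export
current_from_levels <- function(u, params, cfg = mapping_config()) {
  u * params$C * cfg$Vs / cfg$dt
}

#' Scale spike times to step indices
#'
#' A spike at physical time `t` ms falls into discrete step
#' `floor(t / dt)`; spikes mapped to the same step are merged into one
#' event whose multiplicity is recorded.
#'
#' @param times Spike times, ms (non-negative).
#' @param cfg A [mapping_config()].
#' @return A data frame with columns `step` (0-based index) and `count`.
#' @export
scale_spike_times <- function(times, cfg = mapping_config()) {
  if (length(times) == 0)
    return(data.frame(step = integer(0), count = integer(0)))
  if (any(times < 0)) stop("spike times must be non-negative")
  steps <- floor(times / cfg$dt)
  tab <- table(steps)
  data.frame(step = as.integer(names(tab)), count = as.integer(tab))
}

#' Build a fixed-point compartment configuration
#'
#' Runs the full parameter mapping --- decay words, threshold, bias --- and
#' returns the quantized compartment ready for the emulator. Keeps the
#' originating parameters and mapping configuration so state traces can be
#' inverse-mapped back to physical units.
#'
#' @param params A [neuron_params()].
#' @param cfg A [mapping_config()].
#' @return An object of class `loihi_compartment` with fields `delta_v`,
#'   `delta_v_stored`, `delta_u`, `delta_u_stored`, `theta_mant`,
#'   `theta_eff`, `bias_mant`, `bias_exp`, `bias_eff`, `params`, `cfg`.
#' @examples
#' comp <- loihi_compartment(lif_table1()[["1"]])
#' comp$delta_v      # 164 at dt = 1 ms for tau_v = 25 ms
#' comp$theta_eff    # 270016 levels above the reset origin
#' @export
loihi_compartment <- function(params, cfg = mapping_config()) {
  dv <- compute_voltage_decay(params$tau_v, cfg)
  du <- compute_current_decay(params$tau_syn, cfg)
  th <- map_threshold(params, cfg)
  b  <- map_bias(params, cfg)
  structure(list(delta_v = dv$delta, delta_v_stored = dv$stored,
                 delta_u = du$delta, delta_u_stored = du$stored,
                 theta_mant = th$theta_mant, theta_eff = th$theta_eff,
                 bias_mant = b$bias_mant, bias_exp = b$bias_exp,
                 bias_eff = b$bias_eff, bias_target = b$target,
                 params = params, cfg = cfg),
            class = "loihi_compartment")
}

#' @export
print.loihi_compartment <- function(x, ...) {
  cat("fixed-point compartment\n")
  cat(sprintf("  delta_v = %d (stored %d), delta_u = %d (stored %d)\n",
              x$delta_v, x$delta_v_stored, x$delta_u, x$delta_u_stored))
  cat(sprintf("  theta_mant = %d (effective %d levels)\n",
              x$theta_mant, x$theta_eff))
  cat(sprintf("  bias = %d * 2^%d = %d levels/step (target %.2f)\n",
              x$bias_mant, x$bias_exp, x$bias_eff, x$bias_target))
  invisible(x)
}
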