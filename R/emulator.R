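#' Single fixed-point compartment update
#'
#' One step of the discrete compartment dynamics, bit-faithful to the
#' hardware arithmetic:
#' \enumerate{
#'   \item current decay: `u' = floor(u * (4096 - delta_u) / 4096)`, then
#'     add the step's integer spike input;
#'   \item voltage decay: `v' = floor(v * (4096 - delta_v) / 4096)`, then
#'     add the effective bias and the updated current `u'`;
#'   \item saturation of both states to `+/-(2^23 - 1)` (clamp, not wrap);
#'   \item strict threshold test `v' > theta_eff`; on a spike `v'` resets
#'     to 0.
#' }
#' Truncation after the decay multiply is `floor` (arithmetic-shift
#' semantics). The update order makes the current value seen by the
#' voltage update the current of the same step.
#'
#' @param v,u Integer-valued state (membrane potential and synaptic
#'   current, state levels).
#' @param comp A [loihi_compartment()].
#' @param spike_input Integer level increment delivered to `u` this step.
#' @param threshold Apply the threshold/reset test (default `TRUE`).
#' @param threshold_before_u If `TRUE`, the threshold test is applied to
#'   the voltage before the current term is added (diagnostic switch for
#'   the in-step ordering, which differs between hardware generations).
#' @return A list with `v`, `u`, `spiked` (logical) and `saturated`
#'   (count of states clamped this step).
#' @examples
#' comp <- loihi_compartment(lif_table1()[["1"]])
#' loihi_step(1000, 0, comp, threshold = FALSE)$v  # floor(1000*3932/4096) + bias
#' @export
loihi_step <- function(v, u, comp, spike_input = 0, threshold = TRUE,
                       threshold_before_u = FALSE) {
  sat <- 0L
  u <- floor(u * (.LEVELS - comp$delta_u) / .LEVELS) + spike_input
  if (abs(u) > .STATE_MAX) { u <- sign(u) * .STATE_MAX; sat <- sat + 1L }
  v_dec <- floor(v * (.LEVELS - comp$delta_v) / .LEVELS) + comp$bias_eff
  v <- v_dec + u
  if (abs(v) > .STATE_MAX) { v <- sign(v) * .STATE_MAX; sat <- sat + 1L }
  spiked <- FALSE
  if (threshold) {
    test_v <- if (threshold_before_u) v_dec else v
    if (test_v > comp$theta_eff) { spiked <- TRUE; v <- 0 }
  }
  list(v = v, u = u, spiked = spiked, saturated = sat)
}

#' Run the fixed-point compartment emulator
#'
#' Iterates [loihi_step()] from `v = u = 0`, recording post-update state at
#' every step. The run is deterministic: identical inputs give bit-identical
#' traces.
#'
#' @param comp A [loihi_compartment()].
#' @param spike_inputs Integer per-step input schedule for the current
#'   state (length `n_steps`), or `NULL` for none.
#' @param n_steps Number of steps (`>= 1`).
#' @inheritParams loihi_step
#' @return An object of class `emulator_run`: `v_trace`, `u_trace`
#'   (integer-valued, length `n_steps`), `spike_steps` (1-based step
#'   indices), `n_saturated`, and the compartment.
#' @export
simulate_emulator <- function(comp, spike_inputs = NULL, n_steps,
                              threshold = TRUE, threshold_before_u = FALSE) {
  stopifnot(n_steps >= 1)
  if (is.null(spike_inputs)) spike_inputs <- numeric(n_steps)
  if (length(spike_inputs) != n_steps)
    stop("spike_inputs schedule length must equal n_steps")
  v <- 0; u <- 0
  vt <- numeric(n_steps); ut <- numeric(n_steps)
  spikes <- integer(0); nsat <- 0L
  du_mult <- .LEVELS - comp$delta_u
  dv_mult <- .LEVELS - comp$delta_v
  b <- comp$bias_eff; theta <- comp$theta_eff
  for (k in seq_len(n_steps)) {
    u <- floor(u * du_mult / .LEVELS) + spike_inputs[k]
    if (abs(u) > .STATE_MAX) { u <- sign(u) * .STATE_MAX; nsat <- nsat + 1L }
    v_dec <- floor(v * dv_mult / .LEVELS) + b
    v <- v_dec + u
    if (abs(v) > .STATE_MAX) { v <- sign(v) * .STATE_MAX; nsat <- nsat + 1L }
    if (threshold) {
      test_v <- if (threshold_before_u) v_dec else v
      if (test_v > theta) { spikes <- c(spikes, k); v <- 0 }
    }
    vt[k] <- v; ut[k] <- u
  }
  structure(list(v_trace = vt, u_trace = ut, spike_steps = spikes,
                 n_saturated = nsat, n_steps = n_steps, comp = comp,
                 threshold = threshold),
            class = "emulator_run")
}

#' @export
print.emulator_run <- function(x, ...) {
  cat(sprintf("emulator run: %d steps, %d spike(s), %d saturation event(s)\n",
              x$n_steps, length(x$spike_steps), x$n_saturated))
  invisible(x)
}

#' Real-valued fixed point of the compartment voltage
#'
#' Diagnostic closed form of the voltage the discrete update relaxes to
#' under constant drive, ignoring truncation: `bias_eff * 4096 / delta_v`.
#' Comparing it with the effective threshold predicts tonic firing.
#'
#' @param comp A [loihi_compartment()].
#' @return Fixed-point voltage, state levels (real-valued).
#' @export
steady_state <- function(comp) {
  comp$bias_eff * .LEVELS / comp$delta_v
}

#' Integer input schedule for a stimulus
#'
#' Converts a stimulus into the per-step integer current increments the
#' emulator consumes: spike trains are binned with [scale_spike_times()]
#' and weighted with [weight_to_levels()]; bias stimuli contribute nothing
#' here (constant drive is folded into the compartment bias).
#'
#' @param stimulus A stimulus object or `NULL`.
#' @param params A [neuron_params()].
#' @param cfg A [mapping_config()].
#' @param n_steps Schedule length.
#' @return Integer vector of length `n_steps`.
#' @export
stimulus_schedule <- function(stimulus, params, cfg, n_steps) {
  sched <- numeric(n_steps)
  times_in <- .stimulus_times(stimulus)
  if (length(times_in) > 0) {
    w_int <- weight_to_levels(stimulus$weight_pA, params, cfg)
    sc <- scale_spike_times(times_in, cfg)
    sc <- sc[sc$step < n_steps, , drop = FALSE]
    sched[sc$step + 1] <- sc$count * w_int
  }
  sched
}

#' Paired run of both backends
#'
#' Simulates the same neuron, stimulus and duration on the continuous
#' reference (exact integration) and on the fixed-point emulator (after
#' mapping the parameters through [loihi_compartment()]), with matching
#' grids and spike delivery, ready for [compare_runs()].
#'
#' @param params A [neuron_params()].
#' @param stimulus A stimulus object or `NULL` (intrinsic bias).
#' @param T Duration, ms.
#' @param cfg A [mapping_config()]; its `dt` sets both the emulator step
#'   and the reference grid.
#' @param threshold Apply threshold/reset on both backends. The default
#'   `FALSE` records the free subthreshold trajectories, the mode used for
#'   state-fidelity statistics.
#' @return A list with elements `ref` (a `state_trace`), `emu` (an
#'   `emulator_run`), `params`, `cfg`.
#' @export
simulate_pair <- function(params, stimulus = NULL, T, cfg = mapping_config(),
                          threshold = FALSE) {
  params_eff <- .effective_params(params, stimulus)
  n <- round(T / cfg$dt)
  comp <- loihi_compartment(params_eff, cfg)
  sched <- stimulus_schedule(stimulus, params_eff, cfg, n)
  ref <- simulate_reference(params, stimulus, T = T, h = cfg$dt,
                            threshold = threshold)
  emu <- simulate_emulator(comp, sched, n_steps = n, threshold = threshold)
  list(ref = ref, emu = emu, params = params_eff, cfg = cfg)
}
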