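#' Random excitatory/inhibitory network specification
#'
#' Describes a randomly connected population of LIF neurons split into an
#' excitatory and an inhibitory class: every ordered pair of distinct
#' neurons is connected independently with probability `p_conn`, the
#' synaptic weight is set by the presynaptic class, and each neuron is
#' mapped to its own fixed-point compartment.
#'
#' @param N Neuron count.
#' @param ei_ratio Excitatory fraction; the excitatory class has
#'   `round(ei_ratio * N)` neurons (the default 0.5 gives a 1:1 split).
#' @param p_conn Connection probability for each ordered pair, in `[0, 1]`.
#' @param w_exc Excitatory synaptic weight, pA (`>= 0`).
#' @param w_inh Inhibitory synaptic weight, pA (`<= 0`).
#' @param params_exc,params_inh [neuron_params()] for each class.
#' @param seed Integer seed making the wiring deterministic.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(N, ei_ratio = 0.5, p_conn = 0.1,
                         w_exc = 20, w_inh = -20,
                         params_exc = neuron_params(25, 170.21, -70, -70, -43,
                                                    Ie = 200, label = "E"),
                         params_inh = neuron_params(22, 170, -70, -70, -43,
                                                    Ie = 200, label = "I"),
                         seed = 1L) {
  stopifnot(N >= 1, p_conn >= 0, p_conn <= 1,
            ei_ratio >= 0, ei_ratio <= 1)
  if (w_exc < 0) stop("w_exc must be non-negative (pA)")
  if (w_inh > 0) stop("w_inh must be non-positive (pA)")
  structure(list(N = as.integer(N), ei_ratio = ei_ratio, p_conn = p_conn,
                 w_exc = w_exc, w_inh = w_inh, params_exc = params_exc,
                 params_inh = params_inh, seed = as.integer(seed)),
            class = "network_spec")
}

#' Build a random network: wiring plus per-neuron compartments
#'
#' Draws the adjacency (each ordered pair `i != j` independently with
#' probability `p_conn`; no self-connections), assigns class-dependent
#' weights, and maps every neuron's parameters through
#' [loihi_compartment()]. Deterministic under the spec's seed; the ambient
#' RNG state is restored afterwards. Representability errors from the
#' parameter mapping propagate per neuron.
#'
#' @param spec A [network_spec()].
#' @param cfg A [mapping_config()] shared by all neurons.
#' @return An object of class `lif_network`: `spec`, `cfg`, `classes`
#'   (character vector `"E"`/`"I"`), `params` (per-neuron list), `comps`
#'   (per-neuron compartments), `adj` (logical N x N, rows = presynaptic),
#'   `W` (physical weights, pA), `n_edges`.
#' @export
build_random_network <- function(spec, cfg = mapping_config()) {
  N <- spec$N
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  n_exc <- round(spec$ei_ratio * N)
  classes <- rep(c("E", "I"), c(n_exc, N - n_exc))
  adj <- matrix(stats::runif(N * N) < spec$p_conn, N, N)
  diag(adj) <- FALSE
  w_class <- ifelse(classes == "E", spec$w_exc, spec$w_inh)
  W <- adj * w_class  # row i = presynaptic neuron i
  params <- lapply(seq_len(N), function(i)
    if (classes[i] == "E") spec$params_exc else spec$params_inh)
  comps <- lapply(params, loihi_compartment, cfg = cfg)
  structure(list(spec = spec, cfg = cfg, classes = classes,
                 params = params, comps = comps, adj = adj, W = W,
                 n_edges = sum(adj)),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat(sprintf("random E/I network: N = %d (%d E / %d I), %d edges (p = %g)\n",
              x$spec$N, sum(x$classes == "E"), sum(x$classes == "I"),
              x$n_edges, x$spec$p_conn))
  invisible(x)
}

#' Simulate a network on either backend
#'
#' Event-driven population simulation: a spike emitted at step `k` adds
#' the (scaled) synaptic weight to each postsynaptic current at step
#' `k + 1` (fixed one-step delay). On the `"reference"` backend every
#' neuron advances by its exact propagator in physical units; on the
#' `"emulator"` backend every neuron runs the fixed-point update with
#' weights converted per postsynaptic neuron via [weight_to_levels()].
#' Deterministic given the network and backend.
#'
#' @param net A `lif_network` from [build_random_network()].
#' @param backend `"reference"` or `"emulator"`.
#' @param T Duration, ms.
#' @param record_traces Also record per-neuron membrane-potential traces
#'   (in mV on both backends, the emulator trace inverse-mapped).
#' @param threshold Apply threshold/reset spiking (default `TRUE`).
#' @return An object of class `network_run`: `spikes` (data frame
#'   `neuron_id`, `step`, `time_ms`, sorted), `backend`, `n_steps`, and
#'   when requested `traces` (matrix `n_steps` x N, mV).
#' @export
simulate_network <- function(net, backend = c("reference", "emulator"),
                             T = 500, record_traces = FALSE,
                             threshold = TRUE) {
  backend <- match.arg(backend)
  cfg <- net$cfg
  N <- net$spec$N
  n <- round(T / cfg$dt)
  spk_id <- list(); spk_step <- list(); m <- 0L
  traces <- if (record_traces) matrix(NA_real_, n, N) else NULL

  if (backend == "reference") {
    tv <- vapply(net$params, `[[`, numeric(1), "tau_v")
    Theta <- vapply(net$params, `[[`, numeric(1), "Theta")
    Vr <- vapply(net$params, `[[`, numeric(1), "Vr")
    P <- lapply(net$params, build_propagator, h = cfg$dt)
    pII <- vapply(P, function(p) p["I", "I"], numeric(1))
    pVI <- vapply(P, function(p) p["V", "I"], numeric(1))
    pVV <- vapply(P, function(p) p["V", "V"], numeric(1))
    pVk <- vapply(P, function(p) p["V", "k"], numeric(1))
    V <- vapply(net$params, `[[`, numeric(1), "EL")
    I <- numeric(N); pending <- numeric(N)
    for (k in seq_len(n)) {
      I <- I + pending
      V <- pVV * V + pVI * I + pVk
      I <- pII * I
      spiked <- if (threshold) V > Theta else rep(FALSE, N)
      if (any(spiked)) {
        V[spiked] <- Vr[spiked]
        m <- m + 1L
        spk_id[[m]] <- which(spiked); spk_step[[m]] <- k
        pending <- as.numeric(crossprod(net$W, spiked))
      } else pending <- numeric(N)
      if (record_traces) traces[k, ] <- V
    }
  } else {
    dv <- vapply(net$comps, `[[`, numeric(1), "delta_v")
    du <- vapply(net$comps, `[[`, numeric(1), "delta_u")
    b <- vapply(net$comps, `[[`, numeric(1), "bias_eff")
    theta <- vapply(net$comps, `[[`, numeric(1), "theta_eff")
    Vr <- vapply(net$params, `[[`, numeric(1), "Vr")
    # weight in levels depends on the postsynaptic capacitance
    Cpost <- vapply(net$params, `[[`, numeric(1), "C")
    Wint <- .quantize(sweep(net$W, 2, cfg$dt / (Cpost * cfg$Vs), `*`),
                      cfg$rounding)
    v <- numeric(N); u <- numeric(N); pending <- numeric(N)
    for (k in seq_len(n)) {
      u <- floor(u * (.LEVELS - du) / .LEVELS) + pending
      u <- pmin(pmax(u, -.STATE_MAX), .STATE_MAX)
      v <- floor(v * (.LEVELS - dv) / .LEVELS) + b + u
      v <- pmin(pmax(v, -.STATE_MAX), .STATE_MAX)
      spiked <- if (threshold) v > theta else rep(FALSE, N)
      if (any(spiked)) {
        v[spiked] <- 0
        m <- m + 1L
        spk_id[[m]] <- which(spiked); spk_step[[m]] <- k
        pending <- as.numeric(crossprod(Wint, spiked))
      } else pending <- numeric(N)
      if (record_traces) traces[k, ] <- v * cfg$Vs + Vr
    }
  }

  if (m > 0) {
    ids <- unlist(spk_id)
    steps <- rep(unlist(spk_step), vapply(spk_id, length, integer(1)))
    ord <- order(steps, ids)
    spikes <- data.frame(neuron_id = ids[ord], step = steps[ord])
  } else {
    spikes <- data.frame(neuron_id = integer(0), step = integer(0))
  }
  spikes$time_ms <- spikes$step * cfg$dt
  structure(list(spikes = spikes, backend = backend, n_steps = n,
                 traces = traces, cfg = cfg),
            class = "network_run")
}

#' @export
print.network_run <- function(x, ...) {
  cat(sprintf("network run (%s backend): %d steps, %d spikes from %d neurons\n",
              x$backend, x$n_steps, nrow(x$spikes),
              length(unique(x$spikes$neuron_id))))
  invisible(x)
}

#' Synthesize a multi-class parameter ensemble
#'
#' Draws `n` LIF parameter sets uniformly from configured physiological
#' ranges (time constant, capacitance, bias current), labelled
#' alternately excitatory/inhibitory --- the structure used for
#' ensemble-level fidelity checks when a curated multi-class parameter
#' collection is not available. Ranges default to spans typical of
#' cortical point-model fits.
#'
#' @param n Number of parameter sets.
#' @param tau_v_range,C_range,Ie_range Uniform sampling ranges (ms, pF, pA).
#' @param seed Integer seed.
#' @return A list of [neuron_params()] with labels `"E1"`, `"I2"`, ...
#' @export
sample_ensemble_params <- function(n, tau_v_range = c(10, 40),
                                   C_range = c(80, 300),
                                   Ie_range = c(0, 250), seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cls <- if (i %% 2 == 1) "E" else "I"
    neuron_params(tau_v = stats::runif(1, tau_v_range[1], tau_v_range[2]),
                  C = stats::runif(1, C_range[1], C_range[2]),
                  EL = -70, Vr = -70, Theta = -43,
                  Ie = stats::runif(1, Ie_range[1], Ie_range[2]),
                  label = paste0(cls, i))
  })
}
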