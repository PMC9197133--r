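#' Spike train
#'
#' An identified source emitting spikes at strictly increasing,
#' non-negative times (ms).
#'
#' @param source_id Integer source identifier.
#' @param times Spike times, ms.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(source_id, times) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("spike times must be non-negative")
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing within a source")
  structure(list(source_id = as.integer(source_id), times = times),
            class = "spike_train")
}

#' Constant-bias stimulus
#'
#' Drives a run with a constant injected current, overriding the bias
#' stored in the neuron parameters.
#'
#' @param bias_pA Injected current, pA.
#' @return An object of class `stimulus` with `kind = "bias"`.
#' @export
stimulus_bias <- function(bias_pA) {
  structure(list(kind = "bias", bias_pA = bias_pA), class = "stimulus")
}

#' External spike-train stimulus
#'
#' Drives a run with one or more frozen spike trains delivered through the
#' exponential synaptic kernel with a common physical weight.
#'
#' @param trains A list of [spike_train()] objects (a single train is
#'   accepted as-is).
#' @param weight_pA Synaptic weight applied to every delivered spike, pA.
#' @return An object of class `stimulus` with `kind = "spikes"`.
#' @export
stimulus_spikes <- function(trains, weight_pA = 100) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (!all(vapply(trains, inherits, logical(1), "spike_train")))
    stop("trains must be spike_train objects")
  structure(list(kind = "spikes", trains = trains, weight_pA = weight_pA),
            class = "stimulus")
}

# Effective parameters for a run: a bias stimulus overrides params$Ie;
# spike stimuli leave the intrinsic bias untouched.
.effective_params <- function(params, stimulus) {
  if (!is.null(stimulus) && stimulus$kind == "bias") {
    params$Ie <- stimulus$bias_pA
  }
  params
}

# Pooled spike times of a stimulus (empty for bias drive).
.stimulus_times <- function(stimulus) {
  if (is.null(stimulus) || stimulus$kind != "spikes") return(numeric(0))
  sort(unlist(lapply(stimulus$trains, `[[`, "times")))
}

#' Packaged external spike-time table
#'
#' The frozen five-source spike-time table used by the external-spike
#' fidelity experiment: five Poisson-generated trains (nominal 5 Hz over a
#' 500 ms window), frozen so both backends receive identical input.
#'
#' @return A list of five [spike_train()] objects (sources 0--4).
#' @examples
#' trains <- table2_spike_trains()
#' lengths(lapply(trains, `[[`, "times"))  # 1, 1, 5, 2, 2 spikes
#' @export
table2_spike_trains <- function() {
  path <- system.file("extdata", "table2_spike_times.tsv",
                      package = "lifbridge", mustWork = TRUE)
  read_spike_table(path)
}

#' Read a two-column spike table
#'
#' Plain-text spike tables have one row per spike: `source_id` and
#' `time_ms`, tab- or comma-separated with a header.
#'
#' @param path File path.
#' @return A list of [spike_train()] objects, one per source, ordered by
#'   source id.
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) stop("spike table not found: ", path)
  tab <- utils::read.delim(path, sep = "", header = TRUE)
  if (!all(c("source_id", "time_ms") %in% names(tab)))
    stop("spike table must have columns source_id and time_ms")
  ids <- sort(unique(tab$source_id))
  lapply(ids, function(id)
    spike_train(id, sort(tab$time_ms[tab$source_id == id])))
}

#' Write a two-column spike table
#'
#' @param trains A list of [spike_train()] objects.
#' @param path Output file path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  tab <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$times) == 0) NULL
    else data.frame(source_id = tr$source_id, time_ms = tr$times)))
  if (is.null(tab)) tab <- data.frame(source_id = integer(0),
                                      time_ms = numeric(0))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Frozen Poisson spike sources
#'
#' Generates `n_sources` independent homogeneous Poisson spike trains of
#' the given rate over `[0, T)` ms. A fixed seed freezes the trains, so the
#' same stimulus can be replayed identically on both backends. The ambient
#' RNG state is left untouched.
#'
#' @param n_sources Number of sources.
#' @param rate Firing rate, Hz.
#' @param T Duration, ms. Spikes beyond `T` are never generated
#'   (truncation at the window).
#' @param seed Optional integer seed freezing the trains.
#' @return A list of [spike_train()] objects with source ids `0:(n-1)`.
#' @export
poisson_sources <- function(n_sources, rate, T, seed = NULL) {
  stopifnot(n_sources >= 1, rate >= 0, T > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  lapply(seq_len(n_sources) - 1L, function(id) {
    n <- stats::rpois(1, rate * T / 1000)
    spike_train(id, sort(stats::runif(n, 0, T)))
  })
}
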