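#' Physical LIF neuron parameters
#'
#' Bundles the parameters of a leaky integrate-and-fire point neuron in the
#' physical units used by electrophysiology-derived model databases:
#' milliseconds, millivolts, picoamperes and picofarads. The membrane
#' resistance is derived, `R = tau_v / C` (in GOhm, so that `R * Ie` is in
#' mV when `Ie` is in pA).
#'
#' @param tau_v Membrane time constant (ms). Must be positive.
#' @param C Membrane capacitance (pF). Must be positive.
#' @param EL Resting potential (mV).
#' @param Vr Reset potential (mV).
#' @param Theta Firing threshold (mV). Must exceed `Vr`.
#' @param Ie Constant bias (trans-membrane) current (pA).
#' @param tau_syn Synaptic current time constant (ms), used when the neuron
#'   receives spike input through the exponential synaptic kernel.
#' @param label Optional identifier carried through outputs.
#'
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params(tau_v = 25, C = 170.21, EL = -70, Vr = -70,
#'                    Theta = -43, Ie = 200)
#' p$R * p$Ie  # steady-state depolarisation above EL, mV
#' @export
neuron_params <- function(tau_v, C, EL, Vr, Theta, Ie = 0, tau_syn = 2,
                          label = NULL) {
  stopifnot(is.numeric(tau_v), is.numeric(C), is.numeric(EL),
            is.numeric(Vr), is.numeric(Theta), is.numeric(Ie),
            is.numeric(tau_syn))
  if (tau_v <= 0) stop("tau_v must be positive (ms)")
  if (C <= 0) stop("C must be positive (pF)")
  if (Theta <= Vr) stop("firing threshold Theta must exceed reset Vr")
  if (tau_syn <= 0) stop("tau_syn must be positive (ms)")
  structure(list(tau_v = tau_v, C = C, R = tau_v / C, EL = EL, Vr = Vr,
                 Theta = Theta, Ie = Ie, tau_syn = tau_syn, label = label),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat(sprintf("  tau_v = %g ms, C = %g pF (R = %.5g GOhm)\n",
              x$tau_v, x$C, x$R))
  cat(sprintf("  EL = %g mV, Vr = %g mV, Theta = %g mV\n",
              x$EL, x$Vr, x$Theta))
  cat(sprintf("  Ie = %g pA, tau_syn = %g ms\n", x$Ie, x$tau_syn))
  invisible(x)
}

# Column names follow the parameter-table layout of the packaged fixture
# (units embedded in the names so files are self-describing).
.param_columns <- c(
  tau_v = "membrane_time_constant_ms",
  Theta = "membrane_potential_threshold_mV",
  EL    = "resting_potential_mV",
  Vr    = "voltage_reset_mV",
  Ie    = "current_pA",
  C     = "membrane_capacitance_pF"
)

#' Load LIF parameter tables (CSV or JSON)
#'
#' Reads a parameter table with one row (or JSON object) per neuron model and
#' the self-describing column names of the packaged fixture:
#' `membrane_time_constant_ms`, `membrane_potential_threshold_mV`,
#' `resting_potential_mV`, `voltage_reset_mV`, `current_pA`,
#' `membrane_capacitance_pF`, plus an optional `dataset` identifier and an
#' optional `tau_syn_ms` column. Values are validated (positive time constant
#' and capacitance, threshold above reset).
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A named list of [neuron_params()] objects.
#' @seealso [lif_table1()] for the packaged two-model fixture.
#' @export
load_neuron_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    csv  = utils::read.csv(path, check.names = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    stop("unsupported parameter file extension: ", ext)
  )
  missing <- setdiff(unname(.param_columns), names(tab))
  if (length(missing) > 0)
    stop("parameter table ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  labels <- if ("dataset" %in% names(tab)) as.character(tab$dataset)
            else as.character(seq_len(nrow(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    neuron_params(
      tau_v = tab[[.param_columns[["tau_v"]]]][i],
      C     = tab[[.param_columns[["C"]]]][i],
      EL    = tab[[.param_columns[["EL"]]]][i],
      Vr    = tab[[.param_columns[["Vr"]]]][i],
      Theta = tab[[.param_columns[["Theta"]]]][i],
      Ie    = tab[[.param_columns[["Ie"]]]][i],
      tau_syn = if ("tau_syn_ms" %in% names(tab)) tab$tau_syn_ms[i] else 2,
      label = labels[i]
    )
  })
  names(out) <- labels
  out
}

#' Packaged two-model LIF parameter set
#'
#' The two single-neuron parameter sets used throughout the fidelity
#' experiments: a bias-current-driven model (dataset 1: tau_v = 25 ms,
#' C = 170.21 pF, 200 pA bias) and a spike-driven model (dataset 2:
#' tau_v = 22 ms, C = 170 pF, zero bias). Both share EL = Vr = -70 mV and
#' a -43 mV threshold.
#'
#' @return A named list of two [neuron_params()] objects (`"1"` and `"2"`).
#' @export
lif_table1 <- function() {
  load_neuron_params(system.file("extdata", "table1_lif_params.csv",
                                 package = "lifbridge", mustWork = TRUE))
}
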