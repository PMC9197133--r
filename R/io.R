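#' Write a paired run to a structured run directory
#'
#' Lays out a deterministic, self-describing run directory: a `trace/`
#' group with one columnar text table per backend, a `spikes/` group with
#' the event tables, the serialized validation report and configuration,
#' a log, and a `manifest.json` listing every artifact with its MD5
#' content hash. The grouped layout mirrors the spike-report containers of
#' large-simulation ecosystems using plain-text tables (no binary
#' container format is required to reload a run bit-exactly).
#'
#' @param run_dir Output directory (created, with a logged notice, if
#'   missing).
#' @param ref A `state_trace`, or `NULL`.
#' @param emu An `emulator_run`, or `NULL`.
#' @param report A `validation_report`, or `NULL`.
#' @param config A list of run settings recorded verbatim (should include
#'   the seed).
#' @return The manifest data frame (`file`, `bytes`, `md5`), invisibly.
#' @export
write_run <- function(run_dir, ref = NULL, emu = NULL, report = NULL,
                      config = list()) {
  log_lines <- character(0)
  note <- function(msg) log_lines <<- c(log_lines, msg)
  if (!dir.exists(run_dir)) {
    dir.create(run_dir, recursive = TRUE)
    note(paste("created run directory", run_dir))
  }
  for (g in c("trace", "spikes"))
    dir.create(file.path(run_dir, g), showWarnings = FALSE)

  files <- character(0)
  put <- function(rel) files <<- c(files, rel)

  if (!is.null(ref)) {
    utils::write.csv(
      data.frame(time_ms = ref$times, V_mV = ref$V, I_pA = ref$I),
      file.path(run_dir, "trace", "reference.csv"), row.names = FALSE)
    utils::write.csv(data.frame(time_ms = ref$spikes),
                     file.path(run_dir, "spikes", "reference.csv"),
                     row.names = FALSE)
    put("trace/reference.csv"); put("spikes/reference.csv")
    note(sprintf("wrote reference trace (%d samples)", length(ref$times)))
  }
  if (!is.null(emu)) {
    utils::write.csv(
      data.frame(step = seq_len(emu$n_steps),
                 v = format(emu$v_trace, scientific = FALSE, trim = TRUE),
                 u = format(emu$u_trace, scientific = FALSE, trim = TRUE)),
      file.path(run_dir, "trace", "emulator.csv"), row.names = FALSE,
      quote = FALSE)
    utils::write.csv(data.frame(step = emu$spike_steps),
                     file.path(run_dir, "spikes", "emulator.csv"),
                     row.names = FALSE)
    # mapping attributes needed to inverse-map the integer trace
    attrs <- c(emu$comp$cfg[c("Vs", "dt", "rounding")],
               list(Vr_mV = emu$comp$params$Vr,
                    C_pF = emu$comp$params$C,
                    delta_v = emu$comp$delta_v, delta_u = emu$comp$delta_u,
                    theta_eff = emu$comp$theta_eff,
                    bias_eff = emu$comp$bias_eff))
    jsonlite::write_json(attrs, file.path(run_dir, "trace",
                                          "emulator_attrs.json"),
                         auto_unbox = TRUE, digits = NA)
    put("trace/emulator.csv"); put("spikes/emulator.csv")
    put("trace/emulator_attrs.json")
    note(sprintf("wrote emulator trace (%d steps)", emu$n_steps))
  }
  if (!is.null(report)) {
    jsonlite::write_json(report_to_list(report),
                         file.path(run_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    put("report.json")
    note("wrote validation report")
  }
  jsonlite::write_json(config, file.path(run_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  put("config.json")

  files <- sort(files)
  paths <- file.path(run_dir, files)
  manifest <- data.frame(file = files,
                         bytes = file.size(paths),
                         md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), log_lines),
             file.path(run_dir, "log.txt"))
  invisible(manifest)
}

#' Reload a run directory
#'
#' Reads back the tables written by [write_run()]. Integer emulator traces
#' round-trip bit-exactly through the text encoding.
#'
#' @param run_dir A directory written by [write_run()].
#' @return A list with any of `reference` (data frame), `emulator` (data
#'   frame with numeric `v`, `u`), `ref_spikes`, `emu_spikes`,
#'   `emulator_attrs`, `report`, `config`, `manifest`.
#' @export
read_run <- function(run_dir) {
  if (!dir.exists(run_dir)) stop("run directory not found: ", run_dir)
  out <- list()
  grab_csv <- function(rel) {
    p <- file.path(run_dir, rel)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  grab_json <- function(rel) {
    p <- file.path(run_dir, rel)
    if (file.exists(p)) jsonlite::fromJSON(p) else NULL
  }
  out$reference <- grab_csv("trace/reference.csv")
  out$emulator <- grab_csv("trace/emulator.csv")
  if (!is.null(out$emulator)) {
    out$emulator$v <- as.numeric(out$emulator$v)
    out$emulator$u <- as.numeric(out$emulator$u)
  }
  out$ref_spikes <- grab_csv("spikes/reference.csv")
  out$emu_spikes <- grab_csv("spikes/emulator.csv")
  out$emulator_attrs <- grab_json("trace/emulator_attrs.json")
  out$report <- grab_json("report.json")
  out$config <- grab_json("config.json")
  out$manifest <- grab_json("manifest.json")
  out
}

#' Serialize a validation report to a plain list
#'
#' Flattens a `validation_report` (dropping the bulky paired-sample table)
#' for JSON export alongside the companion columnar tables.
#'
#' @param report A `validation_report`.
#' @return A nested list of plain vectors.
#' @export
report_to_list <- function(report) {
  list(n = report$n,
       membrane_potential = list(
         rmse_mV = report$v$rmse,
         rmse_per_ms = report$v$rmse_per_ms,
         pearson_r = report$v$pearson,
         trend_intercept = report$v$trend[["intercept"]],
         trend_slope = report$v$trend[["slope"]]),
       current = if (is.null(report$i)) NULL else list(
         rmse_pA = report$i$rmse,
         pearson_r = report$i$pearson),
       histogram_v = report$histogram_v,
       raster = report$raster,
       mapping = list(Vs = report$cfg$Vs, dt = report$cfg$dt,
                      rounding = report$cfg$rounding))
}
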