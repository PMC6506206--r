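#' Read a spike-time table
#'
#' CSV with header columns `cell_id`, `spike_time_s`. Times are sorted within
#' cell (with a message when the input was unsorted) and exact duplicate
#' timestamps within a cell are collapsed with a warning. Malformed rows
#' raise an error naming their line numbers.
#'
#' @param path CSV file path.
#' @return Tibble `cell_id`, `spike_time_s`; empty (with a warning) for an
#'   empty file.
#' @export
read_spike_table <- function(path) {
  df <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                         progress = FALSE))
  if (!nrow(df)) {
    warn(sprintf("'%s' contains no spikes.", path))
    return(tibble::tibble(cell_id = integer(), spike_time_s = numeric()))
  }
  if (!all(c("cell_id", "spike_time_s") %in% names(df))) {
    abort("spike table needs columns `cell_id` and `spike_time_s`.")
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$spike_time_s))))
  if (length(bad)) {
    abort(sprintf("malformed spike_time_s at line(s): %s",
                  paste(bad + 1L, collapse = ", ")))
  }
  df$spike_time_s <- as.numeric(df$spike_time_s)
  unsorted <- df %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::summarise(u = is.unsorted(.data$spike_time_s), .groups = "drop")
  if (any(unsorted$u)) {
    message("unsorted spike times: sorting within cell.")
  }
  out <- df %>%
    dplyr::select("cell_id", "spike_time_s") %>%
    dplyr::arrange(.data$cell_id, .data$spike_time_s)
  dup <- duplicated(out)
  if (any(dup)) {
    warn(sprintf("%d duplicate timestamps collapsed.", sum(dup)))
    out <- out[!dup, ]
  }
  tibble::as_tibble(out)
}

#' Write a spike-time table
#'
#' @param spikes Tibble `cell_id`, `spike_time_s`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path) {
  readr::write_csv(spikes[, c("cell_id", "spike_time_s")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write a membrane-potential trace
#'
#' Plain-text container: commented header lines carrying the sampling rate
#' and units, then one `vm_mv` sample per line.
#'
#' @param vm Trace, mV.
#' @param fs Sampling rate, Hz.
#' @param path Output path.
#' @param units Units string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vm_trace <- function(vm, fs, path, units = "mV") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz: %.10g", fs),
    sprintf("# units: %s", units),
    "vm_mv",
    formatC(vm, format = "g", digits = 10)
  ), con)
  invisible(path)
}

#' Read a membrane-potential trace
#'
#' Reads the container written by [write_vm_trace()]: the header must carry
#' `sampling_rate_hz` and `units` (mV enforced). Traces sampled faster than
#' `resample_to_hz` can be resampled (polyphase FIR) on request, as when
#' 33 kHz acquisitions are analyzed at 10 kHz.
#'
#' @param path Input path.
#' @param resample_to_hz Optional target rate, Hz.
#' @return Numeric trace with attributes `fs` and `units`.
#' @export
read_vm_trace <- function(path, resample_to_hz = NULL) {
  hdr <- readLines(path, n = 10)
  get_field <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  fs <- get_field("sampling_rate_hz")
  units <- get_field("units")
  if (is.null(fs)) abort("vm trace header lacks `sampling_rate_hz`.")
  if (is.null(units)) abort("vm trace header lacks `units`.")
  if (tolower(units) != "mv") abort(sprintf("unsupported Vm units '%s' (need mV).", units))
  fs <- as.numeric(fs)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!"vm_mv" %in% names(df)) abort("vm trace file lacks a `vm_mv` column.")
  vm <- as.numeric(df$vm_mv)
  if (!is.null(resample_to_hz) && abs(resample_to_hz - fs) > 1e-9) {
    vm <- resample_trace(vm, fs, resample_to_hz)
    fs <- resample_to_hz
  }
  structure(vm, fs = fs, units = "mV")
}

# zero-phase FIR anti-alias low-pass (mirrored edge padding), then linear
# interpolation onto the target grid; upsampling skips the filter
resample_trace <- function(x, fs_in, fs_out) {
  xout <- seq(1, length(x), by = fs_in / fs_out)
  if (fs_out < fs_in) {
    np <- min(256L, length(x) - 1L)
    xp <- c(rev(x[2:(np + 1L)]), x,
            rev(x[(length(x) - np):(length(x) - 1L)]))
    f <- signal::fir1(64, fs_out / fs_in)
    f <- f / sum(f) # exactly unit DC gain
    x <- signal::filtfilt(f, xp)[(np + 1L):(np + length(x))]
  }
  approx(seq_along(x), x, xout = xout)$y
}

#' Assemble (or load) a pipeline run configuration
#'
#' A run configuration is a named list with explicit seeds for every
#' stochastic stage and the key stage parameters; it round-trips losslessly
#' through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param seed Global seed; per-stage seeds default to offsets from it.
#' @param n_synapses Synthetic cohort size.
#' @param n_spikes_target Approximate presynaptic spikes per pair.
#' @param lgn_rate_hz Presynaptic rate used for the synthetic trains.
#' @param jitter_ms STA jitter range.
#' @param n_boot Bootstrap replicates for the STA band.
#' @param isi_split_ms STSP short/long boundary.
#' @param span_ms Detector span.
#' @param stages Character vector of stages to run, in order, from
#'   `c("synth", "sta", "detect", "stats", "lif")`.
#' @param lif_n_inputs,lif_trials LIF comparison size.
#' @param lif_duration_s LIF simulated duration.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_synapses = 8, n_spikes_target = 600,
                       lgn_rate_hz = 10, jitter_ms = 16, n_boot = 500,
                       isi_split_ms = 50, span_ms = 6,
                       stages = c("synth", "sta", "detect", "stats", "lif"),
                       lif_n_inputs = 20, lif_trials = 3,
                       lif_duration_s = 20) {
  structure(
    list(seed = seed, n_synapses = n_synapses,
         n_spikes_target = n_spikes_target, lgn_rate_hz = lgn_rate_hz,
         jitter_ms = jitter_ms, n_boot = n_boot, isi_split_ms = isi_split_ms,
         span_ms = span_ms, stages = stages, lif_n_inputs = lif_n_inputs,
         lif_trials = lif_trials, lif_duration_s = lif_duration_s),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "run_config")
}
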