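#' Activation time of a transmembrane-potential series
#'
#' The activation time of a node is the time of the first sample at which
#' `V_m` reaches the depolarization threshold. The threshold is not part of
#' the output format; -70 mV with an upward crossing is a common,
#' configurable choice.
#'
#' @param series numeric `V_m` samples at consecutive printing steps.
#' @param print_dt seconds per step.
#' @param threshold mV; default -70.
#' @return Seconds since the first sample (`(i - 1) * print_dt` for the
#'   first qualifying sample `i`), or `NA` if the threshold is never
#'   reached.
#' @examples
#' activation_time(c(-85, -85, 40, 20), print_dt = 25e-6)
#' @export
activation_time <- function(series, print_dt, threshold = -70) {
  stopifnot(length(series) >= 1, is.numeric(series))
  i <- which(series >= threshold)[1]
  if (is.na(i)) NA_real_ else (i - 1) * print_dt
}

#' Peak voltage of a series
#'
#' @param series numeric samples.
#' @return The maximum value. See [peak_index()] for the position.
#' @export
peak_voltage <- function(series) {
  stopifnot(length(series) >= 1, is.numeric(series))
  max(series)
}

#' @describeIn peak_voltage 1-based index of the peak; ties resolve to the
#'   earliest sample.
#' @export
peak_index <- function(series) {
  stopifnot(length(series) >= 1, is.numeric(series))
  which.max(series)
}

#' Activation-time and peak-voltage maps over a dataset
#'
#' Reads every node's full `V_m` time series (the per-node access pattern
#' that is pathological under default-style chunks) and reduces each to its
#' activation time and peak.
#'
#' @param reader an [h5_reader()].
#' @param variable 1-based index of the transmembrane potential; default 1.
#' @param threshold activation threshold in mV.
#' @return Tibble with one row per node: `node`, `activation_time_s`,
#'   `peak_vm`, `peak_step` (0-based step of the peak).
#' @export
postprocess_maps <- function(reader, variable = 1, threshold = -70) {
  stopifnot(inherits(reader, "h5_reader"))
  dt <- reader$spec$print_dt
  purrr::map_dfr(seq_len(reader$spec$n_nodes), function(n) {
    s <- read_node_series(reader, n, variable)
    tibble::tibble(
      node = n,
      activation_time_s = activation_time(s, dt, threshold),
      peak_vm = peak_voltage(s),
      peak_step = peak_index(s) - 1
    )
  })
}

#' Convert a dataset to per-timestep slab files
#'
#' The conversion access pattern of visualization export: one output record
#' per printing step holding that step's full node-by-variable slab. The
#' record format is a minimal self-describing header line followed by the
#' slab's raw little-endian doubles in node-major order — a stand-in for
#' mesh-aware visualization formats, which need geometry this dataset does
#' not carry. Concatenating all records reconstructs the dataset.
#'
#' @param reader an [h5_reader()].
#' @param out_dir directory for the records (created if missing).
#' @return Tibble with one row per step: `t`, `path`, `bytes`.
#' @export
convert_timesteps <- function(reader, out_dir) {
  stopifnot(inherits(reader, "h5_reader"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  purrr::map_dfr(seq_len(reader$spec$n_timesteps), function(t) {
    slab <- read_timestep_slab(reader, t)
    path <- file.path(out_dir, sprintf("step_%05d.dat", t))
    con <- file(path, "wb")
    header <- sprintf("h5layout-slab t=%d nodes=%d vars=%d\n",
                      t, nrow(slab), ncol(slab))
    writeChar(header, con, eos = NULL)
    writeBin(as.vector(t(slab)), con, size = 8, endian = "little")
    close(con)
    tibble::tibble(t = t, path = path, bytes = file.size(path))
  })
}

#' Read back one slab record written by [convert_timesteps()]
#'
#' @param path a `step_*.dat` record.
#' @return Numeric `N x V` matrix.
#' @export
read_slab_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readLines(con, n = 1)
  m <- regmatches(header, regexec("t=(\\d+) nodes=(\\d+) vars=(\\d+)", header))[[1]]
  if (length(m) != 4) stop("not a slab record: ", path, call. = FALSE)
  n <- as.integer(m[3])
  v <- as.integer(m[4])
  vals <- readBin(con, "double", n * v, size = 8, endian = "little")
  matrix(vals, nrow = n, ncol = v, byrow = TRUE)
}
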