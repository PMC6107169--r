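#' Parameters for synthetic cardiac simulation output
#'
#' The generator emulates the *shape* and post-processing products of
#' bidomain simulation output — it is not an electrophysiology model. A
#' planar activation wave sweeps the node index at `activation_speed`
#' nodes per printing step; each node rests at `resting_potential`, steps
#' to `peak_potential` at its activation step, then relaxes exponentially
#' back toward rest with time constant `repolarization_tau` (in steps).
#' Optional Gaussian noise is added to the transmembrane potential. The
#' second variable, the extracellular potential, is a scaled mirror
#' \eqn{\phi_e = -0.1\, V_m}: any second field exercises the I/O paths
#' identically.
#'
#' @param n_nodes mesh nodes.
#' @param n_timesteps printing time steps; default 151 (an initial state
#'   plus 150 printed steps).
#' @param print_dt seconds per printing step; default 25 µs.
#' @param activation_speed nodes activated per step; defaults to
#'   `ceiling(n_nodes / n_timesteps)` so the wave crosses the whole mesh
#'   within the recording.
#' @param resting_potential,peak_potential mV; defaults -85 and +40.
#' @param repolarization_tau decay time constant in steps; default 20.
#' @param noise_sd Gaussian noise s.d. on `V_m`, mV; default 0.
#' @param seed RNG seed used by [generate_cardiac_output()].
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_nodes, n_timesteps = 151, print_dt = 25e-6,
                         activation_speed = NULL,
                         resting_potential = -85, peak_potential = 40,
                         repolarization_tau = 20, noise_sd = 0, seed = 1) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  n_timesteps <- check_count(n_timesteps, "n_timesteps")
  if (is.null(activation_speed)) {
    activation_speed <- ceiling(n_nodes / n_timesteps)
  }
  stopifnot(
    is.numeric(print_dt), print_dt > 0,
    is.numeric(activation_speed), activation_speed >= 1,
    is.numeric(repolarization_tau), repolarization_tau > 0,
    is.numeric(noise_sd), noise_sd >= 0,
    peak_potential > resting_potential
  )
  seed <- check_count(seed, "seed", min = 0)
  structure(
    list(
      n_nodes = n_nodes, n_timesteps = n_timesteps, print_dt = print_dt,
      activation_speed = activation_speed,
      resting_potential = resting_potential, peak_potential = peak_potential,
      repolarization_tau = repolarization_tau, noise_sd = noise_sd, seed = seed
    ),
    class = "synth_params"
  )
}

#' Generate synthetic simulation output with known ground truth
#'
#' @param params a [synth_params()].
#' @return A list with:
#'   * `values`: numeric array of dim \eqn{(D_t, D_N, 2)} — `V_m` then
#'     `phi_e`, in mV;
#'   * `truth`: tibble with one row per node: `node` (1-based),
#'     `activation_step` (0-based step of the upstroke),
#'     `activation_time_s`, `peak_vm` (mV). Nodes the wave does not reach
#'     within the recording carry `NA` activation and a resting peak.
#'   * `spec`: the matching [sim_output_spec()].
#'
#' Output is reproducible: the generator seeds its own RNG stream from
#' `params$seed` and restores the caller's RNG state on exit.
#' @examples
#' out <- generate_cardiac_output(synth_params(n_nodes = 50, n_timesteps = 30))
#' dim(out$values)
#' @export
generate_cardiac_output <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  n_t <- params$n_timesteps
  n_n <- params$n_nodes
  act_step <- floor((seq_len(n_n) - 1) / params$activation_speed)
  activated <- act_step < n_t

  tt <- seq_len(n_t) - 1 # 0-based step times
  rest <- params$resting_potential
  amp <- params$peak_potential - rest
  # elapsed steps since activation, negative before the upstroke
  dt_mat <- outer(tt, act_step, `-`)
  vm <- rest + amp * exp(-pmax(dt_mat, 0) / params$repolarization_tau) * (dt_mat >= 0)
  if (params$noise_sd > 0) {
    vm <- vm + stats::rnorm(length(vm), sd = params$noise_sd)
  }
  values <- array(c(vm, -0.1 * vm), dim = c(n_t, n_n, 2))

  truth <- tibble::tibble(
    node = seq_len(n_n),
    activation_step = ifelse(activated, act_step, NA_real_),
    activation_time_s = ifelse(activated, act_step * params$print_dt, NA_real_),
    peak_vm = ifelse(activated, params$peak_potential, rest)
  )

  list(
    values = values,
    truth = truth,
    spec = sim_output_spec(n_t, n_n, 2, print_dt = params$print_dt)
  )
}

#' Generate synthetic output and write it through the HDF5 writer
#'
#' Convenience wrapper: [generate_cardiac_output()] followed by one
#' [write_timestep()] per step and [close()].
#'
#' @param params a [synth_params()].
#' @param path HDF5 file to create.
#' @param ... passed to [h5_writer()] (`chunk`, `target_chunk_bytes`,
#'   `default_style`, `cache`, `alignment`, ...).
#' @return A list: the generator output plus `writer` (the closed writer
#'   handle, for its instrumentation counters).
#' @export
generate_to_h5 <- function(params, path, ...) {
  out <- generate_cardiac_output(params)
  w <- h5_writer(path, out$spec, ...)
  for (t in seq_len(params$n_timesteps)) {
    write_timestep(w, t, out$values[t, , , drop = TRUE])
  }
  close(w)
  c(out, list(writer = w))
}

#' Storage arithmetic for a simulation output dataset
#'
#' One printing step of \eqn{D_N} nodes and \eqn{D_v} 8-byte variables
#' occupies \eqn{8 D_N D_v} bytes. Labels use decimal units (1 MB =
#' \eqn{10^6} B) rendered to three significant digits, the convention used
#' when quoting dataset sizes.
#'
#' @param spec a [sim_output_spec()].
#' @return One-row tibble: `bytes_per_timestep`, `total_bytes`, and their
#'   decimal-unit labels.
#' @examples
#' dataset_bytes(sim_output_spec(100, 3253316)) # 52.1 MB/step, 5.21 GB total
#' @export
dataset_bytes <- function(spec) {
  stopifnot(inherits(spec, "sim_output_spec"))
  per_step <- 8 * spec$n_nodes * spec$n_variables
  total <- per_step * spec$n_timesteps
  tibble::tibble(
    bytes_per_timestep = per_step,
    total_bytes = total,
    per_timestep_label = format_bytes_decimal(per_step),
    total_label = format_bytes_decimal(total)
  )
}

#' Render a byte count in decimal units
#'
#' @param bytes numeric byte count(s).
#' @return Character, e.g. `"52.1 MB"`; three significant digits, decimal
#'   (powers of 1000) units.
#' @export
format_bytes_decimal <- function(bytes) {
  vapply(as.double(bytes), function(b) {
    units <- c("B", "kB", "MB", "GB", "TB", "PB")
    pow <- if (b <= 0) 0 else min(floor(log10(b) / 3), length(units) - 1)
    val <- signif(b / 1000^pow, 3)
    paste(format(val, scientific = FALSE, trim = TRUE), units[pow + 1])
  }, character(1))
}
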