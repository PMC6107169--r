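#' The three compared I/O strategies
#'
#' @param target_chunk_bytes planning target for the two "new" strategies.
#' @param max_write_bytes write cap for the default-style chunk.
#' @return Tibble with one row per strategy: `strategy` (`"default"`,
#'   `"new"`, `"new+cache"`), `default_style`, `cache`.
#' @export
bench_strategies <- function(target_chunk_bytes = 131072,
                             max_write_bytes = 2^31) {
  tibble::tibble(
    strategy = c("default", "new", "new+cache"),
    default_style = c(TRUE, FALSE, FALSE),
    cache = c(FALSE, FALSE, TRUE),
    target_chunk_bytes = target_chunk_bytes,
    max_write_bytes = max_write_bytes
  )
}

# analytic read-cost metrics for one layout: the post-processing pattern
# (per-node series) and the conversion pattern (per-timestep slabs).
# Reads are costed at chunk granularity, mirroring the whole-chunk caching
# of the HDF5 default (POSIX) read driver: touching a chunk reads it in
# full, as one contiguous region.
layout_read_costs <- function(dataset, chunk) {
  dims <- dataset$dims
  cdims <- chunk$dims
  counts <- ceiling(dims / cdims)
  # per-node series (all times, one node, all variables): the chunks
  # touched depend only on the node's chunk column, which exists in
  # ceiling(D_N / C_2) variants; weight by column width.
  node_chunk_reads <- dims[2] * counts[1] * counts[3]
  # per slab: every chunk column at that time row
  conv_chunk_reads <- dims[1] * counts[2] * counts[3]
  tibble::tibble(
    postproc_chunk_reads = node_chunk_reads,
    postproc_bytes = node_chunk_reads * chunk$byte_size,
    dataconv_chunk_reads = conv_chunk_reads,
    dataconv_bytes = conv_chunk_reads * chunk$byte_size
  )
}

#' Compare chunking strategies on synthetic output
#'
#' For each strategy — default-style chunks, planned ("new") chunks, and
#' planned chunks with the write cache — the driver writes the same
#' synthetic dataset to a real HDF5 file, recomputes the activation-time
#' and peak-voltage maps (per-node reads), converts every timestep to a
#' slab record (per-slab reads), and reports deterministic cost metrics:
#' instrumented storage write and read calls, and analytic chunk-granular
#' read costs from the disk layout model. Wall-clock seconds are recorded
#' for interest only; they depend on the machine and are never asserted.
#'
#' @param params a [synth_params()].
#' @param dir working directory for the HDF5 files and converted records;
#'   default a fresh temporary directory.
#' @param target_chunk_bytes planning target for the "new" strategies.
#' @param max_write_bytes write cap for the default-style chunk.
#' @param nprocs_model number of processes for the analytic multi-process
#'   slab metrics (no processes are spawned).
#' @param threshold activation threshold, mV.
#' @param keep_files keep the HDF5 files and records on disk.
#' @return A `bench_report`: tibble with one row per strategy and stage
#'   (`output`, `dataconv`, `postproc`) and columns `storage_calls`,
#'   `chunk_reads`, `bytes`, `seconds`, plus per-strategy chunk metadata.
#'   The post-processing maps of each strategy are attached as the
#'   `"maps"` attribute; they are identical across strategies by
#'   construction, which the test suite asserts.
#' @export
run_benchmark <- function(params, dir = tempfile("h5bench"),
                          target_chunk_bytes = 131072,
                          max_write_bytes = 2^31, nprocs_model = 1,
                          threshold = -70, keep_files = FALSE) {
  stopifnot(inherits(params, "synth_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strategies <- bench_strategies(target_chunk_bytes, max_write_bytes)
  data <- generate_cardiac_output(params)
  dataset <- as_dataset_shape(data$spec)

  maps <- list()
  rows <- purrr::pmap_dfr(strategies, function(strategy, default_style, cache,
                                               target_chunk_bytes,
                                               max_write_bytes) {
    path <- file.path(dir, paste0(gsub("[^a-z]", "_", strategy), ".h5"))

    t_out <- system.time({
      w <- h5_writer(path, data$spec,
                     default_style = default_style, cache = cache,
                     target_chunk_bytes = target_chunk_bytes,
                     max_write_bytes = max_write_bytes)
      for (t in seq_len(params$n_timesteps)) {
        write_timestep(w, t, data$values[t, , , drop = TRUE])
      }
      close(w)
    })["elapsed"]

    r <- h5_reader(path)
    t_post <- system.time(
      map <- postprocess_maps(r, threshold = threshold)
    )["elapsed"]
    postproc_calls <- r$read_calls
    conv_dir <- file.path(dir, paste0(gsub("[^a-z]", "_", strategy), "_conv"))
    t_conv <- system.time(conv <- convert_timesteps(r, conv_dir))["elapsed"]
    dataconv_calls <- r$read_calls - postproc_calls
    close(r)
    maps[[strategy]] <<- map

    costs <- layout_read_costs(dataset, w$chunk)
    grid <- chunk_grid(dataset, w$chunk)
    proc_chunks <- sum(vapply(
      seq_len(nprocs_model) - 1,
      function(rk) chunks_touched_by_process(rk, nprocs_model, dataset, w$chunk),
      numeric(1)
    ))
    if (!keep_files) unlink(c(path, conv_dir), recursive = TRUE)

    total_bytes <- 8 * prod(dataset$dims)
    tibble::tibble(
      strategy = strategy,
      stage = c("output", "dataconv", "postproc"),
      storage_calls = c(w$storage_writes, dataconv_calls, postproc_calls),
      chunk_reads = c(NA, costs$dataconv_chunk_reads, costs$postproc_chunk_reads),
      bytes = c(total_bytes, costs$dataconv_bytes, costs$postproc_bytes),
      seconds = as.numeric(c(t_out, t_conv, t_post)),
      chunk_dims = list(w$chunk$dims),
      chunk_bytes = w$chunk$byte_size,
      total_chunks = grid$total_chunks,
      waste_fraction = grid$waste_fraction,
      proc_chunks_touched = proc_chunks
    )
  })

  structure(rows, class = c("bench_report", class(rows)), maps = maps,
            params = params)
}

#' One-line-per-strategy summary of a benchmark report
#'
#' @param x a `bench_report`.
#' @param ... unused.
#' @return Tibble with one row per strategy: write calls, post-processing
#'   chunk reads and bytes, chunk metadata.
#' @export
glance.bench_report <- function(x, ...) {
  dplyr::select(
    tidyr::pivot_wider(
      dplyr::select(tibble::as_tibble(x), "strategy", "stage", "storage_calls"),
      names_from = "stage", values_from = "storage_calls",
      names_prefix = "calls_"
    ),
    dplyr::everything()
  ) |>
    dplyr::left_join(
      dplyr::distinct(
        tibble::as_tibble(x),
        .data$strategy, .data$chunk_bytes, .data$total_chunks,
        .data$waste_fraction
      ),
      by = "strategy"
    )
}

#' Plot benchmark cost metrics
#'
#' Bar panels of the deterministic cost metrics per strategy and stage:
#' storage calls and bytes moved (log scale).
#'
#' @param object a `bench_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bench_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  "strategy", "stage", "storage_calls", "bytes"),
    cols = c("storage_calls", "bytes"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value,
                                   fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "I/O cost by strategy and stage",
      subtitle = "storage calls and bytes moved (log scale)"
    )
}

#' @rdname run_benchmark
#' @param x a `bench_report`.
#' @param ... unused.
#' @export
print.bench_report <- function(x, ...) {
  cat("<bench_report>\n")
  NextMethod()
}
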