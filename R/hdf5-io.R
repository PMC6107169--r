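#' Describe a simulation output dataset
#'
#' Simulation output is a three-dimensional array of 8-byte floats: time in
#' the first dimension, mesh nodes in the second, recorded variables in the
#' third. The default two variables are the transmembrane potential `V_m`
#' and the extracellular potential `phi_e`, recorded every printing time
#' step.
#'
#' @param n_timesteps printing time steps \eqn{D_t}.
#' @param n_nodes mesh nodes \eqn{D_N}.
#' @param n_variables recorded variables per node \eqn{D_v}.
#' @param variable_names,variable_units character vectors of length
#'   `n_variables`.
#' @param print_dt simulation seconds per printing step; default 25 µs.
#' @return An object of class `sim_output_spec`.
#' @examples
#' sim_output_spec(151, 3253316)
#' @export
sim_output_spec <- function(n_timesteps, n_nodes, n_variables = 2,
                            variable_names = c("V_m", "phi_e")[seq_len(n_variables)],
                            variable_units = rep("mV", n_variables),
                            print_dt = 25e-6) {
  n_timesteps <- check_count(n_timesteps, "n_timesteps")
  n_nodes <- check_count(n_nodes, "n_nodes")
  n_variables <- check_count(n_variables, "n_variables")
  if (length(variable_names) != n_variables || length(variable_units) != n_variables) {
    stop("variable names/units must have one entry per variable", call. = FALSE)
  }
  stopifnot(is.numeric(print_dt), length(print_dt) == 1, print_dt > 0)
  structure(
    list(
      n_timesteps = n_timesteps, n_nodes = n_nodes, n_variables = n_variables,
      variable_names = as.character(variable_names),
      variable_units = as.character(variable_units),
      print_dt = print_dt
    ),
    class = "sim_output_spec"
  )
}

#' @export
print.sim_output_spec <- function(x, ...) {
  cat(
    "<sim_output_spec> ", x$n_timesteps, " steps x ", x$n_nodes, " nodes x ",
    x$n_variables, " variables (", paste(x$variable_names, collapse = ", "),
    "), print_dt ", format(x$print_dt), " s\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn sim_output_spec The corresponding [dataset_shape()]
#'   \eqn{(D_t, D_N, D_v)} with 8-byte elements.
#' @param spec a `sim_output_spec`.
#' @export
as_dataset_shape <- function(spec) {
  stopifnot(inherits(spec, "sim_output_spec"))
  dataset_shape(c(spec$n_timesteps, spec$n_nodes, spec$n_variables), 8)
}

resolve_chunk <- function(dataset, chunk, target_chunk_bytes, default_style,
                          max_write_bytes) {
  if (!is.null(chunk)) {
    if (!inherits(chunk, "chunk_shape")) {
      chunk <- chunk_shape(chunk, dataset$element_size,
                           spans = all(chunk == dataset$dims))
    }
    if (any(chunk$dims > dataset$dims)) {
      stop("chunk exceeds dataset dimensions", call. = FALSE)
    }
    chunk
  } else if (isTRUE(default_style)) {
    default_chunk(dataset, max_write_bytes)
  } else {
    plan_chunks(dataset, target_chunk_bytes)
  }
}

#' Open an HDF5 writer for simulation output
#'
#' Creates the file (one chunked float64 dataset named `Data`, with
#' attributes `Variable Names`, `Variable Units` and `Print timestep (s)`)
#' and returns a handle for sequential per-timestep writes via
#' [write_timestep()]. Chunking is either given explicitly, planned from a
#' byte target with [plan_chunks()], or default-style via [default_chunk()].
#'
#' With `cache = TRUE` the writer buffers a window of \eqn{C_t} timesteps
#' (the chunk extent in time) for its owned node range — a reserved store of
#' \eqn{C_t \times N_n \times N_v} values — and flushes the whole window in
#' one storage operation when full, instead of issuing one small write per
#' step. The cache mode is fixed at construction; [close()] flushes any
#' partial final window. With `alignment > 0` the file is created with the
#' HDF5 alignment property and early chunk allocation, so every chunk
#' starts on a multiple of `alignment` bytes.
#'
#' @param path file to create (overwritten).
#' @param spec a [sim_output_spec()].
#' @param chunk explicit chunk dims (vector or [chunk_shape()]), or `NULL`
#'   to plan.
#' @param target_chunk_bytes planning target when `chunk` is `NULL`;
#'   default 128 kiB.
#' @param default_style use the default-style time-slab chunk instead of
#'   the planner.
#' @param max_write_bytes write cap for `default_style`; default
#'   \eqn{2^{31}} B.
#' @param cache enable the time-window write cache (fixed at construction).
#' @param alignment chunk start alignment in bytes; 0 for packed.
#' @param node_range 1-based `c(first, count)` of nodes owned by this
#'   writer; default all nodes.
#' @return An `h5_writer` handle (an environment). Fields of interest:
#'   `$storage_writes`, the number of storage-level write operations issued
#'   so far.
#' @export
h5_writer <- function(path, spec, chunk = NULL, target_chunk_bytes = 131072,
                      default_style = FALSE, max_write_bytes = 2^31,
                      cache = FALSE, alignment = 0,
                      node_range = c(1, spec$n_nodes)) {
  stopifnot(inherits(spec, "sim_output_spec"))
  dataset <- as_dataset_shape(spec)
  chunk <- resolve_chunk(dataset, chunk, target_chunk_bytes, default_style,
                         max_write_bytes)
  alignment <- check_count(alignment, "alignment", min = 0)
  node_range <- c(check_count(node_range[1], "node_range[1]"),
                  check_count(node_range[2], "node_range[2]"))
  if (node_range[1] + node_range[2] - 1 > spec$n_nodes) {
    stop("`node_range` exceeds the node dimension", call. = FALSE)
  }

  .Call(C_h5_create_chunked, path, dataset$dims, chunk$dims,
        as.double(alignment))
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "Data")
  rhdf5::h5writeAttribute(spec$variable_names, did, "Variable Names",
                          variableLengthString = TRUE)
  rhdf5::h5writeAttribute(spec$variable_units, did, "Variable Units",
                          variableLengthString = TRUE)
  rhdf5::h5writeAttribute(spec$print_dt, did, "Print timestep (s)")
  rhdf5::H5Dclose(did)

  w <- new.env(parent = emptyenv())
  w$path <- path
  w$spec <- spec
  w$dataset <- dataset
  w$chunk <- chunk
  w$fid <- fid
  w$cache_enabled <- isTRUE(cache)
  w$alignment <- alignment
  w$node_start <- node_range[1]
  w$n_nodes_owned <- node_range[2]
  w$c_t <- chunk$dims[1]
  w$buffer <- if (w$cache_enabled) {
    array(NA_real_, dim = c(w$c_t, w$n_nodes_owned, spec$n_variables))
  }
  w$fill <- 0
  w$next_t <- 1
  w$storage_writes <- 0
  w$closed <- FALSE
  class(w) <- "h5_writer"
  w
}

#' @export
print.h5_writer <- function(x, ...) {
  cat(
    "<h5_writer> ", x$path, "\n  chunk {", paste(x$chunk$dims, collapse = ", "),
    "}, cache ", if (x$cache_enabled) "on" else "off",
    ", wrote ", x$next_t - 1, "/", x$spec$n_timesteps, " steps in ",
    x$storage_writes, " storage writes\n",
    sep = ""
  )
  invisible(x)
}

# one storage-level write of `nt` consecutive timesteps starting at t0
# (1-based). `values` has dim (nt, N_n, N_v); the file's R-side view is
# (vars, nodes, time), hence the aperm.
write_block <- function(w, t0, values) {
  nt <- dim(values)[1]
  rhdf5::h5write(
    aperm(values, c(3, 2, 1)),
    w$fid, "Data",
    index = list(
      seq_len(w$spec$n_variables),
      w$node_start + seq_len(w$n_nodes_owned) - 1,
      t0 + seq_len(nt) - 1
    )
  )
  w$storage_writes <- w$storage_writes + 1
  invisible(w)
}

flush_cache <- function(w) {
  if (w$fill > 0) {
    t0 <- w$next_t - w$fill
    write_block(w, t0, w$buffer[seq_len(w$fill), , , drop = FALSE])
    w$fill <- 0
  }
  invisible(w)
}

#' Write one printing timestep
#'
#' Timesteps must be written in order (`t = 1, 2, ...`). Without the cache
#' the block lands in the file immediately as one storage write; with the
#' cache it is buffered, and once \eqn{C_t} steps have accumulated the
#' whole window is written in a single storage operation.
#'
#' @param writer an [h5_writer()].
#' @param t 1-based timestep index; must equal the next unwritten step.
#' @param values numeric `N_n x N_v` matrix for the writer's owned nodes
#'   (a vector is accepted when `N_v == 1`).
#' @return The writer, invisibly.
#' @export
write_timestep <- function(writer, t, values) {
  stopifnot(inherits(writer, "h5_writer"))
  if (writer$closed) stop("writer is closed", call. = FALSE)
  t <- check_count(t, "t")
  if (t != writer$next_t) {
    stop("timesteps must be written sequentially: expected t = ",
         writer$next_t, ", got ", t, call. = FALSE)
  }
  if (t > writer$spec$n_timesteps) {
    stop("dataset holds only ", writer$spec$n_timesteps, " timesteps", call. = FALSE)
  }
  values <- as.matrix(values)
  if (!all(dim(values) == c(writer$n_nodes_owned, writer$spec$n_variables))) {
    stop("`values` must be ", writer$n_nodes_owned, " x ",
         writer$spec$n_variables, call. = FALSE)
  }
  writer$next_t <- t + 1
  if (writer$cache_enabled) {
    writer$fill <- writer$fill + 1
    writer$buffer[writer$fill, , ] <- values
    if (writer$fill == writer$c_t) flush_cache(writer)
  } else {
    write_block(writer, t, array(values, dim = c(1, dim(values))))
  }
  invisible(writer)
}

#' Close a writer or reader
#'
#' Closing a writer flushes any partially filled cache window, so a time
#' extent that is not a multiple of \eqn{C_t} loses no data.
#'
#' @param con an [h5_writer()] or [h5_reader()].
#' @param ... unused.
#' @return The handle, invisibly.
#' @export
close.h5_writer <- function(con, ...) {
  if (!con$closed) {
    flush_cache(con)
    rhdf5::H5Fclose(con$fid)
    con$closed <- TRUE
  }
  invisible(con)
}

#' Open simulation output for reading
#'
#' @param path an HDF5 file written by [h5_writer()] (dataset `Data`).
#' @return An `h5_reader` handle with fields `spec` (recovered from the
#'   file's attributes and extents), `chunk` (the file's chunk dims, in
#'   time/nodes/variables order) and `read_calls` (storage-level reads
#'   issued so far).
#' @export
h5_reader <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  did <- rhdf5::H5Dopen(fid, "Data")
  sid <- rhdf5::H5Dget_space(did)
  rdims <- rhdf5::H5Sget_simple_extent_dims(sid)$size # R view: (vars, nodes, time)
  rhdf5::H5Sclose(sid)
  pid <- rhdf5::H5Dget_create_plist(did)
  cdims <- rhdf5::H5Pget_chunk(pid) # file (C) order: (time, nodes, vars)
  rhdf5::H5Pclose(pid)
  attrs <- tryCatch(rhdf5::h5readAttributes(fid, "Data"), error = function(e) list())
  rhdf5::H5Dclose(did)
  dims <- rev(rdims)
  r <- new.env(parent = emptyenv())
  r$path <- path
  r$fid <- fid
  r$spec <- sim_output_spec(
    dims[1], dims[2], dims[3],
    variable_names = attrs[["Variable Names"]] %||% paste0("var", seq_len(dims[3])),
    variable_units = attrs[["Variable Units"]] %||% rep("", dims[3]),
    print_dt = as.double(attrs[["Print timestep (s)"]] %||% 1)
  )
  r$chunk <- chunk_shape(cdims, 8, spans = all(cdims == dims))
  r$read_calls <- 0
  r$closed <- FALSE
  class(r) <- "h5_reader"
  r
}

#' @export
print.h5_reader <- function(x, ...) {
  cat(
    "<h5_reader> ", x$path, "\n  ", x$spec$n_timesteps, " x ",
    x$spec$n_nodes, " x ", x$spec$n_variables, ", chunk {",
    paste(x$chunk$dims, collapse = ", "), "}, ", x$read_calls,
    " reads issued\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname close.h5_writer
#' @export
close.h5_reader <- function(con, ...) {
  if (!con$closed) {
    rhdf5::H5Fclose(con$fid)
    con$closed <- TRUE
  }
  invisible(con)
}

#' Read the full time series of one node and variable
#'
#' The canonical post-processing access pattern: all time points for one
#' node, then all for the next. Under default-style chunks every such read
#' cuts across every chunk of the file; under planned chunks it stays
#' within one column of small chunks.
#'
#' @param reader an [h5_reader()].
#' @param node 1-based node index.
#' @param variable 1-based variable index.
#' @return Numeric vector of length \eqn{D_t}.
#' @export
read_node_series <- function(reader, node, variable = 1) {
  stopifnot(inherits(reader, "h5_reader"))
  node <- check_count(node, "node")
  variable <- check_count(variable, "variable")
  if (node > reader$spec$n_nodes || variable > reader$spec$n_variables) {
    stop("node or variable out of range", call. = FALSE)
  }
  out <- rhdf5::h5read(reader$fid, "Data", index = list(variable, node, NULL))
  reader$read_calls <- reader$read_calls + 1
  as.vector(out)
}

#' Read one timestep's full node slab
#'
#' The conversion access pattern: every node and variable at a single time.
#'
#' @param reader an [h5_reader()].
#' @param t 1-based timestep index.
#' @return Numeric `N x V` matrix (nodes by variables).
#' @export
read_timestep_slab <- function(reader, t) {
  stopifnot(inherits(reader, "h5_reader"))
  t <- check_count(t, "t")
  if (t > reader$spec$n_timesteps) stop("timestep out of range", call. = FALSE)
  out <- rhdf5::h5read(reader$fid, "Data", index = list(NULL, NULL, t))
  reader$read_calls <- reader$read_calls + 1
  # R view is (vars, nodes, 1): transpose to nodes x vars
  t(matrix(out, nrow = reader$spec$n_variables))
}

#' Chunk dimensions of a file's `Data` dataset
#'
#' @param path HDF5 file.
#' @return Numeric vector of chunk extents in file (time, nodes,
#'   variables) order.
#' @export
h5_chunk_dims <- function(path) {
  r <- h5_reader(path)
  on.exit(close(r))
  r$chunk$dims
}
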