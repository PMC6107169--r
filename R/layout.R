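#' Model the serialization of a (chunked) dataset to a linear byte space
#'
#' Digital storage is one-dimensional, so a multidimensional dataset must be
#' mapped to byte offsets. This model serializes chunks in row-major order
#' over the chunk grid, packed sequentially from `base_offset`, and elements
#' in row-major order within each chunk. An unchunked dataset is the special
#' case of a single chunk spanning the dataset, which reduces to plain
#' row-major order.
#'
#' Real HDF5 files locate chunks at irregular positions chosen by a B-tree
#' index in write order; the fixed packed order here is a modelling
#' assumption that makes seek/segment costs deterministic and testable.
#' With `alignment > 0` every chunk start (and the base) is rounded up to a
#' multiple of `alignment`, emulating the HDF5 alignment property used to
#' place each chunk on a filesystem stripe boundary.
#'
#' @param dataset a [dataset_shape()].
#' @param chunk a [chunk_shape()], or `NULL` for an unchunked (spanning)
#'   layout.
#' @param base_offset starting byte offset of the data, default 0.
#' @param alignment byte multiple at which chunks start; 0 means packed.
#' @return An object of class `linear_layout`.
#' @examples
#' linear_layout(dataset_shape(c(10, 10)))
#' @export
linear_layout <- function(dataset, chunk = NULL, base_offset = 0, alignment = 0) {
  stopifnot(inherits(dataset, "dataset_shape"))
  if (is.null(chunk)) {
    chunk <- chunk_shape(dataset$dims, dataset$element_size, spans = TRUE)
  }
  stopifnot(inherits(chunk, "chunk_shape"))
  if (length(chunk$dims) != length(dataset$dims) || any(chunk$dims > dataset$dims)) {
    stop("chunk must be no larger than the dataset in every dimension", call. = FALSE)
  }
  base_offset <- check_count(base_offset, "base_offset", min = 0)
  alignment <- check_count(alignment, "alignment", min = 0)
  chunk_stride <- chunk$byte_size
  if (alignment > 0) {
    chunk_stride <- ceiling(chunk_stride / alignment) * alignment
    base_offset <- ceiling(base_offset / alignment) * alignment
  }
  structure(
    list(
      dataset = dataset,
      chunk = chunk,
      counts = ceiling(dataset$dims / chunk$dims),
      base_offset = base_offset,
      alignment = alignment,
      chunk_stride = chunk_stride
    ),
    class = "linear_layout"
  )
}

#' @export
print.linear_layout <- function(x, ...) {
  cat(
    "<linear_layout> dataset {", paste(x$dataset$dims, collapse = ", "),
    "}, chunk {", paste(x$chunk$dims, collapse = ", "), "}",
    if (x$alignment > 0) paste0(", aligned to ", x$alignment, " B"), "\n",
    sep = ""
  )
  invisible(x)
}

# row-major rank of 0-based index rows (matrix) over extents `dims`
row_major_rank <- function(index, dims) {
  if (is.null(dim(index))) index <- matrix(index, nrow = 1)
  strides <- rev(cumprod(rev(c(dims[-1], 1))))
  as.vector(index %*% strides)
}

#' Byte offset of dataset elements under a linear layout
#'
#' Indices are 0-based. Each element lives in chunk
#' \eqn{g_i = \lfloor i_i / C_i \rfloor} at within-chunk position
#' \eqn{r_i = i_i - g_i C_i}; its offset is the chunk's start (row-major
#' chunk rank times the chunk stride) plus the row-major rank of \eqn{r}
#' within the chunk, times the element size.
#'
#' @param layout a [linear_layout()].
#' @param index 0-based index vector, or a matrix with one index per row.
#' @return Byte offset(s), as doubles.
#' @examples
#' lay <- linear_layout(dataset_shape(c(10, 10)))
#' element_offset(lay, c(3, 2)) # 1-based entry (4,3) -> 32 elements in
#' @export
element_offset <- function(layout, index) {
  stopifnot(inherits(layout, "linear_layout"))
  if (is.null(dim(index))) index <- matrix(as.double(index), nrow = 1)
  storage.mode(index) <- "double"
  if (ncol(index) != length(layout$dataset$dims)) {
    stop("index must have one entry per dataset dimension", call. = FALSE)
  }
  if (any(index < 0) || any(sweep(index, 2, layout$dataset$dims, `>=`))) {
    stop("index out of range", call. = FALSE)
  }
  cdims <- layout$chunk$dims
  g <- floor(sweep(index, 2, cdims, `/`))
  r <- index - sweep(g, 2, cdims, `*`)
  chunk_rank <- row_major_rank(g, layout$counts)
  within <- row_major_rank(r, cdims)
  layout$base_offset + chunk_rank * layout$chunk_stride +
    within * layout$dataset$element_size
}

#' One-based row-major ordinal, matrix style
#'
#' Convenience mirror of conventional matrix notation indexed from 1: the
#' position on disk of an entry of an unchunked row-major dataset, counted
#' from 1. Entry (4,3) of a 10x10 dataset is the 33rd element.
#'
#' @param dims dataset extents.
#' @param index1 1-based index vector (or matrix of rows).
#' @return 1-based ordinal(s).
#' @examples
#' element_ordinal(c(10, 10), c(4, 3)) # 33
#' @export
element_ordinal <- function(dims, index1) {
  dims <- check_extents(dims, "dims")
  if (is.null(dim(index1))) index1 <- matrix(as.double(index1), nrow = 1)
  storage.mode(index1) <- "double"
  if (any(index1 < 1) || any(sweep(index1, 2, dims, `>`))) {
    stop("index out of range", call. = FALSE)
  }
  row_major_rank(index1 - 1, dims) + 1
}

#' Create a hyperslab selection
#'
#' A rectangular selection of a dataset: 0-based inclusive `start` and a
#' per-dimension `count` of selected elements.
#'
#' @param start 0-based start index vector.
#' @param count per-dimension element counts, all `>= 1`.
#' @return An object of class `hyperslab`.
#' @export
hyperslab <- function(start, count) {
  start <- check_index0(start, "start")
  count <- check_extents(count, "count")
  if (length(start) != length(count)) {
    stop("`start` and `count` must have the same length", call. = FALSE)
  }
  structure(list(start = start, count = count), class = "hyperslab")
}

check_slab <- function(slab, dataset) {
  stopifnot(inherits(slab, "hyperslab"), inherits(dataset, "dataset_shape"))
  if (length(slab$start) != length(dataset$dims) ||
      any(slab$start + slab$count > dataset$dims)) {
    stop("hyperslab does not fit inside the dataset", call. = FALSE)
  }
  invisible(slab)
}

# all 0-based indices of a hyperslab, one per row (row-major over the slab)
slab_indices <- function(slab) {
  grids <- lapply(seq_along(slab$start), function(i) {
    slab$start[i] + seq_len(slab$count[i]) - 1
  })
  as.matrix(rev(expand.grid(rev(grids))))
}

#' Contiguous-segment cost of a hyperslab access
#'
#' Lists the byte offset of every selected element under the layout, sorts
#' them, and counts maximal runs of consecutive offsets. One segment means
#' a single contiguous read; each additional segment implies a disk seek.
#' Reading a row of a row-major dataset is one segment; reading a column
#' seeks before every element unless the chunks are column-shaped.
#'
#' @param layout a [linear_layout()].
#' @param slab a [hyperslab()] within the dataset.
#' @return One-row tibble: `segments`, `bytes_read`, `gap_bytes` (bytes
#'   skipped between segments), `chunks_touched`.
#' @examples
#' lay <- linear_layout(dataset_shape(c(10, 10)))
#' segments_for_selection(lay, hyperslab(c(3, 2), c(5, 1))) # a column: 5 seeks
#' @export
segments_for_selection <- function(layout, slab) {
  stopifnot(inherits(layout, "linear_layout"))
  check_slab(slab, layout$dataset)
  n_sel <- prod(slab$count)
  if (n_sel > 1e6) {
    stop("selection too large to enumerate (", n_sel, " elements)", call. = FALSE)
  }
  esize <- layout$dataset$element_size
  offs <- sort(element_offset(layout, slab_indices(slab)))
  gaps <- diff(offs) - esize
  tibble::tibble(
    segments = 1 + sum(gaps > 0),
    bytes_read = esize * n_sel,
    gap_bytes = sum(gaps[gaps > 0]),
    chunks_touched = chunks_touched_by_slab(layout$dataset, layout$chunk, slab)
  )
}

#' Chunks intersected by a hyperslab
#'
#' Counted analytically: in each dimension the slab touches chunk rows
#' \eqn{\lfloor s_i / C_i \rfloor} through
#' \eqn{\lfloor (s_i + n_i - 1) / C_i \rfloor}; the total is the product of
#' the per-dimension counts.
#'
#' @param dataset a [dataset_shape()].
#' @param chunk a [chunk_shape()].
#' @param slab a [hyperslab()].
#' @return Number of chunks containing at least one selected element.
#' @export
chunks_touched_by_slab <- function(dataset, chunk, slab) {
  check_slab(slab, dataset)
  lo <- floor(slab$start / chunk$dims)
  hi <- floor((slab$start + slab$count - 1) / chunk$dims)
  prod(hi - lo + 1)
}

#' Contiguous node block owned by a parallel process
#'
#' Mesh nodes are partitioned into `nprocs` contiguous blocks along the
#' second (node) dimension; each process's block spans all other
#' dimensions, giving slabs of approximate shape
#' \eqn{\{D_t, D_N / j, D_v\}} that are orthogonal to default-style
#' time-chunks. Remainder nodes go to the lowest ranks (ceil-first), so
#' block sizes differ by at most one.
#'
#' @param rank 0-based process rank.
#' @param nprocs number of processes \eqn{j}; must not exceed the node
#'   count.
#' @param dataset a [dataset_shape()] with at least two dimensions.
#' @return A [hyperslab()] for the rank's block.
#' @examples
#' process_slab(0, 4, dataset_shape(c(151, 100, 2)))
#' @export
process_slab <- function(rank, nprocs, dataset) {
  stopifnot(inherits(dataset, "dataset_shape"))
  if (length(dataset$dims) < 2) {
    stop("process slabs need at least 2 dimensions", call. = FALSE)
  }
  nprocs <- check_count(nprocs, "nprocs")
  rank <- check_index0(rank, "rank", upper = nprocs)
  d_n <- dataset$dims[2]
  if (nprocs > d_n) {
    stop("more processes (", nprocs, ") than nodes (", d_n, ")", call. = FALSE)
  }
  base <- floor(d_n / nprocs)
  rem <- d_n - base * nprocs
  count2 <- base + (rank < rem)
  start2 <- rank * base + min(rank, rem)
  start <- rep(0, length(dataset$dims))
  count <- dataset$dims
  start[2] <- start2
  count[2] <- count2
  hyperslab(start, count)
}

#' Chunks a process's block intersects
#'
#' With default-style chunks spanning the node dimension, every process's
#' slab cuts across every chunk; with planned (small) chunks a process only
#' touches the chunk columns overlapping its node block.
#'
#' @inheritParams process_slab
#' @param chunk a [chunk_shape()].
#' @return Integer count of chunks intersecting the rank's slab.
#' @export
chunks_touched_by_process <- function(rank, nprocs, dataset, chunk) {
  slab <- process_slab(rank, nprocs, dataset)
  chunks_touched_by_slab(dataset, chunk, slab)
}
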