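# Independent oracles, deliberately naive: loops and direct arithmetic,
# no calls into the code paths they check.

# chunk dims for a target extent, direct transcription of the definition
oracle_dims_for_target <- function(dims, t_elems) {
  x <- numeric(length(dims))
  cd <- numeric(length(dims))
  for (i in seq_along(dims)) {
    x[i] <- ceiling(dims[i] / t_elems)
    cd[i] <- ceiling(dims[i] / x[i])
  }
  list(dims = cd, spans = all(x == 1))
}

# exhaustive search over every T in 1..max(dims) for the stopping point of
# the incremental search, then the single-step overshoot correction
oracle_plan <- function(dims, element_size, target_bytes) {
  stop_t <- NA
  for (t_elems in seq_len(max(dims))) {
    ch <- oracle_dims_for_target(dims, t_elems)
    cb <- element_size * prod(ch$dims)
    if (cb >= target_bytes || ch$spans) {
      stop_t <- t_elems
      break
    }
  }
  ch <- oracle_dims_for_target(dims, stop_t)
  if (element_size * prod(ch$dims) > target_bytes) {
    ch <- oracle_dims_for_target(dims, stop_t - 1)
  }
  ch$dims
}

# byte offset of one 0-based index under the packed chunked layout,
# computed with scalar loops
oracle_offset <- function(index, dims, cdims, element_size,
                          base_offset = 0, alignment = 0) {
  n <- length(dims)
  counts <- ceiling(dims / cdims)
  stride <- element_size * prod(cdims)
  if (alignment > 0) {
    stride <- ceiling(stride / alignment) * alignment
    base_offset <- ceiling(base_offset / alignment) * alignment
  }
  chunk_rank <- 0
  within <- 0
  for (i in seq_len(n)) {
    g <- floor(index[i] / cdims[i])
    r <- index[i] - g * cdims[i]
    chunk_rank <- chunk_rank * counts[i] + g
    within <- within * cdims[i] + r
  }
  base_offset + chunk_rank * stride + within * element_size
}

# run-length segment count of a hyperslab: enumerate every selected
# element's offset with oracle_offset, sort, count runs
oracle_segments <- function(start, count, dims, cdims, element_size,
                            alignment = 0) {
  idx_list <- lapply(seq_along(dims), function(i) start[i] + 0:(count[i] - 1))
  grid <- expand.grid(idx_list)
  offs <- apply(as.matrix(grid), 1, oracle_offset, dims = dims, cdims = cdims,
                element_size = element_size, alignment = alignment)
  offs <- sort(offs)
  if (length(offs) == 1) return(1)
  1 + sum(diff(offs) != element_size)
}

# brute-force count of chunks whose extent intersects a slab
oracle_chunks_touched <- function(start, count, dims, cdims) {
  counts <- ceiling(dims / cdims)
  grid <- expand.grid(lapply(counts, function(k) 0:(k - 1)))
  hits <- apply(as.matrix(grid), 1, function(g) {
    all(g * cdims < start + count & (g + 1) * cdims > start)
  })
  sum(hits)
}

# all 0-based indices of a hyperslab, one per row
slab_indices_for_test <- function(slab) {
  grids <- lapply(seq_along(slab$start), function(i) {
    slab$start[i] + seq_len(slab$count[i]) - 1
  })
  as.matrix(rev(expand.grid(rev(grids))))
}

# small random dataset shapes with bounded element count
random_dims <- function(max_ndim = 3, max_prod = 1e4) {
  n <- sample(1:max_ndim, 1)
  repeat {
    d <- sample(1:40, n, replace = TRUE)
    if (prod(d) <= max_prod) return(d)
  }
}

random_slab <- function(dims) {
  start <- vapply(dims, function(d) sample(0:(d - 1), 1), numeric(1))
  count <- vapply(seq_along(dims), function(i) {
    sample(seq_len(dims[i] - start[i]), 1)
  }, numeric(1))
  list(start = start, count = count)
}

random_chunk_dims <- function(dims) {
  vapply(dims, function(d) sample(seq_len(d), 1), numeric(1))
}
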