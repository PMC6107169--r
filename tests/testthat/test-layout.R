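test_that("row-major ordinals match conventional matrix notation", {
  expect_equal(element_ordinal(c(10, 10), c(4, 3)), 33)
  expect_equal(element_ordinal(c(10, 10), c(10, 10)), 100)
  expect_equal(element_ordinal(c(10, 10), c(1, 1)), 1)
  # the column (4,3)..(8,3) lands on every tenth element
  col <- cbind(4:8, 3)
  expect_equal(element_ordinal(c(10, 10), col), c(33, 43, 53, 63, 73))
  expect_error(element_ordinal(c(10, 10), c(11, 1)), "out of range")
})

test_that("first element sits at the base offset", {
  lay <- linear_layout(dataset_shape(c(5, 6, 2)), chunk_shape(c(2, 3, 2)),
                       base_offset = 96)
  expect_equal(element_offset(lay, c(0, 0, 0)), 96)
  expect_error(element_offset(lay, c(5, 0, 0)), "out of range")
})

test_that("row reads are contiguous, column reads seek per element", {
  lay <- linear_layout(dataset_shape(c(10, 10)))
  # row (3,4)..(3,8): one contiguous run
  row <- segments_for_selection(lay, hyperslab(c(2, 3), c(1, 5)))
  expect_equal(row$segments, 1)
  expect_equal(row$bytes_read, 40)
  # column (4,3)..(8,3): five runs, a seek before each
  col <- segments_for_selection(lay, hyperslab(c(3, 2), c(5, 1)))
  expect_equal(col$segments, 5)
  # column-shaped chunks make the same read a single contiguous run
  laycol <- linear_layout(dataset_shape(c(10, 10)), chunk_shape(c(10, 1)))
  expect_equal(segments_for_selection(laycol, hyperslab(c(3, 2), c(5, 1)))$segments, 1)
})

test_that("segment counts equal the run-length oracle on random layouts", {
  set.seed(101)
  for (i in 1:25) {
    dims <- random_dims(max_ndim = 3, max_prod = 1e4)
    cdims <- random_chunk_dims(dims)
    alignment <- sample(c(0, 0, 64, 256), 1)
    ds <- dataset_shape(dims)
    lay <- linear_layout(ds, chunk_shape(cdims), alignment = alignment)
    sl <- random_slab(dims)
    got <- segments_for_selection(lay, hyperslab(sl$start, sl$count))
    expect_equal(
      got$segments,
      oracle_segments(sl$start, sl$count, dims, cdims, 8, alignment)
    )
    expect_equal(
      got$chunks_touched,
      oracle_chunks_touched(sl$start, sl$count, dims, cdims)
    )
  }
})

test_that("offsets are injective and packed layouts fill the allocation", {
  set.seed(5)
  for (i in 1:15) {
    dims <- random_dims(max_ndim = 3, max_prod = 2000)
    cdims <- random_chunk_dims(dims)
    ds <- dataset_shape(dims)
    lay <- linear_layout(ds, chunk_shape(cdims))
    sl <- hyperslab(rep(0, length(dims)), dims)
    offs <- element_offset(lay, slab_indices_for_test(sl))
    expect_equal(anyDuplicated(offs), 0)
    alloc_bytes <- chunk_grid(ds, chunk_shape(cdims))$allocated_elements * 8
    expect_true(all(offs >= 0 & offs + 8 <= alloc_bytes))
    if (all(dims %% cdims == 0)) {
      # no edge waste: every allocated byte is some element's
      expect_equal(sort(offs), seq(0, alloc_bytes - 8, by = 8))
    }
  }
})

test_that("per-node series is never costlier under planned chunks", {
  set.seed(23)
  for (i in 1:10) {
    d_t <- sample(20:60, 1)
    d_n <- sample(50:200, 1)
    ds <- dataset_shape(c(d_t, d_n, 2))
    planned <- plan_chunks(ds, target_bytes = 1024)
    deflt <- default_chunk(ds, max_write_bytes = ceiling(d_t / 3) * 16 * d_n)
    lay_p <- linear_layout(ds, planned)
    lay_d <- linear_layout(ds, deflt)
    for (node in sample(0:(d_n - 1), 5)) {
      slab <- hyperslab(c(0, node, 0), c(d_t, 1, 2))
      sp <- segments_for_selection(lay_p, slab)
      sd <- segments_for_selection(lay_d, slab)
      expect_lte(sp$segments, sd$segments)
      # whole-chunk read cost (the default read driver caches full chunks)
      expect_lte(sp$chunks_touched * planned$byte_size,
                 sd$chunks_touched * deflt$byte_size)
    }
  }
})

test_that("process slabs partition the node dimension", {
  ds <- dataset_shape(c(151, 100, 2))
  sl <- process_slab(0, 4, ds)
  expect_equal(sl$start, c(0, 0, 0))
  expect_equal(sl$count, c(151, 25, 2))

  # ceil-first remainder: earlier ranks take the extra node
  ds <- dataset_shape(c(151, 10, 2))
  sizes <- vapply(0:2, function(r) process_slab(r, 3, ds)$count[2], numeric(1))
  expect_equal(sizes, c(4, 3, 3))

  # union of slabs covers the nodes exactly once
  for (j in c(1, 3, 7)) {
    slabs <- lapply(0:(j - 1), process_slab, nprocs = j, dataset = ds)
    covered <- unlist(lapply(slabs, function(s) s$start[2] + seq_len(s$count[2]) - 1))
    expect_equal(sort(covered), 0:9)
  }
  expect_error(process_slab(0, 11, ds), "more processes")
})

test_that("chunk intersection counts match brute force per process", {
  ds <- dataset_shape(c(151, 3253316, 2))
  chunk <- chunk_shape(c(151, 434, 2))
  for (rk in c(0, 1, 95, 191)) {
    expect_equal(
      chunks_touched_by_process(rk, 192, ds, chunk),
      oracle_chunks_touched(process_slab(rk, 192, ds)$start,
                            process_slab(rk, 192, ds)$count,
                            ds$dims, chunk$dims)
    )
  }

  # default-style chunks span the nodes: every process crosses every chunk
  ds2 <- dataset_shape(c(100, 60, 2))
  deflt <- chunk_shape(c(10, 60, 2))
  for (rk in 0:3) {
    expect_equal(chunks_touched_by_process(rk, 4, ds2, deflt), 10)
  }

  # chunk equal to one process slab: exactly one chunk
  ds3 <- dataset_shape(c(20, 40, 2))
  expect_equal(
    chunks_touched_by_process(1, 4, ds3, chunk_shape(c(20, 10, 2))), 1
  )
})
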