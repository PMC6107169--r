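bench_dims <- dataset_shape(c(151, 3253316, 2))

test_that("chunk dims for a target extent minimise edge waste", {
  ch <- calculate_chunk_dims(bench_dims, 434)
  expect_equal(ch$dims, c(151, 434, 2))
  expect_equal(ch$byte_size, 1048544)
  expect_false(ch$spans)

  # target larger than every extent: one spanning chunk
  ch <- calculate_chunk_dims(dataset_shape(10), 20)
  expect_equal(ch$dims, 10)
  expect_true(ch$spans)

  # 4 chunks of 88 cover 350 with 2 elements wasted; 4 chunks of 87 do not
  ch <- calculate_chunk_dims(dataset_shape(350), 100)
  expect_equal(ch$dims, 88)
  grid <- chunk_grid(dataset_shape(350), ch)
  expect_equal(grid$total_chunks, 4)
  expect_equal(grid$allocated_elements, 352)
  expect_true(4 * 87 < 350)

  expect_error(calculate_chunk_dims(bench_dims, 0), "target_elems")
})

test_that("byte-target planning reproduces the worked chunk shapes", {
  ch <- plan_chunks(bench_dims, target_bytes = 2^20)
  expect_equal(ch$dims, c(151, 434, 2))
  expect_equal(ch$byte_size, 1048544)

  # whole dataset below target: one spanning chunk
  ch <- plan_chunks(dataset_shape(c(2, 2, 2)), target_bytes = 1e9)
  expect_true(ch$spans)
  expect_equal(ch$byte_size, 64)

  # 1-D exhaustive case: T = 10 is the largest with 8*C <= 80
  ch <- plan_chunks(dataset_shape(1000), target_bytes = 80)
  expect_equal(ch$dims, 10)
  expect_equal(ch$byte_size, 80)

  expect_error(plan_chunks(dataset_shape(10), target_bytes = 4),
               "smaller than one element")
})

test_that("incremental and binary searches agree with the exhaustive oracle", {
  set.seed(42)
  for (i in 1:60) {
    dims <- random_dims()
    esize <- sample(c(1, 4, 8), 1)
    target <- sample(esize:(esize * prod(dims) * 2), 1)
    ds <- dataset_shape(dims, esize)
    inc <- plan_chunks(ds, target)
    bin <- plan_chunks(ds, target, method = "binary")
    expect_equal(inc$dims, bin$dims)
    expect_equal(inc$dims, oracle_plan(dims, esize, target))
    # bound: spans or within target
    expect_true(inc$spans || inc$byte_size <= target)
    # per-dimension minimal cover: x*C >= D and x*(C-1) < D
    x <- ceiling(dims / inc$dims)
    expect_true(all(x * inc$dims >= dims))
    expect_true(all(x * (inc$dims - 1) < dims))
  }
})

test_that("chunk byte size is non-decreasing in the target extent", {
  set.seed(7)
  for (i in 1:20) {
    dims <- random_dims()
    sizes <- vapply(seq_len(max(dims) + 2), function(t) {
      calculate_chunk_dims(dataset_shape(dims), t)$byte_size
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("planned dims minimise waste among chunks with the same grid", {
  set.seed(11)
  for (i in 1:20) {
    dims <- random_dims()
    ds <- dataset_shape(dims)
    ch <- plan_chunks(ds, sample(8:(8 * prod(dims)), 1))
    counts <- ceiling(dims / ch$dims)
    planned_waste <- chunk_grid(ds, ch)$waste_fraction
    # any other dim-1 extent with the same chunk count wastes at least as much
    for (t in seq_len(dims[1])) {
      if (ceiling(dims[1] / t) == counts[1] && length(dims) >= 1) {
        alt <- chunk_shape(c(t, ch$dims[-1]), ds$element_size)
        expect_gte(chunk_grid(ds, alt)$waste_fraction, planned_waste)
      }
    }
  }
})

test_that("chunk grid accounting matches the worked edge-waste example", {
  grid <- chunk_grid(dataset_shape(c(350, 1000)), chunk_shape(c(100, 1000)))
  expect_equal(grid$counts, c(4, 1))
  expect_equal(grid$waste_fraction, 0.125)

  grid <- chunk_grid(bench_dims, chunk_shape(c(151, 434, 2)))
  expect_equal(grid$total_chunks, 7497)

  grid <- chunk_grid(dataset_shape(c(6, 4)), chunk_shape(c(6, 4), spans = TRUE))
  expect_equal(grid$total_chunks, 1)
  expect_equal(grid$waste_fraction, 0)

  expect_error(chunk_grid(dataset_shape(c(5, 5)), chunk_shape(c(6, 1))),
               "exceeds")
})

test_that("default-style chunks cap the time extent at the write limit", {
  ch <- default_chunk(bench_dims, max_write_bytes = 2^31)
  expect_equal(ch$dims, c(41, 3253316, 2))

  # whole dataset under the cap: chunk capped at D_1
  ch <- default_chunk(dataset_shape(c(10, 4, 2)), max_write_bytes = 2^31)
  expect_equal(ch$dims, c(10, 4, 2))
  expect_true(ch$spans)

  ch <- default_chunk(dataset_shape(c(100, 1000, 2)), max_write_bytes = 64000)
  expect_equal(ch$dims[1], 4)

  # one slab larger than the cap: impossible, report the minimum limit
  expect_error(default_chunk(dataset_shape(c(100, 1000, 2)), max_write_bytes = 8000),
               "16000")
  expect_error(default_chunk(dataset_shape(5)), "2 dimensions")
})
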