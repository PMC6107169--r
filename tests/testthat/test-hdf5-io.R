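tmp_h5 <- function() tempfile(fileext = ".h5")

small_spec <- sim_output_spec(10, 40, 2, print_dt = 25e-6)

write_all <- function(path, values, ...) {
  spec <- sim_output_spec(dim(values)[1], dim(values)[2], dim(values)[3])
  w <- h5_writer(path, spec, ...)
  for (t in seq_len(dim(values)[1])) {
    write_timestep(w, t, values[t, , , drop = TRUE])
  }
  close(w)
  w
}

test_that("created files carry the planned chunking and metadata", {
  path <- tmp_h5()
  spec <- sim_output_spec(151, 2000, 2)
  w <- h5_writer(path, spec, target_chunk_bytes = 2^20)
  close(w)
  planned <- plan_chunks(dataset_shape(c(151, 2000, 2)), 2^20)
  expect_equal(h5_chunk_dims(path), planned$dims)

  r <- h5_reader(path)
  expect_equal(r$spec$n_timesteps, 151)
  expect_equal(r$spec$n_nodes, 2000)
  expect_equal(r$spec$variable_names, c("V_m", "phi_e"))
  expect_equal(r$spec$print_dt, 25e-6)
  close(r)
  unlink(path)
})

test_that("a chunk equal to the dataset gives a single-chunk file", {
  path <- tmp_h5()
  w <- h5_writer(path, small_spec, chunk = c(10, 40, 2))
  close(w)
  cdims <- h5_chunk_dims(path)
  expect_equal(cdims, c(10, 40, 2))
  expect_equal(chunk_grid(dataset_shape(c(10, 40, 2)),
                          chunk_shape(cdims))$total_chunks, 1)
  unlink(path)
})

test_that("writes must be sequential and correctly shaped", {
  path <- tmp_h5()
  w <- h5_writer(path, small_spec, chunk = c(2, 40, 2))
  vals <- matrix(0, 40, 2)
  write_timestep(w, 1, vals)
  expect_error(write_timestep(w, 3, vals), "sequentially")
  expect_error(write_timestep(w, 2, matrix(0, 39, 2)), "must be")
  close(w)
  expect_error(write_timestep(w, 2, vals), "closed")
  unlink(path)
})

test_that("cached and uncached writers produce identical files", {
  set.seed(31)
  grid <- list(
    c(d_t = 6, c_t = 3), # divisible window
    c(d_t = 5, c_t = 3), # partial final window
    c(d_t = 7, c_t = 1), # degenerate cache of one step
    c(d_t = 4, c_t = 4), # single full-extent window
    c(d_t = 9, c_t = 4)
  )
  for (g in grid) {
    n_n <- sample(3:30, 1)
    n_v <- sample(1:3, 1)
    values <- array(rnorm(g["d_t"] * n_n * n_v), dim = c(g["d_t"], n_n, n_v))
    chunk <- c(g["c_t"], n_n, n_v)
    p1 <- tmp_h5(); p2 <- tmp_h5()
    w_plain <- write_all(p1, values, chunk = chunk, cache = FALSE)
    w_cache <- write_all(p2, values, chunk = chunk, cache = TRUE)

    # flush accounting: one storage write per step vs one per window
    expect_equal(w_plain$storage_writes, unname(g["d_t"]))
    expect_equal(w_cache$storage_writes, unname(ceiling(g["d_t"] / g["c_t"])))

    r1 <- h5_reader(p1); r2 <- h5_reader(p2)
    for (t in seq_len(unname(g["d_t"]))) {
      s1 <- read_timestep_slab(r1, t)
      expect_identical(s1, read_timestep_slab(r2, t))
      expect_equal(s1, matrix(values[t, , ], nrow = n_n, ncol = n_v))
    }
    close(r1); close(r2)
    unlink(c(p1, p2))
  }
})

test_that("closing flushes a partial window exactly once", {
  path <- tmp_h5()
  spec <- sim_output_spec(5, 8, 2)
  w <- h5_writer(path, spec, chunk = c(3, 8, 2), cache = TRUE)
  vals <- array(seq_len(5 * 8 * 2), dim = c(5, 8, 2))
  for (t in 1:3) write_timestep(w, t, vals[t, , ])
  expect_equal(w$storage_writes, 1) # window [1,3] flushed at step 3
  for (t in 4:5) write_timestep(w, t, vals[t, , ])
  expect_equal(w$storage_writes, 1) # remainder still buffered
  close(w)
  expect_equal(w$storage_writes, 2) # close flushed the 2-step remainder
  close(w)
  expect_equal(w$storage_writes, 2) # idempotent

  r <- h5_reader(path)
  for (t in 1:5) {
    expect_equal(read_timestep_slab(r, t), matrix(vals[t, , ], 8, 2))
  }
  close(r)
  unlink(path)
})

test_that("node series reads recover written columns", {
  set.seed(17)
  values <- array(rnorm(10 * 40 * 2), dim = c(10, 40, 2))
  path <- tmp_h5()
  write_all(path, values, chunk = c(4, 7, 2))
  r <- h5_reader(path)
  for (n in c(1, 13, 40)) {
    for (v in 1:2) {
      expect_equal(read_node_series(r, n, v), values[, n, v])
    }
  }
  expect_equal(r$read_calls, 6)
  expect_error(read_node_series(r, 41, 1), "out of range")
  expect_error(read_timestep_slab(r, 11), "out of range")
  close(r)
  unlink(path)
})

test_that("alignment pads the file without changing any value", {
  p <- synth_params(n_nodes = 30, n_timesteps = 8, seed = 4)
  f1 <- tmp_h5(); f2 <- tmp_h5()
  out1 <- generate_to_h5(p, f1, chunk = c(3, 10, 2))
  out2 <- generate_to_h5(p, f2, chunk = c(3, 10, 2), alignment = 65536)
  expect_gte(file.size(f2), file.size(f1))
  r1 <- h5_reader(f1); r2 <- h5_reader(f2)
  for (t in seq_len(8)) {
    expect_identical(read_timestep_slab(r1, t), read_timestep_slab(r2, t))
  }
  close(r1); close(r2)
  unlink(c(f1, f2))
})

test_that("partitioned writers fill disjoint node ranges", {
  spec <- sim_output_spec(4, 10, 2)
  values <- array(seq_len(4 * 10 * 2), dim = c(4, 10, 2))
  path <- tmp_h5()
  # two writers sharing one file is not the model here; write ranges in turn
  w <- h5_writer(path, spec, chunk = c(2, 5, 2), node_range = c(1, 6))
  for (t in 1:4) write_timestep(w, t, values[t, 1:6, ])
  close(w)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5write(aperm(values[, 7:10, , drop = FALSE], c(3, 2, 1)),
                 fid, "Data", index = list(1:2, 7:10, 1:4))
  rhdf5::H5Fclose(fid)
  r <- h5_reader(path)
  for (t in 1:4) {
    expect_equal(read_timestep_slab(r, t), matrix(values[t, , ], 10, 2))
  }
  close(r)
  unlink(path)
})

test_that("full-scale storage arithmetic is computed, not allocated", {
  db <- dataset_bytes(sim_output_spec(151, 3253316, 2))
  expect_equal(db$bytes_per_timestep, 8 * 3253316 * 2)
  expect_equal(db$per_timestep_label, "52.1 MB")
})
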