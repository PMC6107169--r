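# h5layout

Chunk layout planning and I/O cost modelling for HDF5 time-series
simulation output.

Large simulations — the motivating case is whole-heart electrophysiology,
with two electric potentials recorded at ~3.25 million mesh nodes every
25 µs printing step — write one 3-D HDF5 dataset (time × nodes ×
variables) and then read it back with the opposite access pattern:
post-processing wants one node's full time series at a time. The chunk
shape, fixed at dataset creation, decides whether those reads are cheap or
drag the whole file through the chunk cache. `h5layout` provides:

- **`plan_chunks()`** — a dimension-agnostic chunk planner driven by one
  parameter, the target chunk size in bytes \(T_B\). For the largest
  feasible per-dimension target \(T\) it returns
  \(C_i = \lceil D_i / \lceil D_i / T\rceil \rceil\), the minimal cover of
  each dimension for its chunk count, subject to
  \(e\prod_i C_i \le T_B\) or the chunk spanning the dataset. Companion
  tools: `default_chunk()` (conventional time-slab chunks under a write
  cap), `chunk_grid()` (edge-waste accounting).
- **A disk layout model** — `linear_layout()`, `element_offset()`,
  `element_ordinal()`, `segments_for_selection()`, `process_slab()`,
  `chunks_touched_by_process()`: byte offsets, contiguous-segment/seek
  counts and chunk-touch counts for hyperslab accesses under any chunking.
- **A striping model** — `striping_config()`, `stripes_of_file()`,
  `ost_for_offset()`, `recommended_stripe_count()`,
  `osts_touched_by_range()`, `chunk_ost_fanout()`: Lustre-style
  round-robin stripe placement over object storage targets and the effect
  of aligning chunks to stripe boundaries.
- **A real HDF5 writer with cached writes** — `h5_writer()` buffers a
  window of \(C_t \times N_n \times N_v\) values and flushes it as one
  storage operation, cutting write calls from \(D_t\) to
  \(\lceil D_t / C_t\rceil\); `h5_reader()`, `read_node_series()`,
  `read_timestep_slab()` cover both access patterns.
- **Synthetic cardiac-like output and a benchmark driver** —
  `generate_cardiac_output()` (planar activation wave with known
  activation times and peaks), `postprocess_maps()`,
  `convert_timesteps()`, `run_benchmark()` comparing the three layout
  strategies with deterministic cost metrics.

## Worked example

Plan chunks for the benchmark-scale dataset (151 time slices, 3,253,316
nodes, 2 variables of 8-byte floats) with a 1 MiB target:

```r
library(h5layout)

bench <- dataset_shape(c(151, 3253316, 2))
(ch <- plan_chunks(bench, target_bytes = 2^20))
#> <chunk_shape> dims {151, 434, 2}, 1048544 B
chunk_grid(bench, ch)
#> <chunk_grid> counts {1, 7497, 1}, 7497 chunks, waste 0.01174%
default_chunk(bench)$dims
#> [1]      41 3253316       2
dataset_bytes(sim_output_spec(100, 3253316))[, 3:4]
#> # A tibble: 1 × 2
#>   per_timestep_label total_label
#>   <chr>              <chr>
#> 1 52.1 MB            5.21 GB
```

The planned chunk spans the full time extent at 434 nodes per chunk and
sits 32 B under the 1 MiB target, so reading one node's series touches a
single ~1 MB chunk instead of the three ~2 GB time-slab chunks of the
default layout. The expected 100-step file (5.21 GB) calls for 2–6
stripes under the one-stripe-per-1–4-GB rule:

```r
recommended_stripe_count(dataset_bytes(sim_output_spec(100, 3253316))$total_bytes)
#> # A tibble: 1 × 2
#>     low  high
#>   <dbl> <dbl>
#> 1     2     6
```

End to end at desk scale — generate synthetic output, write it cached,
and recover the activation map:

```r
p <- synth_params(n_nodes = 2000, n_timesteps = 151, seed = 1)
out <- generate_to_h5(p, "sim.h5", target_chunk_bytes = 131072, cache = TRUE)
out$writer$storage_writes   # flushes: ceil(151 / C_t), not 151
r <- h5_reader("sim.h5")
maps <- postprocess_maps(r)   # tibble: node, activation_time_s, peak_vm
close(r)
```

A thin command-line front end covering the same operations ships in
`inst/cli/h5layout` (subcommands `plan`, `cost`, `stripes`, `generate`,
`bench`).

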