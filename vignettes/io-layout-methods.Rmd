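---
title: "Chunk layout planning and I/O cost modelling for time-series simulation output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunk layout planning and I/O cost modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h5layout)
```

## The problem

Large simulations — the motivating case is whole-heart electrophysiology,
where two electric potentials are recorded at every node of a ~3.25-million
node mesh at every printing time step — write their output as one
multidimensional HDF5 dataset, conventionally time × nodes × variables.
Storage hardware is one-dimensional, so the dataset must be serialized, and
the serialization order decides which accesses are cheap. Two antagonistic
access patterns coexist: the solver writes one time slab (all nodes, one
step) at a time, while post-processing — activation-time maps, peak-voltage
maps — reads one node's full time series at a time. A layout tuned to one
pattern is pathological for the other.

HDF5's answer is *chunking*: the dataset is tiled into repeating blocks,
each stored contiguously. The chunk shape is fixed at dataset creation, so
it must be chosen once, before the access patterns run. This package
implements and models a complete layout strategy:

1. a dimension-agnostic **chunk-shape planner** driven by a single
   parameter, the target chunk size in bytes;
2. an analytic **disk layout model** (offsets, contiguous segments,
   chunks touched) explaining *why* shapes behave as they do;
3. a **striping model** for Lustre-style parallel filesystems (round-robin
   stripe placement over object storage targets, stripe-count heuristics,
   chunk-to-stripe alignment);
4. a real **HDF5 writer with a cached write mode** that aggregates
   per-timestep writes into chunk-sized flushes;
5. a **synthetic generator** of cardiac-like output with known ground
   truth, and a **benchmark driver** comparing the strategies with
   deterministic cost metrics.

## The planner

Let \(\vec D = (D_1,\dots,D_N)\) be the dataset extents and \(T_B\) the
byte target. For a candidate per-dimension extent \(T\) (in elements), the
minimum number of \(T\)-sized chunks spanning dimension \(i\) is
\(x_i = \lceil D_i/T \rceil\), and the smallest extent that still covers
the dimension with \(x_i\) chunks is \(C_i = \lceil D_i/x_i \rceil\). The
planner returns the chunk for the largest \(T\) such that the chunk either
spans the dataset or satisfies \(e \prod_i C_i \le T_B\) (element size
\(e\)). The double rounded division is the heart of the method: HDF5
allocates the minimum whole number of chunks containing the dataset, so an
arbitrary chunk shape can waste large fractions of the file at the edges,
while \(C_i = \lceil D_i / \lceil D_i/T \rceil \rceil\) is, for its chunk
count, the minimal cover — per dimension, \(x_i C_i \ge D_i\) and
\(x_i (C_i - 1) < D_i\).

```{r}
bench <- dataset_shape(c(151, 3253316, 2))   # time x nodes x variables
plan_chunks(bench, target_bytes = 2^20)
chunk_grid(bench, plan_chunks(bench, target_bytes = 2^20))
```

The reference search is the incremental loop (increase \(T\), step back
once on overshoot — valid because the byte size is non-decreasing in
\(T\)); `method = "binary"` bisects the same monotone stopping predicate
and is property-tested equal everywhere. Two planner conventions are
deliberate generalisations: the element size is a parameter (default 8 B,
double precision) rather than a constant, and a byte target smaller than
one element is rejected as unsatisfiable rather than silently clamped.

Defaults: `target_bytes = 131072` (128 kiB), a good small-problem setting;
around 1 MiB is recommended for large problems, where it matches common
filesystem stripe sizes. For comparison, `default_chunk()` builds the
conventional time-slab chunk \(\{C_t, D_2, \dots, D_N\}\) whose extent is
capped by the maximum single write of the MPI-IO layer
(default \(2^{31}\) B, the ROMIO signed-32-bit limit; on the benchmark
dims this gives \(C_t = 41\)).

One bookkeeping note: the benchmark recordings comprise 150 printed steps
but a time extent of 151 — the initial state occupies the first slice. The
planner is generic in \(D_1\); the worked examples use 151 as published.

## The disk layout model

`linear_layout()` serializes chunks in row-major order over the chunk
grid, packed sequentially (optionally padded so each chunk starts on an
`alignment`-byte boundary), and elements row-major within each chunk. Real
HDF5 places chunks at irregular offsets chosen by a B-tree in write order;
the fixed packed order is a modelling assumption that makes costs
deterministic, and B-tree metadata reads are ignored. Indices are 0-based
half-open internally; `element_ordinal()` mirrors 1-based matrix notation
(entry (4,3) of a 10×10 dataset is the 33rd element on disk).

`segments_for_selection()` enumerates a hyperslab's byte offsets and
counts maximal contiguous runs — each extra segment is a disk seek. A row
of an unchunked 10×10 dataset is one run; a column is five runs of one
element each, and becomes a single run under column-shaped chunks:

```{r}
flat <- linear_layout(dataset_shape(c(10, 10)))
segments_for_selection(flat, hyperslab(c(3, 2), c(5, 1)))
cols <- linear_layout(dataset_shape(c(10, 10)), chunk_shape(c(10, 1)))
segments_for_selection(cols, hyperslab(c(3, 2), c(5, 1)))
```

(The published description of the companion *row* example contains an
off-by-one — a five-element row labelled with four ordinals; the
self-consistent column ordinals 33, 43, 53, 63, 73 are the ones frozen
into the tests.)

`process_slab()` models the parallel partition: nodes are split into
contiguous blocks, one per process, each spanning all times and variables
— slabs *orthogonal* to default-style chunks, which is why with time-slab
chunks every process crosses every chunk. Remainders go to the lowest
ranks (an equal partition is assumed at full scale; some deterministic
rule is needed at desk scale, and ceil-first is stated and tested).

Two read-cost granularities matter and the package keeps both explicit.
Element granularity (segments, above) captures seek counts for direct
access. But the HDF5 default (POSIX) read driver used by post-processing
caches *whole chunks*: touching a chunk reads all of it. At chunk
granularity the per-node read cost is `chunks_touched × chunk_bytes`,
which is what separates the layouts — under default-style chunks a single
node's series drags in the entire file, under planned ~1 MiB chunks only
one small chunk column. At element granularity the two layouts tie (a
node's series is always \(D_t\) runs of \(D_v\) values), so the benchmark
reports chunk-granular reads for the post-processing and conversion
stages.

## The striping model

Parallel filesystems split a file into stripes of size \(S\) placed
round-robin over \(c\) of the available object storage targets (OSTs),
starting from a first OST the filesystem picks at random (explicit or
seeded here — never hidden). `stripes_of_file()` enumerates the
placement; `recommended_stripe_count()` encodes the one-stripe-per-1–4-GB
rule of thumb (decimal GB, rounded up — for the 5.21 GB benchmark file,
between 2 and 6 stripes).

Stripe sizes must be multiples of 64 kiB (a page-size compatibility rule),
which forces binary stripe units: "1 MB" stripes are \(2^{20}\) B here.
Dataset sizes in *reports* use decimal units (52.1 MB per step), matching
the storage-arithmetic convention; both conventions are unit-labelled.

Alignment connects the two models: a chunk slightly under one stripe that
starts mid-stripe usually spans two stripes, hence two OSTs per chunk
read. Creating the layout with `alignment = stripe_size` pads every chunk
start to a stripe boundary and caps the fan-out at one OST per chunk
(`chunk_ost_fanout()` tabulates this), at the price of padding — wasted
space that makes alignment a trade-off, not a default.

## Cached writes

Simulation output arrives one printing step at a time. Parallel
filesystems sustain high bandwidth on few large writes and poor
performance on many small ones, so the writer offers a cached mode: a
reserved buffer of \(C_t \times N_n \times N_v\) values (chunk time
extent, owned nodes, variables) absorbs per-step writes, and when
\(C_t\) steps have accumulated the whole window is flushed as one storage
operation. The mode is fixed at construction — a switchable cache would
need flush-on-switch logic for no benefit. A time extent that is not a
multiple of \(C_t\) leaves a partial window; `close()` flushes it, so
cached and uncached files are value-identical for every extent (a
property-tested contract). Flush counts drop from \(D_t\) to
\(\lceil D_t / C_t \rceil\).

The writer creates real HDF5 files (one `Data` dataset of little-endian
doubles with variable-name, unit and printing-step attributes). File
creation goes through a small C routine because the alignment property
must be set on the file-access list at creation, with chunk storage
allocated early so every chunk lands on its aligned offset; all subsequent
I/O is ordinary HDF5 hyperslab access. The time extent is fixed at
creation (the benchmark's shape is known ahead); extendable datasets and
true multi-process MPI writes are out of scope — the single-process writer
is the reference implementation and the layout model carries the
multi-process analysis analytically (`nprocs_model`).

## Synthetic data and what it does (not) show

`generate_cardiac_output()` stands in for the PDE solve, which is out of
scope. A planar wave activates nodes in index order at `activation_speed`
nodes per step; each node rests at −85 mV, steps to +40 mV at activation,
and relaxes exponentially (τ = 20 steps) back toward rest; optional
Gaussian noise is added, and the extracellular potential is the scaled
mirror \(\phi_e = -0.1\,V_m\). Defaults follow the benchmark's recording
conditions: 151 time slices, 25 µs printing step, two 8-byte variables;
the wave speed defaults to `ceiling(n_nodes / n_timesteps)` so the wave
crosses the whole mesh within the recording. The waveform's only job is to
give post-processing a well-defined ground truth: with zero noise the
recovered activation time and peak equal the truth exactly, and with 1 mV
of noise ≥ 99% of activation times stay within one printing step (the
−70 mV threshold sits 15 mV above rest, many noise standard deviations
away). None of this emulates real action-potential morphology, mesh
geometry, or spatial correlation of noise — passing tests certify the I/O
machinery and the detectors' contracts, not electrophysiological fidelity.

The activation detector itself (first sample at or above −70 mV, upward
crossing) is a configurable convention: output formats do not define one.

## The benchmark driver

`run_benchmark()` compares the three strategies — default-style chunks,
planned ("new") chunks, planned chunks with the write cache — by actually
writing the same synthetic dataset three times, recomputing the
activation/peak maps (per-node reads) and per-step slab conversion
records, and reporting deterministic metrics: instrumented storage write
and read calls plus the layout model's chunk-granular read costs. The
conversion records are a minimal header-plus-doubles format: true
visualization formats need mesh geometry this dataset does not carry, and
only the read pattern matters here. Wall-clock seconds are printed for
interest and never asserted — they are machine properties. The maps are
bitwise identical across strategies (layout cannot change data), the
cached writer's flush count is strictly smaller, and the per-node read
bytes under planned chunks are strictly below default-style — the
directional pattern of the published full-scale comparison.

The test suite exercises the driver at 60 steps × 800 nodes with the
default-style write cap scaled to keep the full-scale proportions (a
2³¹-byte cap at desk scale would let the default chunk span the whole
dataset and collapse the comparison); property batteries run on random
datasets of up to 10⁴ elements. These sizes keep the whole suite under a
minute while covering every contract; nothing about the method depends on
them.

## Known limitations

- The layout model's packed chunk order is an idealisation of HDF5's
  B-tree allocation; segment counts are exact for the model, indicative
  for real files.
- OST bandwidth, contention, lock hold times and aggregator scheduling
  are not modelled — the striping model counts placements and fan-out
  only.
- The HDF5 chunk cache's eviction policy (and its historical
  unavailability under the MPI-IO write driver) is not modelled; the
  package's write cache is its own, driver-independent mechanism.
- Wall-clock performance claims are out of scope by design; every
  asserted quantity is a count, a size or a value equality.
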