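#' Lustre-style striping configuration
#'
#' A striped file is split into fixed-size stripes placed round-robin over
#' `stripe_count` consecutive object storage targets (OSTs), starting from
#' `first_ost` (chosen at random by the real filesystem to load-balance;
#' explicit here, optionally drawn with a seed). The stripe size must be a
#' multiple of 64 kiB, the page-size compatibility constraint parallel
#' filesystems enforce.
#'
#' @param stripe_size bytes per stripe \eqn{S}, a multiple of 65536;
#'   default 1 MiB, the common system default.
#' @param stripe_count number of OSTs \eqn{c} the file spans.
#' @param first_ost 0-based id of the OST holding the first stripe, or
#'   `NULL` to draw one uniformly (uses the current RNG state).
#' @param total_osts OSTs in the filesystem; default 48.
#' @return An object of class `striping_config`.
#' @examples
#' striping_config(stripe_count = 3, first_ost = 6)
#' @export
striping_config <- function(stripe_size = 2^20, stripe_count = 4,
                            first_ost = NULL, total_osts = 48) {
  stripe_size <- check_count(stripe_size, "stripe_size")
  if (stripe_size %% 65536 != 0) {
    stop("`stripe_size` must be a multiple of 65536 (64 kiB)", call. = FALSE)
  }
  total_osts <- check_count(total_osts, "total_osts")
  stripe_count <- check_count(stripe_count, "stripe_count")
  if (stripe_count > total_osts) {
    stop("`stripe_count` cannot exceed `total_osts`", call. = FALSE)
  }
  if (is.null(first_ost)) {
    first_ost <- sample.int(total_osts, 1) - 1
  }
  first_ost <- check_count(first_ost, "first_ost", min = 0)
  if (first_ost >= total_osts) {
    stop("`first_ost` must be below `total_osts`", call. = FALSE)
  }
  structure(
    list(
      stripe_size = stripe_size, stripe_count = stripe_count,
      first_ost = first_ost, total_osts = total_osts
    ),
    class = "striping_config"
  )
}

#' @export
print.striping_config <- function(x, ...) {
  cat(
    "<striping_config> S = ", format(x$stripe_size, scientific = FALSE),
    " B, c = ", x$stripe_count, ", first OST ", x$first_ost,
    " of ", x$total_osts, "\n",
    sep = ""
  )
  invisible(x)
}

#' OST holding a byte offset
#'
#' Stripe \eqn{\lfloor o / S \rfloor} of the file lands on the
#' \eqn{(\lfloor o / S \rfloor \bmod c)}-th target of the cycle that starts
#' at `first_ost` and wraps modulo `total_osts`.
#'
#' @param cfg a [striping_config()].
#' @param offset byte offset(s) into the file, 0-based.
#' @return OST id(s).
#' @examples
#' cfg <- striping_config(stripe_count = 3, first_ost = 6)
#' ost_for_offset(cfg, c(0, 4.25 * 2^20))
#' @export
ost_for_offset <- function(cfg, offset) {
  stopifnot(inherits(cfg, "striping_config"))
  offset <- check_index0(offset, "offset")
  (cfg$first_ost + floor(offset / cfg$stripe_size) %% cfg$stripe_count) %%
    cfg$total_osts
}

#' Enumerate the stripes of a file
#'
#' @param cfg a [striping_config()].
#' @param file_size file size in bytes.
#' @return A tibble with one row per stripe: `stripe` (0-based index),
#'   `ost`, `offset`, `size`. All stripes have size \eqn{S} except possibly
#'   the last; sizes sum to `file_size`.
#' @examples
#' stripes_of_file(striping_config(stripe_count = 3, first_ost = 6), 4.5 * 2^20)
#' @export
stripes_of_file <- function(cfg, file_size) {
  stopifnot(inherits(cfg, "striping_config"))
  file_size <- check_count(file_size, "file_size")
  n <- ceiling(file_size / cfg$stripe_size)
  idx <- seq_len(n) - 1
  offsets <- idx * cfg$stripe_size
  sizes <- rep(cfg$stripe_size, n)
  sizes[n] <- file_size - cfg$stripe_size * (n - 1)
  tibble::tibble(
    stripe = idx,
    ost = ost_for_offset(cfg, offsets),
    offset = offsets,
    size = sizes
  )
}

#' Recommended stripe-count range for a file size
#'
#' The rule of thumb for large shared files is one stripe per 1 GB to one
#' stripe per 4 GB of file size (decimal GB). The bounds are rounded up and
#' floored at one stripe.
#'
#' @param file_size file size in bytes.
#' @return One-row tibble with `low` and `high` stripe counts.
#' @examples
#' recommended_stripe_count(5.21e9) # between 2 and 6
#' @export
recommended_stripe_count <- function(file_size) {
  file_size <- check_count(file_size, "file_size")
  low <- max(1, ceiling(file_size / 4e9))
  high <- max(low, ceiling(file_size / 1e9))
  tibble::tibble(low = low, high = high)
}

#' Distinct OSTs touched by a byte range
#'
#' A read of `length` bytes from `start_offset` overlaps
#' \eqn{\lfloor s/S \rfloor} through \eqn{\lfloor (s + L - 1)/S \rfloor}
#' stripes; the count of distinct OSTs among them measures how many storage
#' servers one access fans out to. A chunk no larger than a stripe touches
#' one OST when chunk starts are aligned to stripe boundaries, and
#' typically two when packed.
#'
#' @param cfg a [striping_config()].
#' @param start_offset 0-based byte offset of the range.
#' @param length range length in bytes, `>= 1`.
#' @return Integer count of distinct OSTs.
#' @export
osts_touched_by_range <- function(cfg, start_offset, length) {
  stopifnot(inherits(cfg, "striping_config"))
  start_offset <- check_index0(start_offset, "start_offset")
  length <- check_count(length, "length")
  stripes <- seq(floor(start_offset / cfg$stripe_size),
                 floor((start_offset + length - 1) / cfg$stripe_size))
  length(unique(ost_for_offset(cfg, stripes * cfg$stripe_size)))
}

#' Per-chunk OST fan-out of a chunked layout on a striped file
#'
#' Tabulates, for every chunk of a [linear_layout()], how many OSTs a
#' whole-chunk read touches under a [striping_config()]. Aligning chunk
#' starts to stripe boundaries (layout `alignment = stripe_size`) caps the
#' fan-out at one OST for chunks no larger than a stripe, at the price of
#' padding between chunks.
#'
#' @param layout a [linear_layout()].
#' @param cfg a [striping_config()].
#' @return Tibble with one row per chunk: `chunk` (0-based row-major
#'   index), `offset`, `osts`.
#' @export
chunk_ost_fanout <- function(layout, cfg) {
  stopifnot(inherits(layout, "linear_layout"), inherits(cfg, "striping_config"))
  n <- prod(layout$counts)
  if (n > 1e5) {
    stop("too many chunks to tabulate (", n, ")", call. = FALSE)
  }
  offsets <- layout$base_offset + (seq_len(n) - 1) * layout$chunk_stride
  tibble::tibble(
    chunk = seq_len(n) - 1,
    offset = offsets,
    osts = vapply(
      offsets,
      function(o) osts_touched_by_range(cfg, o, layout$chunk$byte_size),
      numeric(1)
    )
  )
}
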