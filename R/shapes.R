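#' Describe a multidimensional dataset
#'
#' A dataset shape is the vector of extents \eqn{\vec{D} = (D_1, \dots, D_N)}
#' of an N-dimensional array together with the storage size of one element in
#' bytes. For cardiac simulation output the conventional order is time,
#' nodes, variables, i.e. \eqn{(D_t, D_N, D_v)}, but nothing in the planner
#' or the layout model assumes three dimensions.
#'
#' Extents are held as doubles so that products such as
#' \eqn{151 \times 3253316 \times 2} stay exact (they remain far below
#' \eqn{2^{53}}); all values must still be whole numbers.
#'
#' @param dims integer vector of per-dimension extents, all `>= 1`.
#' @param element_size bytes per element, default 8 (double precision).
#' @return An object of class `dataset_shape`.
#' @examples
#' dataset_shape(c(151, 3253316, 2))
#' @export
dataset_shape <- function(dims, element_size = 8) {
  dims <- check_extents(dims, "dims")
  if (length(dims) < 1) {
    stop("`dims` must have at least one dimension", call. = FALSE)
  }
  element_size <- check_count(element_size, "element_size")
  structure(
    list(dims = dims, element_size = element_size),
    class = "dataset_shape"
  )
}

#' Describe a chunk shape
#'
#' A chunk shape is the tile \eqn{\vec{C} = (C_1, \dots, C_N)} into which a
#' chunked dataset is divided, its size in bytes, and whether it spans the
#' whole dataset (a single-chunk layout). Usually produced by [plan_chunks()],
#' [calculate_chunk_dims()] or [default_chunk()] rather than constructed
#' directly.
#'
#' @param dims integer vector of chunk extents, same length as the dataset's.
#' @param element_size bytes per element.
#' @param spans logical: does the chunk equal the dataset in every dimension?
#' @return An object of class `chunk_shape` with fields `dims`, `byte_size`
#'   (`element_size * prod(dims)`), `spans` and `element_size`.
#' @export
chunk_shape <- function(dims, element_size = 8, spans = FALSE) {
  dims <- check_extents(dims, "dims")
  element_size <- check_count(element_size, "element_size")
  structure(
    list(
      dims = dims,
      byte_size = element_size * prod(dims),
      spans = isTRUE(spans),
      element_size = element_size
    ),
    class = "chunk_shape"
  )
}

#' @export
print.dataset_shape <- function(x, ...) {
  cat(
    "<dataset_shape> dims {", paste(format(x$dims, scientific = FALSE, trim = TRUE), collapse = ", "),
    "}, ", x$element_size, " B/element, ",
    format_bytes_decimal(n_elements(x) * x$element_size), " total\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.chunk_shape <- function(x, ...) {
  cat(
    "<chunk_shape> dims {", paste(format(x$dims, scientific = FALSE, trim = TRUE), collapse = ", "),
    "}, ", format(x$byte_size, scientific = FALSE), " B",
    if (x$spans) ", spans dataset", "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn dataset_shape Total number of elements \eqn{\prod D_i}.
#' @param x a `dataset_shape`.
#' @export
n_elements <- function(x) prod(x$dims)

#' Tidy a chunk shape into a one-row tibble
#'
#' @param x a `chunk_shape`.
#' @param ... unused.
#' @export
tidy.chunk_shape <- function(x, ...) {
  tibble::tibble(
    dims = list(x$dims),
    byte_size = x$byte_size,
    spans = x$spans,
    element_size = x$element_size
  )
}

# -- input checking helpers ---------------------------------------------------

check_extents <- function(x, what) {
  x <- as.double(x)
  if (length(x) == 0 || anyNA(x) || any(x < 1) || any(x != floor(x))) {
    stop("`", what, "` must be a vector of positive whole numbers", call. = FALSE)
  }
  x
}

check_count <- function(x, what, min = 1) {
  x <- as.double(x)
  if (length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop("`", what, "` must be a single whole number >= ", min, call. = FALSE)
  }
  x
}

check_index0 <- function(x, what, upper) {
  x <- as.double(x)
  if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop("`", what, "` must be non-negative whole numbers", call. = FALSE)
  }
  if (!missing(upper) && any(x >= upper)) {
    stop("`", what, "` out of range", call. = FALSE)
  }
  x
}
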