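#' Neuron mask collections
#'
#' A `mask_set` holds the binary masks of all neurons in one field of view,
#' either ground truth or detections. Each mask is stored as a two-column
#' integer matrix of 0-based `(row, col)` pixel coordinates; the set carries
#' the canvas shape `(H, W)`. The 0-based convention matches the on-disk
#' regions JSON and is used everywhere in the package.
#'
#' @param masks list of two-column integer matrices, one per neuron, each
#'   row a 0-based `(row, col)` pixel.
#' @param shape integer vector `c(H, W)`, the canvas size in pixels.
#' @return an object of class `mask_set`.
#' @export
mask_set <- function(masks, shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be two positive integers (H, W)")
  masks <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    m <- matrix(as.integer(round(m)), ncol = 2L,
                dimnames = list(NULL, c("row", "col")))
    if (nrow(m) == 0L)
      stop("mask ", i - 1L, " is empty")
    if (any(m < 0L) || any(m[, 1L] >= shape[1L]) || any(m[, 2L] >= shape[2L]))
      stop("mask ", i - 1L, " has out-of-bounds coordinates")
    unique(m)
  })
  structure(list(masks = masks, shape = shape), class = "mask_set")
}

#' @export
length.mask_set <- function(x) length(x$masks)

#' @export
print.mask_set <- function(x, ...) {
  areas <- vapply(x$masks, nrow, integer(1))
  cat(sprintf("mask_set: %d neuron(s) on a %d x %d canvas\n",
              length(x$masks), x$shape[1], x$shape[2]))
  if (length(areas))
    cat(sprintf("  mask area (px): min %d, median %s, max %d\n",
                min(areas), format(stats::median(areas)), max(areas)))
  invisible(x)
}

# flat pixel keys (0-based row-major) for fast set arithmetic
mask_keys <- function(m, shape) m[, 1L] * shape[2L] + m[, 2L]

#' Convert between masks and label rasters
#'
#' `masks_to_raster` renders a `mask_set` as an integer label matrix
#' (0 = background, k = neuron with id k-1; later masks overwrite earlier
#' ones where they overlap). `raster_to_masks` inverts it.
#'
#' @param ms a `mask_set`.
#' @return `masks_to_raster`: an `H x W` integer matrix.
#' @export
masks_to_raster <- function(ms) {
  stopifnot(inherits(ms, "mask_set"))
  r <- matrix(0L, ms$shape[1L], ms$shape[2L])
  for (i in seq_along(ms$masks)) {
    m <- ms$masks[[i]]
    r[cbind(m[, 1L] + 1L, m[, 2L] + 1L)] <- i
  }
  r
}

#' @rdname masks_to_raster
#' @param raster integer label matrix, 0 = background.
#' @export
raster_to_masks <- function(raster) {
  ids <- sort(unique(raster[raster > 0L]))
  masks <- lapply(ids, function(k) {
    idx <- which(raster == k, arr.ind = TRUE)
    cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
  })
  mask_set(masks, dim(raster))
}

# binary raster for a single coordinate mask
mask_to_binary <- function(m, shape) {
  r <- matrix(FALSE, shape[1L], shape[2L])
  r[cbind(m[, 1L] + 1L, m[, 2L] + 1L)] <- TRUE
  r
}

binary_to_mask <- function(b) {
  idx <- which(b, arr.ind = TRUE)
  cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
}

# bounding box (r0, c0, r1, c1), half-open, 0-based
mask_bbox <- function(m) {
  c(min(m[, 1L]), min(m[, 2L]), max(m[, 1L]) + 1L, max(m[, 2L]) + 1L)
}
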