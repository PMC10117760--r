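#' Tile grid for over-sized fields of view
#'
#' Mesoscopic images are far larger than the network input, so they are
#' split into a regular grid of tiles, predicted per tile, and the
#' detections recombined. The grid has `ceil(H / stride) x ceil(W / stride)`
#' tiles with `stride = tile_size - overlap`; border tiles are clipped to
#' the image, so every pixel is covered by at least one tile. The default
#' 100 px tile with no overlap reproduces the published tile count for a
#' 1,792 x 1,682 px mesoscopic field (306 tiles); an overlap of about one
#' neuron diameter (20 px) is recommended in practice so that no neuron is
#' split across every tile that sees it.
#'
#' @param H,W image size in pixels.
#' @param tile_size tile side(s) in px, scalar or `c(h, w)`.
#' @param overlap overlap between neighbouring tiles in px (>= 0,
#'   `< tile_size`).
#' @return an object of class `tile_grid`: list with `tile_size`,
#'   `overlap`, `shape`, and `offsets` — a row-major matrix of 0-based
#'   `(row0, col0)` tile origins — plus `sizes`, the clipped `(h, w)` of
#'   each tile.
#' @export
make_grid <- function(H, W, tile_size = 100L, overlap = 0L) {
  tile_size <- as.integer(rep(tile_size, length.out = 2L))
  overlap <- as.integer(rep(overlap, length.out = 2L))
  stopifnot(H >= 1, W >= 1, all(tile_size >= 1), all(overlap >= 0))
  if (any(overlap >= tile_size))
    stop("overlap must be smaller than tile_size")
  stride <- tile_size - overlap
  nr <- ceiling(H / stride[1L])
  nc <- ceiling(W / stride[2L])
  off <- cbind(row0 = rep((seq_len(nr) - 1L) * stride[1L], each = nc),
               col0 = rep((seq_len(nc) - 1L) * stride[2L], times = nr))
  sizes <- cbind(h = pmin(off[, 1L] + tile_size[1L], H) - off[, 1L],
                 w = pmin(off[, 2L] + tile_size[2L], W) - off[, 2L])
  structure(list(tile_size = tile_size, overlap = overlap,
                 shape = c(as.integer(H), as.integer(W)),
                 offsets = off, sizes = sizes),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d tiles of %d x %d px (overlap %d) on %d x %d\n",
              nrow(x$offsets), x$tile_size[1L], x$tile_size[2L],
              x$overlap[1L], x$shape[1L], x$shape[2L]))
  invisible(x)
}

#' Extract the image patch of one tile
#'
#' @param image full-field `H x W` matrix.
#' @param grid a [make_grid()] result.
#' @param k tile index (1-based, row-major).
#' @return the clipped tile submatrix.
#' @export
tile_image <- function(image, grid, k) {
  o <- grid$offsets[k, ]; s <- grid$sizes[k, ]
  image[(o[1L] + 1L):(o[1L] + s[1L]), (o[2L] + 1L):(o[2L] + s[2L]),
        drop = FALSE]
}

#' Recombine per-tile detections into a full-field mask set
#'
#' Translates each tile's detections into global coordinates and collapses
#' cross-tile duplicates: any two detections with IoU at or above
#' `merge_iou` are merged by pixel union, keeping the higher score.
#' Merging runs to a fixed point, so the operation is idempotent.
#'
#' @param per_tile list (one element per tile, aligned with
#'   `grid$offsets`) of detection lists; each detection is a list with
#'   `mask` (two-column 0-based coordinates, tile-local) and `score`.
#' @param grid the [make_grid()] used to cut the tiles.
#' @param merge_iou IoU threshold for duplicate collapse (default 0.5,
#'   matching the evaluation threshold).
#' @return list with `masks` (a [mask_set()] in global coordinates) and
#'   `scores`.
#' @export
merge_tiles <- function(per_tile, grid, merge_iou = 0.5) {
  stopifnot(length(per_tile) == nrow(grid$offsets))
  dets <- list()
  for (k in seq_along(per_tile)) {
    o <- grid$offsets[k, ]; s <- grid$sizes[k, ]
    for (d in per_tile[[k]]) {
      m <- d$mask
      if (any(m < 0L) || any(m[, 1L] >= s[1L]) || any(m[, 2L] >= s[2L]))
        stop("detection outside tile ", k, " bounds")
      g <- cbind(row = m[, 1L] + o[1L], col = m[, 2L] + o[2L])
      dets[[length(dets) + 1L]] <- list(mask = g, score = d$score)
    }
  }
  repeat {
    changed <- FALSE
    if (length(dets) >= 2L) {
      ord <- order(vapply(dets, `[[`, numeric(1), "score"),
                   decreasing = TRUE)
      dets <- dets[ord]
      kept <- list()
      for (d in dets) {
        merged <- FALSE
        for (i in seq_along(kept)) {
          if (mask_iou(kept[[i]]$mask, d$mask, grid$shape) >= merge_iou) {
            kept[[i]]$mask <- unique(rbind(kept[[i]]$mask, d$mask))
            kept[[i]]$score <- max(kept[[i]]$score, d$score)
            merged <- TRUE; changed <- TRUE; break
          }
        }
        if (!merged) kept[[length(kept) + 1L]] <- d
      }
      dets <- kept
    }
    if (!changed) break
  }
  ms <- mask_set(lapply(dets, `[[`, "mask"), grid$shape)
  list(masks = ms, scores = vapply(dets, `[[`, numeric(1), "score"))
}
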