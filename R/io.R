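#' Read a video stack from a multi-page TIFF
#'
#' Integer TIFFs are scaled to `[0, 1]` by their dtype maximum (so 8-bit
#' and 16-bit encodings of the same scene read identically). If a sidecar
#' `<path>.range.json` written by [write_video()] is present, the affine
#' intensity transform it records is inverted, recovering the original
#' arbitrary-unit fluorescence values. All pages must share one size.
#'
#' @param path TIFF file path.
#' @return `T x H x W` numeric array.
#' @export
read_video <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1L]])
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra channels
    if (!all(dim(p)[1:2] == d1[1:2]))
      stop("page ", i, " has size ", paste(dim(p), collapse = "x"),
           ", expected ", paste(d1[1:2], collapse = "x"))
    pages[[i]] <- p
  }
  video <- array(0, dim = c(length(pages), d1[1L], d1[2L]))
  for (i in seq_along(pages)) video[i, , ] <- pages[[i]]
  side <- paste0(path, ".range.json")
  if (file.exists(side)) {
    rg <- jsonlite::read_json(side, simplifyVector = TRUE)
    video <- video * rg$scale + rg$offset
  }
  if (any(!is.finite(video))) stop("video contains non-finite values")
  video
}

#' Write a video stack to a multi-page TIFF
#'
#' TIFF samples live on a `[0, 1]` grid, so with `bits = 32` the stack is
#' first mapped by the affine transform `(v - offset) / scale` with
#' `offset = floor(min)` and `scale = ceiling(max) - offset`; the
#' transform is recorded in a sidecar `<path>.range.json` that
#' [read_video()] inverts, making the round trip exact to 32-bit
#' quantisation (about 2e-10 of the intensity range). With `bits = 8` or
#' `16` values are clipped to `[0, 1]` and quantised, with no sidecar —
#' the viewer-friendly convention.
#'
#' @param video `T x H x W` numeric array.
#' @param path output file path.
#' @param bits bits per sample: 8, 16 or 32.
#' @export
write_video <- function(video, path, bits = 32L) {
  check_video(video)
  stopifnot(bits %in% c(8L, 16L, 32L))
  if (bits == 32L) {
    offset <- floor(min(video))
    scale <- max(ceiling(max(video)) - offset, 1)
    video <- (video - offset) / scale
    jsonlite::write_json(list(offset = offset, scale = scale),
                         paste0(path, ".range.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    video <- pmin(pmax(video, 0), 1)
    side <- paste0(path, ".range.json")
    if (file.exists(side)) unlink(side)
  }
  pages <- lapply(seq_len(dim(video)[1L]), function(t) video[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read and write 2D images (TIFF or PNG by extension)
#'
#' @param image `H x W` matrix with values in `[0, 1]` (clipped on write).
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param bits bits per sample for TIFF output.
#' @export
write_image <- function(image, path, bits = 8L) {
  image <- pmin(pmax(unclass(image), 0), 1)
  attributes(image) <- list(dim = dim(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(image, path)
  else tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read and write neuron regions JSON
#'
#' The on-disk format is the community regions-JSON convention: an array
#' of objects, each with a `"coordinates"` field listing `[row, col]`
#' pixel pairs. Coordinates are 0-based everywhere in this package and on
#' disk (community files vary; this package states its convention rather
#' than guessing). `write_regions` wraps the array in an object that also
#' records the canvas `"shape"`; `read_regions` accepts both the wrapped
#' object and a bare array (then `shape` must be given or is inferred
#' from the largest coordinate).
#'
#' @param ms a [mask_set()].
#' @param path JSON file path.
#' @export
write_regions <- function(ms, path) {
  stopifnot(inherits(ms, "mask_set"))
  regions <- lapply(ms$masks, function(m)
    list(coordinates = unname(cbind(m[, 1L], m[, 2L]))))
  jsonlite::write_json(list(shape = ms$shape, regions = regions), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_regions
#' @param shape optional canvas shape `c(H, W)` when reading a bare array.
#' @export
read_regions <- function(path, shape = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$regions)) {
    if (is.null(shape)) shape <- unlist(x$shape)
    x <- x$regions
  }
  masks <- lapply(seq_along(x), function(i) {
    co <- x[[i]]$coordinates
    if (is.null(co)) stop("region ", i - 1L, " has no coordinates field")
    m <- do.call(rbind, lapply(co, function(p) as.integer(unlist(p)[1:2])))
    colnames(m) <- c("row", "col")
    m
  })
  if (is.null(shape)) {
    all_px <- do.call(rbind, masks)
    shape <- c(max(all_px[, 1L]) + 1L, max(all_px[, 2L]) + 1L)
  }
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (any(m < 0L) || any(m[, 1L] >= shape[1L]) || any(m[, 2L] >= shape[2L]))
      stop("region ", i - 1L, " has out-of-bounds coordinates")
  }
  mask_set(masks, shape)
}

#' Read and write label-raster TIFFs
#'
#' 16-bit single-page TIFF: 0 is background and pixel value `k` marks the
#' neuron with 0-based id `k - 1`.
#'
#' @param ms a [mask_set()].
#' @param path TIFF path.
#' @export
write_label_raster <- function(ms, path) {
  r <- masks_to_raster(ms)
  if (max(r) > 65535L) stop("too many neurons for a 16-bit raster")
  tiff::writeTIFF(r / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  img <- tiff::readTIFF(path)
  raster_to_masks(matrix(as.integer(round(img * 65535)), nrow(img)))
}

#' Read a run configuration YAML
#'
#' Nested blocks (`preprocess`, `fusion`, `model`, `augment`, `synthetic`)
#' are validated by their module constructors before any computation
#' starts; unknown fields in a block raise an error naming the field.
#'
#' @param path YAML file path.
#' @return list with classed sub-configs plus `seed` and `out_dir`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(block, ctor) {
    if (is.null(y[[block]])) return(ctor())
    args <- y[[block]]
    known <- names(formals(ctor))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop("unknown field(s) in '", block, "': ", paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  list(preprocess = build("preprocess", correlation_config),
       fusion = build("fusion", fusion_config),
       model = build("model", model_config),
       augment = build("augment", augment_config),
       synthetic = build("synthetic", synthetic_config),
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
       out_dir = if (is.null(y$out_dir)) "." else y$out_dir)
}
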