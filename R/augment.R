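#' Training-time augmentation configuration
#'
#' The augmentation menu contains five operations: horizontal flip,
#' vertical flip, rotation (90, 180 or 270 degrees), scaling (factor drawn
#' from `scale_range`) and additive Gaussian noise (s.d. drawn uniformly
#' from `noise_sigma_range`, on the 0-255 intensity scale and applied
#' after rescaling to the image's own range). For each call a count
#' `k ~ Uniform{0..max_ops}` is drawn and `k` distinct operations are
#' sampled without replacement, then applied in a fixed canonical order
#' (flips, rotation, scaling, noise) so runs are reproducible.
#'
#' @param rotations allowed rotation angles in degrees.
#' @param scale_range scaling factor range.
#' @param noise_sigma_range Gaussian noise s.d. range on the 0-255 scale.
#' @param max_ops maximum number of operations per call, in `0..5`.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(rotations = c(90, 180, 270),
                           scale_range = c(0.8, 1.5),
                           noise_sigma_range = c(0, 5),
                           max_ops = 5L) {
  max_ops <- as.integer(max_ops)
  stopifnot(max_ops >= 0L, max_ops <= 5L,
            all(rotations %in% c(90, 180, 270)),
            scale_range[1L] <= scale_range[2L],
            noise_sigma_range[1L] >= 0)
  structure(list(rotations = rotations, scale_range = scale_range,
                 noise_sigma_range = noise_sigma_range, max_ops = max_ops),
            class = "augment_config")
}

# rotate a matrix by 90/180/270 degrees (counter-clockwise)
rot_mat <- function(m, angle) {
  switch(as.character(angle),
         "90" = t(m)[ncol(m):1, , drop = FALSE],
         "180" = m[nrow(m):1, ncol(m):1, drop = FALSE],
         "270" = t(m)[, nrow(m):1, drop = FALSE],
         stop("unsupported angle ", angle))
}

# resize to factor s, then center-crop / zero-pad back to the original canvas
scale_to_canvas <- function(m, s, nearest = FALSE) {
  H <- nrow(m); W <- ncol(m)
  h2 <- max(1L, round(H * s)); w2 <- max(1L, round(W * s))
  f <- if (nearest) "none" else "bilinear"
  r <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h2, h = w2,
                                          filter = f))
  out <- matrix(0, H, W)
  if (h2 >= H) {
    o <- (h2 - H) %/% 2L; rows_src <- (o + 1L):(o + H); rows_dst <- 1:H
  } else {
    o <- (H - h2) %/% 2L; rows_src <- 1:h2; rows_dst <- (o + 1L):(o + h2)
  }
  if (w2 >= W) {
    o <- (w2 - W) %/% 2L; cols_src <- (o + 1L):(o + W); cols_dst <- 1:W
  } else {
    o <- (W - w2) %/% 2L; cols_src <- 1:w2; cols_dst <- (o + 1L):(o + w2)
  }
  out[rows_dst, cols_dst] <- r[rows_src, cols_src]
  out
}

#' Augment an image and its masks consistently
#'
#' Geometric operations transform the image and every mask identically;
#' noise is applied to the image only. A mask emptied by scaling (pushed
#' off the canvas by the centre crop) is dropped with a message.
#'
#' @param image `H x W` numeric matrix.
#' @param masks a [mask_set()] with the same canvas.
#' @param cfg an [augment_config()].
#' @param ops optional character vector forcing exactly these operations
#'   (subset of `c("hflip", "vflip", "rotate", "scale", "noise")`),
#'   bypassing the random draw. Random parameters (angle, factor, sigma)
#'   are still drawn unless given via `params`.
#' @param params optional list overriding operation parameters:
#'   `angle`, `scale`, `noise_sigma`.
#' @return list with `image`, `masks` and `ops` (the applied operations
#'   with their parameters).
#' @export
augment_pair <- function(image, masks, cfg = augment_config(),
                         ops = NULL, params = list()) {
  stopifnot(inherits(masks, "mask_set"),
            all(dim(image) == masks$shape))
  menu <- c("hflip", "vflip", "rotate", "scale", "noise")
  if (is.null(ops)) {
    k <- sample.int(cfg$max_ops + 1L, 1L) - 1L
    ops <- if (k > 0L) sample(menu, k) else character()
  } else stopifnot(all(ops %in% menu))
  ops <- menu[menu %in% ops]  # canonical order
  rasters <- lapply(masks$masks, mask_to_binary, shape = masks$shape)
  applied <- list()
  for (op in ops) {
    if (op == "hflip") {
      image <- image[, ncol(image):1, drop = FALSE]
      rasters <- lapply(rasters, function(r) r[, ncol(r):1, drop = FALSE])
      applied$hflip <- TRUE
    } else if (op == "vflip") {
      image <- image[nrow(image):1, , drop = FALSE]
      rasters <- lapply(rasters, function(r) r[nrow(r):1, , drop = FALSE])
      applied$vflip <- TRUE
    } else if (op == "rotate") {
      ang <- params$angle
      if (is.null(ang)) ang <- sample(cfg$rotations, 1L)
      image <- rot_mat(image, ang)
      rasters <- lapply(rasters, rot_mat, angle = ang)
      applied$rotate <- ang
    } else if (op == "scale") {
      s <- params$scale
      if (is.null(s)) s <- stats::runif(1L, cfg$scale_range[1L],
                                        cfg$scale_range[2L])
      image <- scale_to_canvas(image, s, nearest = FALSE)
      rasters <- lapply(rasters, function(r)
        scale_to_canvas(r * 1, s, nearest = TRUE) > 0.5)
      applied$scale <- s
    } else if (op == "noise") {
      sg <- params$noise_sigma
      if (is.null(sg)) sg <- stats::runif(1L, cfg$noise_sigma_range[1L],
                                          cfg$noise_sigma_range[2L])
      rng <- diff(range(image))
      # sigma is specified on the 0-255 scale; rescale to this image
      eff <- sg / 255 * if (rng > 0) rng else 1
      image <- image + matrix(stats::rnorm(length(image), 0, eff),
                              nrow(image))
      applied$noise <- sg
    }
  }
  keep <- vapply(rasters, any, logical(1))
  if (!all(keep))
    message(sum(!keep), " mask(s) emptied by augmentation; dropped")
  out_masks <- mask_set(lapply(rasters[keep], binary_to_mask),
                        dim(image))
  list(image = image, masks = out_masks, ops = applied)
}
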