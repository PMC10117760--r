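#' Configuration for the local correlation map
#'
#' The correlation map scores, at every pixel, how coherently the
#' neighbourhood's temporal traces co-fluctuate:
#' \deqn{c_w = \frac{\lVert \sum_i a_i f_i \rVert_2}{\sum_i a_i \lVert f_i \rVert_2}}
#' where `f_i` are the traces of the pixels in a square neighbourhood and
#' `a_i` is a Gaussian weight centred on the pixel. By the triangle
#' inequality `c_w` lies in `[0, 1]`, and it approaches 1 where neighbouring
#' traces are proportional with the same sign — i.e. over an active neuron.
#'
#' @param neighborhood_radius neighbourhood half-width in pixels (>= 1);
#'   the support is `(2r+1) x (2r+1)`, centre included.
#' @param gaussian_sigma kernel standard deviation in pixels (> 0).
#'   `Inf` gives uniform weights.
#' @param center_traces subtract each pixel's temporal mean before the
#'   correlation. Without centring a shared fluorescence baseline drives
#'   `c_w` toward 1 everywhere and active neurons do not stand out; on by
#'   default.
#' @return an object of class `correlation_config`.
#' @export
correlation_config <- function(neighborhood_radius = 3L,
                               gaussian_sigma = 1.5,
                               center_traces = TRUE) {
  neighborhood_radius <- as.integer(neighborhood_radius)
  stopifnot(neighborhood_radius >= 1L, gaussian_sigma > 0,
            is.logical(center_traces))
  structure(list(neighborhood_radius = neighborhood_radius,
                 gaussian_sigma = gaussian_sigma,
                 center_traces = center_traces),
            class = "correlation_config")
}

#' Configuration for average/correlation image fusion
#'
#' @param alpha weight of the (min-max normalised) average image in the
#'   convex combination, in `[0, 1]`; the correlation map gets `1 - alpha`.
#' @return an object of class `fusion_config`.
#' @export
fusion_config <- function(alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha), class = "fusion_config")
}

check_video <- function(video) {
  if (!is.array(video) || length(dim(video)) != 3L)
    stop("video must be a T x H x W array")
  if (dim(video)[1L] < 1L) stop("video has no frames")
  if (any(!is.finite(video))) stop("video contains non-finite values")
  invisible(video)
}

#' Average projection of a video
#'
#' Per-pixel arithmetic mean over frames.
#'
#' @param video `T x H x W` numeric array of fluorescence intensities.
#' @return `H x W` matrix.
#' @export
average_projection <- function(video) {
  check_video(video)
  colMeans(video, dims = 1L)
}

gaussian_kernel_weights <- function(radius, sigma) {
  d <- -radius:radius
  w <- if (is.infinite(sigma)) {
    matrix(1, 2L * radius + 1L, 2L * radius + 1L)
  } else {
    outer(d, d, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  }
  w
}

#' Weighted local correlation map
#'
#' Computes `c_w` (see [correlation_config()]) at every pixel. The
#' neighbourhood is truncated at the image borders; because the same
#' weights appear in numerator and denominator, truncation needs no
#' renormalisation. Pixels whose whole neighbourhood has zero-norm traces
#' (dead pixels) get `c_w = 0`.
#'
#' @param video `T x H x W` numeric array with `T >= 2`.
#' @param cfg a [correlation_config()].
#' @return `H x W` matrix of values in `[0, 1]`; relatively large values
#'   indicate neuron locations.
#' @export
correlation_map <- function(video, cfg = correlation_config()) {
  check_video(video)
  d <- dim(video)
  T_ <- d[1L]; H <- d[2L]; W <- d[3L]
  if (T_ < 2L) stop("correlation map needs at least 2 frames")
  if (cfg$center_traces) {
    mu <- colMeans(video, dims = 1L)
    video <- video - rep(mu, each = T_)
  }
  w <- gaussian_kernel_weights(cfg$neighborhood_radius, cfg$gaussian_sigma)
  r <- cfg$neighborhood_radius
  norm_map <- sqrt(colSums(video^2, dims = 1L))         # H x W, ||f||_2
  S <- array(0, dim = d)                                 # sum_i a_i f_i
  den <- matrix(0, H, W)                                 # sum_i a_i ||f_i||
  for (di in -r:r) {
    r0 <- max(1L, 1L - di); r1 <- min(H, H - di)         # dest rows
    if (r0 > r1) next
    rs <- r0:r1
    for (dj in -r:r) {
      c0 <- max(1L, 1L - dj); c1 <- min(W, W - dj)       # dest cols
      if (c0 > c1) next
      cs <- c0:c1
      wt <- w[di + r + 1L, dj + r + 1L]
      S[, rs, cs] <- S[, rs, cs, drop = FALSE] +
        wt * video[, rs + di, cs + dj, drop = FALSE]
      den[rs, cs] <- den[rs, cs, drop = FALSE] +
        wt * norm_map[rs + di, cs + dj, drop = FALSE]
    }
  }
  num <- sqrt(colSums(S^2, dims = 1L))
  cw <- matrix(0, H, W)
  pos <- den > 0
  cw[pos] <- num[pos] / den[pos]
  pmin(pmax(cw, 0), 1)
}

minmax_norm <- function(img) {
  rng <- range(img)
  if (rng[2L] == rng[1L]) {
    warning("constant image: min-max normalisation yields all zeros")
    return(array(0, dim(img)))
  }
  (img - rng[1L]) / (rng[2L] - rng[1L])
}

#' Fuse the average projection with the correlation map
#'
#' Each input is min-max normalised to `[0, 1]` independently, then
#' combined as `alpha * avg + (1 - alpha) * corr`. A constant input
#' normalises to all zeros with a warning.
#'
#' @param avg,corr `H x W` matrices of equal size.
#' @param cfg a [fusion_config()].
#' @param provenance optional identifier (source video / segment) carried
#'   on the result.
#' @return an object of class `fused_image`: `H x W` matrix in `[0, 1]`
#'   with attributes `average`, `corrmap` (the normalised components) and
#'   `provenance`.
#' @export
fuse_images <- function(avg, corr, cfg = fusion_config(), provenance = NULL) {
  if (!all(dim(avg) == dim(corr)))
    stop("average image and correlation map differ in size")
  a <- minmax_norm(avg)
  b <- minmax_norm(corr)
  out <- cfg$alpha * a + (1 - cfg$alpha) * b
  structure(out, class = c("fused_image", class(out)),
            average = a, corrmap = b, provenance = provenance)
}

#' @export
print.fused_image <- function(x, ...) {
  cat(sprintf("fused_image: %d x %d, range [%.3f, %.3f]",
              nrow(x), ncol(x), min(x), max(x)))
  pv <- attr(x, "provenance")
  if (!is.null(pv)) cat(" (", pv, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Split a video into segments and project each to a fused image
#'
#' Implements the video-to-images protocol used for annotated benchmark
#' movies: the video is divided into `n_segments` contiguous, equal
#' temporal segments (any remainder frames go to the earliest segments),
#' and each segment plus the whole video is converted to a fused image —
#' `n_segments + 1` images in total. Segments too short for a correlation
#' map (one frame) get an all-zero correlation component.
#'
#' @param video `T x H x W` array with `T >= n_segments`.
#' @param n_segments number of temporal segments (default 6, giving the
#'   usual 7 images per video).
#' @param corr_cfg a [correlation_config()].
#' @param fusion_cfg a [fusion_config()].
#' @param id identifier prefix recorded in each image's provenance.
#' @return list of `n_segments + 1` [fuse_images()] results; the last
#'   element is the whole-video image. Each carries attribute `frames`,
#'   the 1-based frame range used.
#' @export
split_and_project <- function(video, n_segments = 6L,
                              corr_cfg = correlation_config(),
                              fusion_cfg = fusion_config(),
                              id = "video") {
  check_video(video)
  n_segments <- as.integer(n_segments)
  T_ <- dim(video)[1L]
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (T_ < n_segments)
    stop("video has fewer frames (", T_, ") than segments (", n_segments, ")")
  base <- T_ %/% n_segments
  len <- base + as.integer(seq_len(n_segments) <= T_ %% n_segments)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  project <- function(frames, tag) {
    seg <- video[frames, , , drop = FALSE]
    avg <- average_projection(seg)
    corr <- if (length(frames) >= 2L) correlation_map(seg, corr_cfg)
            else matrix(0, dim(video)[2L], dim(video)[3L])
    out <- fuse_images(avg, corr, fusion_cfg,
                       provenance = paste0(id, ":", tag))
    attr(out, "frames") <- range(frames)
    out
  }
  imgs <- lapply(seq_len(n_segments), function(s)
    project(starts[s]:ends[s], paste0("segment", s)))
  imgs[[n_segments + 1L]] <- project(seq_len(T_), "whole")
  imgs
}
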