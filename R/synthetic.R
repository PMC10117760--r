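#' Configuration of the synthetic two-photon movie generator
#'
#' The generator emulates the structure of motion-corrected two-photon
#' Ca2+ movies that the segmentation method exploits: donut-shaped somata
#' (cytoplasmic indicator makes the ring brighter than the nuclear hole),
#' a mixture of active and inactive neurons, at least one sparsely firing
#' neuron whose resting fluorescence sits at the background level (so it is
#' invisible in the average projection but visible in the correlation map),
#' deliberately overlapping neuron pairs, and additive Gaussian noise.
#'
#' Intensities are arbitrary fluorescence units on a roughly `[0, 1]` scale.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param n_frames number of frames `T`.
#' @param n_neurons number of neurons (>= 1).
#' @param radius_range `c(min, max)` outer soma radius in pixels.
#' @param ring_fraction inner-hole radius as a fraction of the outer
#'   radius, in `(0, 1)`.
#' @param active_fraction fraction of neurons given Ca2+ transients.
#' @param transient_rate_hz transient event rate of ordinary active
#'   neurons, events per second.
#' @param sparse_rate_hz event rate of the designated sparsely firing
#'   neuron; its realised event count is clamped to `[1, 2]` so the sparse
#'   phenomenon is present but weak in every realisation.
#' @param decay_tau_frames exponential decay constant of a transient, in
#'   frames.
#' @param noise_sigma s.d. of the additive Gaussian noise.
#' @param overlap_pairs number of neuron pairs placed so that their masks
#'   share pixels (`<= n_neurons / 2`).
#' @param frame_rate_hz acquisition rate used for rate/duration
#'   bookkeeping.
#' @param background constant background fluorescence.
#' @param transient_amp peak amplitude of a single transient.
#' @param baseline_range range of resting fluorescence (above background)
#'   for neurons other than the sparse one.
#' @param hole_intensity intensity of the nuclear hole relative to the
#'   ring (must be `< 1`).
#' @param seed RNG seed; the same config generates bit-identical movies.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = c(128L, 128L),
                             n_frames = 300L,
                             n_neurons = 12L,
                             radius_range = c(6, 10),
                             ring_fraction = 0.5,
                             active_fraction = 0.5,
                             transient_rate_hz = 0.2,
                             sparse_rate_hz = 0.05,
                             decay_tau_frames = 10,
                             noise_sigma = 0.05,
                             overlap_pairs = 1L,
                             frame_rate_hz = 10,
                             background = 0.2,
                             transient_amp = 0.5,
                             baseline_range = c(0.25, 0.45),
                             hole_intensity = 0.25,
                             seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16L),
            n_frames >= 1L, n_neurons >= 1L,
            radius_range[1L] >= 2, radius_range[2L] >= radius_range[1L],
            2 * radius_range[2L] < min(image_size),
            ring_fraction > 0, ring_fraction < 1,
            active_fraction >= 0, active_fraction <= 1,
            transient_rate_hz > 0, sparse_rate_hz > 0,
            decay_tau_frames > 0, noise_sigma >= 0,
            overlap_pairs >= 0L, overlap_pairs <= n_neurons / 2,
            frame_rate_hz > 0, hole_intensity < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# run expr with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a Ca2+ transient trace
#'
#' Poisson-distributed event times convolved with a causal exponential
#' decay kernel: each event at frame `k` adds
#' `amplitude * exp(-(t - k) / tau)` for `t >= k`.
#'
#' @param n_frames trace length `T` (>= 1).
#' @param rate_hz event rate in events per second.
#' @param tau_frames decay constant in frames.
#' @param frame_rate_hz frames per second (default 10).
#' @param amplitude per-event peak amplitude.
#' @param events optional integer vector of 1-based event frames; when
#'   given, no events are drawn and `rate_hz` is ignored.
#' @param min_events,max_events clamp on the drawn event count.
#' @param seed optional seed for a private RNG stream.
#' @return nonnegative numeric trace of length `n_frames`, with attribute
#'   `events` (the event frames).
#' @export
generate_transients <- function(n_frames, rate_hz, tau_frames,
                                frame_rate_hz = 10, amplitude = 1,
                                events = NULL, min_events = 0L,
                                max_events = Inf, seed = NULL) {
  stopifnot(n_frames >= 1L, tau_frames > 0)
  draw <- function() {
    if (is.null(events)) {
      n_ev <- stats::rpois(1L, rate_hz * n_frames / frame_rate_hz)
      n_ev <- min(max(n_ev, min_events), max_events)
      events <<- if (n_ev > 0) sample.int(n_frames, n_ev, replace = TRUE)
                 else integer()
    }
    trace <- numeric(n_frames)
    for (k in events)
      trace[k:n_frames] <- trace[k:n_frames] +
        amplitude * exp(-(seq.int(k, n_frames) - k) / tau_frames)
    structure(trace, events = sort(as.integer(events)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# separable Gaussian blur, zero boundary, kernel truncated at 3 sigma
gaussian_blur2d <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (d in -r:r) {
    a <- max(1L, 1L - d); b <- min(H, H - d)
    if (a > b) next
    rows <- a:b
    out[rows, ] <- out[rows, ] + k[d + r + 1L] * img[rows + d, ]
  }
  out2 <- matrix(0, H, W)
  for (d in -r:r) {
    a <- max(1L, 1L - d); b <- min(W, W - d)
    if (a > b) next
    cols <- a:b
    out2[, cols] <- out2[, cols] + k[d + r + 1L] * out[, cols + d]
  }
  out2
}

render_soma <- function(center, radius, ring_fraction, hole_intensity,
                        shape, blur_sigma = 1) {
  rr <- matrix(seq_len(shape[1L]) - center[1L], shape[1L], shape[2L])
  cc <- matrix(seq_len(shape[2L]) - center[2L], shape[1L], shape[2L],
               byrow = TRUE)
  d <- sqrt(rr^2 + cc^2)
  hole <- ring_fraction * radius
  raw <- matrix(0, shape[1L], shape[2L])
  raw[d <= radius] <- 1
  raw[d < hole] <- hole_intensity
  profile <- gaussian_blur2d(raw, blur_sigma)
  mask <- binary_to_mask(d <= radius)
  list(profile = profile, mask = mask)
}

#' Generate a ground-truthed synthetic movie
#'
#' Builds `video = background + sum_n profile_n * (baseline_n + trace_n(t))
#' + noise`. Neuron placement uses rejection sampling with a minimum
#' centre distance, except for the designated overlap pairs whose centres
#' are placed close enough that the two disk masks share pixels.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements
#'   \describe{
#'     \item{video}{`T x H x W` array, the noisy movie.}
#'     \item{truth}{object of class `ground_truth`: `masks` (a
#'       [mask_set()]), `active` (logical per neuron), `sparse_id`
#'       (0-based id of the sparsely firing neuron, or `NA`),
#'       `overlap_pairs` (two-column matrix of 0-based ids), `traces`
#'       (`T x n` matrix), `baselines`, `profiles` (list of `H x W`
#'       rendered somata), `background`, `noiseless` (`T x H x W`
#'       noise-free movie), and the `config`.}
#'   }
#' @export
generate_scene <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, generate_scene_impl(cfg))
}

generate_scene_impl <- function(cfg) {
  H <- cfg$image_size[1L]; W <- cfg$image_size[2L]
  n <- cfg$n_neurons
  radii <- stats::runif(n, cfg$radius_range[1L], cfg$radius_range[2L])
  # overlap partners occupy the tail ids: (n-2k+1, n-2k+2), ...
  partner_of <- rep(NA_integer_, n)
  if (cfg$overlap_pairs > 0L) {
    for (p in seq_len(cfg$overlap_pairs)) {
      a <- n - 2L * p + 1L; b <- n - 2L * p + 2L
      partner_of[b] <- a
    }
  }
  centers <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      if (!is.na(partner_of[i])) {
        j <- partner_of[i]
        dist <- floor(0.6 * (radii[i] + radii[j]))
        ang <- stats::runif(1L, 0, 2 * pi)
        cand <- centers[j, ] + dist * c(cos(ang), sin(ang))
      } else {
        cand <- c(stats::runif(1L, radii[i] + 2, H - radii[i] - 1),
                  stats::runif(1L, radii[i] + 2, W - radii[i] - 1))
      }
      if (cand[1L] < radii[i] + 2 || cand[1L] > H - radii[i] - 1 ||
          cand[2L] < radii[i] + 2 || cand[2L] > W - radii[i] - 1) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (isTRUE(partner_of[i] == j)) next  # the designated partner is close by design
        if (sqrt(sum((cand - centers[j, ])^2)) < radii[i] + radii[j] + 3) {
          ok <- FALSE; break
        }
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place ", n, " neurons of radius ",
           cfg$radius_range[2L], " in a ", H, " x ", W,
           " field; reduce n_neurons or radius_range")
  }
  somas <- lapply(seq_len(n), function(i)
    render_soma(centers[i, ], radii[i], cfg$ring_fraction,
                cfg$hole_intensity, c(H, W)))
  masks <- mask_set(lapply(somas, `[[`, "mask"), c(H, W))

  n_active <- round(cfg$active_fraction * n)
  active <- rep(FALSE, n)
  if (n_active > 0) active[sample.int(n, n_active)] <- TRUE
  sparse_id <- if (n_active > 0) which(active)[1L] else NA_integer_

  T_ <- cfg$n_frames
  traces <- matrix(0, T_, n)
  baselines <- numeric(n)
  for (i in seq_len(n)) {
    if (isTRUE(i == sparse_id)) {
      baselines[i] <- 0  # resting fluorescence at background: avg-invisible
      traces[, i] <- generate_transients(T_, cfg$sparse_rate_hz,
                                         cfg$decay_tau_frames,
                                         cfg$frame_rate_hz,
                                         amplitude = cfg$transient_amp,
                                         min_events = 1L, max_events = 2L)
    } else if (active[i]) {
      baselines[i] <- stats::runif(1L, cfg$baseline_range[1L],
                                   cfg$baseline_range[2L])
      traces[, i] <- generate_transients(T_, cfg$transient_rate_hz,
                                         cfg$decay_tau_frames,
                                         cfg$frame_rate_hz,
                                         amplitude = cfg$transient_amp)
    } else {
      baselines[i] <- stats::runif(1L, cfg$baseline_range[1L],
                                   cfg$baseline_range[2L])
    }
  }

  noiseless <- array(cfg$background, dim = c(T_, H, W))
  for (i in seq_len(n)) {
    amp_t <- baselines[i] + traces[, i]            # length T
    noiseless <- noiseless + outer(amp_t, somas[[i]]$profile)
  }
  video <- noiseless
  if (cfg$noise_sigma > 0)
    video <- video + array(stats::rnorm(T_ * H * W, 0, cfg$noise_sigma),
                           dim = c(T_, H, W))

  op <- if (cfg$overlap_pairs > 0L) {
    cbind(a = n - 2L * seq_len(cfg$overlap_pairs) + 1L,
          b = n - 2L * seq_len(cfg$overlap_pairs) + 2L) - 1L
  } else matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b")))

  truth <- structure(list(masks = masks, active = active,
                          sparse_id = if (is.na(sparse_id)) NA_integer_
                                      else sparse_id - 1L,
                          overlap_pairs = op,
                          traces = traces, baselines = baselines,
                          profiles = lapply(somas, `[[`, "profile"),
                          background = cfg$background,
                          noiseless = noiseless, config = cfg),
                     class = "ground_truth")
  list(video = video, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d neurons (%d active), sparse id %s, %d overlap pair(s)\n",
              length(x$masks$masks), sum(x$active),
              ifelse(is.na(x$sparse_id), "none", x$sparse_id),
              nrow(x$overlap_pairs)))
  invisible(x)
}

#' Contrast of the sparsely firing neuron in both projections
#'
#' Quantifies the phenomenon the fused input is designed around: a
#' sparsely firing neuron with background-level resting fluorescence is
#' (nearly) invisible in the average projection but stands out in the
#' correlation map. Background pixels are those farther than
#' `radius + 4 px` from every neuron centre, so blur halos are excluded.
#'
#' @param video `T x H x W` movie from [generate_scene()].
#' @param truth the matching `ground_truth`.
#' @param corr_cfg a [correlation_config()].
#' @return list with `avg_ratio` (mean average-projection intensity on the
#'   sparse mask over the mean background intensity) and `corr_ratio`
#'   (same ratio on the correlation map).
#' @export
scene_contrasts <- function(video, truth, corr_cfg = correlation_config()) {
  if (is.na(truth$sparse_id)) stop("scene has no sparsely firing neuron")
  shape <- truth$masks$shape
  avg <- average_projection(video)
  cw <- correlation_map(video, corr_cfg)
  inmask <- mask_to_binary(truth$masks$masks[[truth$sparse_id + 1L]], shape)
  covered <- matrix(FALSE, shape[1L], shape[2L])
  for (p in truth$profiles) covered <- covered | (p > 1e-3)
  bg <- !covered
  for (m in truth$masks$masks) {
    bb <- mask_bbox(m)
    r0 <- max(1L, bb[1L] - 3L); c0 <- max(1L, bb[2L] - 3L)
    r1 <- min(shape[1L], bb[3L] + 4L); c1 <- min(shape[2L], bb[4L] + 4L)
    bg[r0:r1, c0:c1] <- FALSE
  }
  list(avg_ratio = mean(avg[inmask]) / mean(avg[bg]),
       corr_ratio = mean(cw[inmask]) / mean(cw[bg]))
}
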