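small_cfg <- function(...) {
  synthetic_config(image_size = c(64L, 64L), n_frames = 60L,
                   n_neurons = 6L, radius_range = c(4, 6),
                   overlap_pairs = 1L, ...)
}

test_that("generator conserves counts and is deterministic", {
  cfg <- synthetic_config(image_size = c(96L, 96L), n_frames = 40L,
                          n_neurons = 12L, radius_range = c(4, 6),
                          overlap_pairs = 2L, seed = 5L)
  sc <- generate_scene(cfg)
  expect_length(sc$truth$masks$masks, 12L)
  expect_equal(dim(sc$video), c(40L, 96L, 96L))
  sc2 <- generate_scene(cfg)
  expect_identical(sc$video, sc2$video)
  expect_identical(sc$truth$masks, sc2$truth$masks)
})

test_that("rendered somata are donut-shaped: ring brighter than hole", {
  sc <- generate_scene(small_cfg(seed = 2L))
  cfg <- sc$truth$config
  for (i in seq_along(sc$truth$profiles)) {
    prof <- sc$truth$profiles[[i]]
    m <- sc$truth$masks$masks[[i]]
    bb <- c(min(m[, 1L]), min(m[, 2L]), max(m[, 1L]), max(m[, 2L]))
    ctr <- round(c(mean(m[, 1L]), mean(m[, 2L]))) + 1L
    radius <- (bb[3L] - bb[1L]) / 2
    d <- sqrt(outer((seq_len(64L) - ctr[1L])^2,
                    (seq_len(64L) - ctr[2L])^2, `+`))
    ring <- d >= 0.6 * radius & d <= 0.9 * radius
    hole <- d <= 0.3 * radius
    expect_gt(mean(prof[ring]), mean(prof[hole]))
  }
})

test_that("overlap pairs share pixels and all other pairs are disjoint", {
  sc <- generate_scene(small_cfg(seed = 9L))
  ms <- sc$truth$masks
  op <- sc$truth$overlap_pairs
  expect_equal(nrow(op), 1L)
  shared <- function(i, j)
    sum(caimseg:::mask_keys(ms$masks[[i + 1L]], ms$shape) %in%
        caimseg:::mask_keys(ms$masks[[j + 1L]], ms$shape))
  expect_gte(shared(op[1L, 1L], op[1L, 2L]), 1L)
  n <- length(ms$masks)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (any(op[, 1L] == i - 1L & op[, 2L] == j - 1L)) next
    expect_equal(shared(i - 1L, j - 1L), 0L)
  }
})

test_that("noise-free rendering decomposes into background plus components", {
  sc <- generate_scene(small_cfg(seed = 4L))
  tr <- sc$truth
  recon <- array(tr$background, dim(tr$noiseless))
  for (i in seq_along(tr$profiles))
    recon <- recon + outer(tr$baselines[i] + tr$traces[, i],
                           tr$profiles[[i]])
  expect_equal(recon, tr$noiseless, tolerance = 1e-12)
  # inactive neurons have flat traces; the sparse neuron sits at background
  expect_true(all(tr$traces[, !tr$active] == 0))
  expect_equal(tr$baselines[tr$sparse_id + 1L], 0)
})

test_that("transient traces follow the Poisson-exponential model", {
  expect_equal(generate_transients(50L, rate_hz = 0, tau_frames = 5,
                                   min_events = 0L, seed = 1L),
               numeric(50L), ignore_attr = TRUE)

  tr <- generate_transients(30L, rate_hz = 1, tau_frames = 5,
                            events = 10L)
  expect_equal(tr[10:30], exp(-(0:20) / 5), ignore_attr = TRUE)
  expect_equal(tr[1:9], numeric(9L), ignore_attr = TRUE)

  # Monte-Carlo event count: 0.2 ev/s for 100 s at 10 Hz -> mean 20
  counts <- vapply(1:200, function(s)
    length(attr(generate_transients(1000L, 0.2, 10, frame_rate_hz = 10,
                                    seed = s), "events")), numeric(1))
  se <- sqrt(20 / 200)
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("the sparse neuron is average-invisible but correlation-visible", {
  sc <- generate_scene(synthetic_config(seed = 1L))
  ct <- scene_contrasts(sc$video, sc$truth)
  expect_lt(ct$avg_ratio, 1.2)
  expect_gt(ct$corr_ratio, 1.5)
})
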