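test_that("average projection matches closed forms and the loop oracle", {
  v <- array(5, c(3L, 4L, 6L))
  expect_equal(average_projection(v), matrix(5, 4L, 6L))

  a <- matrix(runif(12), 3L, 4L); b <- matrix(runif(12), 3L, 4L)
  v2 <- array(0, c(2L, 3L, 4L)); v2[1L, , ] <- a; v2[2L, , ] <- b
  expect_equal(average_projection(v2), (a + b) / 2)

  sc <- generate_scene(synthetic_config(image_size = c(32L, 32L),
                                        n_frames = 100L, n_neurons = 2L,
                                        radius_range = c(3, 4),
                                        overlap_pairs = 0L, seed = 0L))
  expect_equal(average_projection(sc$video), oracle_average(sc$video),
               tolerance = 1e-8)

  expect_error(average_projection(array(0, c(0L, 2L, 2L))), "frames")
})

test_that("correlation map reproduces the analytic identity cases", {
  # identical nonzero traces everywhere: weights factor out, c_w = 1
  tr <- sin(seq_len(50)) + 2
  v <- array(rep(tr, 6L * 7L), c(50L, 6L, 7L))
  cw <- correlation_map(v, correlation_config(center_traces = FALSE))
  expect_equal(max(abs(cw - 1)), 0, tolerance = 1e-12)

  # two orthogonal unit-norm traces with equal weights: c_w = sqrt(2)/2
  v2 <- array(0, c(4L, 1L, 2L))
  v2[1L, 1L, 1L] <- 1  # f1 = e1
  v2[2L, 1L, 2L] <- 1  # f2 = e2, orthogonal
  cw2 <- correlation_map(v2, correlation_config(neighborhood_radius = 1L,
                                                gaussian_sigma = Inf,
                                                center_traces = FALSE))
  expect_equal(as.numeric(cw2), rep(sqrt(2) / 2, 2L), tolerance = 1e-12)
})

test_that("correlation map agrees with the per-pixel oracle and separates a neuron", {
  sc <- generate_scene(synthetic_config(image_size = c(24L, 24L),
                                        n_frames = 120L, n_neurons = 1L,
                                        radius_range = c(4, 5),
                                        active_fraction = 1,
                                        overlap_pairs = 0L, seed = 0L))
  cfg <- correlation_config(neighborhood_radius = 2L, gaussian_sigma = 1.5)
  cw <- correlation_map(sc$video, cfg)
  for (px in list(c(1L, 1L), c(12L, 12L), c(24L, 7L), c(5L, 20L)))
    expect_equal(cw[px[1L], px[2L]],
                 oracle_cw(sc$video, px[1L], px[2L], 2L, 1.5, TRUE),
                 tolerance = 1e-10)
  msk <- mask_to_binary_test(sc$truth$masks$masks[[1L]], c(24L, 24L))
  expect_gt(mean(cw[msk]), mean(cw[!msk]))
})

test_that("correlation statistics are frame-order invariant and bounded", {
  set.seed(11)
  v <- array(rnorm(40L * 8L * 8L), c(40L, 8L, 8L))
  perm <- sample(40L)
  expect_equal(average_projection(v), average_projection(v[perm, , ]))
  expect_equal(correlation_map(v), correlation_map(v[perm, , ]))
  for (s in 1:5) {
    set.seed(s)
    vr <- array(rnorm(20L * 6L * 6L), c(20L, 6L, 6L))
    cw <- correlation_map(vr)
    expect_true(all(cw >= 0 & cw <= 1))
  }
  # dead pixels (zero-norm traces) give c_w = 0
  vz <- array(0, c(10L, 4L, 4L))
  expect_equal(correlation_map(vz, correlation_config(center_traces = FALSE)),
               matrix(0, 4L, 4L))
})

test_that("fusion is the documented normalised convex combination", {
  avg <- matrix(c(10, 15, 20, 12), 2L)
  corr <- matrix(c(0, 0.25, 1, 0.5), 2L)
  f <- fuse_images(avg, corr, fusion_config(alpha = 0.5))
  expect_equal(f[2L, 1L], 0.5 * 0.5 + 0.5 * 0.25)  # avg 15, corr 0.25
  expect_true(all(f >= 0 & f <= 1))

  # alpha = 1 returns the normalised average exactly
  f1 <- fuse_images(avg, corr, fusion_config(alpha = 1))
  expect_equal(unclass(f1), (avg - 10) / 10, ignore_attr = TRUE)

  # identical inputs: any alpha returns the normalised input
  f2 <- fuse_images(avg, avg, fusion_config(alpha = 0.3))
  expect_equal(unclass(f2), (avg - 10) / 10, ignore_attr = TRUE)

  expect_warning(fuse_images(matrix(1, 2L, 2L), corr), "constant")

  # monotone in each input when the other is fixed
  avg2 <- avg; avg2[2L, 2L] <- avg[2L, 2L] + 1  # still inside the range
  f3 <- fuse_images(avg2, corr, fusion_config(alpha = 0.5))
  expect_gt(f3[2L, 2L], f[2L, 2L])
})

test_that("segment splitting yields n+1 images partitioning the frames", {
  set.seed(2)
  v <- array(rnorm(100L * 8L * 8L) + 1, c(100L, 8L, 8L))
  imgs <- split_and_project(v, 6L)
  expect_length(imgs, 7L)
  lens <- vapply(imgs[1:6], function(im) {
    fr <- attr(im, "frames"); fr[2L] - fr[1L] + 1L
  }, numeric(1))
  expect_equal(lens, c(17, 17, 17, 17, 16, 16))
  covered <- unlist(lapply(imgs[1:6], function(im) {
    fr <- attr(im, "frames"); fr[1L]:fr[2L]
  }))
  expect_equal(sort(covered), 1:100)

  # whole-video average equals the length-weighted mean of segment averages
  seg_avgs <- lapply(imgs[1:6], function(im) {
    fr <- attr(im, "frames")
    average_projection(v[fr[1L]:fr[2L], , , drop = FALSE])
  })
  wavg <- Reduce(`+`, Map(function(a, l) a * l, seg_avgs, lens)) / 100
  expect_equal(wavg, average_projection(v), tolerance = 1e-12)

  # degenerate one-frame segments: segment average is the frame itself
  v6 <- array(rnorm(6L * 4L * 4L), c(6L, 4L, 4L))
  imgs6 <- suppressWarnings(
    split_and_project(v6, 6L, fusion_cfg = fusion_config(alpha = 1)))
  expect_length(imgs6, 7L)
  expect_equal(unclass(imgs6[[3L]]),
               caimseg:::minmax_norm(v6[3L, , ]), ignore_attr = TRUE)

  expect_error(split_and_project(v6, 7L), "fewer frames")
})
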