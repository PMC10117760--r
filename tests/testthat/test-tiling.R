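test_that("grids cover the image with the documented tile counts", {
  g1 <- make_grid(100L, 100L, 100L, 0L)
  expect_equal(nrow(g1$offsets), 1L)

  # mesoscopic field: 1,682 x 1,792 px with the default 100 px tile
  g2 <- make_grid(1682L, 1792L, 100L, 0L)
  expect_equal(nrow(g2$offsets), 17L * 18L)
  expect_equal(nrow(g2$offsets), 306L)

  # overlapping grid: stride 80 -> ceil(250/80)^2 = 16 tiles, full coverage
  g3 <- make_grid(250L, 250L, 100L, 20L)
  expect_equal(nrow(g3$offsets), 16L)
  covered <- matrix(0L, 250L, 250L)
  for (k in seq_len(nrow(g3$offsets))) {
    o <- g3$offsets[k, ]; s <- g3$sizes[k, ]
    covered[(o[1L] + 1L):(o[1L] + s[1L]),
            (o[2L] + 1L):(o[2L] + s[2L])] <-
      covered[(o[1L] + 1L):(o[1L] + s[1L]),
              (o[2L] + 1L):(o[2L] + s[2L])] + 1L
  }
  expect_true(all(covered >= 1L))

  # zero-overlap grids partition exactly
  g4 <- make_grid(1682L, 1792L, 100L, 0L)
  expect_equal(sum(as.numeric(g4$sizes[, 1L]) * g4$sizes[, 2L]),
               1682 * 1792)

  expect_error(make_grid(100L, 100L, 50L, 50L), "overlap")
})

test_that("tile extraction and merged recombination preserve detections", {
  grid <- make_grid(100L, 100L, 60L, 20L)
  # one detection wholly inside tile 1
  d <- list(mask = as.matrix(expand.grid(row = 10:14, col = 10:14)),
            score = 0.9)
  per_tile <- rep(list(list()), nrow(grid$offsets))
  per_tile[[1L]] <- list(d)
  out <- merge_tiles(per_tile, grid)
  expect_length(out$masks$masks, 1L)
  expect_equal(out$masks$masks[[1L]],
               as.matrix(expand.grid(row = 10:14, col = 10:14)),
               ignore_attr = TRUE)

  # the same physical mask reported by two overlapping tiles collapses
  g <- cbind(row = 45:49, col = 45:49)  # global coords, diagonal strip
  t1_local <- g                          # tile 1 at offset (0, 0)
  k2 <- which(grid$offsets[, 1L] == 40L & grid$offsets[, 2L] == 40L)
  t2_local <- cbind(row = g[, 1L] - 40L, col = g[, 2L] - 40L)
  per_tile <- rep(list(list()), nrow(grid$offsets))
  per_tile[[1L]] <- list(list(mask = t1_local, score = 0.7))
  per_tile[[k2]] <- list(list(mask = t2_local, score = 0.8))
  out2 <- merge_tiles(per_tile, grid)
  expect_length(out2$masks$masks, 1L)
  expect_equal(out2$scores, 0.8)

  # merging an already-merged set changes nothing (idempotence)
  once <- lapply(seq_along(out2$masks$masks), function(i)
    list(mask = out2$masks$masks[[i]], score = out2$scores[i]))
  grid0 <- make_grid(100L, 100L, 100L, 0L)
  twice <- merge_tiles(list(once), grid0)
  expect_equal(twice$masks$masks, out2$masks$masks)

  # out-of-tile coordinates are a data error
  per_bad <- rep(list(list()), nrow(grid$offsets))
  per_bad[[1L]] <- list(list(mask = cbind(row = 70L, col = 5L),
                             score = 0.5))
  expect_error(merge_tiles(per_bad, grid), "outside")
})

test_that("with zero overlap merged count equals the sum of per-tile counts", {
  grid <- make_grid(80L, 80L, 40L, 0L)
  set.seed(15)
  per_tile <- lapply(seq_len(nrow(grid$offsets)), function(k) {
    lapply(seq_len(sample(0:2, 1L)), function(i) {
      r0 <- sample(0:30, 1L); c0 <- sample(0:30, 1L)
      list(mask = as.matrix(expand.grid(row = r0:(r0 + 4L),
                                        col = c0:(c0 + 4L))),
           score = runif(1))
    })
  })
  out <- merge_tiles(per_tile, grid)
  expect_length(out$masks$masks, sum(lengths(per_tile)))
})

test_that("tiled prediction of an overfit model matches single-pass output", {
  fx <- overfit_fixture()
  single <- predict(fx$model, fx$image)
  grid <- make_grid(96L, 96L, 96L, 32L)  # overlapping tiles of one scene
  per_tile <- lapply(seq_len(nrow(grid$offsets)), function(k) {
    det <- predict(fx$model, tile_image(fx$image, grid, k))
    lapply(seq_along(det$masks$masks), function(i)
      list(mask = det$masks$masks[[i]], score = det$scores[i]))
  })
  merged <- merge_tiles(per_tile, grid)
  rep <- evaluate_masks(fx$scene$truth$masks, merged$masks)
  # recombination keeps the recovered neurons without duplicating them
  expect_gte(rep$recall, 0.8)
  expect_gte(rep$precision, 0.8)
})
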