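square_mask <- function(r0, c0, side) {
  as.matrix(expand.grid(row = r0:(r0 + side - 1L),
                        col = c0:(c0 + side - 1L)))
}

test_that("IoU matches closed forms and is a symmetric similarity", {
  a <- square_mask(2L, 2L, 4L)
  expect_equal(mask_iou(a, a), 1)
  b <- square_mask(10L, 10L, 3L)
  expect_equal(mask_iou(a, b), 0)
  inner <- square_mask(3L, 3L, 2L)        # 2x2 inside the 4x4
  expect_equal(mask_iou(a, inner), 4 / 16)
  expect_equal(mask_iou(inner, a), 4 / 16)

  # 1 - IoU behaves like a metric on random triples (triangle inequality)
  ms <- random_mask_set(6L, c(30L, 30L), seed = 8L)$masks
  for (tri in list(c(1, 2, 3), c(2, 4, 6), c(1, 3, 5))) {
    dxy <- 1 - mask_iou(ms[[tri[1L]]], ms[[tri[2L]]], c(30L, 30L))
    dyz <- 1 - mask_iou(ms[[tri[2L]]], ms[[tri[3L]]], c(30L, 30L))
    dxz <- 1 - mask_iou(ms[[tri[1L]]], ms[[tri[3L]]], c(30L, 30L))
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
})

test_that("pair distance applies the IoU-or-containment rule", {
  a <- square_mask(2L, 2L, 4L)
  expect_equal(pair_distance(a, a), 0)
  inner <- square_mask(3L, 3L, 2L)
  # IoU 0.25 < 0.5 but contained -> finite cost 0.75
  expect_equal(pair_distance(a, inner), 0.75)
  # IoU 0.25 without containment -> infinite
  shifted <- square_mask(2L, 2L, 4L); shifted[, 2L] <- shifted[, 2L] + 2L
  iou_val <- mask_iou(a, shifted)
  expect_lt(iou_val, 0.5)
  expect_identical(pair_distance(a, shifted), Inf)
  # IoU >= 0.5 -> 1 - IoU
  big <- square_mask(2L, 2L, 5L)
  expect_equal(pair_distance(big, a), 1 - 16 / 25)
})

test_that("Hungarian matching equals the brute-force permutation oracle", {
  # random finite cost instances up to 6x6, including rectangular ones
  for (s in 1:30) {
    set.seed(s)
    n <- sample(2:6, 1L); m <- n + sample.int(7L - n, 1L) - 1L
    cost <- matrix(runif(n * m), n, m)
    a <- caimseg:::lsap_solve(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 oracle_assignment(cost)$cost, tolerance = 1e-12)
    if (requireNamespace("clue", quietly = TRUE)) {
      cl <- as.integer(clue::solve_LSAP(cost))
      expect_equal(sum(cost[cbind(seq_len(n), a)]),
                   sum(cost[cbind(seq_len(n), cl)]), tolerance = 1e-12)
    }
  }
})

test_that("mask matching finds the permutation and handles empty sets", {
  gt <- random_mask_set(5L, c(40L, 40L), seed = 3L)
  det <- mask_set(gt$masks[c(3L, 1L, 5L, 2L, 4L)], gt$shape)
  mr <- match_masks(gt, det)
  expect_equal(mr$n_tp, 5L)
  expect_equal(mr$pairs$cost, rep(0, 5L))
  expect_equal(mr$pairs$det_id[order(mr$pairs$gt_id)],
               c(1L, 3L, 0L, 4L, 2L))

  empty <- mask_set(list(), gt$shape)
  mr0 <- match_masks(gt, empty)
  expect_equal(mr0$n_tp, 0L)
  expect_equal(mr0$unmatched_gt, 0:4)
})

test_that("matching degrades monotonically as detections are removed", {
  gt <- random_mask_set(5L, c(40L, 40L), seed = 13L)
  set.seed(14)
  det_masks <- lapply(gt$masks, function(m) {
    m2 <- m[sample(nrow(m), max(3L, round(nrow(m) * 0.8))), , drop = FALSE]
    unique(rbind(m2, m2[1, , drop = FALSE] + c(1L, 0L)))
  })
  det <- mask_set(det_masks, gt$shape)
  penalised <- function(d) {
    mr <- match_masks(gt, d)
    sum(mr$pairs$cost) + length(mr$unmatched_gt)  # unmatched GT costs 1
  }
  full <- penalised(det)
  for (drop in seq_along(det$masks))
    expect_gte(penalised(mask_set(det$masks[-drop], det$shape)) + 1e-12,
               full)
})

test_that("metrics reproduce the closed-form rates and conventions", {
  r <- seg_metrics(30L, 32L, 31L)
  expect_equal(round(r$precision, 4), 0.9677)
  expect_equal(round(r$recall, 4), 0.9375)
  expect_equal(round(r$f1, 4), 0.9524)

  perfect <- seg_metrics(7L, 7L, 7L)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  zero <- seg_metrics(0L, 10L, 0L)
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))

  expect_error(seg_metrics(5L, 4L, 10L), "invalid counts")

  # F1 is the harmonic mean: between min and max of P and R
  for (s in 1:20) {
    set.seed(s)
    ngt <- sample(5:40, 1L); ndet <- sample(5:40, 1L)
    ntp <- sample(0:min(ngt, ndet), 1L)
    m <- seg_metrics(ntp, ngt, ndet)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
  }
})

test_that("end-to-end evaluation scores a perturbed detection set sensibly", {
  gt <- random_mask_set(6L, c(50L, 50L), seed = 21L)
  det <- mask_set(c(gt$masks[1:5],
                    list(square_mask(40L, 40L, 3L))), gt$shape)
  rep <- evaluate_masks(gt, det)
  expect_equal(rep$n_tp, 5L)
  expect_equal(rep$precision, 5 / 6)
  expect_equal(rep$recall, 5 / 6)
})
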