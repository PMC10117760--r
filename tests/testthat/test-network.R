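test_that("ECA matches the independent oracle and gates multiplicatively", {
  set.seed(6)
  x <- array(rnorm(5 * 7 * 4), c(5L, 7L, 4L))
  w <- c(0.3, -0.2, 0.5)
  out <- eca(x, w)
  expect_equal(unclass(out), oracle_eca(x, w), ignore_attr = TRUE,
               tolerance = 1e-12)
  gates <- attr(out, "channel_weights")
  expect_true(all(gates > 0 & gates < 1))
  expect_true(all(sign(out) == sign(x) | x == 0))

  # zero input stays zero; constant one-channel input with zero kernel
  # gives logistic(0) = 0.5
  z <- array(0, c(3L, 3L, 2L))
  expect_equal(unclass(eca(z, w)), z, ignore_attr = TRUE)
  one <- array(1, c(4L, 4L, 1L))
  expect_equal(unclass(eca(one, 0)), array(0.5, c(4L, 4L, 1L)),
               ignore_attr = TRUE)

  expect_error(eca(x, c(1, 2)), "odd")
})

test_that("feature fusion follows add/concat channel arithmetic", {
  set.seed(1)
  a <- array(rnorm(4 * 4 * 3), c(4L, 4L, 3L))
  z <- array(0, dim(a))
  expect_equal(fuse_features(a, z, "add"), a)
  b <- array(rnorm(4 * 4 * 5), c(4L, 4L, 5L))
  cc <- fuse_features(a, b, "concat")
  expect_equal(dim(cc), c(4L, 4L, 8L))
  expect_equal(cc[, , 1:3], a)
  expect_equal(cc[, , 4:8], b)
  expect_error(fuse_features(a, b, "add"), "channel")
  expect_error(fuse_features(a, array(0, c(2L, 2L, 3L)), "add"), "mismatch")
  # the flagship configuration fuses with add up and concat down
  cfg <- model_config()
  expect_equal(cfg$fusion_up, "add")
  expect_equal(cfg$fusion_down, "concat")
})

test_that("every ablation arm builds from config alone with predicted sizes", {
  arms <- list(
    full = toy_model_config(),
    no_attention = toy_model_config(attention = "none"),
    no_fpn_plus = toy_model_config(fpn_plus = FALSE),
    no_path_aug = toy_model_config(path_augmentation = FALSE))
  counts <- vapply(arms, function(cfg) n_params(build_model(cfg)),
                   numeric(1))
  expect_length(unique(counts), 4L)

  # path augmentation controls the number of backbone outputs (5 vs 4)
  m5 <- build_model(arms$full)
  m4 <- build_model(arms$no_path_aug)
  expect_length(m5$strides, 5L)
  expect_length(m4$strides, 4L)
  # FPN+ renames the operative pyramid maps Y2..Y6
  expect_equal(m5$levels, paste0("Y", 2:6))
  expect_equal(build_model(arms$no_fpn_plus)$levels, paste0("P", 2:6))

  # ECA adds exactly (number of lateral connections) x kernel weights:
  # 5 FPN laterals + 4 bottom-up laterals, kernel 3
  k <- 3L
  n_lateral <- 5L + 4L
  expect_equal(counts[["full"]] - counts[["no_attention"]], n_lateral * k)

  # a CBAM arm also builds and differs again
  cbam <- n_params(build_model(toy_model_config(attention = "cbam")))
  expect_false(cbam %in% counts)
})

test_that("layer gradients agree with finite differences", {
  set.seed(42)
  params <- list(w1 = array(rnorm(3 * 3 * 2 * 3, 0, 0.5), c(3L, 3L, 2L, 3L)),
                 b1 = rnorm(3, 0, 0.1),
                 eca = rnorm(3, 0, 0.5))
  x <- array(rnorm(6 * 6 * 2), c(6L, 6L, 2L))
  loss_of <- function(p) {
    g <- caimseg:::ag_new(p)
    h <- caimseg:::ag_conv2d(g, caimseg:::ag_const(g, x), "w1", "b1",
                             stride = 2L)
    h <- caimseg:::ag_relu(g, h)
    h <- caimseg:::eca_node(g, h, "eca")
    s <- caimseg:::ag_sigmoid(g, h)
    out <- caimseg:::ag_bce_logits(g, s, array(0.3, dim(s$value)))
    list(value = out$value, graph = g, node = out)
  }
  l <- loss_of(params)
  grads <- caimseg:::ag_backward(l$graph, l$node)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4L, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp)$value - loss_of(pm)$value) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("detector head gradients agree with finite differences", {
  scene <- toy_scene(seed = 11L)
  img <- fused_input(scene)
  model <- build_model(toy_model_config())
  loss_at <- function(m) {
    set.seed(99)  # identical anchor/ROI sampling across evaluations
    model_loss(m, img, scene$truth$masks)$total
  }
  set.seed(99)
  l <- model_loss(model, img, scene$truth$masks)
  grads <- caimseg:::ag_backward(l$graph, l$total_node)
  eps <- 1e-5
  set.seed(123)
  for (nm in c("head.box.fc1.W", "head.mask.conv1.W", "head.box.cls.b")) {
    for (i in sample(length(model$params[[nm]]), 2L)) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("the loss decomposes into its three components and responds to a step", {
  scene <- toy_scene(seed = 11L)
  img <- fused_input(scene)
  model <- build_model(toy_model_config())
  set.seed(5)
  l <- model_loss(model, img, scene$truth$masks)
  expect_true(all(l$components >= 0))
  expect_equal(l$total, sum(l$components), tolerance = 1e-12)

  # one SGD step on a fixed batch decreases the loss
  sch <- train_schedule(list(train_stage("all_layers", 1L, 1e-3, 1L, 1L)),
                        seed = 5L, momentum = 0, weight_decay = 0)
  m2 <- train_model(model, list(list(image = img,
                                     masks = scene$truth$masks)), sch)
  set.seed(5)
  l2 <- model_loss(m2, img, scene$truth$masks)
  expect_lt(l2$total, l$total)
})

test_that("prediction is deterministic and directs oversized images to tiling", {
  model <- build_model(toy_model_config())
  set.seed(3)
  img <- matrix(runif(96 * 96), 96L)
  d1 <- predict(model, img)
  d2 <- predict(model, img)
  expect_identical(d1$scores, d2$scores)
  expect_identical(d1$masks$masks, d2$masks$masks)
  expect_error(predict(model, matrix(0, 200L, 200L)), "make_grid")
})

test_that("an overfit toy detector recovers its scene and rejects blanks", {
  fx <- overfit_fixture()
  det <- predict(fx$model, fx$image)
  rep <- evaluate_masks(fx$scene$truth$masks, det$masks)
  expect_gte(rep$n_tp, 4L)
  mr <- attr(rep, "match")
  expect_true(all(1 - mr$pairs$cost >= 0.5))  # every TP has IoU >= 0.5

  blank <- predict(fx$model, matrix(0, 96L, 96L))
  expect_length(blank$masks$masks, 0L)
})
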