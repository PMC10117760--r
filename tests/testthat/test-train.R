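test_that("published schedules carry the stated stages, rates and step counts", {
  h <- hybrid_schedule()
  expect_length(h$stages, 3L)
  expect_equal(sum(vapply(h$stages, `[[`, integer(1), "epochs")), 200L)
  expect_equal(h$stages[[1L]]$scope, "heads_only")
  expect_equal(vapply(h$stages, `[[`, numeric(1), "learning_rate"),
               c(1e-3, 2e-4, 1e-4))
  expect_equal(vapply(h$stages, `[[`, character(1), "scope"),
               c("heads_only", "all_layers", "all_layers"))
  expect_true(all(vapply(h$stages, `[[`, integer(1),
                         "steps_per_epoch") == 500L))
  expect_true(all(vapply(h$stages, `[[`, integer(1), "batch_size") == 2L))

  n <- neurofinder_schedule()
  expect_length(n$stages, 2L)
  expect_equal(sum(vapply(n$stages, `[[`, integer(1), "epochs")), 150L)
  expect_equal(vapply(n$stages, `[[`, numeric(1), "learning_rate"),
               c(1e-3, 1e-3))
  expect_equal(vapply(n$stages, `[[`, integer(1), "epochs"),
               c(20L, 130L))
  expect_true(all(vapply(n$stages, `[[`, integer(1),
                         "steps_per_epoch") == 50L))
})

test_that("head-only stages freeze everything outside the heads to the bit", {
  scene <- toy_scene(seed = 21L)
  img <- fused_input(scene)
  model <- build_model(toy_model_config())
  before <- model$params
  sch <- train_schedule(list(train_stage("heads_only", 1L, 1e-3, 5L, 1L)),
                        seed = 2L)
  m2 <- train_model(model, list(list(image = img,
                                     masks = scene$truth$masks)), sch)
  head_nm <- grep("^head\\.", names(before), value = TRUE)
  frozen <- setdiff(names(before), head_nm)
  for (nm in frozen) expect_identical(m2$params[[nm]], before[[nm]])
  expect_false(all(vapply(head_nm, function(nm)
    identical(m2$params[[nm]], before[[nm]]), logical(1))))
})

test_that("training descends on an overfittable set and is seed-deterministic", {
  scenes <- list(toy_scene(seed = 31L), toy_scene(seed = 32L))
  data <- lapply(scenes, function(s)
    list(image = fused_input(s), masks = s$truth$masks))
  sch <- train_schedule(list(train_stage("all_layers", 5L, 5e-3, 10L, 1L)),
                        seed = 4L)
  m1 <- train_model(build_model(toy_model_config()), data, sch)
  h <- m1$loss_history
  expect_equal(nrow(h), 5L)  # loss history length = total epochs
  expect_lt(h$total[5L], h$total[1L])

  m2 <- train_model(build_model(toy_model_config()), data, sch)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("cross-validation tests every group once without leakage", {
  make_group <- function(seed) {
    s1 <- toy_scene(seed = seed)
    s2 <- toy_scene(seed = seed + 50L)
    list(train = list(list(image = fused_input(s1),
                           masks = s1$truth$masks)),
         test = list(list(image = fused_input(s2),
                          masks = s2$truth$masks)))
  }
  groups <- lapply(c(61L, 62L), make_group)
  sch <- train_schedule(list(train_stage("all_layers", 1L, 5e-3, 8L, 1L)),
                        seed = 6L)
  reports <- cross_validate(groups, "two_round_hybrid",
                            toy_model_config(), sch)
  expect_length(reports, 2L)
  for (gi in seq_along(reports)) {
    r <- reports[[gi]]
    expect_s3_class(r, "metrics_report")
    expect_true(all(c("n_tp", "n_gt", "n_detected", "precision",
                      "recall", "f1") %in% names(r)))
    # the tested items never appear in their model's training set
    expect_length(intersect(attr(r, "train_ids"), attr(r, "test_ids")), 0L)
    # two_round: the model that tests group gi trained on the other group
    expect_false(any(grepl(sprintf("^g%d\\.", gi), attr(r, "train_ids"))))
  }
  expect_error(cross_validate(groups[1], "two_round_hybrid",
                              toy_model_config(), sch))

  single <- cross_validate(groups, "ten_round_single",
                           toy_model_config(), sch)
  expect_length(single, 2L)
  for (gi in seq_along(single))
    expect_true(all(grepl(sprintf("^g%d\\.train", gi),
                          attr(single[[gi]], "train_ids"))))
})
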