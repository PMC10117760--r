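# Shared fixtures. The overfit fixture (a toy detector trained to
# convergence on one synthetic scene) is expensive, so it is built once
# per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

toy_scene <- function(seed = 3L) {
  generate_scene(synthetic_config(image_size = c(96L, 96L), n_frames = 80L,
                                  n_neurons = 5L, radius_range = c(6, 9),
                                  overlap_pairs = 0L, seed = seed))
}

toy_model_config <- function(...) {
  model_config(backbone_depth = "tiny", input_size = 128L, ...)
}

fused_input <- function(scene) {
  unclass(fuse_images(average_projection(scene$video),
                      correlation_map(scene$video)))
}

# detector overfit on one synthetic scene; returns model + scene + image
overfit_fixture <- function() {
  if (!is.null(.fixture_env$overfit)) return(.fixture_env$overfit)
  scene <- toy_scene()
  img <- fused_input(scene)
  schedule <- train_schedule(list(train_stage("all_layers", 10L, 5e-3,
                                              40L, 1L)), seed = 7L)
  model <- train_model(build_model(toy_model_config()),
                       list(list(image = img, masks = scene$truth$masks)),
                       schedule)
  .fixture_env$overfit <- list(model = model, scene = scene, image = img)
  .fixture_env$overfit
}
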