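#' Training stage and schedule constructors
#'
#' A stage fixes the trainable scope (`heads_only` freezes everything
#' except the classification/regression and mask heads; `all_layers`
#' trains the whole network), the epoch count, learning rate, steps per
#' epoch and batch size. A schedule is an ordered list of stages plus
#' optimiser settings (stochastic gradient descent with momentum 0.9 and
#' weight decay 1e-4, the Mask R-CNN convention) and a seed.
#'
#' The "head" scope deliberately excludes the RPN: proposals come from
#' the (frozen) backbone+RPN while only the per-ROI heads adapt, which is
#' the convention when fine-tuning from pre-trained weights.
#'
#' @param scope `"heads_only"` or `"all_layers"`.
#' @param epochs,steps_per_epoch,batch_size positive integers.
#' @param learning_rate positive learning rate.
#' @return `train_stage`: a classed list.
#' @export
train_stage <- function(scope = c("all_layers", "heads_only"),
                        epochs, learning_rate,
                        steps_per_epoch = 500L, batch_size = 2L) {
  scope <- match.arg(scope)
  stopifnot(epochs >= 1L, learning_rate > 0, steps_per_epoch >= 1L,
            batch_size >= 1L)
  structure(list(scope = scope, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size)),
            class = "train_stage")
}

#' @rdname train_stage
#' @param stages list of [train_stage()] objects.
#' @param momentum,weight_decay SGD settings.
#' @param seed RNG seed for sampling and augmentation during training.
#' @param augment optional [augment_config()] applied to every drawn
#'   sample; `NULL` disables augmentation.
#' @export
train_schedule <- function(stages, momentum = 0.9, weight_decay = 1e-4,
                           seed = 1L, augment = NULL) {
  stopifnot(length(stages) >= 1L,
            all(vapply(stages, inherits, logical(1), "train_stage")))
  structure(list(stages = stages, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 augment = augment),
            class = "train_schedule")
}

#' The staged hybrid-dataset schedule
#'
#' Three stages totalling 200 epochs: 50 epochs of head-only training at
#' learning rate 1e-3, 100 epochs of full-network training at 2e-4, and
#' 50 more full-network epochs at 1e-4; 500 steps per epoch with batch
#' size two throughout.
#'
#' @inheritParams train_schedule
#' @return a [train_schedule()].
#' @export
hybrid_schedule <- function(seed = 1L, augment = NULL) {
  train_schedule(list(
    train_stage("heads_only", 50L, 1e-3, 500L, 2L),
    train_stage("all_layers", 100L, 2e-4, 500L, 2L),
    train_stage("all_layers", 50L, 1e-4, 500L, 2L)),
    seed = seed, augment = augment)
}

#' The benchmark fine-tuning schedule
#'
#' Two stages totalling 150 epochs: 20 head-only epochs and 130
#' full-network epochs, both at learning rate 1e-3; 50 steps per epoch
#' with batch size two.
#'
#' @inheritParams train_schedule
#' @return a [train_schedule()].
#' @export
neurofinder_schedule <- function(seed = 1L, augment = NULL) {
  train_schedule(list(
    train_stage("heads_only", 20L, 1e-3, 50L, 2L),
    train_stage("all_layers", 130L, 1e-3, 50L, 2L)),
    seed = seed, augment = augment)
}

scope_params <- function(model, scope) {
  nm <- names(model$params)
  switch(scope,
         all_layers = nm,
         heads_only = grep("^head\\.", nm, value = TRUE),
         stop("unknown scope: ", scope))
}

#' Train the detector on a dataset
#'
#' Runs the schedule's stages in order, toggling the trainable scope.
#' Each step draws `batch_size` samples (uniformly, from the seeded
#' stream), accumulates gradients of the combined loss, clips the global
#' gradient norm at 5, and applies an SGD-with-momentum update to the
#' in-scope parameters only; out-of-scope parameters are untouched to the
#' bit. The per-epoch mean of the total loss and its components is
#' recorded in `model$loss_history`. Training is deterministic given the
#' schedule seed.
#'
#' @param model a [build_model()] result.
#' @param dataset list of samples, each a list with `image` (matrix) and
#'   `masks` (a [mask_set()]).
#' @param schedule a [train_schedule()].
#' @param verbose print per-epoch losses.
#' @return the trained model, with `loss_history` (data frame: stage,
#'   epoch, total, classification, regression, mask).
#' @export
train_model <- function(model, dataset, schedule, verbose = FALSE) {
  stopifnot(inherits(model, "caimseg_model"),
            inherits(schedule, "train_schedule"), length(dataset) >= 1L)
  with_seed(schedule$seed, train_model_impl(model, dataset, schedule,
                                            verbose))
}

train_model_impl <- function(model, dataset, schedule, verbose) {
  vel <- lapply(model$params, function(p) p * 0)  # preserves shape/class
  history <- list()
  for (si in seq_along(schedule$stages)) {
    stage <- schedule$stages[[si]]
    scope <- scope_params(model, stage$scope)
    for (epoch in seq_len(stage$epochs)) {
      acc <- c(total = 0, classification = 0, regression = 0, mask = 0)
      for (step in seq_len(stage$steps_per_epoch)) {
        grads <- NULL
        batch_loss <- 0
        comps <- c(classification = 0, regression = 0, mask = 0)
        for (bi in seq_len(stage$batch_size)) {
          idx <- sample.int(length(dataset), 1L)
          smp <- dataset[[idx]]
          img <- smp$image; msk <- smp$masks
          if (!is.null(schedule$augment)) {
            aug <- augment_pair(unclass(img), msk, schedule$augment)
            if (length(aug$masks$masks) > 0L) {
              img <- aug$image; msk <- aug$masks
            }
          }
          l <- tryCatch(model_loss(model, img, msk), error = function(e)
            stop("stage ", si, " epoch ", epoch, " step ", step, ": ",
                 conditionMessage(e)))
          gstep <- ag_backward(l$graph, l$total_node)
          if (is.null(grads)) grads <- gstep
          else for (nm in names(gstep))
            grads[[nm]] <- (grads[[nm]] %||% 0) + gstep[[nm]]
          batch_loss <- batch_loss + l$total
          comps <- comps + l$components
        }
        nb <- stage$batch_size
        # global gradient-norm clip (at 5) for stability
        gn <- sqrt(sum(vapply(grads, function(x) sum((x / nb)^2),
                              numeric(1))))
        clip <- if (gn > 5) 5 / gn else 1
        for (nm in intersect(names(grads), scope)) {
          p <- model$params[[nm]]
          gval <- as.vector(grads[[nm]]) * (clip / nb) +
            schedule$weight_decay * as.vector(p)
          v <- schedule$momentum * as.vector(vel[[nm]]) -
            stage$learning_rate * gval
          vel[[nm]][] <- v
          model$params[[nm]][] <- as.vector(p) + v
        }
        acc <- acc + c(batch_loss, comps) / nb
      }
      acc <- acc / stage$steps_per_epoch
      history[[length(history) + 1L]] <-
        data.frame(stage = si, epoch = length(history) + 1L,
                   total = acc[["total"]],
                   classification = acc[["classification"]],
                   regression = acc[["regression"]], mask = acc[["mask"]])
      if (verbose)
        message(sprintf("stage %d epoch %d: loss %.4f", si,
                        length(history), acc[["total"]]))
    }
  }
  model$loss_history <- do.call(rbind, history)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validation over grouped datasets
#'
#' Two protocols over a list of groups (each group a list with `train`
#' and `test` sample lists, samples as in [train_model()]):
#' \describe{
#'   \item{two_round_hybrid}{groups are split into two halves; each
#'     half's model is trained on the union of the *other* half's
#'     training data and tested on this half's test items, so every group
#'     is tested exactly once by a model that never saw its data.}
#'   \item{ten_round_single}{one model per group, trained on that group's
#'     training samples and tested on its own test samples.}
#' }
#'
#' @param groups list of groups; for `two_round_hybrid` the count must be
#'   even.
#' @param protocol `"two_round_hybrid"` or `"ten_round_single"`.
#' @param model_cfg a [model_config()] used to build each fold's model.
#' @param schedule a [train_schedule()] applied per fold.
#' @param iou_threshold evaluation matching threshold.
#' @return list of per-group [seg_metrics()] reports (one per group, in
#'   input order), each with attributes `train_ids` and `test_ids` — the
#'   identity-tracked sample sets of the model that produced it.
#' @export
cross_validate <- function(groups,
                           protocol = c("two_round_hybrid",
                                        "ten_round_single"),
                           model_cfg = model_config(),
                           schedule, iou_threshold = 0.5) {
  protocol <- match.arg(protocol)
  stopifnot(length(groups) >= 2L)
  sample_ids <- function(gi, part, n)
    sprintf("g%d.%s%d", gi, part, seq_len(n))
  test_group <- function(model, grp, gi, train_ids) {
    counts <- c(tp = 0L, gt = 0L, det = 0L)
    for (smp in grp$test) {
      det <- predict(model, smp$image)
      mr <- match_masks(smp$masks, det$masks, iou_threshold = iou_threshold)
      counts <- counts + c(mr$n_tp, length(smp$masks$masks),
                           length(det$masks$masks))
    }
    rep <- seg_metrics(counts[["tp"]], counts[["gt"]], counts[["det"]])
    attr(rep, "train_ids") <- train_ids
    attr(rep, "test_ids") <- sample_ids(gi, "test", length(grp$test))
    rep
  }
  reports <- vector("list", length(groups))
  if (protocol == "two_round_hybrid") {
    if (length(groups) %% 2L != 0L)
      stop("two_round_hybrid needs an even number of groups")
    half <- length(groups) / 2L
    halves <- list(seq_len(half), half + seq_len(half * 2L - half))
    halves[[2L]] <- setdiff(seq_along(groups), halves[[1L]])
    for (h in 1:2) {
      other <- halves[[3L - h]]
      train_set <- do.call(c, lapply(other, function(gi) groups[[gi]]$train))
      train_ids <- unlist(lapply(other, function(gi)
        sample_ids(gi, "train", length(groups[[gi]]$train))))
      model <- build_model(model_cfg)
      model <- train_model(model, train_set, schedule)
      for (gi in halves[[h]])
        reports[[gi]] <- test_group(model, groups[[gi]], gi, train_ids)
    }
  } else {
    for (gi in seq_along(groups)) {
      model <- build_model(model_cfg)
      model <- train_model(model, groups[[gi]]$train, schedule)
      reports[[gi]] <- test_group(model, groups[[gi]], gi,
                                  sample_ids(gi, "train",
                                             length(groups[[gi]]$train)))
    }
  }
  reports
}
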