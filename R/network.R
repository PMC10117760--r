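#' Detector architecture configuration
#'
#' Describes every switchable component of the segmentation network, so
#' that each ablation arm (attention off, bottom-up path off, extra
#' down-sampling off, fusion-mode variants) is constructible from
#' configuration alone.
#'
#' The network is a compact Mask R-CNN-style detector: a residual
#' backbone producing feature maps C2-C5 at strides 4-32 (plus C6 at
#' stride 64 when `path_augmentation` is on), a feature pyramid (FPN)
#' whose lateral connections optionally pass through an efficient channel
#' attention (ECA) gate, an optional additional top-down-connected
#' bottom-up path producing maps Y2-Y6 (`fpn_plus`), a region proposal
#' network shared across levels, ROI-Align feature pooling, and parallel
#' classification/box-regression and mask heads. Up-sampling fusion uses
#' `fusion_up` ("add" by default) and down-sampling fusion uses
#' `fusion_down` ("concat" by default, always followed by a cross-stage
#' partial (CSP) layer).
#'
#' @param backbone_depth one of `"tiny"`, `"small"`, `"standard"` —
#'   channel widths of the residual backbone. The published architecture
#'   family uses an ImageNet-scale backbone; the widths here are scaled
#'   for CPU execution while preserving the topology.
#' @param attention `"eca"`, `"cbam"` or `"none"`.
#' @param eca_kernel odd 1D-convolution kernel size of the ECA gate, or
#'   `"adaptive"` for the channel-dependent rule
#'   `k = nearest odd (log2(C)/2 + 1/2)`.
#' @param fpn_plus add the extra bottom-up pyramid path (maps Y2-Y6).
#' @param path_augmentation add one more down-sampling stage after C5,
#'   turning the four backbone outputs into five.
#' @param fusion_up,fusion_down `"add"` or `"concat"` feature-fusion mode
#'   for the top-down and bottom-up paths.
#' @param csp_depth number of bottleneck blocks inside each CSP layer.
#' @param anchor_scales anchor side lengths in pixels, ascending, one per
#'   pyramid level (levels at strides 4, 8, 16, 32, 64).
#' @param max_instances detection cap per image; fields of view in this
#'   domain hold roughly 100-400 neurons.
#' @param score_threshold minimum classification score of a detection.
#' @param input_size square network input side; images are zero-padded to
#'   this size, and must not exceed it (tile larger images with
#'   [make_grid()]).
#' @param init_seed seed of the weight initialisation stream.
#' @return an object of class `model_config`.
#' @export
model_config <- function(backbone_depth = "small",
                         attention = "eca",
                         eca_kernel = 3L,
                         fpn_plus = TRUE,
                         path_augmentation = TRUE,
                         fusion_up = "add",
                         fusion_down = "concat",
                         csp_depth = 1L,
                         anchor_scales = c(8, 16, 32, 64, 128),
                         max_instances = 500L,
                         score_threshold = 0.5,
                         input_size = 512L,
                         init_seed = 1L) {
  backbone_depth <- match.arg(backbone_depth, c("tiny", "small", "standard"))
  attention <- match.arg(attention, c("eca", "cbam", "none"))
  fusion_up <- match.arg(fusion_up, c("add", "concat"))
  fusion_down <- match.arg(fusion_down, c("add", "concat"))
  if (!identical(eca_kernel, "adaptive")) {
    eca_kernel <- as.integer(eca_kernel)
    if (eca_kernel < 1L || eca_kernel %% 2L == 0L)
      stop("eca_kernel must be odd and >= 1")
  }
  if (is.unsorted(anchor_scales, strictly = TRUE))
    stop("anchor_scales must be strictly ascending")
  stopifnot(csp_depth >= 1L, max_instances >= 1L,
            score_threshold >= 0, score_threshold <= 1)
  n_levels <- if (path_augmentation) 5L else 4L
  if (length(anchor_scales) < n_levels)
    stop("need at least ", n_levels, " anchor scales for ", n_levels,
         " pyramid levels")
  max_stride <- if (path_augmentation) 64L else 32L
  input_size <- as.integer(input_size)
  if (input_size %% max_stride != 0L)
    stop("input_size must be a multiple of ", max_stride)
  structure(list(backbone_depth = backbone_depth, attention = attention,
                 eca_kernel = eca_kernel, fpn_plus = fpn_plus,
                 path_augmentation = path_augmentation,
                 fusion_up = fusion_up, fusion_down = fusion_down,
                 csp_depth = as.integer(csp_depth),
                 anchor_scales = anchor_scales,
                 max_instances = as.integer(max_instances),
                 score_threshold = score_threshold,
                 input_size = input_size,
                 init_seed = as.integer(init_seed)),
            class = "model_config")
}

backbone_widths <- function(depth) {
  switch(depth,
         tiny = list(stem = 8L, stages = c(8L, 16L, 24L, 32L, 32L),
                     fpn = 16L, fc = 64L),
         small = list(stem = 16L, stages = c(16L, 32L, 48L, 64L, 64L),
                      fpn = 32L, fc = 128L),
         standard = list(stem = 32L, stages = c(32L, 64L, 128L, 256L, 256L),
                         fpn = 64L, fc = 256L))
}

eca_kernel_for <- function(cfg, channels) {
  if (!identical(cfg$eca_kernel, "adaptive")) return(cfg$eca_kernel)
  k <- round(log2(channels) / 2 + 0.5)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

## ---- parameter initialisation ----

init_conv <- function(params, name, kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  params[[paste0(name, ".W")]] <-
    array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)),
          c(kh, kw, cin, cout))
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_fc <- function(params, name, din, dout) {
  params[[paste0(name, ".W")]] <-
    matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout)
  params[[paste0(name, ".b")]] <- numeric(dout)
  params
}

init_csp <- function(params, prefix, cin, cout, depth) {
  h <- cout %/% 2L
  params <- init_conv(params, paste0(prefix, ".a"), 1L, 1L, cin, h)
  params <- init_conv(params, paste0(prefix, ".b"), 1L, 1L, cin, h)
  for (i in seq_len(depth)) {
    params <- init_conv(params, paste0(prefix, ".bn", i, ".c1"), 1L, 1L, h, h)
    params <- init_conv(params, paste0(prefix, ".bn", i, ".c2"), 3L, 3L, h, h)
  }
  init_conv(params, paste0(prefix, ".out"), 1L, 1L, 2L * h, cout)
}

init_attention <- function(params, cfg, site, channels) {
  if (cfg$attention == "eca") {
    k <- eca_kernel_for(cfg, channels)
    params[[paste0(site, ".eca.w")]] <- stats::rnorm(k, 0, 0.5)
  } else if (cfg$attention == "cbam") {
    hidden <- max(channels %/% 4L, 1L)
    params <- init_fc(params, paste0(site, ".cbam.fc1"), channels, hidden)
    params <- init_fc(params, paste0(site, ".cbam.fc2"), hidden, channels)
    params <- init_conv(params, paste0(site, ".cbam.sp"), 7L, 7L, 2L, 1L)
  }
  params
}

#' Build the segmentation network
#'
#' Instantiates all weights of the configured architecture with
#' He-scaled Gaussian initialisation (seeded by `cfg$init_seed`, so a
#' config maps to a reproducible model). Weights trained elsewhere can be
#' loaded afterwards with [load_weights()].
#'
#' @param cfg a [model_config()].
#' @return an object of class `caimseg_model`: list with `config`,
#'   `params` (named list of weight arrays), `levels` (pyramid level
#'   names), `strides`, and `loss_history` (filled by [train_model()]).
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  wd <- backbone_widths(cfg$backbone_depth)
  n_levels <- if (cfg$path_augmentation) 5L else 4L
  stage_names <- paste0("c", 2L:(1L + n_levels))
  F <- wd$fpn
  params <- with_seed(cfg$init_seed, {
    p <- list()
    p <- init_conv(p, "backbone.stem", 3L, 3L, 1L, wd$stem)
    cin <- wd$stem
    for (s in seq_len(n_levels)) {
      nm <- paste0("backbone.", stage_names[s])
      if (s == 1L) {
        p <- init_conv(p, paste0(nm, ".down1"), 3L, 3L, cin, wd$stages[s])
        p <- init_conv(p, paste0(nm, ".down2"), 3L, 3L, wd$stages[s],
                       wd$stages[s])
      } else {
        p <- init_conv(p, paste0(nm, ".down1"), 3L, 3L, cin, wd$stages[s])
      }
      p <- init_conv(p, paste0(nm, ".res1"), 3L, 3L, wd$stages[s],
                     wd$stages[s])
      p <- init_conv(p, paste0(nm, ".res2"), 3L, 3L, wd$stages[s],
                     wd$stages[s])
      cin <- wd$stages[s]
    }
    plevels <- paste0("P", 2L:(1L + n_levels))
    for (s in seq_len(n_levels)) {
      p <- init_conv(p, paste0("fpn.lat.", plevels[s]), 1L, 1L,
                     wd$stages[s], F)
      p <- init_attention(p, cfg, paste0("fpn.", plevels[s]), F)
      p <- init_conv(p, paste0("fpn.smooth.", plevels[s]), 3L, 3L, F, F)
      if (cfg$fusion_up == "concat" && s < n_levels)
        p <- init_csp(p, paste0("fpn.csp.", plevels[s]), 2L * F, F,
                      cfg$csp_depth)
    }
    if (cfg$fpn_plus) {
      ylevels <- paste0("Y", 3L:(1L + n_levels))
      for (nm in ylevels) {
        p <- init_conv(p, paste0("fpnplus.down.", nm), 3L, 3L, F, F)
        p <- init_conv(p, paste0("fpnplus.lat.", nm), 1L, 1L, F, F)
        p <- init_attention(p, cfg, paste0("fpnplus.", nm), F)
        if (cfg$fusion_down == "concat")
          p <- init_csp(p, paste0("fpnplus.csp.", nm), 2L * F, F,
                        cfg$csp_depth)
      }
    }
    p <- init_conv(p, "rpn.conv", 3L, 3L, F, F)
    p <- init_conv(p, "rpn.obj", 1L, 1L, F, 1L)
    p <- init_conv(p, "rpn.box", 1L, 1L, F, 4L)
    p <- init_fc(p, "head.box.fc1", 7L * 7L * F, wd$fc)
    p <- init_fc(p, "head.box.cls", wd$fc, 2L)
    p <- init_fc(p, "head.box.reg", wd$fc, 4L)
    p <- init_conv(p, "head.mask.conv1", 3L, 3L, F, F)
    p <- init_conv(p, "head.mask.conv2", 3L, 3L, F, F)
    p <- init_conv(p, "head.mask.conv3", 3L, 3L, F, F)
    p <- init_conv(p, "head.mask.out", 1L, 1L, F, 1L)
    p
  })
  levels <- if (cfg$fpn_plus) paste0("Y", 2L:(1L + n_levels))
            else paste0("P", 2L:(1L + n_levels))
  structure(list(config = cfg, params = params,
                 levels = levels,
                 strides = c(4L, 8L, 16L, 32L, 64L)[seq_len(n_levels)],
                 loss_history = NULL),
            class = "caimseg_model")
}

#' Total number of trainable parameters
#'
#' @param model a [build_model()] result.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.caimseg_model <- function(x, ...) {
  cfg <- x$config
  cat("caimseg_model:", cfg$backbone_depth, "backbone,",
      length(x$levels), "pyramid levels (", paste(x$levels, collapse = " "),
      ")\n")
  cat(sprintf("  attention: %s | FPN+: %s | path augmentation: %s | fusion up/down: %s/%s\n",
              cfg$attention, cfg$fpn_plus, cfg$path_augmentation,
              cfg$fusion_up, cfg$fusion_down))
  cat(sprintf("  %d parameters; input %d px; %s\n", n_params(x),
              cfg$input_size,
              if (is.null(x$loss_history)) "untrained"
              else sprintf("trained (%d epochs)", nrow(x$loss_history))))
  invisible(x)
}

#' @export
summary.caimseg_model <- function(object, ...) {
  print(object)
  groups <- c(backbone = "^backbone\\.", fpn = "^fpn\\.",
              fpn_plus = "^fpnplus\\.", rpn = "^rpn\\.",
              heads = "^head\\.")
  for (gname in names(groups)) {
    nm <- grep(groups[[gname]], names(object$params), value = TRUE)
    if (length(nm))
      cat(sprintf("  %-9s %8d params in %3d arrays\n", gname,
                  sum(vapply(object$params[nm], length, integer(1))),
                  length(nm)))
  }
  invisible(object)
}

#' @export
plot.caimseg_model <- function(x, ...) {
  if (is.null(x$loss_history)) stop("model has no loss history; train first")
  h <- x$loss_history
  graphics::plot(h$epoch, h$total, type = "b", xlab = "epoch",
                 ylab = "mean total loss", main = "training loss", ...)
  invisible(x)
}

#' @export
coef.caimseg_model <- function(object, ...) object$params

#' Save and load model weights
#'
#' Checkpoints are RDS files holding the named parameter list. Loading
#' verifies that names and shapes match the model's architecture, which
#' is how externally pre-trained weights are brought in.
#'
#' @param model a `caimseg_model`.
#' @param path checkpoint file path.
#' @export
save_weights <- function(model, path) {
  saveRDS(model$params, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  p <- readRDS(path)
  if (!setequal(names(p), names(model$params)))
    stop("checkpoint parameters do not match this architecture")
  for (nm in names(model$params))
    if (!identical(dim(p[[nm]]), dim(model$params[[nm]])) ||
        length(p[[nm]]) != length(model$params[[nm]]))
      stop("shape mismatch for parameter ", nm)
  model$params <- p[names(model$params)]
  model
}

## ---- graph building blocks ----

csp_node <- function(g, x, prefix, depth) {
  a <- ag_conv2d(g, x, paste0(prefix, ".a.W"), paste0(prefix, ".a.b"))
  b <- ag_conv2d(g, x, paste0(prefix, ".b.W"), paste0(prefix, ".b.b"))
  for (i in seq_len(depth)) {
    y <- ag_relu(g, ag_conv2d(g, a, paste0(prefix, ".bn", i, ".c1.W"),
                              paste0(prefix, ".bn", i, ".c1.b")))
    y <- ag_conv2d(g, y, paste0(prefix, ".bn", i, ".c2.W"),
                   paste0(prefix, ".bn", i, ".c2.b"))
    a <- ag_relu(g, ag_add(g, a, y))
  }
  ag_conv2d(g, ag_concat_c(g, a, b), paste0(prefix, ".out.W"),
            paste0(prefix, ".out.b"))
}

eca_node <- function(g, x, wname) {
  s <- ag_gap(g, x)
  s <- ag_conv1d(g, s, wname)
  s <- ag_sigmoid(g, s)
  ag_scale_channels(g, x, s)
}

cbam_node <- function(g, x, site) {
  # channel attention: shared MLP over GAP and GMP descriptors
  mlp <- function(v) {
    h <- ag_relu(g, ag_fc(g, v, paste0(site, ".cbam.fc1.W"),
                          paste0(site, ".cbam.fc1.b")))
    ag_fc(g, h, paste0(site, ".cbam.fc2.W"), paste0(site, ".cbam.fc2.b"))
  }
  ca <- ag_sigmoid(g, ag_add(g, mlp(ag_gap(g, x)), mlp(ag_gmp(g, x))))
  ca_vec <- ag_push(g, as.numeric(ca$value), list(ca),
                    function(d) list(matrix(d, 1L)))
  x <- ag_scale_channels(g, x, ca_vec)
  # spatial attention: 7x7 conv over channel mean/max maps
  xd <- dim(x$value)
  mean_map <- ag_push(g, array(rowMeans(matrix(x$value, xd[1L] * xd[2L],
                                               xd[3L])), c(xd[1:2], 1L)),
                      list(x), function(d)
                        list(array(rep(d, xd[3L]) / xd[3L], xd)))
  xv <- x$value
  mx <- apply(xv, c(1L, 2L), max)
  amax <- apply(xv, c(1L, 2L), which.max)
  max_map <- ag_push(g, array(mx, c(xd[1:2], 1L)), list(x), function(d) {
    z <- array(0, xd)
    ij <- as.matrix(expand.grid(seq_len(xd[1L]), seq_len(xd[2L])))
    z[cbind(ij, as.vector(amax))] <- as.vector(d)
    list(z)
  })
  sp <- ag_sigmoid(g, ag_conv2d(g, ag_concat_c(g, mean_map, max_map),
                                paste0(site, ".cbam.sp.W"),
                                paste0(site, ".cbam.sp.b")))
  ag_scale_spatial(g, x, sp)
}

attention_node <- function(g, x, cfg, site) {
  switch(cfg$attention,
         none = x,
         eca = eca_node(g, x, paste0(site, ".eca.w")),
         cbam = cbam_node(g, x, site))
}

res_stage <- function(g, x, prefix, two_downs = FALSE) {
  x <- ag_relu(g, ag_conv2d(g, x, paste0(prefix, ".down1.W"),
                            paste0(prefix, ".down1.b"), stride = 2L))
  if (two_downs)
    x <- ag_relu(g, ag_conv2d(g, x, paste0(prefix, ".down2.W"),
                              paste0(prefix, ".down2.b"), stride = 2L))
  y <- ag_relu(g, ag_conv2d(g, x, paste0(prefix, ".res1.W"),
                            paste0(prefix, ".res1.b")))
  y <- ag_conv2d(g, y, paste0(prefix, ".res2.W"), paste0(prefix, ".res2.b"))
  ag_relu(g, ag_add(g, x, y))
}

# returns the final pyramid feature nodes, named by model$levels
forward_pyramid <- function(g, model, img) {
  cfg <- model$config
  n_levels <- length(model$strides)
  x <- ag_const(g, array(img, c(dim(img), 1L)))
  x <- ag_relu(g, ag_conv2d(g, x, "backbone.stem.W", "backbone.stem.b"))
  feats <- vector("list", n_levels)
  for (s in seq_len(n_levels)) {
    prefix <- paste0("backbone.c", s + 1L)
    x <- res_stage(g, x, prefix, two_downs = (s == 1L))
    feats[[s]] <- x
  }
  plevels <- paste0("P", 2L:(1L + n_levels))
  lats <- lapply(seq_len(n_levels), function(s) {
    l <- ag_conv2d(g, feats[[s]], paste0("fpn.lat.", plevels[s], ".W"),
                   paste0("fpn.lat.", plevels[s], ".b"))
    attention_node(g, l, cfg, paste0("fpn.", plevels[s]))
  })
  P <- vector("list", n_levels)
  P[[n_levels]] <- lats[[n_levels]]
  for (s in seq.int(n_levels - 1L, 1L)) {
    up <- ag_upsample2(g, P[[s + 1L]])
    P[[s]] <- if (cfg$fusion_up == "add") ag_add(g, lats[[s]], up)
              else csp_node(g, ag_concat_c(g, lats[[s]], up),
                            paste0("fpn.csp.", plevels[s]), cfg$csp_depth)
  }
  for (s in seq_len(n_levels))
    P[[s]] <- ag_conv2d(g, P[[s]], paste0("fpn.smooth.", plevels[s], ".W"),
                        paste0("fpn.smooth.", plevels[s], ".b"))
  if (!cfg$fpn_plus) {
    names(P) <- plevels
    return(P)
  }
  ylevels <- paste0("Y", 2L:(1L + n_levels))
  Y <- vector("list", n_levels)
  Y[[1L]] <- P[[1L]]
  for (s in 2L:n_levels) {
    nm <- ylevels[s]
    d <- ag_relu(g, ag_conv2d(g, Y[[s - 1L]],
                              paste0("fpnplus.down.", nm, ".W"),
                              paste0("fpnplus.down.", nm, ".b"),
                              stride = 2L))
    l <- ag_conv2d(g, P[[s]], paste0("fpnplus.lat.", nm, ".W"),
                   paste0("fpnplus.lat.", nm, ".b"))
    l <- attention_node(g, l, cfg, paste0("fpnplus.", nm))
    Y[[s]] <- if (cfg$fusion_down == "add") ag_add(g, d, l)
              else csp_node(g, ag_concat_c(g, d, l),
                            paste0("fpnplus.csp.", nm), cfg$csp_depth)
  }
  names(Y) <- ylevels
  Y
}

rpn_heads <- function(g, pyramid) {
  lapply(pyramid, function(p) {
    h <- ag_relu(g, ag_conv2d(g, p, "rpn.conv.W", "rpn.conv.b"))
    list(obj = ag_conv2d(g, h, "rpn.obj.W", "rpn.obj.b"),
         box = ag_conv2d(g, h, "rpn.box.W", "rpn.box.b"))
  })
}

## ---- standalone ops ----

#' Efficient channel attention
#'
#' Global average pooling reduces an `H x W x C` feature map to a
#' C-vector, a short bias-free 1D convolution (zero-padded, not circular)
#' mixes neighbouring channels, a logistic squashes the result into
#' `(0, 1)`, and the input is rescaled channel-wise by these weights.
#' Because the gate is purely multiplicative, zeros stay zeros and no
#' element changes sign.
#'
#' @param feature `H x W x C` numeric array.
#' @param weights numeric vector of odd length: the 1D kernel.
#' @return array of the same shape as `feature`; attribute
#'   `channel_weights` holds the per-channel gates.
#' @export
eca <- function(feature, weights) {
  if (length(dim(feature)) != 3L) stop("feature must be H x W x C")
  if (length(weights) %% 2L == 0L) stop("ECA kernel length must be odd")
  g <- ag_new(list(w = as.numeric(weights)))
  x <- ag_const(g, feature)
  gates <- ag_sigmoid(g, ag_conv1d(g, ag_gap(g, x), "w"))
  out <- ag_scale_channels(g, x, gates)
  structure(out$value, channel_weights = gates$value)
}

#' Fuse two feature maps
#'
#' `add` requires identical shapes and sums elementwise; `concat` stacks
#' along the channel axis (inside the network a concatenation is always
#' followed by a CSP layer that mixes and re-compresses the channels).
#'
#' @param a,b numeric `H x W x C` arrays with equal spatial size.
#' @param mode `"add"` or `"concat"`.
#' @return fused array.
#' @export
fuse_features <- function(a, b, mode = c("add", "concat")) {
  mode <- match.arg(mode)
  da <- dim(a); db <- dim(b)
  if (length(da) != 3L || length(db) != 3L || !all(da[1:2] == db[1:2]))
    stop("spatial shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  if (mode == "add") {
    if (da[3L] != db[3L])
      stop("add fusion needs equal channel counts: ", da[3L], " vs ", db[3L])
    a + b
  } else {
    array(c(a, b), c(da[1L], da[2L], da[3L] + db[3L]))
  }
}

## ---- boxes, anchors, NMS ----

# boxes are (r0, c0, r1, c1), half-open, 0-based, in input-image pixels
anchor_boxes <- function(hf, wf, stride, scale) {
  ctr <- expand.grid(r = (seq_len(hf) - 0.5) * stride,
                     c = (seq_len(wf) - 0.5) * stride)  # r varies fastest
  cbind(ctr$r - scale / 2, ctr$c - scale / 2,
        ctr$r + scale / 2, ctr$c + scale / 2)
}

box_decode <- function(anchors, deltas) {
  ah <- anchors[, 3L] - anchors[, 1L]
  aw <- anchors[, 4L] - anchors[, 2L]
  acy <- (anchors[, 1L] + anchors[, 3L]) / 2
  acx <- (anchors[, 2L] + anchors[, 4L]) / 2
  cy <- deltas[, 1L] * ah + acy
  cx <- deltas[, 2L] * aw + acx
  h <- ah * exp(pmin(pmax(deltas[, 3L], -4), 4))
  w <- aw * exp(pmin(pmax(deltas[, 4L], -4), 4))
  cbind(cy - h / 2, cx - w / 2, cy + h / 2, cx + w / 2)
}

box_encode <- function(boxes, anchors) {
  ah <- anchors[, 3L] - anchors[, 1L]
  aw <- anchors[, 4L] - anchors[, 2L]
  acy <- (anchors[, 1L] + anchors[, 3L]) / 2
  acx <- (anchors[, 2L] + anchors[, 4L]) / 2
  bh <- pmax(boxes[, 3L] - boxes[, 1L], 1e-3)
  bw <- pmax(boxes[, 4L] - boxes[, 2L], 1e-3)
  bcy <- (boxes[, 1L] + boxes[, 3L]) / 2
  bcx <- (boxes[, 2L] + boxes[, 4L]) / 2
  cbind((bcy - acy) / ah, (bcx - acx) / aw, log(bh / ah), log(bw / aw))
}

box_clip <- function(boxes, H, W) {
  cbind(pmin(pmax(boxes[, 1L], 0), H), pmin(pmax(boxes[, 2L], 0), W),
        pmin(pmax(boxes[, 3L], 0), H), pmin(pmax(boxes[, 4L], 0), W))
}

box_iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  r0 <- outer(A[, 1L], B[, 1L], pmax)
  c0 <- outer(A[, 2L], B[, 2L], pmax)
  r1 <- outer(A[, 3L], B[, 3L], pmin)
  c1 <- outer(A[, 4L], B[, 4L], pmin)
  inter <- pmax(r1 - r0, 0) * pmax(c1 - c0, 0)
  areaA <- pmax(A[, 3L] - A[, 1L], 0) * pmax(A[, 4L] - A[, 2L], 0)
  areaB <- pmax(B[, 3L] - B[, 1L], 0) * pmax(B[, 4L] - B[, 2L], 0)
  un <- outer(areaA, areaB, `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

nms_boxes <- function(boxes, scores, iou_thr) {
  keep <- integer()
  ord <- order(scores, decreasing = TRUE)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1L]
    iou <- box_iou_matrix(boxes[i, , drop = FALSE],
                          boxes[rest, , drop = FALSE])[1L, ]
    ord <- rest[iou < iou_thr]
  }
  keep
}

# assign each ROI to the pyramid level whose anchor scale is nearest (in
# log2) to sqrt(box area)
roi_levels <- function(boxes, scales) {
  side <- sqrt(pmax((boxes[, 3L] - boxes[, 1L]) *
                    (boxes[, 4L] - boxes[, 2L]), 1))
  vapply(side, function(s) which.min(abs(log2(s / scales))), integer(1))
}

# pooled ROI features, batched per level then restored to input order:
# returns an (S, S, C, n) node
roi_align_multilevel <- function(g, pyramid, strides, scales, boxes, S) {
  lev <- roi_levels(boxes, scales[seq_along(pyramid)])
  parts <- list()
  ord <- integer()
  for (l in sort(unique(lev))) {
    idx <- which(lev == l)
    parts[[length(parts) + 1L]] <-
      ag_roi_align(g, pyramid[[l]], boxes[idx, , drop = FALSE] / strides[l],
                   S)
    ord <- c(ord, idx)
  }
  node <- if (length(parts) == 1L) parts[[1L]] else ag_cat4(g, parts)
  ag_perm4(g, node, order(ord))
}

## ---- input handling ----

prepare_input <- function(model, image) {
  image <- unclass(image)
  if (is.null(dim(image)) || length(dim(image)) != 2L)
    stop("image must be a 2D matrix")
  S <- model$config$input_size
  if (nrow(image) > S || ncol(image) > S)
    stop("image (", nrow(image), " x ", ncol(image), ") exceeds the ",
         "network input size (", S, "); split it with make_grid()/",
         "merge_tiles() from the tiling module")
  out <- matrix(0, S, S)
  out[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  out
}

## ---- loss ----

#' Training loss of the detector on one image
#'
#' Total loss is the sum of three components, each nonnegative:
#' classification (RPN objectness binary cross-entropy plus ROI softmax
#' cross-entropy), box regression (smooth-L1 on positive RPN anchors and
#' foreground ROIs), and segmentation mask (per-pixel binary
#' cross-entropy of the 28 x 28 mask logits of foreground ROIs).
#' Anchor/ROI sampling draws from the current RNG stream; seed the caller
#' for reproducibility.
#'
#' @param model a `caimseg_model`.
#' @param image `H x W` matrix (values in `[0, 1]`), at most
#'   `input_size` on each side.
#' @param masks ground-truth [mask_set()] for the image.
#' @return list with `total` (numeric), `components` (named numeric:
#'   `classification`, `regression`, `mask`), and internals for the
#'   trainer (`graph`, `total_node`).
#' @export
model_loss <- function(model, image, masks) {
  cfg <- model$config
  if (!inherits(masks, "mask_set") || length(masks$masks) == 0L)
    stop("training needs at least one ground-truth mask")
  img <- prepare_input(model, image)
  S <- cfg$input_size
  gt_boxes <- do.call(rbind, lapply(masks$masks, mask_bbox))
  gt_boxes <- matrix(as.numeric(gt_boxes), ncol = 4L)
  gt_rasters <- lapply(masks$masks, mask_to_binary, shape = masks$shape)

  g <- ag_new(model$params)
  pyramid <- forward_pyramid(g, model, img)
  rpn <- rpn_heads(g, pyramid)
  strides <- model$strides
  scales <- cfg$anchor_scales[seq_along(strides)]

  anchors <- lapply(seq_along(strides), function(l) {
    fd <- dim(pyramid[[l]]$value)
    anchor_boxes(fd[1L], fd[2L], strides[l], scales[l])
  })
  all_anchors <- do.call(rbind, anchors)
  n_per_level <- vapply(anchors, nrow, integer(1))
  level_of <- rep(seq_along(anchors), n_per_level)

  ## RPN targets
  iou <- box_iou_matrix(all_anchors, gt_boxes)
  best_gt <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(nrow(iou)), best_gt)]
  pos <- best_iou >= 0.5
  for (j in seq_len(ncol(iou))) {      # every GT claims its best anchor
    b <- which.max(iou[, j])
    if (iou[b, j] > 0) pos[b] <- TRUE
  }
  neg <- best_iou < 0.3 & !pos
  pos_idx <- which(pos)
  if (length(pos_idx) > 32L) pos_idx <- sample(pos_idx, 32L)
  neg_idx <- which(neg)
  n_neg <- min(length(neg_idx), 64L - length(pos_idx))
  if (length(neg_idx) > n_neg) neg_idx <- sample(neg_idx, n_neg)

  sel <- c(pos_idx, neg_idx)
  sel_by_level <- split(seq_along(sel), level_of[sel])
  obj_nodes <- lapply(names(sel_by_level), function(lch) {
    l <- as.integer(lch)
    local_idx <- sel[sel_by_level[[lch]]] - c(0L, cumsum(n_per_level))[l]
    ag_take(g, rpn[[l]]$obj, local_idx)
  })
  obj_logits <- ag_cat_vec(g, obj_nodes)
  # targets aligned with the concatenation order of sel_by_level
  tgt <- c(rep(1, length(pos_idx)), rep(0, length(neg_idx)))
  tgt_concat <- tgt[unlist(sel_by_level, use.names = FALSE)]
  rpn_obj_loss <- ag_bce_logits(g, obj_logits, tgt_concat)

  rpn_box_loss <- ag_zero_scalar(g)
  if (length(pos_idx)) {
    pos_by_level <- split(seq_along(pos_idx), level_of[pos_idx])
    box_nodes <- lapply(names(pos_by_level), function(lch) {
      l <- as.integer(lch)
      aidx <- pos_idx[pos_by_level[[lch]]] - c(0L, cumsum(n_per_level))[l]
      fd <- dim(rpn[[l]]$box$value)
      np <- fd[1L] * fd[2L]
      flat <- as.vector(outer(aidx, (seq_len(4L) - 1L) * np, `+`))
      nd <- ag_take(g, rpn[[l]]$box, flat)
      ag_push(g, matrix(nd$value, ncol = 4L), list(nd),
              function(d) list(as.numeric(d)))
    })
    box_pred <- ag_rbind(g, box_nodes)
    ord_pos <- unlist(pos_by_level, use.names = FALSE)
    enc <- box_encode(gt_boxes[best_gt[pos_idx[ord_pos]], , drop = FALSE],
                      all_anchors[pos_idx[ord_pos], , drop = FALSE])
    rpn_box_loss <- ag_smooth_l1(g, box_pred, enc)
  }

  ## proposals (no gradient through box coordinates)
  prop <- make_proposals(rpn, anchors, S, pre_nms = 200L, post_nms = 50L)
  proposals <- rbind(prop$boxes, gt_boxes)

  piou <- box_iou_matrix(proposals, gt_boxes)
  pbest <- max.col(piou, ties.method = "first")
  pbiou <- piou[cbind(seq_len(nrow(piou)), pbest)]
  fg <- which(pbiou >= 0.5)
  bg <- which(pbiou < 0.5)
  if (length(fg) > 16L) fg <- sample(fg, 16L)
  if (length(bg) > 16L) bg <- sample(bg, 16L)
  rois <- proposals[c(fg, bg), , drop = FALSE]
  roi_labels <- c(rep(2L, length(fg)), rep(1L, length(bg)))

  roi_cls_loss <- ag_zero_scalar(g)
  roi_box_loss <- ag_zero_scalar(g)
  mask_loss <- ag_zero_scalar(g)
  if (nrow(rois)) {
    pooled <- roi_align_multilevel(g, pyramid, strides, scales, rois, 7L)
    flat <- ag_flatten_rois(g, pooled)
    h <- ag_relu(g, ag_fc(g, flat, "head.box.fc1.W", "head.box.fc1.b"))
    cls_logits <- ag_fc(g, h, "head.box.cls.W", "head.box.cls.b")
    roi_cls_loss <- ag_softmax_ce(g, cls_logits, roi_labels)
    if (length(fg)) {
      reg <- ag_fc(g, h, "head.box.reg.W", "head.box.reg.b")
      reg_fg <- ag_take_rows(g, reg, seq_along(fg))
      enc <- box_encode(gt_boxes[pbest[fg], , drop = FALSE],
                        rois[seq_along(fg), , drop = FALSE])
      roi_box_loss <- ag_smooth_l1(g, reg_fg, enc)

      mrois <- rois[seq_along(fg), , drop = FALSE]
      mp <- roi_align_multilevel(g, pyramid, strides, scales, mrois, 14L)
      m <- ag_relu(g, ag_conv2d_batch(g, mp, "head.mask.conv1.W",
                                      "head.mask.conv1.b"))
      m <- ag_relu(g, ag_conv2d_batch(g, m, "head.mask.conv2.W",
                                      "head.mask.conv2.b"))
      m <- ag_upsample2_batch(g, m)
      m <- ag_relu(g, ag_conv2d_batch(g, m, "head.mask.conv3.W",
                                      "head.mask.conv3.b"))
      mlogits <- ag_conv2d_batch(g, m, "head.mask.out.W", "head.mask.out.b")
      mtgt <- array(0, dim(mlogits$value))
      for (i in seq_along(fg))
        mtgt[, , 1L, i] <- crop_mask_to_box(gt_rasters[[pbest[fg[i]]]],
                                            mrois[i, ], 28L)
      mask_loss <- ag_bce_logits(g, mlogits, mtgt)
    }
  }

  classification <- ag_wsum(g, list(rpn_obj_loss, roi_cls_loss))
  regression <- ag_wsum(g, list(rpn_box_loss, roi_box_loss))
  total <- ag_wsum(g, list(classification, regression, mask_loss))
  comp <- c(classification = classification$value,
            regression = regression$value, mask = mask_loss$value)
  for (nm in names(comp))
    if (!is.finite(comp[nm]))
      stop("non-finite ", nm, " loss")
  list(total = total$value, components = comp,
       graph = g, total_node = total)
}

# decode RPN outputs into scored proposal boxes (values only)
make_proposals <- function(rpn, anchors, S, pre_nms, post_nms) {
  scores <- unlist(lapply(rpn, function(r) as.numeric(r$obj$value)),
                   use.names = FALSE)
  deltas <- do.call(rbind, lapply(rpn, function(r) {
    fd <- dim(r$box$value)
    matrix(r$box$value, fd[1L] * fd[2L], 4L)
  }))
  all_anchors <- do.call(rbind, anchors)
  keep <- order(scores, decreasing = TRUE)[seq_len(min(pre_nms,
                                                       length(scores)))]
  boxes <- box_clip(box_decode(all_anchors[keep, , drop = FALSE],
                               deltas[keep, , drop = FALSE]), S, S)
  ok <- (boxes[, 3L] - boxes[, 1L]) >= 2 & (boxes[, 4L] - boxes[, 2L]) >= 2
  boxes <- boxes[ok, , drop = FALSE]
  sc <- scores[keep][ok]
  if (!nrow(boxes)) return(list(boxes = boxes, scores = sc))
  k <- nms_boxes(boxes, sc, 0.7)
  k <- k[seq_len(min(post_nms, length(k)))]
  list(boxes = boxes[k, , drop = FALSE], scores = sc[k])
}

# bilinear crop of a binary ground-truth raster to a box, resampled to
# an out x out target in [0, 1] then binarised
crop_mask_to_box <- function(raster, box, out) {
  H <- nrow(raster); W <- ncol(raster)
  r0 <- max(0L, floor(box[1L])); c0 <- max(0L, floor(box[2L]))
  r1 <- min(H, ceiling(box[3L])); c1 <- min(W, ceiling(box[4L]))
  if (r1 - r0 < 1L || c1 - c0 < 1L) return(matrix(0, out, out))
  sub <- raster[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE] * 1
  (bilinear_resize_cpp(sub, out, out) > 0.5) * 1
}

## ---- prediction ----

#' Segment neurons in a fused image
#'
#' Runs the detector: region proposals from the RPN, classification and
#' box refinement, non-maximum suppression, then per-detection mask
#' prediction pasted back into image coordinates. Deterministic given the
#' model (no RNG is consumed).
#'
#' @param object a `caimseg_model`.
#' @param image `H x W` matrix in `[0, 1]` (e.g. a [fuse_images()]
#'   result), no larger than the configured input size — tile larger
#'   images with [make_grid()].
#' @param score_threshold optional override of the config threshold.
#' @param ... unused.
#' @return an object of class `caimseg_detections`: list with `masks` (a
#'   [mask_set()]), `boxes`, `scores`.
#' @export
predict.caimseg_model <- function(object, image,
                                  score_threshold = NULL, ...) {
  model <- object
  cfg <- model$config
  if (is.null(score_threshold)) score_threshold <- cfg$score_threshold
  H0 <- nrow(image); W0 <- ncol(image)
  img <- prepare_input(model, image)
  S <- cfg$input_size
  g <- ag_new(model$params)
  pyramid <- forward_pyramid(g, model, img)
  rpn <- rpn_heads(g, pyramid)
  strides <- model$strides
  scales <- cfg$anchor_scales[seq_along(strides)]
  anchors <- lapply(seq_along(strides), function(l) {
    fd <- dim(pyramid[[l]]$value)
    anchor_boxes(fd[1L], fd[2L], strides[l], scales[l])
  })
  prop <- make_proposals(rpn, anchors, S, pre_nms = 300L, post_nms = 100L)
  empty <- function() structure(list(masks = mask_set(list(), c(H0, W0)),
                                     boxes = matrix(0, 0L, 4L),
                                     scores = numeric()),
                                class = "caimseg_detections")
  if (!nrow(prop$boxes)) return(empty())
  pooled <- roi_align_multilevel(g, pyramid, strides, scales, prop$boxes, 7L)
  flat <- ag_flatten_rois(g, pooled)
  h <- ag_relu(g, ag_fc(g, flat, "head.box.fc1.W", "head.box.fc1.b"))
  cls <- ag_fc(g, h, "head.box.cls.W", "head.box.cls.b")$value
  pr <- exp(cls - apply(cls, 1L, max))
  pr <- pr / rowSums(pr)
  fg_prob <- pr[, 2L]
  reg <- ag_fc(g, h, "head.box.reg.W", "head.box.reg.b")$value
  keep <- which(fg_prob >= score_threshold)
  if (!length(keep)) return(empty())
  refined <- box_clip(box_decode(prop$boxes[keep, , drop = FALSE],
                                 reg[keep, , drop = FALSE]), S, S)
  sc <- fg_prob[keep]
  ok <- (refined[, 3L] - refined[, 1L]) >= 2 &
        (refined[, 4L] - refined[, 2L]) >= 2
  refined <- refined[ok, , drop = FALSE]; sc <- sc[ok]
  if (!nrow(refined)) return(empty())
  k <- nms_boxes(refined, sc, 0.5)
  k <- k[seq_len(min(cfg$max_instances, length(k)))]
  refined <- refined[k, , drop = FALSE]; sc <- sc[k]
  mp <- roi_align_multilevel(g, pyramid, strides, scales, refined, 14L)
  m <- ag_relu(g, ag_conv2d_batch(g, mp, "head.mask.conv1.W",
                                  "head.mask.conv1.b"))
  m <- ag_relu(g, ag_conv2d_batch(g, m, "head.mask.conv2.W",
                                  "head.mask.conv2.b"))
  m <- ag_upsample2_batch(g, m)
  m <- ag_relu(g, ag_conv2d_batch(g, m, "head.mask.conv3.W",
                                  "head.mask.conv3.b"))
  mlogits <- ag_conv2d_batch(g, m, "head.mask.out.W", "head.mask.out.b")$value
  masks <- list(); boxes <- list(); scores <- numeric()
  for (i in seq_len(nrow(refined))) {
    b <- refined[i, ]
    r0 <- max(0L, as.integer(floor(b[1L])))
    c0 <- max(0L, as.integer(floor(b[2L])))
    r1 <- min(H0, as.integer(ceiling(b[3L])))
    c1 <- min(W0, as.integer(ceiling(b[4L])))
    if (r1 - r0 < 1L || c1 - c0 < 1L) next
    prob <- 1 / (1 + exp(-mlogits[, , 1L, i]))
    up <- bilinear_resize_cpp(prob, r1 - r0, c1 - c0)
    bin <- up >= 0.5
    if (!any(bin)) next
    px <- which(bin, arr.ind = TRUE)
    masks[[length(masks) + 1L]] <-
      cbind(row = px[, 1L] - 1L + r0, col = px[, 2L] - 1L + c0)
    boxes[[length(boxes) + 1L]] <- c(r0, c0, r1, c1)
    scores <- c(scores, sc[i])
  }
  structure(list(masks = mask_set(masks, c(H0, W0)),
                 boxes = if (length(boxes)) do.call(rbind, boxes)
                         else matrix(0, 0L, 4L),
                 scores = scores),
            class = "caimseg_detections")
}

#' @export
print.caimseg_detections <- function(x, ...) {
  cat(sprintf("caimseg_detections: %d neuron(s)", length(x$masks$masks)))
  if (length(x$scores))
    cat(sprintf(", scores %.2f-%.2f", min(x$scores), max(x$scores)))
  cat("\n")
  invisible(x)
}
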