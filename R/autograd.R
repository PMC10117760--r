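# Minimal reverse-mode automatic differentiation on a linear tape.
#
# A graph holds the parameter store (named list of arrays) and a list of
# nodes in creation order. Each node is an environment with a value, its
# parent nodes and a backward closure that maps the node's output gradient
# to a list of parent gradients (closures capture whatever forward caches
# they need). ag_backward walks the tape in reverse and accumulates
# parameter gradients by name. Sizes in this package are small (feature
# maps of a few thousand elements, tens of ROIs), so plain R arrays plus
# BLAS matmul and a few Rcpp kernels are entirely adequate.

ag_new <- function(params) {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 512L)
  g$n <- 0L
  g$params <- params
  g
}

ag_push <- function(g, value, parents = list(), backward = NULL,
                    param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  nd$param <- param
  g$n <- g$n + 1L
  if (g$n > length(g$nodes))
    g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  g$nodes[[g$n]] <- nd
  nd
}

ag_const <- function(g, value) ag_push(g, value)

ag_param <- function(g, name) {
  v <- g$params[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  ag_push(g, v, param = name)
}

# backpropagate from a scalar loss node; returns named list of parameter
# gradients
ag_backward <- function(g, loss) {
  loss$grad <- 1
  grads <- list()
  for (i in seq.int(g$n, 1L)) {
    nd <- g$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      grads[[nd$param]] <- if (is.null(grads[[nd$param]])) nd$grad
                           else grads[[nd$param]] + nd$grad
    }
    if (is.null(nd$backward)) next
    pg <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (j > length(pg) || is.null(pg[[j]])) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
  }
  grads
}

## ---- tensor ops (H, W, C) ----

ag_conv2d <- function(g, x, wname, bname, stride = 1L, pad = NULL) {
  Wp <- ag_param(g, wname)
  bp <- ag_param(g, bname)
  wd <- dim(Wp$value)                     # kh, kw, cin, cout
  if (is.null(pad)) pad <- (wd[1L] - 1L) %/% 2L
  xd <- dim(x$value)
  stopifnot(xd[3L] == wd[3L])
  cols <- im2col_cpp(x$value, xd[1L], xd[2L], xd[3L], wd[1L], wd[2L],
                     stride, pad)
  Wm <- matrix(Wp$value, wd[1L] * wd[2L] * wd[3L], wd[4L])
  Ho <- (xd[1L] + 2L * pad - wd[1L]) %/% stride + 1L
  Wo <- (xd[2L] + 2L * pad - wd[2L]) %/% stride + 1L
  outm <- crossprod(Wm, cols) + bp$value  # cout x P, bias recycles per row
  val <- array(t(outm), c(Ho, Wo, wd[4L]))
  ag_push(g, val, list(x, Wp, bp), function(dout) {
    dm <- matrix(dout, Ho * Wo, wd[4L])   # P x cout
    dcols <- Wm %*% t(dm)
    dx <- col2im_cpp(dcols, xd[1L], xd[2L], xd[3L], wd[1L], wd[2L],
                     stride, pad)
    dW <- array(cols %*% dm, wd)
    list(dx, dW, colSums(dm))
  })
}

ag_relu <- function(g, x) {
  keep <- x$value > 0
  ag_push(g, x$value * keep, list(x), function(d) list(d * keep))
}

ag_add <- function(g, a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ag_push(g, a$value + b$value, list(a, b), function(d) list(d, d))
}

ag_concat_c <- function(g, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:2] == db[1:2]))
  val <- array(c(a$value, b$value), c(da[1L], da[2L], da[3L] + db[3L]))
  ag_push(g, val, list(a, b), function(d) {
    list(d[, , seq_len(da[3L]), drop = FALSE],
         d[, , da[3L] + seq_len(db[3L]), drop = FALSE])
  })
}

ag_upsample2 <- function(g, x) {
  xd <- dim(x$value)
  val <- x$value[rep(seq_len(xd[1L]), each = 2L),
                 rep(seq_len(xd[2L]), each = 2L), , drop = FALSE]
  ag_push(g, val, list(x), function(d) {
    o <- d[seq(1L, 2L * xd[1L], 2L), , , drop = FALSE] +
         d[seq(2L, 2L * xd[1L], 2L), , , drop = FALSE]
    list(o[, seq(1L, 2L * xd[2L], 2L), , drop = FALSE] +
         o[, seq(2L, 2L * xd[2L], 2L), , drop = FALSE])
  })
}

# global average pooling to a channel vector
ag_gap <- function(g, x) {
  xd <- dim(x$value)
  n <- xd[1L] * xd[2L]
  val <- colMeans(matrix(x$value, n, xd[3L]))
  ag_push(g, val, list(x), function(d) {
    list(array(rep(d / n, each = n), xd))
  })
}

# global max pooling to a channel vector (used by the CBAM arm)
ag_gmp <- function(g, x) {
  xd <- dim(x$value)
  m <- matrix(x$value, xd[1L] * xd[2L], xd[3L])
  amax <- max.col(t(m), ties.method = "first")
  val <- m[cbind(amax, seq_len(xd[3L]))]
  ag_push(g, val, list(x), function(d) {
    dm <- matrix(0, xd[1L] * xd[2L], xd[3L])
    dm[cbind(amax, seq_len(xd[3L]))] <- d
    list(array(dm, xd))
  })
}

# zero-padded (non-circular) same-size 1D convolution over a channel
# vector; no bias
ag_conv1d <- function(g, v, wname) {
  wp <- ag_param(g, wname)
  k <- length(wp$value)
  stopifnot(k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  C <- length(v$value)
  vp <- c(rep(0, p), v$value, rep(0, p))
  M <- t(vapply(seq_len(C), function(c) vp[c:(c + k - 1L)], numeric(k)))
  val <- as.numeric(M %*% wp$value)
  w <- wp$value
  ag_push(g, val, list(v, wp), function(d) {
    dv <- numeric(C + 2L * p)
    for (j in seq_len(k)) {
      idx <- seq_len(C) + j - 1L
      dv[idx] <- dv[idx] + w[j] * d
    }
    list(dv[(p + 1L):(p + C)], as.numeric(crossprod(M, d)))
  })
}

ag_sigmoid <- function(g, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_push(g, s, list(x), function(d) list(d * s * (1 - s)))
}

# multiply each channel of x by the matching entry of vector node s
ag_scale_channels <- function(g, x, s) {
  xd <- dim(x$value)
  stopifnot(length(s$value) == xd[3L])
  val <- x$value * rep(s$value, each = xd[1L] * xd[2L])
  xv <- x$value; sv <- s$value
  ag_push(g, val, list(x, s), function(d) {
    list(d * rep(sv, each = xd[1L] * xd[2L]),
         colSums(matrix(d * xv, xd[1L] * xd[2L], xd[3L])))
  })
}

# multiply every channel of x by a 1-channel spatial map m (H, W, 1)
ag_scale_spatial <- function(g, x, m) {
  xd <- dim(x$value)
  mm <- array(m$value[, , 1L], xd[1:2])
  val <- x$value * as.vector(mm)
  xv <- x$value
  ag_push(g, val, list(x, m), function(d) {
    dm <- rowSums(matrix(d * xv, xd[1L] * xd[2L], xd[3L]))
    list(d * as.vector(mm), array(dm, c(xd[1L], xd[2L], 1L)))
  })
}

ag_add_vec <- function(g, a, b) {
  ag_push(g, a$value + b$value, list(a, b), function(d) list(d, d))
}

ag_relu_vec <- ag_relu
ag_sigmoid_vec <- ag_sigmoid

## ---- matrix (fully connected) ops ----

ag_fc <- function(g, x, wname, bname) {
  Wp <- ag_param(g, wname)
  bp <- ag_param(g, bname)
  X <- x$value
  if (is.null(dim(X))) X <- matrix(X, 1L)
  val <- X %*% Wp$value + matrix(bp$value, nrow(X), length(bp$value),
                                 byrow = TRUE)
  W <- Wp$value
  ag_push(g, val, list(x, Wp, bp), function(d) {
    list(d %*% t(W), crossprod(X, d), colSums(d))
  })
}

# (S, S, C, n) -> n x (S*S*C) with rows aligned to ROIs
ag_flatten_rois <- function(g, x) {
  xd <- dim(x$value)
  D <- prod(xd[1:3])
  val <- t(matrix(x$value, D, xd[4L]))
  ag_push(g, val, list(x), function(d) list(array(t(d), xd)))
}

ag_take_rows <- function(g, x, rows) {
  xd <- dim(x$value)
  val <- x$value[rows, , drop = FALSE]
  ag_push(g, val, list(x), function(d) {
    z <- array(0, xd)
    z[rows, ] <- d
    list(z)
  })
}

# take a flat index subset of an array node; idx must be duplicate-free
ag_take <- function(g, x, idx) {
  xd <- dim(x$value)
  if (is.null(xd)) xd <- length(x$value)
  val <- x$value[idx]
  ag_push(g, val, list(x), function(d) {
    z <- array(0, xd)
    z[idx] <- d
    list(z)
  })
}

ag_cat_vec <- function(g, nodes) {
  lens <- vapply(nodes, function(n) length(n$value), integer(1))
  val <- unlist(lapply(nodes, `[[`, "value"), use.names = FALSE)
  ends <- cumsum(lens)
  ag_push(g, val, nodes, function(d) {
    lapply(seq_along(nodes), function(i)
      d[(ends[i] - lens[i] + 1L):ends[i]])
  })
}

ag_rbind <- function(g, nodes) {
  rows <- vapply(nodes, function(n) nrow(n$value), integer(1))
  val <- do.call(rbind, lapply(nodes, `[[`, "value"))
  ends <- cumsum(rows)
  ag_push(g, val, nodes, function(d) {
    lapply(seq_along(nodes), function(i)
      d[(ends[i] - rows[i] + 1L):ends[i], , drop = FALSE])
  })
}

# concatenate (S, S, C, n_i) blocks along the 4th dim
ag_cat4 <- function(g, nodes) {
  ns <- vapply(nodes, function(n) dim(n$value)[4L], integer(1))
  d1 <- dim(nodes[[1L]]$value)
  val <- array(unlist(lapply(nodes, `[[`, "value"), use.names = FALSE),
               c(d1[1:3], sum(ns)))
  ends <- cumsum(ns)
  ag_push(g, val, nodes, function(d) {
    lapply(seq_along(nodes), function(i)
      d[, , , (ends[i] - ns[i] + 1L):ends[i], drop = FALSE])
  })
}

# reorder ROIs along the 4th dim (inverse permutation handled in backward)
ag_perm4 <- function(g, x, ord) {
  val <- x$value[, , , ord, drop = FALSE]
  inv <- order(ord)
  ag_push(g, val, list(x), function(d) list(d[, , , inv, drop = FALSE]))
}

ag_roi_align <- function(g, feat, rois, S) {
  fd <- dim(feat$value)
  rois <- matrix(as.numeric(rois), ncol = 4L)
  val <- roi_align_cpp(feat$value, fd[1L], fd[2L], fd[3L], rois, S)
  ag_push(g, val, list(feat), function(d) {
    list(roi_align_back_cpp(d, fd[1L], fd[2L], fd[3L], rois, S))
  })
}

# batched conv over (S, S, C, n): shared weights, per-ROI im2col
ag_conv2d_batch <- function(g, x, wname, bname, stride = 1L, pad = NULL) {
  Wp <- ag_param(g, wname)
  bp <- ag_param(g, bname)
  wd <- dim(Wp$value)
  if (is.null(pad)) pad <- (wd[1L] - 1L) %/% 2L
  xd <- dim(x$value)
  n <- xd[4L]
  Wm <- matrix(Wp$value, wd[1L] * wd[2L] * wd[3L], wd[4L])
  Ho <- (xd[1L] + 2L * pad - wd[1L]) %/% stride + 1L
  Wo <- (xd[2L] + 2L * pad - wd[2L]) %/% stride + 1L
  cols_list <- lapply(seq_len(n), function(i)
    im2col_cpp(x$value[, , , i, drop = TRUE], xd[1L], xd[2L], xd[3L],
               wd[1L], wd[2L], stride, pad))
  cols <- do.call(cbind, cols_list)          # rows x (P*n), ROI-major cols
  outm <- crossprod(Wm, cols) + bp$value     # cout x (P*n)
  # columns are ordered p within i; reshape to (Ho, Wo, n, cout) then move n last
  val <- aperm(array(t(outm), c(Ho, Wo, n, wd[4L])), c(1L, 2L, 4L, 3L))
  P <- Ho * Wo
  ag_push(g, val, list(x, Wp, bp), function(dout) {
    dm <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), P * n, wd[4L])
    dcols <- Wm %*% t(dm)
    dx <- array(0, xd)
    for (i in seq_len(n))
      dx[, , , i] <- col2im_cpp(dcols[, ((i - 1L) * P + 1L):(i * P),
                                      drop = FALSE],
                                xd[1L], xd[2L], xd[3L], wd[1L], wd[2L],
                                stride, pad)
    dW <- array(cols %*% dm, wd)
    list(dx, dW, colSums(dm))
  })
}

ag_upsample2_batch <- function(g, x) {
  xd <- dim(x$value)
  val <- x$value[rep(seq_len(xd[1L]), each = 2L),
                 rep(seq_len(xd[2L]), each = 2L), , , drop = FALSE]
  ag_push(g, val, list(x), function(d) {
    o <- d[seq(1L, 2L * xd[1L], 2L), , , , drop = FALSE] +
         d[seq(2L, 2L * xd[1L], 2L), , , , drop = FALSE]
    list(o[, seq(1L, 2L * xd[2L], 2L), , , drop = FALSE] +
         o[, seq(2L, 2L * xd[2L], 2L), , , drop = FALSE])
  })
}

## ---- losses (scalar-valued nodes) ----

ag_bce_logits <- function(g, x, target) {
  xv <- x$value
  n <- length(xv)
  l <- pmax(xv, 0) - xv * target + log1p(exp(-abs(xv)))
  ag_push(g, mean(l), list(x), function(d) {
    list(d * (1 / (1 + exp(-xv)) - target) / n)
  })
}

ag_softmax_ce <- function(g, logits, labels) {
  X <- logits$value
  n <- nrow(X)
  Z <- X - apply(X, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  val <- -mean(log(pmax(P[cbind(seq_len(n), labels)], 1e-12)))
  ag_push(g, val, list(logits), function(d) {
    G <- P
    G[cbind(seq_len(n), labels)] <- G[cbind(seq_len(n), labels)] - 1
    list(d * G / n)
  })
}

ag_smooth_l1 <- function(g, x, target) {
  dv <- x$value - target
  n <- length(dv)
  l <- ifelse(abs(dv) < 1, 0.5 * dv^2, abs(dv) - 0.5)
  ag_push(g, mean(l), list(x), function(d) {
    list(d * pmax(pmin(dv, 1), -1) / n)
  })
}

# weighted sum of scalar nodes
ag_wsum <- function(g, nodes, weights = rep(1, length(nodes))) {
  val <- sum(vapply(seq_along(nodes), function(i)
    weights[i] * nodes[[i]]$value, numeric(1)))
  ag_push(g, val, nodes, function(d)
    lapply(weights, function(w) d * w))
}

ag_zero_scalar <- function(g) ag_const(g, 0)
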