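# Independent oracles used to freeze expected values; each is a direct,
# unoptimised restatement of the defining formula, sharing no code with
# the implementation it checks.

# per-pixel mean by explicit loop-and-sum
oracle_average <- function(video) {
  d <- dim(video)
  out <- matrix(0, d[2L], d[3L])
  for (r in seq_len(d[2L])) for (c in seq_len(d[3L])) {
    s <- 0
    for (t in seq_len(d[1L])) s <- s + video[t, r, c]
    out[r, c] <- s / d[1L]
  }
  out
}

# weighted correlation c_w at a single pixel by direct neighbourhood loop
oracle_cw <- function(video, r, c, radius, sigma, center) {
  d <- dim(video)
  num <- numeric(d[1L]); den <- 0
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > d[2L] || cc < 1 || cc > d[3L]) next
    w <- if (is.infinite(sigma)) 1 else exp(-(dr^2 + dc^2) / (2 * sigma^2))
    f <- video[, rr, cc]
    if (center) f <- f - mean(f)
    num <- num + w * f
    den <- den + w * sqrt(sum(f^2))
  }
  if (den == 0) 0 else sqrt(sum(num^2)) / den
}

# exhaustive minimum-cost assignment over all permutations (n <= 6)
oracle_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 6L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf; best_a <- NULL
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best) { best <- tot; best_a <- p }
    }
  }
  list(cost = best, assignment = best_a)
}

# ECA forward by explicit GAP -> sliding-window conv -> logistic -> scale
oracle_eca <- function(feature, weights) {
  d <- dim(feature)
  C <- d[3L]; k <- length(weights); p <- (k - 1L) / 2L
  gap <- vapply(seq_len(C), function(c) mean(feature[, , c]), numeric(1))
  padded <- c(rep(0, p), gap, rep(0, p))
  conv <- vapply(seq_len(C), function(c)
    sum(padded[c:(c + k - 1L)] * weights), numeric(1))
  gate <- 1 / (1 + exp(-conv))
  out <- feature
  for (c in seq_len(C)) out[, , c] <- feature[, , c] * gate[c]
  out
}

mask_to_binary_test <- function(m, shape) {
  r <- matrix(FALSE, shape[1L], shape[2L])
  r[cbind(m[, 1L] + 1L, m[, 2L] + 1L)] <- TRUE
  r
}

random_mask_set <- function(n, shape, seed) {
  set.seed(seed)
  masks <- lapply(seq_len(n), function(i) {
    cy <- sample(3:(shape[1L] - 4L), 1L)
    cx <- sample(3:(shape[2L] - 4L), 1L)
    r <- sample(2:3, 1L)
    px <- expand.grid(row = (cy - r):(cy + r), col = (cx - r):(cx + r))
    d <- sqrt((px$row - cy)^2 + (px$col - cx)^2)
    as.matrix(px[d <= r, ])
  })
  mask_set(masks, shape)
}
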