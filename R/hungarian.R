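# Minimum-cost one-to-one assignment (Hungarian algorithm), implemented as
# shortest augmenting paths with dual potentials (Jonker-Volgenant style),
# O(n^2 m). Rows are assigned one column each; requires nrow <= ncol (the
# caller transposes if needed). All costs must be finite.
#
# Returns an integer vector a with a[i] = column assigned to row i.
lsap_solve <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  INF <- Inf
  # potentials u (rows, 1..n) and v (cols, 1..m); way[j] = previous column
  # on the alternating path; matched[j] = row matched to column j (0 = free)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  matched <- integer(m + 1L)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    # dummy column 0 holds the row being inserted
    matched[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- matched[j0 + 1L]
      delta <- INF
      j1 <- 0L
      cr <- cost[i0, ]
      cur <- cr - u[i0 + 0L] - v[2L:(m + 1L)]
      upd <- !used[2L:(m + 1L)] & cur < minv
      if (any(upd)) {
        minv[upd] <- cur[upd]
        way[which(upd) + 1L] <- j0
      }
      free_j <- which(!used[2L:(m + 1L)])
      if (length(free_j)) {
        k <- free_j[which.min(minv[free_j])]
        delta <- minv[k]
        j1 <- k
      }
      # update potentials
      for (j in 0L:m) {
        if (used[j + 1L]) {
          u[matched[j + 1L]] <- u[matched[j + 1L]] + delta
          if (j > 0L) v[j + 1L] <- v[j + 1L] - delta
        }
      }
      minv[!used[2L:(m + 1L)]] <- minv[!used[2L:(m + 1L)]] - delta
      j0 <- j1
      if (matched[j0 + 1L] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0 + 1L]
      matched[j0 + 1L] <- matched[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (matched[j + 1L] > 0L) assign[matched[j + 1L]] <- j
  assign
}

# u indexing note: u is addressed by row id (1..n); u[i0 + 0L] keeps the
# expression symmetric with the 1-based offset used for v and matched.
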