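# Independent oracles used across the suite. These deliberately avoid the
# package's own canonicalization / graph machinery: orbits are computed on
# rendered coordinates, grid distances by a standalone Dijkstra, and
# regression coefficients by closed-form normal equations.

# draw m random id sequences of length len (matrix m x len)
sample_segment_matrix <- function(m, len, seed) {
  withr::with_seed(seed, {
    matrix(sample(0:15, m * len, replace = TRUE), nrow = m)
  })
}

# geometric orbit signature of a spec: minimal string over the 8 point
# symmetries applied to the rendered trajectory coordinates
oracle_orbit_signature <- function(segments, fpp = 4L) {
  pts <- effcomm:::.traj_points(path_spec(segments), fpp)
  mats <- list(
    matrix(c(1, 0, 0, 1), 2), matrix(c(0, 1, -1, 0), 2),
    matrix(c(-1, 0, 0, -1), 2), matrix(c(0, -1, 1, 0), 2),
    matrix(c(1, 0, 0, -1), 2), matrix(c(-1, 0, 0, 1), 2),
    matrix(c(0, 1, 1, 0), 2), matrix(c(0, -1, -1, 0), 2)
  )
  sigs <- vapply(mats, function(M) {
    q <- pts %*% t(M)
    paste(sprintf("%.6f", as.numeric(t(q))), collapse = ",")
  }, character(1))
  min(sigs)
}

# Dijkstra over an 8-connected cell grid, written independently of igraph:
# simple O(V^2) scan, adequate for the coarse oracle grids used in tests.
oracle_grid_distance <- function(blocked, h, from_cell, to_cell) {
  nx <- nrow(blocked); ny <- ncol(blocked)
  dist <- matrix(Inf, nx, ny)
  done <- matrix(FALSE, nx, ny)
  dist[from_cell[1], from_cell[2]] <- 0
  offs <- rbind(c(1, 0, h), c(-1, 0, h), c(0, 1, h), c(0, -1, h),
                c(1, 1, h * sqrt(2)), c(1, -1, h * sqrt(2)),
                c(-1, 1, h * sqrt(2)), c(-1, -1, h * sqrt(2)))
  repeat {
    d <- dist; d[done] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    ui <- (u - 1L) %% nx + 1L; uj <- (u - 1L) %/% nx + 1L
    done[ui, uj] <- TRUE
    if (ui == to_cell[1] && uj == to_cell[2]) break
    for (k in seq_len(nrow(offs))) {
      vi <- ui + offs[k, 1]; vj <- uj + offs[k, 2]
      if (vi >= 1 && vi <= nx && vj >= 1 && vj <= ny &&
          !blocked[vi, vj] && !done[vi, vj]) {
        alt <- dist[ui, uj] + offs[k, 3]
        if (alt < dist[vi, vj]) dist[vi, vj] <- alt
      }
    }
  }
  dist[to_cell[1], to_cell[2]]
}

# closed-form simple-regression coefficients (normal equations)
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# shared across expensive tests: one study-1 set and rarity predictor
study1_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_study1_set(7)
    cache
  }
})
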