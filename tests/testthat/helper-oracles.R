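# Independent brute-force oracles. These deliberately re-derive results
# with naive algorithms (queue-based BFS, triple loops, bisection) so that
# the package's implementations are checked against a different code path.

# 26-connected component of TRUE voxels containing `seed`, by BFS
oracle_component_26 <- function(fg, seed) {
  d <- dim(fg)
  seen <- array(FALSE, d)
  queue <- list(seed)
  if (!fg[seed[1], seed[2], seed[3]]) return(seen)
  seen[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      u <- v + c(di, dj, dk)
      if (any(u < 1) || any(u > d)) next
      if (fg[u[1], u[2], u[3]] && !seen[u[1], u[2], u[3]]) {
        seen[u[1], u[2], u[3]] <- TRUE
        queue[[length(queue) + 1]] <- u
      }
    }
  }
  seen
}

# hole filling oracle: 6-connected BFS over background from all exterior
# face voxels; unreached background = holes
oracle_fill_holes <- function(fg) {
  d <- dim(fg)
  reach <- array(FALSE, d)
  queue <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if ((i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3]) &&
        !fg[i, j, k] && !reach[i, j, k]) {
      reach[i, j, k] <- TRUE
      queue[[length(queue) + 1]] <- c(i, j, k)
    }
  }
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (s in 1:6) {
      u <- v + steps[s, ]
      if (any(u < 1) || any(u > d)) next
      if (!fg[u[1], u[2], u[3]] && !reach[u[1], u[2], u[3]]) {
        reach[u[1], u[2], u[3]] <- TRUE
        queue[[length(queue) + 1]] <- u
      }
    }
  }
  fg | (!fg & !reach)
}

# triple-loop scaled Laplacian with replicate padding
oracle_laplacian <- function(vox, w) {
  d <- dim(vox)
  out <- array(0, d)
  clamp <- function(x, n) pmin(pmax(x, 1L), n)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      acc <- acc + w[di + 2, dj + 2, dk + 2] *
        vox[clamp(i + di, d[1]), clamp(j + dj, d[2]), clamp(k + dk, d[3])]
    }
    out[i, j, k] <- vox[i, j, k] - acc
  }
  out
}

# Clopper-Pearson endpoints by bisection on the binomial tail conditions
oracle_cp_ci <- function(x, n, level = 0.95, tol = 1e-12) {
  a <- (1 - level) / 2
  bisect <- function(f, lo, hi) {
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - a, 0, x / n)
  upper <- if (x == n) 1 else
    bisect(function(p) a - stats::pbinom(x, n, p), x / n, 1)
  c(lower = lower, upper = upper)
}

# voxel indices of a ball of radius r_mm on a grid
oracle_ball_indices <- function(r_mm, spacing, shape) {
  g <- as.matrix(expand.grid(i = 1:shape[1], j = 1:shape[2], k = 1:shape[3]))
  ctr <- (shape - 1) * spacing / 2
  pts <- sweep(g - 1, 2, spacing, `*`)
  g[rowSums(sweep(pts, 2, ctr)^2) <= r_mm^2, , drop = FALSE]
}
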