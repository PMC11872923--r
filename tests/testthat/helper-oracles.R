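# Independent brute-force oracles used across the suite. These deliberately
# use naive algorithms (double loops, enumeration, dense grids) so they stay
# independent of the implementation paths they check.

# Sholl: walk every edge x every radius
oracle_sholl_counts <- function(m, radii, types = "dendrite") {
  s <- m[m$parent == -1L, ]
  idx <- match(m$parent, m$id)
  counts <- integer(length(radii))
  for (i in seq_len(nrow(m))) {
    if (is.na(idx[i])) next
    if (!(m$type[i] %in% c(3L))) next
    r1 <- sqrt((m$x[i] - s$x)^2 + (m$y[i] - s$y)^2 + (m$z[i] - s$z)^2)
    p <- idx[i]
    r0 <- sqrt((m$x[p] - s$x)^2 + (m$y[p] - s$y)^2 + (m$z[p] - s$z)^2)
    lo <- min(r0, r1); hi <- max(r0, r1)
    for (k in seq_along(radii))
      if (lo < radii[k] && hi >= radii[k]) counts[k] <- counts[k] + 1L
  }
  counts
}

# Density map: per-pixel double loop over edges
oracle_density_map <- function(m, x, y, sigma, types = "dendrite") {
  idx <- match(m$parent, m$id)
  g <- matrix(0, nrow = length(y), ncol = length(x))
  for (i in seq_len(nrow(m))) {
    if (is.na(idx[i]) || m$type[i] != 3L) next
    p <- idx[i]
    mx <- (m$x[i] + m$x[p]) / 2; my <- (m$y[i] + m$y[p]) / 2
    len <- sqrt((m$x[i] - m$x[p])^2 + (m$y[i] - m$y[p])^2 + (m$z[i] - m$z[p])^2)
    for (r in seq_along(y)) for (c in seq_along(x))
      g[r, c] <- g[r, c] +
        len * exp(-((x[c] - mx)^2 + (y[r] - my)^2) / (2 * sigma^2))
  }
  g
}

# Convex hull by O(n^3) edge test: a directed pair (i, j) is a hull edge iff
# every other point lies strictly left of line i->j, or collinear and within
# the segment. Edge-interior collinear points never qualify as edge
# endpoints, so the unique endpoints are exactly the hull vertices.
oracle_hull_vertices <- function(p) {
  n <- nrow(p)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- TRUE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cr <- (p[j, 1] - p[i, 1]) * (p[k, 2] - p[i, 2]) -
        (p[j, 2] - p[i, 2]) * (p[k, 1] - p[i, 1])
      if (cr < -1e-12) { ok <- FALSE; break }
      if (abs(cr) <= 1e-12) {
        d_ij <- sum((p[j, ] - p[i, ])^2)
        t_k <- sum((p[k, ] - p[i, ]) * (p[j, ] - p[i, ])) / d_ij
        if (t_k < -1e-12 || t_k > 1 + 1e-12) { ok <- FALSE; break }
      }
    }
    if (ok) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
  }
  sort(which(on_hull))
}

# Segment-segment minimum distance by dense parameter grid + local refinement
oracle_segseg_dist <- function(p0, p1, q0, q1, ngrid = 200) {
  ss <- seq(0, 1, length.out = ngrid)
  tt <- seq(0, 1, length.out = ngrid)
  P <- outer(ss, rep(1, ngrid))
  best <- Inf
  for (s in ss) {
    a <- p0 + s * (p1 - p0)
    d2 <- colSums((outer(q1 - q0, tt) + (q0 - a))^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# dG/R pixelwise oracle following the definition arithmetic directly
oracle_dgr_linescan <- function(movie, roi, background, baseline_window) {
  tms <- (seq_len(nrow(movie$green)) - 1) * movie$ms_per_line
  bidx <- tms >= baseline_window[1] & tms < baseline_window[2]
  val <- function(mask) {
    G <- movie$green[, mask, drop = FALSE]
    R <- movie$red[, mask, drop = FALSE]
    g <- apply(G, 1, mean)
    (g - mean(g[bidx])) / mean(apply(R, 1, mean)[bidx])
  }
  val(roi) - val(background)
}

# Wilcoxon signed-rank exact p by explicit enumeration over sign patterns
oracle_wilcoxon_exact <- function(x, mu0 = 0, alternative = "greater") {
  d <- x - mu0
  r_all <- rank(abs(d))
  nz <- which(d != 0)
  rk <- r_all[nz]
  n <- length(nz)
  W_obs <- sum(rk[d[nz] > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% rk)
  switch(alternative,
         greater = mean(W_all >= W_obs - 1e-12),
         less = mean(W_all <= W_obs + 1e-12),
         two.sided = min(1, 2 * min(mean(W_all >= W_obs - 1e-12),
                                    mean(W_all <= W_obs + 1e-12))))
}

# one-way balanced random-intercept variance components by ANOVA moments
oracle_oneway_varcomp <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g); n <- length(y) / k
  gm <- tapply(y, g, mean)
  msb <- n * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[g])^2) / (k * (n - 1))
  c(between = (msb - msw) / n, within = msw)
}

# random small tree builder for property tests
random_tree <- function(n_nodes = 30, seed = 1) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 4, parent = -1L)
  for (i in 2:n_nodes) {
    parent <- sample(nodes$id, 1)
    p <- nodes[nodes$id == parent, ]
    nodes <- rbind(nodes, data.frame(
      id = i, type = 3L, x = p$x + rnorm(1, 0, 12), y = p$y + rnorm(1, 0, 12),
      z = p$z + rnorm(1, 0, 4), radius = 0.5, parent = parent))
  }
  morphology(nodes)
}

# balanced one-way random-intercept simulator shared by stats tests
sim_oneway <- function(k = 10, n = 6, sd_b = 1, sd_w = 0.5, seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(k), each = n))
  y <- rep(rnorm(k, 0, sd_b), each = n) + rnorm(k * n, 0, sd_w)
  data.frame(y = y, g = g)
}
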