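# Morphometry: pia-up rotation, Sholl profiles, Gaussian density maps and
# Jarvis-march convex hulls.

#' Rotate a morphology so the pial direction points up
#'
#' Rigid rotation about the soma mapping `pia_direction` onto +y. Soma
#' coordinates are unchanged and all pairwise distances are preserved.
#'
#' @param m A [morphology()].
#' @param pia_direction Numeric length-3 vector pointing towards the pia.
#' @return The rotated [morphology()].
#' @export
rotate_pia_up <- function(m, pia_direction) {
  stopifnot(inherits(m, "morphology"), length(pia_direction) == 3L)
  v <- as.numeric(pia_direction)
  nv <- sqrt(sum(v^2))
  if (nv <= 0) stopf("pia_direction must be a non-zero vector")
  v <- v / nv
  up <- c(0, 1, 0)
  R <- rotation_between(v, up)
  s <- soma_node(m)
  p0 <- c(s$x, s$y, s$z)
  xyz <- as.matrix(m[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, p0)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, p0, `+`)
  m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
  m
}

# Rotation matrix mapping unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  cth <- sum(a * b)
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    o <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    ax <- o - sum(o * a) * a
    ax <- ax / sqrt(sum(ax^2))
    K <- skew(ax)
    return(diag(3) + 2 * K %*% K)
  }
  ax <- ax / s
  K <- skew(ax)
  diag(3) + s * K + (1 - cth) * K %*% K
}

skew <- function(u) {
  matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
         nrow = 3, byrow = TRUE)
}

#' Sholl analysis
#'
#' Counts tree edges straddling concentric spheres around the soma, stepping
#' outwards at a fixed radial increment (default 6.5 um). An edge crossing k
#' radii is counted once at each. The cumulative curve is normalized to end at
#' 1 and `r75` is the interpolated radius containing 75% of crossings.
#'
#' @param m A [morphology()].
#' @param step Radial step in micrometres.
#' @param types Compartment filter (default dendrites only).
#' @return A `sholl_profile`: list with `radii`, `counts`,
#'   `cumulative_fraction`, `r75`, `step`.
#' @export
sholl <- function(m, step = 6.5, types = "dendrite") {
  stopifnot(inherits(m, "morphology"))
  assert_scalar_num(step, "step", lower = 1e-9)
  s <- soma_node(m)
  e <- morpho_edges(m, types)
  if (nrow(e) == 0L) {
    warnf("no compartments after filtering; returning zero profile")
    out <- list(radii = step, counts = 0L, cumulative_fraction = NA_real_,
                r75 = NA_real_, step = step)
    class(out) <- "sholl_profile"
    return(out)
  }
  r0 <- sqrt((e$x0 - s$x)^2 + (e$y0 - s$y)^2 + (e$z0 - s$z)^2)
  r1 <- sqrt((e$x1 - s$x)^2 + (e$y1 - s$y)^2 + (e$z1 - s$z)^2)
  rmin <- pmin(r0, r1); rmax <- pmax(r0, r1)
  radii <- seq(step, ceiling(max(rmax) / step) * step, by = step)
  counts <- vapply(radii, function(R) sum(rmin < R & rmax >= R), integer(1))
  tot <- sum(counts)
  cf <- if (tot > 0) cumsum(counts) / tot else rep(NA_real_, length(counts))
  r75 <- interp_quantile_radius(radii, cf, 0.75, step)
  out <- list(radii = radii, counts = counts, cumulative_fraction = cf,
              r75 = r75, step = step)
  class(out) <- "sholl_profile"
  out
}

interp_quantile_radius <- function(radii, cf, q, step) {
  if (all(is.na(cf))) return(NA_real_)
  i <- which(cf >= q)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) {
    lo_r <- radii[1] - step; lo_c <- 0
  } else {
    lo_r <- radii[i - 1]; lo_c <- cf[i - 1]
  }
  if (cf[i] == lo_c) return(radii[i])
  lo_r + (q - lo_c) / (cf[i] - lo_c) * (radii[i] - lo_r)
}

#' Gaussian density map of a morphology (XY projection)
#'
#' Each edge contributes a 2-D Gaussian centred on its XY midpoint with
#' amplitude proportional to its length; maps may be peak-normalized and/or
#' mirrored about the soma's vertical axis (mirrored maps are left-right
#' symmetric by construction).
#'
#' @param m A [morphology()].
#' @param sigma Gaussian width in micrometres (default 25).
#' @param pitch Grid pixel pitch in micrometres.
#' @param normalization `"peak"` or `"none"`.
#' @param mirror Sum the map with its left-right reflection.
#' @param types Compartment filter.
#' @return A `density_map`: list with `grid` (matrix, rows = y), `x`, `y`,
#'   `sigma`, `pitch`, `normalization`, `mirrored`.
#' @export
density_map <- function(m, sigma = 25, pitch = 5, normalization = c("peak", "none"),
                        mirror = FALSE, types = "dendrite") {
  stopifnot(inherits(m, "morphology"))
  assert_scalar_num(sigma, "sigma", lower = 1e-9)
  assert_scalar_num(pitch, "pitch", lower = 1e-9)
  normalization <- match.arg(normalization)
  s <- soma_node(m)
  e <- morpho_edges(m, types)
  if (nrow(e) == 0L) stopf("no compartments after filtering")
  mx <- (e$x0 + e$x1) / 2; my <- (e$y0 + e$y1) / 2
  amp <- edge_lengths(e)
  pad <- 3 * sigma
  # grid symmetric about the soma x so mirroring is exact on the grid
  half_w <- max(abs(c(mx - s$x))) + pad
  nxh <- ceiling(half_w / pitch)
  x <- s$x + seq(-nxh, nxh) * pitch
  y <- seq(floor((min(my) - pad) / pitch), ceiling((max(my) + pad) / pitch)) * pitch
  g <- matrix(0, nrow = length(y), ncol = length(x))
  for (i in seq_along(amp)) {
    gx <- exp(-((x - mx[i])^2) / (2 * sigma^2))
    gy <- exp(-((y - my[i])^2) / (2 * sigma^2))
    g <- g + amp[i] * (gy %o% gx)
  }
  if (mirror) g <- g + g[, rev(seq_len(ncol(g))), drop = FALSE]
  if (normalization == "peak") g <- g / max(g)
  out <- list(grid = g, x = x, y = y, sigma = sigma, pitch = pitch,
              normalization = normalization, mirrored = mirror)
  class(out) <- "density_map"
  out
}

#' Convex hull by Jarvis march (gift wrapping)
#'
#' Returns hull vertices in counter-clockwise order starting from the
#' lowest-then-leftmost point; collinear points interior to hull edges are
#' excluded.
#'
#' @param points Two-column matrix or data.frame of XY coordinates.
#' @return Matrix of hull vertices (CCW). For degenerate input (< 3 points or
#'   all collinear) the extreme points are returned with attribute
#'   `degenerate = TRUE`.
#' @export
convex_hull_2d <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) < 2L) stopf("points must have two columns")
  p <- unique(p[, 1:2, drop = FALSE])
  n <- nrow(p)
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  degenerate <- function(q) {
    structure(q, degenerate = TRUE)
  }
  if (n < 3L) return(degenerate(p))
  # collinearity check
  col_all <- TRUE
  for (i in 3:n) if (abs(cross2(p[1, ], p[2, ], p[i, ])) > 1e-12) { col_all <- FALSE; break }
  if (col_all) {
    d <- rowSums(sweep(p, 2, p[which.min(p[, 1] + 1e-9 * p[, 2]), ])^2)
    return(degenerate(p[c(which.min(d), which.max(d)), , drop = FALSE]))
  }
  start <- order(p[, 2], p[, 1])[1]
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (i in seq_len(n)) {
      if (i == cur || i == cand) next
      cr <- cross2(p[cur, ], p[cand, ], p[i, ])
      if (cr < -1e-12) {
        cand <- i        # i lies right of cur->cand: wrap further clockwise
      } else if (abs(cr) <= 1e-12) {
        # collinear: keep the farther point so edge-interior points drop out
        d_cand <- sum((p[cand, ] - p[cur, ])^2)
        d_i <- sum((p[i, ] - p[cur, ])^2)
        if (d_i > d_cand) cand <- i
      }
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) stopf("hull walk failed to terminate")
  }
  out <- p[hull, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}
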