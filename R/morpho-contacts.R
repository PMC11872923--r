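# Putative synaptic contact detection: closest approaches between a
# presynaptic axon and a postsynaptic dendrite, merged over a small radius so
# one apposition spanning several reconstruction nodes counts once.

#' Vectorized minimum distance between 3-D segment pairs
#'
#' Clamped closest-point computation (element i: segment P0[i]->P1[i] versus
#' Q0[i]->Q1[i]). Used by [detect_contacts()] and by brute-force test oracles.
#'
#' @param p0,p1,q0,q1 n x 3 matrices of segment endpoints.
#' @return List with `dist` (n), `cp` and `cq` (n x 3 closest points).
#' @export
segment_distance <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0; d2 <- q1 - q0; r <- p0 - q0
  a <- rowSums(d1 * d1); e <- rowSums(d2 * d2); f <- rowSums(d2 * r)
  c_ <- rowSums(d1 * r); b <- rowSums(d1 * d2)
  denom <- a * e - b * b
  s <- ifelse(denom > 1e-12, pmin(pmax((b * f - c_ * e) / denom, 0), 1), 0)
  t_ <- ifelse(e > 1e-12, (b * s + f) / e, 0)
  # re-clamp: if t was clamped, recompute s
  tlo <- t_ < 0; thi <- t_ > 1
  t_ <- pmin(pmax(t_, 0), 1)
  s <- ifelse(tlo, pmin(pmax(ifelse(a > 1e-12, -c_ / a, 0), 0), 1), s)
  s <- ifelse(thi, pmin(pmax(ifelse(a > 1e-12, (b - c_) / a, 0), 0), 1), s)
  cp <- p0 + d1 * s
  cq <- q0 + d2 * t_
  list(dist = sqrt(rowSums((cp - cq)^2)), cp = cp, cq = cq, s = s, t = t_)
}

#' Detect putative synaptic contacts between two reconstructions
#'
#' Finds all loci where a presynaptic axon edge passes within `threshold`
#' (default 2 um) of a postsynaptic dendrite edge, merging candidate loci
#' closer than `merge_radius` into a single contact at the closest approach.
#'
#' @param pair A `reconstruction_pair` (list with `pre` and `post`
#'   morphologies), or any list with those elements.
#' @param threshold Contact distance in micrometres.
#' @param merge_radius Merge radius in micrometres.
#' @return data.frame with one row per contact: `x`, `y`, `z` (midpoint of the
#'   closest approach), `min_distance`, `distance_to_soma` (radial, from the
#'   postsynaptic soma), `path_distance_to_soma` (along the dendrite), and
#'   `y_offset` (contact y minus soma y).
#' @export
detect_contacts <- function(pair, threshold = 2.0, merge_radius = 3.0) {
  pre <- pair$pre; post <- pair$post
  if (is.null(pre) || is.null(post)) stopf("pair must carry 'pre' and 'post'")
  ax <- morpho_edges(pre, "axon")
  de <- morpho_edges(post, "dendrite")
  if (nrow(ax) == 0L) stopf("presynaptic morphology has no axon")
  if (nrow(de) == 0L) stopf("postsynaptic morphology has no dendrite")
  ia <- rep(seq_len(nrow(ax)), times = nrow(de))
  id <- rep(seq_len(nrow(de)), each = nrow(ax))
  res <- segment_distance(
    cbind(ax$x0, ax$y0, ax$z0)[ia, , drop = FALSE],
    cbind(ax$x1, ax$y1, ax$z1)[ia, , drop = FALSE],
    cbind(de$x0, de$y0, de$z0)[id, , drop = FALSE],
    cbind(de$x1, de$y1, de$z1)[id, , drop = FALSE])
  hit <- which(res$dist < threshold)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      min_distance = numeric(0), distance_to_soma = numeric(0),
                      path_distance_to_soma = numeric(0), y_offset = numeric(0))
  if (!length(hit)) return(empty)
  mid <- (res$cp[hit, , drop = FALSE] + res$cq[hit, , drop = FALSE]) / 2
  d <- res$dist[hit]
  grp <- if (length(hit) == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(mid), method = "single"),
                  h = merge_radius)
  s <- soma_node(post)
  path_d <- dendrite_path_distances(post)
  out <- do.call(rbind, lapply(split(seq_along(hit), grp), function(ii) {
    best <- ii[which.min(d[ii])]
    pos <- mid[best, ]
    edge_i <- id[hit[best]]
    pd <- path_d[as.character(de$child_id[edge_i])]
    data.frame(x = pos[1], y = pos[2], z = pos[3], min_distance = d[best],
               distance_to_soma = sqrt(sum((pos - c(s$x, s$y, s$z))^2)),
               path_distance_to_soma = unname(pd),
               y_offset = pos[2] - s$y)
  }))
  rownames(out) <- NULL
  out[order(out$distance_to_soma), , drop = FALSE]
}

# Path distance from soma to each node, named by node id.
dendrite_path_distances <- function(m) {
  idx <- match(m$parent, m$id)
  elen <- numeric(nrow(m))
  ok <- !is.na(idx)
  elen[ok] <- sqrt((m$x[ok] - m$x[idx[ok]])^2 + (m$y[ok] - m$y[idx[ok]])^2 +
                   (m$z[ok] - m$z[idx[ok]])^2)
  dist <- rep(NA_real_, nrow(m))
  dist[which(m$parent == -1L)] <- 0
  # nodes in SWC order are not guaranteed topological; iterate until settled
  repeat {
    todo <- which(is.na(dist) & ok)
    if (!length(todo)) break
    ready <- todo[!is.na(dist[idx[todo]])]
    if (!length(ready)) break
    dist[ready] <- dist[idx[ready]] + elen[ready]
  }
  stats::setNames(dist, m$id)
}

#' Summary statistics for a set of putative contacts
#'
#' @param contacts data.frame from [detect_contacts()].
#' @param radius Reporting radius in micrometres (default 100).
#' @return List: `n`, `mean_distance`, `fraction_within_radius` (radial and
#'   path variants), `y_offsets`, `n_below_soma`, and the Wilcoxon signed-rank
#'   p-value of the y-offsets against zero (two-sided, plus the one-sided
#'   "below" p).
#' @export
contact_stats <- function(contacts, radius = 100) {
  n <- nrow(contacts)
  if (n == 0L)
    return(list(n = 0L, mean_distance = NA_real_,
                fraction_within_radius = NA_real_,
                fraction_within_radius_path = NA_real_,
                y_offsets = numeric(0), n_below_soma = 0L,
                p_below = NA_real_, p_two_sided = NA_real_))
  w2 <- wilcoxon_signed_rank(contacts$y_offset, mu0 = 0,
                             alternative = "two.sided")
  w1 <- wilcoxon_signed_rank(contacts$y_offset, mu0 = 0,
                             alternative = "less")
  list(n = n,
       mean_distance = mean(contacts$distance_to_soma),
       fraction_within_radius = mean(contacts$distance_to_soma <= radius),
       fraction_within_radius_path =
         mean(contacts$path_distance_to_soma <= radius, na.rm = TRUE),
       y_offsets = contacts$y_offset,
       n_below_soma = sum(contacts$y_offset < 0),
       p_below = w1$p, p_two_sided = w2$p)
}
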