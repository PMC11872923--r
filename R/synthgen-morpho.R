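# Synthetic morphology generation: basket-cell dendritic arbors confined to
# a soma-centred envelope, and connected PC->BC pairs with planted
# axo-dendritic contacts.

#' Morphology generator parameters
#'
#' @param n_stems Primary dendrites leaving the soma.
#' @param radius_envelope Soma-centred extent (um, default 150): dendritic
#'   growth never leaves this radius.
#' @param branch_prob Per-step branching probability.
#' @param step_length Compartment step (um).
#' @param axon_descent_bias Probability that planted contact loci (and PC
#'   axon progress) lie below the BC soma.
#' @param max_nodes Node budget per tree.
#' @param z_extent Maximum |z| of dendritic nodes (um): arbors are
#'   near-planar, as in slice reconstructions.
#' @export
morpho_gen_params <- function(n_stems = 5, radius_envelope = 150,
                              branch_prob = 0.08, step_length = 10,
                              axon_descent_bias = 0.8, max_nodes = 400,
                              z_extent = 10) {
  assert_scalar_num(radius_envelope, "radius_envelope", lower = 1e-9)
  assert_scalar_num(n_stems, "n_stems", lower = 1)
  assert_scalar_num(branch_prob, "branch_prob", lower = 0, upper = 1)
  assert_scalar_num(step_length, "step_length", lower = 1e-9)
  assert_scalar_num(axon_descent_bias, "axon_descent_bias", lower = 0, upper = 1)
  structure(list(n_stems = as.integer(n_stems),
                 radius_envelope = radius_envelope,
                 branch_prob = branch_prob, step_length = step_length,
                 axon_descent_bias = axon_descent_bias,
                 max_nodes = as.integer(max_nodes), z_extent = z_extent),
            class = "morpho_gen_params")
}

#' Generate a basket-cell morphology
#'
#' Random-walk dendritic growth from a soma at the origin: `n_stems` stems,
#' per-step direction jitter, optional branching, growth clipped to the
#' radius envelope (so all dendritic path length lies within it).
#'
#' @param params A [morpho_gen_params()].
#' @param seed RNG seed; output is a pure function of (params, seed).
#' @return A [morphology()] (soma root + dendrites).
#' @export
gen_bc_morphology <- function(params = morpho_gen_params(), seed = 1) {
  stopifnot(inherits(params, "morpho_gen_params"))
  with_seed(seed, {
    nodes <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                             radius = 5, parent = -1L))
    nid <- 1L
    # growth fronts: position, direction, parent id, remaining steps
    n_steps <- max(1L, as.integer(params$radius_envelope %/% params$step_length))
    fronts <- lapply(seq_len(params$n_stems), function(i) {
      phi <- stats::runif(1, 0, 2 * pi)
      dz <- stats::runif(1, -0.2, 0.2)
      d <- c(cos(phi), sin(phi), dz)
      list(pos = c(0, 0, 0), dir = d / sqrt(sum(d^2)), parent = 1L,
           steps = n_steps)
    })
    while (length(fronts) && nid < params$max_nodes) {
      f <- fronts[[1]]; fronts <- fronts[-1]
      if (f$steps <= 0L) next
      d <- f$dir + stats::rnorm(3, 0, 0.35) * c(1, 1, 0.3)
      d <- d / sqrt(sum(d^2))
      pos <- f$pos + params$step_length * d
      pos[3] <- max(-params$z_extent, min(params$z_extent, pos[3]))
      if (sqrt(sum(pos^2)) > params$radius_envelope) {
        # bend back toward the soma instead of leaving the envelope
        inward <- -pos / sqrt(sum(pos^2))
        d <- d + 1.5 * inward
        d <- d / sqrt(sum(d^2))
        pos <- f$pos + params$step_length * d
        pos[3] <- max(-params$z_extent, min(params$z_extent, pos[3]))
        if (sqrt(sum(pos^2)) > params$radius_envelope) next
      }
      nid <- nid + 1L
      nodes[[length(nodes) + 1L]] <-
        data.frame(id = nid, type = 3L, x = pos[1], y = pos[2], z = pos[3],
                   radius = 0.5, parent = f$parent)
      nxt <- list(pos = pos, dir = d, parent = nid, steps = f$steps - 1L)
      fronts[[length(fronts) + 1L]] <- nxt
      if (stats::runif(1) < params$branch_prob && nid < params$max_nodes) {
        bd <- d + stats::rnorm(3, 0, 0.8) * c(1, 1, 0.3)
        bd <- bd / sqrt(sum(bd^2))
        fronts[[length(fronts) + 1L]] <-
          list(pos = pos, dir = bd, parent = nid,
               steps = max(1L, f$steps %/% 2L))
      }
    }
    morphology(do.call(rbind, nodes))
  })
}

#' Generate a connected PC->BC reconstruction pair with planted contacts
#'
#' Builds a BC dendritic arbor and a PC whose axon descends from above the
#' BC soma, travelling in a clearance plane (z = 30 um, far from the
#' near-planar dendrites) and dipping down to pass within ~1.2 um of exactly
#' `n_contacts` chosen dendritic loci. Loci are sampled below the BC soma
#' with probability `axon_descent_bias` and are required to be isolated
#' (> 4 um from unrelated dendrite edges) so the planted contact count is
#' exact.
#'
#' @param params A [morpho_gen_params()].
#' @param n_contacts Number of planted contacts (>= 0).
#' @param seed RNG seed.
#' @param approach_dist Closest approach of the planted dips (um).
#' @param max_tries Locus rejection budget before a generation error.
#' @return `reconstruction_pair`: list with `pre` (PC), `post` (BC),
#'   `planted_contacts` (data.frame x, y, z, y_offset), `params`.
#' @export
gen_connected_pair <- function(params = morpho_gen_params(), n_contacts = 3,
                               seed = 1, approach_dist = 1.2,
                               max_tries = 300) {
  if (n_contacts < 0) stopf("n_contacts must be >= 0")
  bc <- gen_bc_morphology(params, seed = child_seed(seed, 1))
  with_seed(child_seed(seed, 2), {
    de <- morpho_edges(bc, "dendrite")
    if (nrow(de) < max(2L, n_contacts)) stopf("BC arbor too small")
    mid <- cbind((de$x0 + de$x1) / 2, (de$y0 + de$y1) / 2, (de$z0 + de$z1) / 2)
    z_plane <- 30
    chosen <- integer(0)
    tries <- 0L
    while (length(chosen) < n_contacts) {
      tries <- tries + 1L
      if (tries > max_tries) stopf("could not place %d isolated contacts", n_contacts)
      below <- stats::runif(1) < params$axon_descent_bias
      cand_pool <- which(if (below) mid[, 2] < 0 else rep(TRUE, nrow(de)))
      cand_pool <- setdiff(cand_pool, chosen)
      if (!length(cand_pool)) next
      ci <- sample(cand_pool, 1)
      # isolation: the vertical dip segment must stay clear of every other
      # dendrite edge, and of previously chosen loci
      dip_top <- c(mid[ci, 1], mid[ci, 2], z_plane)
      dip_bot <- c(mid[ci, 1], mid[ci, 2], mid[ci, 3] + approach_dist)
      others <- setdiff(seq_len(nrow(de)), ci)
      n_o <- length(others)
      dd <- segment_distance(
        matrix(dip_top, n_o, 3, byrow = TRUE),
        matrix(dip_bot, n_o, 3, byrow = TRUE),
        cbind(de$x0, de$y0, de$z0)[others, , drop = FALSE],
        cbind(de$x1, de$y1, de$z1)[others, , drop = FALSE])$dist
      if (min(dd) <= 4) next
      if (length(chosen) &&
          min(sqrt(rowSums(sweep(mid[chosen, , drop = FALSE], 2, mid[ci, ])^2))) <= 8)
        next
      chosen <- c(chosen, ci)
    }
    # order loci top-down so the axon descends; add soma + descent path
    ord <- chosen[order(mid[chosen, 2], decreasing = TRUE)]
    soma_pc <- c(stats::runif(1, -30, 30), 140, z_plane)
    pts <- list(soma_pc)
    add <- function(p) pts[[length(pts) + 1L]] <<- p
    for (ci in ord) {
      add(c(mid[ci, 1], mid[ci, 2], z_plane))
      add(c(mid[ci, 1], mid[ci, 2], mid[ci, 3] + approach_dist))
      add(c(mid[ci, 1] + 1.5, mid[ci, 2], z_plane))
    }
    add(c(pts[[length(pts)]][1], -params$radius_envelope - 30, z_plane))
    pc_nodes <- do.call(rbind, lapply(seq_along(pts), function(i) {
      p <- pts[[i]]
      data.frame(id = i, type = if (i == 1L) 1L else 2L,
                 x = p[1], y = p[2], z = p[3],
                 radius = if (i == 1L) 8 else 0.4,
                 parent = if (i == 1L) -1L else i - 1L)
    }))
    planted <- if (length(ord))
      data.frame(x = mid[ord, 1], y = mid[ord, 2],
                 z = mid[ord, 3] + approach_dist / 2,
                 y_offset = mid[ord, 2])
    else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    y_offset = numeric(0))
    structure(list(pre = morphology(pc_nodes), post = bc,
                   planted_contacts = planted, params = params,
                   n_contacts = n_contacts),
              class = "reconstruction_pair")
  })
}
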