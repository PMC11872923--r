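# Morphometry: SWC IO, rotation, Sholl, density maps, hulls, contacts.

test_that("SWC round trip is lossless and malformed input errors name the problem", {
  toy <- morphology(data.frame(
    id = 1:3, type = c(1, 3, 3), x = c(0, 10, 20), y = c(0, 0, 5),
    z = 0, radius = c(4, 0.5, 0.5), parent = c(-1, 1, 2)))
  tf <- tempfile(fileext = ".swc")
  write_swc(toy, tf)
  back <- read_swc(tf)
  expect_equal(as.data.frame(back), as.data.frame(toy), tolerance = 1e-12)

  # 500-node generated tree round-trips field-for-field
  m <- random_tree(500, seed = 7)
  tf2 <- tempfile(fileext = ".swc")
  write_swc(m, tf2)
  expect_equal(as.data.frame(read_swc(tf2)), as.data.frame(m),
               tolerance = 1e-9)

  bad <- c("1 1 0 0 0 4 -1", "2 3 1 1 1 0.5 99")
  tf3 <- tempfile(); writeLines(bad, tf3)
  expect_error(read_swc(tf3), "missing parent")
  expect_error(read_swc(textConnection("1 1 0 0 0 4")), "7 columns")
  expect_error(morphology(data.frame(id = c(1, 1), type = 1, x = 0, y = 0,
                                     z = 0, radius = 1, parent = c(-1, 1))),
               "duplicate")
})

test_that("rotate_pia_up maps the pia direction to +y and is an isometry", {
  m <- random_tree(40, seed = 3)
  # +y already: identity
  expect_equal(as.data.frame(rotate_pia_up(m, c(0, 1, 0))),
               as.data.frame(m), tolerance = 1e-12)
  # +x: 90 degree rotation, (10, 0, 0) -> (0, 10, 0)
  one <- morphology(data.frame(id = 1:2, type = c(1, 3), x = c(0, 10),
                               y = 0, z = 0, radius = c(4, 1),
                               parent = c(-1, 1)))
  r <- rotate_pia_up(one, c(1, 0, 0))
  expect_equal(unlist(r[2, c("x", "y", "z")]), c(x = 0, y = 10, z = 0),
               tolerance = 1e-12)
  # random directions preserve all pairwise distances
  for (s in 1:5) {
    set.seed(s)
    v <- rnorm(3)
    r <- rotate_pia_up(m, v)
    d0 <- dist(as.matrix(m[, c("x", "y", "z")]))
    d1 <- dist(as.matrix(r[, c("x", "y", "z")]))
    expect_lt(max(abs(d0 - d1)), 1e-9)
    # and Sholl is rotation invariant
    expect_equal(sholl(r)$counts, sholl(m)$counts)
  }
})

test_that("sholl matches hand geometry and the brute-force oracle", {
  # single straight 20-um dendrite: crossings at 6.5, 13, 19.5 only
  line <- morphology(data.frame(
    id = 1:2, type = c(1, 3), x = c(0, 20), y = 0, z = 0,
    radius = c(4, 0.5), parent = c(-1, 1)))
  p <- sholl(line)
  expect_equal(p$counts[p$radii <= 19.5], rep(1L, 3))
  expect_true(all(p$counts[p$radii > 20] == 0))

  expect_warning(pr <- sholl(morphology(data.frame(
    id = 1, type = 1, x = 0, y = 0, z = 0, radius = 4, parent = -1))),
    "zero profile")
  expect_equal(sum(pr$counts), 0)

  for (s in 1:12) {
    m <- random_tree(sample(10:60, 1), seed = s)
    p <- sholl(m)
    expect_equal(p$counts, oracle_sholl_counts(m, p$radii),
                 info = sprintf("seed %d", s))
    expect_true(all(diff(p$cumulative_fraction) >= -1e-12))
    expect_equal(p$cumulative_fraction[length(p$cumulative_fraction)], 1)
  }
})

test_that("density_map matches the per-pixel double-loop oracle and honours flags", {
  m <- random_tree(25, seed = 11)
  dm <- density_map(m, sigma = 15, pitch = 10, normalization = "none")
  expect_equal(dm$grid, oracle_density_map(m, dm$x, dm$y, 15),
               tolerance = 1e-8)
  pk <- density_map(m, sigma = 15, pitch = 10, normalization = "peak")
  expect_equal(max(pk$grid), 1)
  mir <- density_map(m, sigma = 15, pitch = 10, mirror = TRUE)
  expect_equal(mir$grid, mir$grid[, rev(seq_len(ncol(mir$grid)))],
               tolerance = 1e-12)

  # single compartment: one Gaussian, peak 1 at its centre
  single <- morphology(data.frame(id = 1:2, type = c(1, 3), x = c(0, 10),
                                  y = c(0, 0), z = 0, radius = c(4, 1),
                                  parent = c(-1, 1)))
  d1 <- density_map(single, sigma = 25, pitch = 5)
  at <- which(d1$grid == max(d1$grid), arr.ind = TRUE)
  expect_equal(d1$x[at[2]], 5)   # edge midpoint x
  expect_equal(d1$y[at[1]], 0)
})

test_that("convex_hull_2d is a CCW Jarvis march matching the O(n^3) oracle", {
  tri <- rbind(c(0, 0), c(4, 0), c(2, 3))
  h <- convex_hull_2d(tri)
  expect_equal(nrow(h), 3)
  # CCW orientation: signed area positive
  area <- sum(h[, 1] * h[c(2:nrow(h), 1), 2] - h[c(2:nrow(h), 1), 1] * h[, 2]) / 2
  expect_gt(area, 0)

  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  expect_equal(nrow(convex_hull_2d(sq)), 4)
  # collinear edge-interior point excluded
  col3 <- rbind(c(0, 0), c(2, 0), c(1, 0), c(0, 2))
  expect_false(any(apply(convex_hull_2d(col3), 1, function(v)
    isTRUE(all.equal(v, c(1, 0))))))
  # degenerate inputs flagged
  expect_true(isTRUE(attr(convex_hull_2d(rbind(c(0, 0), c(1, 1))), "degenerate")))
  expect_true(isTRUE(attr(convex_hull_2d(cbind(0:4, 0:4)), "degenerate")))

  for (s in 1:15) {
    set.seed(100 + s)
    n <- sample(10:60, 1)
    p <- matrix(round(rnorm(2 * n), 2), ncol = 2)
    p <- unique(p)
    h <- convex_hull_2d(p)
    want <- oracle_hull_vertices(p)
    got <- sort(match(split(h, row(h)),
                      split(p, row(p))))
    # compare as coordinate sets
    hs <- apply(h, 1, paste, collapse = ",")
    ws <- apply(p[want, , drop = FALSE], 1, paste, collapse = ",")
    expect_setequal(hs, ws)
  }
})

test_that("segment distance and contact detection match closed forms and oracles", {
  # parallel segments 5 um apart
  d <- segment_distance(rbind(c(0, 0, 0)), rbind(c(10, 0, 0)),
                        rbind(c(0, 5, 0)), rbind(c(10, 5, 0)))
  expect_equal(d$dist, 5)
  # perpendicular skew segments, closest approach 1.2 um
  d2 <- segment_distance(rbind(c(-5, 0, 0)), rbind(c(5, 0, 0)),
                         rbind(c(0, -5, 1.2)), rbind(c(0, 5, 1.2)))
  expect_equal(d2$dist, 1.2)
  # random pairs vs dense-grid oracle
  set.seed(5)
  for (i in 1:40) {
    p0 <- rnorm(3, 0, 5); p1 <- rnorm(3, 0, 5)
    q0 <- rnorm(3, 0, 5); q1 <- rnorm(3, 0, 5)
    fast <- segment_distance(rbind(p0), rbind(p1), rbind(q0), rbind(q1))$dist
    slow <- oracle_segseg_dist(p0, p1, q0, q1)
    expect_lt(abs(fast - slow), 0.05)
    expect_lte(fast, slow + 1e-9)  # grid oracle can only overestimate
  }
})

test_that("detect_contacts recovers planted contacts, is threshold-monotone and symmetric in distance", {
  for (s in c(2, 9, 17)) {
    pair <- gen_connected_pair(n_contacts = 3, seed = s)
    ct <- detect_contacts(pair)
    expect_equal(nrow(ct), 3)
    # recovered loci sit at the planted loci
    pl <- pair$planted_contacts
    for (i in seq_len(nrow(ct))) {
      dd <- sqrt((pl$x - ct$x[i])^2 + (pl$y - ct$y[i])^2 + (pl$z - ct$z[i])^2)
      expect_lt(min(dd), 3)
    }
    # threshold monotonicity: contacts at 1 um form a subset of those at 2 um
    ct1 <- detect_contacts(pair, threshold = 1.0)
    expect_lte(nrow(ct1), nrow(ct))
    expect_true(all(ct1$min_distance < 1.0))
  }
  pair0 <- gen_connected_pair(n_contacts = 0, seed = 21)
  expect_equal(nrow(detect_contacts(pair0)), 0)
  expect_error(detect_contacts(list(pre = gen_bc_morphology(seed = 1),
                                    post = gen_bc_morphology(seed = 2))),
               "no axon")
})

test_that("contact_stats summarises distances and the below-soma test", {
  ct <- data.frame(x = 0, y = 0, z = 0, min_distance = 1,
                   distance_to_soma = rep(50, 6),
                   path_distance_to_soma = rep(60, 6),
                   y_offset = c(-30, -20, -50, -10, -5, -40))
  cs <- contact_stats(ct)
  expect_equal(cs$fraction_within_radius, 1.0)
  expect_equal(cs$n_below_soma, 6)
  expect_equal(cs$p_below, 1 / 2^6)   # all-negative one-sided exact
})
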