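# dG/R quantification, diameter estimation, bAP profiling, linearity.

make_linescan <- function(green, red, stim_onset = 300, ms_per_line = 1,
                          pixels_per_um = 2) {
  linescan_movie(green, red, ms_per_line, pixels_per_um, stim_onset,
                 roi = seq(55, 75), background = c(1:15, 114:128))
}

test_that("compute_dgr matches closed forms and the pixelwise oracle", {
  nt <- 600; npx <- 128
  R <- matrix(500, nt, npx)
  # constant green -> dgr identically 0
  mv <- make_linescan(matrix(200, nt, npx), R)
  tr <- compute_dgr(mv)
  expect_equal(tr$dgr, rep(0, nt))
  # noise-free step of dG = 0.2 R after onset in the roi, quiet background
  G <- matrix(200, nt, npx)
  G[301:nt, 55:75] <- 200 + 0.2 * 500
  mv2 <- make_linescan(G, R)
  tr2 <- compute_dgr(mv2)
  expect_equal(tr2$dgr[1:300], rep(0, 300))
  expect_equal(tr2$dgr[302:nt], rep(0.2, nt - 301))
  # planted transient + common drift on all pixels (equal red means):
  # background subtraction removes the drift exactly
  set.seed(1)
  drift <- 30 * sin(seq_len(nt) / 60)
  planted <- c(rep(0, 300), 0.3 * exp(-(1:300) / 120))
  G3 <- matrix(200, nt, npx) + drift
  G3[, 55:75] <- G3[, 55:75] + planted * 500
  mv3 <- make_linescan(G3, R)
  tr3 <- compute_dgr(mv3)
  expect_equal(tr3$dgr, planted - mean(planted[201:300]), tolerance = 1e-9)
  # pixelwise oracle equivalence on a noisy movie
  G4 <- matrix(rnorm(nt * npx, 200, 5), nt, npx)
  R4 <- matrix(rnorm(nt * npx, 500, 5), nt, npx)
  mv4 <- make_linescan(G4, R4)
  tr4 <- compute_dgr(mv4)
  expect_equal(tr4$dgr,
               oracle_dgr_linescan(mv4, 55:75, c(1:15, 114:128),
                                   tr4$baseline_window),
               tolerance = 1e-10)
  # baseline closure holds for arbitrary input
  bw <- tr4$baseline_window
  bidx <- tr4$time >= bw[1] & tr4$time < bw[2]
  expect_lt(abs(mean(tr4$dgr[bidx])), 1e-12)
})

test_that("dG/R is invariant to common gain and fails on degenerate red", {
  set.seed(2)
  nt <- 500
  G <- matrix(rnorm(nt * 128, 300, 10), nt, 128)
  R <- matrix(rnorm(nt * 128, 600, 10), nt, 128)
  mv <- make_linescan(G, R)
  mv_scaled <- make_linescan(3.7 * G, 3.7 * R)
  expect_equal(compute_dgr(mv)$dgr, compute_dgr(mv_scaled)$dgr,
               tolerance = 1e-12)
  mv_bad <- make_linescan(G, R - 600)
  expect_error(compute_dgr(mv_bad), "red")
  expect_error(compute_dgr(mv, roi = rep(FALSE, 128)), "mask")
})

test_that("integrate_transient matches a direct-summation oracle", {
  tr0 <- structure(list(dgr = rep(0, 1000), time = 0:999,
                        baseline_window = c(0, 100), stim_onset = 100),
                   class = "ca_transient")
  expect_equal(integrate_transient(tr0), 0)
  tr5 <- tr0; tr5$dgr <- rep(0.05, 1000)
  expect_equal(integrate_transient(tr5, c(0, 900)), 5)
  set.seed(3)
  for (i in 1:20) {
    w <- sort(sample(50:800, 2))
    y <- rnorm(1000, 0, 0.3)
    tr <- tr0; tr$dgr <- y
    idx <- which(tr$time - 100 >= w[1] & tr$time - 100 < w[2])
    oracle <- 100 * sum(y[idx]) / length(idx)
    expect_equal(integrate_transient(tr, w), oracle, tolerance = 1e-10)
  }
  expect_error(integrate_transient(tr0, c(500, 500)), "empty")
})

test_that("diameter estimation recovers planted profile widths", {
  nt <- 400; npx <- 128; px <- 1:npx
  mk <- function(prof) make_linescan(matrix(100, nt, npx),
                                     matrix(rep(prof, each = nt), nt))
  # Gaussian of known sigma: FWHM = 2.3548 sigma
  sg <- 6
  gmov <- mk(40 + 900 * exp(-((px - 64)^2) / (2 * sg^2)))
  expect_equal(estimate_dendrite_diameter(gmov), 2.3548 * sg / 2,
               tolerance = 0.02)
  # two-pixel boxcar at 2 px/um -> 1.0 um
  prof <- rep(0, npx); prof[64:65] <- 800
  expect_equal(estimate_dendrite_diameter(mk(prof)), 1.0, tolerance = 0.26)
  # flat profile errors
  expect_error(estimate_dendrite_diameter(mk(rep(50, npx))), "profile")
  # recovery sweep with noise: within 10%
  set.seed(4)
  for (sg in c(3, 5, 8)) {
    prof <- 40 + 900 * exp(-((px - 64)^2) / (2 * sg^2))
    R <- matrix(rep(prof, each = nt), nt) + matrix(rnorm(nt * npx, 0, 15), nt)
    mv <- make_linescan(matrix(100, nt, npx), R)
    est <- estimate_dendrite_diameter(mv)
    expect_lt(abs(est - 2.3548 * sg / 2) / (2.3548 * sg / 2), 0.1)
  }
})

test_that("bap_distance_profile fits planted length constants and boost", {
  # noise-free: lambda recovered exactly; beta = 0 gives zero boost
  ca0 <- synth_ca_params(noise_green = 0, noise_red = 0, boost_slope_beta = 0)
  mov <- gen_linescan_dataset(ca0, distances = seq(10, 150, by = 20),
                              n_repeats = 1, seed = 1)
  meas <- do.call(rbind, lapply(mov, function(mv) {
    truth <- attr(mv, "truth")
    data.frame(location = truth$location, distance = mv$distance_to_soma,
               state = mv$state,
               integral = integrate_transient(compute_dgr(mv), c(0, 275)),
               diameter = estimate_dendrite_diameter(mv))
  }))
  prof <- bap_distance_profile(meas)
  expect_equal(prof$lambda_rest, 100, tolerance = 1e-3)
  expect_lt(max(abs(prof$boost)), 1e-6)
  # monotone decrement on noise-free data
  rest <- meas[meas$state == "rest", ]
  rest <- rest[order(rest$distance), ]
  expect_true(all(diff(rest$integral * rest$diameter) < 0))
  # unmatched pairs error
  expect_error(bap_distance_profile(meas[meas$state == "rest", ]),
               "unmatched|depolarized")
})

test_that("linearity_analysis reproduces planted interaction terms and sign conventions", {
  # gamma = 0, noise-free: exactly 100%
  ca <- synth_ca_params(interaction_gamma = 0, noise_green = 0, noise_red = 0)
  r <- linearity_analysis(gen_framescan_dataset(ca, n_repeats = 2, seed = 1))
  expect_equal(r$supralinearity, 100, tolerance = 1e-9)
  # gamma = 0.4 -> 140%; gamma = -0.1 -> 90% (sublinear sign convention)
  ca2 <- synth_ca_params(interaction_gamma = 0.4, noise_green = 0, noise_red = 0)
  expect_equal(
    linearity_analysis(gen_framescan_dataset(ca2, n_repeats = 2, seed = 2))$supralinearity,
    140, tolerance = 1e-9)
  ca3 <- synth_ca_params(interaction_gamma = -0.10, noise_green = 0, noise_red = 0)
  expect_equal(
    linearity_analysis(gen_framescan_dataset(ca3, n_repeats = 2, seed = 3))$supralinearity,
    90, tolerance = 1e-9)
  # printed-group-mean arithmetic: one segment with Both 7.8 and Sum 5.6
  # gives a per-segment ratio of 139.3 (not the study's 143, which is the
  # mean of per-segment ratios)
  expect_equal(round(100 * 7.8 / 5.6, 1), 139.3)
  # repeats requirement enforced
  expect_error(gen_framescan_dataset(ca, n_repeats = 1), "n_repeats")
})
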