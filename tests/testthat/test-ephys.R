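# Spike metrics, input resistance, QC, EPSP/PPR measurement, plasticity
# magnitude and CV quantal analysis.

flat_sweep <- function(n = 5000, rate = 10000, vm = -70, events = NULL, ...) {
  cc_sweep(rep(vm, n), rate, events = events, ...)
}

alpha_epsp <- function(tms, onset, amp, tau = 5) {
  v <- numeric(length(tms)); on <- tms >= onset
  td <- tms[on] - onset
  v[on] <- amp * (td / tau) * exp(1 - td / tau)
  v
}

test_that("detect_spikes finds planted waveforms with correct height and half-width", {
  expect_equal(nrow(detect_spikes(flat_sweep())), 0)
  rate <- 40000
  tms <- (0:(0.05 * rate)) * 1000 / rate
  # triangular spike: rise 0.3 ms, fall 0.9 ms, from -70 threshold crossing
  v <- rep(-70, length(tms))
  t0 <- 20
  tri <- pmax(0, pmin((tms - t0) / 0.3, 1 - (tms - t0 - 0.3) / 0.9)) * 100
  v <- v + tri
  sp <- detect_spikes(cc_sweep(v, rate))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$peak, 30, tolerance = 0.1)
  # half width of a triangle of height h: rise+fall span at h/2 = 0.6 ms,
  # but height is measured from the dV/dt threshold voltage
  lvl <- sp$threshold + sp$height / 2
  expect_equal(sp$half_width,
               (0.3 + 0.9) - (lvl + 70) / 100 * 0.3 - (lvl + 70) / 100 * 0.9,
               tolerance = 2 * 1000 / rate)
  # refractory merges double-crossings within 1 ms
  v2 <- rep(-70, length(tms)) +
    100 * exp(-((tms - 10)^2) / 0.05) + 100 * exp(-((tms - 25)^2) / 0.05)
  expect_equal(nrow(detect_spikes(cc_sweep(v2, rate))), 2)
})

test_that("rheobase_metrics uses the first spiking step and the accommodation fallback", {
  fam <- gen_step_family(rheobase_pa = 120, steps_pa = seq(60, 200, by = 20),
                         accommodation = 2.0, seed = 1)
  m <- rheobase_metrics(fam)
  expect_equal(m$rheobase_current, 120)
  expect_gt(m$half_width, 0)
  # single spike at rheobase: frequency metrics come from the next step
  expect_false(is.na(m$accommodation))
  # hand-built trains: ISIs 10..20 ms -> f_first 100 Hz, accommodation 2
  rate <- 20000
  tms <- (0:(0.7 * rate - 1)) * 1000 / rate
  spikes_at <- function(times) {
    v <- rep(-70, length(tms))
    for (t0 in times) v <- v + 100 * exp(-((tms - t0)^2) / (2 * 0.25^2))
    cc_sweep(v, rate, events = data.frame(kind = "current_pulse",
                                          onset = 100, amplitude = NA,
                                          duration = 500))
  }
  sub <- flat_sweep(length(tms), rate,
                    events = data.frame(kind = "current_pulse", onset = 100,
                                        amplitude = 100, duration = 500))
  one <- spikes_at(150)
  one$events$amplitude <- 120
  nxt <- spikes_at(150 + cumsum(c(0, seq(10, 20, length.out = 5))))
  nxt$events$amplitude <- 140
  mm <- rheobase_metrics(list(sub, one, nxt))
  expect_equal(mm$rheobase_current, 120)
  expect_equal(mm$inst_freq_first, 100, tolerance = 0.02)
  expect_equal(mm$accommodation, 2.0, tolerance = 0.02)
  # regular train: accommodation 1
  reg <- spikes_at(seq(150, 550, by = 25)); reg$events$amplitude <- 120
  expect_equal(rheobase_metrics(list(sub, reg))$accommodation, 1.0,
               tolerance = 1e-6)
  expect_error(rheobase_metrics(list(sub)), "rheobase")
})

test_that("input_resistance implements Ohm's law on the test pulse", {
  rate <- 10000
  tms <- (0:(9000 - 1)) * 1000 / rate
  ev <- data.frame(kind = "test_pulse", onset = 300, amplitude = -25,
                   duration = 250)
  # planted -2.5 mV deflection -> 100 MOhm
  v <- rep(-70, length(tms))
  v[tms >= 300 & tms < 550] <- -72.5
  expect_equal(input_resistance(cc_sweep(v, rate, events = ev)), 100)
  expect_equal(input_resistance(flat_sweep(9000, events = ev)), 0)
  # exponential charging with tau up to 30 ms recovered within 2%
  for (tau in c(10, 20, 30)) {
    v <- rep(-70, length(tms))
    on <- tms >= 300 & tms < 550
    v[on] <- -70 - 3.75 * (1 - exp(-(tms[on] - 300) / tau))
    rin <- input_resistance(cc_sweep(v, rate, events = ev))
    expect_lt(abs(rin - 150) / 150, 0.02)
  }
})

test_that("qc_filter truncates at the first violation, matching a per-sweep scan", {
  mk <- function(rin_mohm, vm = -70, temp = 33) {
    rate <- 10000
    tms <- (0:(9000 - 1)) * 1000 / rate
    v <- rep(vm, 9000)
    on <- tms >= 300 & tms < 550
    v[on] <- vm - 25 * rin_mohm / 1000
    cc_sweep(v, rate, events = data.frame(kind = "test_pulse", onset = 300,
                                          amplitude = -25, duration = 250),
             temperature = temp)
  }
  stable <- lapply(rep(150, 12), mk)
  qs <- qc_filter(stable)
  expect_true(all(qs$pass_mask))
  expect_true(is.na(qs$truncation_index))
  # Rin ramp: +40% reached gradually; oracle scan gives the exact index
  rins <- c(rep(150, 10), seq(155, 230, by = 15))
  drift <- lapply(rins, mk)
  qd <- qc_filter(drift)
  oracle_idx <- which(abs(rins - mean(rins[1:5])) / mean(rins[1:5]) > 0.30)[1]
  expect_equal(qd$truncation_index, oracle_idx)
  expect_true(all(!qd$pass_mask[oracle_idx:length(rins)]))
  # temperature excursions fail those sweeps
  temps <- c(rep(33, 6), rep(31, 3), rep(33, 3))
  qt <- qc_filter(lapply(temps, function(tp) mk(150, temp = tp)),
                  mode = "discard")
  expect_equal(which(!qt$pass_mask), 7:9)
  # resting potential drift
  qv <- qc_filter(lapply(c(rep(-70, 6), rep(-60, 6)), function(v) mk(150, vm = v)))
  expect_equal(qv$truncation_index, 7L)
})

test_that("measure_epsp is exact on planted kinetics and offset-invariant", {
  rate <- 10000
  n <- 4000
  tms <- (0:(n - 1)) * 1000 / rate
  flat <- flat_sweep(n, rate)
  expect_equal(measure_epsp(flat, 200)$amplitude, 0)
  v <- -70 + alpha_epsp(tms, 201.5, 1.5)
  m <- measure_epsp(cc_sweep(v, rate), 200)
  expect_equal(m$amplitude, 1.5, tolerance = 0.01)
  expect_equal(m$latency, 1.5 + 1.03, tolerance = 0.35) # 20% rise of alpha
  # offset invariance
  m2 <- measure_epsp(cc_sweep(v + 13.7, rate), 200)
  expect_equal(m2$amplitude, m$amplitude, tolerance = 1e-12)
  # spike contamination flags and omits
  vs <- v + 100 * exp(-((tms - 210)^2) / (2 * 0.25^2))
  ms <- measure_epsp(cc_sweep(vs, rate), 200)
  expect_true(ms$contaminated)
  expect_true(is.na(ms$amplitude))
  # unbiased under noise: 600 draws, mean within 3 SE
  set.seed(9)
  amps <- replicate(600, {
    vn <- v + rnorm(n, 0, 0.05)
    measure_epsp(cc_sweep(vn, rate), 200)$amplitude
  })
  expect_lt(abs(mean(amps) - 1.5), 3 * sd(amps) / sqrt(length(amps)) + 0.005)
})

test_that("paired_pulse decay correction beats the naive measurement", {
  rate <- 10000
  n <- 6000
  tms <- (0:(n - 1)) * 1000 / rate
  onsets <- c(200, 200 + 1000 / 30)
  # fully decayed pair: PPR exactly 1 and 0.5
  v_far <- -70 + alpha_epsp(tms, 201.5, 1, tau = 2) +
    alpha_epsp(tms, onsets[2] + 1.5, 1, tau = 2)
  pp <- paired_pulse(cc_sweep(v_far, rate), onsets[1], onsets[2])
  expect_equal(pp$ppr, 1.0, tolerance = 0.01)
  v_half <- -70 + alpha_epsp(tms, 201.5, 1, tau = 2) +
    alpha_epsp(tms, onsets[2] + 1.5, 0.5, tau = 2)
  expect_equal(paired_pulse(cc_sweep(v_half, rate), onsets[1], onsets[2])$ppr,
               0.5, tolerance = 0.01)
  # overlapping kinetics (tau 8 and 10 ms): corrected PPR within 5% of
  # truth, naive estimate demonstrably worse
  for (tau_ov in c(8, 10)) {
    v_ov <- -70 + alpha_epsp(tms, 201.5, 1, tau = tau_ov) +
      alpha_epsp(tms, onsets[2] + 1.5, 0.7, tau = tau_ov)
    ppc <- paired_pulse(cc_sweep(v_ov, rate), onsets[1], onsets[2])
    ppn <- paired_pulse(cc_sweep(v_ov, rate), onsets[1], onsets[2],
                        correct_decay = FALSE)
    expect_lt(abs(ppc$ppr - 0.7) / 0.7, 0.05)
    expect_gt(abs(ppn$ppr - 0.7), abs(ppc$ppr - 0.7))
  }
  # EPSP1 below the noise floor leaves PPR undefined
  tiny <- -70 + alpha_epsp(tms, 201.5, 0.01, tau = 2)
  expect_true(paired_pulse(cc_sweep(tiny, rate), onsets[1], onsets[2])$undefined)
})

test_that("plasticity_magnitude recovers planted effect sizes", {
  # null: identical epochs, ratio ~ 100, dPPR ~ 0
  m0 <- release_model(quantal_cv = 0, trial_noise_cv = 0,
                      recording_noise_sd = 0.01)
  ex0 <- gen_plasticity_experiment(m0, plasticity_ground_truth(), seed = 5)
  pr0 <- plasticity_magnitude(ex0)
  expect_equal(pr0$ratio, 100, tolerance = 8)
  expect_equal(pr0$delta_ppr, 0, tolerance = 0.12)
  # deterministic check: p 0.5 -> 0.4 with no quantal/trial/recording noise
  # is exact at the amplitude level (N p q: 0.75 -> 0.6 mV)
  det <- release_model(n_sites = 5, release_prob = 0.5, quantal_size = 1,
                       quantal_cv = 0, trial_noise_cv = 0,
                       recording_noise_sd = 0)
  tr <- plasticity_ground_truth("presynaptic_dp", 0.8, "synchronous")
  set.seed(1)
  amps_b <- draw_release_amplitudes(det, 5000)
  det2 <- det; det2$release_prob <- 0.4
  amps_a <- draw_release_amplitudes(det2, 5000)
  expect_equal(mean(amps_b$amp1), 2.5, tolerance = 0.05)
  expect_equal(mean(amps_a$amp1), 2.0, tolerance = 0.05)
  # trace-level pipeline: planted ratio 0.8 recovered
  exd <- gen_plasticity_experiment(det, tr, n_baseline = 35, n_post = 60,
                                   seed = 6)
  prd <- plasticity_magnitude(exd)
  expect_equal(prd$ratio, 80, tolerance = 6)
  # insufficient sweeps errors
  exs <- gen_plasticity_experiment(m0, plasticity_ground_truth(),
                                   n_baseline = 6, n_post = 4, seed = 7)
  expect_error(plasticity_magnitude(exs), "insufficient")
})

test_that("cv_analysis reproduces the binomial quantal signatures", {
  # identical epochs -> (1, 1)
  set.seed(11)
  x <- rnorm(200, 1, 0.2)
  cv_same <- cv_analysis(x, x)
  expect_equal(cv_same$mean_norm, 1)
  expect_equal(cv_same$inv_cv2_norm, 1)
  # presynaptic dp: closed form (N p'/(1-p')) / (N p/(1-p)) = 2/3 at
  # p 0.5 -> 0.4; mean_norm 0.8; below the diagonal
  m1 <- release_model(release_prob = 0.5, quantal_size = 1, quantal_cv = 0,
                      trial_noise_cv = 0)
  m2 <- m1; m2$release_prob <- 0.4
  a1 <- draw_release_amplitudes(m1, 10000)$amp1
  a2 <- draw_release_amplitudes(m2, 10000)$amp1
  cv_pre <- cv_analysis(a1, a2)
  se3 <- 3 * 0.667 * sqrt(2 / 10000) * 4  # generous 3-SE-scale band
  expect_equal(cv_pre$inv_cv2_norm, (5 * 0.4 / 0.6) / (5 * 0.5 / 0.5),
               tolerance = 0.06)
  expect_equal(cv_pre$mean_norm, 0.8, tolerance = 0.03)
  expect_equal(cv_pre$quadrant, "presynaptic")
  # postsynaptic dq: pure scaling leaves 1/CV^2 unchanged
  cv_post <- cv_analysis(a1, 0.8 * a1)
  expect_equal(cv_post$inv_cv2_norm, 1, tolerance = 1e-9)
  expect_equal(cv_post$mean_norm, 0.8)
  expect_equal(cv_post$quadrant, "postsynaptic")
  # multiplicative rescale invariance of inv_cv2_norm
  cv_resc <- cv_analysis(3 * a1, 3 * a2)
  expect_equal(cv_resc$inv_cv2_norm, cv_pre$inv_cv2_norm, tolerance = 1e-12)
  # small epochs warn and attach a bootstrap CI
  expect_warning(cv_small <- cv_analysis(rnorm(6, 1, 0.1), rnorm(6, 1, 0.1)),
                 "bootstrap")
  expect_true(!is.null(cv_small$inv_cv2_norm_ci))
})

test_that("quantal law: sample 1/CV^2 converges to N p / (1 - p)", {
  m <- release_model(n_sites = 5, release_prob = 0.5, quantal_size = 0.3,
                     quantal_cv = 0, trial_noise_cv = 0)
  set.seed(13)
  a <- draw_release_amplitudes(m, 10000)$amp1
  inv_cv2 <- (mean(a) / sd(a))^2
  # SE of 1/CV^2 by delta method ~ inv_cv2 * sqrt(2/n) * sqrt(2)
  se <- inv_cv2 * 2 / sqrt(10000)
  expect_lt(abs(inv_cv2 - 5 * 0.5 / 0.5), 3 * se + 0.15)
})
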