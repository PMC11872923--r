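# Synthetic electrophysiology: binomial quantal release model, plasticity
# experiments with pre- or postsynaptically expressed effects, current-step
# spike trains and optomapping scenes.

#' Binomial quantal release model
#'
#' @param n_sites Release sites N (>= 1).
#' @param release_prob Release probability p in [0, 1].
#' @param quantal_size Quantal amplitude q (mV, > 0).
#' @param quantal_cv CV of the single-quantum amplitude.
#' @param depletion_frac Fraction of released sites unavailable for the
#'   second pulse of a 30-Hz pair.
#' @param recording_noise_sd Per-sample recording noise (mV).
#' @param trial_noise_cv Common multiplicative trial-to-trial noise (CV);
#'   applied to both pulses of a sweep. Set 0 for exact quantal statistics.
#' @export
release_model <- function(n_sites = 5, release_prob = 0.5, quantal_size = 0.3,
                          quantal_cv = 0.3, depletion_frac = 0.15,
                          recording_noise_sd = 0.05, trial_noise_cv = 0.3) {
  assert_scalar_num(n_sites, "n_sites", lower = 1)
  assert_scalar_num(release_prob, "release_prob", lower = 0, upper = 1)
  assert_scalar_num(quantal_size, "quantal_size", lower = 1e-12)
  assert_scalar_num(quantal_cv, "quantal_cv", lower = 0)
  assert_scalar_num(depletion_frac, "depletion_frac", lower = 0, upper = 1)
  structure(list(n_sites = as.integer(n_sites), release_prob = release_prob,
                 quantal_size = quantal_size, quantal_cv = quantal_cv,
                 depletion_frac = depletion_frac,
                 recording_noise_sd = recording_noise_sd,
                 trial_noise_cv = trial_noise_cv),
            class = "release_model")
}

#' Expected first-pulse EPSP amplitude, N p q
#' @param model A [release_model()].
#' @export
expected_epsp1 <- function(model) {
  model$n_sites * model$release_prob * model$quantal_size
}

#' Draw paired-pulse EPSP amplitudes from a release model
#'
#' First pulse: k1 ~ Binomial(N, p) quanta of size q (quantal CV applied per
#' released quantum). Second pulse: each released site is unavailable with
#' probability `depletion_frac`; k2 ~ Binomial(available, p). A common
#' multiplicative trial factor (CV `trial_noise_cv`) scales both pulses.
#'
#' @param model A [release_model()].
#' @param n Number of sweeps.
#' @return data.frame `amp1`, `amp2` (mV, noiseless of recording noise).
#' @export
draw_release_amplitudes <- function(model, n) {
  N <- model$n_sites; p <- model$release_prob; q <- model$quantal_size
  k1 <- stats::rbinom(n, N, p)
  a1 <- k1 * q + stats::rnorm(n, 0, q * model$quantal_cv * sqrt(pmax(k1, 0)))
  depleted <- stats::rbinom(n, k1, model$depletion_frac)
  avail <- N - depleted
  k2 <- stats::rbinom(n, avail, p)
  a2 <- k2 * q + stats::rnorm(n, 0, q * model$quantal_cv * sqrt(pmax(k2, 0)))
  if (model$trial_noise_cv > 0) {
    f <- 1 + stats::rnorm(n, 0, model$trial_noise_cv)
    a1 <- a1 * f; a2 <- a2 * f
  }
  data.frame(amp1 = a1, amp2 = a2)
}

#' Ground truth of a planted plasticity effect
#'
#' @param expression_locus `"none"`, `"presynaptic_dp"` (release probability
#'   scaled) or `"postsynaptic_dq"` (quantal size scaled).
#' @param effect_size Multiplicative factor applied after induction (> 0);
#'   must be 1 when the locus is `"none"`.
#' @param condition Induction condition label.
#' @export
plasticity_ground_truth <- function(expression_locus = c("none", "presynaptic_dp",
                                                         "postsynaptic_dq"),
                                    effect_size = 1,
                                    condition = "control") {
  expression_locus <- match.arg(expression_locus)
  assert_scalar_num(effect_size, "effect_size", lower = 1e-12)
  if (expression_locus == "none" && effect_size != 1)
    stopf("locus 'none' requires effect_size = 1")
  structure(list(expression_locus = expression_locus,
                 effect_size = effect_size, condition = condition),
            class = "plasticity_ground_truth")
}

apply_effect <- function(model, truth) {
  m <- model
  if (truth$expression_locus == "presynaptic_dp")
    m$release_prob <- min(1, m$release_prob * truth$effect_size)
  if (truth$expression_locus == "postsynaptic_dq")
    m$quantal_size <- m$quantal_size * truth$effect_size
  m
}

# Render one current-clamp sweep: resting Vm, paired EPSPs (alpha kinetics),
# a -25 pA / 250 ms test pulse, recording noise.
render_plasticity_sweep <- function(amp1, amp2, model, sweep_time,
                                    sample_rate = 10000, duration_ms = 900,
                                    stim_onsets = c(200, 200 + 1000 / 30),
                                    latency = 1.5, tau = 5,
                                    rin_mohm = 150, rest_mv = -70,
                                    temperature = 33) {
  n <- as.integer(duration_ms * sample_rate / 1000)
  tms <- (seq_len(n) - 1) * 1000 / sample_rate
  alpha <- function(t0, amp) {
    v <- numeric(n); on <- tms >= t0
    td <- tms[on] - t0
    v[on] <- amp * (td / tau) * exp(1 - td / tau)
    v
  }
  pulse_on <- 500; pulse_dur <- 250; pulse_pa <- -25
  rc_tau <- 15
  defl <- numeric(n)
  on <- tms >= pulse_on & tms < pulse_on + pulse_dur
  defl[on] <- (pulse_pa * rin_mohm / 1000) * (1 - exp(-(tms[on] - pulse_on) / rc_tau))
  off <- tms >= pulse_on + pulse_dur
  defl[off] <- (pulse_pa * rin_mohm / 1000) *
    (1 - exp(-pulse_dur / rc_tau)) * exp(-(tms[off] - pulse_on - pulse_dur) / rc_tau)
  v <- rest_mv + alpha(stim_onsets[1] + latency, amp1) +
    alpha(stim_onsets[2] + latency, amp2) + defl +
    stats::rnorm(n, 0, model$recording_noise_sd)
  cc_sweep(v, sample_rate,
           events = data.frame(
             kind = c("spiral_scan", "spiral_scan", "test_pulse"),
             onset = c(stim_onsets, pulse_on),
             amplitude = c(NA, NA, pulse_pa),
             duration = c(7, 7, pulse_dur)),
           temperature = temperature, sweep_time = sweep_time)
}

#' Generate a synthetic plasticity experiment for one connection
#'
#' Baseline sweeps are drawn from the release model; post-induction sweeps
#' from the model with the planted effect applied to p or q. Sweeps carry
#' 30-Hz paired stimuli, a QC test pulse, resting potential and recording
#' noise; ground truth and induction metadata are attached.
#'
#' @param model A [release_model()].
#' @param truth A [plasticity_ground_truth()].
#' @param protocol An [induction_spec()] (metadata only at this level).
#' @param n_baseline,n_post Sweep counts (protocol: 35-40 baseline,
#'   post monitored for up to 1 h).
#' @param seed RNG seed.
#' @param inter_sweep_s Seconds between sweeps (default 30).
#' @param ... Passed to the sweep renderer.
#' @return `plasticity_experiment`: list with `sweeps`, `stim_onsets`,
#'   `induction_time` (s), `condition`, `truth`, `model`.
#' @export
gen_plasticity_experiment <- function(model = release_model(),
                                      truth = plasticity_ground_truth(),
                                      protocol = induction_spec(truth$condition),
                                      n_baseline = 35, n_post = 60,
                                      seed = 1, inter_sweep_s = 30, ...) {
  stopifnot(inherits(model, "release_model"),
            inherits(truth, "plasticity_ground_truth"))
  with_seed(seed, {
    post_model <- apply_effect(model, truth)
    amps_b <- draw_release_amplitudes(model, n_baseline)
    amps_p <- draw_release_amplitudes(post_model, n_post)
    t_base <- (seq_len(n_baseline) - 1) * inter_sweep_s
    induction_time <- t_base[n_baseline] + 2 * inter_sweep_s
    t_post <- induction_time + seq_len(n_post) * inter_sweep_s
    stim_onsets <- c(200, 200 + 1000 / 30)
    sweeps <- c(
      lapply(seq_len(n_baseline), function(i)
        render_plasticity_sweep(amps_b$amp1[i], amps_b$amp2[i], model,
                                sweep_time = t_base[i],
                                stim_onsets = stim_onsets, ...)),
      lapply(seq_len(n_post), function(i)
        render_plasticity_sweep(amps_p$amp1[i], amps_p$amp2[i], post_model,
                                sweep_time = t_post[i],
                                stim_onsets = stim_onsets, ...)))
    structure(list(sweeps = sweeps, stim_onsets = stim_onsets,
                   induction_time = induction_time,
                   condition = truth$condition, truth = truth,
                   model = model, protocol = protocol,
                   amplitudes = list(before = amps_b, after = amps_p)),
              class = "plasticity_experiment")
  })
}

#' Generate a current-step family for spike metrics
#'
#' 500-ms depolarizing steps of increasing amplitude; suprathreshold steps
#' elicit regular or accommodating spike trains (template action-potential
#' waveforms planted at computed times).
#'
#' @param rheobase_pa True rheobase (pA).
#' @param steps_pa Step amplitudes (pA).
#' @param accommodation Ratio of first to last instantaneous frequency.
#' @param base_rate_hz Firing rate at rheobase + 1 step.
#' @param seed RNG seed.
#' @return List of [cc_sweep()]s ordered by step amplitude.
#' @export
gen_step_family <- function(rheobase_pa = 120, steps_pa = seq(20, 300, by = 20),
                            accommodation = 1.0, base_rate_hz = 40, seed = 1,
                            sample_rate = 40000) {
  with_seed(seed, {
    lapply(steps_pa, function(a) {
      dur <- 700; on <- 100; off <- 600
      n <- as.integer(dur * sample_rate / 1000)
      tms <- (seq_len(n) - 1) * 1000 / sample_rate
      v <- rep(-70, n) + stats::rnorm(n, 0, 0.02)
      if (a >= rheobase_pa) {
        over <- (a - rheobase_pa) / 20
        nspk <- max(1L, as.integer(1 + over * base_rate_hz / 2))
        if (nspk > 1) {
          # ISIs geometrically stretched so f_first / f_last = accommodation
          isi1 <- 500 / (nspk + (accommodation - 1) * nspk / 2)
          ratios <- if (nspk > 2)
            accommodation^(seq(0, 1, length.out = nspk - 1)) else accommodation
          isis <- isi1 * ratios
          times <- on + 5 + cumsum(c(0, isis))
        } else times <- on + 5
        times <- times[times < off - 5]
        for (t0 in times) v <- v + spike_waveform(tms, t0)
      }
      cc_sweep(v, sample_rate,
               events = data.frame(kind = "current_pulse", onset = on,
                                   amplitude = a, duration = 500))
    })
  })
}

# stereotyped AP: Gaussian waveform peaking 100 mV above rest (~ +30 mV from
# -70 mV rest) with the requested full width at half maximum
spike_waveform <- function(tms, t0, height = 100, width = 0.6) {
  v <- numeric(length(tms))
  s <- width / 2.3548
  on <- tms >= t0 - 3 & tms <= t0 + 3
  v[on] <- height * exp(-((tms[on] - t0)^2) / (2 * s^2))
  v
}

#' Generate an optomapping scene with ground-truth connectivity
#'
#' @param n_cells Candidate presynaptic cells.
#' @param connect_prob Connection probability per cell.
#' @param amp_range EPSP amplitude range (mV) for connected cells.
#' @param noise_sd Recording noise SD (mV).
#' @param seed RNG seed.
#' @param n_repeats Stimulation sweeps (default 20).
#' @param latency EPSP latency after spiral onset (ms).
#' @return `optomap_scene`: list with `centroids`, `plan`, `truth`
#'   (data.frame cell, connected, amplitude), `sweeps`.
#' @export
gen_optomap_scene <- function(n_cells = 10, connect_prob = 0.3,
                              amp_range = c(0.3, 1.0), noise_sd = 0.05,
                              seed = 1, n_repeats = 20, latency = 1.5,
                              sample_rate = 10000) {
  with_seed(seed, {
    centroids <- cbind(x = stats::runif(n_cells, -150, 150),
                       y = stats::runif(n_cells, -150, 150))
    plan <- build_stimulus_plan(centroids, repeats = n_repeats)
    connected <- stats::runif(n_cells) < connect_prob
    amps <- ifelse(connected, stats::runif(n_cells, amp_range[1], amp_range[2]), 0)
    n <- as.integer(plan$sweep_duration_ms * sample_rate / 1000)
    tms <- (seq_len(n) - 1) * 1000 / sample_rate
    tau <- 5
    sweeps <- lapply(seq_len(n_repeats), function(k) {
      v <- rep(-70, n) + stats::rnorm(n, 0, noise_sd)
      for (ci in which(connected)) {
        for (o in plan$spiral_onsets[[ci]]) {
          a <- amps[ci] * exp(stats::rnorm(1, 0, 0.1))
          on <- tms >= o + latency
          td <- tms[on] - (o + latency)
          v[on] <- v[on] + a * (td / tau) * exp(1 - td / tau)
        }
      }
      cc_sweep(v, sample_rate,
               events = data.frame(kind = "spiral_scan",
                                   onset = unlist(plan$spiral_onsets)),
               sweep_time = (k - 1) * plan$inter_sweep_s)
    })
    structure(list(centroids = centroids, plan = plan,
                   truth = data.frame(cell = seq_len(n_cells),
                                      connected = connected,
                                      amplitude = amps),
                   sweeps = sweeps),
              class = "optomap_scene")
  })
}
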