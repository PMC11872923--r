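# Two-photon optogenetic plasticity-mapping logic: spiral stimulation
# trajectories, sequential stimulation plans, connection detection from sweep
# sets, randomized induction assignment and induction scheduling.

#' Archimedean spiral stimulation trajectory
#'
#' r(theta) = spacing * theta / (2 pi), sampled at a constant angular-progress
#' rate over the scan duration; the endpoint sits at radius diameter/2.
#'
#' @param center XY centre (um).
#' @param diameter Spiral diameter (um), default 15.
#' @param spacing Revolution spacing (um), default 1.
#' @param duration Scan duration (ms), default 7.
#' @param sample_interval Output sampling interval (ms).
#' @param parameterization `"angular"` (constant d theta/dt, default) or
#'   `"arc"` (constant linear speed).
#' @return `spiral_trajectory`: data.frame `t` (ms), `x`, `y` plus parameter
#'   attributes.
#' @export
archimedean_spiral <- function(center = c(0, 0), diameter = 15, spacing = 1,
                               duration = 7, sample_interval = 0.01,
                               parameterization = c("angular", "arc")) {
  parameterization <- match.arg(parameterization)
  assert_scalar_num(diameter, "diameter", lower = 1e-9)
  assert_scalar_num(spacing, "spacing", lower = 1e-9)
  assert_scalar_num(duration, "duration", lower = 1e-9)
  b <- spacing / (2 * pi)
  theta_max <- (diameter / 2) / b
  tt <- seq(0, duration, by = sample_interval)
  if (parameterization == "angular") {
    th <- theta_max * tt / duration
  } else {
    # arc length s(theta) = b/2 (theta sqrt(1+theta^2) + asinh(theta))
    s_of <- function(th) b / 2 * (th * sqrt(1 + th^2) + asinh(th))
    s_tot <- s_of(theta_max)
    s_t <- s_tot * tt / duration
    th <- vapply(s_t, function(s)
      stats::uniroot(function(u) s_of(u) - s, c(0, theta_max),
                     tol = 1e-10)$root, numeric(1))
  }
  r <- b * th
  out <- data.frame(t = tt, x = center[1] + r * cos(th),
                    y = center[2] + r * sin(th))
  structure(out, class = c("spiral_trajectory", "data.frame"),
            diameter = diameter, spacing = spacing, duration = duration,
            theta_max = theta_max, revolutions = theta_max / (2 * pi))
}

# Arc length of an Archimedean spiral r = b theta, used as an oracle in tests.
spiral_arc_length <- function(spacing, theta_max) {
  b <- spacing / (2 * pi)
  b / 2 * (theta_max * sqrt(1 + theta_max^2) + asinh(theta_max))
}

#' Build a sequential stimulation plan
#'
#' Each candidate cell receives a burst of 2 spiral scans (7 ms each) at
#' 30 Hz; bursts are separated by 500 ms across cells; the whole sequence is
#' repeated over `repeats` sweeps spaced `inter_sweep_s` seconds apart.
#'
#' @param cell_centroids data.frame or matrix of candidate-cell XY centres.
#' @param repeats Sweeps, default 20.
#' @param n_spirals Spirals per burst (default 2).
#' @param burst_hz Within-burst spiral rate (Hz), default 30.
#' @param inter_cell_ms Gap between cell bursts (ms), default 500.
#' @param inter_sweep_s Inter-sweep interval (s), default 25.
#' @return `stimulus_plan`: list with per-cell burst onsets (`onsets`, ms
#'   within a sweep), `repeats`, timing constants, `sweep_duration_ms`.
#' @export
build_stimulus_plan <- function(cell_centroids, repeats = 20, n_spirals = 2,
                                burst_hz = 30, inter_cell_ms = 500,
                                inter_sweep_s = 25) {
  xy <- as.matrix(cell_centroids)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 1L) stopf("need at least one candidate cell")
  isi_ms <- 1000 / burst_hz
  burst_onset <- (seq_len(n) - 1) * inter_cell_ms
  spiral_onsets <- lapply(burst_onset, function(o) o + (seq_len(n_spirals) - 1) * isi_ms)
  dur <- burst_onset[n] + (n_spirals - 1) * isi_ms + 7 + 300
  structure(list(centroids = xy, n_cells = n, repeats = repeats,
                 burst_onsets = burst_onset, spiral_onsets = spiral_onsets,
                 n_spirals = n_spirals, burst_hz = burst_hz,
                 inter_cell_ms = inter_cell_ms, inter_sweep_s = inter_sweep_s,
                 sweep_duration_ms = dur),
            class = "stimulus_plan")
}

#' Detect synaptic connections from optomapping sweeps
#'
#' For each candidate cell, the EPSP amplitude at its first spiral onset is
#' measured on every sweep; the cell is called connected when the mean
#' amplitude exceeds `k_sigma` standard errors of the baseline noise and the
#' response latency is physiological.
#'
#' @param sweeps List of [cc_sweep()]s aligned to `plan` (one per repeat).
#' @param plan A [build_stimulus_plan()] result.
#' @param k_sigma Detection threshold in noise SEM units, default 3.
#' @param window EPSP search window after stimulation (ms).
#' @param latency_range Acceptable median latency (ms after spiral onset).
#' @return `connection_map`: data.frame per cell with `mean_amplitude`,
#'   `noise_sd`, `statistic` (amplitude / SEM), `latency`, `connected`,
#'   `induction` (NA until assigned).
#' @export
detect_connections <- function(sweeps, plan, k_sigma = 3, window = 30,
                               latency_range = c(0.5, 6)) {
  stopifnot(inherits(plan, "stimulus_plan"))
  nswp <- length(sweeps)
  if (nswp < 2L) stopf("need at least two sweeps")
  # baseline noise: the same measurement statistic applied at stimulus-free
  # onsets late in the inter-burst gaps of each sweep
  sweep_ms <- min(vapply(sweeps, function(sw)
    length(sw$voltage) * 1000 / sw$sample_rate, numeric(1)))
  null_onsets <- plan$burst_onsets + plan$inter_cell_ms - (window + 20)
  null_onsets <- null_onsets[null_onsets > 20 &
                               null_onsets + window + 5 < sweep_ms]
  noise <- unlist(lapply(sweeps, function(sw)
    vapply(null_onsets, function(o)
      measure_epsp(sw, o, search_ms = window, check_spikes = FALSE)$amplitude,
      numeric(1))))
  noise_sd <- stats::sd(noise)
  out <- do.call(rbind, lapply(seq_len(plan$n_cells), function(ci) {
    onset <- plan$spiral_onsets[[ci]][1]
    mm <- lapply(sweeps, function(sw)
      measure_epsp(sw, onset, search_ms = window))
    amps <- vapply(mm, function(m) m$amplitude, numeric(1))
    lats <- vapply(mm, function(m) m$latency, numeric(1))
    ok <- is.finite(amps)
    mean_amp <- mean(amps[ok])
    stat <- mean_amp / (noise_sd / sqrt(sum(ok)))
    med_lat <- stats::median(lats[ok], na.rm = TRUE)
    lat_ok <- is.finite(med_lat) && med_lat >= latency_range[1] &&
      med_lat <= latency_range[2]
    data.frame(cell = ci, mean_amplitude = mean_amp, noise_sd = noise_sd,
               statistic = stat, latency = med_lat,
               connected = stat > k_sigma && lat_ok,
               induction = NA_character_)
  }))
  rownames(out) <- NULL
  class(out) <- c("connection_map", "data.frame")
  out
}

#' Randomly assign induction conditions to connected cells
#'
#' Round-robin over a seeded shuffle, so condition counts differ by at most
#' one among connected cells; unconnected cells stay unassigned.
#'
#' @param map A `connection_map`.
#' @param conditions Condition labels.
#' @param seed RNG seed.
#' @return The map with `induction` filled in for connected cells.
#' @export
assign_inductions <- function(map,
                              conditions = c("synchronous", "asynchronous", "control"),
                              seed = 1) {
  idx <- which(map$connected)
  if (!length(idx)) return(map)
  with_seed(seed, {
    ord <- sample(idx)
    map$induction[ord] <- rep_len(conditions, length(ord))
  })
  map
}

#' Induction protocol specification
#'
#' @param condition `"synchronous"`, `"asynchronous"` or `"control"`.
#' @param delta_t Timing offset (ms) between EPSP onset and the postsynaptic
#'   pulse train: +10 for synchronous, -90 for asynchronous.
#' @param pairing_freq Pairing frequency (Hz), default 50.
#' @param n_pre,n_post Pulses per train, default 5 each.
#' @param repeats Induction repeats, default 15.
#' @param inter_repeat_s Seconds between repeats, default 25.
#' @export
induction_spec <- function(condition = c("synchronous", "asynchronous", "control"),
                           delta_t = NULL, pairing_freq = 50,
                           n_pre = 5, n_post = 5, repeats = 15,
                           inter_repeat_s = 25) {
  condition <- match.arg(condition)
  delta_t <- delta_t %||% switch(condition, synchronous = 10,
                                 asynchronous = -90, control = NA_real_)
  structure(list(condition = condition, delta_t = delta_t,
                 pairing_freq = pairing_freq, n_pre = n_pre,
                 n_post = if (condition == "control") 0L else n_post,
                 repeats = repeats, inter_repeat_s = inter_repeat_s),
            class = "induction_spec")
}

#' Schedule an induction repeat
#'
#' Timing differences are relative to EPSP onset: postsynaptic pulses are
#' offset so that the first pulse starts `delta_t` ms after the first EPSP
#' onset (synchronous), or so that the first EPSP onset lands 10 ms after
#' the last pulse (asynchronous, delta_t = -90 with 5 pulses at 50 Hz).
#'
#' @param spec An [induction_spec()].
#' @param measured_epsp_latency EPSP latency after spiral onset (ms).
#' @return List: `pre_onsets` (spiral scans, ms), `post_onsets` (current
#'   pulses, ms; empty for control), `epsp_onsets`.
#' @export
schedule_induction <- function(spec, measured_epsp_latency = 1.5) {
  isi <- 1000 / spec$pairing_freq
  pre0 <- (seq_len(spec$n_pre) - 1) * isi
  if (spec$condition == "control")
    return(list(pre_onsets = pre0, post_onsets = numeric(0),
                epsp_onsets = pre0 + measured_epsp_latency))
  if (spec$condition == "synchronous") {
    pre <- pre0
    post <- pre + measured_epsp_latency + spec$delta_t
  } else {
    post <- (seq_len(spec$n_post) - 1) * isi
    # first EPSP onset at -delta_t after the first pulse
    pre <- -spec$delta_t - measured_epsp_latency + pre0
  }
  list(pre_onsets = pre, post_onsets = post,
       epsp_onsets = pre + measured_epsp_latency)
}

#' Run the plasticity pipeline over a set of connections
#'
#' Applies [plasticity_magnitude()] to each experiment and pools results by
#' induction condition (mean +/- SEM), mirroring the pooled after/before,
#' change-in-PPR and CV summaries of an optomapping plasticity study.
#'
#' @param experiments List of `plasticity_experiment`s, each carrying its
#'   assigned `condition`.
#' @param ... Passed to [plasticity_magnitude()].
#' @return List: `per_connection` data.frame and `pooled` data.frame (one row
#'   per condition: ratio, delta PPR, normalized 1/CV^2, mean_norm, n).
#' @export
run_plasticity_pipeline <- function(experiments, ...) {
  rows <- lapply(seq_along(experiments), function(i) {
    ex <- experiments[[i]]
    pr <- plasticity_magnitude(ex, ...)
    data.frame(connection = i,
               condition = ex$condition %||% "unspecified",
               ratio = pr$ratio, delta_ppr = pr$delta_ppr,
               ppr_before = pr$ppr_before, ppr_after = pr$ppr_after,
               mean_norm = pr$mean_norm, inv_cv2_norm = pr$inv_cv2_norm,
               quadrant = pr$quadrant)
  })
  per <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(split(per, per$condition), function(df)
    data.frame(condition = df$condition[1], n = nrow(df),
               ratio = mean(df$ratio), ratio_sem = sem(df$ratio),
               delta_ppr = mean(df$delta_ppr), delta_ppr_sem = sem(df$delta_ppr),
               mean_norm = mean(df$mean_norm),
               inv_cv2_norm = mean(df$inv_cv2_norm))))
  rownames(pooled) <- NULL
  list(per_connection = per, pooled = pooled)
}
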