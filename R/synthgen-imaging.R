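# Synthetic two-channel Ca2+ imaging data: distance-dependent bAP line scans
# with depolarization boosting, and three-condition (EPSPs/APs/Both) frame
# scans with a tunable interaction term.

#' Parameters of the synthetic Ca2+ generator
#'
#' @param amplitude_at_soma Peak dG/R of the bAP transient at distance 0
#'   (dimensionless).
#' @param decay_length_lambda Exponential length constant of the bAP
#'   decrement (um).
#' @param boost_slope_beta Distance-dependent multiplicative depolarization
#'   boost (per um): expected amplitude scales by (1 + beta d) when
#'   depolarized.
#' @param interaction_gamma Supralinear interaction of the Both condition
#'   under synchronous timing (0 = exactly linear summation; default 0.43,
#'   i.e. 143% supralinearity).
#' @param interaction_gamma_async Interaction under asynchronous timing
#'   (default -0.10, mildly sublinear).
#' @param noise_green,noise_red Per-pixel shot-noise scales (SD =
#'   scale * sqrt(signal)).
#' @param depth_attenuation Fluorescence loss per um of depth (both
#'   channels).
#' @param ca_decay_tau Transient decay time constant (ms).
#' @param diameter Dendrite diameter (um) encoded in the red profile.
#' @param epsp_dgr_int,ap_dgr_int Expected dG/R integrals (percent, 0-1000 ms
#'   window) of the EPSPs-only and APs-only frame-scan responses.
#' @export
synth_ca_params <- function(amplitude_at_soma = 0.5, decay_length_lambda = 100,
                            boost_slope_beta = 0.005,
                            interaction_gamma = 0.43,
                            interaction_gamma_async = -0.10,
                            noise_green = 0.8, noise_red = 0.8,
                            depth_attenuation = 0.005, ca_decay_tau = 200,
                            diameter = 1.0, epsp_dgr_int = 3.1,
                            ap_dgr_int = 2.5) {
  if (!is.numeric(decay_length_lambda) || length(decay_length_lambda) != 1L ||
      is.na(decay_length_lambda) || decay_length_lambda <= 0)
    stopf("'decay_length_lambda' must be positive (Inf allowed)")
  if (interaction_gamma < -1) stopf("interaction_gamma must be >= -1")
  if (noise_green < 0 || noise_red < 0) stopf("noise scales must be >= 0")
  assert_scalar_num(depth_attenuation, "depth_attenuation", lower = 0)
  structure(as.list(environment()), class = "synth_ca_params")
}

# decaying transient time course, unit peak amplitude, onset in ms
transient_course <- function(tms, onset, tau, rise = 5) {
  f <- numeric(length(tms))
  on <- tms >= onset
  td <- tms[on] - onset
  f[on] <- (1 - exp(-td / rise)) * exp(-td / tau)
  f
}

# mean of transient_course over [0, window] ms after onset, for converting
# target integrals (percent) into peak amplitudes
transient_integral_factor <- function(tau, window = 1000, rise = 5, dt = 1) {
  tt <- seq(0, window - dt, by = dt)
  mean((1 - exp(-tt / rise)) * exp(-tt / tau))
}

#' Generate a synthetic bAP line-scan dataset
#'
#' Per distance d and state, the expected green transient amplitude is
#' amplitude_at_soma * exp(-d / lambda) * (1 + beta d [depolarized]); the red
#' channel carries a Gaussian dendrite profile of known diameter; both
#' channels are attenuated with imaging depth; shot noise is signal-scaled
#' Gaussian.
#'
#' @param ca A [synth_ca_params()].
#' @param distances Dendritic distances to scan (um).
#' @param states Conditions to interleave.
#' @param n_repeats Repeats per distance x state.
#' @param seed RNG seed.
#' @param n_lines,n_pixels,ms_per_line,pixels_per_um,stim_onset Scan geometry.
#' @return List of [linescan_movie()]s with the planted amplitude attached as
#'   attribute `truth`.
#' @export
gen_linescan_dataset <- function(ca = synth_ca_params(),
                                 distances = seq(10, 150, length.out = 12),
                                 states = c("rest", "depolarized"),
                                 n_repeats = 10, seed = 1,
                                 n_lines = 800, n_pixels = 128,
                                 ms_per_line = 1, pixels_per_um = 1.84,
                                 stim_onset = 300) {
  stopifnot(inherits(ca, "synth_ca_params"))
  if (!length(distances)) stopf("empty distance list")
  with_seed(seed, {
    tms <- (seq_len(n_lines) - 1) * ms_per_line
    px <- seq_len(n_pixels)
    x0 <- n_pixels / 2
    sigma_px <- (ca$diameter / 2.3548) * pixels_per_um
    prof <- 1000 * exp(-((px - x0)^2) / (2 * sigma_px^2))
    bg_level <- 60
    course <- transient_course(tms, stim_onset, ca$ca_decay_tau)
    out <- list()
    for (di in seq_along(distances)) {
      d <- distances[di]
      depth <- 20 + 0.3 * d
      att <- exp(-ca$depth_attenuation * depth)
      for (st in states) for (k in seq_len(n_repeats)) {
        A <- ca$amplitude_at_soma * exp(-d / ca$decay_length_lambda) *
          (1 + ca$boost_slope_beta * d * (st == "depolarized"))
        roi <- abs(px - x0) <= 2 * sigma_px
        # Ca2+ signal scales with indicator content, i.e. with the red
        # structural signal, and is confined to the dendrite (roi band):
        # dG/R then equals A * course exactly in expectation
        Rclean <- matrix(rep(prof + bg_level, each = n_lines),
                         nrow = n_lines) * att
        Gclean <- (matrix(rep(0.3 * prof + bg_level, each = n_lines),
                          nrow = n_lines) +
                   outer(A * course, (prof + bg_level) * roi)) * att
        G <- Gclean + stats::rnorm(length(Gclean)) * ca$noise_green *
          sqrt(pmax(Gclean, 0))
        R <- Rclean + stats::rnorm(length(Rclean)) * ca$noise_red *
          sqrt(pmax(Rclean, 0))
        background <- px <= 15 | px > n_pixels - 15
        mv <- linescan_movie(G, R, ms_per_line, pixels_per_um, stim_onset,
                             distance_to_soma = d, depth = depth, state = st,
                             roi = roi, background = background)
        attr(mv, "truth") <- list(amplitude = A, distance = d,
                                  diameter = ca$diameter, location = di,
                                  repeat_ = k)
        out[[length(out) + 1L]] <- mv
      }
    }
    out
  })
}

#' Generate an interleaved EPSPs/APs/Both frame-scan dataset
#'
#' One dendritic segment: n_repeats of each condition, interleaved. The
#' expected Both response is (1 + gamma) * (EPSPs + APs), with gamma taken
#' from `interaction_gamma` (synchronous) or `interaction_gamma_async`.
#'
#' @param ca A [synth_ca_params()].
#' @param timing `"synchronous"` or `"asynchronous"`.
#' @param n_repeats Repeats per condition (>= 2).
#' @param seed RNG seed.
#' @param segment Segment identifier attached to the movies.
#' @param segment_scale Multiplicative response scale of this segment
#'   (models segment-to-segment variability).
#' @param n_frames,rows,cols,ms_per_frame,stim_onset Scan geometry (64 x 8
#'   pixels at 8 ms/frame over 2 s by default).
#' @return List of [framescan_movie()]s in interleaved sweep order, planted
#'   truth attached to each as attribute `truth`.
#' @export
gen_framescan_dataset <- function(ca = synth_ca_params(),
                                  timing = c("synchronous", "asynchronous"),
                                  n_repeats = 16, seed = 1, segment = 1L,
                                  segment_scale = 1,
                                  n_frames = 250, rows = 8, cols = 64,
                                  ms_per_frame = 8, stim_onset = 400) {
  stopifnot(inherits(ca, "synth_ca_params"))
  timing <- match.arg(timing)
  if (n_repeats < 2) stopf("n_repeats must be >= 2")
  gamma <- if (timing == "synchronous") ca$interaction_gamma
           else ca$interaction_gamma_async
  with_seed(seed, {
    tms <- (seq_len(n_frames) - 1) * ms_per_frame
    course <- transient_course(tms, stim_onset, ca$ca_decay_tau)
    intf <- transient_integral_factor(ca$ca_decay_tau)
    A_e <- ca$epsp_dgr_int / 100 / intf * segment_scale
    A_a <- ca$ap_dgr_int / 100 / intf * segment_scale
    amps <- c(EPSPs = A_e, APs = A_a, Both = (1 + gamma) * (A_e + A_a))
    # spatial profile: Gaussian dendrite band across the frame
    rr <- matrix(seq_len(rows), rows, cols)
    cc_ <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    prof <- 800 * exp(-((rr - (rows + 1) / 2)^2) / (2 * 1.5^2))
    bg_level <- 60
    roi <- prof > 0.5 * max(prof) & cc_ > 10 & cc_ <= cols - 10
    background <- rr <= 1
    sig_mask <- roi        # Ca2+ signal confined to the imaged dendrite band
    conditions <- rep(c("EPSPs", "APs", "Both"), n_repeats)
    out <- vector("list", length(conditions))
    for (i in seq_along(conditions)) {
      cond <- conditions[i]
      A <- amps[[cond]]
      Rcl <- array(rep(prof + bg_level, n_frames),
                   dim = c(rows, cols, n_frames))
      Gcl <- array(rep(0.3 * prof + bg_level, n_frames),
                   dim = c(rows, cols, n_frames)) +
        array(as.vector((prof + bg_level) * sig_mask) %o% (A * course),
              dim = c(rows, cols, n_frames))
      # reorder to frames x rows x cols
      Gcl <- aperm(Gcl, c(3, 1, 2)); Rcl <- aperm(Rcl, c(3, 1, 2))
      G <- Gcl + stats::rnorm(length(Gcl)) * ca$noise_green * sqrt(pmax(Gcl, 0))
      R <- Rcl + stats::rnorm(length(Rcl)) * ca$noise_red * sqrt(pmax(Rcl, 0))
      mv <- framescan_movie(G, R, ms_per_frame, roi, background, stim_onset,
                            condition = cond, timing = timing,
                            segment = segment)
      attr(mv, "truth") <- list(gamma = gamma, amplitude = A,
                                expected_integral = 100 * A * intf)
      out[[i]] <- mv
    }
    out
  })
}

#' Generate a multi-segment frame-scan study
#'
#' @param ca A [synth_ca_params()].
#' @param timing Pairing timing.
#' @param n_segments Dendritic segments.
#' @param n_repeats Repeats per condition per segment.
#' @param seed RNG seed.
#' @param segment_sd Log-normal SD of the per-segment response scale.
#' @return Flat list of [framescan_movie()]s across all segments.
#' @export
gen_framescan_segments <- function(ca = synth_ca_params(),
                                   timing = "synchronous", n_segments = 8,
                                   n_repeats = 16, seed = 1,
                                   segment_sd = 0.2) {
  with_seed(seed, {
    scales <- exp(stats::rnorm(n_segments, 0, segment_sd))
    seeds <- vapply(seq_len(n_segments), function(i) child_seed(seed, i),
                    numeric(1))
    unlist(lapply(seq_len(n_segments), function(si)
      gen_framescan_dataset(ca, timing, n_repeats, seed = seeds[si],
                            segment = si, segment_scale = scales[si])),
      recursive = FALSE)
  })
}
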