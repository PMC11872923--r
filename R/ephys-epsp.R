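# EPSP amplitude, paired-pulse ratio, plasticity magnitude and
# coefficient-of-variation quantal analysis.

#' Measure an EPSP amplitude
#'
#' Amplitude is the mean over a ~1-ms window centred on the post-onset peak
#' (searched up to `search_ms` after onset, bounded to stay clear of the next
#' pulse in 30-Hz pairs) minus the mean of the 8 ms just before onset.
#' Latency is the time from stimulus onset to the 20%-of-peak rise point
#' (on a lightly smoothed trace); for
#' extracellular stimulation it is expected at 1-2 ms and flagged otherwise.
#'
#' @param sw A [cc_sweep()].
#' @param epsp_onset Stimulus onset (ms).
#' @param search_ms Peak search horizon after onset.
#' @param peak_win_ms Measurement window width (ms).
#' @param base_ms Pre-onset baseline length (ms).
#' @param latency_range Expected latency band for flagging (ms), or NULL.
#' @param check_spikes Flag and omit the amplitude if a spike contaminates
#'   the search window.
#' @return List: `amplitude` (mV, NA if contaminated), `latency` (ms),
#'   `latency_ok`, `contaminated`, `peak_time` (ms).
#' @export
measure_epsp <- function(sw, epsp_onset, search_ms = 30, peak_win_ms = 1,
                         base_ms = 8, latency_range = NULL,
                         check_spikes = TRUE) {
  v <- sw$voltage
  dt_ms <- 1000 / sw$sample_rate
  i_on <- ms_to_idx(sw, epsp_onset)
  i_end <- ms_to_idx(sw, epsp_onset + search_ms)
  if (i_end <= i_on) stopf("search window outside sweep")
  base_idx <- ms_to_idx(sw, epsp_onset - base_ms):max(1L, i_on - 1L)
  base <- mean(v[base_idx])
  contaminated <- FALSE
  if (check_spikes) {
    sub <- cc_sweep(v[i_on:i_end], sw$sample_rate)
    if (nrow(detect_spikes(sub)) > 0L) contaminated <- TRUE
  }
  # locate the peak on a ~0.5-ms smoothed copy (reduces the upward bias of
  # picking the max of raw noise), then average the raw trace around it
  seg_pk <- v[i_on:i_end]
  ks0 <- max(1L, as.integer(round(0.5 / dt_ms)))
  if (ks0 > 1L && length(seg_pk) > ks0) {
    sm <- as.numeric(stats::filter(seg_pk, rep(1 / ks0, ks0), sides = 2))
    seg_pk <- ifelse(is.na(sm), seg_pk, sm)
  }
  pk_rel <- which.max(seg_pk)
  pk_i <- i_on + pk_rel - 1L
  hw <- max(1L, as.integer(round(peak_win_ms / dt_ms / 2)))
  w0 <- max(i_on, pk_i - hw); w1 <- min(length(v), pk_i + hw)
  amp <- mean(v[w0:w1]) - base
  # 20%-of-amplitude rise point, on a ~0.5-ms smoothed trace to resist noise
  lat <- NA_real_
  if (amp > 0) {
    level <- base + 0.2 * amp
    seg <- v[i_on:pk_i]
    ks <- max(1L, as.integer(round(0.5 / dt_ms)))
    if (ks > 1L && length(seg) > ks)
      seg <- stats::filter(seg, rep(1 / ks, ks), sides = 2) |> as.numeric() |>
        (\(z) ifelse(is.na(z), seg, z))()
    ix <- which(seg >= level)[1]
    if (!is.na(ix)) {
      if (ix == 1L) lat <- 0
      else {
        frac <- (level - seg[ix - 1]) / (seg[ix] - seg[ix - 1])
        lat <- ((ix - 2) + frac) * dt_ms
      }
    }
  }
  latency_ok <- if (is.null(latency_range) || is.na(lat)) NA
    else lat >= latency_range[1] && lat <= latency_range[2]
  list(amplitude = if (contaminated) NA_real_ else amp,
       latency = lat, latency_ok = latency_ok,
       contaminated = contaminated, peak_time = (pk_i - 1) * dt_ms)
}

#' Paired-pulse EPSP amplitudes and ratio
#'
#' EPSP2 is measured after subtracting the extrapolated single-exponential
#' decay of EPSP1 (fit to the 10 ms preceding the second stimulus); a naive
#' uncorrected mode is available for sensitivity analysis.
#'
#' @param sw A [cc_sweep()].
#' @param onset1,onset2 Stimulus onsets (ms).
#' @param noise_floor Amplitudes at or below this (mV) leave PPR undefined.
#' @param correct_decay Apply the exponential decay correction.
#' @param ... Passed to [measure_epsp()].
#' @return List: `epsp1`, `epsp2` (mV), `ppr` (NA with `undefined = TRUE` if
#'   EPSP1 is at or below the noise floor).
#' @export
paired_pulse <- function(sw, onset1, onset2, noise_floor = 0.05,
                         correct_decay = TRUE, ...) {
  stopifnot(onset2 > onset1)
  gap <- onset2 - onset1
  m1 <- measure_epsp(sw, onset1, search_ms = min(30, gap - 1), ...)
  v <- sw$voltage
  dt_ms <- 1000 / sw$sample_rate
  if (correct_decay && !is.na(m1$amplitude) && m1$amplitude > noise_floor) {
    fit_idx <- ms_to_idx(sw, onset2 - 10):ms_to_idx(sw, onset2)
    base_idx <- ms_to_idx(sw, onset1 - 8):ms_to_idx(sw, onset1)
    v0 <- mean(v[base_idx])
    yy <- v[fit_idx] - v0
    tt <- (fit_idx - 1) * dt_ms
    corr <- rep(0, length(v))
    if (all(yy > 0)) {
      cf <- stats::coef(stats::lm(log(yy) ~ tt))
      tau <- -1 / cf[2]
      if (is.finite(tau) && tau > 0) {
        # subtract from the fit window onward, so the EPSP2 pre-onset
        # baseline is corrected too
        t_all <- (seq_along(v) - 1) * dt_ms
        later <- t_all >= onset2 - 10
        corr[later] <- exp(cf[1] + cf[2] * t_all[later])
      }
    }
    sw2 <- sw
    sw2$voltage <- v - corr
  } else sw2 <- sw
  m2 <- measure_epsp(sw2, onset2, search_ms = min(30, gap - 1), ...)
  undefined <- is.na(m1$amplitude) || m1$amplitude <= noise_floor
  list(epsp1 = m1$amplitude, epsp2 = m2$amplitude,
       ppr = if (undefined || is.na(m2$amplitude)) NA_real_
             else m2$amplitude / m1$amplitude,
       undefined = undefined)
}

#' Plasticity magnitude from a plasticity experiment
#'
#' Applies QC, measures EPSP1/EPSP2 on every passing sweep, and compares the
#' baseline epoch against the post-induction epoch starting `post_start_min`
#' minutes after induction: after/before ratio (percent), PPRs and their
#' change, and CV diagnostics.
#'
#' @param exp A `plasticity_experiment` (see
#'   [gen_plasticity_experiment()]): list with `sweeps`, `stim_onsets`
#'   (length-2 ms), `induction_time` (s).
#' @param post_start_min Post-epoch start, minutes after induction.
#' @param min_sweeps Minimum passing sweeps required per epoch.
#' @param ppr_mode `"per_sweep"` (mean of per-sweep EPSP2/EPSP1, undefined
#'   sweeps excluded) or `"ratio_of_means"`.
#' @return `plasticity_result` list: `epsp_before`, `epsp_after`, `ratio`
#'   (percent), `ppr_before`, `ppr_after`, `delta_ppr`, `cv_before`,
#'   `cv_after`, `mean_norm`, `inv_cv2_norm`, per-sweep table.
#' @export
plasticity_magnitude <- function(exp, post_start_min = 10, min_sweeps = 5,
                                 ppr_mode = c("per_sweep", "ratio_of_means")) {
  ppr_mode <- match.arg(ppr_mode)
  qc <- qc_filter(exp$sweeps)
  times <- vapply(exp$sweeps, function(s) s$sweep_time, numeric(1))
  meas <- lapply(exp$sweeps, paired_pulse,
                 onset1 = exp$stim_onsets[1], onset2 = exp$stim_onsets[2])
  tab <- data.frame(
    sweep_time = times, pass = qc$pass_mask,
    epsp1 = vapply(meas, function(m) m$epsp1 %||% NA_real_, numeric(1)),
    epsp2 = vapply(meas, function(m) m$epsp2 %||% NA_real_, numeric(1)),
    ppr = vapply(meas, function(m) m$ppr %||% NA_real_, numeric(1)))
  before <- tab$pass & times < exp$induction_time & !is.na(tab$epsp1)
  after <- tab$pass & times >= exp$induction_time + 60 * post_start_min &
    !is.na(tab$epsp1)
  if (sum(before) < min_sweeps || sum(after) < min_sweeps)
    stopf("insufficient passing sweeps (before %d, after %d, need %d)",
          sum(before), sum(after), min_sweeps)
  ep_b <- mean(tab$epsp1[before]); ep_a <- mean(tab$epsp1[after])
  ppr_epoch <- function(idx) {
    if (ppr_mode == "per_sweep") mean(tab$ppr[idx], na.rm = TRUE)
    else mean(tab$epsp2[idx], na.rm = TRUE) / mean(tab$epsp1[idx], na.rm = TRUE)
  }
  ppr_b <- ppr_epoch(before); ppr_a <- ppr_epoch(after)
  cv <- cv_analysis(tab$epsp1[before], tab$epsp1[after])
  structure(list(epsp_before = ep_b, epsp_after = ep_a,
                 ratio = 100 * ep_a / ep_b,
                 ppr_before = ppr_b, ppr_after = ppr_a,
                 delta_ppr = ppr_a - ppr_b,
                 cv_before = cv$cv_before, cv_after = cv$cv_after,
                 mean_norm = cv$mean_norm, inv_cv2_norm = cv$inv_cv2_norm,
                 quadrant = cv$quadrant,
                 n_before = sum(before), n_after = sum(after),
                 table = tab, qc = qc),
            class = "plasticity_result")
}

#' Coefficient-of-variation quantal analysis
#'
#' Under a binomial release model, 1/CV^2 of EPSP amplitudes is N p / (1 - p)
#' (independent of quantal size q), so joint movement of the normalized mean
#' and normalized 1/CV^2 diagnoses where plasticity is expressed: points
#' below the diagonal (1/CV^2 falling faster than the mean) indicate a
#' presynaptic change in release probability; points on/above the diagonal
#' with a changed mean indicate a postsynaptic change in quantal size.
#'
#' @param before_amps,after_amps EPSP1 amplitudes (mV) per epoch.
#' @param n_boot Bootstrap replicates for the CI attached when an epoch has
#'   fewer than 10 sweeps.
#' @return List: `cv_before`, `cv_after`, `mean_norm`, `inv_cv2_norm`,
#'   `quadrant` (`"presynaptic"`, `"postsynaptic"`, `"no_change"`), and
#'   optionally `inv_cv2_norm_ci`.
#' @export
cv_analysis <- function(before_amps, after_amps, n_boot = 500) {
  b <- before_amps[is.finite(before_amps)]
  a <- after_amps[is.finite(after_amps)]
  cvb <- stats::sd(b) / mean(b)
  cva <- stats::sd(a) / mean(a)
  mean_norm <- mean(a) / mean(b)
  inv_cv2_norm <- (1 / cva^2) / (1 / cvb^2)
  quadrant <- if (abs(mean_norm - 1) < 0.05 && abs(inv_cv2_norm - 1) < 0.1)
    "no_change"
  else if (inv_cv2_norm < mean_norm) "presynaptic" else "postsynaptic"
  out <- list(cv_before = cvb, cv_after = cva, mean_norm = mean_norm,
              inv_cv2_norm = inv_cv2_norm, quadrant = quadrant)
  if (length(b) < 10 || length(a) < 10) {
    warnf("CV analysis on < 10 sweeps per epoch; attaching bootstrap CI")
    boots <- replicate(n_boot, {
      bb <- sample(b, replace = TRUE); aa <- sample(a, replace = TRUE)
      (mean(aa)^2 / stats::var(aa)) / (mean(bb)^2 / stats::var(bb))
    })
    out$inv_cv2_norm_ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  out
}
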