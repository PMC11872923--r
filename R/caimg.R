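# Two-channel Ca2+ transient quantification (dG/R), dendrite diameter
# estimation, bAP attenuation profiling and EPSP/AP/Both linearity analysis.
#
# dG/R at time t is (G_roi(t) - mean baseline G_roi) / (mean baseline R_roi),
# minus the identical quantity computed on a background mask. The red channel
# is Ca2+-insensitive, so the denominator is its baseline mean: the ratio is
# depth-robust because scattering attenuates both channels alike.

#' Construct a line-scan movie
#'
#' @param green,red Matrices (lines x pixels), same shape; arbitrary
#'   fluorescence units.
#' @param ms_per_line Line period in ms.
#' @param pixels_per_um Spatial sampling along the line.
#' @param stim_onset Stimulus onset in ms from scan start.
#' @param distance_to_soma,depth Location of the scanned dendrite (um).
#' @param state `"rest"` or `"depolarized"`.
#' @param roi,background Optional default pixel masks (logical or index).
#' @export
linescan_movie <- function(green, red, ms_per_line, pixels_per_um, stim_onset,
                           distance_to_soma = NA_real_, depth = NA_real_,
                           state = "rest", roi = NULL, background = NULL) {
  stopifnot(is.matrix(green), is.matrix(red), all(dim(green) == dim(red)))
  assert_scalar_num(ms_per_line, "ms_per_line", lower = 1e-9)
  dur <- nrow(green) * ms_per_line
  if (stim_onset < 0 || stim_onset >= dur)
    stopf("stim_onset (%g ms) outside scan duration (%g ms)", stim_onset, dur)
  structure(list(green = green, red = red, ms_per_line = ms_per_line,
                 pixels_per_um = pixels_per_um, stim_onset = stim_onset,
                 distance_to_soma = distance_to_soma, depth = depth,
                 state = state, roi = roi, background = background),
            class = "linescan_movie")
}

#' Construct a frame-scan movie
#'
#' @param green,red 3-D arrays (frames x rows x cols).
#' @param ms_per_frame Frame period in ms.
#' @param roi,background Disjoint, non-empty logical masks (rows x cols).
#' @param stim_onset Stimulus onset (ms).
#' @param condition `"EPSPs"`, `"APs"` or `"Both"`.
#' @param timing `"synchronous"` or `"asynchronous"`.
#' @param segment Dendritic segment identifier.
#' @export
framescan_movie <- function(green, red, ms_per_frame, roi, background,
                            stim_onset, condition, timing = "synchronous",
                            segment = 1L) {
  stopifnot(length(dim(green)) == 3L, all(dim(green) == dim(red)))
  stopifnot(is.logical(roi), is.logical(background),
            all(dim(roi) == dim(green)[2:3]),
            all(dim(background) == dim(green)[2:3]))
  if (!any(roi) || !any(background)) stopf("roi and background must be non-empty")
  if (any(roi & background)) stopf("roi and background must be disjoint")
  condition <- match.arg(condition, c("EPSPs", "APs", "Both"))
  structure(list(green = green, red = red, ms_per_frame = ms_per_frame,
                 roi = roi, background = background, stim_onset = stim_onset,
                 condition = condition, timing = timing, segment = segment),
            class = "framescan_movie")
}

movie_dt <- function(movie) {
  if (inherits(movie, "linescan_movie")) movie$ms_per_line else movie$ms_per_frame
}

# time x n_mask_pixels matrix of the chosen channel restricted to a mask
mask_timeseries <- function(movie, channel, mask) {
  if (inherits(movie, "linescan_movie")) {
    m <- movie[[channel]]
    if (is.logical(mask)) mask <- which(mask)
    if (!length(mask)) stopf("empty mask")
    m[, mask, drop = FALSE]
  } else {
    a <- movie[[channel]]
    nt <- dim(a)[1]
    flat <- matrix(a, nrow = nt)
    idx <- which(as.vector(mask))
    if (!length(idx)) stopf("empty mask")
    flat[, idx, drop = FALSE]
  }
}

#' Compute a background-subtracted dG/R transient
#'
#' @param movie A [linescan_movie()] or [framescan_movie()].
#' @param roi,background Masks; default to the movie's own.
#' @param baseline_window Length-2 ms interval ending at (or before) stimulus
#'   onset; defaults to the 100 ms (line scans) or 200 ms (frame scans)
#'   preceding the stimulus.
#' @return A `ca_transient`: list with `dgr`, `time` (ms), `baseline_window`,
#'   `stim_onset`. The baseline-window mean of `dgr` is zero by construction.
#' @export
compute_dgr <- function(movie, roi = NULL, background = NULL,
                        baseline_window = NULL) {
  roi <- roi %||% movie$roi
  background <- background %||% movie$background
  if (is.null(roi) || is.null(background)) stopf("roi and background required")
  dt <- movie_dt(movie)
  nt <- if (inherits(movie, "linescan_movie")) nrow(movie$green) else dim(movie$green)[1]
  tms <- (seq_len(nt) - 1) * dt
  if (is.null(baseline_window)) {
    blen <- if (inherits(movie, "linescan_movie")) 100 else 200
    baseline_window <- c(max(0, movie$stim_onset - blen), movie$stim_onset)
  }
  if (baseline_window[2] > movie$stim_onset + 1e-9)
    stopf("baseline window must precede stimulus onset")
  bidx <- tms >= baseline_window[1] & tms < baseline_window[2]
  if (!any(bidx)) stopf("empty baseline window")
  one <- function(mask) {
    G <- rowMeans(mask_timeseries(movie, "green", mask))
    R <- rowMeans(mask_timeseries(movie, "red", mask))
    Rb <- mean(R[bidx])
    if (Rb <= 0) stopf("non-positive baseline red signal")
    (G - mean(G[bidx])) / Rb
  }
  dgr <- one(roi) - one(background)
  structure(list(dgr = dgr, time = tms, baseline_window = baseline_window,
                 stim_onset = movie$stim_onset),
            class = "ca_transient")
}

#' Integrate a Ca2+ transient
#'
#' Time-averaged dG/R over an integration window after stimulus onset,
#' reported in percent (x100). Default window 0-1000 ms; the bAP protocol
#' uses 0-275 ms.
#'
#' @param transient A `ca_transient` from [compute_dgr()].
#' @param window Length-2 ms interval relative to stimulus onset.
#' @return Scalar percent value.
#' @export
integrate_transient <- function(transient, window = c(0, 1000)) {
  stopifnot(inherits(transient, "ca_transient"), length(window) == 2L)
  if (window[2] <= window[1]) stopf("empty integration window")
  t_rel <- transient$time - transient$stim_onset
  idx <- t_rel >= window[1] & t_rel < window[2]
  if (!any(idx)) stopf("integration window outside the time base")
  100 * mean(transient$dgr[idx])
}

#' Estimate dendrite diameter from the red channel
#'
#' Full width at half maximum of the time-averaged red line profile above its
#' background level (profile median), converted to micrometres.
#'
#' @param movie A [linescan_movie()].
#' @return Diameter in micrometres.
#' @export
estimate_dendrite_diameter <- function(movie) {
  stopifnot(inherits(movie, "linescan_movie"))
  prof <- colMeans(movie$red)
  bg <- stats::median(prof)
  pk <- which.max(prof)
  amp <- prof[pk] - bg
  if (amp <= 3 * stats::mad(prof - bg)) stopf("no dominant profile above background")
  half <- bg + amp / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(pk)) else pk:length(prof)
    below <- which(prof[idx] < half)[1]
    if (is.na(below) || below == 1L) return(NA_real_)
    i1 <- idx[below - 1L]; i2 <- idx[below]
    i1 + (half - prof[i1]) / (prof[i2] - prof[i1]) * (i2 - i1)
  }
  xl <- cross("left"); xr <- cross("right")
  if (is.na(xl) || is.na(xr)) stopf("profile does not return to background")
  abs(xr - xl) / movie$pixels_per_um
}

#' bAP attenuation profile over dendritic distance
#'
#' Takes diameter-corrected dG/R integrals at matched rest/depolarized
#' locations, fits an exponential length constant per state, and correlates
#' the depolarization boost with distance.
#'
#' @param measurements data.frame with columns `location`, `distance`,
#'   `state` (`"rest"`/`"depolarized"`), `integral` (percent) and `diameter`
#'   (um); one row per location x state.
#' @param boost `"difference"` (depolarized - rest, default) or `"ratio"`.
#' @return `bap_profile` list: per-location table, fitted `lambda` per state,
#'   `boost` series, and the Pearson correlation of boost vs distance.
#' @export
bap_distance_profile <- function(measurements, boost = c("difference", "ratio")) {
  boost <- match.arg(boost)
  need <- c("location", "distance", "state", "integral", "diameter")
  if (!all(need %in% names(measurements)))
    stopf("measurements need columns: %s", paste(need, collapse = ", "))
  measurements$corrected <- measurements$integral * measurements$diameter
  # average over repeats within location x state before pairing
  measurements <- stats::aggregate(
    cbind(distance, corrected) ~ location + state, data = measurements, FUN = mean)
  wide <- merge(
    measurements[measurements$state == "rest",
                 c("location", "distance", "corrected")],
    measurements[measurements$state == "depolarized",
                 c("location", "corrected")],
    by = "location", suffixes = c("_rest", "_depol"))
  if (nrow(wide) == 0L || nrow(wide) <
      length(unique(measurements$location)))
    stopf("unmatched rest/depolarized pairs")
  fits <- lapply(c(rest = "corrected_rest", depol = "corrected_depol"),
                 function(cn) fit_exp_decay(wide$distance, wide[[cn]]))
  bv <- if (boost == "difference") wide$corrected_depol - wide$corrected_rest
        else wide$corrected_depol / wide$corrected_rest
  corr <- tryCatch(pearson(wide$distance, bv),
                   error = function(e) list(r = NA_real_, p = NA_real_))
  structure(list(table = wide, lambda_rest = fits$rest$lambda,
                 lambda_depolarized = fits$depol$lambda,
                 amplitude_rest = fits$rest$a,
                 amplitude_depolarized = fits$depol$a,
                 boost = bv, boost_metric = boost,
                 boost_distance_r = corr$r, boost_distance_p = corr$p),
            class = "bap_profile")
}

# y ~ a * exp(-d / lambda); log-linear start, nls refinement.
fit_exp_decay <- function(d, y) {
  eps <- max(y) * 1e-6
  lf <- stats::lm(log(pmax(y, eps)) ~ d)
  l0 <- -1 / stats::coef(lf)[2]
  a0 <- exp(stats::coef(lf)[1])
  if (!is.finite(l0) || l0 <= 0) { l0 <- max(d) * 10; a0 <- mean(y) }
  fit <- tryCatch(
    suppressWarnings(stats::nls(y ~ a * exp(-d / lambda),
               start = list(a = a0, lambda = l0),
               control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(a = unname(a0), lambda = unname(l0)))
  co <- stats::coef(fit)
  list(a = unname(co["a"]), lambda = unname(co["lambda"]))
}

#' EPSP/AP/Both linearity analysis
#'
#' For each dendritic segment, averages dG/R integrals per condition across
#' interleaved repeats, forms Sum = EPSPs + APs, and reports supralinearity =
#' 100 x Both / Sum. The group statistic is the mean of per-segment ratios,
#' not the ratio of group means.
#'
#' @param movies List of [framescan_movie()]s covering >= 2 repeats each of
#'   conditions EPSPs, APs and Both (any number of segments).
#' @param window Integration window (ms after stimulus onset).
#' @return `linearity_result`: per-segment table, group means/SEM of the Both
#'   and Sum integrals, and `supralinearity` (mean percent) with SEM.
#' @export
linearity_analysis <- function(movies, window = c(0, 1000)) {
  stopifnot(length(movies) > 0L)
  info <- data.frame(
    segment = vapply(movies, function(m) as.integer(m$segment), integer(1)),
    condition = vapply(movies, function(m) m$condition, character(1)),
    integral = vapply(movies, function(m)
      integrate_transient(compute_dgr(m), window), numeric(1)))
  per_seg <- do.call(rbind, lapply(split(info, info$segment), function(df) {
    cnt <- table(df$condition)
    if (length(cnt) < 3L || any(cnt < 2L))
      stopf("each segment needs >= 2 repeats of all three conditions")
    mn <- tapply(df$integral, df$condition, mean)
    data.frame(segment = df$segment[1], epsps = mn[["EPSPs"]],
               aps = mn[["APs"]], both = mn[["Both"]],
               sum = mn[["EPSPs"]] + mn[["APs"]])
  }))
  bad <- per_seg$sum <= 0
  if (any(bad)) {
    message(sprintf("excluding %d segment(s) with non-positive Sum: %s",
                    sum(bad), paste(per_seg$segment[bad], collapse = ", ")))
    per_seg <- per_seg[!bad, , drop = FALSE]
  }
  if (nrow(per_seg) == 0L) stopf("no usable segments")
  per_seg$supralinearity <- 100 * per_seg$both / per_seg$sum
  rownames(per_seg) <- NULL
  structure(list(
    per_segment = per_seg,
    dgr_both = mean(per_seg$both), dgr_both_sem = sem(per_seg$both),
    dgr_sum = mean(per_seg$sum), dgr_sum_sem = sem(per_seg$sum),
    supralinearity = mean(per_seg$supralinearity),
    supralinearity_sem = sem(per_seg$supralinearity)),
    class = "linearity_result")
}
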