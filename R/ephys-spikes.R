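# Current-clamp sweep container, spike detection and intrinsic-excitability
# metrics (rheobase, instantaneous frequency, accommodation), input
# resistance and sweep-level quality control.

#' Construct a current-clamp sweep
#'
#' @param voltage Membrane potential (mV).
#' @param sample_rate Hz (> 1 kHz).
#' @param current Injected current (pA), optional.
#' @param events data.frame of stimulus events: columns `kind`
#'   (`extracellular_stim`, `spiral_scan`, `current_pulse`, `test_pulse`),
#'   `onset` (ms), and optionally `amplitude` (pA) and `duration` (ms).
#' @param temperature Bath temperature (degC).
#' @param sweep_time Seconds since experiment start.
#' @export
cc_sweep <- function(voltage, sample_rate, current = NULL, events = NULL,
                  temperature = 33, sweep_time = 0) {
  assert_scalar_num(sample_rate, "sample_rate", lower = 1000)
  if (!is.null(current) && length(current) != length(voltage))
    stopf("voltage and current must have the same length")
  events <- events %||% data.frame(kind = character(0), onset = numeric(0))
  structure(list(voltage = as.numeric(voltage), current = current,
                 sample_rate = sample_rate, events = events,
                 temperature = temperature, sweep_time = sweep_time),
            class = "sweep")
}

sweep_time_ms <- function(sw) (seq_along(sw$voltage) - 1) * 1000 / sw$sample_rate

ms_to_idx <- function(sw, ms) pmax(1L, pmin(length(sw$voltage),
                                            as.integer(round(ms * sw$sample_rate / 1000)) + 1L))

#' Detect action potentials in a sweep
#'
#' Spikes are upward dV/dt threshold crossings (default 20 mV/ms) with a 1-ms
#' refractory period. Threshold voltage is taken at the crossing sample,
#' height is peak minus threshold, and half-width is measured at half-height
#' with linear interpolation.
#'
#' @param sw A [cc_sweep()].
#' @param dvdt_threshold mV/ms.
#' @param refractory_ms Minimum spike separation.
#' @return data.frame: `time` (ms), `threshold`, `peak`, `height`,
#'   `half_width` (ms); zero rows for subthreshold traces.
#' @export
detect_spikes <- function(sw, dvdt_threshold = 20, refractory_ms = 1) {
  v <- sw$voltage
  dt_ms <- 1000 / sw$sample_rate
  dvdt <- c(0, diff(v)) / dt_ms
  up <- which(dvdt >= dvdt_threshold & c(0, dvdt[-length(dvdt)]) < dvdt_threshold)
  empty <- data.frame(time = numeric(0), threshold = numeric(0),
                      peak = numeric(0), height = numeric(0),
                      half_width = numeric(0))
  if (!length(up)) return(empty)
  keep <- c(TRUE, diff(up) * dt_ms >= refractory_ms)
  # refractory: greedy scan
  sel <- integer(0); last <- -Inf
  for (i in up) {
    if ((i - last) * dt_ms >= refractory_ms) { sel <- c(sel, i); last <- i }
  }
  out <- lapply(sel, function(i) {
    thr <- v[i]
    win_end <- min(length(v), i + as.integer(5 / dt_ms))
    pk_rel <- which.max(v[i:win_end])
    pk_i <- i + pk_rel - 1L
    pk <- v[pk_i]
    h <- pk - thr
    half <- thr + h / 2
    rise <- interp_cross(v, i, pk_i, half, dt_ms, rising = TRUE)
    fall_end <- min(length(v), pk_i + as.integer(10 / dt_ms))
    fall <- interp_cross(v, pk_i, fall_end, half, dt_ms, rising = FALSE)
    data.frame(time = (i - 1) * dt_ms, threshold = thr, peak = pk, height = h,
               half_width = if (is.na(rise) || is.na(fall)) NA_real_ else fall - rise)
  })
  do.call(rbind, out)
}

interp_cross <- function(v, from, to, level, dt_ms, rising) {
  if (to <= from) return((from - 1) * dt_ms)
  seg <- v[from:to]
  idx <- if (rising) which(seg >= level)[1] else which(seg < level)[1]
  if (is.na(idx) || idx == 1L) return(if (rising) (from - 1) * dt_ms else NA_real_)
  i1 <- idx - 1L; i2 <- idx
  frac <- (level - seg[i1]) / (seg[i2] - seg[i1])
  ((from - 1) + (i1 - 1) + frac) * dt_ms
}

#' Spike-train metrics from a current-step family
#'
#' Uses the smallest step that elicits at least one spike (the rheobase
#' trace) for threshold/height/half-width; instantaneous frequency and
#' accommodation come from that trace if it holds >= 2 spikes, otherwise from
#' the next higher step. Accommodation is the ratio of the first to last
#' instantaneous frequency.
#'
#' @param step_family List of [cc_sweep()]s ordered by increasing step current;
#'   each must carry a `current_pulse` event with an `amplitude` (pA).
#' @return `spike_train_metrics` list.
#' @export
rheobase_metrics <- function(step_family) {
  amps <- vapply(step_family, function(s) {
    ev <- s$events[s$events$kind == "current_pulse", , drop = FALSE]
    if (!nrow(ev)) stopf("sweep lacks a current_pulse event")
    ev$amplitude[1]
  }, numeric(1))
  if (is.unsorted(amps)) stopf("steps must be ordered by amplitude")
  spikes <- lapply(step_family, detect_spikes)
  first <- which(vapply(spikes, nrow, integer(1)) >= 1L)[1]
  if (is.na(first)) stopf("no sweep elicited spikes; rheobase undefined")
  sp <- spikes[[first]]
  freq_src <- sp
  if (nrow(sp) < 2L) {
    nxt <- first + 1L
    while (nxt <= length(spikes) && nrow(spikes[[nxt]]) < 2L) nxt <- nxt + 1L
    if (nxt <= length(spikes)) freq_src <- spikes[[nxt]]
  }
  isi <- diff(freq_src$time)
  inst_first <- if (length(isi)) 1000 / isi[1] else NA_real_
  inst_last <- if (length(isi)) 1000 / isi[length(isi)] else NA_real_
  structure(list(rheobase_current = amps[first],
                 threshold = sp$threshold[1], height = sp$height[1],
                 half_width = sp$half_width[1],
                 inst_freq_first = inst_first, inst_freq_last = inst_last,
                 accommodation = inst_first / inst_last),
            class = "spike_train_metrics")
}

#' Input resistance from a hyperpolarizing test pulse
#'
#' Steady-state deflection (mean of the last 50 ms of the pulse) relative to
#' the 50 ms preceding pulse onset, divided by the pulse amplitude.
#'
#' @param sw A [cc_sweep()] with a `test_pulse` event (`onset` ms, `amplitude`
#'   pA, `duration` ms; defaults -25 pA, 250 ms).
#' @return Resistance in megaohms.
#' @export
input_resistance <- function(sw) {
  ev <- sw$events[sw$events$kind == "test_pulse", , drop = FALSE]
  if (!nrow(ev)) stopf("sweep lacks a test_pulse event")
  onset <- ev$onset[1]
  amp <- if ("amplitude" %in% names(ev)) ev$amplitude[1] else -25
  dur <- if ("duration" %in% names(ev)) ev$duration[1] else 250
  if (amp == 0) stopf("test pulse amplitude is zero")
  v <- sw$voltage
  base <- mean(v[ms_to_idx(sw, onset - 50):max(1L, ms_to_idx(sw, onset) - 1L)])
  steady <- mean(v[ms_to_idx(sw, onset + dur - 50):
                     max(1L, ms_to_idx(sw, onset + dur) - 1L)])
  1000 * (steady - base) / amp    # mV / pA -> GOhm -> x1000 = MOhm
}

resting_vm <- function(sw, window_ms = 50) {
  first_ev <- suppressWarnings(min(sw$events$onset))
  end <- if (is.finite(first_ev)) max(window_ms, first_ev - 50) else window_ms
  mean(sw$voltage[1:ms_to_idx(sw, min(end, window_ms))])
}

#' Sweep-level quality control
#'
#' Flags sweeps whose input resistance drifts more than `rin_tol` (fraction)
#' or resting potential more than `vm_tol` (mV) from the reference (mean of
#' the first `n_ref` sweeps), or whose temperature leaves `temp_range`. The
#' record is truncated at the first failure: all later sweeps fail too.
#'
#' @param sweeps List of [cc_sweep()]s in acquisition order.
#' @param rin_tol,vm_tol,temp_range QC thresholds.
#' @param n_ref Number of initial sweeps defining the reference.
#' @return `qc_record`: `input_resistance`, `resting_vm`, `temperature`,
#'   per-sweep `pass_mask`, `truncation_index` (NA if clean).
#' @export
qc_filter <- function(sweeps, rin_tol = 0.30, vm_tol = 8,
                      temp_range = c(32, 34), n_ref = 5,
                      mode = c("truncate", "discard")) {
  mode <- match.arg(mode)
  n <- length(sweeps)
  rin <- vapply(sweeps, input_resistance, numeric(1))
  vm <- vapply(sweeps, resting_vm, numeric(1))
  temp <- vapply(sweeps, function(s) s$temperature, numeric(1))
  nr <- min(n_ref, n)
  rin_ref <- mean(rin[1:nr]); vm_ref <- mean(vm[1:nr])
  fail <- abs(rin - rin_ref) / abs(rin_ref) > rin_tol |
    abs(vm - vm_ref) > vm_tol |
    temp < temp_range[1] | temp > temp_range[2]
  trunc <- which(fail)[1]
  pass <- !fail
  if (mode == "truncate" && !is.na(trunc)) pass[trunc:n] <- FALSE
  structure(list(input_resistance = rin, resting_vm = vm, temperature = temp,
                 pass_mask = pass,
                 truncation_index = if (is.na(trunc)) NA_integer_ else trunc),
            class = "qc_record")
}
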