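#' Stimulation-locked EMG trace
#'
#' @param samples numeric vector of EMG samples (microvolts).
#' @param rate_hz sampling rate (samples per second).
#' @param t0_s time of the first sample relative to the stimulus (seconds;
#'   negative means pre-stimulus).
#' @return an object of class `emg_trace`.
#' @export
emg_trace <- function(samples, rate_hz, t0_s) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("trace must have at least 2 samples")
  if (!is.finite(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  structure(list(samples = samples, rate_hz = rate_hz, t0_s = t0_s),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat("emg_trace:", length(x$samples), "samples @", x$rate_hz, "Hz, t0 =",
      x$t0_s, "s\n")
  invisible(x)
}

trace_times <- function(trace) {
  trace$t0_s + (seq_along(trace$samples) - 1L) / trace$rate_hz
}

# steady-state initial filter state for a unit-step input (per-sample state
# of the transposed direct-form-II realisation)
lfilter_zi <- function(b, a) {
  a0 <- a[1]
  n <- max(length(a), length(b)) - 1L
  a <- c(a, rep(0, n + 1L - length(a))) / a0
  b <- c(b, rep(0, n + 1L - length(b))) / a0
  rhs <- b[-1] - a[-1] * b[1]
  if (n == 1L) return(rhs / (1 + a[2]))
  companion <- rbind(-a[-1], cbind(diag(1, n - 1L), rep(0, n - 1L)))
  solve(diag(n) - t(companion), rhs)
}

# forward-backward IIR filtering with odd-reflection padding and
# steady-state initial conditions (zero-phase, squared magnitude response)
filtfilt_zi <- function(b, a, x) {
  padlen <- 3L * (max(length(a), length(b)) - 1L + 1L)
  n <- length(x)
  if (n <= padlen)
    stop("trace too short for zero-phase filtering (need > ", padlen,
         " samples)")
  ext <- c(2 * x[1] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase high-pass filter an EMG trace
#'
#' High-pass Butterworth filter applied forward and backward (bi-directional,
#' zero phase shift). Defaults follow the standard motor-mapping
#' preprocessing: 30 Hz cutoff, 2nd order.
#'
#' @param trace an [emg_trace].
#' @param cutoff_hz high-pass cutoff frequency (Hz).
#' @param order filter order of each pass.
#' @return the filtered [emg_trace] (same length, rate and time base).
#' @export
highpass_filter <- function(trace, cutoff_hz = 30, order = 2) {
  if (trace$rate_hz <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the cutoff frequency")
  flt <- signal::butter(order, cutoff_hz / (trace$rate_hz / 2), type = "high")
  trace$samples <- filtfilt_zi(flt$b, flt$a, trace$samples)
  trace
}

#' Pre-stimulus baseline standard deviation
#'
#' Standard deviation (population convention, 1/N) of the samples in the
#' window `[-window_ms, 0)` before the stimulus.
#'
#' @param trace an [emg_trace] (normally already high-pass filtered).
#' @param window_ms baseline window length before the stimulus (ms).
#' @return baseline SD in microvolts.
#' @export
baseline_sd <- function(trace, window_ms = 200) {
  t <- trace_times(trace)
  if (t[1] > -window_ms / 1000 + 1e-12)
    stop("trace does not cover the ", window_ms, " ms pre-stimulus window")
  sel <- t >= -window_ms / 1000 - 1e-12 & t < 0
  x <- trace$samples[sel]
  if (length(x) < 2L) stop("too few samples in the baseline window")
  sqrt(mean((x - mean(x))^2))
}

#' Classify a trace as MEP or non-MEP
#'
#' Peak-to-peak amplitude in the post-stimulus response window, accepted as a
#' motor-evoked potential when it is larger than `k_sd` times the
#' pre-stimulus baseline SD and smaller than the artifact bound
#' `upper_limit_uv` (both strict).
#'
#' @param trace an [emg_trace], already high-pass filtered.
#' @param response_window_ms two-element window (ms post-stimulus) searched
#'   for the peak-to-peak deflection.
#' @param baseline_window_ms baseline window passed to [baseline_sd()].
#' @param k_sd lower-bound multiplier of the baseline SD.
#' @param upper_limit_uv artifact-rejection upper bound (microvolts; 10 mV).
#' @return list with `p2p_uv`, `baseline_sd_uv`, `is_mep`, and `reason`
#'   (one of `"ok"`, `"below_threshold"`, `"artifact_too_large"`).
#' @export
detect_mep <- function(trace, response_window_ms = c(15, 50),
                       baseline_window_ms = 200, k_sd = 20,
                       upper_limit_uv = 10000) {
  t <- trace_times(trace)
  w <- response_window_ms / 1000
  if (w[1] < t[1] - 1e-12 || w[2] > t[length(t)] + 1e-12)
    stop("response window outside trace")
  sel <- t >= w[1] - 1e-12 & t <= w[2] + 1e-12
  x <- trace$samples[sel]
  if (length(x) < 2L) stop("response window contains too few samples")
  p2p <- max(x) - min(x)
  bsd <- baseline_sd(trace, baseline_window_ms)
  if (p2p >= upper_limit_uv) {
    reason <- "artifact_too_large"
  } else if (p2p <= k_sd * bsd) {
    reason <- "below_threshold"
  } else {
    reason <- "ok"
  }
  list(p2p_uv = p2p, baseline_sd_uv = bsd, is_mep = reason == "ok",
       reason = reason)
}

#' Find the hotspot among stimulation events
#'
#' Returns the event with the largest MEP peak-to-peak amplitude; ties go to
#' the earliest event.
#'
#' @param events data.frame of stimulation events with a `p2p_uv` column, or
#'   any data.frame accompanied by `p2p_uv`.
#' @param p2p_uv optional numeric vector overriding `events$p2p_uv`.
#' @return list with `index` (row of the winning event) and `event` (that
#'   row of `events`).
#' @export
find_hotspot <- function(events, p2p_uv = events$p2p_uv) {
  if (is.null(p2p_uv) || length(p2p_uv) == 0L || nrow(events) == 0L)
    stop("no events to search")
  if (length(p2p_uv) != nrow(events))
    stop("p2p_uv must have one value per event")
  idx <- which.max(p2p_uv) # first maximum = lowest index on ties
  list(index = idx, event = events[idx, , drop = FALSE])
}

#' Estimate the resting motor threshold
#'
#' The resting motor threshold (RMT) is the lowest stimulator intensity at
#' which the MEP amplitude exceeds `threshold_uv` in at least `n_required`
#' out of `n_trials` stimulations.
#'
#' @param trials named list mapping stimulator intensity (names coercible to
#'   numeric) to the vector of MEP peak-to-peak amplitudes at that intensity.
#' @param threshold_uv amplitude criterion (microvolts).
#' @param n_required minimum number of suprathreshold trials.
#' @param n_trials required number of trials per intensity.
#' @return list with `rmt_intensity` and `per_intensity_counts` (data.frame
#'   with `intensity`, `n_above`, `n_total`).
#' @export
estimate_rmt <- function(trials, threshold_uv = 50, n_required = 5,
                         n_trials = 10) {
  ints <- as.numeric(names(trials))
  if (anyNA(ints)) stop("trial names must be numeric intensities")
  ord <- order(ints)
  counts <- data.frame(
    intensity = ints[ord],
    n_above = vapply(trials[ord], function(a) sum(a > threshold_uv), 0L),
    n_total = vapply(trials[ord], length, 0L),
    row.names = NULL
  )
  if (any(counts$n_total != n_trials))
    stop("each intensity must have exactly ", n_trials, " trials")
  hit <- counts$n_above >= n_required
  if (!any(hit))
    stop("no tested intensity reaches ", n_required, " of ", n_trials,
         " responses above ", threshold_uv, " uV")
  list(rmt_intensity = counts$intensity[which(hit)[1]],
       per_intensity_counts = counts)
}
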