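#' Chest-wall displacement model
#'
#' Displacement of the chest wall over time for a subject breathing at
#' `rr` breaths/min with heart rate `hr` beats/min:
#'
#' \deqn{d(t) = A_r (1 + m \sin(2\pi t / T_{pb})) \sin(2\pi f_r t)
#'            + A_c \sin(2\pi f_c t)}
#'
#' where \eqn{A_r} = `resp_amp`, \eqn{m} = `pb_depth`, \eqn{T_{pb}} =
#' `pb_period`, \eqn{f_r} = `rr/60`, \eqn{A_c} = `cardiac_amp`, and
#' \eqn{f_c} = `hr/60`. With `pb_depth > 0` the tidal-breathing envelope is
#' itself periodic (periodic breathing), which places spectral sidebands at
#' \eqn{f_r \pm 1/T_{pb}}.
#'
#' @param t Numeric vector of times in seconds, monotonically increasing.
#' @param profile A [subject_profile()].
#' @return Numeric vector of displacements in meters, one per element of `t`.
#' @export
#' @examples
#' p <- subject_profile(rr = 20, hr = 100)
#' d <- chest_displacement(seq(0, 10, by = 0.05), p)
chest_displacement <- function(t, profile) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!all(is.finite(t))) stop("chest_displacement: t must be finite")
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("chest_displacement: t must be monotonically increasing")
  }
  resp_env <- profile$resp_amp *
    (1 + profile$pb_depth * sin(2 * pi * t / profile$pb_period))
  resp_env * sin(2 * pi * (profile$rr / 60) * t) +
    profile$cardiac_amp * sin(2 * pi * (profile$hr / 60) * t)
}

# Displacement with optionally drifting rates. Rates drift linearly at
# `*_drift` BPM per second; phase is the exact integral of the
# instantaneous frequency so the reference streams and the motion agree.
displacement_with_drift <- function(t, profile, hr_drift = 0, rr_drift = 0) {
  if (hr_drift == 0 && rr_drift == 0) {
    return(chest_displacement(t, profile))
  }
  phase_resp <- 2 * pi * ((profile$rr / 60) * t + (rr_drift / 60) * t^2 / 2)
  phase_card <- 2 * pi * ((profile$hr / 60) * t + (hr_drift / 60) * t^2 / 2)
  resp_env <- profile$resp_amp *
    (1 + profile$pb_depth * sin(2 * pi * t / profile$pb_period))
  resp_env * sin(phase_resp) + profile$cardiac_amp * sin(phase_card)
}

#' Baseband recording container
#'
#' A UWB radar baseband recording: a nonnegative `n_bins x n_samples`
#' amplitude matrix (one slow-time series per range bin) plus the
#' acquisition geometry.
#'
#' @param amplitude Numeric matrix, `n_bins x n_samples`, finite and
#'   nonnegative.
#' @param geometry A [radar_geometry()]; `nrow(amplitude)` must equal
#'   `geometry$n_bins`.
#' @param t0 Start time of the recording in seconds.
#' @return An object of class `baseband_recording`.
#' @export
baseband_recording <- function(amplitude, geometry, t0 = 0) {
  stopifnot(
    is.matrix(amplitude),
    inherits(geometry, "radar_geometry"),
    nrow(amplitude) == geometry$n_bins
  )
  if (!all(is.finite(amplitude))) {
    stop("baseband_recording: amplitudes must be finite")
  }
  if (any(amplitude < 0)) {
    stop("baseband_recording: amplitudes must be nonnegative")
  }
  structure(list(amplitude = amplitude, geometry = geometry, t0 = t0),
            class = "baseband_recording")
}

#' @export
print.baseband_recording <- function(x, ...) {
  cat(sprintf("<baseband_recording> %d bins x %d samples (%.1f s at %g Hz)\n",
              nrow(x$amplitude), ncol(x$amplitude),
              ncol(x$amplitude) / x$geometry$fs, x$geometry$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording A [baseband_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$amplitude) / recording$geometry$fs
}

#' Simulate a UWB baseband recording with known ground truth
#'
#' Generates a bins-by-samples amplitude matrix for a subject whose chest
#' moves according to [chest_displacement()]. Bin `b` centered at range
#' \eqn{r_b} receives
#' \deqn{a_b(t) = |E(r_b)\,(1 + \kappa\, d(t)) + \varepsilon_b(t)|}
#' with a Gaussian reflection envelope \eqn{E} centered at the subject's
#' range, a linear displacement-to-amplitude gain \eqn{\kappa}
#' (small-motion regime, so the spectral content of the amplitude equals
#' that of the displacement), and i.i.d. Gaussian noise whose standard
#' deviation is `noise_sd * (10 - sensitivity) / 5`. The modulus models the
#' envelope detector: baseband amplitudes are nonnegative. Clutter
#' [movement_event()]s multiply the affected bins by `1 + magnitude` over
#' their interval.
#'
#' Ground-truth vitals are emitted at 3 Hz, matching a bedside patient
#' monitor; they are constant unless a drift is configured.
#'
#' @param geometry A [radar_geometry()].
#' @param profile A [subject_profile()].
#' @param duration Recording length in seconds, `>= 10`; must yield an
#'   integer number of samples.
#' @param noise_sd Baseline noise standard deviation in amplitude units,
#'   before the sensitivity scaling.
#' @param events List of [movement_event()]s.
#' @param seed Integer seed fixing all randomness.
#' @param kappa Displacement-to-amplitude gain, 1/meters.
#' @param hr_drift,rr_drift Linear drift of the true rates, BPM per second.
#' @param ref_fs Reference-monitor sampling rate, Hz.
#'
#' @return A list with elements `recording` (a [baseband_recording()]) and
#'   `vitals` (a tibble with columns `time`, `hr`, `rr` at `ref_fs` Hz).
#' @export
#' @examples
#' sim <- simulate_recording(radar_geometry(), subject_profile(),
#'                           duration = 60, seed = 1)
#' sim$recording
#' head(sim$vitals)
simulate_recording <- function(geometry = radar_geometry(),
                               profile = subject_profile(),
                               duration = 300,
                               noise_sd = 0.01,
                               events = list(),
                               seed = 1L,
                               kappa = 50,
                               hr_drift = 0,
                               rr_drift = 0,
                               ref_fs = 3) {
  stopifnot(
    inherits(geometry, "radar_geometry"),
    inherits(profile, "subject_profile"),
    "duration must be >= 10 s" = duration >= 10
  )
  n_samples <- duration * geometry$fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("duration * fs must be an integer number of samples")
  }
  n_samples <- as.integer(round(n_samples))
  if (profile$subject_range < geometry$zone_start ||
      profile$subject_range > geometry$zone_end) {
    warning(sprintf(
      "subject_range %.2f m lies outside the detection zone [%.2f, %.2f] m",
      profile$subject_range, geometry$zone_start, geometry$zone_end))
  }
  for (ev in events) {
    stopifnot(inherits(ev, "movement_event"))
    if (ev$start + ev$duration > duration || ev$start < 0) {
      stop(sprintf("movement_event [%g, %g] s lies outside the recording span [0, %g] s",
                   ev$start, ev$start + ev$duration, duration))
    }
    if (any(ev$affected_bins > geometry$n_bins)) {
      stop("movement_event affects bins beyond n_bins")
    }
  }

  t <- (seq_len(n_samples) - 1) / geometry$fs
  d <- displacement_with_drift(t, profile, hr_drift, rr_drift)
  env <- exp(-0.5 * ((bin_ranges(geometry) - profile$subject_range) /
                       profile$range_spread)^2)
  # outer product: each bin is the envelope-weighted modulated carrier
  amp <- env %o% (1 + kappa * d)

  sd_eff <- noise_sd * (10 - geometry$sensitivity) / 5
  if (sd_eff > 0) {
    set.seed(as.integer(seed))
    amp <- amp + matrix(stats::rnorm(length(amp), sd = sd_eff),
                        nrow = nrow(amp))
  }
  for (ev in events) {
    idx <- which(t >= ev$start & t < ev$start + ev$duration)
    amp[ev$affected_bins, idx] <- amp[ev$affected_bins, idx] * (1 + ev$magnitude)
  }
  amp <- abs(amp)

  n_ref <- as.integer(round(duration * ref_fs))
  t_ref <- (seq_len(n_ref) - 1) / ref_fs
  vitals <- tibble::tibble(
    time = t_ref,
    hr = profile$hr + hr_drift * t_ref,
    rr = profile$rr + rr_drift * t_ref
  )
  list(recording = baseband_recording(amp, geometry), vitals = vitals)
}
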