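#' Radar acquisition geometry
#'
#' Describes the range-bin layout and sampling of a UWB pulse radar in the
#' configuration used for bedside vital-sign monitoring: 52 range bins of
#' 0.0388 m starting at a 0.3 m range offset, a 0.4--1.0 m detection zone,
#' and 20 baseband samples per second per bin.
#'
#' @param n_bins Number of range bins.
#' @param bin_length Length of one range bin in meters.
#' @param range_offset Distance from the antenna to the first bin, meters.
#' @param zone_start,zone_end Detection-zone limits in meters.
#' @param fs Baseband sampling rate per bin, samples/s.
#' @param carrier_freq Carrier frequency in Hz (metadata only; not used in
#'   the amplitude model).
#' @param sensitivity Device sensitivity level, integer 0--9. Higher
#'   sensitivity resolves smaller motions but admits more noise; the
#'   simulator maps it to a noise multiplier `(10 - sensitivity) / 5`.
#'
#' @return An object of class `radar_geometry`.
#' @export
#' @examples
#' geom <- radar_geometry()
#' bin_ranges(geom)[1:5]
radar_geometry <- function(n_bins = 52L,
                           bin_length = 0.0388,
                           range_offset = 0.3,
                           zone_start = 0.4,
                           zone_end = 1.0,
                           fs = 20,
                           carrier_freq = 7.46e9,
                           sensitivity = 5L) {
  stopifnot(
    "n_bins must be >= 1" = is.numeric(n_bins) && n_bins >= 1,
    "bin_length must be > 0" = is.numeric(bin_length) && bin_length > 0,
    "zone_start must be < zone_end" = zone_start < zone_end,
    "fs must be > 0" = is.numeric(fs) && fs > 0,
    "sensitivity must be in 0..9" = sensitivity >= 0 && sensitivity <= 9
  )
  structure(
    list(
      n_bins = as.integer(n_bins), bin_length = bin_length,
      range_offset = range_offset, zone_start = zone_start,
      zone_end = zone_end, fs = fs, carrier_freq = carrier_freq,
      sensitivity = as.integer(sensitivity)
    ),
    class = "radar_geometry"
  )
}

#' Range-bin center distances
#'
#' Bin `b` (0-based) is centered at `range_offset + (b + 1/2) * bin_length`.
#'
#' @param geometry A [radar_geometry()].
#' @return Numeric vector of bin-center ranges in meters, length `n_bins`.
#' @export
bin_ranges <- function(geometry) {
  stopifnot(inherits(geometry, "radar_geometry"))
  geometry$range_offset + (seq_len(geometry$n_bins) - 0.5) * geometry$bin_length
}

#' @export
print.radar_geometry <- function(x, ...) {
  cat(sprintf(
    "<radar_geometry> %d bins x %.4f m, offset %.2f m, zone [%.2f, %.2f] m, fs %g Hz, sensitivity %d\n",
    x$n_bins, x$bin_length, x$range_offset, x$zone_start, x$zone_end,
    x$fs, x$sensitivity
  ))
  invisible(x)
}

#' Subject motion profile for the synthetic simulator
#'
#' Parameterizes the chest-wall displacement of a monitored child: tidal
#' breathing of amplitude `resp_amp` whose envelope may itself be modulated
#' periodically (periodic breathing, common in infant sleep), plus a much
#' smaller cardiac component. Defaults describe a paediatric subject:
#' HR 110 beats/min, RR 30 breaths/min, ~5 mm respiratory and ~0.5 mm
#' cardiac chest-wall excursion, mild periodic-breathing modulation, lying
#' 0.7 m from the antenna.
#'
#' @param rr Respiratory rate, breaths/min (6--80).
#' @param hr Heart rate, beats/min (40--240).
#' @param resp_amp Respiratory chest-wall displacement amplitude, meters.
#' @param cardiac_amp Cardiac displacement amplitude, meters.
#' @param pb_depth Periodic-breathing modulation index in `[0, 1)`; 0 means
#'   steady tidal breathing.
#' @param pb_period Periodic-breathing cycle length, seconds.
#' @param subject_range Distance of the chest wall from the antenna, meters.
#' @param range_spread Spatial extent of the reflecting body, meters
#'   (standard deviation of the Gaussian reflection envelope over range).
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(rr = 30,
                            hr = 110,
                            resp_amp = 5e-3,
                            cardiac_amp = 5e-4,
                            pb_depth = 0.3,
                            pb_period = 15,
                            subject_range = 0.7,
                            range_spread = 0.1) {
  vals <- c(rr = rr, hr = hr, resp_amp = resp_amp, cardiac_amp = cardiac_amp,
            pb_depth = pb_depth, pb_period = pb_period,
            subject_range = subject_range, range_spread = range_spread)
  if (!all(is.finite(vals))) {
    stop("subject_profile: all fields must be finite, got non-finite ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  stopifnot(
    "rr must be in [6, 80] breaths/min" = rr >= 6 && rr <= 80,
    "hr must be in [40, 240] beats/min" = hr >= 40 && hr <= 240,
    "pb_depth must be in [0, 1)" = pb_depth >= 0 && pb_depth < 1,
    "pb_period must be > 0" = pb_period > 0,
    "resp_amp must be >= 0" = resp_amp >= 0,
    "cardiac_amp must be >= 0" = cardiac_amp >= 0,
    "range_spread must be > 0" = range_spread > 0
  )
  structure(as.list(vals), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> HR %g bpm, RR %g brpm, resp %.1f mm, cardiac %.2f mm, pb %.0f%% / %g s, at %.2f m\n",
    x$hr, x$rr, 1e3 * x$resp_amp, 1e3 * x$cardiac_amp, 100 * x$pb_depth,
    x$pb_period, x$subject_range
  ))
  invisible(x)
}

#' Intermittent clutter / movement event
#'
#' Models gross interference near the bed (a nurse or parent leaning in):
#' for `duration` seconds starting at `start`, the amplitudes of
#' `affected_bins` are multiplied by `1 + magnitude`.
#'
#' @param start Event onset, seconds from the start of the recording.
#' @param duration Event length in seconds, `> 0`.
#' @param magnitude Dimensionless amplitude multiplier increment, `>= 0`.
#' @param affected_bins Integer vector of 1-based bin indices.
#'
#' @return An object of class `movement_event`.
#' @export
movement_event <- function(start, duration, magnitude = 5, affected_bins) {
  stopifnot(
    "duration must be > 0" = duration > 0,
    "magnitude must be >= 0" = magnitude >= 0,
    "start must be >= 0" = start >= 0,
    "affected_bins must be positive indices" = all(affected_bins >= 1)
  )
  structure(
    list(start = start, duration = duration, magnitude = magnitude,
         affected_bins = as.integer(affected_bins)),
    class = "movement_event"
  )
}
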