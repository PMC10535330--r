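#' Movement score of an epoch
#'
#' The movement score is the sum over range bins and time of the absolute
#' differences between consecutive baseband amplitude samples:
#' \deqn{S = \sum_b \sum_t |a_b(t+1) - a_b(t)|.}
#' It is a proxy for gross motion and clutter near the bed; clean
#' quiet-sleep epochs score low, a nurse or parent leaning into the
#' detection zone scores high. Scores below 300 (in device amplitude units,
#' over a 10 s epoch) indicate the absence of significant clutter.
#'
#' @param epoch_amplitude Numeric matrix, `n_bins x n_samples_in_epoch`,
#'   with at least 2 time samples.
#' @return A single nonnegative score.
#' @export
#' @examples
#' movement_score(matrix(1, 4, 200))  # constant -> 0
movement_score <- function(epoch_amplitude) {
  stopifnot(is.matrix(epoch_amplitude), ncol(epoch_amplitude) >= 2)
  if (!all(is.finite(epoch_amplitude))) {
    stop("movement_score: amplitudes must be finite")
  }
  nc <- ncol(epoch_amplitude)
  sum(abs(epoch_amplitude[, -1, drop = FALSE] -
            epoch_amplitude[, -nc, drop = FALSE]))
}

#' Partition a recording into scored epochs
#'
#' Splits a recording into consecutive non-overlapping epochs of
#' `epoch_len` seconds (the unit of estimation: one HR and one RR value
#' each) and computes the [movement_score()] of every epoch. A trailing
#' remainder shorter than one epoch is dropped with a warning.
#'
#' @param recording A [baseband_recording()].
#' @param epoch_len Epoch length in seconds.
#' @return A tibble with one row per epoch: `epoch` (1-based index),
#'   `start_s`, `start_index`, `end_index` (half-open sample range,
#'   1-based), and `movement`. The epoch length and sampling rate are
#'   attached as attributes `epoch_len` and `fs`.
#' @export
partition_epochs <- function(recording, epoch_len = 10) {
  stopifnot(inherits(recording, "baseband_recording"), epoch_len > 0)
  fs <- recording$geometry$fs
  spe <- as.integer(round(epoch_len * fs)) # samples per epoch
  n <- ncol(recording$amplitude)
  if (n < spe) stop("recording shorter than one epoch")
  n_epochs <- n %/% spe
  if (n %% spe != 0) {
    warning(sprintf("dropping trailing %d samples (< one %g s epoch)",
                    n %% spe, epoch_len))
  }
  starts <- (seq_len(n_epochs) - 1L) * spe + 1L
  scores <- vapply(starts, function(s) {
    movement_score(recording$amplitude[, s:(s + spe - 1L), drop = FALSE])
  }, numeric(1))
  out <- tibble::tibble(
    epoch = seq_len(n_epochs),
    start_s = (starts - 1L) / fs,
    start_index = starts,
    end_index = starts + spe,
    movement = scores
  )
  attr(out, "epoch_len") <- epoch_len
  attr(out, "fs") <- fs
  out
}

#' Exclusion-rule configuration
#'
#' Movement-based data exclusion: within each 5-minute window, if strictly
#' more than `max_exceed` epochs have movement strictly above
#' `movement_threshold`, the whole window is discarded.
#'
#' @param movement_threshold Score above which an epoch counts as
#'   high-movement.
#' @param window_len Exclusion-window length in seconds.
#' @param max_exceed Maximum tolerated number of high-movement epochs per
#'   window; one more discards the window.
#' @return An object of class `exclusion_config`.
#' @export
exclusion_config <- function(movement_threshold = 300,
                             window_len = 300,
                             max_exceed = 10L) {
  stopifnot(movement_threshold >= 0, window_len > 0, max_exceed > 0)
  structure(list(movement_threshold = movement_threshold,
                 window_len = window_len,
                 max_exceed = as.integer(max_exceed)),
            class = "exclusion_config")
}

#' Apply the movement-based exclusion rule
#'
#' Groups epochs into consecutive (tumbling) windows of
#' `config$window_len` seconds and flags every epoch of a window as
#' discarded iff strictly more than `config$max_exceed` of the window's
#' epochs have movement strictly greater than
#' `config$movement_threshold`. Kept windows contribute all their epochs,
#' including the high-movement ones; a trailing partial window is judged by
#' the same strict count.
#'
#' @param epochs An epoch tibble from [partition_epochs()].
#' @param config An [exclusion_config()].
#' @return The epoch tibble with a logical `kept` column added.
#' @export
apply_exclusion <- function(epochs, config = exclusion_config()) {
  stopifnot(inherits(config, "exclusion_config"),
            all(c("epoch", "movement") %in% names(epochs)))
  epoch_len <- attr(epochs, "epoch_len")
  if (is.null(epoch_len)) epoch_len <- 10
  epw <- max(1L, as.integer(round(config$window_len / epoch_len)))
  out <- epochs |>
    dplyr::mutate(.window = (.data$epoch - 1L) %/% epw) |>
    dplyr::group_by(.data$.window) |>
    dplyr::mutate(kept = sum(.data$movement > config$movement_threshold) <=
                    config$max_exceed) |>
    dplyr::ungroup() |>
    dplyr::select(-".window")
  attr(out, "epoch_len") <- attr(epochs, "epoch_len")
  attr(out, "fs") <- attr(epochs, "fs")
  out
}

#' Ground-truth labels per epoch
#'
#' Each epoch's true HR and RR label is the arithmetic mean of the
#' reference-monitor samples falling inside the epoch — 30 samples for a
#' 10 s epoch at the monitor's 3 Hz rate.
#'
#' @param vitals Reference tibble with columns `time`, `hr`, `rr`
#'   (as produced by [simulate_recording()]).
#' @param epochs Epoch tibble from [partition_epochs()] (optionally after
#'   [apply_exclusion()]).
#' @return The epoch tibble with numeric `hr_label` and `rr_label` columns.
#' @export
label_epochs <- function(vitals, epochs) {
  stopifnot(all(c("time", "hr", "rr") %in% names(vitals)),
            all(c("start_s") %in% names(epochs)))
  epoch_len <- attr(epochs, "epoch_len")
  if (is.null(epoch_len)) epoch_len <- 10
  dt <- stats::median(diff(vitals$time))
  n_expected <- as.integer(round(epoch_len / dt))
  kept <- if ("kept" %in% names(epochs)) epochs$kept else rep(TRUE, nrow(epochs))
  labs <- purrr::map2(epochs$start_s, kept, function(s0, k) {
    idx <- which(vitals$time >= s0 - 1e-9 & vitals$time < s0 + epoch_len - 1e-9)
    if (length(idx) != n_expected) {
      if (k) {
        stop(sprintf(
          "epoch starting at %g s has %d reference samples (expected %d)",
          s0, length(idx), n_expected))
      }
      return(c(hr = NA_real_, rr = NA_real_))
    }
    c(hr = mean(vitals$hr[idx]), rr = mean(vitals$rr[idx]))
  })
  out <- epochs |>
    dplyr::mutate(hr_label = purrr::map_dbl(labs, "hr"),
                  rr_label = purrr::map_dbl(labs, "rr"))
  attr(out, "epoch_len") <- attr(epochs, "epoch_len")
  attr(out, "fs") <- attr(epochs, "fs")
  out
}
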