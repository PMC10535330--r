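#' Spectrogram configuration
#'
#' Parameters of the band-limited short-time Fourier transform used to turn
#' a 10 s epoch into an image. Defaults reproduce the published geometry:
#' a 25-sample Hamming window with nominal 90% overlap (integer hop 3,
#' i.e. 88% — the unique integer hop giving 59 frames per bin and hence
#' 177 = 3 x 59 time columns), transform length 756 so that exactly 144
#' one-sided DFT bins have center frequencies inside the 0.2--4.0 Hz
#' analysis band (indices 8..151 at fs = 20 Hz).
#'
#' `demean` subtracts the epoch mean of each signal, and `analytic`
#' transforms it to its analytic (one-sided-spectrum) form before framing.
#' Both default to `TRUE`: the baseband amplitude carries a large DC
#' baseline, and with a 1.25 s window the spectral mirror of a ~0.3 Hz
#' respiratory tone otherwise leaks across the narrow band and biases the
#' apparent peak toward the band edge.
#'
#' @param fs Sampling rate, Hz.
#' @param epoch_len Epoch length, seconds.
#' @param window_len STFT window length, samples.
#' @param hop Frame hop, samples.
#' @param nfft Zero-padded transform length, samples.
#' @param band Two-element analysis band in Hz.
#' @param n_sel_bins Number of range bins per image.
#' @param demean Subtract the per-epoch mean before transforming.
#' @param analytic Use the analytic signal (Hilbert transform).
#' @return An object of class `stft_config` with derived fields `n_samples`
#'   (samples per epoch), `freq_rows` (0-based DFT bin indices in band),
#'   `freqs` (their center frequencies), `n_freq`, and `n_frames`.
#' @export
#' @examples
#' cfg <- stft_config()
#' c(cfg$n_freq, cfg$n_frames)  # 144 rows, 59 frames per bin
stft_config <- function(fs = 20, epoch_len = 10, window_len = 25, hop = 3,
                        nfft = 756, band = c(0.2, 4.0), n_sel_bins = 3,
                        demean = TRUE, analytic = TRUE) {
  stopifnot(
    "hop must be >= 1" = hop >= 1,
    "window_len must fit in one epoch" = window_len <= epoch_len * fs,
    "nfft must be >= window_len" = nfft >= window_len,
    "band must lie within (0, fs/2]" =
      band[1] > 0 && band[2] > band[1] && band[2] <= fs / 2
  )
  n_samples <- as.integer(round(epoch_len * fs))
  all_freqs <- (seq_len(nfft) - 1) * fs / nfft
  rows <- which(all_freqs >= band[1] - 1e-12 & all_freqs <= band[2] + 1e-12)
  structure(list(
    fs = fs, epoch_len = epoch_len, window_len = as.integer(window_len),
    hop = as.integer(hop), nfft = as.integer(nfft), band = band,
    n_sel_bins = as.integer(n_sel_bins), demean = demean, analytic = analytic,
    n_samples = n_samples,
    freq_rows = rows - 1L,
    freqs = all_freqs[rows],
    n_freq = length(rows),
    n_frames = as.integer((n_samples - window_len) %/% hop + 1L)
  ), class = "stft_config")
}

#' @export
print.stft_config <- function(x, ...) {
  cat(sprintf(
    "<stft_config> %d-sample Hamming, hop %d, nfft %d, band [%g, %g] Hz -> %d x %d per bin\n",
    x$window_len, x$hop, x$nfft, x$band[1], x$band[2], x$n_freq, x$n_frames))
  invisible(x)
}

# symmetric Hamming window, the classic 0.54 - 0.46 cos form
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Analytic signal via the FFT method: zero the negative frequencies,
# double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Select the range bins that carry the subject
#'
#' Estimates the subject's range as the bin with maximal amplitude
#' variance over the kept epochs (the chest wall modulates its bin far more
#' than empty air does) and returns that bin together with its two nearest
#' neighbors in range — the bins with the least range difference from the
#' target. Ties in variance break toward the smaller bin index; at the
#' array edges the triplet is clamped inward.
#'
#' @param recording A [baseband_recording()].
#' @param epochs Optional epoch tibble (after [apply_exclusion()]); when
#'   supplied, variance is computed over kept epochs only.
#' @return Integer vector of 3 ascending 1-based bin indices.
#' @export
select_bins <- function(recording, epochs = NULL) {
  stopifnot(inherits(recording, "baseband_recording"))
  amp <- recording$amplitude
  if (nrow(amp) < 3) stop("select_bins: need at least 3 range bins")
  if (!is.null(epochs)) {
    kept <- if ("kept" %in% names(epochs)) epochs$kept else rep(TRUE, nrow(epochs))
    if (!any(kept)) stop("select_bins: no kept epochs")
    cols <- unlist(purrr::map2(
      epochs$start_index[kept], epochs$end_index[kept],
      function(a, b) seq.int(a, b - 1L)))
    amp <- amp[, cols, drop = FALSE]
  }
  v <- apply(amp, 1, stats::var)
  target <- which.max(v)  # which.max takes the first (smallest) on ties
  lo <- min(max(target - 1L, 1L), nrow(amp) - 2L)
  seq.int(lo, lo + 2L)
}

#' Band-limited STFT magnitude of one epoch signal
#'
#' Short-time Fourier transform of a single bin's epoch signal: the signal
#' is (optionally) demeaned and made analytic, cut into
#' Hamming-windowed frames of `window_len` samples every `hop` samples,
#' each frame zero-padded to `nfft` and transformed; the rows returned are
#' the DFT bins whose center frequencies lie in `band`, in ascending
#' frequency order.
#'
#' @param signal Numeric vector of exactly `config$n_samples` samples.
#' @param config An [stft_config()].
#' @return Magnitude matrix of dimension `config$n_freq x config$n_frames`
#'   (144 x 59 at the defaults).
#' @export
stft_band_magnitude <- function(signal, config = stft_config()) {
  stopifnot(inherits(config, "stft_config"))
  if (length(signal) != config$n_samples) {
    stop(sprintf("stft_band_magnitude: expected %d samples, got %d",
                 config$n_samples, length(signal)))
  }
  if (!all(is.finite(signal))) stop("stft_band_magnitude: non-finite signal")
  x <- signal
  if (config$demean) x <- x - mean(x)
  if (config$analytic) x <- analytic_signal(x)
  w <- hamming_window(config$window_len)
  pad <- complex(config$nfft - config$window_len)
  rows <- config$freq_rows + 1L
  out <- matrix(0, config$n_freq, config$n_frames)
  for (k in seq_len(config$n_frames)) {
    s <- (k - 1L) * config$hop
    seg <- x[(s + 1L):(s + config$window_len)] * w
    out[, k] <- Mod(stats::fft(c(seg, pad)))[rows]
  }
  out
}

#' Spectrogram image of one epoch
#'
#' Horizontally concatenates the per-bin band-limited STFT magnitudes of
#' the selected range bins, in ascending bin-index order, into one
#' `n_freq x (n_sel_bins * n_frames)` image (144 x 177 at the defaults).
#'
#' @param recording A [baseband_recording()].
#' @param epoch One row of the epoch tibble, or a 1-based epoch index.
#' @param selected_bins Ascending bin indices from [select_bins()].
#' @param config An [stft_config()].
#' @param epochs The epoch tibble (needed when `epoch` is an index).
#' @return An object of class `spectro_image`: list with `image`
#'   (magnitude matrix), `selected_bins`, `epoch_index`, `freqs`.
#' @export
build_image <- function(recording, epoch, selected_bins,
                        config = stft_config(), epochs = NULL) {
  stopifnot(inherits(recording, "baseband_recording"),
            length(selected_bins) == config$n_sel_bins)
  if (is.numeric(epoch) && length(epoch) == 1) {
    stopifnot(!is.null(epochs))
    epoch <- epochs[epochs$epoch == epoch, ]
    stopifnot(nrow(epoch) == 1)
  }
  sel <- sort(as.integer(selected_bins))
  cols <- seq.int(epoch$start_index, epoch$end_index - 1L)
  blocks <- lapply(sel, function(b) {
    stft_band_magnitude(recording$amplitude[b, cols], config)
  })
  img <- do.call(cbind, blocks)
  structure(list(image = img, selected_bins = sel,
                 epoch_index = epoch$epoch, freqs = config$freqs),
            class = "spectro_image")
}

#' @export
print.spectro_image <- function(x, ...) {
  cat(sprintf("<spectro_image> %d x %d, epoch %d, bins %s\n",
              nrow(x$image), ncol(x$image), x$epoch_index,
              paste(x$selected_bins, collapse = ",")))
  invisible(x)
}

#' Model-ready tensor from a spectrogram image
#'
#' Min--max scales the magnitude image to `[0, 255]` (an all-constant
#' image maps to 0), bilinearly resizes it to 224 x 224, replicates it
#' across 3 channels, and applies the backbone's standard input
#' preprocessing: symmetric scaling to `[-1, 1]` for the `tiny-test`
#' backbone, ImageNet channel-mean subtraction for `vgg16`, or none.
#'
#' @param image A [build_image()] result, or a bare magnitude matrix.
#' @param preprocess Backbone preprocessing: `"tiny-test"`, `"vgg16"`, or
#'   `"none"`.
#' @param size Output height/width in pixels.
#' @return A `size x size x 3` numeric array.
#' @export
to_model_input <- function(image, preprocess = c("tiny-test", "vgg16", "none"),
                           size = 224L) {
  preprocess <- match.arg(preprocess)
  m <- if (inherits(image, "spectro_image")) image$image else image
  stopifnot(is.matrix(m))
  if (!all(is.finite(m))) stop("to_model_input: non-finite image values")
  rng <- range(m)
  scaled <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) * 255 else m * 0
  resized <- EBImage::resize(EBImage::Image(scaled), w = size, h = size,
                             filter = "bilinear")
  px <- as.numeric(EBImage::imageData(resized))
  px <- array(rep(px, 3), dim = c(size, size, 3))
  switch(preprocess,
    "tiny-test" = (px - 127.5) / 127.5,
    "vgg16" = {
      means <- c(123.68, 116.779, 103.939)  # ImageNet RGB channel means
      for (ch in 1:3) px[, , ch] <- px[, , ch] - means[ch]
      px
    },
    "none" = px
  )
}

#' Build spectrogram images and model tensors for all kept epochs
#'
#' Convenience wrapper running [select_bins()], [build_image()] and
#' [to_model_input()] over every kept epoch of a recording.
#'
#' @param recording A [baseband_recording()].
#' @param epochs Epoch tibble (after [apply_exclusion()] and
#'   [label_epochs()] as needed).
#' @param config An [stft_config()].
#' @param preprocess Passed to [to_model_input()].
#' @return A tibble with one row per kept epoch: `epoch`, `hr_label` /
#'   `rr_label` when present, a `image` list-column of [build_image()]
#'   objects and a `tensor` list-column of 224 x 224 x 3 arrays.
#' @export
featurize_epochs <- function(recording, epochs, config = stft_config(),
                             preprocess = "tiny-test") {
  kept <- if ("kept" %in% names(epochs)) epochs$kept else rep(TRUE, nrow(epochs))
  rows <- epochs[kept, ]
  if (nrow(rows) == 0) stop("featurize_epochs: no data after exclusion")
  sel <- select_bins(recording, epochs)
  imgs <- purrr::map(seq_len(nrow(rows)), function(i) {
    build_image(recording, rows[i, ], sel, config)
  })
  out <- tibble::tibble(
    epoch = rows$epoch,
    image = imgs,
    tensor = purrr::map(imgs, to_model_input, preprocess = preprocess)
  )
  for (cl in c("hr_label", "rr_label")) {
    if (cl %in% names(rows)) out[[cl]] <- rows[[cl]]
  }
  out
}
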