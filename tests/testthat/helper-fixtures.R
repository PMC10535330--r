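# Shared synthetic fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small pooled dataset: 3 subjects x 4 epochs (40 s each), with slow
# label drift so per-epoch labels are not constant within a subject.
small_featurized <- function() {
  cached("small_featurized", {
    set.seed(7)
    parts <- lapply(1:3, function(s) {
      p <- subject_profile(rr = c(18, 28, 38)[s], hr = c(90, 120, 160)[s],
                           subject_range = c(0.55, 0.7, 0.85)[s])
      sim <- simulate_recording(profile = p, duration = 40, noise_sd = 0.02,
                                seed = 70 + s, hr_drift = 0.05,
                                rr_drift = 0.02)
      ep <- label_epochs(sim$vitals,
                         apply_exclusion(partition_epochs(sim$recording)))
      cbind(featurize_epochs(sim$recording, ep), subject = s)
    })
    data <- dplyr::bind_rows(parts)
    data$epoch <- seq_len(nrow(data))
    data
  })
}

# Random model-input tensors at a reduced resolution for head-mechanics
# tests (the backbone accepts any size large enough for the head).
random_tensors <- function(n, size = 100, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(stats::runif(size * size * 3) * 2 - 1,
                                       c(size, size, 3)))
}

# Epoch tibble built directly from a movement-score vector (10 s epochs).
epochs_from_scores <- function(scores, epoch_len = 10, fs = 20) {
  spe <- epoch_len * fs
  out <- tibble::tibble(
    epoch = seq_along(scores),
    start_s = (seq_along(scores) - 1) * epoch_len,
    start_index = (seq_along(scores) - 1L) * as.integer(spe) + 1L,
    end_index = (seq_along(scores) - 1L) * as.integer(spe) + as.integer(spe) + 1L,
    movement = scores
  )
  attr(out, "epoch_len") <- epoch_len
  attr(out, "fs") <- fs
  out
}
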