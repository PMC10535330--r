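test_that("stft configuration reproduces the published image geometry", {
  cfg <- stft_config()
  expect_identical(cfg$n_freq, 144L)
  expect_identical(cfg$n_frames, 59L)
  expect_identical(range(cfg$freq_rows), c(8L, 151L))
  expect_true(all(diff(cfg$freqs) > 0))
  expect_true(all(cfg$freqs >= 0.2 - 1e-12 & cfg$freqs <= 4.0 + 1e-12))
  expect_error(stft_config(band = c(0, 4)), "band")
  expect_error(stft_config(hop = 0), "hop")
})

test_that("band-limited stft matches a direct per-frame DFT oracle", {
  cfg <- stft_config(demean = FALSE, analytic = FALSE)
  set.seed(9)
  x <- rnorm(200)
  got <- stft_band_magnitude(x, cfg)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:24) / 24)
  oracle <- matrix(0, 144, 59)
  for (fr in 1:59) {
    seg <- x[((fr - 1) * 3 + 1):((fr - 1) * 3 + 25)] * w
    for (r in 1:144) {
      k <- 7 + r  # 0-based DFT index 8..151
      oracle[r, fr] <- Mod(sum(seg * exp(-2i * pi * k * (0:24) / 756)))
    }
  }
  expect_equal(got, oracle, tolerance = 1e-10)

  expect_equal(stft_band_magnitude(rep(0, 200), cfg), matrix(0, 144, 59))
  expect_error(stft_band_magnitude(rnorm(100), cfg), "expected 200")
  expect_error(stft_band_magnitude(c(rnorm(199), NA), cfg), "finite")
})

test_that("a pure tone peaks at its frequency in every frame", {
  cfg <- stft_config()
  t <- (0:199) / 20
  img <- stft_band_magnitude(sin(2 * pi * 1.0 * t), cfg)
  peaks <- cfg$freqs[apply(img, 2, which.max)]
  expect_true(all(abs(peaks - 1.0) <= 20 / 756 + 1e-12))
})

test_that("analytic processing keeps low-frequency peaks on target", {
  # amplitude-like signal: DC baseline plus a 0.333 Hz respiratory tone
  t <- (0:199) / 20
  x <- 1 + 0.25 * sin(2 * pi * (20 / 60) * t)
  onebin <- 20 / 756
  peak_of <- function(cfg) {
    cfg$freqs[which.max(rowMeans(stft_band_magnitude(x, cfg)))]
  }
  expect_lt(abs(peak_of(stft_config()) - 1 / 3), onebin + 1e-12)
  # without the analytic signal the mirror drags the peak to the band edge
  raw_peak <- peak_of(stft_config(analytic = FALSE))
  expect_gt(abs(raw_peak - 1 / 3), 3 * onebin)
})

test_that("bin selection targets the most variable bin and its neighbors", {
  p <- subject_profile(subject_range = 0.7, range_spread = 0.03)
  sim <- simulate_recording(profile = p, duration = 60, noise_sd = 0, seed = 1)
  ep <- apply_exclusion(partition_epochs(sim$recording))
  sel <- select_bins(sim$recording, ep)
  # 0-based bin round((0.7 - 0.3)/0.0388) = 10 -> 1-based 11
  expect_true(11L %in% sel)
  expect_identical(sel, sort(sel))
  expect_identical(length(sel), 3L)

  # variance concentrated in the first bin: edge clamp to {1,2,3}
  m <- matrix(1, 10, 400)
  m[1, ] <- rnorm(400)
  rec <- baseband_recording(abs(m), radar_geometry(n_bins = 10))
  expect_identical(select_bins(rec), 1:3)

  # equal-variance tie breaks toward the smaller index
  m2 <- matrix(1, 10, 400)
  m2[4, ] <- rep(c(1, 2), 200)
  m2[7, ] <- rep(c(1, 2), 200)
  rec2 <- baseband_recording(m2, radar_geometry(n_bins = 10))
  expect_identical(select_bins(rec2), 3:5)

  expect_error(select_bins(baseband_recording(matrix(1, 2, 400),
                                              radar_geometry(n_bins = 2))),
               "at least 3")
})

test_that("epoch images concatenate per-bin spectrograms in bin order", {
  sim <- simulate_recording(duration = 60, seed = 4)
  ep <- apply_exclusion(partition_epochs(sim$recording))
  sel <- select_bins(sim$recording, ep)
  cfg <- stft_config()
  img <- build_image(sim$recording, 1, sel, cfg, epochs = ep)
  expect_identical(dim(img$image), c(144L, 177L))
  expect_true(all(is.finite(img$image)) && all(img$image >= 0))

  # block k is exactly the stft of the k-th selected bin
  cols <- seq.int(ep$start_index[1], ep$end_index[1] - 1L)
  for (k in 1:3) {
    blk <- stft_band_magnitude(sim$recording$amplitude[sel[k], cols], cfg)
    expect_equal(img$image[, ((k - 1) * 59 + 1):(k * 59)], blk)
  }

  # identical bin signals give three identical blocks
  m <- matrix(rep(abs(rnorm(200)), each = 5), 5, 200, byrow = FALSE)
  rec <- baseband_recording(m, radar_geometry(n_bins = 5))
  ep1 <- partition_epochs(rec)
  im2 <- build_image(rec, 1, 1:3, cfg, epochs = ep1)
  expect_equal(im2$image[, 1:59], im2$image[, 60:118])
  expect_equal(im2$image[, 1:59], im2$image[, 119:177])
})

test_that("model tensors are scaled, resized and channel-replicated", {
  ten <- to_model_input(matrix(5, 144, 177), preprocess = "none")
  expect_identical(dim(ten), c(224L, 224L, 3L))
  expect_true(all(ten == 0))  # constant image maps to zero

  sim <- simulate_recording(duration = 60, seed = 4)
  ep <- apply_exclusion(partition_epochs(sim$recording))
  img <- build_image(sim$recording, 1, select_bins(sim$recording, ep),
                     epochs = ep)
  ten2 <- to_model_input(img, preprocess = "none")
  expect_identical(dim(ten2), c(224L, 224L, 3L))
  expect_true(all(ten2 >= 0 & ten2 <= 255))
  expect_identical(ten2[, , 1], ten2[, , 2])
  expect_identical(ten2[, , 1], ten2[, , 3])

  # min-max scaling is monotone (224x224 input makes the resize exact)
  set.seed(10)
  m <- matrix(runif(224 * 224), 224)
  t3 <- to_model_input(m, preprocess = "none")[, , 1]
  ord <- order(as.vector(m))
  expect_true(all(diff(as.vector(t3)[ord]) >= 0))
  expect_equal(t3, (m - min(m)) / (max(m) - min(m)) * 255, tolerance = 1e-12)

  expect_error(to_model_input(matrix(c(1, Inf, 1, 1), 2)), "finite")
})

test_that("a noise-free subject's image peaks at its vital frequencies", {
  p <- subject_profile(rr = 20, hr = 100, cardiac_amp = 5e-3, pb_depth = 0)
  sim <- simulate_recording(profile = p, duration = 60, noise_sd = 0, seed = 1)
  ep <- apply_exclusion(partition_epochs(sim$recording))
  sel <- select_bins(sim$recording, ep)
  cfg <- stft_config()
  prof <- rowMeans(build_image(sim$recording, 1, sel, cfg, epochs = ep)$image)
  onebin <- 20 / 756
  expect_lt(abs(cfg$freqs[which.max(prof)] - 20 / 60), onebin + 1e-12)
  # cardiac line: largest local maximum above 1 Hz
  lm <- which(diff(sign(diff(prof))) == -2) + 1
  lm <- lm[cfg$freqs[lm] > 1]
  card <- lm[which.max(prof[lm])]
  expect_lt(abs(cfg$freqs[card] - 100 / 60), onebin + 1e-12)
})

test_that("featurize_epochs returns one row per kept epoch with labels", {
  data <- small_featurized()
  expect_identical(nrow(data), 12L)
  expect_true(all(c("epoch", "image", "tensor", "hr_label", "rr_label")
                  %in% names(data)))
  expect_identical(dim(data$tensor[[1]]), c(224L, 224L, 3L))

  # exclusion of everything is a clean error
  sim <- simulate_recording(duration = 40, seed = 1)
  ep <- partition_epochs(sim$recording)
  ep$kept <- FALSE
  expect_error(featurize_epochs(sim$recording, ep), "no data after exclusion")
})
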