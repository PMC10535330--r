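test_that("movement score is the summed absolute successive difference", {
  expect_equal(movement_score(matrix(1, 4, 200)), 0)
  expect_equal(movement_score(matrix(c(0, 0, 3, 3), 1)), 3)

  set.seed(5)
  m <- matrix(rnorm(100), 5, 20)
  oracle <- 0
  for (b in 1:5) for (k in 1:19) oracle <- oracle + abs(m[b, k + 1] - m[b, k])
  expect_equal(movement_score(m), oracle)

  expect_error(movement_score(matrix(c(1, NA), 1)), "finite")
  expect_error(movement_score(matrix(1, 3, 1)))
})

test_that("movement score is scale-equivariant and additive over halves", {
  set.seed(6)
  m <- matrix(runif(52 * 200), 52)
  for (cc in c(0, 0.5, 2, 10)) {
    expect_equal(movement_score(cc * m), cc * movement_score(m))
  }
  left <- m[, 1:100]
  right <- m[, 101:200]
  boundary <- sum(abs(m[, 101] - m[, 100]))
  expect_equal(movement_score(m),
               movement_score(left) + movement_score(right) + boundary)
})

test_that("recordings partition into consecutive, fully scored epochs", {
  sim <- simulate_recording(duration = 300, seed = 2)
  ep <- partition_epochs(sim$recording)
  expect_identical(nrow(ep), 30L)
  expect_identical(ep$start_index, seq(1L, by = 200L, length.out = 30))
  expect_identical(ep$end_index - ep$start_index, rep(200L, 30))
  # scores equal movement_score applied to each epoch slice
  manual <- vapply(seq_len(30), function(k) {
    movement_score(sim$recording$amplitude[, ((k - 1) * 200 + 1):(k * 200)])
  }, numeric(1))
  expect_equal(ep$movement, manual)

  sim95 <- simulate_recording(duration = 95, seed = 2)
  expect_warning(ep95 <- partition_epochs(sim95$recording), "trailing")
  expect_identical(nrow(ep95), 9L)

  short <- baseband_recording(matrix(1, 52, 100), radar_geometry())
  expect_error(partition_epochs(short), "shorter than one epoch")
})

test_that("a quiet subject stays under the exclusion threshold", {
  p <- subject_profile(resp_amp = 1e-3, cardiac_amp = 1e-4)
  sim <- simulate_recording(profile = p, duration = 120, noise_sd = 0, seed = 1)
  ep <- partition_epochs(sim$recording)
  expect_true(all(ep$movement < 300))
  expect_true(all(apply_exclusion(ep)$kept))
})

test_that("window exclusion uses strict counts on both thresholds", {
  # 11 epochs above 300 in a 30-epoch window: whole window discarded
  ep <- epochs_from_scores(c(rep(301, 11), rep(0, 19)))
  expect_false(any(apply_exclusion(ep)$kept))
  # exactly 10 above: kept, including the high-movement epochs
  ep <- epochs_from_scores(c(rep(301, 10), rep(0, 20)))
  expect_true(all(apply_exclusion(ep)$kept))
  # scores exactly at the threshold do not count (strict >)
  ep <- epochs_from_scores(c(rep(300, 30)))
  expect_true(all(apply_exclusion(ep)$kept))
  # all-zero scores: kept
  expect_true(all(apply_exclusion(epochs_from_scores(rep(0, 30)))$kept))
  # windows are judged independently
  ep <- epochs_from_scores(c(rep(301, 11), rep(0, 19), rep(0, 30)))
  kept <- apply_exclusion(ep)$kept
  expect_false(any(kept[1:30]))
  expect_true(all(kept[31:60]))
  # trailing partial window uses the same strict rule
  ep <- epochs_from_scores(c(rep(0, 30), rep(301, 11)))
  expect_false(any(apply_exclusion(ep)$kept[31:41]))
})

test_that("raising the movement threshold never discards a kept window", {
  set.seed(8)
  for (i in 1:20) {
    scores <- stats::rexp(60, rate = 1 / 250)
    ep <- epochs_from_scores(scores)
    k1 <- apply_exclusion(ep, exclusion_config(movement_threshold = 200))$kept
    k2 <- apply_exclusion(ep, exclusion_config(movement_threshold = 400))$kept
    expect_true(all(k2[k1]))
  }
})

test_that("epoch labels are the mean of the 30 in-epoch reference samples", {
  ep <- epochs_from_scores(rep(0, 2))
  vit <- tibble::tibble(time = (0:59) / 3, hr = rep(120, 60), rr = rep(30, 60))
  lab <- label_epochs(vit, ep)
  expect_equal(lab$hr_label, c(120, 120))

  vit2 <- tibble::tibble(time = (0:29) / 3, hr = 1:30, rr = 30:1)
  lab2 <- label_epochs(vit2, epochs_from_scores(0))
  expect_equal(lab2$hr_label, 15.5)
  expect_equal(lab2$rr_label, 15.5)

  # linear ramp: label equals the brute-force mean of the covered samples
  vit3 <- tibble::tibble(time = (0:89) / 3, hr = 100 + (0:89) * 0.2,
                         rr = 20 + (0:89) * 0.1)
  lab3 <- label_epochs(vit3, epochs_from_scores(rep(0, 3)))
  for (k in 1:3) {
    idx <- ((k - 1) * 30 + 1):(k * 30)
    expect_equal(lab3$hr_label[k], mean(vit3$hr[idx]))
    expect_equal(lab3$rr_label[k], mean(vit3$rr[idx]))
  }

  # a kept epoch with missing reference samples is an error
  vit_short <- tibble::tibble(time = (0:39) / 3, hr = rep(120, 40),
                              rr = rep(30, 40))
  expect_error(label_epochs(vit_short, epochs_from_scores(rep(0, 2))),
               "reference samples")
})
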