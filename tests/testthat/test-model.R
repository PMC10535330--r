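test_that("model construction is seeded and reproducible", {
  m1 <- build_vitals_model(model_spec(), seed = 42, input_size = 100)
  m2 <- build_vitals_model(model_spec(), seed = 42, input_size = 100)
  expect_identical(m1$heads, m2$heads)
  expect_identical(m1$backbone, m2$backbone)
  m3 <- build_vitals_model(model_spec(), seed = 43, input_size = 100)
  expect_false(identical(m1$heads$hr$Wc, m3$heads$hr$Wc))
  # the two branches are structurally identical but independently seeded
  expect_identical(dim(m1$heads$hr$W1), dim(m1$heads$rr$W1))
  expect_false(identical(m1$heads$hr$Wc, m1$heads$rr$Wc))
})

test_that("a forward pass yields two finite rates per image", {
  m <- build_vitals_model(model_spec(), seed = 1)
  ten <- random_tensors(3, size = 224, seed = 2)
  pr <- predict(m, ten)
  expect_identical(dim(pr), c(3L, 2L))
  expect_true(all(is.finite(pr$hr_hat)) && all(is.finite(pr$rr_hat)))
  # batch-of-1 equals the matching element of batch-of-N
  pr1 <- predict(m, ten[1])
  expect_equal(pr1$hr_hat, pr$hr_hat[1])
  expect_equal(pr1$rr_hat, pr$rr_hat[1])
})

test_that("vgg16 demands pretrained weights instead of a silent fallback", {
  expect_error(build_vitals_model(model_spec("vgg16"), seed = 1),
               "weights_file")
  expect_error(model_spec(backbone_frozen = FALSE), "frozen")
})

test_that("training changes only the added head layers", {
  m <- build_vitals_model(model_spec(), seed = 1, input_size = 100)
  ten <- random_tensors(8, seed = 3)
  lab <- tibble::tibble(hr = runif(8, 80, 180), rr = runif(8, 15, 40))
  before <- backbone_checksum(m)
  mt <- train_vitals_model(m, ten, train_config(max_epochs = 3, seed = 1),
                           labels = lab)
  expect_identical(backbone_checksum(mt), before)
  expect_false(identical(m$heads$hr$Wc, mt$heads$hr$Wc))

  # zero learning rate leaves every head weight unchanged
  m0 <- train_vitals_model(m, ten, train_config(learning_rate = 0,
                                                max_epochs = 2, seed = 1),
                           labels = lab)
  expect_equal(m0$heads, m$heads)
})

test_that("training is reproducible and overfits a small set", {
  base <- random_tensors(2, seed = 4)
  ten <- c(rep(base[1], 16), rep(base[2], 16))
  lab <- tibble::tibble(hr = rep(c(90, 150), each = 16),
                        rr = rep(c(15, 35), each = 16))
  m <- build_vitals_model(model_spec(), seed = 5, input_size = 100)
  cfg <- train_config(max_epochs = 150, batch_size = 8, seed = 6)
  t1 <- train_vitals_model(m, ten, cfg, labels = lab)
  t2 <- train_vitals_model(m, ten, cfg, labels = lab)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$heads, t2$heads)

  # loss decreases on average and predictions approach the group labels
  h <- t1$history$train_loss
  expect_lt(mean(utils::tail(h, 5)), mean(utils::head(h, 5)))
  pr <- predict(t1, base)
  expect_equal(pr$hr_hat, c(90, 150), tolerance = 0.02)
  expect_equal(pr$rr_hat, c(15, 35), tolerance = 0.02)
})

test_that("the two branches are independent", {
  m <- build_vitals_model(model_spec(), seed = 7, input_size = 100)
  ten <- random_tensors(2, seed = 8)
  pr <- predict(m, ten)
  m_zeroed <- m
  for (nm in names(m_zeroed$heads$rr)) {
    m_zeroed$heads$rr[[nm]] <- m_zeroed$heads$rr[[nm]] * 0
  }
  pr2 <- predict(m_zeroed, ten)
  expect_equal(pr2$hr_hat, pr$hr_hat)
  expect_true(all(pr2$rr_hat == 0))
})

test_that("validation restores each branch at its own best epoch", {
  data <- small_featurized()
  m <- build_vitals_model(model_spec(), seed = 1)
  mt <- train_vitals_model(m, data[1:9, ], train_config(max_epochs = 6, seed = 2),
                           validation = list(data = data[10:12, ]))
  expect_identical(nrow(mt$history), 6L)
  expect_true(all(c("val_loss_hr", "val_loss_rr") %in% names(mt$history)))
  expect_true(all(is.finite(mt$history$val_loss)))
})

test_that("tidy and glance summarize a fitted model", {
  data <- small_featurized()
  m <- build_vitals_model(model_spec(), seed = 1)
  mt <- train_vitals_model(m, data, train_config(max_epochs = 2, seed = 1))
  td <- tidy(mt)
  expect_true(all(c("epoch", "metric", "loss") %in% names(td)))
  gl <- glance(mt)
  expect_identical(gl$epochs_trained, 2L)
  expect_identical(gl$backbone, "tiny-test")
  expect_true(is.finite(gl$final_train_loss))
})
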