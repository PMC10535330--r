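test_that("cv plans partition the epochs into near-equal folds", {
  p <- make_cv_plan(100, seed = 1)
  expect_identical(sort(unique(p$fold)), 1:10)
  expect_true(all(table(p$fold) == 10))

  p2 <- make_cv_plan(101, seed = 1)
  sizes <- sort(as.integer(table(p2$fold)))
  expect_identical(sizes, c(rep(10L, 9), 11L))

  expect_identical(make_cv_plan(57, seed = 3), make_cv_plan(57, seed = 3))
  expect_false(identical(make_cv_plan(57, seed = 3)$fold,
                         make_cv_plan(57, seed = 4)$fold))
  expect_error(make_cv_plan(5), "n_folds")
  # every epoch appears in exactly one fold
  expect_identical(p$epoch, 1:100)
})

test_that("agreement statistics match their definitions", {
  s <- agreement_stats(c(100, 110), c(100, 110))
  expect_equal(unlist(s[c("mae", "mean_bias", "loa")]),
               c(mae = 0, mean_bias = 0, loa = 0))

  s2 <- agreement_stats(c(100, 110), c(98, 112))
  expect_equal(s2$mae, 2)
  expect_equal(s2$mean_bias, 0)

  # constant sequences have undefined correlation
  expect_true(is.na(agreement_stats(c(5, 5, 5), c(1, 2, 3))$corr))
  expect_error(agreement_stats(1:3, 1:4), "length mismatch")
})

test_that("agreement statistics match an independent element-wise oracle", {
  set.seed(11)
  truth <- runif(1000, 60, 200)
  est <- truth + rnorm(1000, 1, 8)
  s <- agreement_stats(truth, est)
  n <- 1000
  d <- truth - est
  mae_o <- sum(abs(d)) / n
  bias_o <- sum(d) / n
  loa_o <- 1.96 * sqrt(sum((d - bias_o)^2) / (n - 1))
  mt <- sum(truth) / n
  me <- sum(est) / n
  corr_o <- sum((truth - mt) * (est - me)) /
    sqrt(sum((truth - mt)^2) * sum((est - me)^2))
  expect_equal(s$mae, mae_o, tolerance = 1e-10)
  expect_equal(s$mean_bias, bias_o, tolerance = 1e-10)
  expect_equal(s$loa, loa_o, tolerance = 1e-10)
  expect_equal(s$corr, corr_o, tolerance = 1e-10)

  # swapping arguments preserves mae/loa and flips the bias
  sw <- agreement_stats(est, truth)
  expect_equal(sw$mae, s$mae)
  expect_equal(sw$loa, s$loa)
  expect_equal(sw$mean_bias, -s$mean_bias)
  expect_equal(sw$corr, s$corr)
})

test_that("bias +/- LOA brackets about 95% of Gaussian differences", {
  set.seed(12)
  truth <- rnorm(2000, 120, 10)
  est <- truth + rnorm(2000, 0.5, 3)
  s <- agreement_stats(truth, est)
  d <- truth - est
  cover <- mean(d >= s$mean_bias - s$loa & d <= s$mean_bias + s$loa)
  expect_gt(cover, 0.92)
  expect_lt(cover, 0.98)
})

test_that("cross-validation plumbing is exact for reference predictors", {
  data <- small_featurized()
  plan <- make_cv_plan(nrow(data), n_folds = 3, seed = 2)

  oracle <- function(train, test) {
    tibble::tibble(hr_hat = test$hr_label, rr_hat = test$rr_label)
  }
  rep1 <- evaluate_cv(data, plan, predictor = oracle)
  expect_identical(nrow(rep1$per_fold), 6L)  # n_folds x 2 vitals
  expect_true(all(rep1$per_fold$mae == 0))
  expect_equal(rep1$per_fold$corr, rep(1, 6))
  # every epoch predicted exactly once per vital
  expect_identical(sort(unique(rep1$predictions$epoch)), data$epoch)
  expect_identical(nrow(rep1$predictions), 2L * nrow(data))

  mean_pred <- function(train, test) {
    tibble::tibble(hr_hat = rep(mean(train$hr_label), nrow(test)),
                   rr_hat = rep(mean(train$rr_label), nrow(test)))
  }
  rep2 <- evaluate_cv(data, plan, predictor = mean_pred)
  expect_true(all(is.na(rep2$per_fold$corr)))
  for (k in 1:3) {
    test_idx <- which(plan$fold == k)
    mu <- mean(data$hr_label[-test_idx])
    expect_equal(rep2$per_fold$mae[rep2$per_fold$fold == k &
                                     rep2$per_fold$vital == "hr"],
                 mean(abs(data$hr_label[test_idx] - mu)))
  }
})

test_that("subject-wise grouping keeps each subject in one fold", {
  data <- small_featurized()
  plan <- make_cv_plan(nrow(data), n_folds = 3, seed = 5)
  oracle <- function(train, test) {
    tibble::tibble(hr_hat = test$hr_label, rr_hat = test$rr_label)
  }
  rep_g <- evaluate_cv(data, plan, predictor = oracle, group = data$subject)
  by_subj <- rep_g$predictions |>
    dplyr::left_join(dplyr::select(data, "epoch", "subject"), by = "epoch") |>
    dplyr::distinct(.data$subject, .data$fold)
  expect_identical(nrow(by_subj), 3L)
})

test_that("the neural model runs through cross-validation end to end", {
  data <- small_featurized()
  plan <- make_cv_plan(nrow(data), n_folds = 2, seed = 3)
  rep_m <- evaluate_cv(data, plan, spec = model_spec(),
                       config = train_config(max_epochs = 2, seed = 1))
  expect_s3_class(rep_m, "agreement_report")
  expect_identical(nrow(rep_m$per_fold), 4L)
  expect_true(all(is.finite(rep_m$per_fold$mae)))
  tab <- report_table(rep_m)
  expect_identical(names(tab),
                   c("fold", "rr_mae", "rr_corr", "rr_bias", "rr_loa",
                     "hr_mae", "hr_corr", "hr_bias", "hr_loa"))
  gl <- glance(rep_m)
  expect_identical(nrow(gl), 1L)
  expect_s3_class(autoplot(rep_m), "ggplot")
  expect_s3_class(autoplot(rep_m, type = "scatter"), "ggplot")
  expect_s3_class(plot_spectro_image(data$image[[1]]), "ggplot")
})
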