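#' Cross-validation plan over pooled epochs
#'
#' Seeded uniform random partition of the pooled epochs into `n_folds`
#' folds of sizes differing by at most one. Within each CV iteration the
#' nine training folds are further split (seeded) into an inner training
#' set (`inner_train_frac`, default 75%) and a validation set used for
#' model selection.
#'
#' Pooling mixes epochs of one subject across folds — that is the
#' protocol implemented here; see [evaluate_cv()]'s `group` argument for a
#' subject-wise alternative.
#'
#' @param n_epochs Number of pooled epochs.
#' @param n_folds Number of folds.
#' @param inner_train_frac Fraction of the training folds used for inner
#'   training (the rest monitors validation loss).
#' @param seed Integer seed.
#' @return An object of class `cv_plan`: tibble with columns `epoch` and
#'   `fold`, plus attributes `n_folds`, `inner_train_frac`, `seed`.
#' @export
make_cv_plan <- function(n_epochs, n_folds = 10L, inner_train_frac = 0.75,
                         seed = 1L) {
  stopifnot("need at least n_folds epochs" = n_epochs >= n_folds,
            inner_train_frac > 0, inner_train_frac < 1)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(n_folds), n_epochs))
  out <- tibble::tibble(epoch = seq_len(n_epochs), fold = fold)
  class(out) <- c("cv_plan", class(out))
  attr(out, "n_folds") <- as.integer(n_folds)
  attr(out, "inner_train_frac") <- inner_train_frac
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Agreement statistics between true and estimated rates
#'
#' The four agreement measures used per fold and per vital: mean absolute
#' error, Pearson correlation, Bland--Altman mean bias
#' (`mean(true - est)`), and the limit of agreement half-width
#' `1.96 * sd(true - est)` (sample SD, n-1 denominator). Correlation is
#' reported as `NA` when either sequence is constant.
#'
#' @param truth Numeric vector of true rates (BPM).
#' @param estimate Numeric vector of estimates, same length (>= 2).
#' @return One-row tibble: `mae`, `corr`, `mean_bias`, `loa`.
#' @export
#' @examples
#' agreement_stats(c(100, 110), c(98, 112))  # mae 2, bias 0
agreement_stats <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("agreement_stats: length mismatch")
  }
  stopifnot(length(truth) >= 2)
  d <- truth - estimate
  corr <- if (stats::sd(truth) == 0 || stats::sd(estimate) == 0) {
    NA_real_
  } else {
    stats::cor(truth, estimate)
  }
  tibble::tibble(
    mae = mean(abs(d)),
    corr = corr,
    mean_bias = mean(d),
    loa = 1.96 * stats::sd(d)
  )
}

#' Cross-validated evaluation of the vitals regressor
#'
#' For each fold: split the remaining folds 75/25 into inner-train and
#' validation, train the dual-branch model (restoring the lowest
#' validation-loss epoch), predict the held-out fold, and compute
#' [agreement_stats()] per vital. Backbone features are computed once and
#' shared across folds (the backbone is frozen).
#'
#' @param data Featurized epoch tibble from [featurize_epochs()] with
#'   `tensor`, `hr_label`, `rr_label` columns.
#' @param plan A [make_cv_plan()] for `nrow(data)` epochs.
#' @param spec A [model_spec()].
#' @param config A [train_config()]; per-fold seeds are derived from
#'   `config$seed` and the fold index.
#' @param predictor Optional function
#'   `function(train_data, test_data) -> tibble(hr_hat, rr_hat)` replacing
#'   the neural model (used to validate the evaluation plumbing with
#'   reference predictors).
#' @param group Optional grouping vector (e.g. subject id per epoch);
#'   when supplied, folds from `plan` are reassigned so whole groups stay
#'   in one fold (subject-wise CV; not the pooled protocol).
#' @return An object of class `agreement_report`: list with `per_fold`
#'   (fold x vital agreement tibble), `pooled` (per-vital stats over all
#'   held-out predictions), and `predictions` (epoch, fold, vital, truth,
#'   estimate).
#' @export
evaluate_cv <- function(data, plan, spec = model_spec(),
                        config = train_config(), predictor = NULL,
                        group = NULL) {
  stopifnot(inherits(plan, "cv_plan"), nrow(plan) == nrow(data))
  n_folds <- attr(plan, "n_folds")
  frac <- attr(plan, "inner_train_frac")
  fold <- plan$fold
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(data))
    set.seed(attr(plan, "seed"))
    g <- unique(group)
    gf <- sample(rep_len(seq_len(n_folds), length(g)))
    fold <- gf[match(group, g)]
  }

  use_model <- is.null(predictor)
  shared_features <- NULL
  proto <- NULL
  if (use_model) {
    proto <- build_vitals_model(spec, seed = config$seed)
    shared_features <- backbone_features(proto, data$tensor)
  }

  per_fold <- list()
  preds <- list()
  for (k in seq_len(n_folds)) {
    test_idx <- which(fold == k)
    train_idx <- which(fold != k)
    if (length(test_idx) == 0) next
    est <- tryCatch({
      if (use_model) {
        set.seed(config$seed + 1000L * k)
        inner <- sample(train_idx, size = max(1L, round(frac * length(train_idx))))
        val <- setdiff(train_idx, inner)
        fold_cfg <- config
        fold_cfg$seed <- config$seed + k
        m <- build_vitals_model(spec, seed = config$seed + k)
        m$backbone <- proto$backbone  # one shared frozen backbone across folds
        m <- train_vitals_model(
          m, data[inner, ], fold_cfg,
          validation = if (length(val) > 0) list(data = data[val, ]) else NULL,
          features = shared_features[inner],
          validation_features = if (length(val) > 0) shared_features[val] else NULL)
        stats::predict(m, data[test_idx, ],
                       features = shared_features[test_idx])
      } else {
        predictor(data[train_idx, ], data[test_idx, ])
      }
    }, error = function(e) {
      stop(sprintf("evaluation failed in fold %d: %s", k, conditionMessage(e)))
    })
    fold_stats <- dplyr::bind_rows(
      dplyr::mutate(agreement_stats(data$hr_label[test_idx], est$hr_hat),
                    vital = "hr", .before = 1),
      dplyr::mutate(agreement_stats(data$rr_label[test_idx], est$rr_hat),
                    vital = "rr", .before = 1)
    )
    per_fold[[k]] <- dplyr::mutate(fold_stats, fold = k, .before = 1)
    preds[[k]] <- tibble::tibble(
      epoch = rep(data$epoch[test_idx], 2),
      fold = k,
      vital = rep(c("hr", "rr"), each = length(test_idx)),
      truth = c(data$hr_label[test_idx], data$rr_label[test_idx]),
      estimate = c(est$hr_hat, est$rr_hat)
    )
  }
  predictions <- dplyr::bind_rows(preds)
  pooled <- predictions |>
    dplyr::group_by(.data$vital) |>
    dplyr::reframe(agreement_stats(.data$truth, .data$estimate))
  structure(list(per_fold = dplyr::bind_rows(per_fold), pooled = pooled,
                 predictions = predictions),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\nPer-fold:\n")
  print(x$per_fold, n = Inf)
  cat("Pooled:\n")
  print(x$pooled)
  invisible(x)
}

#' Wide (one row per fold) layout of an agreement report
#'
#' Reshapes the per-fold statistics into the 8-column fold-by-fold layout
#' (RR MAE, RR corr, RR bias, RR LOA, then the HR block).
#'
#' @param report An [evaluate_cv()] result.
#' @return Tibble with columns `fold`, `rr_mae`, `rr_corr`, `rr_bias`,
#'   `rr_loa`, `hr_mae`, `hr_corr`, `hr_bias`, `hr_loa`.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  report$per_fold |>
    dplyr::rename(bias = "mean_bias") |>
    tidyr::pivot_wider(names_from = "vital",
                       values_from = c("mae", "corr", "bias", "loa"),
                       names_glue = "{vital}_{.value}") |>
    dplyr::select("fold", "rr_mae", "rr_corr", "rr_bias", "rr_loa",
                  "hr_mae", "hr_corr", "hr_bias", "hr_loa")
}

#' @rdname tidy.vitals_model
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$per_fold

#' @rdname glance.vitals_model
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  x$pooled |>
    dplyr::rename(bias = "mean_bias") |>
    tidyr::pivot_wider(names_from = "vital",
                       values_from = c("mae", "corr", "bias", "loa"),
                       names_glue = "{vital}_{.value}")
}

#' Bland--Altman / scatter plot data and figure
#'
#' `autoplot` draws, per vital, either a Bland--Altman plot (difference
#' against mean, with the bias and bias +/- LOA lines) or a true-vs-
#' estimated scatter.
#'
#' @param object An `agreement_report`.
#' @param type `"bland-altman"` or `"scatter"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object,
                                      type = c("bland-altman", "scatter"),
                                      ...) {
  type <- match.arg(type)
  df <- object$predictions |>
    dplyr::mutate(mean_ = (.data$truth + .data$estimate) / 2,
                  diff_ = .data$truth - .data$estimate)
  if (type == "bland-altman") {
    lines <- df |>
      dplyr::group_by(.data$vital) |>
      dplyr::summarise(bias = mean(.data$diff_),
                       loa = 1.96 * stats::sd(.data$diff_)) |>
      tidyr::pivot_longer(-"vital") |>
      dplyr::group_by(.data$vital) |>
      dplyr::reframe(y = c(.data$value[.data$name == "bias"],
                           .data$value[.data$name == "bias"] +
                             c(-1, 1) * .data$value[.data$name == "loa"]))
    ggplot2::ggplot(df, ggplot2::aes(.data$mean_, .data$diff_)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$y),
                          linetype = "dashed") +
      ggplot2::facet_wrap(~vital, scales = "free") +
      ggplot2::labs(x = "Mean of true and estimated (BPM)",
                    y = "True - estimated (BPM)")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$estimate)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::facet_wrap(~vital, scales = "free") +
      ggplot2::labs(x = "True (BPM)", y = "Estimated (BPM)")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrogram image
#'
#' @param image A [build_image()] result.
#' @return A ggplot raster of the band-limited spectrogram.
#' @export
plot_spectro_image <- function(image) {
  stopifnot(inherits(image, "spectro_image"))
  df <- tidyr::expand_grid(row = seq_len(nrow(image$image)),
                           col = seq_len(ncol(image$image)))
  df$freq <- image$freqs[df$row]
  df$magnitude <- image$image[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$freq,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Time column (3 bins x 59 frames)",
                  y = "Frequency (Hz)", fill = "|STFT|")
}
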