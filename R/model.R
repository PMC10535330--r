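#' Dual-branch model specification
#'
#' Architecture of the transfer-learning regressor: a pretrained (frozen)
#' convolutional backbone shared by two structurally identical branches,
#' one per vital sign. Each branch appends a 3x3 convolution with 16
#' filters, 3x3 max-pooling, and dense layers of 8 (ReLU), 4 (ReLU) and 1
#' (linear) unit for the regression output.
#'
#' Two backbones are available: `"vgg16"` — the VGG-16 convolutional stack,
#' which requires ImageNet weights supplied via `weights_file` — and
#' `"tiny-test"` — a small seeded random two-layer stack with the same
#' interface, used for tests and desk-scale experiments where no weight
#' download is possible.
#'
#' @param backbone `"tiny-test"` or `"vgg16"`.
#' @param backbone_frozen Keep the backbone weights fixed during training.
#'   Only `TRUE` is supported: the trainable set is the added layers of
#'   both branches.
#' @param head_conv_filters Filters in each branch's added convolution.
#' @param head_dense Sizes of the two ReLU dense layers.
#' @param weights_file Optional path to an RDS file of pretrained backbone
#'   weights (required for `"vgg16"`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(backbone = c("tiny-test", "vgg16"),
                       backbone_frozen = TRUE,
                       head_conv_filters = 16L,
                       head_dense = c(8L, 4L),
                       weights_file = NULL) {
  backbone <- match.arg(backbone)
  if (!isTRUE(backbone_frozen)) {
    stop("model_spec: only backbone_frozen = TRUE is supported; ",
         "the trainable set is the added layers of both branches")
  }
  structure(list(backbone = backbone, backbone_frozen = TRUE,
                 head_conv_filters = as.integer(head_conv_filters),
                 head_dense = as.integer(head_dense),
                 weights_file = weights_file),
            class = "model_spec")
}

#' Optimizer and training configuration
#'
#' Adam with learning rate 0.005 and inverse-time decay 0.001 per update,
#' mean-squared-error loss summed over the two outputs, batch size 32.
#' Targets are z-scored internally per branch (training-set mean/SD) and
#' predictions mapped back to BPM; `standardize_labels = FALSE` disables
#' this.
#'
#' @param learning_rate Adam base learning rate.
#' @param decay Inverse-time learning-rate decay per update:
#'   `lr_t = lr / (1 + decay * t)`.
#' @param batch_size Minibatch size.
#' @param max_epochs Number of training epochs.
#' @param seed Integer seed for head initialization order-independent
#'   shuffling.
#' @param standardize_labels Z-score the targets during training.
#' @param standardize_features Z-score the frozen backbone features
#'   element-wise with training-set statistics before they enter the
#'   heads (stored in the model and re-applied at prediction time).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.005, decay = 0.001,
                         batch_size = 32L, max_epochs = 20L, seed = 1L,
                         standardize_labels = TRUE,
                         standardize_features = TRUE) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, decay = decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 standardize_labels = isTRUE(standardize_labels),
                 standardize_features = isTRUE(standardize_features)),
            class = "train_config")
}

# Backbone layer stacks. Each layer: conv (k, pad, weights (k*k*Cin) x F,
# bias, ReLU) or pool (size, stride). Weights for tiny-test are seeded He
# draws; vgg16 requires supplied weights.
tiny_backbone <- function() {
  ws1 <- init_matrix(3 * 3 * 3, 8, he_sd(3 * 3 * 3))
  ws2 <- init_matrix(3 * 3 * 8, 16, he_sd(3 * 3 * 8))
  list(
    list(type = "conv", k = 3L, pad = 0L, weights = ws1, bias = numeric(8)),
    list(type = "pool", size = 4L, stride = 4L),
    list(type = "conv", k = 3L, pad = 0L, weights = ws2, bias = numeric(16)),
    list(type = "pool", size = 4L, stride = 4L)
  )
}

vgg16_channels <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
vgg16_pool_after <- c(2, 4, 7, 10, 13)

vgg16_backbone <- function(weights_file) {
  if (is.null(weights_file) || !file.exists(weights_file %||% "")) {
    stop("Pretrained VGG-16 weights are required for backbone = \"vgg16\" ",
         "but no weights_file was supplied. Download the ImageNet ",
         "convolutional weights (notop), convert them to an RDS list of ",
         "per-layer (k*k*Cin) x F weight matrices and bias vectors, and ",
         "pass its path as model_spec(weights_file = ...). ",
         "Use backbone = \"tiny-test\" for weight-free experiments.")
  }
  w <- readRDS(weights_file)
  layers <- list()
  cin <- 3L
  for (i in seq_along(vgg16_channels)) {
    f <- vgg16_channels[i]
    stopifnot(identical(dim(w[[i]]$weights), c(3L * 3L * cin, as.integer(f))))
    layers[[length(layers) + 1L]] <-
      list(type = "conv", k = 3L, pad = 1L, weights = w[[i]]$weights,
           bias = w[[i]]$bias)
    if (i %in% vgg16_pool_after) {
      layers[[length(layers) + 1L]] <- list(type = "pool", size = 2L, stride = 2L)
    }
    cin <- as.integer(f)
  }
  layers
}

backbone_out_channels <- function(layers) {
  convs <- Filter(function(l) l$type == "conv", layers)
  ncol(convs[[length(convs)]]$weights)
}

# Forward one tensor through a backbone stack (ReLU after every conv).
backbone_forward <- function(layers, x) {
  for (l in layers) {
    x <- switch(l$type,
      conv = relu(conv_forward(x, l$weights, l$bias, l$k, pad = l$pad)),
      pool = maxpool_forward(x, l$size, l$stride))
  }
  x
}

# Element-wise feature standardization with stored statistics. Values are
# winsorized at +/- 6 SD so a sample outside the training distribution
# cannot drive the heads into wild extrapolation.
apply_feat_scale <- function(features, scale) {
  lapply(features, function(f) {
    z <- (as.vector(f) - scale$mean) / scale$sd
    array(pmin(pmax(z, -6), 6), dim = dim(f))
  })
}

new_head <- function(c_feat, n_flat, filters, dense) {
  list(
    Wc = init_matrix(3 * 3 * c_feat, filters, he_sd(3 * 3 * c_feat)),
    bc = numeric(filters),
    W1 = init_matrix(n_flat, dense[1], he_sd(n_flat)),
    b1 = numeric(dense[1]),
    W2 = init_matrix(dense[1], dense[2], he_sd(dense[1])),
    b2 = numeric(dense[2]),
    W3 = init_matrix(dense[2], 1, sqrt(1 / dense[2])),
    b3 = numeric(1)
  )
}

#' Build the dual-branch vitals regressor
#'
#' Constructs the frozen backbone and the two seeded branch heads. The
#' backbone is shared; the heads (one for HR, one for RR) fork after the
#' last backbone feature map and are the only trainable parameters.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed fixing backbone (tiny-test) and head
#'   initialization.
#' @param input_size Input image side length in pixels.
#' @return An object of class `vitals_model`.
#' @export
#' @examples
#' m <- build_vitals_model(model_spec("tiny-test"), seed = 1)
#' m
build_vitals_model <- function(spec = model_spec(), seed = 1L,
                               input_size = 224L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(as.integer(seed))
  backbone <- switch(spec$backbone,
    "tiny-test" = tiny_backbone(),
    "vgg16" = vgg16_backbone(spec$weights_file))
  # probe the feature geometry with a zero input
  feat <- backbone_forward(backbone, array(0, c(input_size, input_size, 3)))
  fd <- dim(feat)
  conv_hw <- fd[1:2] - 2L  # 3x3 valid head conv
  if (any(conv_hw < 3L)) stop("backbone feature map too small for the head")
  pool_idx <- pool_index_table(conv_hw[1], conv_hw[2], 3L, 3L)
  n_flat <- nrow(pool_idx) * spec$head_conv_filters
  heads <- list(
    hr = new_head(fd[3], n_flat, spec$head_conv_filters, spec$head_dense),
    rr = new_head(fd[3], n_flat, spec$head_conv_filters, spec$head_dense)
  )
  structure(list(
    spec = spec, backbone = backbone, heads = heads,
    input_size = as.integer(input_size),
    geom = list(feat_dim = fd, conv_hw = conv_hw, n_cells = prod(conv_hw),
                pool_idx = pool_idx, n_flat = n_flat),
    label_scale = NULL, history = NULL
  ), class = "vitals_model")
}

#' @export
print.vitals_model <- function(x, ...) {
  np <- sum(vapply(unlist(x$heads, recursive = FALSE), length, numeric(1)))
  cat(sprintf(
    "<vitals_model> backbone %s (frozen), feature map %s, 2 branches, %d trainable parameters%s\n",
    x$spec$backbone, paste(x$geom$feat_dim, collapse = "x"), np,
    if (is.null(x$history)) " (untrained)" else sprintf(
      ", trained %d epochs", nrow(x$history))))
  invisible(x)
}

#' Backbone feature maps for a set of input tensors
#'
#' Runs the frozen backbone over each tensor. Exposed so cross-validation
#' can compute features once and reuse them across folds and branches.
#'
#' @param model A [build_vitals_model()] result.
#' @param tensors List of `input_size x input_size x 3` arrays.
#' @return List of feature arrays.
#' @export
backbone_features <- function(model, tensors) {
  stopifnot(inherits(model, "vitals_model"))
  lapply(tensors, function(x) backbone_forward(model$backbone, x))
}

# Stack per-sample head-conv im2col matrices into one big matrix.
stack_head_cols <- function(model, features) {
  mats <- lapply(features, im2col, k = 3L)
  list(X = do.call(rbind, mats), n = length(features),
       ncells = model$geom$n_cells)
}

# Batched head forward for samples `rows` (sample indices) of a stacked
# im2col matrix. Returns prediction and caches for backward.
head_forward <- function(params, stacked, rows, geom, want_cache = FALSE) {
  nc <- stacked$ncells
  b <- length(rows)
  ridx <- rep((rows - 1L) * nc, each = nc) + rep.int(seq_len(nc), b)
  Xb <- stacked$X[ridx, , drop = FALSE]
  z1 <- sweep(Xb %*% params$Wc, 2, params$bc, "+")
  a1 <- relu(z1)
  # batched max-pool over the conv grid
  idx <- geom$pool_idx
  npc <- nrow(idx)
  nchan <- ncol(z1)
  rowbase <- rep((seq_len(b) - 1L) * nc, each = npc)
  p <- matrix(-Inf, b * npc, nchan)
  amax <- matrix(1L, b * npc, nchan)
  for (m in seq_len(ncol(idx))) {
    cand <- a1[rowbase + rep.int(idx[, m], b), , drop = FALSE]
    upd <- cand > p
    p[upd] <- cand[upd]
    amax[upd] <- m
  }
  v <- matrix(0, b, npc * nchan)
  for (ch in seq_len(nchan)) {
    v[, (ch - 1L) * npc + seq_len(npc)] <- t(matrix(p[, ch], npc, b))
  }
  z2 <- sweep(v %*% params$W1, 2, params$b1, "+")
  h1 <- relu(z2)
  z3 <- sweep(h1 %*% params$W2, 2, params$b2, "+")
  h2 <- relu(z3)
  y <- drop(h2 %*% params$W3) + params$b3
  if (!want_cache) return(y)
  list(y = y, Xb = Xb, z1 = z1, amax = amax, v = v, z2 = z2, h1 = h1,
       z3 = z3, h2 = h2, b = b, rowbase = rowbase, npc = npc, nchan = nchan,
       nc = nc)
}

# Gradients of the summed-MSE loss w.r.t. one head's parameters given
# dL/dy for each batch sample.
head_backward <- function(params, cache, gy, geom) {
  gy <- matrix(gy, ncol = 1)
  gW3 <- t(cache$h2) %*% gy
  gb3 <- sum(gy)
  gh2 <- (gy %*% t(params$W3)) * (cache$z3 > 0)
  gW2 <- t(cache$h1) %*% gh2
  gb2 <- colSums(gh2)
  gh1 <- (gh2 %*% t(params$W2)) * (cache$z2 > 0)
  gW1 <- t(cache$v) %*% gh1
  gb1 <- colSums(gh1)
  gv <- gh1 %*% t(params$W1)
  npc <- cache$npc
  b <- cache$b
  idx <- geom$pool_idx
  ga1 <- matrix(0, b * cache$nc, cache$nchan)
  cellj <- rep.int(seq_len(npc), b)
  for (ch in seq_len(cache$nchan)) {
    gp_ch <- as.vector(t(gv[, (ch - 1L) * npc + seq_len(npc), drop = FALSE]))
    rows_ch <- cache$rowbase + idx[cbind(cellj, cache$amax[, ch])]
    ga1[cbind(rows_ch, rep.int(ch, length(rows_ch)))] <- gp_ch
  }
  gz1 <- ga1 * (cache$z1 > 0)
  list(Wc = t(cache$Xb) %*% gz1, bc = colSums(gz1),
       W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

resolve_training_data <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("tensor", "hr_label", "rr_label") %in% names(x)))
    list(tensors = x$tensor,
         labels = tibble::tibble(hr = x$hr_label, rr = x$rr_label))
  } else {
    stopifnot(is.list(x), !is.null(labels),
              all(c("hr", "rr") %in% names(labels)))
    list(tensors = x, labels = tibble::as_tibble(labels[c("hr", "rr")]))
  }
}

#' Train the dual-branch regressor
#'
#' Trains the added layers of both branches with Adam on the
#' mean-squared-error loss summed over the HR and RR outputs. The backbone
#' stays frozen; with `validation` supplied, the head weights from the
#' epoch with the lowest validation loss are restored at the end.
#'
#' @param model A [build_vitals_model()] result.
#' @param data A tibble from [featurize_epochs()] (columns `tensor`,
#'   `hr_label`, `rr_label`) or a list of input tensors (then supply
#'   `labels`).
#' @param config A [train_config()].
#' @param labels Tibble with columns `hr`, `rr` when `data` is a bare list.
#' @param validation Optional held-out set in the same form as `data`
#'   (list with elements `data` and optionally `labels`).
#' @param features,validation_features Optional precomputed
#'   [backbone_features()] lists (cross-validation reuse).
#' @return The trained `vitals_model`, with a `history` tibble of per-epoch
#'   train (and validation) loss.
#' @export
train_vitals_model <- function(model, data, config = train_config(),
                               labels = NULL, validation = NULL,
                               features = NULL, validation_features = NULL) {
  stopifnot(inherits(model, "vitals_model"), inherits(config, "train_config"))
  td <- resolve_training_data(data, labels)
  n <- length(td$tensors)
  stopifnot("need at least one batch" = n >= 1,
            nrow(td$labels) == n)
  set.seed(config$seed)
  if (is.null(features)) features <- backbone_features(model, td$tensors)
  if (config$standardize_features) {
    fmat <- vapply(features, as.vector, numeric(prod(model$geom$feat_dim)))
    mu <- rowMeans(fmat)
    sdv <- apply(fmat, 1, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    model$feat_scale <- list(mean = mu, sd = sdv)
    features <- apply_feat_scale(features, model$feat_scale)
  } else {
    model$feat_scale <- NULL
  }
  stacked <- stack_head_cols(model, features)

  scale_of <- function(v) {
    s <- stats::sd(v)
    c(mean = mean(v), sd = if (is.finite(s) && s > 0) s else 1)
  }
  if (config$standardize_labels) {
    model$label_scale <- list(hr = scale_of(td$labels$hr),
                              rr = scale_of(td$labels$rr))
  } else {
    model$label_scale <- list(hr = c(mean = 0, sd = 1), rr = c(mean = 0, sd = 1))
  }
  y_t <- list(
    hr = (td$labels$hr - model$label_scale$hr["mean"]) / model$label_scale$hr["sd"],
    rr = (td$labels$rr - model$label_scale$rr["mean"]) / model$label_scale$rr["sd"]
  )

  vstacked <- NULL
  yv <- NULL
  if (!is.null(validation)) {
    vd <- resolve_training_data(validation$data %||% validation,
                                validation$labels)
    vf <- validation_features %||% backbone_features(model, vd$tensors)
    if (!is.null(model$feat_scale)) vf <- apply_feat_scale(vf, model$feat_scale)
    vstacked <- stack_head_cols(model, vf)
    yv <- list(
      hr = (vd$labels$hr - model$label_scale$hr["mean"]) / model$label_scale$hr["sd"],
      rr = (vd$labels$rr - model$label_scale$rr["mean"]) / model$label_scale$rr["sd"]
    )
  }

  params <- c(stats::setNames(model$heads$hr, paste0("hr.", names(model$heads$hr))),
              stats::setNames(model$heads$rr, paste0("rr.", names(model$heads$rr))))
  state <- adam_init(params)
  split_heads <- function(p) list(
    hr = stats::setNames(p[paste0("hr.", c("Wc","bc","W1","b1","W2","b2","W3","b3"))],
                         c("Wc","bc","W1","b1","W2","b2","W3","b3")),
    rr = stats::setNames(p[paste0("rr.", c("Wc","bc","W1","b1","W2","b2","W3","b3"))],
                         c("Wc","bc","W1","b1","W2","b2","W3","b3")))

  branch_loss <- function(hp, st, yy) {
    yh <- head_forward(hp, st, seq_len(st$n), model$geom)
    mean((yy - yh)^2)
  }

  history <- NULL
  # the two branches are independent; each is restored from its own
  # lowest-validation-loss epoch
  best <- list(hr = list(loss = Inf, params = NULL),
               rr = list(loss = Inf, params = NULL))
  for (ep in seq_len(config$max_epochs)) {
    order_ <- sample.int(n)
    batches <- split(order_, ceiling(seq_along(order_) / config$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      hp <- split_heads(params)
      b <- length(batch)
      ch <- head_forward(hp$hr, stacked, batch, model$geom, want_cache = TRUE)
      cr <- head_forward(hp$rr, stacked, batch, model$geom, want_cache = TRUE)
      res_h <- ch$y - y_t$hr[batch]
      res_r <- cr$y - y_t$rr[batch]
      loss <- mean(res_h^2) + mean(res_r^2)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      }
      ep_loss <- ep_loss + loss * b
      gh <- head_backward(hp$hr, ch, 2 * res_h / b, model$geom)
      gr <- head_backward(hp$rr, cr, 2 * res_r / b, model$geom)
      grads <- c(stats::setNames(gh, paste0("hr.", names(gh))),
                 stats::setNames(gr, paste0("rr.", names(gr))))
      upd <- adam_step(params, grads, state,
                       lr = config$learning_rate, decay = config$decay)
      params <- upd$params
      state <- upd$state
    }
    hp <- split_heads(params)
    vl_hr <- if (is.null(vstacked)) NA_real_ else branch_loss(hp$hr, vstacked, yv$hr)
    vl_rr <- if (is.null(vstacked)) NA_real_ else branch_loss(hp$rr, vstacked, yv$rr)
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = ep, train_loss = ep_loss / n,
      val_loss = vl_hr + vl_rr, val_loss_hr = vl_hr, val_loss_rr = vl_rr))
    if (!is.null(vstacked)) {
      if (vl_hr < best$hr$loss) best$hr <- list(loss = vl_hr, params = hp$hr)
      if (vl_rr < best$rr$loss) best$rr <- list(loss = vl_rr, params = hp$rr)
    }
  }
  hp <- split_heads(params)
  model$heads <- if (is.null(vstacked)) hp else
    list(hr = best$hr$params, rr = best$rr$params)
  model$history <- history
  model
}

#' Predict HR and RR for spectrogram tensors
#'
#' @param object A trained (or freshly built) `vitals_model`.
#' @param newdata A tibble with a `tensor` list-column or a list of input
#'   tensors.
#' @param features Optional precomputed [backbone_features()] list.
#' @param ... Unused.
#' @return A tibble with columns `hr_hat`, `rr_hat` (beats/breaths per
#'   minute), one row per input.
#' @export
predict.vitals_model <- function(object, newdata, features = NULL, ...) {
  tensors <- if (is.data.frame(newdata)) newdata$tensor else newdata
  if (is.null(features)) features <- backbone_features(object, tensors)
  if (!is.null(object$feat_scale)) {
    features <- apply_feat_scale(features, object$feat_scale)
  }
  stacked <- stack_head_cols(object, features)
  yh <- head_forward(object$heads$hr, stacked, seq_len(stacked$n), object$geom)
  yr <- head_forward(object$heads$rr, stacked, seq_len(stacked$n), object$geom)
  sc <- object$label_scale %||%
    list(hr = c(mean = 0, sd = 1), rr = c(mean = 0, sd = 1))
  tibble::tibble(hr_hat = as.numeric(yh * sc$hr[["sd"]] + sc$hr[["mean"]]),
                 rr_hat = as.numeric(yr * sc$rr[["sd"]] + sc$rr[["mean"]]))
}

#' Checksum of the backbone weights (freezing contract)
#'
#' @param model A `vitals_model`.
#' @return A single numeric checksum; invariant under training while the
#'   backbone is frozen.
#' @export
backbone_checksum <- function(model) {
  convs <- Filter(function(l) l$type == "conv", model$backbone)
  param_checksum(lapply(convs, function(l) c(as.numeric(l$weights), l$bias)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted vitals model
#'
#' @param x A trained `vitals_model`.
#' @param ... Unused.
#' @return Long tibble: `epoch`, `metric` (`train_loss` / `val_loss`),
#'   `loss`.
#' @export
tidy.vitals_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), metric = character(),
                          loss = numeric()))
  }
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric",
                      values_to = "loss") |>
    dplyr::filter(is.finite(.data$loss))
}

#' One-row summary of a fitted vitals model
#'
#' @param x A `vitals_model`.
#' @param ... Unused.
#' @return Tibble with backbone, parameter count, epochs trained, and
#'   final train/validation loss.
#' @method glance vitals_model
#' @export
glance.vitals_model <- function(x, ...) {
  np <- sum(vapply(unlist(x$heads, recursive = FALSE), length, numeric(1)))
  tibble::tibble(
    backbone = x$spec$backbone,
    n_trainable = np,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$train_loss, 1),
    final_val_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$val_loss, 1)
  )
}
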