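# Minimal CNN machinery in base-R matrix ops. Convolutions are computed as
# im2col matrix products; only what the frozen-backbone regressor needs is
# implemented (forward everywhere, backward through the trainable heads).

# Zero-pad an H x W x C array by p pixels on each spatial side.
pad_array <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# im2col: each output row is one k x k x C receptive field, flattened in
# (dy, dx, channel) order; rows run over output positions column-major
# (down each output column first), matching R array layout.
im2col <- function(x, k, stride = 1, pad = 0) {
  x <- pad_array(x, pad)
  d <- dim(x)
  ho <- (d[1] - k) %/% stride + 1L
  wo <- (d[2] - k) %/% stride + 1L
  out <- matrix(0, ho * wo, k * k * d[3])
  ri <- (seq_len(ho) - 1L) * stride  # top-left offsets
  ci <- (seq_len(wo) - 1L) * stride
  base <- as.vector(outer(ri, ci * d[1], "+"))  # linear index of each field
  xv <- as.vector(x)
  hw <- d[1] * d[2]
  col <- 1L
  for (c in seq_len(d[3])) {
    off <- (c - 1L) * hw
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        out[, col] <- xv[base + dy + (dx - 1L) * d[1] + off]
        col <- col + 1L
      }
    }
  }
  attr(out, "out_dim") <- c(ho, wo)
  out
}

# 2-D convolution of one H x W x C array with weights (k*k*C) x F.
conv_forward <- function(x, weights, bias, k, stride = 1, pad = 0) {
  cols <- im2col(x, k, stride, pad)
  z <- sweep(cols %*% weights, 2, bias, "+")
  od <- attr(cols, "out_dim")
  array(z, c(od[1], od[2], ncol(weights)))
}

# Max-pooling of an H x W x C array (values only; used in frozen stacks).
maxpool_forward <- function(x, size, stride = size) {
  d <- dim(x)
  ho <- (d[1] - size) %/% stride + 1L
  wo <- (d[2] - size) %/% stride + 1L
  out <- array(-Inf, c(ho, wo, d[3]))
  for (dy in seq_len(size)) {
    for (dx in seq_len(size)) {
      rows <- (seq_len(ho) - 1L) * stride + dy
      cols <- (seq_len(wo) - 1L) * stride + dx
      out <- pmax(out, x[rows, cols, , drop = FALSE])
    }
  }
  out
}

relu <- function(x) pmax(x, 0)

# Pooling index table for the batched head path: for a ho x wo input grid
# pooled with size/stride, returns a (n_cells x size^2) matrix of linear
# positions into the ho*wo column-major position space.
pool_index_table <- function(ho, wo, size, stride = size) {
  po <- (ho - size) %/% stride + 1L
  qo <- (wo - size) %/% stride + 1L
  cells <- expand.grid(py = seq_len(po), px = seq_len(qo))
  members <- expand.grid(dy = seq_len(size), dx = seq_len(size))
  idx <- matrix(0L, nrow(cells), nrow(members))
  for (m in seq_len(nrow(members))) {
    r <- (cells$py - 1L) * stride + members$dy[m]
    cc <- (cells$px - 1L) * stride + members$dx[m]
    idx[, m] <- r + (cc - 1L) * ho
  }
  attr(idx, "pooled_dim") <- c(po, qo)
  idx
}

# Seeded weight initializers (He-style for ReLU layers).
init_matrix <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

he_sd <- function(fan_in) sqrt(2 / fan_in)

# One Adam step with Keras-style inverse-time learning-rate decay:
# lr_t = lr / (1 + decay * iteration). `state` holds m, v, iter.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       iter = 0L)
}

adam_step <- function(params, grads, state, lr = 0.005, decay = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$iter <- state$iter + 1L
  t <- state$iter
  lr_t <- lr / (1 + decay * (t - 1))
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Deterministic checksum of a weight list (freezing contract checks).
param_checksum <- function(params) {
  sum(vapply(params, function(p) sum(as.numeric(p)), numeric(1)))
}
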