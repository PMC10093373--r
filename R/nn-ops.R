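# Low-level neural-network operations.
#
# No deep-learning framework is used: layers are plain matrix operations
# with hand-written backward passes (verified against finite differences in
# the test suite). Feature maps are stored as a list
#   fm = list(x = (H*W*N) x C matrix, h, w, n)
# with row order: row index fastest, then column, then sample.

#' Numerically stable softmax
#'
#' @param z A finite numeric vector, or a matrix whose rows are transformed
#'   independently.
#' @return Probabilities of the same shape: non-negative, each (row) summing
#'   to 1; invariant under adding a constant to `z`.
#' @export
#' @examples
#' softmax(c(1, 0))
softmax <- function(z) {
  if (length(z) == 0L) stop_invalid("`z` must be non-empty")
  if (!all(is.finite(z))) stop_invalid("`z` must be finite")
  if (is.matrix(z)) {
    m <- apply(z, 1L, max)
    e <- exp(z - m)
    return(e / rowSums(e))
  }
  e <- exp(z - max(z))
  e / sum(e)
}

#' Batch-averaged cross-entropy loss
#'
#' `-sum(l * log p)` per sample, averaged over the batch, with one-hot target
#' rows `l`. Predicted probabilities are floored at 1e-12 inside the log so a
#' saturated wrong prediction yields a large finite loss instead of `Inf`.
#'
#' @param onehot A matrix (or vector) of one-hot target rows.
#' @param prob A matrix (or vector) of predicted probability rows.
#' @return A scalar >= 0; 0 exactly when every true class has probability 1.
#' @export
cross_entropy_loss <- function(onehot, prob) {
  if (is.null(dim(onehot))) onehot <- matrix(onehot, nrow = 1L)
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
  if (!identical(dim(onehot), dim(prob))) {
    stop_invalid("`onehot` and `prob` must have the same shape")
  }
  -mean(rowSums(onehot * log(pmax(prob, 1e-12))))
}

#' Step-decay learning-rate schedule
#'
#' The learning rate is divided by 10 every 30 epochs:
#' `lr = lr0 * 0.1 ^ floor(epoch / 30)`.
#'
#' @param lr0 Initial learning rate (> 0).
#' @param epoch Zero-based epoch index (>= 0); may be a vector.
#' @return The learning rate(s) at `epoch`.
#' @export
#' @examples
#' lr_schedule(0.01, c(0, 29, 30, 60))
lr_schedule <- function(lr0, epoch) {
  check_number(lr0, "lr0", min = 1e-300)
  if (any(epoch < 0) || any(epoch != round(epoch))) {
    stop_invalid("`epoch` must contain non-negative integers")
  }
  lr0 * 0.1^(epoch %/% 30)
}

onehot_matrix <- function(labels, n_classes) {
  out <- matrix(0, length(labels), n_classes)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

# ---- layer parameter constructors (draw from the current RNG) ----

conv_init <- function(k, cin, cout, groups = 1L) {
  stopifnot(cin %% groups == 0L, cout %% groups == 0L)
  cin_g <- cin %/% groups
  sdw <- sqrt(2 / (k * k * cin_g))
  list(W = array(rnorm(k * k * cin_g * cout, 0, sdw), dim = c(k, k, cin_g, cout)),
       b = numeric(cout))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

bn_state_init <- function(c) {
  list(mean = numeric(c), var = rep(1, c), count = 0)
}

dense_init <- function(din, dout) {
  list(W = matrix(rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

# ---- convolution ----

# row indices of the (Hp*Wp*n) padded matrix touched by kernel offset (dy,dx)
conv_offset_rows <- function(dy, dx, hp, wp, n, out_h, out_w, stride) {
  hh <- dy + stride * (0:(out_h - 1L))
  ww <- dx + stride * (0:(out_w - 1L))
  pix <- as.vector(outer(hh, (ww - 1L) * hp, "+"))
  as.vector(outer(pix, (seq_len(n) - 1L) * hp * wp, "+"))
}

conv_forward <- function(fm, p, stride = 1L, pad = NULL, groups = 1L) {
  k <- dim(p$W)[1L]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  h <- fm$h; w <- fm$w; n <- fm$n
  cin <- ncol(fm$x); cout <- length(p$b)
  hp <- h + 2L * pad; wp <- w + 2L * pad

  if (pad > 0L) {
    idx <- conv_offset_rows(pad + 1L, pad + 1L, hp, wp, n, h, w, 1L)
    mpad <- matrix(0, hp * wp * n, cin)
    mpad[idx, ] <- fm$x
  } else {
    idx <- NULL
    mpad <- fm$x
  }
  out_h <- (h + 2L * pad - k) %/% stride + 1L
  out_w <- (w + 2L * pad - k) %/% stride + 1L

  cin_g <- cin %/% groups; cout_g <- cout %/% groups
  out <- matrix(rep(p$b, each = out_h * out_w * n), out_h * out_w * n, cout)
  rows <- vector("list", k * k)
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      ro <- conv_offset_rows(dy, dx, hp, wp, n, out_h, out_w, stride)
      rows[[(dy - 1L) * k + dx]] <- ro
      for (g in seq_len(groups)) {
        ic <- (g - 1L) * cin_g + seq_len(cin_g)
        oc <- (g - 1L) * cout_g + seq_len(cout_g)
        wo <- matrix(p$W[dy, dx, , oc], cin_g, cout_g)
        out[, oc] <- out[, oc] + mpad[ro, ic, drop = FALSE] %*% wo
      }
    }
  }
  list(out = list(x = out, h = out_h, w = out_w, n = n),
       cache = list(mpad = mpad, rows = rows, idx = idx, k = k,
                    groups = groups, cin = cin, cout = cout,
                    dims = c(hp = hp, wp = wp, n = n)))
}

conv_backward <- function(dout, cache, p) {
  k <- cache$k; groups <- cache$groups
  cin <- cache$cin; cout <- cache$cout
  cin_g <- cin %/% groups; cout_g <- cout %/% groups
  dW <- array(0, dim = dim(p$W))
  db <- colSums(dout)
  dmpad <- matrix(0, nrow(cache$mpad), cin)
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      ro <- cache$rows[[(dy - 1L) * k + dx]]
      for (g in seq_len(groups)) {
        ic <- (g - 1L) * cin_g + seq_len(cin_g)
        oc <- (g - 1L) * cout_g + seq_len(cout_g)
        xo <- cache$mpad[ro, ic, drop = FALSE]
        dW[dy, dx, , oc] <- crossprod(xo, dout[, oc, drop = FALSE])
        wo <- matrix(p$W[dy, dx, , oc], cin_g, cout_g)
        dmpad[ro, ic] <- dmpad[ro, ic, drop = FALSE] +
          dout[, oc, drop = FALSE] %*% t(wo)
      }
    }
  }
  dx <- if (is.null(cache$idx)) dmpad else dmpad[cache$idx, , drop = FALSE]
  list(dx = dx, dp = list(W = dW, b = db))
}

# ---- batch normalization (per channel) ----

bn_forward <- function(x, p, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    m <- colMeans(x)
    v <- pmax(0, colMeans(x * x) - m * m)
    state$mean <- if (state$count == 0) m else (1 - momentum) * state$mean + momentum * m
    state$var  <- if (state$count == 0) v else (1 - momentum) * state$var + momentum * v
    state$count <- state$count + 1
  } else {
    m <- state$mean; v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2L, m, "-"), 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = out, state = state,
       cache = list(xhat = xhat, inv = inv, training = training))
}

bn_backward <- function(dout, cache, p) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, p$gamma, "*")
  if (cache$training) {
    nr <- nrow(dout)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2L, cache$inv, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dx = dx, dp = list(gamma = dgamma, beta = dbeta))
}

# ---- simple elementwise / pooling / dense ops ----

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

sigmoid_forward <- function(x) {
  s <- plogis(x)
  list(out = s, cache = s)
}
sigmoid_backward <- function(dout, cache) dout * cache * (1 - cache)

# global average pooling: (H*W*N) x C -> N x C
gap_forward <- function(fm) {
  grp <- rep(seq_len(fm$n), each = fm$h * fm$w)
  out <- rowsum(fm$x, grp) / (fm$h * fm$w)
  rownames(out) <- NULL
  list(out = out, cache = list(h = fm$h, w = fm$w, n = fm$n))
}
gap_backward <- function(dout, cache) {
  grp <- rep(seq_len(cache$n), each = cache$h * cache$w)
  dout[grp, , drop = FALSE] / (cache$h * cache$w)
}

dense_forward <- function(x, p) {
  list(out = sweep(x %*% p$W, 2L, p$b, "+"), cache = x)
}
dense_backward <- function(dout, cache, p) {
  list(dx = dout %*% t(p$W),
       dp = list(W = crossprod(cache, dout), b = colSums(dout)))
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  keep <- 1 - rate
  mask <- matrix(rbinom(length(x), 1L, keep), nrow(x), ncol(x)) / keep
  list(out = x * mask, cache = mask)
}
dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# softmax + cross-entropy fused head; labels are 0-based
softmax_ce_forward <- function(logits, labels) {
  prob <- softmax(logits)
  loss <- cross_entropy_loss(onehot_matrix(labels, ncol(logits)), prob)
  list(prob = prob, loss = loss)
}
softmax_ce_backward <- function(prob, labels) {
  (prob - onehot_matrix(labels, ncol(prob))) / nrow(prob)
}
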