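# Deep belief network classifier.
#
# Restricted Boltzmann machines: bipartite energy model over binary visible
# units v (length n) and hidden units h (length m),
#   E(v,h) = -a'v - b'h - v'Wh,   p(v,h) = exp(-E)/Z,
# with logistic conditionals in both directions. RBMs are trained by
# contrastive divergence (CD-k), stacked greedily (each layer's hidden
# activation probabilities feed the next layer's visible units), then a
# multinomial logistic output layer is attached and the whole stack is
# fine-tuned with supervised backpropagation.

#' RBM parameter container
#'
#' @param n,m Number of visible / hidden units.
#' @param seed Optional seed; weights ~ N(0, 0.01), biases 0.
#' @param W,a,b Optional explicit weight matrix (n x m), visible biases
#'   (length n), hidden biases (length m).
#' @return An `rbm_params` list.
#' @export
rbm_params <- function(n, m, seed = NULL, W = NULL, a = NULL, b = NULL) {
  check_number(n, "n", min = 1, integer = TRUE)
  check_number(m, "m", min = 1, integer = TRUE)
  if (is.null(W)) {
    W <- if (is.null(seed)) matrix(rnorm(n * m, 0, 0.01), n, m) else
      with_seed(seed, matrix(rnorm(n * m, 0, 0.01), n, m))
  }
  a <- a %||% numeric(n)
  b <- b %||% numeric(m)
  if (!identical(dim(W), c(as.integer(n), as.integer(m))) ||
      length(a) != n || length(b) != m || !all(is.finite(c(W, a, b)))) {
    stop_invalid("inconsistent or non-finite RBM parameters")
  }
  structure(list(W = W, a = as.numeric(a), b = as.numeric(b),
                 n = as.integer(n), m = as.integer(m)),
            class = "rbm_params")
}

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) stop_invalid("`%s` must be binary (0/1)", name)
  as.numeric(x)
}

#' RBM joint-configuration energy
#'
#' `E(v, h) = -sum(a*v) - sum(b*h) - v' W h`.
#'
#' @param v Binary visible vector (length n).
#' @param h Binary hidden vector (length m).
#' @param params An [rbm_params()].
#' @return A scalar energy.
#' @export
rbm_energy <- function(v, h, params) {
  stopifnot(inherits(params, "rbm_params"))
  if (length(v) != params$n || length(h) != params$m) {
    stop_invalid("v/h lengths must match the RBM (n=%d, m=%d)", params$n, params$m)
  }
  v <- check_binary(v, "v"); h <- check_binary(h, "h")
  -sum(params$a * v) - sum(params$b * h) - drop(v %*% params$W %*% h)
}

enumerate_states <- function(k) {
  # 2^k x k matrix of all binary vectors
  m <- matrix(0, 2^k, k)
  for (j in seq_len(k)) m[, j] <- rep(rep(0:1, each = 2^(j - 1L)), length.out = 2^k)
  m
}

#' Exact RBM partition function by enumeration
#'
#' `Z = sum over all 2^(n+m) states of exp(-E(v,h))`; refused for
#' `n + m > 20`.
#'
#' @param params An [rbm_params()].
#' @return The scalar `Z`.
#' @export
partition_function <- function(params) {
  stopifnot(inherits(params, "rbm_params"))
  if (params$n + params$m > 20L) {
    stop_size("exact enumeration limited to n + m <= 20 (got %d)",
              params$n + params$m)
  }
  V <- enumerate_states(params$n)
  H <- enumerate_states(params$m)
  # -E over the grid: (a'v) + (b'h) + v'Wh
  e <- outer(drop(V %*% params$a), drop(H %*% params$b), "+") +
    V %*% params$W %*% t(H)
  sum(exp(e))
}

#' Hidden-unit conditional probabilities
#'
#' `p(h_j = 1 | v) = logistic(b_j + sum_i W_ij v_i)`. Accepts a single
#' visible vector or a matrix with one configuration per row; mean-field
#' inputs in \[0,1\] are allowed.
#'
#' @param v Visible vector (length n) or matrix (rows x n), values in \[0,1\].
#' @param params An [rbm_params()].
#' @return Probabilities in (0,1), same leading shape as `v`.
#' @export
conditional_hidden <- function(v, params) {
  stopifnot(inherits(params, "rbm_params"))
  if (is.null(dim(v))) {
    if (length(v) != params$n) stop_invalid("`v` must have length n = %d", params$n)
    return(plogis(params$b + drop(v %*% params$W)))
  }
  if (ncol(v) != params$n) stop_invalid("`v` must have n = %d columns", params$n)
  plogis(sweep(v %*% params$W, 2L, params$b, "+"))
}

#' Visible-unit conditional probabilities
#'
#' `p(v_i = 1 | h) = logistic(a_i + sum_j W_ij h_j)` — the mirror of
#' [conditional_hidden()].
#'
#' @param h Hidden vector (length m) or matrix (rows x m), values in \[0,1\].
#' @param params An [rbm_params()].
#' @return Probabilities in (0,1).
#' @export
conditional_visible <- function(h, params) {
  stopifnot(inherits(params, "rbm_params"))
  if (is.null(dim(h))) {
    if (length(h) != params$m) stop_invalid("`h` must have length m = %d", params$m)
    return(plogis(params$a + drop(params$W %*% h)))
  }
  if (ncol(h) != params$m) stop_invalid("`h` must have m = %d columns", params$m)
  plogis(sweep(h %*% t(params$W), 2L, params$a, "+"))
}

#' Exact mean log-likelihood of visible data (enumerable RBMs)
#'
#' Uses the analytic free energy with the enumerated partition function;
#' subject to the same `n + m <= 20` guard.
#'
#' @param data Matrix of visible rows in \[0,1\].
#' @param params An [rbm_params()].
#' @return Mean log-likelihood over rows.
#' @export
rbm_log_likelihood <- function(data, params) {
  z <- partition_function(params)
  act <- sweep(data %*% params$W, 2L, params$b, "+")
  free <- drop(data %*% params$a) + rowSums(log1p(exp(act)))
  mean(free) - log(z)
}

#' Train one RBM with contrastive divergence
#'
#' CD-k: sample hidden states from the data, reconstruct visibles (mean
#' field), alternate k times, then update
#' `dW = lr * (<v p_h(v)> - <v_k p_h(v_k)>)` per minibatch (no momentum,
#' no weight decay).
#'
#' @param data Matrix of visible rows, values in \[0,1\].
#' @param n_hidden Number of hidden units.
#' @param cd_steps Gibbs steps `k` (default 1).
#' @param lr Learning rate (>= 0; 0 leaves the parameters untouched).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @param params Optional warm-start [rbm_params()].
#' @return An `rbm_params` with attribute `"history"`: a tibble of per-epoch
#'   mean squared reconstruction error.
#' @export
train_rbm_cd <- function(data, n_hidden, cd_steps = 1L, lr = 0.1,
                         epochs = 10L, batch_size = 16L, seed = 1L,
                         params = NULL) {
  if (!is.matrix(data) || nrow(data) == 0L) stop_invalid("`data` must be a non-empty matrix")
  if (any(data < 0 | data > 1)) stop_invalid("`data` values must lie in [0, 1]")
  check_number(lr, "lr", min = 0)
  check_number(cd_steps, "cd_steps", min = 1, integer = TRUE)
  n <- ncol(data)
  p <- params %||% rbm_params(n, n_hidden, seed = derive_seed(seed, 17L))
  hist <- numeric(epochs)
  p <- with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(data))
      errs <- c()
      for (bi in seq_len(ceiling(nrow(data) / batch_size))) {
        take <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, nrow(data))]
        v0 <- data[take, , drop = FALSE]
        ph0 <- conditional_hidden(v0, p)
        vk <- v0; phk <- ph0
        for (k in seq_len(cd_steps)) {
          hk <- matrix(rbinom(length(phk), 1L, phk), nrow(phk), ncol(phk))
          vk <- conditional_visible(hk, p)
          phk <- conditional_hidden(vk, p)
        }
        nb <- length(take)
        p$W <- p$W + lr * (crossprod(v0, ph0) - crossprod(vk, phk)) / nb
        p$a <- p$a + lr * colMeans(v0 - vk)
        p$b <- p$b + lr * colMeans(ph0 - phk)
        errs <- c(errs, mean((v0 - vk)^2))
      }
      hist[ep] <- mean(errs)
    }
    p
  })
  attr(p, "history") <- tibble::tibble(epoch = seq_len(epochs),
                                       reconstruction_error = hist)
  p
}

#' DBN configuration
#'
#' @param layer_sizes Hidden-layer widths; `NULL` (default) takes three
#'   hidden layers `c(256, 128, 64)` capped at 4x the feature dimension at
#'   fit time.
#' @param cd_steps CD-k Gibbs steps (default 1).
#' @param rbm_lr,rbm_epochs Pre-training rate / epochs per RBM.
#' @param finetune_lr,finetune_epochs Supervised fine-tuning rate / epochs.
#' @param batch_size Minibatch size for both phases.
#' @param seed Integer seed.
#' @return A `dbn_config` list.
#' @export
dbn_config <- function(layer_sizes = NULL, cd_steps = 1L, rbm_lr = 0.3,
                       rbm_epochs = 30L, finetune_lr = 0.5,
                       finetune_epochs = 100L, batch_size = 8L, seed = 1L) {
  if (!is.null(layer_sizes)) {
    if (length(layer_sizes) < 1L || any(layer_sizes < 1)) {
      stop_invalid("`layer_sizes` must contain positive widths")
    }
    layer_sizes <- as.integer(layer_sizes)
  }
  check_number(rbm_lr, "rbm_lr", min = 1e-300)
  check_number(finetune_lr, "finetune_lr", min = 1e-300)
  structure(list(layer_sizes = layer_sizes, cd_steps = as.integer(cd_steps),
                 rbm_lr = rbm_lr, rbm_epochs = as.integer(rbm_epochs),
                 finetune_lr = finetune_lr,
                 finetune_epochs = as.integer(finetune_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "dbn_config")
}

#' Train a DBN classifier by greedy RBM stacking
#'
#' Features are min-max rescaled to \[0,1\] and treated as visible-unit
#' activation probabilities. Each RBM is trained with CD-k on the previous
#' layer's hidden activation probabilities; the stack is then topped with a
#' multinomial logistic layer and fine-tuned end to end by backpropagating
#' the cross-entropy through the logistic layers.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer labels in `[0, n_classes)`, one per row.
#' @param config A [dbn_config()].
#' @param n_classes Number of classes; defaults to `max(labels) + 1`.
#' @return A `dbn_classifier` with layers, the feature scaling, and
#'   training histories.
#' @export
stack_dbn <- function(features, labels, config = dbn_config(),
                      n_classes = max(labels) + 1L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stop_invalid("`labels` length must equal nrow(features)")
  }
  if (any(labels < 0 | labels >= n_classes)) {
    stop_invalid("labels must be in [0, %d)", n_classes)
  }
  d <- ncol(features)
  sizes <- config$layer_sizes %||% pmin(c(256L, 128L, 64L), 4L * d)
  scale <- minmax_fit(features)
  x <- minmax_apply(features, scale)

  rbms <- list()
  cur <- x
  pre_hist <- list()
  for (li in seq_along(sizes)) {
    p <- train_rbm_cd(cur, sizes[li], cd_steps = config$cd_steps,
                      lr = config$rbm_lr, epochs = config$rbm_epochs,
                      batch_size = config$batch_size,
                      seed = derive_seed(config$seed, li))
    pre_hist[[li]] <- attr(p, "history")
    rbms[[li]] <- p
    cur <- conditional_hidden(cur, p)
  }

  # supervised stack: logistic layers initialized from the RBM weights
  layers <- lapply(rbms, function(p) list(W = p$W, b = p$b))
  out_layer <- with_seed(derive_seed(config$seed, 99L),
                         dense_init(sizes[length(sizes)], n_classes))
  out_layer$W <- out_layer$W * 0.1

  n <- nrow(x)
  ft_hist <- numeric(config$finetune_epochs)
  mu <- 0.9  # fine-tuning momentum
  vel <- list(layers = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
              out = list(W = out_layer$W * 0, b = out_layer$b * 0))
  with_seed(derive_seed(config$seed, 100L), {
    for (ep in seq_len(config$finetune_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (bi in seq_len(ceiling(n / config$batch_size))) {
        take <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
        xb <- x[take, , drop = FALSE]
        acts <- list(xb)
        for (l in layers) {
          acts[[length(acts) + 1L]] <-
            plogis(sweep(acts[[length(acts)]] %*% l$W, 2L, l$b, "+"))
        }
        top <- acts[[length(acts)]]
        logits <- sweep(top %*% out_layer$W, 2L, out_layer$b, "+")
        sm <- softmax_ce_forward(logits, labels[take])
        losses <- c(losses, sm$loss)
        dlogit <- softmax_ce_backward(sm$prob, labels[take])
        dW_out <- crossprod(top, dlogit); db_out <- colSums(dlogit)
        dtop <- dlogit %*% t(out_layer$W)
        for (li in rev(seq_along(layers))) {
          a <- acts[[li + 1L]]
          dz <- dtop * a * (1 - a)
          dW <- crossprod(acts[[li]], dz); db <- colSums(dz)
          dtop <- dz %*% t(layers[[li]]$W)
          vel$layers[[li]]$W <- mu * vel$layers[[li]]$W - config$finetune_lr * dW
          vel$layers[[li]]$b <- mu * vel$layers[[li]]$b - config$finetune_lr * db
          layers[[li]]$W <- layers[[li]]$W + vel$layers[[li]]$W
          layers[[li]]$b <- layers[[li]]$b + vel$layers[[li]]$b
        }
        vel$out$W <- mu * vel$out$W - config$finetune_lr * dW_out
        vel$out$b <- mu * vel$out$b - config$finetune_lr * db_out
        out_layer$W <- out_layer$W + vel$out$W
        out_layer$b <- out_layer$b + vel$out$b
      }
      ft_hist[ep] <- mean(losses)
    }
  })

  structure(list(layers = layers, out_layer = out_layer, scale = scale,
                 rbms = rbms, n_classes = as.integer(n_classes),
                 config = config,
                 pretrain_history = pre_hist,
                 finetune_history = tibble::tibble(
                   epoch = seq_len(config$finetune_epochs), loss = ft_hist)),
            class = "dbn_classifier")
}

dbn_forward_probs <- function(model, features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (ncol(features) != nrow(model$layers[[1L]]$W)) {
    stop_invalid("feature dimension %d does not match the model (%d)",
                 ncol(features), nrow(model$layers[[1L]]$W))
  }
  cur <- minmax_apply(features, model$scale)
  for (l in model$layers) cur <- plogis(sweep(cur %*% l$W, 2L, l$b, "+"))
  softmax(sweep(cur %*% model$out_layer$W, 2L, model$out_layer$b, "+"))
}

#' Predict classes and probabilities from a DBN classifier
#'
#' @param object A `dbn_classifier`.
#' @param features Numeric matrix of samples (rows).
#' @param ... Unused.
#' @return A tibble with `.pred_class` (0-based integer, the row-wise argmax)
#'   and one `.pred_<k>` probability column per class; rows sum to 1 and
#'   preserve input order.
#' @export
predict.dbn_classifier <- function(object, features, ...) {
  prob <- dbn_forward_probs(object, features)
  out <- tibble::tibble(.pred_class = max.col(prob, ties.method = "first") - 1L)
  for (k in seq_len(object$n_classes)) out[[paste0(".pred_", k - 1L)]] <- prob[, k]
  out
}

#' @export
print.dbn_classifier <- function(x, ...) {
  cat(sprintf("<dbn_classifier> %d -> %s -> %d classes\n",
              nrow(x$layers[[1L]]$W),
              paste(vapply(x$layers, function(l) ncol(l$W), integer(1)),
                    collapse = " -> "),
              x$n_classes))
  invisible(x)
}
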