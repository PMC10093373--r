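# Attention-CNN feature extractor.
#
# Architecture: a 1x1 convolution stem, four stages of residual bottleneck
# modules (1x1 reduce -> 3x3 context -> 1x1 expand, batch-normalized, with
# projection shortcuts at stage boundaries), global average pooling, and a
# fully connected head with dropout and a softmax output. The 3x3 convolution
# inside each module is replaced by a contextual-transformer (CoT) attention
# block unless `use_cot = FALSE` (ablation). With the default [2,2,2,2]
# module distribution the conventional module count is 26: the stem, plus
# 8 bottleneck modules of 3 convolutions each, plus the FC head.

#' Feature-extractor configuration
#'
#' @param stage_module_counts Integer vector of length 4: residual modules
#'   per stage (all >= 1; default `c(2, 2, 2, 2)`).
#' @param stage_channels Integer vector of length 4: output channels per
#'   stage (default `c(8, 16, 32, 64)`, a desk-scale width).
#' @param input_size Input image side in pixels (default 32; images are
#'   expected as `input_size` x `input_size` x 3).
#' @param n_classes Number of classes (>= 2).
#' @param feature_dim Width of the penultimate fully connected layer whose
#'   activations are exported as features (default 32).
#' @param use_cot Use CoT attention blocks in place of plain 3x3
#'   convolutions (default `TRUE`).
#' @return A `mafnet_config` list.
#' @export
mafnet_config <- function(stage_module_counts = c(2L, 2L, 2L, 2L),
                          stage_channels = c(8L, 16L, 32L, 64L),
                          input_size = 32L,
                          n_classes = 2L,
                          feature_dim = 32L,
                          use_cot = TRUE) {
  if (length(stage_module_counts) != 4L || any(stage_module_counts < 1)) {
    stop_invalid("`stage_module_counts` must be 4 integers >= 1")
  }
  if (length(stage_channels) != 4L || any(stage_channels < 1)) {
    stop_invalid("`stage_channels` must be 4 positive integers")
  }
  check_number(input_size, "input_size", min = 8, integer = TRUE)
  check_number(n_classes, "n_classes", min = 2, integer = TRUE)
  check_number(feature_dim, "feature_dim", min = 1, integer = TRUE)
  check_flag(use_cot, "use_cot")
  structure(list(stage_module_counts = as.integer(stage_module_counts),
                 stage_channels = as.integer(stage_channels),
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 feature_dim = as.integer(feature_dim),
                 use_cot = use_cot),
            class = "mafnet_config")
}

#' Conventional convolution-module count of a configuration
#'
#' Counts the stem, three convolutions per bottleneck module, and the FC
#' head as one module each (attention-internal and projection convolutions
#' are not counted). The default configuration gives 26.
#'
#' @param config A [mafnet_config()] or a built/trained network.
#' @return An integer module count.
#' @export
mafnet_module_count <- function(config) {
  if (inherits(config, "mafnet")) config <- config$config
  1L + 3L * sum(config$stage_module_counts) + 1L
}

cot_groups <- function(c) {
  if (c %% 4L == 0L) 4L else if (c %% 2L == 0L) 2L else 1L
}

cot_init <- function(channels, kernel = 3L) {
  g <- cot_groups(channels)
  list(key = conv_init(kernel, channels, channels, groups = g),
       key_bn = bn_init(channels),
       att1 = conv_init(1L, 2L * channels, channels),
       att2 = conv_init(1L, channels, channels),
       val = conv_init(1L, channels, channels))
}

cot_state_init <- function(channels) list(key_bn = bn_state_init(channels))

cot_forward_fm <- function(fm, p, state, kernel, training) {
  g <- cot_groups(ncol(fm$x))
  key <- conv_forward(fm, p$key, stride = 1L, groups = g)
  kbn <- bn_forward(key$out$x, p$key_bn, state$key_bn, training)
  state$key_bn <- kbn$state
  static <- kbn$out
  catx <- list(x = cbind(static, fm$x), h = fm$h, w = fm$w, n = fm$n)
  a1 <- conv_forward(catx, p$att1)
  a1r <- relu_forward(a1$out$x)
  a2 <- conv_forward(list(x = a1r$out, h = fm$h, w = fm$w, n = fm$n), p$att2)
  gate <- sigmoid_forward(a2$out$x)
  val <- conv_forward(fm, p$val)
  out <- static + gate$out * val$out$x
  list(out = list(x = out, h = fm$h, w = fm$w, n = fm$n),
       state = state,
       cache = list(key = key$cache, kbn = kbn$cache, a1 = a1$cache,
                    a1r = a1r$cache, a2 = a2$cache, gate = gate$cache,
                    val = val$cache, static = static, v = val$out$x,
                    c = ncol(fm$x)))
}

cot_backward_fm <- function(dout, cache, p) {
  cc <- cache$c
  dstatic <- dout
  dgate <- dout * cache$v
  dv <- dout * cache$gate
  bv <- conv_backward(dv, cache$val, p$val)
  da2 <- sigmoid_backward(dgate, cache$gate)
  b2 <- conv_backward(da2, cache$a2, p$att2)
  da1 <- relu_backward(b2$dx, cache$a1r)
  b1 <- conv_backward(da1, cache$a1, p$att1)
  dstatic <- dstatic + b1$dx[, seq_len(cc), drop = FALSE]
  dx_cat <- b1$dx[, cc + seq_len(cc), drop = FALSE]
  bkbn <- bn_backward(dstatic, cache$kbn, p$key_bn)
  bkey <- conv_backward(bkbn$dx, cache$key, p$key)
  list(dx = bkey$dx + dx_cat + bv$dx,
       dp = list(key = bkey$dp, key_bn = bkbn$dp, att1 = b1$dp,
                 att2 = b2$dp, val = bv$dp))
}

#' Contextual-transformer attention block
#'
#' Standalone application of one CoT block: a static context from a grouped
#' `kernel` x `kernel` convolution of the input, fused with a dynamic path in
#' which an attention map — computed from the concatenated static context and
#' input (the query) through two 1x1 convolutions — gates a 1x1 value
#' embedding. Output shape equals input shape.
#'
#' @param x An H x W x C array (one feature map).
#' @param kernel Odd integer >= 3 (default 3).
#' @param params Optional block parameters (as created internally); if
#'   `NULL`, fresh parameters are drawn from the current RNG state.
#' @return An H x W x C array, with the static-context path attached as
#'   attribute `"static"`.
#' @export
cot_block <- function(x, kernel = 3L, params = NULL) {
  check_number(kernel, "kernel", min = 3, integer = TRUE)
  if (kernel %% 2L == 0L) stop_invalid("`kernel` must be odd, got %d", kernel)
  d <- dim(x)
  if (length(d) != 3L || d[3L] < 1L) stop_invalid("`x` must be an H x W x C array")
  cc <- d[3L]
  if (is.null(params)) params <- cot_init(cc, kernel)
  fm <- list(x = matrix(x, d[1L] * d[2L], cc), h = d[1L], w = d[2L], n = 1L)
  res <- cot_forward_fm(fm, params, cot_state_init(cc), kernel, training = TRUE)
  out <- array(res$out$x, dim = d)
  attr(out, "static") <- array(res$cache$static, dim = d)
  out
}

module_meta <- function(cin, cout, stride, use_cot) {
  list(cin = cin, mid = max(1L, cout %/% 2L), cout = cout,
       stride = as.integer(stride), use_cot = use_cot,
       proj = (cin != cout || stride != 1L))
}

module_init <- function(m) {
  p <- list(conv1 = conv_init(1L, m$cin, m$mid),
            bn1 = bn_init(m$mid),
            inner = if (m$use_cot) cot_init(m$mid) else conv_init(3L, m$mid, m$mid),
            bn2 = bn_init(m$mid),
            conv3 = conv_init(1L, m$mid, m$cout),
            bn3 = bn_init(m$cout))
  if (m$proj) {
    p$proj <- conv_init(1L, m$cin, m$cout)
    p$proj_bn <- bn_init(m$cout)
  }
  p
}

module_state_init <- function(m) {
  s <- list(bn1 = bn_state_init(m$mid),
            inner = if (m$use_cot) cot_state_init(m$mid) else NULL,
            bn2 = bn_state_init(m$mid),
            bn3 = bn_state_init(m$cout))
  if (m$proj) s$proj_bn <- bn_state_init(m$cout)
  s
}

module_forward <- function(fm, p, s, m, training) {
  c1 <- conv_forward(fm, p$conv1, stride = m$stride)
  b1 <- bn_forward(c1$out$x, p$bn1, s$bn1, training); s$bn1 <- b1$state
  r1 <- relu_forward(b1$out)
  fm1 <- list(x = r1$out, h = c1$out$h, w = c1$out$w, n = c1$out$n)

  if (m$use_cot) {
    inner <- cot_forward_fm(fm1, p$inner, s$inner, 3L, training)
    s$inner <- inner$state
  } else {
    inner <- conv_forward(fm1, p$inner)
  }
  b2 <- bn_forward(inner$out$x, p$bn2, s$bn2, training); s$bn2 <- b2$state
  r2 <- relu_forward(b2$out)
  fm2 <- list(x = r2$out, h = fm1$h, w = fm1$w, n = fm1$n)

  c3 <- conv_forward(fm2, p$conv3)
  b3 <- bn_forward(c3$out$x, p$bn3, s$bn3, training); s$bn3 <- b3$state

  if (m$proj) {
    pr <- conv_forward(fm, p$proj, stride = m$stride)
    pb <- bn_forward(pr$out$x, p$proj_bn, s$proj_bn, training); s$proj_bn <- pb$state
    sc <- pb$out
  } else {
    pr <- NULL; pb <- NULL
    sc <- fm$x
  }
  ro <- relu_forward(b3$out + sc)
  list(out = list(x = ro$out, h = fm1$h, w = fm1$w, n = fm1$n),
       state = s,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache, fm1 = fm1,
                    inner = inner$cache, b2 = b2$cache, r2 = r2$cache,
                    c3 = c3$cache, b3 = b3$cache,
                    pr = if (m$proj) pr$cache, pb = if (m$proj) pb$cache,
                    ro = ro$cache))
}

module_backward <- function(dout, cache, p, m) {
  d <- relu_backward(dout, cache$ro)
  # shortcut branch
  if (m$proj) {
    bpb <- bn_backward(d, cache$pb, p$proj_bn)
    bpr <- conv_backward(bpb$dx, cache$pr, p$proj)
    dsc <- bpr$dx
  } else {
    dsc <- d
  }
  # main branch
  bb3 <- bn_backward(d, cache$b3, p$bn3)
  bc3 <- conv_backward(bb3$dx, cache$c3, p$conv3)
  dr2 <- relu_backward(bc3$dx, cache$r2)
  bb2 <- bn_backward(dr2, cache$b2, p$bn2)
  if (m$use_cot) {
    binner <- cot_backward_fm(bb2$dx, cache$inner, p$inner)
  } else {
    binner <- conv_backward(bb2$dx, cache$inner, p$inner)
  }
  dr1 <- relu_backward(binner$dx, cache$r1)
  bb1 <- bn_backward(dr1, cache$b1, p$bn1)
  bc1 <- conv_backward(bb1$dx, cache$c1, p$conv1)
  dx <- bc1$dx + dsc
  dp <- list(conv1 = bc1$dp, bn1 = bb1$dp, inner = binner$dp,
             bn2 = bb2$dp, conv3 = bc3$dp, bn3 = bb3$dp)
  if (m$proj) {
    dp$proj <- bpr$dp
    dp$proj_bn <- bpb$dp
  }
  list(dx = dx, dp = dp)
}

#' Build the attention-CNN feature extractor
#'
#' @param config A [mafnet_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `mafnet` object (untrained): parameters, batch-norm state,
#'   per-module metadata and the configuration.
#' @export
#' @examples
#' net <- build_mafnet(mafnet_config(n_classes = 3), seed = 1)
#' mafnet_module_count(net)
build_mafnet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mafnet_config"))
  metas <- list()
  cin <- config$stage_channels[1L]
  for (s in 1:4) {
    metas[[s]] <- list()
    for (mi in seq_len(config$stage_module_counts[s])) {
      stride <- if (s > 1L && mi == 1L) 2L else 1L
      metas[[s]][[mi]] <- module_meta(cin, config$stage_channels[s], stride,
                                      config$use_cot)
      cin <- config$stage_channels[s]
    }
  }
  params <- with_seed(seed, {
    p <- list(stem = conv_init(1L, 3L, config$stage_channels[1L]),
              stem_bn = bn_init(config$stage_channels[1L]),
              stages = lapply(metas, function(st) lapply(st, module_init)),
              fc1 = dense_init(config$stage_channels[4L], config$feature_dim),
              fc2 = dense_init(config$feature_dim, config$n_classes))
    p
  })
  state <- list(stem_bn = bn_state_init(config$stage_channels[1L]),
                stages = lapply(metas, function(st) lapply(st, module_state_init)))
  structure(list(config = config, meta = metas, params = params,
                 state = state, history = NULL, seed = as.integer(seed)),
            class = "mafnet")
}

check_image_batch <- function(net, images) {
  if (is_tibble(images)) images <- images$image
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  sz <- net$config$input_size
  ok <- vapply(images, function(im) identical(dim(im), c(sz, sz, 3L)), logical(1))
  if (!all(ok)) {
    stop_invalid("images must be %d x %d x 3 arrays matching the network input size",
                 sz, sz)
  }
  images
}

mafnet_forward <- function(net, images, training = FALSE, labels = NULL,
                           dropout = 0) {
  images <- check_image_batch(net, images)
  fm <- images_to_matrix(images)
  fm <- list(x = fm$x, h = fm$h, w = fm$w, n = fm$n)
  p <- net$params; s <- net$state
  caches <- list()

  st <- conv_forward(fm, p$stem)
  sb <- bn_forward(st$out$x, p$stem_bn, s$stem_bn, training); s$stem_bn <- sb$state
  sr <- relu_forward(sb$out)
  cur <- list(x = sr$out, h = st$out$h, w = st$out$w, n = st$out$n)
  caches$stem <- list(conv = st$cache, bn = sb$cache, relu = sr$cache)

  caches$stages <- list()
  for (si in 1:4) {
    caches$stages[[si]] <- list()
    for (mi in seq_along(net$meta[[si]])) {
      mf <- module_forward(cur, p$stages[[si]][[mi]], s$stages[[si]][[mi]],
                           net$meta[[si]][[mi]], training)
      s$stages[[si]][[mi]] <- mf$state
      caches$stages[[si]][[mi]] <- mf$cache
      cur <- mf$out
    }
  }

  gp <- gap_forward(cur)
  f1 <- dense_forward(gp$out, p$fc1)
  fr <- relu_forward(f1$out)
  features <- fr$out
  dr <- dropout_forward(features, dropout, training)
  f2 <- dense_forward(dr$out, p$fc2)
  prob <- softmax(f2$out)
  caches$head <- list(gap = gp$cache, f1 = f1$cache, fr = fr$cache,
                      dr = dr$cache, f2 = f2$cache,
                      shape = list(h = cur$h, w = cur$w, n = cur$n))
  out <- list(prob = prob, features = features, state = s)
  if (!is.null(labels)) {
    out$loss <- cross_entropy_loss(onehot_matrix(labels, net$config$n_classes), prob)
  }
  if (training) out$caches <- caches
  out
}

mafnet_backward <- function(net, fwd, labels) {
  p <- net$params
  caches <- fwd$caches
  dlogits <- softmax_ce_backward(fwd$prob, labels)
  bf2 <- dense_backward(dlogits, caches$head$f2, p$fc2)
  ddr <- dropout_backward(bf2$dx, caches$head$dr)
  dfr <- relu_backward(ddr, caches$head$fr)
  bf1 <- dense_backward(dfr, caches$head$f1, p$fc1)
  dgap <- gap_backward(bf1$dx, caches$head$gap)

  grads <- list(fc1 = bf1$dp, fc2 = bf2$dp)
  d <- dgap
  gstages <- vector("list", 4L)
  for (si in 4:1) {
    nm <- length(net$meta[[si]])
    gstages[[si]] <- vector("list", nm)
    for (mi in nm:1) {
      mb <- module_backward(d, caches$stages[[si]][[mi]],
                            p$stages[[si]][[mi]], net$meta[[si]][[mi]])
      gstages[[si]][[mi]] <- mb$dp
      d <- mb$dx
    }
  }
  grads$stages <- gstages
  dsr <- relu_backward(d, caches$stem$relu)
  bsb <- bn_backward(dsr, caches$stem$bn, p$stem_bn)
  bst <- conv_backward(bsb$dx, caches$stem$conv, p$stem)
  grads$stem <- bst$dp
  grads$stem_bn <- bsb$dp
  # order grads like params so nested_map2 lines up
  list(stem = grads$stem, stem_bn = grads$stem_bn, stages = grads$stages,
       fc1 = grads$fc1, fc2 = grads$fc2)
}

#' Training settings for the feature extractor
#'
#' Defaults follow the reference operating point: initial learning rate 0.01,
#' dropout 0.5, batch size 5, 50 epochs. The learning rate follows
#' [lr_schedule()] (divided by 10 every 30 epochs).
#'
#' @param lr0 Initial learning rate (> 0).
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Number of epochs (>= 1).
#' @param dropout Dropout rate on the penultimate features, in \[0, 1).
#' @param seed Integer seed controlling shuffling, dropout and any
#'   initialization performed during training.
#' @return A `train_settings` list.
#' @export
train_settings <- function(lr0 = 0.01, batch_size = 5L, epochs = 50L,
                           dropout = 0.5, seed = 1L) {
  check_number(lr0, "lr0", min = 1e-300)
  check_number(batch_size, "batch_size", min = 1, integer = TRUE)
  check_number(epochs, "epochs", min = 1, integer = TRUE)
  check_number(dropout, "dropout", min = 0, max = 1 - 1e-9)
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_settings")
}

# reset all batch-norm running statistics (count 0 => next training-mode
# batch assigns its statistics directly)
reset_bn_states <- function(state) {
  if (is.list(state)) {
    if (!is.null(state$count)) return(bn_state_init(length(state$mean)))
    return(lapply(state, reset_bn_states))
  }
  state
}

# recompute batch-norm statistics with one full-batch forward pass over the
# training images; small-batch training leaves the running averages far from
# the final weights' activation statistics, which would corrupt eval-mode
# inference
refresh_bn_stats <- function(net, images, max_images = 256L) {
  if (length(images) > max_images) {
    images <- images[sample.int(length(images), max_images)]
  }
  net$state <- reset_bn_states(net$state)
  fwd <- mafnet_forward(net, images, training = TRUE, dropout = 0)
  net$state <- fwd$state
  net
}

# global gradient-norm clipping keeps large learning rates stable in the
# deep configuration; the clip threshold is generous and rarely active at
# the reference rate 0.01
clip_grads <- function(grads, max_norm = 5) {
  sq <- 0
  walk_sq <- function(g) {
    if (is.list(g)) return(invisible(lapply(g, walk_sq)))
    sq <<- sq + sum(g * g)
    invisible(NULL)
  }
  walk_sq(grads)
  nrm <- sqrt(sq)
  if (nrm <= max_norm) return(grads)
  nested_map(grads, function(g) g * (max_norm / nrm))
}

sgd_update <- function(params, grads, velocity, lr, momentum = 0.9) {
  if (is.null(velocity)) velocity <- nested_map(grads, function(g) g * 0)
  velocity <- nested_map2(velocity, grads, function(v, g) momentum * v - lr * g)
  params <- nested_map2(params, velocity, function(p, v) p + v)
  list(params = params, velocity = velocity)
}

#' Train the feature extractor
#'
#' Minimizes the batch cross-entropy with momentum SGD (momentum 0.9) under
#' the step-decay schedule of [lr_schedule()]. Training is deterministic
#' given `settings$seed` (single-threaded).
#'
#' @param net A `mafnet` from [build_mafnet()].
#' @param dataset A dataset tibble (columns `image`, `label`) or a list with
#'   elements `images` and `labels` (0-based).
#' @param settings A [train_settings()].
#' @return The trained `mafnet`; `$history` is a tibble with one row per
#'   epoch (`epoch`, `loss`, `lr`, `accuracy` on the training batch stream).
#' @export
train_mafnet <- function(net, dataset, settings = train_settings()) {
  stopifnot(inherits(net, "mafnet"), inherits(settings, "train_settings"))
  if (is_tibble(dataset)) {
    images <- dataset$image; labels <- dataset$label
  } else {
    images <- dataset$images; labels <- dataset$labels
  }
  if (length(images) == 0L) stop_invalid("`dataset` is empty")
  if (any(labels < 0 | labels >= net$config$n_classes)) {
    stop_invalid("labels must be in [0, %d)", net$config$n_classes)
  }
  images <- check_image_batch(net, images)
  n <- length(images)
  velocity <- NULL
  hist <- vector("list", settings$epochs)
  net <- with_seed(settings$seed, {
    for (epoch in seq_len(settings$epochs) - 1L) {
      lr <- lr_schedule(settings$lr0, epoch)
      ord <- sample.int(n)
      losses <- c(); hits <- 0L
      for (b in seq_len(ceiling(n / settings$batch_size))) {
        take <- ord[((b - 1L) * settings$batch_size + 1L):min(b * settings$batch_size, n)]
        fwd <- mafnet_forward(net, images[take], training = TRUE,
                              labels = labels[take], dropout = settings$dropout)
        net$state <- fwd$state
        grads <- clip_grads(mafnet_backward(net, fwd, labels[take]))
        up <- sgd_update(net$params, grads, velocity, lr)
        net$params <- up$params
        velocity <- up$velocity
        losses <- c(losses, fwd$loss)
        hits <- hits + sum(max.col(fwd$prob) - 1L == labels[take])
      }
      hist[[epoch + 1L]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                           lr = lr, accuracy = hits / n)
    }
    refresh_bn_stats(net, images)
  })
  net$history <- dplyr::bind_rows(hist)
  net$trained <- TRUE
  net
}

#' Extract penultimate-layer features
#'
#' Evaluation-mode forward pass returning the penultimate fully connected
#' activations, one row per input image in input order.
#'
#' @param net A (trained or initialized) `mafnet`.
#' @param images A dataset tibble, a list of image arrays, or one array.
#' @return An `n x feature_dim` numeric matrix.
#' @export
extract_features <- function(net, images) {
  fwd <- mafnet_forward(net, images, training = FALSE)
  fwd$features
}

#' @export
print.mafnet <- function(x, ...) {
  cat(sprintf(
    "<mafnet> %s, %d conv modules, %d parameters, input %dx%dx3, %d classes\n",
    if (x$config$use_cot) "CoT attention" else "plain 3x3 conv",
    mafnet_module_count(x), nested_length(x$params),
    x$config$input_size, x$config$input_size, x$config$n_classes))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                nrow(x$history), tail(x$history$loss, 1)))
  }
  invisible(x)
}
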