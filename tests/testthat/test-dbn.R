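test_that("RBM energy is the literal bilinear form", {
  p0 <- rbm_params(2, 2, W = matrix(0, 2, 2))
  expect_equal(rbm_energy(c(0, 0), c(0, 0), p0), 0)
  # zero parameters: every configuration has zero energy
  for (v in list(c(0, 0), c(1, 0), c(1, 1))) {
    for (h in list(c(0, 0), c(0, 1), c(1, 1))) {
      expect_equal(rbm_energy(v, h, p0), 0)
    }
  }
  # hand-set 2x2 parameters against a scalar sum
  W <- matrix(c(0.5, -1, 2, 0.25), 2, 2)
  a <- c(0.1, -0.2); b <- c(0.3, 0.4)
  p <- rbm_params(2, 2, W = W, a = a, b = b)
  v <- c(1, 1); h <- c(1, 0)
  hand <- -(a[1] + a[2]) - b[1] - (W[1, 1] + W[2, 1])
  expect_equal(rbm_energy(v, h, p), hand, tolerance = 1e-15)

  # energy is linear: doubling all parameters doubles the energy
  p2 <- rbm_params(2, 2, W = 2 * W, a = 2 * a, b = 2 * b)
  expect_equal(rbm_energy(v, h, p2), 2 * rbm_energy(v, h, p), tolerance = 1e-15)

  expect_error(rbm_energy(c(0.5, 0), c(0, 0), p),
               class = "dermhgso_invalid_argument")
  expect_error(rbm_energy(c(0, 0, 0), c(0, 0), p),
               class = "dermhgso_invalid_argument")
})

test_that("partition function enumerates exactly", {
  # zero parameters: every state contributes exp(0)
  expect_equal(partition_function(rbm_params(2, 2, W = matrix(0, 2, 2))), 16)
  # n = m = 1, w = ln 2: states contribute 1 + 1 + 1 + 2
  expect_equal(partition_function(rbm_params(1, 1, W = matrix(log(2), 1, 1))), 5)
  expect_error(partition_function(rbm_params(12, 12, seed = 1)),
               class = "dermhgso_size_error")
})

test_that("joint probabilities normalize for random enumerable RBMs", {
  set.seed(10)
  for (rep in 1:5) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    p <- rbm_params(n, m, W = matrix(rnorm(n * m), n, m),
                    a = rnorm(n), b = rnorm(m))
    z <- partition_function(p)
    total <- 0
    for (vi in 0:(2^n - 1)) {
      v <- as.integer(intToBits(vi))[seq_len(n)]
      for (hi in 0:(2^m - 1)) {
        h <- as.integer(intToBits(hi))[seq_len(m)]
        total <- total + exp(-rbm_energy(v, h, p)) / z
      }
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("logistic conditionals equal enumeration-derived conditionals", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    p <- rbm_params(n, m, W = matrix(rnorm(n * m), n, m),
                    a = rnorm(n), b = rnorm(m))
    v <- sample(0:1, n, replace = TRUE)
    # exact conditional p(h_j = 1 | v) from the joint
    joint <- vapply(0:(2^m - 1), function(hi) {
      h <- as.integer(intToBits(hi))[seq_len(m)]
      exp(-rbm_energy(v, h, p))
    }, numeric(1))
    hmat <- t(vapply(0:(2^m - 1), function(hi) {
      as.integer(intToBits(hi))[seq_len(m)]
    }, integer(m)))
    exact <- colSums(hmat * joint) / sum(joint)
    expect_equal(conditional_hidden(v, p), exact, tolerance = 1e-10)

    # mirror direction via the transposed model
    h <- sample(0:1, m, replace = TRUE)
    pt <- rbm_params(m, n, W = t(p$W), a = p$b, b = p$a)
    expect_equal(conditional_visible(h, p), conditional_hidden(h, pt),
                 tolerance = 1e-12)
  }
  # zero parameters: all conditionals are 1/2, monotone in the bias
  p0 <- rbm_params(3, 2, W = matrix(0, 3, 2))
  expect_equal(conditional_hidden(c(1, 0, 1), p0), rep(0.5, 2))
  pb <- rbm_params(3, 2, W = matrix(0, 3, 2), b = c(10, -10))
  ph <- conditional_hidden(c(0, 0, 0), pb)
  expect_gt(ph[1], 0.99); expect_lt(ph[2], 0.01)
  expect_error(conditional_hidden(c(1, 0), p0),
               class = "dermhgso_invalid_argument")
})

test_that("contrastive divergence reduces reconstruction error on patterns", {
  pats <- matrix(rep(c(1, 1, 0, 0, 1, 0,
                       0, 0, 1, 1, 0, 1), 10), ncol = 6, byrow = TRUE)
  drops <- vapply(1:5, function(seed) {
    p <- train_rbm_cd(pats, n_hidden = 4, lr = 0.2, epochs = 25,
                      batch_size = 8, seed = seed)
    h <- attr(p, "history")$reconstruction_error
    mean(head(h, 3)) - mean(tail(h, 3))
  }, numeric(1))
  expect_gte(sum(drops > 0), 4)

  # zero learning rate leaves the parameters untouched
  init <- rbm_params(6, 4, seed = 42)
  p0 <- train_rbm_cd(pats, 4, lr = 0, epochs = 3, seed = 1, params = init)
  expect_equal(p0$W, init$W)
  expect_equal(p0$a, init$a)
  expect_equal(p0$b, init$b)

  # seeded reproducibility
  pa <- train_rbm_cd(pats, 4, lr = 0.2, epochs = 5, seed = 9)
  pb <- train_rbm_cd(pats, 4, lr = 0.2, epochs = 5, seed = 9)
  expect_identical(pa$W, pb$W)
  expect_error(train_rbm_cd(pats * 2, 4), class = "dermhgso_invalid_argument")
  expect_error(train_rbm_cd(matrix(numeric(0), 0, 3), 4),
               class = "dermhgso_invalid_argument")
})

test_that("stacked DBN shapes, determinism and separable-feature accuracy", {
  set.seed(12)
  n <- 40
  centers <- matrix(c(0, 0, 0, 3, 3, 3), 2, 3, byrow = TRUE)
  feats <- rbind(
    sweep(matrix(rnorm(n * 3, 0, 0.4), n, 3), 2, centers[1, ], "+"),
    sweep(matrix(rnorm(n * 3, 0, 0.4), n, 3), 2, centers[2, ], "+"))
  labels <- rep(0:1, each = n)
  cfg <- dbn_config(layer_sizes = c(8, 8, 8), rbm_epochs = 10,
                    finetune_epochs = 60, seed = 5)
  model <- stack_dbn(feats, labels, cfg)

  # propagated representation widths match the configured layer sizes
  expect_equal(vapply(model$layers, function(l) ncol(l$W), integer(1)),
               c(8L, 8L, 8L))
  expect_equal(nrow(model$layers[[1]]$W), 3L)

  model2 <- stack_dbn(feats, labels, cfg)
  expect_identical(model$layers, model2$layers)
  expect_identical(model$out_layer, model2$out_layer)

  # held-out accuracy on fresh draws from the same clusters
  set.seed(13)
  fresh <- rbind(
    sweep(matrix(rnorm(20 * 3, 0, 0.4), 20, 3), 2, centers[1, ], "+"),
    sweep(matrix(rnorm(20 * 3, 0, 0.4), 20, 3), 2, centers[2, ], "+"))
  pred <- predict(model, fresh)
  expect_gte(mean(pred$.pred_class == rep(0:1, each = 20)), 0.9)

  expect_error(stack_dbn(feats, labels[-1], cfg),
               class = "dermhgso_invalid_argument")
})

test_that("default hidden widths are capped at four times the feature width", {
  set.seed(14)
  feats <- matrix(runif(30 * 4), 30, 4)
  labels <- rep(0:1, 15)
  model <- stack_dbn(feats, labels,
                     dbn_config(rbm_epochs = 2, finetune_epochs = 2, seed = 1))
  widths <- vapply(model$layers, function(l) ncol(l$W), integer(1))
  expect_true(all(widths <= 16L))
  expect_equal(length(widths), 3L)
})

test_that("prediction matches a by-hand forward pass and preserves order", {
  # one hidden layer, hand-set weights
  model <- structure(list(
    layers = list(list(W = matrix(c(1, -1, 0.5, 2), 2, 2), b = c(0.1, -0.1))),
    out_layer = list(W = matrix(c(1, 0, -1, 1), 2, 2), b = c(0, 0.2)),
    scale = list(lo = c(0, 0), hi = c(1, 1)),
    n_classes = 2L), class = "dbn_classifier")
  x <- matrix(c(0.2, 0.8,
                0.2, 0.8,
                0.9, 0.1), 3, 2, byrow = TRUE)
  pred <- predict(model, x)
  h <- plogis(c(0.2 * 1 + 0.8 * (-1) + 0.1, 0.2 * 0.5 + 0.8 * 2 - 0.1))
  logits <- c(h[1] * 1 + h[2] * 0, h[1] * (-1) + h[2] * 1 + 0.2)
  pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
  expect_equal(unlist(pred[1, c(".pred_0", ".pred_1")], use.names = FALSE),
               pr, tolerance = 1e-12)
  # duplicated row predicts identically; rows sum to 1
  expect_equal(pred[1, ], pred[2, ])
  expect_equal(pred$.pred_0 + pred$.pred_1, rep(1, 3), tolerance = 1e-12)
  expect_error(predict(model, matrix(0.5, 2, 3)),
               class = "dermhgso_invalid_argument")
})
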