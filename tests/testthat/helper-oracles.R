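# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (scalar loops, literal formulas) and share no
# code with the implementation under test.

# reflect index k into 1..n without repeating the edge pixel
.refl <- function(k, n) {
  while (k < 1L || k > n) {
    if (k < 1L) k <- 2L - k
    if (k > n) k <- 2L * n - k
  }
  k
}

.border_pixel <- function(img, i, j, border) {
  h <- nrow(img); w <- ncol(img)
  if (border == "reflect") {
    img[.refl(i, h), .refl(j, w)]
  } else {
    if (i < 1L || i > h || j < 1L || j > w) 0 else img[i, j]
  }
}

naive_local_stats <- function(img, window, border) {
  p <- (window - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  mu <- matrix(0, h, w); va <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- numeric(0)
      for (di in -p:p) {
        for (dj in -p:p) {
          vals <- c(vals, .border_pixel(img, i + di, j + dj, border))
        }
      }
      mu[i, j] <- mean(vals)
      va[i, j] <- mean(vals^2) - mean(vals)^2
    }
  }
  va[va < 0] <- 0
  list(mean = mu, variance = va)
}

# literal per-pixel application of the shrinkage rule
naive_wiener <- function(img, window, sigma2, border) {
  st <- naive_local_stats(img, window, border)
  if (identical(sigma2, "auto")) sigma2 <- mean(st$variance)
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      lv <- st$variance[i, j]
      out[i, j] <- if (sigma2 == 0) {
        img[i, j]
      } else if (lv <= sigma2) {
        st$mean[i, j]
      } else {
        img[i, j] - (sigma2 / lv) * (img[i, j] - st$mean[i, j])
      }
    }
  }
  out
}

# scalar-loop one-vs-rest metrics from a confusion matrix
naive_metrics <- function(cm) {
  k <- nrow(cm)
  total <- sum(cm)
  out <- NULL
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    acc <- if (total == 0) 0 else (tp + tn) / total
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    out <- rbind(out, c(acc, sens, spec, f1, mcc))
  }
  colnames(out) <- c("accuracy", "sensitivity", "specificity", "fscore", "mcc")
  out
}

# equal-budget uniform random search baseline (minimization)
random_search <- function(objective, lower, upper, n_evals) {
  best <- Inf
  d <- length(lower)
  for (i in seq_len(n_evals)) {
    x <- lower + runif(d) * (upper - lower)
    f <- objective(x)
    if (f < best) best <- f
  }
  best
}

# small lesion dataset at a given extractor scale
tiny_lesion_data <- function(n_per_class, n_classes, size = 16, noise = 0.05,
                             seed = 1) {
  generate_lesion_dataset(rep(n_per_class, n_classes), image_size = size,
                          noise_sigma = noise, seed = seed)
}

tiny_mafnet_config <- function(n_classes, size = 16, use_cot = TRUE) {
  mafnet_config(stage_module_counts = c(1, 1, 1, 1),
                stage_channels = c(4, 8, 8, 8),
                input_size = size, n_classes = n_classes,
                feature_dim = 8, use_cot = use_cot)
}

# classic 2-D test functions
sphere_fn <- function(x) sum(x^2)
rosenbrock_fn <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
rastrigin_fn <- function(x) 20 + sum(x^2 - 10 * cos(2 * pi * x))
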