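test_that("class prototypes are deterministic, distinct and colour-spaced", {
  p1 <- lesion_prototypes(3, seed = 42)
  p2 <- lesion_prototypes(3, seed = 42)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 3L)

  # pairwise max-channel colour distance >= 0.2 for every class count and
  # several seeds
  for (k in 2:7) {
    for (seed in c(0, 1, 7)) {
      pr <- lesion_prototypes(k, seed = seed)
      cols <- do.call(rbind, pr$lesion_color)
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          expect_gte(max(abs(cols[i, ] - cols[j, ])), 0.2)
        }
      }
      # shape parameters pairwise distinct
      expect_equal(anyDuplicated(pr$asymmetry), 0L)
      expect_equal(anyDuplicated(pr$border_irregularity), 0L)
    }
  }
  expect_error(lesion_prototypes(8, 0), class = "dermhgso_invalid_argument")
  expect_error(lesion_prototypes(1, 0), class = "dermhgso_invalid_argument")
})

test_that("rendering is deterministic, bounded and degenerate-safe", {
  proto <- lesion_prototypes(2, seed = 1)[1, ]

  set.seed(99); img1 <- render_lesion(proto, 32, noise_sigma = 0)
  set.seed(99); img2 <- render_lesion(proto, 32, noise_sigma = 0)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(32L, 32L, 3L))
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_identical(attr(img1, "label"), proto$class_id)

  # background == lesion colour and zero noise gives a constant image
  flat <- list(class_id = 0L, asymmetry = 0.5, border_irregularity = 0.5,
               lesion_color = c(0.4, 0.4, 0.4), background_color = c(0.4, 0.4, 0.4),
               scale = 0.5)
  set.seed(1)
  cimg <- render_lesion(flat, 32, 0)
  expect_equal(max(cimg) - min(cimg), 0)

  expect_error(render_lesion(proto, 32, noise_sigma = -0.1),
               class = "dermhgso_invalid_argument")
  expect_error(render_lesion(proto, 8), class = "dermhgso_invalid_argument")
})

test_that("lesion occupies between 5% and 60% of the image", {
  for (seed in 1:4) {
    pr <- lesion_prototypes(4, seed = seed)
    for (i in seq_len(4)) {
      spec <- as.list(pr[i, ])
      spec$lesion_color <- c(0, 0, 0)
      spec$background_color <- c(1, 1, 1)
      spec$lesion_color <- list(spec$lesion_color)[[1]]
      set.seed(seed * 10 + i)
      img <- render_lesion(list(class_id = 0L, asymmetry = pr$asymmetry[i],
                                border_irregularity = pr$border_irregularity[i],
                                lesion_color = c(0, 0, 0),
                                background_color = c(1, 1, 1),
                                scale = pr$scale[i]), 64, 0)
      frac <- mean(img[, , 1] < 0.5)
      expect_gt(frac, 0.05)
      expect_lt(frac, 0.60)
    }
  }
})

test_that("additive noise magnitude follows the folded-normal law", {
  # mean |noisy - clean| for N(0, sigma) noise is sigma * sqrt(2/pi); colours
  # are mid-range so [0,1] clipping is negligible at 5 sigma
  spec <- list(class_id = 0L, asymmetry = 0.3, border_irregularity = 0.3,
               lesion_color = c(0.45, 0.5, 0.55),
               background_color = c(0.55, 0.5, 0.45), scale = 0.5)
  sigma <- 0.1
  set.seed(7); clean <- render_lesion(spec, 128, 0)
  set.seed(7); noisy <- render_lesion(spec, 128, sigma)
  d <- abs(noisy - clean)
  n <- length(d)  # 128*128*3 pixels
  expected <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("dataset generation conserves counts and is seed-reproducible", {
  d1 <- generate_lesion_dataset(c(5, 5), image_size = 16, seed = 3)
  d2 <- generate_lesion_dataset(c(5, 5), image_size = 16, seed = 3)
  expect_identical(d1$image, d2$image)
  expect_identical(d1$label, d2$label)

  d3 <- generate_lesion_dataset(c(50, 50, 50), image_size = 16, seed = 1)
  d4 <- generate_lesion_dataset(c(50, 50, 50), image_size = 16, seed = 2)
  expect_equal(as.integer(table(d3$label)), c(50L, 50L, 50L))
  expect_equal(as.integer(table(d4$label)), c(50L, 50L, 50L))
  expect_false(identical(d3$image[[1]], d4$image[[1]]))

  # archive-shaped class inventory: counts come out exactly as configured
  big <- generate_lesion_dataset(c(374, 254, 1372), image_size = 16,
                                 noise_sigma = 0, seed = 5)
  expect_equal(nrow(big), 2000L)
  expect_equal(as.integer(table(big$label)), c(374L, 254L, 1372L))

  expect_error(generate_lesion_dataset(c(5, 0), seed = 1),
               class = "dermhgso_invalid_argument")
  expect_error(generate_lesion_dataset(c(5, 5), n_classes = 3, seed = 1),
               class = "dermhgso_invalid_argument")
})

test_that("PNG + manifest round trip preserves labels and quantized pixels", {
  ds <- generate_lesion_dataset(c(3, 3), image_size = 16, noise_sigma = 0.05,
                                seed = 9)
  dir <- withr::local_tempdir()
  write_lesion_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_lesion_dataset(dir)
  expect_equal(back$label, ds$label)
  expect_equal(back$filename, ds$filename)
  for (i in seq_len(nrow(ds))) {
    expect_lt(max(abs(back$image[[i]] - ds$image[[i]])), 0.5 / 255 + 1e-12)
  }
  expect_error(read_lesion_dataset(file.path(dir, "missing")),
               class = "dermhgso_invalid_argument")
})

test_that("noiseless classes are separable by nearest centroid on mean RGB", {
  ds <- generate_lesion_dataset(c(15, 15, 15), image_size = 32,
                                noise_sigma = 0, seed = 4)
  feats <- t(vapply(ds$image, function(im) apply(im, 3, mean), numeric(3)))
  cents <- do.call(rbind, lapply(sort(unique(ds$label)), function(k) {
    colMeans(feats[ds$label == k, , drop = FALSE])
  }))
  pred <- apply(feats, 1, function(f) {
    which.min(colSums((t(cents) - f)^2)) - 1L
  })
  expect_gte(mean(pred == ds$label), 0.99)
})
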