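# Synthetic dermoscopy-style lesion images.
#
# Classes are encoded by shape asymmetry, border irregularity and lesion
# colour, the morphological cues a dermatologist reads. Images are noisy
# perturbed-ellipse lesions on a skin-toned background; additive Gaussian
# pixel noise exercises the Wiener denoising stage.

# Fixed palette of 7 lesion colours with pairwise max-channel distance
# >= 0.25, so that +/-0.02 jitter keeps any pair >= 0.2 apart.
LESION_PALETTE <- list(
  c(0.25, 0.15, 0.10),  # dark brown
  c(0.70, 0.35, 0.25),  # reddish
  c(0.35, 0.45, 0.70),  # blue-grey
  c(0.75, 0.65, 0.30),  # yellowish
  c(0.15, 0.40, 0.30),  # dark olive
  c(0.55, 0.20, 0.50),  # violet
  c(0.85, 0.80, 0.75)   # pale
)

SKIN_TONE <- c(0.87, 0.67, 0.55)

#' Class prototypes for synthetic lesions
#'
#' Builds `n_classes` lesion prototypes with pairwise-distinct colour and
#' shape parameters. Colours are drawn from a fixed well-separated palette
#' (pairwise max-channel distance at least 0.2 after jitter); asymmetry and
#' border irregularity are spread over \[0.15, 0.85\] in opposite orders so
#' every pair of classes differs in at least two cues.
#'
#' @param n_classes Number of classes, between 2 and 7.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A tibble with one row per class: `class_id` (0-based), `asymmetry`,
#'   `border_irregularity`, `scale`, and list-columns `lesion_color`,
#'   `background_color` (RGB triples in \[0,1\]).
#' @export
#' @examples
#' lesion_prototypes(3, seed = 42)
lesion_prototypes <- function(n_classes, seed = 1L) {
  check_number(n_classes, "n_classes", min = 2, max = 7, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  k <- as.integer(n_classes)
  with_seed(seed, {
    jit <- function(n, a) runif(n, -a, a)
    asym <- seq(0.15, 0.85, length.out = k) + jit(k, 0.03)
    irr  <- seq(0.85, 0.15, length.out = k) + jit(k, 0.03)
    cols <- lapply(seq_len(k), function(i) {
      pmin(1, pmax(0, LESION_PALETTE[[i]] + jit(3, 0.02)))
    })
    bgs <- lapply(seq_len(k), function(i) {
      pmin(1, pmax(0, SKIN_TONE + jit(3, 0.02)))
    })
    tibble::tibble(
      class_id = seq_len(k) - 1L,
      asymmetry = pmin(1, pmax(0, asym)),
      border_irregularity = pmin(1, pmax(0, irr)),
      lesion_color = cols,
      background_color = bgs,
      scale = runif(k, 0.42, 0.55)
    )
  })
}

as_lesion_spec <- function(spec) {
  if (is_tibble(spec)) {
    stopifnot(nrow(spec) == 1L)
    spec <- as.list(spec)
    spec$lesion_color <- spec$lesion_color[[1L]]
    spec$background_color <- spec$background_color[[1L]]
  }
  need <- c("class_id", "asymmetry", "border_irregularity",
            "lesion_color", "background_color", "scale")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop_invalid("lesion spec missing fields: %s",
                                 paste(miss, collapse = ", "))
  check_number(spec$asymmetry, "asymmetry", 0, 1)
  check_number(spec$border_irregularity, "border_irregularity", 0, 1)
  check_number(spec$scale, "scale", min = 1e-6, max = 1 - 1e-6)
  spec
}

#' Render one synthetic lesion image
#'
#' Draws a perturbed ellipse (axis ratio set by `asymmetry`, sinusoidal
#' boundary perturbation with amplitude set by `border_irregularity`) on a
#' skin-toned background, then adds clipped Gaussian pixel noise. Per-image
#' nuisance (centre jitter, rotation, perturbation phase) and the noise are
#' drawn from the current RNG state, so rendering is reproducible under
#' [withr::with_seed()] or `set.seed()`.
#'
#' @param spec A one-row tibble from [lesion_prototypes()], or an equivalent
#'   named list.
#' @param image_size Side of the square image in pixels (>= 16).
#' @param noise_sigma Standard deviation of the additive Gaussian pixel noise
#'   (intensity units, >= 0). Pixels are clipped to \[0,1\] after adding noise.
#' @return An `image_size` x `image_size` x 3 array in \[0,1\] with attribute
#'   `label` equal to `spec$class_id`.
#' @export
render_lesion <- function(spec, image_size = 64L, noise_sigma = 0) {
  spec <- as_lesion_spec(spec)
  check_number(image_size, "image_size", min = 16, integer = TRUE)
  check_number(noise_sigma, "noise_sigma", min = 0)
  s <- as.integer(image_size)

  cx <- 0.5 + runif(1, -0.05, 0.05)
  cy <- 0.5 + runif(1, -0.05, 0.05)
  rot <- runif(1, 0, 2 * pi)
  phase <- runif(1, 0, 2 * pi)
  freq <- sample(4:7, 1L)

  # normalized pixel coordinates
  g <- (seq_len(s) - 0.5) / s
  xg <- matrix(g, s, s, byrow = TRUE) - cx   # x varies along columns
  yg <- matrix(g, s, s) - cy                 # y varies along rows
  xr <- cos(rot) * xg + sin(rot) * yg
  yr <- -sin(rot) * xg + cos(rot) * yg

  r1 <- spec$scale / 2
  r2 <- r1 * (1 - 0.55 * spec$asymmetry)
  u <- xr / r1
  v <- yr / r2
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  boundary <- 1 + 0.25 * spec$border_irregularity * sin(freq * theta + phase)
  # soft one-pixel edge
  edge <- 1.5 / (s * min(r1, r2))
  alpha <- pmin(1, pmax(0, (boundary - rho) / edge + 0.5))

  img <- array(0, dim = c(s, s, 3L))
  for (ch in 1:3) {
    img[, , ch] <- spec$background_color[ch] +
      alpha * (spec$lesion_color[ch] - spec$background_color[ch])
  }
  if (noise_sigma > 0) {
    img <- img + rnorm(length(img), 0, noise_sigma)
    img <- pmin(pmax(img, 0), 1)  # argument order keeps the dim attribute
  }
  attr(img, "label") <- as.integer(spec$class_id)
  img
}

#' Generate a labelled synthetic lesion dataset
#'
#' @param n_per_class Integer vector of per-class sample counts (all >= 1).
#' @param n_classes Number of classes; defaults to `length(n_per_class)`.
#' @param image_size Square image side in pixels (default 64).
#' @param noise_sigma Gaussian pixel-noise standard deviation (default 0.05,
#'   a mild corruption the Wiener stage can act on).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A tibble with columns `id`, `filename`, `label` (0-based integer)
#'   and list-column `image` (H x W x 3 arrays in \[0,1\]); the prototype
#'   table is attached as attribute `"prototypes"`.
#' @export
#' @examples
#' ds <- generate_lesion_dataset(c(5, 5), seed = 7)
#' table(ds$label)
generate_lesion_dataset <- function(n_per_class,
                                    n_classes = length(n_per_class),
                                    image_size = 64L,
                                    noise_sigma = 0.05,
                                    seed = 1L) {
  if (length(n_per_class) != n_classes) {
    stop_invalid("`n_per_class` must have length `n_classes` (%d)", n_classes)
  }
  if (any(n_per_class < 1 | n_per_class != round(n_per_class))) {
    stop_invalid("all `n_per_class` entries must be integers >= 1")
  }
  protos <- lesion_prototypes(n_classes, seed = derive_seed(seed, 1L))
  n_total <- sum(n_per_class)
  labels <- rep(protos$class_id, times = n_per_class)
  images <- with_seed(derive_seed(seed, 2L), {
    lapply(labels, function(lab) {
      render_lesion(protos[protos$class_id == lab, ],
                    image_size = image_size, noise_sigma = noise_sigma)
    })
  })
  ds <- tibble::tibble(
    id = sprintf("img_%05d", seq_len(n_total)),
    filename = sprintf("img_%05d.png", seq_len(n_total)),
    label = as.integer(labels),
    image = images
  )
  attr(ds, "prototypes") <- protos
  attr(ds, "noise_sigma") <- noise_sigma
  ds
}

#' Extract the `filename,label` manifest of a dataset
#' @param dataset A dataset tibble from [generate_lesion_dataset()] or
#'   [read_lesion_dataset()].
#' @return A tibble with columns `filename` and `label`.
#' @export
dataset_manifest <- function(dataset) {
  dplyr::select(as_tibble(dataset), "filename", "label")
}

#' Write a dataset to disk as 8-bit PNGs plus a CSV manifest
#'
#' Pixel intensities are quantized to 8 bits by scaling with 255 and rounding
#' half to even before writing.
#'
#' @inheritParams dataset_manifest
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_lesion_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::walk2(dataset$image, dataset$filename, function(img, fn) {
    q <- round(img * 255) / 255
    png::writePNG(q, target = file.path(dir, fn))
  })
  readr::write_csv(dataset_manifest(dataset), file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read an image dataset laid out as PNG/JPEG files plus a CSV manifest
#'
#' This is also the adapter for externally supplied corpora (e.g. public
#' dermoscopy archives re-arranged as one directory of images plus a
#' `filename,label` CSV).
#'
#' @param dir Directory containing the image files.
#' @param manifest Path to the manifest CSV (header `filename,label`);
#'   defaults to `manifest.csv` inside `dir`.
#' @return A dataset tibble with columns `id`, `filename`, `label`, `image`.
#' @export
read_lesion_dataset <- function(dir, manifest = file.path(dir, "manifest.csv")) {
  if (!file.exists(manifest)) {
    stop_invalid("manifest file not found: %s", manifest)
  }
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  if (!all(c("filename", "label") %in% names(man))) {
    stop_invalid("manifest must have columns `filename` and `label`")
  }
  images <- lapply(man$filename, function(fn) {
    img <- png::readPNG(file.path(dir, fn))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE] |> array(dim = c(dim(img)[1:2], 3L))
  })
  tibble::tibble(
    id = tools::file_path_sans_ext(man$filename),
    filename = man$filename,
    label = as.integer(man$label),
    image = images
  )
}
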