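# Locally adaptive Wiener denoising.
#
# Each pixel is shrunk toward its local window mean by the ratio of the
# global noise variance to the local variance:
#
#   out = x - (s2 / lv) * (x - mu)   where lv > s2
#   out = mu                         where lv <= s2 (clamped form)
#
# with mu and lv the mean and variance over a square window around the
# pixel and s2 the global noise variance. At s2 = 0 the filter is the
# identity; as lv grows with s2 fixed (edges), the output approaches the
# input, which preserves structure while flattening homogeneous regions.

#' Wiener filter configuration
#'
#' @param window Odd integer side of the local square window (default 3).
#' @param noise_variance `"auto"` (estimate the global noise variance as the
#'   mean of the local-variance image) or an explicit value >= 0.
#' @param border One of `"reflect"` or `"constant"`; how pixels beyond the
#'   image border are filled when computing local statistics.
#' @return A `wiener_config` list.
#' @export
wiener_config <- function(window = 3L, noise_variance = "auto",
                          border = c("reflect", "constant")) {
  check_number(window, "window", min = 3, integer = TRUE)
  if (window %% 2L == 0L) stop_invalid("`window` must be odd, got %d", window)
  border <- match.arg(border)
  if (!identical(noise_variance, "auto")) {
    check_number(noise_variance, "noise_variance", min = 0)
  }
  structure(list(window = as.integer(window),
                 noise_variance = noise_variance,
                 border = border),
            class = "wiener_config")
}

pad_matrix <- function(x, p, border) {
  h <- nrow(x); w <- ncol(x)
  if (border == "reflect") {
    # reflect without repeating the edge pixel (style of symmetric padding
    # with the border row mirrored: 321|123...); for p < h this is standard
    ri <- c(rev(seq_len(p) + 1L), seq_len(h), h - seq_len(p))
    ci <- c(rev(seq_len(p) + 1L), seq_len(w), w - seq_len(p))
    x[ri, ci, drop = FALSE]
  } else {
    out <- matrix(0, h + 2L * p, w + 2L * p)
    out[p + seq_len(h), p + seq_len(w)] <- x
    out
  }
}

#' Per-pixel local mean and variance
#'
#' Mean and (population) variance over a `window` x `window` neighbourhood of
#' every pixel, with the stated border handling.
#'
#' @param image A 2-D numeric matrix of finite intensities.
#' @param window Odd integer window side.
#' @param border `"reflect"` (default) or `"constant"` (zero fill).
#' @return A list with matrices `mean` and `variance`, each the shape of
#'   `image`; the variance is clamped to be >= 0.
#' @export
local_statistics <- function(image, window = 3L, border = "reflect") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_invalid("`image` must be a numeric matrix")
  }
  if (!all(is.finite(image))) stop_invalid("`image` contains non-finite pixels")
  check_number(window, "window", min = 3, integer = TRUE)
  if (window %% 2L == 0L) stop_invalid("`window` must be odd, got %d", window)
  border <- match.arg(border, c("reflect", "constant"))

  p <- (window - 1L) %/% 2L
  xp <- pad_matrix(image, p, border)
  h <- nrow(image); w <- ncol(image)
  s1 <- matrix(0, h, w)
  s2 <- matrix(0, h, w)
  for (dy in 0:(window - 1L)) {
    for (dx in 0:(window - 1L)) {
      blk <- xp[dy + seq_len(h), dx + seq_len(w), drop = FALSE]
      s1 <- s1 + blk
      s2 <- s2 + blk * blk
    }
  }
  nn <- window * window
  mu <- s1 / nn
  va <- s2 / nn - mu * mu
  va[va < 0] <- 0  # numerical clamp; keeps the matrix shape
  list(mean = mu, variance = va)
}

#' Adaptive Wiener denoising
#'
#' Applies the local Wiener shrinkage rule to a 2-D intensity image or,
#' channel by channel, to an H x W x C array. Where the local variance does
#' not exceed the global noise variance the output is clamped to the local
#' mean (this also covers constant windows, where the local variance is 0).
#'
#' @param image A 2-D matrix or 3-D array of finite intensities.
#' @param config A [wiener_config()].
#' @return The denoised image, same shape as the input.
#' @export
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' identical(wiener_denoise(img, wiener_config(noise_variance = 0)), img)
wiener_denoise <- function(image, config = wiener_config()) {
  stopifnot(inherits(config, "wiener_config"))
  if (!all(is.finite(image))) stop_invalid("`image` contains non-finite pixels")
  d <- dim(image)
  if (is.null(d) || length(d) < 2L || length(d) > 3L) {
    stop_invalid("`image` must be a 2-D matrix or 3-D array")
  }
  if (length(d) == 3L) {
    out <- image
    for (ch in seq_len(d[3L])) {
      out[, , ch] <- wiener_denoise(matrix(image[, , ch], d[1L], d[2L]), config)
    }
    return(out)
  }
  stats <- local_statistics(image, config$window, config$border)
  mu <- stats$mean
  lv <- stats$variance
  s2 <- if (identical(config$noise_variance, "auto")) mean(lv) else config$noise_variance
  if (s2 == 0) return(image)
  gain <- ifelse(lv > s2, 1 - s2 / lv, 0)
  mu + gain * (image - mu)
}

#' Denoise every image of a dataset
#'
#' @param dataset A dataset tibble (list-column `image`).
#' @param config A [wiener_config()].
#' @return The dataset with the `image` column replaced by denoised images.
#' @export
wiener_denoise_dataset <- function(dataset, config = wiener_config()) {
  dataset$image <- lapply(dataset$image, wiener_denoise, config = config)
  dataset
}
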