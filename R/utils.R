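# Internal helpers shared across modules.

# abort with a consistent class so callers can test for invalid arguments
stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "dermhgso_invalid_argument")
}

stop_size <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "dermhgso_size_error")
}

stop_eval <- function(msg, ..., data = NULL) {
  rlang::abort(sprintf(msg, ...), class = "dermhgso_evaluation_error", data = data)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (integer && x != round(x)) {
    stop_invalid("`%s` must be an integer, got %s", name, format(x))
  }
  if (x < min || x > max) {
    stop_invalid("`%s` must be in [%s, %s], got %s", name,
                 format(min), format(max), format(x))
  }
  invisible(x)
}

# run `code` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a child seed from a master seed; keeps values < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + offset * 7919L) %% 2147483647)
}

# flatten a list of H x W x 3 image arrays into the (H*W*N) x C matrix layout
# used by the network ops (row order: h fastest, then w, then sample)
images_to_matrix <- function(images) {
  n <- length(images)
  d <- dim(images[[1L]])
  a <- array(unlist(images, use.names = FALSE), dim = c(d[1L], d[2L], d[3L], n))
  a <- aperm(a, c(1L, 2L, 4L, 3L))
  dim(a) <- c(d[1L] * d[2L] * n, d[3L])
  list(x = a, h = d[1L], w = d[2L], n = n, c = d[3L])
}

# min-max rescale columns of a matrix to [0, 1]; constant columns map to 0
minmax_fit <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  list(lo = lo, hi = hi)
}

minmax_apply <- function(x, scale) {
  rng <- scale$hi - scale$lo
  rng[rng == 0] <- 1
  sweep(sweep(x, 2L, scale$lo, "-"), 2L, rng, "/")
}

# map over the leaves (numeric arrays) of two parallel nested lists
nested_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(nested_map2, a, b, MoreArgs = list(f = f))
    attributes(out) <- attributes(a)
    return(out)
  }
  f(a, b)
}

nested_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, nested_map, f = f)
    attributes(out) <- attributes(a)
    return(out)
  }
  f(a)
}

# sum of all leaf lengths (parameter count)
nested_length <- function(a) {
  if (is.list(a)) return(sum(vapply(a, nested_length, numeric(1))))
  length(a)
}
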