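# Hyperparameter search space: named bounded dimensions mapped to and from
# continuous optimizer positions.

#' Hyperparameter search space
#'
#' Describes the tuned dimensions. `type` is one of:
#' * `"continuous"` — position passes through;
#' * `"log"` — position lives in log10 space and is exponentiated on decode;
#' * `"integer"` — position rounds to the nearest integer in range;
#' * `"categorical"` — position rounds to an index into `values`.
#'
#' The default space spans the extractor's training knobs around the
#' reference operating point (learning rate 0.01, batch 5, 50 epochs,
#' dropout 0.5): `lr0` log-scaled in \[1e-4, 1e-1\], `batch_size` in
#' \{2..64\}, `epochs` in \{5..50\}, `dropout` in \[0, 0.7\].
#'
#' @param dims A tibble with columns `name`, `type`, `lower`, `upper`, and
#'   optionally a `values` list-column for categorical dimensions; `NULL`
#'   for the default space.
#' @return A `hyperparameter_space` tibble.
#' @export
hyperparameter_space <- function(dims = NULL) {
  if (is.null(dims)) {
    dims <- tibble::tibble(
      name = c("lr0", "batch_size", "epochs", "dropout"),
      type = c("log", "integer", "integer", "continuous"),
      lower = c(1e-4, 2, 5, 0),
      upper = c(1e-1, 64, 50, 0.7),
      values = list(NULL, NULL, NULL, NULL)
    )
  }
  if (!all(c("name", "type", "lower", "upper") %in% names(dims))) {
    stop_invalid("`dims` needs columns name, type, lower, upper")
  }
  if (!all(dims$type %in% c("continuous", "log", "integer", "categorical"))) {
    stop_invalid("unknown dimension type")
  }
  if (!"values" %in% names(dims)) dims$values <- vector("list", nrow(dims))
  structure(as_tibble(dims), class = c("hyperparameter_space", class(dims)))
}

#' Optimizer bounds of a hyperparameter space
#'
#' @param space A [hyperparameter_space()].
#' @return A [search_bounds()] in encoded (position) coordinates: log10
#'   bounds for log dimensions, index bounds for categorical ones.
#' @export
space_bounds <- function(space) {
  lo <- numeric(nrow(space)); hi <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    switch(space$type[i],
      log = { lo[i] <- log10(space$lower[i]); hi[i] <- log10(space$upper[i]) },
      categorical = { lo[i] <- 1; hi[i] <- length(space$values[[i]]) },
      { lo[i] <- space$lower[i]; hi[i] <- space$upper[i] })
  }
  search_bounds(lo, hi)
}

#' Decode an optimizer position into trainer settings
#'
#' Continuous dimensions pass through, log dimensions are exponentiated,
#' integer dimensions round to the nearest valid value, categorical
#' dimensions round to an index into their value set.
#' `decode_position(encode_settings(s)) == s` for representable settings.
#'
#' @param position Numeric vector within [space_bounds()].
#' @param space A [hyperparameter_space()].
#' @return A named list of decoded settings.
#' @export
#' @examples
#' sp <- hyperparameter_space()
#' decode_position(c(-2, 4.7, 30, 0.5), sp)$batch_size  # 5
decode_position <- function(position, space) {
  b <- space_bounds(space)
  if (length(position) != nrow(space)) {
    stop_invalid("position length %d does not match the %d-dimensional space",
                 length(position), nrow(space))
  }
  if (any(position < b$lower - 1e-9) || any(position > b$upper + 1e-9)) {
    stop_invalid("position outside the search bounds")
  }
  out <- list()
  for (i in seq_len(nrow(space))) {
    out[[space$name[i]]] <- switch(space$type[i],
      continuous = position[i],
      log = 10^position[i],
      integer = as.integer(min(max(round(position[i]), space$lower[i]),
                               space$upper[i])),
      categorical = space$values[[i]][[min(max(round(position[i]), 1L),
                                           length(space$values[[i]]))]])
  }
  out
}

#' Encode trainer settings as an optimizer position
#'
#' @param settings A named list (or `train_settings`) containing every
#'   dimension of `space`.
#' @inheritParams decode_position
#' @return A numeric position vector.
#' @export
encode_settings <- function(settings, space) {
  vapply(seq_len(nrow(space)), function(i) {
    v <- settings[[space$name[i]]]
    if (is.null(v)) stop_invalid("settings missing dimension `%s`", space$name[i])
    switch(space$type[i],
      continuous = as.numeric(v),
      log = log10(as.numeric(v)),
      integer = as.numeric(v),
      categorical = as.numeric(which(vapply(space$values[[i]],
                                            identical, logical(1), v))[1L]))
  }, numeric(1))
}
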