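# Evaluation surface: stratified split, confusion matrix, per-class
# one-vs-rest metrics (accuracy, sensitivity, specificity, F-score, MCC)
# and their unweighted macro averages.

#' Stratified train/test split
#'
#' Per-class proportions are preserved: each class contributes
#' `floor(prop * n_k)` training samples, then the remaining training slots
#' (up to `round(prop * N)` in total) go to the classes with the largest
#' fractional remainders (ties to the lower class id). Which samples land in
#' which side is randomized under `seed`.
#'
#' @param dataset A tibble with a `label` column (each class needs >= 2
#'   samples).
#' @param train_fraction Training proportion (default 0.7).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`; disjoint and exhaustive.
#' @export
#' @examples
#' ds <- tibble::tibble(label = rep(0:1, each = 50), x = 1:100)
#' sp <- stratified_split(ds, 0.7, seed = 1)
#' table(sp$train$label)
stratified_split <- function(dataset, train_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  check_number(train_fraction, "train_fraction", min = 1e-9, max = 1 - 1e-9)
  counts <- table(dataset$label)
  if (any(counts < 2L)) {
    stop_invalid("every class needs at least 2 samples (smallest has %d)",
                 min(counts))
  }
  classes <- as.integer(names(counts))
  nk <- as.integer(counts)
  target_total <- round(train_fraction * sum(nk))
  base <- floor(train_fraction * nk)
  frac <- train_fraction * nk - base
  extra <- target_total - sum(base)
  if (extra > 0) {
    give <- order(-frac, classes)[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  take_n <- setNames(base, names(counts))

  idx_train <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      rows <- which(dataset$label == classes[i])
      sample(rows, take_n[i])
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  list(train = dataset[idx_train, , drop = FALSE],
       test = dataset[setdiff(seq_len(nrow(dataset)), idx_train), , drop = FALSE])
}

#' Confusion matrix
#'
#' @param truth,estimate Equal-length 0-based label vectors in `[0, K)`.
#' @param n_classes Number of classes `K`; defaults to 1 + the largest label
#'   seen.
#' @return A K x K integer matrix, rows = true class, columns = predicted
#'   class, dimnames the 0-based class ids.
#' @export
confusion_matrix <- function(truth, estimate, n_classes = NULL) {
  if (length(truth) != length(estimate)) {
    stop_invalid("`truth` and `estimate` must have equal length")
  }
  n_classes <- n_classes %||% (max(c(truth, estimate)) + 1L)
  if (any(c(truth, estimate) < 0) || any(c(truth, estimate) >= n_classes)) {
    stop_invalid("labels must lie in [0, %d)", n_classes)
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1L),
                               pred = 0:(n_classes - 1L)))
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, estimate[i] + 1L] <- cm[truth[i] + 1L, estimate[i] + 1L] + 1L
  }
  cm
}

metric_or_zero <- function(num, den) if (den == 0) 0 else num / den

#' Per-class one-vs-rest metrics
#'
#' For each class k, with TP/FP/FN/TN from treating k as positive:
#' accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' F-score `2TP/(2TP+FP+FN)`, and Matthews correlation
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any metric with a
#' zero denominator is defined as 0.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return A tibble with one row per class: `class`, `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `sensitivity`, `specificity`, `fscore`, `mcc` (proportions
#'   in \[0,1\], `mcc` in \[-1,1\]).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  k <- nrow(cm)
  total <- sum(cm)
  rows <- lapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    tibble::tibble(
      class = i - 1L, tp = tp, fp = fp, fn = fn, tn = tn,
      accuracy = metric_or_zero(tp + tn, total),
      sensitivity = metric_or_zero(tp, tp + fn),
      specificity = metric_or_zero(tn, tn + fp),
      fscore = metric_or_zero(2 * tp, 2 * tp + fp + fn),
      mcc = metric_or_zero(tp * tn - fp * fn, mcc_den)
    )
  })
  dplyr::bind_rows(rows)
}

#' Full evaluation report
#'
#' Per-class one-vs-rest metrics plus their unweighted macro averages.
#'
#' @param truth,estimate 0-based label vectors, or pass a confusion matrix
#'   as `cm` instead.
#' @param n_classes Number of classes.
#' @param cm Optionally a precomputed [confusion_matrix()].
#' @return An `evaluation_report`: list with `confusion` (matrix),
#'   `per_class` (tibble) and `macro` (one-row tibble of the five averaged
#'   metrics). Metric values are proportions; see [report_table()] for the
#'   0-100 display scale.
#' @export
evaluation_report <- function(truth = NULL, estimate = NULL, n_classes = NULL,
                              cm = NULL) {
  cm <- cm %||% confusion_matrix(truth, estimate, n_classes)
  pc <- per_class_metrics(cm)
  macro <- dplyr::summarise(pc, dplyr::across(
    c("accuracy", "sensitivity", "specificity", "fscore", "mcc"), mean))
  structure(list(confusion = cm, per_class = pc, macro = macro),
            class = "evaluation_report")
}

#' Report table on the 0-100 display scale
#'
#' One row per class plus an `average` row, metrics multiplied by 100 and
#' rounded to two decimals.
#'
#' @param report An [evaluation_report()].
#' @return A tibble with columns `class`, `accuracy`, `sensitivity`,
#'   `specificity`, `fscore`, `mcc`.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  cols <- c("accuracy", "sensitivity", "specificity", "fscore", "mcc")
  pc <- dplyr::mutate(report$per_class, class = as.character(class))
  avg <- dplyr::mutate(report$macro, class = "average")
  out <- dplyr::bind_rows(pc[, c("class", cols)], avg[, c("class", cols)])
  dplyr::mutate(out, dplyr::across(dplyr::all_of(cols), ~ round(100 * .x, 2)))
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report An [evaluation_report()].
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) readr::write_csv(report_table(report), path_csv)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(per_class = report$per_class,
                              macro = report$macro,
                              confusion = report$confusion),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> (0-100 scale)\n")
  print(report_table(x))
  invisible(x)
}
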