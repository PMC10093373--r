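# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @rdname hgso_minimize
#' @param x An `hgso_result`.
#' @param ... Unused.
#' @export
tidy.hgso_result <- function(x, ...) x$history

#' @rdname hgso_minimize
#' @export
glance.hgso_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 n_evaluations = x$n_evaluations,
                 iterations = nrow(x$history),
                 population_size = x$config$population_size,
                 n_clusters = x$config$n_clusters)
}

#' @rdname train_mafnet
#' @param x A `mafnet`.
#' @param ... Unused.
#' @export
tidy.mafnet <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric(),
                                lr = numeric(), accuracy = numeric())
}

#' @rdname train_mafnet
#' @export
glance.mafnet <- function(x, ...) {
  tibble::tibble(
    n_conv_modules = mafnet_module_count(x),
    n_parameters = nested_length(x$params),
    use_cot = x$config$use_cot,
    feature_dim = x$config$feature_dim,
    trained = isTRUE(x$trained),
    final_loss = if (is.null(x$history)) NA_real_ else tail(x$history$loss, 1),
    final_accuracy = if (is.null(x$history)) NA_real_ else tail(x$history$accuracy, 1)
  )
}

#' @rdname stack_dbn
#' @param x A `dbn_classifier`.
#' @param ... Unused.
#' @export
tidy.dbn_classifier <- function(x, ...) x$finetune_history

#' @rdname stack_dbn
#' @export
glance.dbn_classifier <- function(x, ...) {
  tibble::tibble(
    n_hidden_layers = length(x$layers),
    layer_sizes = paste(vapply(x$layers, function(l) ncol(l$W), integer(1)),
                        collapse = ","),
    n_classes = x$n_classes,
    final_loss = tail(x$finetune_history$loss, 1)
  )
}

#' @rdname evaluation_report
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$per_class

#' @rdname evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) x$macro

#' @rdname run_pipeline
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @export
tidy.pipeline_result <- function(x, ...) report_table(x$report)

#' @rdname run_pipeline
#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_cols(
    x$report$macro,
    tibble::tibble(n_train = x$manifest$n_train, n_test = x$manifest$n_test,
                   seed = x$manifest$seed,
                   total_seconds = x$manifest$total_seconds)
  )
}

#' Convergence-trace plot of an HGSO run
#' @param object An `hgso_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hgso_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best-so-far fitness",
                  title = "HGSO convergence") +
    ggplot2::theme_minimal()
}

#' Training-curve plot of the feature extractor
#' @param object A trained `mafnet`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mafnet <- function(object, ...) {
  h <- tidy.mafnet(object)
  long <- tidyr::pivot_longer(h, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", title = "Extractor training") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
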