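# End-to-end orchestration: denoise -> tune -> train extractor ->
# extract features -> train DBN -> evaluate.

resize_image <- function(img, size) {
  if (dim(img)[1L] == size && dim(img)[2L] == size) return(img)
  out <- EBImage::resize(img, w = size, h = size)
  array(pmin(1, pmax(0, out)), dim = c(size, size, 3L))
}

resize_dataset <- function(dataset, size) {
  dataset$image <- lapply(dataset$image, resize_image, size = size)
  dataset
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with desk-scale defaults: a 32-px
#' extractor trained on the winning HGSO settings, tuning at 16 px with a
#' reduced epoch budget inside the fitness, and a compact DBN. The tuning
#' search space is restricted to the extractor's stable operating region at
#' desk scale: learning rate \[3e-3, 3e-2\] (log), batch size \{4..16\},
#' epochs \{8..16\} and dropout \[0, 0.6\]; pass
#' `space = hyperparameter_space()` for the wider default space.
#'
#' @param wiener A [wiener_config()].
#' @param mafnet A [mafnet_config()]; `n_classes` is overridden by the data
#'   at run time.
#' @param hgso An [hgso_config()] (desk-scale default: 6 agents, 2 clusters,
#'   5 iterations).
#' @param space A [hyperparameter_space()] for tuning.
#' @param dbn A [dbn_config()].
#' @param train_fraction Train share of the stratified split (default 0.7).
#' @param skip_wiener,skip_hgso Stage toggles. With `skip_hgso = TRUE` the
#'   extractor trains with the literal reference settings
#'   (lr 0.01, batch 5, 50 epochs, dropout 0.5).
#' @param tune Tuning-scale options: `input_size`, `epoch_scale` (fraction of
#'   the decoded epochs actually run inside the fitness), `max_images`
#'   (cap on inner-training images), `dbn` (light DBN used inside the
#'   fitness).
#' @param seed Master seed; every stage derives its own seed from it.
#' @param out_dir Optional run directory for artifacts (`NULL` = in-memory).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(wiener = wiener_config(),
                            mafnet = mafnet_config(),
                            hgso = hgso_config(population_size = 6L,
                                               n_clusters = 2L,
                                               max_iter = 5L),
                            space = NULL,
                            dbn = dbn_config(layer_sizes = c(32L, 16L),
                                             rbm_epochs = 20L,
                                             finetune_epochs = 150L),
                            train_fraction = 0.7,
                            skip_wiener = FALSE,
                            skip_hgso = FALSE,
                            tune = list(),
                            seed = 1L,
                            out_dir = NULL) {
  space <- space %||% hyperparameter_space(tibble::tibble(
    name = c("lr0", "batch_size", "epochs", "dropout"),
    type = c("log", "integer", "integer", "continuous"),
    lower = c(3e-3, 4, 8, 0),
    upper = c(3e-2, 16, 16, 0.6)
  ))
  tune <- utils::modifyList(list(
    input_size = 16L,
    epoch_scale = 0.5,
    max_images = 60L,
    mafnet = mafnet_config(stage_module_counts = c(1L, 1L, 1L, 1L),
                           stage_channels = c(4L, 8L, 8L, 8L),
                           input_size = 16L, feature_dim = 8L),
    dbn = dbn_config(layer_sizes = c(16L, 8L), rbm_epochs = 10L,
                     finetune_epochs = 100L)
  ), tune)
  check_flag(skip_wiener, "skip_wiener")
  check_flag(skip_hgso, "skip_hgso")
  structure(list(wiener = wiener, mafnet = mafnet, hgso = hgso,
                 space = space, dbn = dbn,
                 train_fraction = train_fraction,
                 skip_wiener = skip_wiener, skip_hgso = skip_hgso,
                 tune = tune, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

with_stage <- function(stage, out_dir, artifacts, code) {
  tryCatch(code, error = function(e) {
    if (!is.null(out_dir)) persist_artifacts(artifacts, out_dir)
    rlang::abort(sprintf("pipeline stage `%s` failed: %s", stage,
                         conditionMessage(e)),
                 class = "dermhgso_stage_error", stage = stage, parent = e)
  })
}

reconfig_mafnet <- function(cfg, n_classes, input_size = NULL) {
  mafnet_config(stage_module_counts = cfg$stage_module_counts,
                stage_channels = cfg$stage_channels,
                input_size = input_size %||% cfg$input_size,
                n_classes = n_classes,
                feature_dim = cfg$feature_dim,
                use_cot = cfg$use_cot)
}

train_and_score <- function(train_ds, val_ds, net_config, settings, dbn_cfg,
                            seed) {
  net <- build_mafnet(net_config, seed = derive_seed(seed, 21L))
  net <- train_mafnet(net, train_ds, settings)
  ftr <- extract_features(net, train_ds)
  fva <- extract_features(net, val_ds)
  dbn_cfg$seed <- derive_seed(seed, 22L)
  model <- stack_dbn(ftr, train_ds$label, dbn_cfg,
                     n_classes = net_config$n_classes)
  pred <- predict(model, fva)
  list(net = net, dbn = model,
       error_pct = misclassification_rate(val_ds$label, pred$.pred_class))
}

#' Run the full classification pipeline
#'
#' Stages, in order: load (or accept) the dataset; Wiener-denoise; resize;
#' stratified 70/30 split; HGSO hyperparameter tuning of the extractor's
#' training settings (misclassification-percentage fitness on an inner
#' validation fold, using a down-scaled extractor); final extractor training
#' with the winning settings; feature extraction; DBN training; evaluation
#' on the held-out test set.
#'
#' @param data A dataset tibble ([generate_lesion_dataset()],
#'   [read_lesion_dataset()]) or a directory path containing images plus a
#'   `manifest.csv`.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: evaluation reports (`report` on test,
#'   `train_report`), the tuned `settings`, the `tuning` trace, the trained
#'   `extractor` and `dbn`, stage `timings`, and the seed/config `manifest`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  artifacts <- list(config = config)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    tibble::tibble(stage = stage,
                   seconds = as.numeric(difftime(Sys.time(), start, units = "secs")))
  }

  s <- Sys.time()
  ds <- with_stage("load", config$out_dir, artifacts, {
    if (is.character(data)) data <- read_lesion_dataset(data)
    stopifnot(is.data.frame(data), all(c("image", "label") %in% names(data)))
    data
  })
  n_classes <- length(unique(ds$label))
  timings$load <- tick("load", s)

  s <- Sys.time()
  ds <- with_stage("preprocess", config$out_dir, artifacts, {
    if (config$skip_wiener) ds else wiener_denoise_dataset(ds, config$wiener)
  })
  timings$preprocess <- tick("preprocess", s)

  s <- Sys.time()
  split <- with_stage("split", config$out_dir, artifacts, {
    stratified_split(ds, config$train_fraction, seed = derive_seed(seed, 3L))
  })
  ds_main <- list(train = resize_dataset(split$train, config$mafnet$input_size),
                  test = resize_dataset(split$test, config$mafnet$input_size))
  timings$split <- tick("split", s)

  s <- Sys.time()
  tuning <- NULL
  settings <- with_stage("tune", config$out_dir, artifacts, {
    if (config$skip_hgso) {
      train_settings(lr0 = 0.01, batch_size = 5L, epochs = 50L, dropout = 0.5,
                     seed = derive_seed(seed, 7L))
    } else {
      tune_cfg <- config$tune
      inner <- stratified_split(split$train, 0.7, seed = derive_seed(seed, 4L))
      inner_tr <- resize_dataset(inner$train, tune_cfg$input_size)
      if (nrow(inner_tr) > tune_cfg$max_images) {
        inner_tr <- inner_tr[seq_len(tune_cfg$max_images), ]
      }
      inner_va <- resize_dataset(inner$test, tune_cfg$input_size)
      net_cfg <- reconfig_mafnet(tune_cfg$mafnet, n_classes,
                                 input_size = tune_cfg$input_size)
      space <- config$space
      fitness <- function(position) {
        dec <- decode_position(position, space)
        st <- train_settings(
          lr0 = dec$lr0, batch_size = dec$batch_size,
          epochs = max(2L, as.integer(round(dec$epochs * tune_cfg$epoch_scale))),
          dropout = dec$dropout, seed = derive_seed(seed, 6L))
        train_and_score(inner_tr, inner_va, net_cfg, st, tune_cfg$dbn,
                        seed)$error_pct
      }
      hcfg <- config$hgso
      hcfg$seed <- derive_seed(seed, 5L)
      tuning <- hgso_minimize(fitness, space_bounds(space), hcfg)
      dec <- decode_position(tuning$best_position, space)
      train_settings(lr0 = dec$lr0, batch_size = dec$batch_size,
                     epochs = dec$epochs, dropout = dec$dropout,
                     seed = derive_seed(seed, 7L))
    }
  })
  artifacts$settings <- settings
  artifacts$tuning <- tuning
  timings$tune <- tick("tune", s)

  s <- Sys.time()
  extractor <- with_stage("train_extractor", config$out_dir, artifacts, {
    net <- build_mafnet(reconfig_mafnet(config$mafnet, n_classes),
                        seed = derive_seed(seed, 8L))
    train_mafnet(net, ds_main$train, settings)
  })
  artifacts$extractor <- extractor
  timings$train_extractor <- tick("train_extractor", s)

  s <- Sys.time()
  feats <- with_stage("extract_features", config$out_dir, artifacts, {
    list(train = extract_features(extractor, ds_main$train),
         test = extract_features(extractor, ds_main$test))
  })
  timings$extract_features <- tick("extract_features", s)

  s <- Sys.time()
  dbn <- with_stage("train_dbn", config$out_dir, artifacts, {
    cfg <- config$dbn
    cfg$seed <- derive_seed(seed, 9L)
    stack_dbn(feats$train, ds_main$train$label, cfg, n_classes = n_classes)
  })
  artifacts$dbn <- dbn
  timings$train_dbn <- tick("train_dbn", s)

  s <- Sys.time()
  reports <- with_stage("evaluate", config$out_dir, artifacts, {
    pred_te <- predict(dbn, feats$test)
    pred_tr <- predict(dbn, feats$train)
    list(test = evaluation_report(ds_main$test$label, pred_te$.pred_class,
                                  n_classes = n_classes),
         train = evaluation_report(ds_main$train$label, pred_tr$.pred_class,
                                   n_classes = n_classes))
  })
  timings$evaluate <- tick("evaluate", s)

  manifest <- list(
    seed = seed,
    stage_order = c("load", "preprocess", "split", "tune", "train_extractor",
                    "extract_features", "train_dbn", "evaluate"),
    stage_seeds = list(split = derive_seed(seed, 3L),
                       inner_split = derive_seed(seed, 4L),
                       hgso = derive_seed(seed, 5L),
                       fitness_training = derive_seed(seed, 6L),
                       final_training = derive_seed(seed, 7L),
                       extractor_init = derive_seed(seed, 8L),
                       dbn = derive_seed(seed, 9L)),
    config_hash = rlang::hash(config),
    n_classes = n_classes,
    n_train = nrow(ds_main$train),
    n_test = nrow(ds_main$test),
    skip_wiener = config$skip_wiener,
    skip_hgso = config$skip_hgso,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- structure(list(
    report = reports$test, train_report = reports$train,
    settings = settings, tuning = tuning,
    extractor = extractor, dbn = dbn,
    features = feats, split = ds_main,
    timings = dplyr::bind_rows(timings), manifest = manifest,
    config = config), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    artifacts$result <- result
    persist_artifacts(artifacts, config$out_dir)
  }
  result
}

persist_artifacts <- function(artifacts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- artifacts$result
  if (!is.null(artifacts$settings)) {
    jsonlite::write_json(unclass(artifacts$settings),
                         file.path(out_dir, "best_settings.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(artifacts$tuning)) {
    readr::write_csv(artifacts$tuning$history,
                     file.path(out_dir, "hgso_trace.csv"))
  }
  if (!is.null(artifacts$extractor)) {
    saveRDS(artifacts$extractor, file.path(out_dir, "extractor.rds"))
    if (!is.null(artifacts$extractor$history)) {
      readr::write_csv(artifacts$extractor$history,
                       file.path(out_dir, "extractor_history.csv"))
    }
  }
  if (!is.null(artifacts$dbn)) {
    saveRDS(artifacts$dbn, file.path(out_dir, "dbn.rds"))
  }
  if (!is.null(res)) {
    write_report(res$report, file.path(out_dir, "report.csv"),
                 file.path(out_dir, "report.json"))
    for (part in c("train", "test")) {
      f <- res$features[[part]]
      colnames(f) <- paste0("f", seq_len(ncol(f)) - 1L)
      readr::write_csv(
        dplyr::bind_cols(tibble::tibble(id = res$split[[part]]$id),
                         as_tibble(f)),
        file.path(out_dir, paste0("features_", part, ".csv")))
    }
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Run pipeline ablations under a shared seed
#'
#' Always runs the full pipeline, plus one variant per requested toggle:
#' `skip_wiener` (no denoising), `skip_hgso` (literal reference training
#' settings: lr 0.01, batch 5, 50 epochs, dropout 0.5), and `plain_conv`
#' (3x3 convolutions instead of CoT attention).
#'
#' @param data As in [run_pipeline()].
#' @param config A [pipeline_config()].
#' @param toggles Character subset of
#'   `c("skip_wiener", "skip_hgso", "plain_conv")`.
#' @return An `ablation_result`: tibble `summary` (one row per variant with
#'   the macro metrics) and the named list of full `runs`.
#' @export
run_ablation <- function(data, config = pipeline_config(),
                         toggles = character(0)) {
  bad <- setdiff(toggles, c("skip_wiener", "skip_hgso", "plain_conv"))
  if (length(bad)) stop_invalid("unknown toggles: %s", paste(bad, collapse = ", "))
  variants <- list(full = config)
  for (tg in toggles) {
    v <- config
    if (tg == "skip_wiener") v$skip_wiener <- TRUE
    if (tg == "skip_hgso") v$skip_hgso <- TRUE
    if (tg == "plain_conv") v$mafnet$use_cot <- FALSE
    variants[[tg]] <- v
  }
  runs <- lapply(variants, function(v) run_pipeline(data, v))
  summary <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    dplyr::bind_cols(tibble::tibble(variant = nm), runs[[nm]]$report$macro)
  }))
  structure(list(summary = summary, runs = runs), class = "ablation_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d train / %d test samples, %d classes; total %.1f s\n",
              x$manifest$n_train, x$manifest$n_test, x$manifest$n_classes,
              x$manifest$total_seconds))
  cat(sprintf("  settings: lr0 %.4g, batch %d, epochs %d, dropout %.2f%s\n",
              x$settings$lr0, x$settings$batch_size, x$settings$epochs,
              x$settings$dropout,
              if (x$config$skip_hgso) " (reference defaults)" else " (HGSO-tuned)"))
  cat("  test-set report (0-100 scale):\n")
  print(report_table(x$report))
  invisible(x)
}
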