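##
## End-to-end orchestration: phantom generation -> augmentation ->
## cross-validated training -> evaluation, plus the HAC-count ablation
## harness.  Everything is reproducible from the config and seed alone.
##

#' Pipeline run configuration
#'
#' @param phantom a [phantom_params()] template.
#' @param train a [train_config()].
#' @param model a [model_config()].
#' @param n_images number of phantoms to generate when no dataset is
#'   supplied.
#' @param ablation_hac_counts HAC module counts swept by [run_ablation()].
#' @param output_dir optional directory for CSV reports and checkpoints.
#' @export
run_config <- function(phantom = phantom_params(), train = train_config(),
                       model = model_config(), n_images = 40L,
                       ablation_hac_counts = 1:6, output_dir = NULL) {
  structure(list(phantom = phantom, train = train, model = model,
                 n_images = as.integer(n_images),
                 ablation_hac_counts = as.integer(ablation_hac_counts),
                 output_dir = output_dir),
            class = "run_config")
}

summarise_records <- function(records) {
  cols <- c("dice", "iou", "acc", "mhd", "delta_tpa")
  do.call(rbind, lapply(cols, function(cl) {
    v <- records[[cl]]
    data.frame(metric = cl, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE))
  }))
}

#' Cross-validated training and evaluation
#'
#' Splits the dataset into `config$train$folds` folds, trains one model
#' per fold on the augmented pool of its training images (GIA + CBVIA),
#' and evaluates every held-out image un-augmented with its fold's model.
#' Returns per-image metric records, per-fold models and the pooled
#' mean +/- SD summary over all images.
#'
#' @param config a [run_config()].
#' @param samples optional list of samples (`image`, `plaque_mask`,
#'   `vessel_mask`); generated from `config$phantom` when `NULL`.
#' @param keep_models retain the trained models in the result (needed for
#'   [ensemble_predict()] on new images).
#' @param verbose print fold progress.
#' @return list with `records` (data.frame, one row per image), `summary`
#'   (mean +/- SD per metric), `fold_plan`, `histories`, `models` (if
#'   kept) and the `seeds` manifest.
#' @export
run_crossval <- function(config = run_config(), samples = NULL,
                         keep_models = TRUE, verbose = FALSE) {
  if (is.null(samples))
    samples <- generate_dataset(config$n_images, config$phantom,
                                seed = config$train$seed)
  dims <- lapply(samples, function(s) dim(s$image))
  if (length(unique(dims)) != 1L)
    stop("inconsistent image sizes across the dataset", call. = FALSE)
  n <- length(samples)
  plan <- make_folds(n, config$train$folds, seed = config$train$seed)

  records <- list()
  models <- list()
  histories <- list()
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$fold_assignments == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    pool <- build_training_set(samples[train_idx])
    tc <- config$train
    tc$seed <- tc$seed + f   # distinct init/order per fold, still seeded
    fit <- train_fold(pool, tc, config$model, verbose = verbose)
    histories[[f]] <- fit$history
    for (i in test_idx) {
      probs <- predict_hrunet(fit$model, samples[[i]]$image)
      rec <- evaluate_masks(samples[[i]]$plaque_mask, prob_to_mask(probs))
      rec$image <- i
      rec$fold <- f
      records[[length(records) + 1L]] <- rec
    }
    if (keep_models) models[[f]] <- fit$model
    if (verbose)
      message(sprintf("fold %d/%d done (test images: %s)", f, plan$k,
                      paste(test_idx, collapse = ", ")))
  }
  records <- do.call(rbind, records)
  res <- list(records = records, summary = summarise_records(records),
              fold_plan = plan, histories = histories,
              models = if (keep_models) models,
              seeds = list(master = config$train$seed,
                           folds = config$train$seed + seq_len(plan$k)))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records,
                     file.path(config$output_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary,
                     file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
  }
  res
}

#' HAC-count ablation harness
#'
#' Re-runs the cross-validation once per HAC module count in
#' `config$ablation_hac_counts` (0 = plain RU-Net; modules fill the
#' deep-to-shallow sites res4, res3, res2, res1, conv_block, final) and
#' tabulates the pooled Dice per count.
#'
#' @inheritParams run_crossval
#' @return data.frame with columns `hacs`, `dice`, `dice_sd`, `iou`,
#'   `mhd`.
#' @export
run_ablation <- function(config = run_config(), samples = NULL,
                         verbose = FALSE) {
  counts <- config$ablation_hac_counts
  if (length(counts) == 0L)
    stop("ablation_hac_counts must be nonempty", call. = FALSE)
  if (is.null(samples))
    samples <- generate_dataset(config$n_images, config$phantom,
                                seed = config$train$seed)
  rows <- lapply(counts, function(cnt) {
    cfg <- config
    cfg$model$hac_placement <- hac_placement_for_count(cnt)
    cv <- run_crossval(cfg, samples = samples, keep_models = FALSE,
                       verbose = verbose)
    s <- cv$summary
    data.frame(hacs = cnt,
               dice = s$mean[s$metric == "dice"],
               dice_sd = s$sd[s$metric == "dice"],
               iou = s$mean[s$metric == "iou"],
               mhd = s$mean[s$metric == "mhd"])
  })
  out <- do.call(rbind, rows)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(config$output_dir, "ablation.csv"),
                     row.names = FALSE)
  }
  out
}

#' Read a pipeline configuration from JSON
#'
#' The file may hold any subset of the sections `phantom`, `train`,
#' `model`, plus the scalars `n_images`, `ablation_hac_counts` and
#' `output_dir`; omitted fields take the package defaults.  The same
#' structure is written by [run_config_to_json()], so configurations
#' round-trip.
#'
#' @param path JSON file path.
#' @return a [run_config()].
#' @export
run_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_args <- function(x) if (is.null(x)) list() else as.list(x)
  mo <- as_args(j$model)
  if (!is.null(mo$hac)) mo$hac <- do.call(hac_spec, as.list(mo$hac))
  if (!is.null(mo$reduced_channels))
    mo$reduced_channels <- unlist(mo$reduced_channels)
  cfg <- run_config(
    phantom = do.call(phantom_params, as_args(j$phantom)),
    train = do.call(train_config, as_args(j$train)),
    model = do.call(model_config, mo))
  if (!is.null(j$n_images)) cfg$n_images <- as.integer(j$n_images)
  if (!is.null(j$ablation_hac_counts))
    cfg$ablation_hac_counts <- as.integer(j$ablation_hac_counts)
  if (!is.null(j$output_dir)) cfg$output_dir <- j$output_dir
  cfg
}

#' @rdname run_config_from_json
#' @param config a [run_config()] to serialise.
#' @export
run_config_to_json <- function(config, path) {
  out <- list(phantom = unclass(config$phantom),
              train = unclass(config$train),
              model = unclass(config$model),
              n_images = config$n_images,
              ablation_hac_counts = config$ablation_hac_counts,
              output_dir = config$output_dir)
  out$model$hac <- unclass(out$model$hac)
  out$model$reduced_channels <- as.list(out$model$reduced_channels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
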