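# End-to-end orchestration: preprocess -> segment -> post-process ->
# measure for inference, and the repeated train/evaluate experiment that
# produces the per-variant metric table.

fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_run_metadata <- function(out_dir, config_list, seed) {
  js <- jsonlite::toJSON(config_list, auto_unbox = TRUE, digits = NA)
  meta <- list(config_hash = fnv1a(as.character(js)), seed = seed,
               r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("raseg")))
  jsonlite::write_json(meta, file.path(out_dir, "run-metadata.json"),
                       auto_unbox = TRUE)
}

#' Run the inference pipeline on a set of frames
#'
#' For every frame: crop the scan region ([strip_periphery()]), resize to
#' the model grid ([resize_to_model()]), predict the probability map,
#' binarize at 0.5, keep the two largest components, measure the
#' inter-muscle distance and apply the diastasis rule. Per-frame failures
#' are caught, reported as invalid rows, and do not stop the batch.
#'
#' @param model a trained `ra_model` (or a checkpoint path).
#' @param frames list of `ra_frame` objects.
#' @param target_size model grid side length (must suit the model's depth).
#' @param preprocess set `FALSE` when frames are already cropped and on the
#'   model grid.
#' @param threshold binarization threshold for the probability map.
#' @param dra_threshold_mm diastasis decision threshold in mm.
#' @param out_dir optional output directory: per-frame masks (PNG), a
#'   `results.csv` summary, per-frame JSON results and a run-metadata JSON
#'   are written there.
#' @return data.frame with one row per frame: `source_id`, `d_px`, `px_mm`,
#'   `D_mm`, `n_regions`, `label`, `valid`.
#' @export
run_predict <- function(model, frames, target_size = 512L, preprocess = TRUE,
                        threshold = 0.5, dra_threshold_mm = 25,
                        out_dir = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    rows[[i]] <- tryCatch({
      f <- if (preprocess) resize_to_model(strip_periphery(fr)$cropped, target_size) else fr
      p <- predict_prob(model, f)
      m <- keep_two_largest(binarize(p, threshold, pixel_size_mm = f$pixel_size_mm))
      meas <- measure_distance(m, dra_threshold_mm = dra_threshold_mm)
      if (!is.null(out_dir)) {
        write_frame_png(m, file.path(out_dir, sprintf("mask%04d.png", i)))
        jsonlite::write_json(
          list(source_id = fr$source_id, d_px = meas$d_px, px_mm = meas$px_mm,
               D_mm = meas$D_mm, n_regions = meas$n_regions,
               label = classify_dra(meas, dra_threshold_mm)),
          file.path(out_dir, sprintf("result%04d.json", i)), auto_unbox = TRUE)
      }
      data.frame(source_id = fr$source_id, d_px = meas$d_px, px_mm = meas$px_mm,
                 D_mm = meas$D_mm, n_regions = meas$n_regions,
                 label = classify_dra(meas, dra_threshold_mm), valid = meas$valid)
    }, error = function(e) {
      warning(sprintf("frame %d (%s) skipped: %s", i, fr$source_id,
                      conditionMessage(e)), call. = FALSE)
      data.frame(source_id = fr$source_id, d_px = NA_integer_, px_mm = NA_real_,
                 D_mm = NA_real_, n_regions = NA_integer_,
                 label = "invalid", valid = FALSE)
    })
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    write_run_metadata(out_dir, list(target_size = target_size,
                                     threshold = threshold,
                                     dra_threshold_mm = dra_threshold_mm),
                       seed = NA)
  }
  res
}

#' Repeated train/evaluate experiment over model variants
#'
#' For each repeat (seed offset by the repeat index) the dataset is split at
#' the patient level, each requested variant is trained from scratch on the
#' identical split, and the held-out test images are segmented, post-
#' processed and evaluated ([evaluate_masks()]). Aggregates are mean +/- sd
#' over repeats of the per-repeat test-set means.
#'
#' @param dataset list of samples (`patient_id`, `image`, `mask`), e.g. from
#'   [generate_dataset()].
#' @param variants subset of `c("plain", "nested", "residual")`.
#' @param n_repeats independent repeats (seed = `seed + repeat - 1`).
#' @param depth,base_channels architecture scale (see [net_config()]).
#' @param config an [train_config()]; its seed is overridden per repeat.
#' @param ratio patient-level split ratio.
#' @param seed base seed.
#' @param out_dir optional directory for the per-repeat and summary CSVs.
#' @return list: `per_repeat` data.frame (one row per repeat x variant) and
#'   `summary` data.frame (mean/sd per variant per metric).
#' @export
run_experiment <- function(dataset, variants = c("plain", "nested", "residual"),
                           n_repeats = 5L, depth = 3L, base_channels = 8L,
                           config = train_config(), ratio = c(7, 1, 2),
                           seed = 1L, out_dir = NULL) {
  pids <- vapply(dataset, function(s) as.character(s$patient_id), "")
  rows <- list()
  for (r in seq_len(n_repeats)) {
    seed_r <- seed + r - 1L
    split <- split_patients(pids, ratio = ratio, seed = seed_r)
    te <- which(split$assignment[pids] == "test")
    for (v in variants) {
      model <- build_model(net_config(v, depth = depth, base_channels = base_channels),
                           seed = seed_r)
      cfg <- config
      cfg$seed <- seed_r
      fitres <- fit(model, dataset, split, cfg)
      pred <- lapply(dataset[te], function(s) {
        img <- if (inherits(s$image, "ra_frame")) s$image$pixels else s$image
        ps <- mask_pixel_size(s$mask)
        keep_two_largest(binarize(predict_prob(fitres$model, img),
                                  pixel_size_mm = ps))
      })
      gt <- lapply(dataset[te], function(s) s$mask)
      ev <- evaluate_masks(pred, gt)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_idx = r, variant = v,
        dice_pct = ev$aggregate["mean", "dice_pct"],
        iou_pct = ev$aggregate["mean", "iou_pct"],
        hd_mm = ev$aggregate["mean", "hd_mm"],
        apde_mm = ev$apde_mm, pearson_r = ev$pearson_r,
        best_epoch = fitres$best_epoch, n_test = length(te))
    }
  }
  per_repeat <- do.call(rbind, rows)
  metrics <- c("dice_pct", "iou_pct", "hd_mm", "apde_mm", "pearson_r")
  summary <- do.call(rbind, lapply(unique(per_repeat$variant), function(v) {
    sub <- per_repeat[per_repeat$variant == v, ]
    out <- data.frame(variant = v)
    for (m in metrics) {
      ms <- mean_sd(sub[[m]])
      out[[paste0(m, "_mean")]] <- ms["mean"]
      out[[paste0(m, "_sd")]] <- ms["sd"]
    }
    out
  }))
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_repeat, file.path(out_dir, "per-repeat.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write_run_metadata(out_dir, list(variants = variants, n_repeats = n_repeats,
                                     depth = depth, base_channels = base_channels,
                                     ratio = ratio), seed = seed)
  }
  list(per_repeat = per_repeat, summary = summary)
}

#' Read a YAML run configuration
#'
#' Convenience reader for the command-line interface: returns the YAML
#' content as a list, with `train` entries converted to a [train_config()]
#' when present.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$train)) cfg$train <- do.call(train_config, cfg$train)
  cfg
}

#' Desk-scale end-to-end benchmark on synthetic phantoms
#'
#' Generates a patient-structured phantom dataset (56 patients, 5 views each,
#' 128 x 128 at 0.5 mm/pixel), splits it 40/8/8 patients (200 train, 40
#' validation, 40 test images), trains a residual-variant network (depth 3,
#' 8 base channels, batch 8, learning rate 0.001, at most `max_epochs`
#' epochs) and evaluates segmentation and distance agreement on the held-out
#' test images. The phantom ground-truth gap plays the role of the manual
#' reference measurement.
#'
#' @param seed seed controlling data generation, split, initialization and
#'   training.
#' @param variant architecture variant (default `"residual"`).
#' @param max_epochs training epoch cap (default 8).
#' @param patience early-stop patience on validation Dice.
#' @return list: `eval` (an [evaluate_masks()] report on the test images),
#'   `pearson_true_vs_pred` (correlation of predicted vs true gap in mm),
#'   `bland_altman` (true vs predicted gap, mm), `history`, `n_test`.
#' @export
benchmark_end_to_end <- function(seed = 1L, variant = "residual",
                                 max_epochs = 8L, patience = 5L) {
  seed <- as.integer(seed)
  ds <- generate_dataset(56, images_per_patient = c(5L, 5L), seed = seed)
  pids <- vapply(ds, function(s) s$patient_id, "")
  split <- split_patients(pids, ratio = c(5, 1, 1), seed = seed)
  model <- build_model(net_config(variant, depth = 3L, base_channels = 8L),
                       seed = seed)
  cfg <- train_config(max_epochs = max_epochs, early_stop_patience = patience,
                      seed = seed)
  fitres <- fit(model, ds, split, cfg)
  te <- which(split$assignment[pids] == "test")
  pred <- lapply(ds[te], function(s)
    keep_two_largest(binarize(predict_prob(fitres$model, s$image$pixels),
                              pixel_size_mm = attr(s$mask, "pixel_size_mm"))))
  gt <- lapply(ds[te], function(s) s$mask)
  ev <- evaluate_masks(pred, gt)
  true_mm <- vapply(ds[te], function(s) s$true_gap_mm, 0)
  pred_mm <- ev$per_image$d_pred_px * ev$per_image$px_mm
  list(eval = ev,
       pearson_true_vs_pred = pearson_r(true_mm, pred_mm),
       bland_altman = bland_altman(true_mm, pred_mm),
       history = fitres$history, best_epoch = fitres$best_epoch,
       pixel_size_mm = 0.5, n_test = length(te))
}
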