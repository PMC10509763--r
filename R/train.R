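# Training protocol: patient-level splitting, flip/contrast augmentation,
# binary cross-entropy loss, and an Adam fit loop with best-checkpoint
# selection on validation Dice and early stopping.

#' Split patients into train/validation/test subsets
#'
#' Patients (not images) are the unit of splitting, so that no patient's
#' images leak across subsets. Ids are permuted by the seed and allocated
#' contiguously; counts follow the ratio by largest-remainder rounding, so
#' every subset deviates from its exact proportion by at most one patient.
#' When at least three patients are available, every subset is guaranteed
#' non-empty (a patient is moved from the largest subset if rounding left
#' one empty).
#'
#' @param patient_ids character vector of patient identifiers (duplicates
#'   allowed; the unique set is split).
#' @param ratio non-negative weights for (train, val, test); default 7:1:2.
#' @param seed RNG seed for the permutation.
#' @return object of class `ra_split`: `assignment`, a named character
#'   vector mapping patient id to `"train"`, `"val"` or `"test"`; `ratio`;
#'   `counts`.
#' @export
split_patients <- function(patient_ids, ratio = c(7, 1, 2), seed = 1L) {
  ids <- unique(as.character(patient_ids))
  if (length(ids) < 3L) stopf("need at least 3 patients to split")
  if (length(ratio) != 3L || any(ratio < 0) || sum(ratio) <= 0)
    stopf("ratio must be three non-negative weights")
  set.seed(as.integer(seed))
  perm <- sample(ids)
  n <- length(ids)
  exact <- n * ratio / sum(ratio)
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(-(exact - counts))[seq_len(rem)] # ties: earlier subset first
    counts[extra] <- counts[extra] + 1
  }
  # guarantee non-empty subsets
  while (any(counts == 0)) {
    counts[which.max(counts)] <- max(counts) - 1
    counts[which(counts == 0)[1L]] <- 1
  }
  subset <- rep(c("train", "val", "test"), times = counts)
  assignment <- stats::setNames(subset, perm)
  structure(list(assignment = assignment, ratio = ratio,
                 counts = stats::setNames(as.integer(counts), c("train", "val", "test"))),
            class = "ra_split")
}

#' @export
print.ra_split <- function(x, ...) {
  cat(sprintf("<ra_split: %d patients -> train %d / val %d / test %d>\n",
              length(x$assignment), x$counts[1], x$counts[2], x$counts[3]))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the optimization protocol used throughout: Adam with
#' learning rate 0.001 and first-moment decay 0.9, batch size 8, up to 100
#' epochs with early stopping (patience 15) on the validation Dice, and
#' horizontal-flip plus contrast augmentation.
#'
#' @param learning_rate Adam step size.
#' @param beta1 first-moment decay (the "momentum" of the optimizer).
#' @param beta2 second-moment decay.
#' @param batch_size images per optimization step.
#' @param max_epochs upper bound on epochs.
#' @param early_stop_patience stop after this many epochs without a new
#'   best validation Dice.
#' @param flip_prob probability of mirroring image and mask about the
#'   vertical axis.
#' @param contrast_range uniform range of the contrast gain applied to the
#'   image only, centered at intensity 128.
#' @param seed RNG seed controlling shuffling and augmentation.
#' @return object of class `ra_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 8L, max_epochs = 100L,
                         early_stop_patience = 15L, flip_prob = 0.5,
                         contrast_range = c(0.7, 1.3), seed = 1L) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (flip_prob < 0 || flip_prob > 1) stopf("flip_prob must lie in [0, 1]")
  if (length(contrast_range) != 2L || contrast_range[1] > contrast_range[2])
    stopf("contrast_range must be c(low, high) with low <= high")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 flip_prob = flip_prob, contrast_range = as.numeric(contrast_range),
                 seed = as.integer(seed)),
            class = "ra_train_config")
}

#' Augment an image/mask pair
#'
#' With probability `flip_prob` both image and mask are mirrored about the
#' vertical axis; a contrast gain drawn uniformly from `contrast_range` is
#' then applied to the image only, pivoting at intensity 128 and clipping to
#' `[0, 255]`. The mask stays strictly binary.
#'
#' @param image intensity matrix in `[0, 255]`.
#' @param mask binary matrix on the same grid.
#' @param config an [train_config()].
#' @param seed optional seed; omit to draw from the current RNG stream.
#' @return list `(image, mask)`.
#' @export
augment <- function(image, mask, config = train_config(), seed = NULL) {
  if (!identical(dim(image), dim(mask))) stopf("image and mask must share a grid")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (runif(1) < config$flip_prob) {
    image <- image[, ncol(image):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  gain <- runif(1, config$contrast_range[1], config$contrast_range[2])
  image <- clamp255(128 + gain * (image - 128))
  list(image = image, mask = mask)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log x + (1-y) log(1-x)]` with predictions
#' clamped to `[eps, 1-eps]`, `eps = 1e-7`. Both foreground and background
#' errors are penalized (a foreground-only sum would be minimized by an
#' all-ones prediction).
#'
#' @param pred probabilities in `[0, 1]` (matrix or array).
#' @param gt binary ground truth of the same shape.
#' @return non-negative scalar loss.
#' @export
bce_loss <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stopf("pred and gt must share a shape")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  y <- as.numeric(gt)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# stack a list of matrices into (H, W, 1, N)
stack4 <- function(ms) {
  d <- dim(ms[[1]])
  array(unlist(ms, use.names = FALSE), c(d[1], d[2], 1L, length(ms)))
}

# validation metrics: mean Dice / IoU of thresholded predictions
validate_model <- function(model, images, masks, batch_size) {
  dices <- numeric(length(images))
  ious <- numeric(length(images))
  i <- 1L
  while (i <= length(images)) {
    idx <- i:min(i + batch_size - 1L, length(images))
    x4 <- stack4(images[idx]) / 255
    fw <- net_forward(model, x4, train = FALSE)
    p4 <- tp_val(fw$tape, fw$out)
    for (u in seq_along(idx)) {
      pm <- binarize(matrix(p4[, , 1L, u], dim(x4)[1], dim(x4)[2]))
      gm <- masks[[idx[u]]]
      if (sum(pm) + sum(gm) == 0L) {
        dices[idx[u]] <- 100; ious[idx[u]] <- 100
      } else {
        dices[idx[u]] <- as.numeric(dice(pm, as_mask(gm)))
        ious[idx[u]] <- as.numeric(miou(pm, as_mask(gm)))
      }
    }
    i <- i + batch_size
  }
  c(dice = mean(dices), iou = mean(ious))
}

#' Fit a segmentation model
#'
#' Adam optimization of the binary cross-entropy over the training images,
#' with per-epoch validation (inference mode, no parameter updates): the
#' parameters achieving the best validation Dice are kept, and training
#' stops early after `early_stop_patience` epochs without improvement.
#'
#' @param model an `ra_model` from [build_model()]; updated in place and
#'   left holding the best-validation parameters.
#' @param dataset list of samples, each a list with `patient_id`, `image`
#'   (intensity matrix) and `mask` (binary matrix). `ra_phantom` samples
#'   work directly (`image` may be an `ra_frame`).
#' @param split an [split_patients()] result covering the dataset's
#'   patients.
#' @param config an [train_config()].
#' @return list: `model`, `history` (data.frame with `epoch`, `train_loss`,
#'   `val_dice`, `val_iou`), `best_epoch`, `best_val_dice`.
#' @export
fit <- function(model, dataset, split, config = train_config()) {
  stopifnot(inherits(model, "ra_model"), inherits(split, "ra_split"),
            inherits(config, "ra_train_config"))
  get_img <- function(s) if (inherits(s$image, "ra_frame")) s$image$pixels else s$image
  subsets <- split$assignment[vapply(dataset, function(s) as.character(s$patient_id), "")]
  tr <- which(subsets == "train")
  va <- which(subsets == "val")
  if (length(tr) == 0L || length(va) == 0L)
    stopf("train and validation subsets must both be non-empty")
  tr_img <- lapply(dataset[tr], get_img)
  tr_msk <- lapply(dataset[tr], function(s) matrix(as.integer(s$mask), nrow(s$mask), ncol(s$mask)))
  va_img <- lapply(dataset[va], get_img)
  va_msk <- lapply(dataset[va], function(s) matrix(as.integer(s$mask), nrow(s$mask), ncol(s$mask)))
  check_grid(model, nrow(tr_img[[1]]), ncol(tr_img[[1]]))

  set.seed(config$seed)
  adam_m <- list(); adam_v <- list(); step <- 0L
  best <- -Inf; best_params <- NULL; best_state <- NULL; best_epoch <- 0L
  since_improve <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric(), val_iou = numeric())

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(seq_along(tr_img))
    losses <- numeric()
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      imgs <- vector("list", length(idx)); msks <- vector("list", length(idx))
      for (u in seq_along(idx)) {
        a <- augment(tr_img[[idx[u]]], tr_msk[[idx[u]]], config)
        imgs[[u]] <- a$image; msks[[u]] <- a$mask
      }
      x4 <- stack4(imgs) / 255
      y4 <- stack4(msks)
      fw <- net_forward(model, x4, train = TRUE)
      p4 <- tp_val(fw$tape, fw$out)
      losses <- c(losses, bce_loss(p4, y4))
      M <- length(p4)
      gout <- (p4 - y4) / (pmax(p4 * (1 - p4), 1e-12)) / M
      grads <- tape_backward(fw$tape, fw$out, gout)
      step <- step + 1L
      lr_t <- config$learning_rate *
        sqrt(1 - config$beta2^step) / (1 - config$beta1^step)
      for (nm in names(grads)) {
        g <- grads[[nm]]
        if (is.null(adam_m[[nm]])) { adam_m[[nm]] <- g * 0; adam_v[[nm]] <- g * 0 }
        adam_m[[nm]] <- config$beta1 * adam_m[[nm]] + (1 - config$beta1) * g
        adam_v[[nm]] <- config$beta2 * adam_v[[nm]] + (1 - config$beta2) * g^2
        model$params[[nm]] <- model$params[[nm]] -
          lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + 1e-8)
      }
      i <- i + config$batch_size
    }
    vm <- validate_model(model, va_img, va_msk, config$batch_size)
    vd <- unname(vm["dice"])
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dice = vd, val_iou = unname(vm["iou"])))
    if (vd > best) {
      best <- vd; best_epoch <- epoch
      best_params <- model$params; best_state <- model$state
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$early_stop_patience) break
    }
  }
  model$params <- best_params
  model$state <- best_state
  rownames(history) <- NULL
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_dice = best)
}
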