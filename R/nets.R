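# The three encoder-decoder segmentation architectures: a plain U-shaped
# network with skip concatenation, a nested-skip variant with dense
# intermediate decoder nodes, and a residual variant whose convolution
# blocks carry identity shortcuts. All emit a single-channel sigmoid
# probability map on the input grid.

#' Configure a segmentation network
#'
#' @param variant `"plain"` (classic U-shaped encoder-decoder),
#'   `"nested"` (dense intermediate skip nodes, deepest-node output) or
#'   `"residual"` (residual convolution blocks with identity shortcuts).
#' @param depth number of resolution levels (default 5; tests use 3).
#'   Input grids must be divisible by `2^(depth-1)`.
#' @param base_channels channel width at the top level, doubled per level
#'   (default 64; reducible to 8 for desk-scale runs).
#' @param in_channels input channels (1 for grayscale ultrasound).
#' @return object of class `ra_net_config`.
#' @export
net_config <- function(variant = c("plain", "nested", "residual"),
                       depth = 5L, base_channels = 64L, in_channels = 1L) {
  variant <- match.arg(variant)
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  if (is.na(depth) || depth < 2L) stopf("depth must be an integer >= 2")
  if (is.na(base_channels) || base_channels < 1L) stopf("base_channels must be >= 1")
  if (in_channels != 1L) stopf("only single-channel input is supported")
  structure(list(variant = variant, depth = depth,
                 base_channels = base_channels, in_channels = 1L),
            class = "ra_net_config")
}

# double-conv block (plain/nested) or residual block (residual variant)
net_block <- function(tp, id, name, cout, variant) {
  if (variant == "residual") {
    cin <- dim(tp_val(tp, id))[3]
    h <- ag_conv(tp, id, paste0(name, ".c1"), cout, 3L)
    h <- ag_bn(tp, h, paste0(name, ".n1"))
    h <- ag_relu(tp, h)
    h <- ag_conv(tp, h, paste0(name, ".c2"), cout, 3L)
    h <- ag_bn(tp, h, paste0(name, ".n2"))
    sc <- if (cin == cout) id else {
      s <- ag_conv(tp, id, paste0(name, ".sc"), cout, 1L)
      ag_bn(tp, s, paste0(name, ".sn"))
    }
    ag_relu(tp, ag_add(tp, h, sc))
  } else {
    h <- ag_conv(tp, id, paste0(name, ".c1"), cout, 3L)
    h <- ag_bn(tp, h, paste0(name, ".n1"))
    h <- ag_relu(tp, h)
    h <- ag_conv(tp, h, paste0(name, ".c2"), cout, 3L)
    h <- ag_bn(tp, h, paste0(name, ".n2"))
    ag_relu(tp, h)
  }
}

# forward pass; x4 is (H, W, 1, N) in [0, 1]. Returns list(tape, out_id).
net_forward <- function(model, x4, train = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  ch <- cfg$base_channels * 2L^(0:(d - 1L))
  tp <- tape_new(model, train)
  id <- ag_input(tp, x4)
  blk_variant <- if (cfg$variant == "residual") "residual" else "plain"
  if (cfg$variant %in% c("plain", "residual")) {
    skips <- integer(d - 1L)
    for (i in seq_len(d)) {
      id <- net_block(tp, id, sprintf("enc%d", i), ch[i], blk_variant)
      if (i < d) {
        skips[i] <- id
        id <- ag_pool(tp, id)
      }
    }
    for (i in rev(seq_len(d - 1L))) {
      id <- ag_tconv(tp, id, sprintf("up%d", i), ch[i])
      id <- ag_concat(tp, c(skips[i], id))
      id <- net_block(tp, id, sprintf("dec%d", i), ch[i], blk_variant)
    }
  } else { # nested: grid of nodes X[i,j], backbone j = 0
    X <- vector("list", d)
    for (i in seq_len(d)) X[[i]] <- vector("list", d)
    id0 <- id
    for (i in seq_len(d)) {
      inp <- if (i == 1L) id0 else ag_pool(tp, X[[i - 1L]][[1L]])
      X[[i]][[1L]] <- net_block(tp, inp, sprintf("x%d_0", i), ch[i], "plain")
    }
    for (j in seq_len(d - 1L)) {
      for (i in seq_len(d - j)) {
        up <- ag_tconv(tp, X[[i + 1L]][[j]], sprintf("u%d_%d", i, j), ch[i])
        prev <- vapply(seq_len(j), function(q) X[[i]][[q]], 0L)
        X[[i]][[j + 1L]] <- net_block(tp, ag_concat(tp, c(prev, up)),
                                      sprintf("x%d_%d", i, j), ch[i], "plain")
      }
    }
    id <- X[[1L]][[d]]
  }
  id <- ag_conv(tp, id, "head", 1L, 1L)
  id <- ag_sigmoid(tp, id)
  list(tape = tp, out = id)
}

#' Build a segmentation model
#'
#' Parameters are initialized with seeded He-normal draws, so the same
#' config and seed always produce identical parameters.
#'
#' @param config an [net_config()].
#' @param seed RNG seed for the parameter initialization.
#' @return model environment of class `ra_model` with fields `config`,
#'   `params` (flat named list of arrays) and `state` (batch-norm running
#'   statistics).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ra_net_config"))
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- list()
  model$state <- list()
  class(model) <- "ra_model"
  set.seed(as.integer(seed))
  s <- 2L^(config$depth - 1L) # smallest legal grid materializes every parameter
  invisible(net_forward(model, array(0, c(2L * s, 2L * s, 1L, 1L)), train = FALSE))
  model
}

#' @export
print.ra_model <- function(x, ...) {
  cat(sprintf("<ra_model %s: depth %d, base %d channels, %d parameters>\n",
              x$config$variant, x$config$depth, x$config$base_channels,
              n_params(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model an `ra_model`.
#' @return integer count.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 0L))

check_grid <- function(model, h, w) {
  s <- 2L^(model$config$depth - 1L)
  if (h %% s != 0L || w %% s != 0L)
    stopf("input grid %d x %d is not divisible by 2^(depth-1) = %d", h, w, s)
}

#' Predict a foreground probability map
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' parameter update); deterministic for fixed parameters. Intensities are
#' scaled to `[0, 1]` internally.
#'
#' @param model an `ra_model`.
#' @param frame an `ra_frame`, or a matrix of intensities in `[0, 255]`.
#' @return numeric matrix of probabilities in `[0, 1]` on the input grid,
#'   with the frame's `pixel_size_mm` attached as an attribute.
#' @export
predict_prob <- function(model, frame) {
  stopifnot(inherits(model, "ra_model"))
  px <- if (inherits(frame, "ra_frame")) frame$pixels else frame
  if (!is.matrix(px)) stopf("frame must be an ra_frame or a matrix")
  check_grid(model, nrow(px), ncol(px))
  fw <- net_forward(model, array(px / 255, c(nrow(px), ncol(px), 1L, 1L)),
                    train = FALSE)
  p <- matrix(tp_val(fw$tape, fw$out), nrow(px), ncol(px))
  if (inherits(frame, "ra_frame")) attr(p, "pixel_size_mm") <- frame$pixel_size_mm
  p
}

#' @rdname predict_prob
#' @param object,... S3 method arguments (`object` is the model, the first
#'   element of `...` the frame).
#' @export
predict.ra_model <- function(object, ...) predict_prob(object, ..1)

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the parameters, the batch-norm
#' state and the architecture config (with a JSON copy of the config
#' embedded for inspection).
#'
#' @param model an `ra_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `ra_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               config_json = jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE),
               params = model$params, state = model$state),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$config <- structure(ck$config, class = "ra_net_config")
  model$params <- ck$params
  model$state <- ck$state
  class(model) <- "ra_model"
  model
}
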