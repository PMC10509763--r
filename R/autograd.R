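# Minimal reverse-mode autograd over 4-D feature maps (H, W, C, N), backing
# the encoder-decoder networks. The tape records one entry per operation;
# gradients flow backwards through the records. Convolutions, pooling and
# transposed convolutions run in compiled code (see src/kernels.cpp);
# batch normalization and the pointwise ops are vectorized R.
#
# Parameters live in a flat named list on the model environment; a
# parameter that does not yet exist is materialized (seeded He init) the
# first time the graph touches it, so one forward pass on a dummy input
# builds the whole parameter set of any architecture.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

tape_new <- function(model, train) {
  tp <- new.env(parent = emptyenv())
  tp$model <- model
  tp$train <- isTRUE(train)
  tp$vals <- list()
  tp$recs <- list()
  tp$n <- 0L
  tp
}

tp_val <- function(tp, id) {
  force(id) # nested op calls in the argument must emit before vals is read
  tp$vals[[id]]
}

tp_emit <- function(tp, val, rec) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  rec$out <- tp$n
  tp$recs[[length(tp$recs) + 1L]] <- rec
  return(tp$n)
}

ag_input <- function(tp, x) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- x
  tp$n
}

need_param <- function(model, name, init) {
  if (is.null(model$params[[name]])) model$params[[name]] <- init()
  model$params[[name]]
}

ag_conv <- function(tp, id, name, cout, k = 3L) {
  x <- tp_val(tp, id)
  cin <- dim(x)[3]
  W <- need_param(tp$model, paste0(name, ".W"), function()
    matrix(rnorm(cout * cin * k * k, 0, sqrt(2 / (cin * k * k))), cout))
  b <- need_param(tp$model, paste0(name, ".b"), function() numeric(cout))
  y <- cpp_conv_fwd(x, W, b, k)
  tp_emit(tp, y, list(op = "conv", x = id, name = name, k = k))
}

ag_tconv <- function(tp, id, name, cout) {
  x <- tp_val(tp, id)
  cin <- dim(x)[3]
  W <- need_param(tp$model, paste0(name, ".W"), function()
    matrix(rnorm(4 * cout * cin, 0, sqrt(2 / (4 * cin))), 4 * cout))
  b <- need_param(tp$model, paste0(name, ".b"), function() numeric(cout))
  y <- cpp_tconv_fwd(x, W, b)
  tp_emit(tp, y, list(op = "tconv", x = id, name = name))
}

# channel-wise batch normalization; per-channel stats over (H, W, N)
ag_bn <- function(tp, id, name) {
  x <- tp_val(tp, id)
  C <- dim(x)[3]
  gamma <- need_param(tp$model, paste0(name, ".gamma"), function() rep(1, C))
  beta <- need_param(tp$model, paste0(name, ".beta"), function() numeric(C))
  st <- tp$model$state
  if (is.null(st[[paste0(name, ".mean")]])) {
    st[[paste0(name, ".mean")]] <- numeric(C)
    st[[paste0(name, ".var")]] <- rep(1, C)
    tp$model$state <- st
  }
  r <- cpp_bn_fwd(x, gamma, beta,
                  tp$model$state[[paste0(name, ".mean")]],
                  tp$model$state[[paste0(name, ".var")]],
                  tp$train, BN_MOMENTUM, BN_EPS)
  if (tp$train) {
    st <- tp$model$state
    st[[paste0(name, ".mean")]] <- r$run_mean
    st[[paste0(name, ".var")]] <- r$run_var
    tp$model$state <- st
  }
  tp_emit(tp, r$y, list(op = "bn", x = id, name = name,
                        cache = list(mu = r$mu, inv_std = r$inv_std)))
}

ag_relu <- function(tp, id) {
  x <- tp_val(tp, id)
  tp_emit(tp, x * (x > 0), list(op = "relu", x = id))
}

ag_pool <- function(tp, id) {
  x <- tp_val(tp, id)
  r <- cpp_maxpool_fwd(x)
  tp_emit(tp, r$y, list(op = "pool", x = id,
                        cache = list(argmax = r$argmax, xdim = dim(x))))
}

ag_concat <- function(tp, ids) {
  xs <- lapply(ids, function(i) tp_val(tp, i))
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], 0)
  y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (x in xs) {
    y[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  tp_emit(tp, y, list(op = "concat", x = ids, cache = list(chans = cs)))
}

ag_add <- function(tp, id1, id2) {
  tp_emit(tp, tp_val(tp, id1) + tp_val(tp, id2), list(op = "add", x = c(id1, id2)))
}

ag_sigmoid <- function(tp, id) {
  x <- tp_val(tp, id)
  y <- array(plogis(x), dim(x))
  tp_emit(tp, y, list(op = "sigmoid", x = id))
}

# reverse pass: returns named list of parameter gradients
tape_backward <- function(tp, out_id, gout) {
  vg <- vector("list", tp$n)
  vg[[out_id]] <- gout
  pg <- list()
  add_pg <- function(name, g) {
    pg[[name]] <<- if (is.null(pg[[name]])) g else pg[[name]] + g
  }
  add_vg <- function(id, g) {
    vg[[id]] <<- if (is.null(vg[[id]])) g else vg[[id]] + g
  }
  params <- tp$model$params
  for (rec in rev(tp$recs)) {
    gy <- vg[[rec$out]]
    if (is.null(gy)) next
    vg[[rec$out]] <- NA # free
    switch(rec$op,
      conv = {
        r <- cpp_conv_bwd(tp_val(tp, rec$x), params[[paste0(rec$name, ".W")]], gy, rec$k)
        add_pg(paste0(rec$name, ".W"), r$gW)
        add_pg(paste0(rec$name, ".b"), r$gb)
        add_vg(rec$x, r$gx)
      },
      tconv = {
        r <- cpp_tconv_bwd(tp_val(tp, rec$x), params[[paste0(rec$name, ".W")]], gy)
        add_pg(paste0(rec$name, ".W"), r$gW)
        add_pg(paste0(rec$name, ".b"), r$gb)
        add_vg(rec$x, r$gx)
      },
      bn = {
        r <- cpp_bn_bwd(tp_val(tp, rec$x), gy, params[[paste0(rec$name, ".gamma")]],
                        rec$cache$mu, rec$cache$inv_std, tp$train)
        add_pg(paste0(rec$name, ".gamma"), r$ggamma)
        add_pg(paste0(rec$name, ".beta"), r$gbeta)
        add_vg(rec$x, r$gx)
      },
      relu = {
        x <- tp_val(tp, rec$x)
        add_vg(rec$x, gy * (x > 0))
      },
      pool = {
        add_vg(rec$x, cpp_maxpool_bwd(gy, rec$cache$argmax, rec$cache$xdim))
      },
      concat = {
        at <- 0L
        for (u in seq_along(rec$x)) {
          ck <- rec$cache$chans[u]
          add_vg(rec$x[u], gy[, , at + seq_len(ck), , drop = FALSE])
          at <- at + ck
        }
      },
      add = {
        add_vg(rec$x[1], gy)
        add_vg(rec$x[2], gy)
      },
      sigmoid = {
        y <- tp_val(tp, rec$out)
        add_vg(rec$x, gy * y * (1 - y))
      },
      stopf("unknown op in tape: %s", rec$op))
  }
  pg
}
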