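#' Configuration of the residual 3D CNN age regressor
#'
#' The architecture is a parameterised 3D ResNet: a stride-2 stem 3x3x3
#' convolution to `channels[1]` (halving each spatial dimension, as
#' ResNet stems do), then one stage per entry of `channels` (each later
#' stage opens with a stride-2 downsampling convolution) holding
#' `n_residual_blocks` identity residual blocks (conv-BN-ReLU-conv-BN
#' plus skip, ReLU), a global average pool, and a linear head producing
#' one age in years. Training minimises mean squared error with Adam.
#'
#' @param input_shape integer length 3; volume dimensions.
#' @param channels integer vector, one entry per resolution stage.
#' @param n_residual_blocks residual blocks per stage; a single number
#'   is recycled, a vector gives each stage its own depth (0 allowed,
#'   e.g. `c(0, 1, 1)` keeps the costly full-resolution stage shallow).
#' @param use_batch_norm use batch normalisation (default TRUE).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param n_epochs training epochs (>= 0).
#' @param normalize z-score each input volume (mean 0, sd 1) before the
#'   network sees it.
#' @param bias_method default bias-correction form for downstream use:
#'   `"invert"` or `"residual"` (see [apply_bias_correction()]).
#' @param seed integer seed for parameter initialisation and shuffling.
#' @return a `model_config` list.
#' @export
model_config <- function(input_shape, channels = c(8L, 16L, 32L),
                         n_residual_blocks = 1L, use_batch_norm = TRUE,
                         learning_rate = 1e-3, batch_size = 8L,
                         n_epochs = 15L, normalize = TRUE,
                         bias_method = c("invert", "residual"),
                         seed = 1L) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, length(channels) >= 1L,
            all(n_residual_blocks >= 0L), n_epochs >= 0L, batch_size >= 1L)
  n_residual_blocks <- rep_len(as.integer(n_residual_blocks),
                               length(channels))
  down_factor <- 2L^length(channels)  # stride-2 stem + stage transitions
  if (any(input_shape < down_factor))
    stop_bad_arg("every input dimension must be >= the total ",
                 "downsampling factor (", down_factor, ")")
  structure(list(input_shape = input_shape,
                 channels = as.integer(channels),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 use_batch_norm = isTRUE(use_batch_norm),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 normalize = isTRUE(normalize),
                 bias_method = match.arg(bias_method),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) residual 3D CNN age model
#'
#' @param cfg a [model_config()].
#' @return an `age_model`: seeded initial parameters, layer geometries,
#'   and the config. Callable on volumes via [predict.age_model()].
#' @export
build_age_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  S <- length(cfg$channels)
  geoms <- list()
  units <- list()
  params <- list()
  buffers <- list()
  uid <- 0L
  dims <- cfg$input_shape

  add_geom <- function(dim, stride) {
    key <- paste(c(dim, stride), collapse = "_")
    if (is.null(geoms[[key]]))
      geoms[[key]] <<- make_conv_geom(dim, 3L, stride, 1L)
    key
  }

  with_rng(cfg$seed, {
    # stride-2 stem
    uid <- uid + 1L
    key <- add_geom(dims, 2L)
    dims <- geoms[[key]]$out_dim
    id <- paste0("u", uid)
    units[[length(units) + 1L]] <- list(id = id, type = "cbr",
                                        c_in = 1L, c_out = cfg$channels[1L],
                                        geom = key)
    params[[paste0(id, ".conv")]] <- conv_init(geoms[[key]], 1L,
                                               cfg$channels[1L])
    if (cfg$use_batch_norm) {
      params[[paste0(id, ".bn")]] <- bn_init(cfg$channels[1L])
      buffers[[paste0(id, ".bn")]] <- bn_buffers_init(cfg$channels[1L])
    }
    for (s in seq_len(S)) {
      if (s > 1L) {
        uid <- uid + 1L
        key <- add_geom(dims, 2L)
        dims <- geoms[[key]]$out_dim
        id <- paste0("u", uid)
        units[[length(units) + 1L]] <- list(id = id, type = "cbr",
                                            c_in = cfg$channels[s - 1L],
                                            c_out = cfg$channels[s],
                                            geom = key)
        params[[paste0(id, ".conv")]] <- conv_init(geoms[[key]],
                                                   cfg$channels[s - 1L],
                                                   cfg$channels[s])
        if (cfg$use_batch_norm) {
          params[[paste0(id, ".bn")]] <- bn_init(cfg$channels[s])
          buffers[[paste0(id, ".bn")]] <- bn_buffers_init(cfg$channels[s])
        }
      }
      for (b in seq_len(cfg$n_residual_blocks[s])) {
        uid <- uid + 1L
        key <- add_geom(dims, 1L)
        id <- paste0("u", uid)
        cc <- cfg$channels[s]
        units[[length(units) + 1L]] <- list(id = id, type = "res",
                                            c_in = cc, c_out = cc,
                                            geom = key)
        for (part in c(".conv1", ".conv2"))
          params[[paste0(id, part)]] <- conv_init(geoms[[key]], cc, cc)
        if (cfg$use_batch_norm) {
          for (part in c(".bn1", ".bn2")) {
            params[[paste0(id, part)]] <- bn_init(cc)
            buffers[[paste0(id, part)]] <- bn_buffers_init(cc)
          }
        }
      }
    }
    cc <- cfg$channels[S]
    params[["head"]] <- list(w = matrix(rnorm(cc, 0, 1 / sqrt(cc)), cc, 1L),
                             b = 0)
  })

  structure(list(cfg = cfg, units = units, geoms = geoms,
                 params = params, buffers = buffers,
                 cache_env = new.env(parent = emptyenv()),
                 target_offset = 0, trained = FALSE),
            class = "age_model")
}

#' @export
#' @method print age_model
print.age_model <- function(x, ...) {
  cat("age_model:", paste(x$cfg$input_shape, collapse = "x"), "input,",
      length(x$units), "conv units, channels",
      paste(x$cfg$channels, collapse = "-"), "|", n_params(x),
      "parameters |", if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

#' Number of trainable parameters of an age model
#' @param model an `age_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "age_model"))
  sum(vapply(model$params,
             function(p) sum(vapply(p, length, integer(1L))), numeric(1L)))
}

# forward pass over a prepared batch matrix X (V x B, single channel);
# returns predictions and (optionally) all caches for backprop
model_forward <- function(model, X, train = FALSE) {
  cfg <- model$cfg
  B <- ncol(X)
  A <- X
  C <- 1L
  caches <- if (train) vector("list", length(model$units)) else NULL
  buffers <- model$buffers
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    g <- model$geoms[[u$geom]]
    if (u$type == "cbr") {
      cv <- conv_fwd(model$params[[paste0(u$id, ".conv")]], g, u$geom,
                     A, C, B, model$cache_env, keep_cache = train)
      Z <- cv$Y
      if (cfg$use_batch_norm) {
        bnk <- paste0(u$id, ".bn")
        if (train) {
          bn <- bn_fwd_train(model$params[[bnk]], buffers[[bnk]], Z,
                             u$c_out, B)
          buffers[[bnk]] <- bn$buf
          Zb <- bn$Y
        } else {
          Zb <- bn_fwd_infer(model$params[[bnk]], buffers[[bnk]], Z,
                             u$c_out, B)
          bn <- NULL
        }
      } else { Zb <- Z; bn <- NULL }
      A <- relu_fwd(Zb)
      if (train) caches[[i]] <- list(conv = cv$cache, bn = bn$cache,
                                     pre = Zb)
    } else {               # residual block
      A_in <- A
      cv1 <- conv_fwd(model$params[[paste0(u$id, ".conv1")]], g, u$geom,
                      A, C, B, model$cache_env, keep_cache = train)
      Z1 <- cv1$Y
      if (cfg$use_batch_norm) {
        k1 <- paste0(u$id, ".bn1")
        if (train) {
          bn1 <- bn_fwd_train(model$params[[k1]], buffers[[k1]], Z1,
                              u$c_out, B)
          buffers[[k1]] <- bn1$buf
          Z1b <- bn1$Y
        } else {
          Z1b <- bn_fwd_infer(model$params[[k1]], buffers[[k1]], Z1,
                              u$c_out, B)
          bn1 <- NULL
        }
      } else { Z1b <- Z1; bn1 <- NULL }
      H <- relu_fwd(Z1b)
      cv2 <- conv_fwd(model$params[[paste0(u$id, ".conv2")]], g, u$geom,
                      H, u$c_out, B, model$cache_env, keep_cache = train)
      Z2 <- cv2$Y
      if (cfg$use_batch_norm) {
        k2 <- paste0(u$id, ".bn2")
        if (train) {
          bn2 <- bn_fwd_train(model$params[[k2]], buffers[[k2]], Z2,
                              u$c_out, B)
          buffers[[k2]] <- bn2$buf
          Z2b <- bn2$Y
        } else {
          Z2b <- bn_fwd_infer(model$params[[k2]], buffers[[k2]], Z2,
                              u$c_out, B)
          bn2 <- NULL
        }
      } else { Z2b <- Z2; bn2 <- NULL }
      Spre <- A_in + Z2b
      A <- relu_fwd(Spre)
      if (train) caches[[i]] <- list(conv1 = cv1$cache, bn1 = bn1$cache,
                                     pre1 = Z1b, H = H,
                                     conv2 = cv2$cache, bn2 = bn2$cache,
                                     pre = Spre)
    }
    C <- u$c_out
  }
  V_last <- nrow(A)
  feat <- matrix(colMeans(A), B, C)                # B x C
  head <- model$params[["head"]]
  y <- as.numeric(feat %*% head$w) + head$b + model$target_offset
  list(y = y, feat = feat, caches = caches, buffers = buffers,
       V_last = V_last, C_last = C, B = B)
}

# backward pass; returns gradients keyed like model$params
model_backward <- function(model, fwd, dy) {
  cfg <- model$cfg
  B <- fwd$B
  grads <- list()
  head <- model$params[["head"]]
  grads[["head"]] <- list(w = crossprod(fwd$feat, matrix(dy, B, 1L)),
                          b = sum(dy))
  dfeat <- matrix(dy, B, 1L) %*% t(head$w)         # B x C
  dA <- matrix(as.numeric(dfeat) / fwd$V_last, fwd$V_last,
               B * fwd$C_last, byrow = TRUE)
  for (i in rev(seq_along(model$units))) {
    u <- model$units[[i]]
    g <- model$geoms[[u$geom]]
    cc <- fwd$caches[[i]]
    if (u$type == "cbr") {
      dZb <- relu_bwd(dA, cc$pre)
      if (cfg$use_batch_norm) {
        bnk <- paste0(u$id, ".bn")
        bb <- bn_bwd(model$params[[bnk]], dZb, cc$bn)
        grads[[bnk]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
        dZ <- bb$dA
      } else dZ <- dZb
      cb <- conv_bwd(model$params[[paste0(u$id, ".conv")]], g, u$geom,
                     dZ, cc$conv, u$c_in, B, model$cache_env)
      grads[[paste0(u$id, ".conv")]] <- list(W = cb$dW, b = cb$db)
      dA <- cb$dA
    } else {
      dS <- relu_bwd(dA, cc$pre)
      # main branch
      if (cfg$use_batch_norm) {
        k2 <- paste0(u$id, ".bn2")
        bb2 <- bn_bwd(model$params[[k2]], dS, cc$bn2)
        grads[[k2]] <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
        dZ2 <- bb2$dA
      } else dZ2 <- dS
      cb2 <- conv_bwd(model$params[[paste0(u$id, ".conv2")]], g, u$geom,
                      dZ2, cc$conv2, u$c_out, B, model$cache_env)
      grads[[paste0(u$id, ".conv2")]] <- list(W = cb2$dW, b = cb2$db)
      dH <- relu_bwd(cb2$dA, cc$pre1)
      if (cfg$use_batch_norm) {
        k1 <- paste0(u$id, ".bn1")
        bb1 <- bn_bwd(model$params[[k1]], dH, cc$bn1)
        grads[[k1]] <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
        dZ1 <- bb1$dA
      } else dZ1 <- dH
      cb1 <- conv_bwd(model$params[[paste0(u$id, ".conv1")]], g, u$geom,
                      dZ1, cc$conv1, u$c_in, B, model$cache_env)
      grads[[paste0(u$id, ".conv1")]] <- list(W = cb1$dW, b = cb1$db)
      dA <- cb1$dA + dS                            # skip connection
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) lapply(p, function(x) {
    list(m = x * 0, v = x * 0)
  }))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(grads)) {
    for (f in names(grads[[k]])) {
      g <- grads[[k]][[f]]
      st <- state[[k]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[k]][[f]] <- params[[k]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[k]][[f]] <- st
    }
  }
  list(params = params, state = state)
}

# z-score each column (volume) when the config asks for it
prepare_inputs <- function(model, X) {
  stopifnot(nrow(X) == prod(model$cfg$input_shape))
  if (!model$cfg$normalize) return(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)
  sdv[sdv == 0] <- 1
  sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
}

as_input_matrix <- function(model, volumes) {
  X <- if (is.matrix(volumes)) volumes else volumes_to_matrix(volumes)
  if (nrow(X) != prod(model$cfg$input_shape))
    stop_bad_arg("volume shape does not match model input_shape")
  X
}

#' Train the age model by Adam on mean squared error
#'
#' Runs seeded minibatch SGD (Adam) on the training volumes, records the
#' per-epoch training loss and validation MAE, and retains the
#' parameters of the best-validation epoch. With `n_epochs = 0` the
#' model is returned unchanged. On the first call the linear head's
#' intercept is anchored at the mean training age so the optimiser
#' starts from the constant-mean predictor.
#'
#' @param model an `age_model` from [build_age_model()].
#' @param train_volumes list of `volume_sample`s (or voxels-x-n matrix).
#' @param train_ages ages for `train_volumes` (taken from the volume
#'   list when omitted).
#' @param val_volumes,val_ages optional validation set; when absent the
#'   final-epoch parameters are kept.
#' @return list with `model` (trained) and `history` (data frame:
#'   epoch, train_loss, val_mae).
#' @export
train_age_model <- function(model, train_volumes, train_ages = NULL,
                            val_volumes = NULL, val_ages = NULL) {
  stopifnot(inherits(model, "age_model"))
  cfg <- model$cfg
  if (is.null(train_ages)) train_ages <- cohort_ages(train_volumes)
  X <- prepare_inputs(model, as_input_matrix(model, train_volumes))
  n <- ncol(X)
  stopifnot(n >= 1L, length(train_ages) == n)
  if (cfg$n_epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(), train_loss = numeric(),
                                     val_mae = numeric())))
  have_val <- !is.null(val_volumes)
  if (have_val) {
    if (is.null(val_ages)) val_ages <- cohort_ages(val_volumes)
    Xv <- prepare_inputs(model, as_input_matrix(model, val_volumes))
  }

  if (!model$trained) model$target_offset <- mean(train_ages)
  params <- model$params
  state <- adam_init(params)
  t_step <- 0L
  best <- list(val = Inf, params = params, buffers = model$buffers)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_mae = numeric())

  with_rng(cfg$seed, {
    for (ep in seq_len(cfg$n_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        sel <- ord[start:min(start + cfg$batch_size - 1L, n)]
        if (length(sel) < 2L && cfg$use_batch_norm) next  # BN needs stats
        model$params <- params
        fwd <- model_forward(model, X[, sel, drop = FALSE], train = TRUE)
        model$buffers <- fwd$buffers
        err <- fwd$y - train_ages[sel]
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop_bad_arg("training diverged: non-finite loss at epoch ", ep,
                       " (try a smaller learning rate)")
        losses <- c(losses, loss)
        dy <- 2 * err / length(sel)
        grads <- model_backward(model, fwd, dy)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, cfg$learning_rate, t_step)
        params <- upd$params
        state <- upd$state
      }
      model$params <- params
      val_mae <- NA_real_
      if (have_val) {
        pv <- predict_matrix(model, Xv, prepared = TRUE)
        val_mae <- mean(abs(pv - val_ages))
        if (val_mae < best$val)
          best <- list(val = val_mae, params = params,
                       buffers = model$buffers)
      }
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = mean(losses),
                                     val_mae = val_mae))
    }
  })
  if (have_val && is.finite(best$val)) {
    model$params <- best$params
    model$buffers <- best$buffers
  } else {
    model$params <- params
  }
  model$trained <- TRUE
  list(model = model, history = hist)
}

# inference on a prepared or raw input matrix, in batches
predict_matrix <- function(model, X, batch_size = 32L, prepared = FALSE) {
  if (!prepared) X <- prepare_inputs(model, X)
  n <- ncol(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    out[sel] <- model_forward(model, X[, sel, drop = FALSE],
                              train = FALSE)$y
  }
  out
}

#' Predict ages for volumes
#'
#' @param object an `age_model`.
#' @param volumes list of `volume_sample`s or a voxels-x-n matrix whose
#'   rows match the model's `input_shape`.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return numeric vector of raw predicted ages (years), one per volume,
#'   in input order.
#' @export
predict.age_model <- function(object, volumes, batch_size = 32L, ...) {
  X <- as_input_matrix(object, volumes)
  predict_matrix(object, X, batch_size = batch_size)
}
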