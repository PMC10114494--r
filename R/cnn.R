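# Method 2: small end-to-end convolutional models trained with either a
# single averaged-label output or m per-reader outputs under a masked loss.
# The trunk (3 valid-convolution blocks + ReLU + global average pooling) and
# its optimiser are implemented directly on BLAS matrix ops: forward passes
# use im2col gathers, backward passes a precomputed sparse scatter matrix.

#' Masked multi-output squared-error loss
#'
#' `loss = sum_i phi_i * (rho_i - d_i)^2`, where `phi_i` is 1 when reader
#' i's label is known and 0 otherwise. Masked entries contribute nothing and
#' their gradient with respect to `rho` is exactly zero; the sentinel held
#' in masked label slots never enters the arithmetic.
#'
#' @param rho Length-m prediction vector.
#' @param d Length-m label vector (masked entries may hold any sentinel).
#' @param phi Length-m binary mask (1 = label known).
#' @return Non-negative scalar.
#' @export
masked_loss <- function(rho, d, phi) {
  if (length(rho) != length(d) || length(rho) != length(phi)) {
    stop("rho, d and phi must have equal length", call. = FALSE)
  }
  if (!all(phi %in% c(0, 1))) stop("phi must be binary", call. = FALSE)
  on_idx <- phi == 1
  sum((rho[on_idx] - d[on_idx])^2)
}

# Batch loss: sum over unmasked terms / count of unmasked terms, so single
# and multi modes see comparable gradient scales. Returns loss and dL/dpred.
masked_batch_loss <- function(pred, d, phi) {
  m <- sum(phi)
  if (m == 0) return(list(loss = 0, grad = pred * 0))
  diff <- (pred - ifelse(phi == 1, d, 0)) * phi
  list(loss = sum(diff^2) / m, grad = 2 * diff / m)
}

#' Stochastic image augmentation
#'
#' Left-right flip with probability `flip_prob`, rotation by a uniform angle
#' in `[-max_rotation_deg, max_rotation_deg]` (bilinear, same output size),
#' and additive Gaussian pixel noise. Deterministic for a fixed seed.
#'
#' @param image Preprocessed image matrix.
#' @param params List with `flip_prob`, `max_rotation_deg`, `noise_sd`.
#' @param seed Optional integer seed.
#' @return Augmented matrix of the same shape.
#' @export
augment <- function(image, params = list(flip_prob = 0.5,
                                         max_rotation_deg = 10,
                                         noise_sd = 0.01),
                    seed = NULL) {
  with_seed(seed, {
    x <- image
    if (params$flip_prob > 0 && stats::runif(1) < params$flip_prob) {
      x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    }
    if (params$max_rotation_deg > 0) {
      ang <- stats::runif(1, -params$max_rotation_deg, params$max_rotation_deg)
      x <- as.matrix(EBImage::rotate(x, ang, output.dim = dim(x),
                                     bg.col = 0))
    }
    if (params$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, params$noise_sd),
                      nrow(x), ncol(x))
    }
    x
  })
}

#' Training configuration for the end-to-end models
#'
#' @param mode `"single"` (one output neuron, averaged labels) or `"multi"`
#'   (`m` output neurons, one per reader, masked loss).
#' @param m Reader count (multi mode).
#' @param feature_dim Penultimate representation width (channels of the last
#'   conv block; default 64 at desk scale).
#' @param learning_rates Non-empty sweep of Adam learning rates; the model
#'   minimizing validation RMSE across the sweep is returned.
#' @param epochs Maximum epochs per learning rate.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience on validation RMSE (`Inf`
#'   disables).
#' @param seed Master seed; trunk init, head init and the data/augmentation
#'   stream use distinct sub-seeds so single and multi runs share identical
#'   trunk initialization, image order and augmentation draws.
#' @param augmentation List with `flip_prob`, `max_rotation_deg`,
#'   `noise_sd`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(mode = c("single", "multi"), m = 13L,
                         feature_dim = 64L,
                         learning_rates = c(3e-3, 1e-3),
                         epochs = 30L, batch_size = 32L,
                         patience = 5L, seed = 1L,
                         augmentation = list(flip_prob = 0.5,
                                             max_rotation_deg = 10,
                                             noise_sd = 0.01)) {
  mode <- match.arg(mode)
  if (!length(learning_rates)) stop("learning_rates must be non-empty", call. = FALSE)
  assert_scalar_number(augmentation$flip_prob, "flip_prob", lo = 0, hi = 1)
  structure(list(mode = mode, m = as.integer(m),
                 feature_dim = as.integer(feature_dim),
                 learning_rates = learning_rates, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), patience = patience,
                 seed = as.integer(seed), augmentation = augmentation),
            class = "train_config")
}

#' Build masked label matrices for multi-predictor training
#'
#' Arranges the long label table as an `m x n` label matrix and binary mask
#' over a fixed reader ordering: each image column has exactly its two
#' scoring readers unmasked; all other entries hold `NA` sentinels that
#' never enter the training arithmetic.
#'
#' @param labels Long label table (`image_id`, `reader_id`, `score`).
#' @param reader_ids Character vector fixing the output-neuron order (e.g.
#'   `names(reader_pool(...))`).
#' @param image_ids Images to include, in column order.
#' @return List with `d` (labels, `NA` where unknown) and `phi` (binary
#'   mask), both `m x n` with dimnames.
#' @export
masked_label_matrix <- function(labels, reader_ids, image_ids) {
  m <- length(reader_ids)
  n <- length(image_ids)
  d <- matrix(NA_real_, m, n, dimnames = list(reader_ids, image_ids))
  sel <- labels$image_id %in% image_ids
  ri <- match(labels$reader_id[sel], reader_ids)
  ci <- match(labels$image_id[sel], image_ids)
  if (anyNA(ri)) stop("label table contains readers missing from reader_ids",
                      call. = FALSE)
  d[cbind(ri, ci)] <- labels$score[sel]
  phi <- 1 * !is.na(d)
  list(d = d, phi = phi)
}

# ---- convolution plumbing -------------------------------------------------

# Geometry and gather/scatter indices for one valid convolution layer.
conv_plan <- function(in_h, in_w, in_c, k, stride) {
  out_h <- (in_h - k) %/% stride + 1L
  out_w <- (in_w - k) %/% stride + 1L
  hw <- in_h * in_w
  off <- as.integer(rep(0:(in_c - 1L) * hw, each = k * k) +
                      rep(rep(0:(k - 1L) * in_h, each = k), in_c) +
                      rep(0:(k - 1L), k * in_c))
  oi <- rep(seq_len(out_h), out_w)
  oj <- rep(seq_len(out_w), each = out_h)
  starts <- (oi - 1L) * stride + 1L + ((oj - 1L) * stride) * in_h
  idx <- outer(off, starts, `+`)
  scatter <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx),
                                  x = 1, dims = c(hw * in_c, length(idx)))
  list(in_h = in_h, in_w = in_w, in_c = in_c, k = k, stride = stride,
       out_h = out_h, out_w = out_w, n_pos = out_h * out_w,
       kkc = k * k * in_c, idx = as.vector(idx), scatter = scatter)
}

conv_forward <- function(plan, W, b, X) {
  B <- ncol(X)
  cols <- X[plan$idx, , drop = FALSE]
  dim(cols) <- c(plan$kkc, plan$n_pos * B)
  pre <- crossprod(W, cols) + b            # F x (P*B); b recycles per column
  f <- ncol(W)
  dim(pre) <- c(f, plan$n_pos, B)
  out <- aperm(pre, c(2L, 1L, 3L))
  dim(out) <- c(plan$n_pos * f, B)
  list(out = out, cols = cols)
}

conv_backward <- function(plan, W, cache_cols, dY) {
  B <- ncol(dY)
  f <- ncol(W)
  dim(dY) <- c(plan$n_pos, f, B)
  dpre <- aperm(dY, c(2L, 1L, 3L))
  dim(dpre) <- c(f, plan$n_pos * B)
  dW <- cache_cols %*% t(dpre)
  db <- rowSums(dpre)
  dcols <- W %*% dpre
  dim(dcols) <- c(plan$kkc * plan$n_pos, B)
  dX <- as.matrix(plan$scatter %*% dcols)
  list(dW = dW, db = db, dX = dX)
}

# ---- model ----------------------------------------------------------------

# Three conv blocks (8, 16, feature_dim channels; strides 2) + ReLU + GAP,
# then a linear head to n_out outputs.
init_cnn <- function(input_size, feature_dim, n_out, seed_trunk, seed_head) {
  chans <- c(1L, 8L, 16L, feature_dim)
  ks <- c(5L, 3L, 3L)
  plans <- vector("list", 3L)
  h <- w <- input_size
  for (l in 1:3) {
    plans[[l]] <- conv_plan(h, w, chans[l], ks[l], 2L)
    h <- plans[[l]]$out_h; w <- plans[[l]]$out_w
  }
  params <- with_seed(seed_trunk, {
    lapply(1:3, function(l) {
      fan_in <- plans[[l]]$kkc
      list(W = matrix(stats::rnorm(fan_in * chans[l + 1L],
                                   sd = sqrt(2 / fan_in)),
                      fan_in, chans[l + 1L]),
           b = rep(0, chans[l + 1L]))
    })
  })
  head <- with_seed(seed_head, {
    list(W = matrix(stats::rnorm(feature_dim * n_out,
                                 sd = sqrt(1 / feature_dim)),
                    feature_dim, n_out),
         b = rep(0, n_out))
  })
  list(plans = plans, conv = params, head = head,
       feature_dim = feature_dim, n_out = n_out, input_size = input_size)
}

cnn_forward <- function(net, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", 3L) else NULL
  a <- X
  for (l in 1:3) {
    cf <- conv_forward(net$plans[[l]], net$conv[[l]]$W, net$conv[[l]]$b, a)
    pre <- cf$out
    a <- pmax(pre, 0)
    if (keep_cache) caches[[l]] <- list(cols = cf$cols, relu = pre > 0)
  }
  p3 <- net$plans[[3]]$n_pos
  B <- ncol(X)
  dim(a) <- c(p3, net$feature_dim * B)
  feat <- colMeans(a)
  dim(feat) <- c(net$feature_dim, B)
  pred <- crossprod(net$head$W, feat) + net$head$b
  list(feat = feat, pred = pred, caches = caches)
}

cnn_backward <- function(net, X, fwd, dpred) {
  B <- ncol(X)
  dhead_W <- fwd$feat %*% t(dpred)
  dhead_b <- rowSums(dpred)
  dfeat <- net$head$W %*% dpred                  # F x B
  p3 <- net$plans[[3]]$n_pos
  da <- matrix(rep(as.vector(dfeat) / p3, each = p3),
               p3 * net$feature_dim, B)
  grads <- vector("list", 3L)
  for (l in 3:1) {
    da <- da * fwd$caches[[l]]$relu
    bk <- conv_backward(net$plans[[l]], net$conv[[l]]$W,
                        fwd$caches[[l]]$cols, da)
    grads[[l]] <- list(W = bk$dW, b = bk$db)
    if (l > 1L) da <- bk$dX
  }
  list(conv = grads, head = list(W = dhead_W, b = dhead_b))
}

# Adam optimiser state and update (standard moments, bias-corrected).
adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = list(conv = lapply(net$conv, zero_like),
                head = zero_like(net$head)),
       v = list(conv = lapply(net$conv, zero_like),
                head = zero_like(net$head)),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in 1:3) {
    for (nm in c("W", "b")) {
      u <- upd(net$conv[[l]][[nm]], grads$conv[[l]][[nm]],
               state$m$conv[[l]][[nm]], state$v$conv[[l]][[nm]])
      net$conv[[l]][[nm]] <- u$p
      state$m$conv[[l]][[nm]] <- u$m
      state$v$conv[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$head[[nm]], grads$head[[nm]],
             state$m$head[[nm]], state$v$head[[nm]])
    net$head[[nm]] <- u$p
    state$m$head[[nm]] <- u$m
    state$v$head[[nm]] <- u$v
  }
  list(net = net, state = state)
}

# Flatten a list of image matrices into the (pixels x batch) matrix the
# conv layers consume.
stack_images <- function(images) {
  vapply(images, as.vector, numeric(length(images[[1]])))
}

#' Train an end-to-end density model
#'
#' Trains the small convolutional model with Adam for each learning rate in
#' the sweep and returns the model minimizing validation RMSE. In `single`
#' mode the target is the per-image averaged reader score (one output
#' neuron). In `multi` mode the head has one output per reader and the
#' masked loss is applied, so only the head weights of readers with known
#' labels receive gradient while the shared trunk is updated by every image.
#' Trunk initialization, image order and augmentation draws are identical
#' across modes for the same seed, so outcome differences are
#' objective-driven. A learning rate whose loss becomes non-finite is
#' recorded as diverged and the sweep continues.
#'
#' @param x_train,x_val Named lists of preprocessed image matrices (all the
#'   same square size).
#' @param y_train,y_val Single mode: numeric label vectors. Multi mode:
#'   `m x n` label matrices (unknown entries arbitrary) accompanied by
#'   binary masks.
#' @param mask_train,mask_val Multi mode only: `m x n` binary matrices, one
#'   column per image with exactly the known-reader entries set to 1.
#' @param config A [train_config()].
#' @return Object of class `density_cnn`: the best network, its `history`
#'   (one row per epoch and learning rate: train loss, validation RMSE),
#'   `best_lr`, `best_val_rmse`, and `diverged` learning rates.
#' @export
train_model <- function(x_train, y_train, x_val, y_val, config,
                        mask_train = NULL, mask_val = NULL) {
  input_size <- nrow(x_train[[1]])
  n_out <- if (config$mode == "single") 1L else config$m
  if (config$mode == "multi" &&
      (is.null(mask_train) || is.null(mask_val))) {
    stop("multi mode requires mask_train and mask_val", call. = FALSE)
  }
  y_train <- if (config$mode == "single") matrix(y_train, 1L) else as.matrix(y_train)
  y_val <- if (config$mode == "single") matrix(y_val, 1L) else as.matrix(y_val)
  phi_train <- if (config$mode == "single") {
    matrix(1, 1L, ncol(y_train))
  } else {
    as.matrix(mask_train)
  }
  phi_val <- if (config$mode == "single") matrix(1, 1L, ncol(y_val)) else as.matrix(mask_val)
  Xval <- stack_images(x_val)
  n <- length(x_train)
  seed_trunk <- child_seed(config$seed, 1L)
  seed_head <- child_seed(config$seed, 2L)
  seed_data <- child_seed(config$seed, 3L)

  history <- list()
  diverged <- character(0)
  best <- NULL
  for (lr in config$learning_rates) {
    net <- init_cnn(input_size, config$feature_dim, n_out, seed_trunk, seed_head)
    state <- adam_init(net)
    lr_best_rmse <- Inf
    lr_best_net <- NULL
    stall <- 0L
    with_seed(seed_data, {
      for (epoch in seq_len(config$epochs)) {
        ord <- sample.int(n)
        epoch_loss <- 0
        n_batches <- 0L
        ok <- TRUE
        for (s in seq(1L, n, by = config$batch_size)) {
          bi <- ord[s:min(s + config$batch_size - 1L, n)]
          Xb <- vapply(bi, function(i) {
            as.vector(augment(x_train[[i]], config$augmentation))
          }, numeric(input_size^2))
          fwd <- cnn_forward(net, Xb, keep_cache = TRUE)
          lb <- masked_batch_loss(fwd$pred, y_train[, bi, drop = FALSE],
                                  phi_train[, bi, drop = FALSE])
          if (!is.finite(lb$loss)) { ok <- FALSE; break }
          grads <- cnn_backward(net, Xb, fwd, lb$grad)
          st <- adam_step(net, grads, state, lr)
          net <- st$net; state <- st$state
          epoch_loss <- epoch_loss + lb$loss
          n_batches <- n_batches + 1L
        }
        if (!ok) {
          diverged <- c(diverged, format(lr))
          break
        }
        vfwd <- cnn_forward(net, Xval)
        vdiff <- (vfwd$pred - ifelse(phi_val == 1, y_val, 0)) * phi_val
        val_rmse <- sqrt(sum(vdiff^2) / sum(phi_val))
        history[[length(history) + 1L]] <- data.frame(
          lr = lr, epoch = epoch, train_loss = epoch_loss / n_batches,
          val_rmse = val_rmse)
        if (val_rmse < lr_best_rmse) {
          lr_best_rmse <- val_rmse
          lr_best_net <- net
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience) break
        }
      }
    })
    if (!is.null(lr_best_net) &&
        (is.null(best) || lr_best_rmse < best$val_rmse)) {
      best <- list(net = lr_best_net, val_rmse = lr_best_rmse, lr = lr)
    }
  }
  if (is.null(best)) stop("all learning rates diverged", call. = FALSE)
  structure(list(net = best$net, config = config,
                 history = do.call(rbind, history),
                 best_lr = best$lr, best_val_rmse = best$val_rmse,
                 diverged = diverged),
            class = "density_cnn")
}

#' @export
print.density_cnn <- function(x, ...) {
  cat(sprintf("density_cnn (%s mode): feature_dim=%d, best lr=%g, val RMSE=%.3f\n",
              x$config$mode, x$config$feature_dim, x$best_lr, x$best_val_rmse))
  invisible(x)
}

#' Untrained control network
#'
#' The seeded, untrained trunk used as the desk-scale stand-in for a
#' generic pretrained backbone when comparing representations.
#'
#' @param input_size Image side length.
#' @param feature_dim Penultimate width.
#' @param seed Integer seed (same sub-seed scheme as [train_model()]).
#' @return A `density_cnn` whose weights are at initialization.
#' @export
untrained_model <- function(input_size, feature_dim = 64L, seed = 1L) {
  net <- init_cnn(input_size, feature_dim, 1L,
                  child_seed(seed, 1L), child_seed(seed, 2L))
  structure(list(net = net,
                 config = list(mode = "untrained", feature_dim = feature_dim),
                 history = NULL, best_lr = NA_real_,
                 best_val_rmse = NA_real_, diverged = character(0)),
            class = "density_cnn")
}

#' Extract the penultimate representation
#'
#' Runs images through the trunk in inference mode (no augmentation, no
#' stochastic layers) and returns the global-average-pooled feature vectors
#' that feed the final linear layer. Rows are batch-composition independent.
#'
#' @param model A `density_cnn`.
#' @param images Named list of preprocessed image matrices.
#' @return n x feature_dim matrix, rownames = image ids.
#' @export
extract_representation <- function(model, images) {
  X <- stack_images(images)
  out <- t(cnn_forward(model$net, X)$feat)
  rownames(out) <- names(images)
  out
}

#' Predict density scores with a trained model
#'
#' @param model A `density_cnn`.
#' @param images Named list of preprocessed image matrices.
#' @return Single mode: named numeric vector. Multi mode: n x m matrix of
#'   per-reader outputs.
#' @export
predict_cnn <- function(model, images) {
  X <- stack_images(images)
  pred <- cnn_forward(model$net, X)$pred
  if (nrow(pred) == 1L) {
    stats::setNames(drop(pred), names(images))
  } else {
    out <- t(pred)
    rownames(out) <- names(images)
    out
  }
}
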