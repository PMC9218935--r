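# Network execution: forward passes, hand-written backpropagation, Adam.
# Feature maps are (H, W, C, N) double arrays; the heavy kernels live in
# src/kernels.cpp, everything channel-wise (batchnorm, activations, the
# stride=kernel transposed convolution GEMM) is vectorized R.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# broadcast a per-channel vector over (H, W, C, N) via exact-multiple recycling
bc_channel <- function(v, d) rep(v, each = d[1] * d[2])

channel_sums <- function(z) {
  d <- dim(z)
  colSums(matrix(aperm(z, c(1, 2, 4, 3)), ncol = d[3]))
}

bn_fwd <- function(x, gamma, beta, st, train) {
  d <- dim(x)
  if (is.null(st)) st <- list(rm = numeric(d[3]), rv = rep(1, d[3]))
  if (train) {
    r <- cpp_bn_train_fwd(x, gamma, beta)
    v <- 1 / r$inv_sd^2 - BN_EPS
    st$rm <- (1 - BN_MOMENTUM) * st$rm + BN_MOMENTUM * r$mu
    st$rv <- (1 - BN_MOMENTUM) * st$rv + BN_MOMENTUM * v
    list(y = r$y, cache = list(lin = x, mu = r$mu, inv_sd = r$inv_sd), st = st)
  } else {
    list(y = cpp_bn_eval_fwd(x, gamma, beta, st$rm, st$rv), cache = NULL,
         st = st)
  }
}

bn_bwd <- function(dy, cache, gamma) {
  r <- cpp_bn_bwd(cache$lin, dy, gamma, cache$mu, cache$inv_sd)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

apply_act <- function(y, act) {
  switch(act,
    none = y,
    relu = cpp_relu(y),
    sigmoid = 1 / (1 + exp(-y)),
    stop("unknown activation: ", act))
}

act_bwd <- function(dy, y_out, act) {
  switch(act,
    none = dy,
    relu = cpp_relu_bwd(dy, y_out),
    sigmoid = dy * y_out * (1 - y_out))
}

# full conv stage: conv (+bias) -> optional batchnorm -> activation
conv_stage_fwd <- function(x, p, bias, batchnorm, act, train, st = NULL) {
  lin <- cpp_conv2d_fwd(x, p$w, if (bias) p$b else NULL)
  bn_cache <- NULL
  if (batchnorm) {
    r <- bn_fwd(lin, p$gamma, p$beta, st, train)
    lin <- r$y; bn_cache <- r$cache; st <- r$st
  }
  y <- apply_act(lin, act)
  list(y = y, cache = list(x = x, bn = bn_cache, y = y), st = st)
}

conv_stage_bwd <- function(dy, p, cache, bias, batchnorm, act) {
  g <- act_bwd(dy, cache$y, act)
  grads <- list()
  if (batchnorm) {
    r <- bn_bwd(g, cache$bn, p$gamma)
    g <- r$dx
    grads$gamma <- r$dgamma
    grads$beta <- r$dbeta
  }
  cb <- cpp_conv2d_bwd(cache$x, p$w, g)
  grads$w <- cb$dw
  if (bias) grads$b <- cb$db
  list(dx = cb$dx, grads = grads[names(p)])
}

dw_stage_fwd <- function(x, p, bias, batchnorm, act, train, st = NULL) {
  lin <- cpp_dwconv_fwd(x, p$w, if (bias) p$b else NULL)
  bn_cache <- NULL
  if (batchnorm) {
    r <- bn_fwd(lin, p$gamma, p$beta, st, train)
    lin <- r$y; bn_cache <- r$cache; st <- r$st
  }
  y <- apply_act(lin, act)
  list(y = y, cache = list(x = x, bn = bn_cache, y = y), st = st)
}

dw_stage_bwd <- function(dy, p, cache, bias, batchnorm, act) {
  g <- act_bwd(dy, cache$y, act)
  grads <- list()
  if (batchnorm) {
    r <- bn_bwd(g, cache$bn, p$gamma)
    g <- r$dx
    grads$gamma <- r$dgamma
    grads$beta <- r$dbeta
  }
  cb <- cpp_dwconv_bwd(cache$x, p$w, g)
  grads$w <- cb$dw
  if (bias) grads$b <- cb$db
  list(dx = cb$dx, grads = grads[names(p)])
}

# transposed convolution, stride == kernel (non-overlapping): pure GEMM
deconv_fwd <- function(x, w, b = NULL) {
  d <- dim(x); K <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(d[3] == cin)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = cin)          # (H*W*N, Cin)
  wm <- matrix(aperm(w, c(3, 1, 2, 4)), nrow = cin)          # (Cin, K*K*Cout)
  y <- xm %*% wm                                             # (H*W*N, K*K*Cout)
  dim(y) <- c(d[1], d[2], d[4], K, K, cout)
  y <- aperm(y, c(4, 1, 5, 2, 6, 3))                         # (K,H,K,W,Cout,N)
  dim(y) <- c(K * d[1], K * d[2], cout, d[4])
  if (!is.null(b)) y <- y + bc_channel(b, dim(y))
  y
}

deconv_bwd <- function(dy, x, w, bias) {
  d <- dim(x); K <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  dyr <- dy
  dim(dyr) <- c(K, d[1], K, d[2], cout, d[4])
  dyr <- aperm(dyr, c(2, 4, 6, 1, 3, 5))                     # (H,W,N,K,K,Cout)
  dym <- matrix(dyr, nrow = d[1] * d[2] * d[4])              # (H*W*N, K*K*Cout)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = cin)
  wm <- matrix(aperm(w, c(3, 1, 2, 4)), nrow = cin)
  dxm <- dym %*% t(wm)                                       # (H*W*N, Cin)
  dim(dxm) <- c(d[1], d[2], d[4], cin)
  dx <- aperm(dxm, c(1, 2, 4, 3))
  dwm <- t(xm) %*% dym                                       # (Cin, K*K*Cout)
  dim(dwm) <- c(cin, K, K, cout)
  dw <- aperm(dwm, c(2, 3, 1, 4))
  grads <- list(w = dw)
  if (bias) grads$b <- channel_sums(dy)
  list(dx = dx, grads = grads)
}

node_spec <- function(node, in_channels) {
  switch(node$kind,
    conv = conv_spec(node$kernel, in_channels, node$out_channels,
                     bias = node$bias, batchnorm = node$batchnorm,
                     relu = identical(node$activation, "relu")),
    ghost = ghost_spec(node$kernel, in_channels, node$out_channels,
                       ratio = node$ratio, cheap_kernel = node$cheap_kernel,
                       bias = node$bias, batchnorm = node$batchnorm,
                       relu = identical(node$activation, "relu")),
    deconv = deconv_spec(node$kernel, in_channels, node$out_channels,
                         bias = node$bias),
    NULL)
}

#' Initialize the learnable parameters of a network
#'
#' Kaiming initialization for every convolutional weight; biases and
#' batchnorm shifts start at zero, batchnorm scales at one. Seed the R RNG
#' before calling for reproducibility.
#'
#' @param net a `network_spec`.
#' @param init `"kaiming"` or `"zero"`.
#' @return list with `params` (trainable arrays per node) and `state`
#'   (batchnorm running statistics per node).
#' @export
net_init <- function(net, init = "kaiming") {
  shapes <- network_shapes(net)
  params <- list(); state <- list()
  for (node in net$nodes) {
    spec <- node_spec(node, if (length(node$inputs))
      shapes[[node$inputs[1]]][1] else NA)
    if (is.null(spec)) next
    params[[node$id]] <- block_weights(spec, init)
    if (node$kind %in% c("conv", "ghost") && node$batchnorm)
      state[[node$id]] <- if (node$kind == "ghost")
        list(primary = NULL, cheap = NULL) else NULL
  }
  list(params = params, state = state)
}

# count learnable scalars by exhaustive enumeration of the weight containers
enumerate_params <- function(params) {
  n <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(params)
  n
}

#' Run a forward pass through a network
#'
#' Executes the graph on a batch of images. Only nodes the output depends on
#' are computed; side branches (e.g. unsupervised deep-supervision arms) are
#' skipped.
#'
#' @param net a `network_spec`.
#' @param params,state from [net_init()] (or a trained fit).
#' @param x input array `(H, W, C)` or `(H, W, C, N)`; for sub-networks with
#'   several inputs, a named list keyed by input-node id.
#' @param train use batch statistics in batchnorm and update running stats.
#' @param keep_cache retain per-node intermediates for backpropagation.
#' @return list with `out` (the output feature map), `values`, `caches`,
#'   `state`.
#' @export
net_forward <- function(net, params, state, x, train = FALSE,
                        keep_cache = FALSE) {
  needed <- network_needed(net)
  input_ids <- net_input_ids(net)
  if (!is.list(x)) {
    stopifnot(length(input_ids) == 1)
    x <- stats::setNames(list(x), input_ids)
  }
  values <- list(); caches <- list()
  for (id in needed) {
    node <- net$nodes[[id]]
    if (node$kind == "input") {
      fm <- as_feature_map(x[[id]])
      d <- dim(fm$x)
      if (!identical(as.integer(d[c(3, 1, 2)]), as.integer(node$shape)))
        stop("input '", id, "' has shape ", paste(d[c(3, 1, 2)], collapse = "x"),
             ", expected ", paste(node$shape, collapse = "x"))
      values[[id]] <- fm$x
      next
    }
    ins <- lapply(node$inputs, function(i) values[[i]])
    p <- params[[id]]
    res <- switch(node$kind,
      conv = {
        r <- conv_stage_fwd(ins[[1]], p, node$bias, node$batchnorm,
                            node$activation, train, state[[id]])
        if (node$batchnorm) state[[id]] <- r$st
        r
      },
      ghost = {
        rp <- conv_stage_fwd(ins[[1]], p$primary, node$bias, node$batchnorm,
                             node$activation, train, state[[id]]$primary)
        rc <- dw_stage_fwd(rp$y, p$cheap, node$bias, node$batchnorm,
                           node$activation, train, state[[id]]$cheap)
        if (node$batchnorm) state[[id]] <- list(primary = rp$st, cheap = rc$st)
        list(y = cat_channels(list(rp$y, rc$y)),
             cache = list(primary = rp$cache, cheap = rc$cache))
      },
      deconv = list(y = deconv_fwd(ins[[1]], p$w, if (node$bias) p$b else NULL),
                    cache = list(x = ins[[1]])),
      maxpool = {
        r <- cpp_maxpool_fwd(ins[[1]], as.integer(node$factor))
        list(y = r$y, cache = list(idx = r$idx, H = dim(ins[[1]])[1],
                                   W = dim(ins[[1]])[2]))
      },
      bilinear_up = list(y = cpp_bilinear_fwd(ins[[1]], as.integer(node$factor)),
                         cache = NULL),
      add = list(y = Reduce(`+`, ins), cache = NULL),
      concat = list(y = cat_channels(ins),
                    cache = list(splits = vapply(ins, function(z) dim(z)[3],
                                                 numeric(1)))),
      stop("unknown node kind: ", node$kind))
    values[[id]] <- res$y
    if (keep_cache) caches[[id]] <- res$cache
  }
  list(out = values[[net$output]], values = values, caches = caches,
       state = state)
}

# backpropagate dloss/dout through the graph; returns per-node gradients
net_backward <- function(net, params, fwd, dout) {
  needed <- network_needed(net)
  acc <- stats::setNames(vector("list", length(needed)), needed)
  acc[[net$output]] <- dout
  grads <- list()
  add_grad <- function(id, g) {
    acc[[id]] <<- if (is.null(acc[[id]])) g else acc[[id]] + g
  }
  for (id in rev(needed)) {
    node <- net$nodes[[id]]
    if (node$kind == "input") next
    g <- acc[[id]]
    if (is.null(g)) next
    cache <- fwd$caches[[id]]
    p <- params[[id]]
    switch(node$kind,
      conv = {
        r <- conv_stage_bwd(g, p, cache, node$bias, node$batchnorm,
                            node$activation)
        grads[[id]] <- r$grads
        add_grad(node$inputs[1], r$dx)
      },
      ghost = {
        ch <- dim(g)[3] %/% 2L
        gp <- cpp_channel_slice(g, 0L, ch)
        gg <- cpp_channel_slice(g, ch, ch)
        rc <- dw_stage_bwd(gg, p$cheap, cache$cheap, node$bias,
                           node$batchnorm, node$activation)
        rp <- conv_stage_bwd(gp + rc$dx, p$primary, cache$primary, node$bias,
                             node$batchnorm, node$activation)
        grads[[id]] <- list(primary = rp$grads, cheap = rc$grads)
        add_grad(node$inputs[1], rp$dx)
      },
      deconv = {
        r <- deconv_bwd(g, cache$x, p$w, node$bias)
        grads[[id]] <- r$grads
        add_grad(node$inputs[1], r$dx)
      },
      maxpool = add_grad(node$inputs[1],
                         cpp_maxpool_bwd(g, cache$idx, cache$H, cache$W)),
      bilinear_up = add_grad(node$inputs[1],
                             cpp_bilinear_bwd(g, as.integer(node$factor))),
      add = for (src in node$inputs) add_grad(src, g),
      concat = {
        at <- 0
        for (k in seq_along(node$inputs)) {
          ck <- cache$splits[k]
          add_grad(node$inputs[k], g[, , at + seq_len(ck), , drop = FALSE])
          at <- at + ck
        }
      })
  }
  grads
}

#' Soft Dice loss
#'
#' `1 - mean_i softDice(p_i, t_i)` over the batch, with a smoothing constant
#' added to numerator and denominator so the loss is defined and
#' differentiable when either region is empty.
#'
#' @param prob probability maps `(H, W, C[, N])` in `[0, 1]`.
#' @param truth binary ground-truth masks, same layout.
#' @param eps smoothing constant (default 1).
#' @return scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(prob, truth, eps = 1) {
  p <- as_feature_map(prob)$x
  t <- as_feature_map(truth)$x
  stopifnot(identical(dim(p), dim(t)))
  n <- dim(p)[4]
  pm <- matrix(p, ncol = n)
  tm <- matrix(t, ncol = n)
  num <- 2 * colSums(pm * tm) + eps
  den <- colSums(pm) + colSums(tm) + eps
  1 - mean(num / den)
}

dice_loss_grad <- function(prob, truth, eps = 1) {
  d <- dim(prob)
  n <- d[4]
  pm <- matrix(prob, ncol = n)
  tm <- matrix(truth, ncol = n)
  num <- 2 * colSums(pm * tm) + eps
  den <- colSums(pm) + colSums(tm) + eps
  # d(1 - mean num/den)/dp = -(2*t*den - num) / den^2 / n
  g <- -(2 * tm * rep(den, each = nrow(tm)) -
           rep(num, each = nrow(tm))) / rep(den^2, each = nrow(tm)) / n
  array(g, dim = d)
}

leaf_apply <- function(p, g, f) {
  if (is.list(p)) {
    out <- p
    for (nm in names(p)) out[[nm]] <- leaf_apply(p[[nm]], g[[nm]], f)
    out
  } else f(p, g)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

# in: params/grads/m/v parallel structures; out: updated triple
adam_step <- function(params, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  rec <- function(p, g, m_, v_, nm) {
    if (is.list(p)) {
      for (k in names(p)) {
        r <- rec(p[[k]], g[[k]], m_[[k]], v_[[k]], k)
        p[[k]] <- r$p; m_[[k]] <- r$m; v_[[k]] <- r$v
      }
      return(list(p = p, m = m_, v = v_))
    }
    if (is.null(g)) g <- p * 0
    if (weight_decay > 0 && identical(nm, "w")) g <- g + weight_decay * p
    m_ <- beta1 * m_ + (1 - beta1) * g
    v_ <- beta2 * v_ + (1 - beta2) * g * g
    mhat <- m_ / (1 - beta1^t)
    vhat <- v_ / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m_, v = v_)
  }
  rec(params, grads, m, v, "")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, initial learning rate 0.001
#' reduced to `initial/2` at epoch 30 and `initial/10` at epoch 50, 60
#' epochs, Dice loss, validation fraction 0.2, Kaiming initialization and L2
#' regularization. An alternative compounding reading of the schedule
#' ("divide the current rate by 10") is available via `schedule_mode`.
#'
#' @param epochs number of epochs.
#' @param batch_size mini-batch size (14 for small images in the reference
#'   protocol, 2 for large ones).
#' @param initial_lr initial Adam learning rate.
#' @param lr_drops data.frame with columns `epoch` and `divisor`.
#' @param schedule_mode `"of_initial"` (divide the initial rate) or
#'   `"compound"` (divide the current rate).
#' @param validation_fraction fraction of the training set held out for
#'   per-epoch validation.
#' @param weight_decay L2 penalty strength on convolution weights.
#' @param loss_eps smoothing constant of the Dice loss.
#' @param seed RNG seed controlling initialization, splits and shuffling.
#' @param repeats number of independent repeats (averaged externally).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 60L, batch_size = 14L, initial_lr = 1e-3,
                         lr_drops = data.frame(epoch = c(30L, 50L),
                                               divisor = c(2, 10)),
                         schedule_mode = c("of_initial", "compound"),
                         validation_fraction = 0.2, weight_decay = 1e-5,
                         loss_eps = 1, seed = 1L, repeats = 1L) {
  schedule_mode <- match.arg(schedule_mode)
  stopifnot(epochs >= 1, validation_fraction > 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_drops = lr_drops,
                 schedule_mode = schedule_mode,
                 validation_fraction = validation_fraction,
                 weight_decay = weight_decay, loss_eps = loss_eps,
                 seed = as.integer(seed), repeats = as.integer(repeats)),
            class = "train_config")
}

#' Learning-rate trace implied by a training configuration
#'
#' @param config a [train_config()].
#' @return numeric vector of length `epochs`.
#' @export
lr_trace <- function(config) {
  lr <- rep(config$initial_lr, config$epochs)
  drops <- config$lr_drops[order(config$lr_drops$epoch), , drop = FALSE]
  cur_div <- 1
  for (k in seq_len(nrow(drops))) {
    e <- drops$epoch[k]
    if (e > config$epochs) next
    cur_div <- if (config$schedule_mode == "of_initial") drops$divisor[k]
               else cur_div * drops$divisor[k]
    lr[e:config$epochs] <- config$initial_lr / cur_div
  }
  lr
}

#' Train a network with Adam and Dice loss
#'
#' Splits off a seeded validation fraction, trains with mini-batch Adam under
#' the configured learning-rate schedule, tracks per-epoch train/validation
#' loss and Dice, and keeps the weights of the best validation epoch.
#'
#' @param net a `network_spec` with a sigmoid single- or multi-channel head.
#' @param x training images `(H, W, C, N)` (or see `manifest`).
#' @param y binary masks `(H, W, Cout, N)`.
#' @param config a [train_config()].
#' @param manifest optionally, a dataset manifest data.frame instead of
#'   `x`/`y`; its `"train"` split is loaded from disk.
#' @param verbose print per-epoch progress.
#' @return a `halfunet_fit` object: `network`, `params` (best validation
#'   weights), `state`, `history` data.frame, `config`, `best_epoch`.
#' @export
train_network <- function(net, x = NULL, y = NULL, config = train_config(),
                          manifest = NULL, verbose = FALSE) {
  if (!is.null(manifest)) {
    arr <- load_manifest_arrays(manifest, split = "train")
    x <- arr$x; y <- arr$y
  }
  x <- as_feature_map(x)$x
  y <- as_feature_map(y)$x
  n <- dim(x)[4]
  if (n < 2) stop("need at least two training images")
  set.seed(config$seed)
  ini <- net_init(net, "kaiming")
  params <- ini$params; state <- ini$state
  m <- zeros_like(params); v <- zeros_like(params)
  n_val <- max(1L, floor(config$validation_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop("validation split consumed the whole training set")
  lrs <- lr_trace(config)
  hist <- data.frame(epoch = seq_len(config$epochs), lr = lrs,
                     train_loss = NA_real_, train_dice = NA_real_,
                     val_loss = NA_real_, val_dice = NA_real_)
  best <- list(dice = -Inf, params = params, state = state, epoch = 0L)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batch_losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      xb <- x[, , , b, drop = FALSE]
      yb <- y[, , , b, drop = FALSE]
      fwd <- net_forward(net, params, state, xb, train = TRUE,
                         keep_cache = TRUE)
      state <- fwd$state
      loss <- dice_loss(fwd$out, yb, config$loss_eps)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep, " (diverged); ",
             "reduce the learning rate or check the inputs")
      grads <- net_backward(net, params, fwd,
                            dice_loss_grad(fwd$out, yb, config$loss_eps))
      step <- step + 1L
      upd <- adam_step(params, grads, m, v, lrs[ep], step,
                       weight_decay = config$weight_decay)
      params <- upd$p; m <- upd$m; v <- upd$v
      batch_losses <- c(batch_losses, loss)
    }
    val <- eval_split(net, params, state, x, y, val_idx, config)
    hist$train_loss[ep] <- mean(batch_losses)
    hist$train_dice[ep] <- 1 - mean(batch_losses)
    hist$val_loss[ep] <- val$loss
    hist$val_dice[ep] <- val$dice
    if (val$dice > best$dice)
      best <- list(dice = val$dice, params = params, state = state, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  train loss %.4f  val dice %.4f",
                      ep, lrs[ep], hist$train_loss[ep], val$dice))
  }
  structure(list(network = net, params = best$params, state = best$state,
                 final_params = params, final_state = state, history = hist,
                 config = config, best_epoch = best$epoch,
                 val_index = val_idx),
            class = "halfunet_fit")
}

eval_split <- function(net, params, state, x, y, idx, config, chunk = 8L) {
  losses <- c(); dices <- c()
  for (b in split(idx, ceiling(seq_along(idx) / chunk))) {
    xb <- x[, , , b, drop = FALSE]
    yb <- y[, , , b, drop = FALSE]
    out <- net_forward(net, params, state, xb, train = FALSE)$out
    losses <- c(losses, dice_loss(out, yb, config$loss_eps))
    for (k in seq_along(b))
      dices <- c(dices, dice(out[, , , k], yb[, , , k]))
  }
  list(loss = mean(losses), dice = mean(dices))
}

#' @export
print.halfunet_fit <- function(x, ...) {
  h <- x$history
  cat("halfunet_fit: '", x$network$name, "', ", nrow(h), " epochs, ",
      enumerate_params(x$params), " learnable parameters\n", sep = "")
  cat(sprintf("best validation Dice %.4f at epoch %d\n",
              max(h$val_dice, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' Predict probability maps from a trained fit
#'
#' @param object a `halfunet_fit`.
#' @param x images `(H, W, C[, N])`.
#' @param chunk images evaluated per forward pass.
#' @param ... unused.
#' @return probability maps with the same batch layout as `x`.
#' @export
predict.halfunet_fit <- function(object, x, chunk = 8L, ...) {
  fm <- as_feature_map(x)
  n <- dim(fm$x)[4]
  outs <- lapply(split(seq_len(n), ceiling(seq_len(n) / chunk)), function(b) {
    net_forward(object$network, object$params, object$state,
                fm$x[, , , b, drop = FALSE], train = FALSE)$out
  })
  out <- if (length(outs) == 1) outs[[1]] else {
    d <- dim(outs[[1]]); d[4] <- n
    arr <- array(0, d)
    at <- 0
    for (o in outs) { arr[, , , at + seq_len(dim(o)[4])] <- o; at <- at + dim(o)[4] }
    arr
  }
  unbatch(out, fm$batched)
}

#' @export
plot.halfunet_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_dice, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "Dice / loss", ...)
  graphics::lines(h$epoch, h$train_loss, lty = 2)
  graphics::legend("bottomright", c("validation Dice", "training loss"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Evaluate a fit (or raw weights) on a test set
#'
#' Computes per-image Dice, sensitivity and specificity at the given
#' threshold and their per-image averages.
#'
#' @param fit a `halfunet_fit`.
#' @param x,y test images and binary masks; alternatively pass `manifest`
#'   (with `split = "test"` records).
#' @param manifest optional dataset manifest data.frame.
#' @param split manifest split to evaluate.
#' @param threshold probability threshold for hard metrics.
#' @return list with `per_image` data.frame and `aggregate` named vector.
#' @export
evaluate_network <- function(fit, x = NULL, y = NULL, manifest = NULL,
                             split = "test", threshold = 0.5) {
  if (!is.null(manifest)) {
    arr <- load_manifest_arrays(manifest, split = split)
    x <- arr$x; y <- arr$y
  }
  x <- as_feature_map(x)$x
  y <- as_feature_map(y)$x
  prob <- predict(fit, x)
  n <- dim(x)[4]
  rows <- lapply(seq_len(n), function(k) {
    p <- prob[, , , k]; t <- y[, , , k]
    data.frame(image = k, dice = dice(p, t, threshold),
               sensitivity = sensitivity(p, t, threshold),
               specificity = specificity(p, t, threshold))
  })
  per_image <- do.call(rbind, rows)
  agg <- c(dice = mean(per_image$dice, na.rm = TRUE),
           sensitivity = mean(per_image$sensitivity, na.rm = TRUE),
           specificity = mean(per_image$specificity, na.rm = TRUE))
  list(per_image = per_image, aggregate = agg)
}
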