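test_that("the learning-rate trace implements the two-drop schedule", {
  tc <- train_config(epochs = 60)
  lr <- lr_trace(tc)
  expect_equal(lr[1:29], rep(0.001, 29))
  expect_equal(lr[30:49], rep(0.0005, 20))
  expect_equal(lr[50:60], rep(0.0001, 11))
  # compounding reading divides the current rate instead
  tc2 <- train_config(epochs = 60, schedule_mode = "compound")
  expect_equal(lr_trace(tc2)[55], 0.001 / 20)
  # drops beyond the horizon are ignored
  expect_equal(lr_trace(train_config(epochs = 10)), rep(0.001, 10))
})

test_that("forward passes are batched, finite and in (0, 1) at several sizes", {
  set.seed(51)
  for (size in c(16, 32)) {
    net <- build_half_unet(tiny_cfg(size = size))
    ini <- net_init(net)
    x <- rand_fm(size, size, 1, 3)
    out <- net_forward(net, ini$params, ini$state, x)$out
    expect_equal(dim(out), c(size, size, 1, 3))
    expect_true(all(is.finite(out)) && all(out > 0) && all(out < 1))
  }
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(52)
  net <- build_half_unet(tiny_cfg(size = 8, base = 4, depth = 2))
  ini <- net_init(net)
  x <- rand_fm(8, 8, 1, 2)
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  lossfun <- function(p)
    dice_loss(net_forward(net, p, ini$state, x, train = TRUE)$out, y)
  fwd <- net_forward(net, ini$params, ini$state, x, train = TRUE,
                     keep_cache = TRUE)
  grads <- halfunet:::net_backward(net, ini$params, fwd,
                                   halfunet:::dice_loss_grad(fwd$out, y))
  probes <- list(list("enc1_b1", c("primary", "w"), 2),
                 list("enc2_b2", c("cheap", "w"), 3),
                 list("dec_b1", c("primary", "gamma"), 1),
                 list("dec_b2", c("cheap", "beta"), 2),
                 list("head", "w", 1), list("head", "b", 1))
  h <- 1e-5
  for (pr in probes) {
    id <- pr[[1]]; path <- pr[[2]]; k <- pr[[3]]
    shift <- function(delta) {
      p2 <- ini$params
      tmp <- p2[[id]]
      if (length(path) == 1) tmp[[path]][k] <- tmp[[path]][k] + delta
      else tmp[[path[1]]][[path[2]]][k] <- tmp[[path[1]]][[path[2]]][k] + delta
      p2[[id]] <- tmp
      p2
    }
    num <- (lossfun(shift(h)) - lossfun(shift(-h))) / (2 * h)
    g <- grads[[id]]
    for (s in path) g <- g[[s]]
    expect_equal(num, g[k], tolerance = 1e-4,
                 label = paste(id, paste(path, collapse = "$"), k))
  }
})

test_that("training learns a separable synthetic task and records its run", {
  set.seed(53)
  ds <- tiny_dataset(regime = "nodule", size = 16, n = 12, seed = 13)
  arr <- load_manifest_arrays(ds$man, "train")
  net <- build_half_unet(tiny_cfg(size = 16, base = 8, depth = 2))
  tc <- train_config(epochs = 6, batch_size = 4, seed = 2,
                     validation_fraction = 0.25)
  fit <- train_network(net, arr$x, arr$y, tc)
  h <- fit$history
  expect_equal(nrow(h), 6)
  expect_equal(h$lr, lr_trace(tc))
  expect_true(all(is.finite(h$train_loss)))
  expect_gt(h$train_dice[6], h$train_dice[1])
  expect_s3_class(fit, "halfunet_fit")
  expect_output(print(fit), "halfunet_fit")

  # prediction on new inputs has the training contract
  te <- load_manifest_arrays(ds$man, "test")
  prob <- predict(fit, te$x)
  expect_equal(dim(prob), dim(te$x))
  expect_true(all(prob > 0 & prob < 1))

  # evaluate() agrees with direct per-image metric calls
  res <- evaluate_network(fit, te$x, te$y)
  k <- 2
  expect_equal(res$per_image$dice[k], dice(prob[, , , k], te$y[, , , k]))
  expect_equal(res$per_image$specificity[k],
               specificity(prob[, , , k], te$y[, , , k]))
  # ground truth as its own prediction scores perfectly; an all-background
  # prediction is perfectly specific
  expect_equal(dice(te$y[, , , 1], te$y[, , , 1]), 1)
  expect_equal(specificity(te$y[, , , 1] * 0, te$y[, , , 1]), 1)
})

test_that("runs are deterministic given the seed, and L2 shrinks the weights", {
  ds <- tiny_dataset(regime = "nodule", size = 16, n = 8, seed = 14)
  arr <- load_manifest_arrays(ds$man, "train")
  net <- build_half_unet(tiny_cfg(size = 16, base = 4, depth = 2))
  tc <- train_config(epochs = 2, batch_size = 3, seed = 5)
  f1 <- train_network(net, arr$x, arr$y, tc)
  f2 <- train_network(net, arr$x, arr$y, tc)
  expect_identical(f1$val_index, f2$val_index)
  expect_equal(f1$history, f2$history)

  wnorm <- function(fit) {
    s <- 0
    walk <- function(p, nm) {
      if (is.list(p)) for (k in names(p)) walk(p[[k]], k)
      else if (identical(nm, "w")) s <<- s + sum(p^2)
    }
    walk(fit$final_params, "")
    s
  }
  tc0 <- train_config(epochs = 2, batch_size = 3, seed = 5, weight_decay = 0)
  tcL <- train_config(epochs = 2, batch_size = 3, seed = 5, weight_decay = 0.05)
  expect_lt(wnorm(train_network(net, arr$x, arr$y, tcL)),
            wnorm(train_network(net, arr$x, arr$y, tc0)))
})

test_that("all six comparison architectures complete a two-epoch smoke train", {
  ds <- tiny_dataset(regime = "nodule", size = 32, n = 32, seed = 15)
  arr <- load_manifest_arrays(ds$man, "train")
  cfg <- tiny_cfg(size = 32, base = 8, depth = 5)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 3)
  for (nm in c("half-unet", "half-unet-dagger", "half-unet-star-u",
               "half-unet-star-d", "unet", "unet3plus")) {
    fit <- train_network(build_network(nm, cfg), arr$x, arr$y, tc)
    expect_true(all(is.finite(fit$history$train_loss)), label = nm)
  }
})

test_that("empty or degenerate training inputs abort with a diagnostic", {
  net <- build_half_unet(tiny_cfg(size = 8, base = 4, depth = 2))
  x1 <- rand_fm(8, 8, 1, 1)
  expect_error(train_network(net, x1, x1 * 0, train_config(epochs = 1)),
               "at least two")
})
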