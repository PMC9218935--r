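# shared fixtures: tiny configurations and an independent naive convolution

tiny_cfg <- function(size = 16L, base = 4L, depth = 3L, cin = 1L)
  arch_config(input_shape = c(cin, size, size), base_channels = base,
              depth = depth)

rand_fm <- function(h, w, c, n = 1) array(stats::rnorm(h * w * c * n),
                                          c(h, w, c, n))

# brute-force "same"-padded stride-1 convolution, the oracle for the runtime
naive_conv <- function(x, w, b = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  K <- dim(w)[1]; Cout <- dim(w)[4]; pad <- (K - 1) / 2
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(Cin)) for (ki in seq_len(K)) for (kj in seq_len(K)) {
        si <- i + ki - 1 - pad; sj <- j + kj - 1 - pad
        if (si >= 1 && si <= H && sj >= 1 && sj <= W)
          acc <- acc + x[si, sj, ci] * w[ki, kj, ci, co]
      }
      y[i, j, co] <- acc
    }
  }
  y
}

tiny_dataset <- function(regime = "nodule", size = 16, n = 6, seed = 3,
                         dir = tempfile("ds")) {
  cfg <- synthetic_config(regime, image_size = size, n_images = n, seed = seed,
                          noise_sd = 0.02)
  man <- generate_dataset(cfg, dir)
  list(cfg = cfg, man = man, dir = dir)
}
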