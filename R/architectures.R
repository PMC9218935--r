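#' Architecture configuration
#'
#' Shared knobs for every builder. The canonical configuration is a
#' single-channel input, five scales, 64 base channels; unified-channel
#' architectures (Half-UNet family) keep 64 channels at every scale, while
#' the doubling baselines (U-Net, UNet3+, the starred variants) double the
#' channel count after each downsampling (64, 128, ..., 1024).
#'
#' @param input_shape `c(channels, height, width)`; height and width must be
#'   divisible by `2^(depth - 1)`.
#' @param base_channels channels at the finest scale (default 64).
#' @param depth number of scales (default 5).
#' @param output_channels channels of the sigmoid output head (default 1).
#' @return an `arch_config` list.
#' @export
arch_config <- function(input_shape = c(1, 128, 128), base_channels = 64L,
                        depth = 5L, output_channels = 1L) {
  stopifnot(depth >= 2, base_channels >= 1, length(input_shape) == 3)
  down <- 2^(depth - 1)
  if (input_shape[2] %% down != 0 || input_shape[3] %% down != 0)
    stop("input height/width must be divisible by ", down,
         " for depth ", depth)
  structure(list(input_shape = as.integer(input_shape),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 output_channels = as.integer(output_channels)),
            class = "arch_config")
}

# two conv-or-ghost blocks forming one encoder/decoder stage
add_stage <- function(net, prefix, from, kind, out_channels) {
  b1 <- paste0(prefix, "_b1"); b2 <- paste0(prefix, "_b2")
  net <- net_add(net, b1, kind, from, out_channels = out_channels)
  net <- net_add(net, b2, kind, b1, out_channels = out_channels)
  net
}

half_unet_core <- function(config, kind, name) {
  base <- config$base_channels
  net <- network_spec(name, config$input_shape)
  taps <- character(config$depth)
  from <- "input"
  for (s in seq_len(config$depth)) {
    if (s > 1) {
      pid <- paste0("pool", s - 1)
      net <- net_add(net, pid, "maxpool", from, factor = 2L)
      from <- pid
    }
    net <- add_stage(net, paste0("enc", s), from, kind, base)
    taps[s] <- from <- paste0("enc", s, "_b2")
  }
  fuse_in <- character(config$depth)
  left_ids <- character()
  for (s in seq_len(config$depth)) {
    if (s == 1) {
      fuse_in[s] <- taps[s]
    } else {
      uid <- paste0("up", 2^(s - 1))
      net <- net_add(net, uid, "bilinear_up", taps[s], factor = 2L^(s - 1L))
      fuse_in[s] <- uid
      left_ids <- c(left_ids, uid)
    }
  }
  net <- net_add(net, "fuse", "add", fuse_in)
  left_ids <- c(left_ids, "fuse")
  net <- net_add(net, "dec_b1", kind, "fuse", out_channels = base)
  net <- net_add(net, "dec_b2", kind, "dec_b1", out_channels = base)
  net <- net_add(net, "head", "conv", "dec_b2", kernel = 1L,
                 out_channels = config$output_channels, bias = TRUE,
                 batchnorm = FALSE, activation = "sigmoid")
  net <- net_set_output(net, "head")
  net$last_fusion <- list(left = left_ids, right = "dec_b1",
                          taps = fuse_in)
  validate_network(net)
  net
}

#' Build Half-UNet and its variants
#'
#' `build_half_unet()` assembles the canonical Half-UNet: an encoder of five
#' stages of two Ghost modules each at a unified 64 channels separated by 2x2
#' max pools, a decoder that bilinearly upsamples all five stage outputs to
#' full resolution and fuses them by addition (no learnable parameters), two
#' further Ghost modules, and a 1x1 sigmoid head. `build_half_unet_dagger()`
#' is the identical topology with every Ghost module replaced by a plain 3x3
#' convolution block. `build_half_unet_star()` doubles the channel count
#' after each downsampling (64..1024, no Ghost modules) and unifies channels
#' in the decoder either by bilinear upsampling + 3x3 convolution
#' (`"upsample_conv"`) or by transposed convolution (`"deconv"`) before the
#' additive fusion.
#'
#' @param config an [arch_config()].
#' @param fusion channel-unification strategy for the starred variants.
#' @return a validated `network_spec`.
#' @export
build_half_unet <- function(config = arch_config()) {
  half_unet_core(config, "ghost", "half-unet")
}

#' @rdname build_half_unet
#' @export
build_half_unet_dagger <- function(config = arch_config()) {
  half_unet_core(config, "conv", "half-unet-dagger")
}

#' @rdname build_half_unet
#' @export
build_half_unet_star <- function(config = arch_config(),
                                 fusion = c("upsample_conv", "deconv")) {
  fusion <- match.arg(fusion)
  base <- config$base_channels
  chs <- base * 2L^(seq_len(config$depth) - 1L)
  name <- paste0("half-unet-star-", if (fusion == "upsample_conv") "u" else "d")
  net <- network_spec(name, config$input_shape)
  taps <- character(config$depth)
  from <- "input"
  for (s in seq_len(config$depth)) {
    if (s > 1) {
      pid <- paste0("pool", s - 1)
      net <- net_add(net, pid, "maxpool", from, factor = 2L)
      from <- pid
    }
    net <- add_stage(net, paste0("enc", s), from, "conv", chs[s])
    taps[s] <- from <- paste0("enc", s, "_b2")
  }
  fuse_in <- character(config$depth)
  for (s in seq_len(config$depth)) {
    if (s == 1) {
      fuse_in[s] <- taps[s]  # already at base channels and full size
    } else if (fusion == "upsample_conv") {
      uid <- paste0("up", 2^(s - 1))
      net <- net_add(net, uid, "bilinear_up", taps[s], factor = 2L^(s - 1L))
      cid <- paste0("unify", s)
      net <- net_add(net, cid, "conv", uid, kernel = 3L, out_channels = base)
      fuse_in[s] <- cid
    } else {
      did <- paste0("deconv", s)
      net <- net_add(net, did, "deconv", taps[s], kernel = 2L^(s - 1L),
                     out_channels = base, bias = TRUE)
      fuse_in[s] <- did
    }
  }
  net <- net_add(net, "fuse", "add", fuse_in)
  net <- net_add(net, "dec_b1", "conv", "fuse", out_channels = base)
  net <- net_add(net, "dec_b2", "conv", "dec_b1", out_channels = base)
  net <- net_add(net, "head", "conv", "dec_b2", kernel = 1L,
                 out_channels = config$output_channels, bias = TRUE,
                 batchnorm = FALSE, activation = "sigmoid")
  net <- net_set_output(net, "head")
  validate_network(net)
  net
}

# U-Net encoder shared by several builders; returns list(net, taps)
unet_encoder <- function(net, config) {
  chs <- config$base_channels * 2L^(seq_len(config$depth) - 1L)
  taps <- character(config$depth)
  from <- "input"
  for (s in seq_len(config$depth)) {
    if (s > 1) {
      pid <- paste0("pool", s - 1)
      net <- net_add(net, pid, "maxpool", from, factor = 2L)
      from <- pid
    }
    net <- add_stage(net, paste0("enc", s), from, "conv", chs[s])
    taps[s] <- from <- paste0("enc", s, "_b2")
  }
  list(net = net, taps = taps, chs = chs)
}

#' Build the baseline U-Net
#'
#' Canonical 2-D U-Net: five encoder stages of double 3x3 convolutions with
#' batch normalization (channels 64 to 1024) separated by 2x2 max pools; a
#' decoder of 2x2/stride-2 transposed convolutions, skip concatenation and a
#' double convolution per stage; and a 1x1 sigmoid head.
#'
#' @param config an [arch_config()].
#' @return a validated `network_spec`.
#' @export
build_unet <- function(config = arch_config()) {
  net <- network_spec("unet", config$input_shape)
  enc <- unet_encoder(net, config)
  net <- enc$net; taps <- enc$taps; chs <- enc$chs
  from <- taps[config$depth]
  for (s in rev(seq_len(config$depth - 1))) {
    did <- paste0("deconv", s)
    net <- net_add(net, did, "deconv", from, kernel = 2L, out_channels = chs[s])
    kid <- paste0("skip", s)
    net <- net_add(net, kid, "concat", c(taps[s], did))
    net <- add_stage(net, paste0("dec", s), kid, "conv", chs[s])
    from <- paste0("dec", s, "_b2")
  }
  net <- net_add(net, "head", "conv", from, kernel = 1L,
                 out_channels = config$output_channels, bias = TRUE,
                 batchnorm = FALSE, activation = "sigmoid")
  net <- net_set_output(net, "head")
  net$last_fusion <- list(left = c("deconv1", "skip1"), right = "dec1_b1",
                          taps = c(taps[1], "deconv1"))
  validate_network(net)
  net
}

# one full-scale aggregation layer: resample every tap to `scale`, unify to
# `width` channels with a 3x3 conv, concat, then a square aggregation conv
add_aggregation <- function(net, prefix, taps, tap_scales, scale, width) {
  unified <- character(length(taps))
  left_ids <- character()
  for (k in seq_along(taps)) {
    src <- taps[k]
    if (tap_scales[k] > scale) {
      rid <- paste0(prefix, "_up", k)
      net <- net_add(net, rid, "bilinear_up", src,
                     factor = as.integer(tap_scales[k] / scale))
      src <- rid; left_ids <- c(left_ids, rid)
    } else if (tap_scales[k] < scale) {
      rid <- paste0(prefix, "_down", k)
      net <- net_add(net, rid, "maxpool", src,
                     factor = as.integer(scale / tap_scales[k]))
      src <- rid; left_ids <- c(left_ids, rid)
    }
    cid <- paste0(prefix, "_unify", k)
    net <- net_add(net, cid, "conv", src, kernel = 3L, out_channels = width)
    unified[k] <- cid
    left_ids <- c(left_ids, cid)
  }
  ccat <- paste0(prefix, "_concat")
  net <- net_add(net, ccat, "concat", unified)
  left_ids <- c(left_ids, ccat)
  agg <- paste0(prefix, "_agg")
  net <- net_add(net, agg, "conv", ccat, kernel = 3L,
                 out_channels = width * length(taps))
  list(net = net, agg = agg, left = left_ids)
}

#' Build the UNet3+-style full-scale aggregation network
#'
#' U-Net encoder (channels doubling to 1024) followed by full-scale
#' aggregation decoder layers: at each decoder scale, every encoder tap is
#' max-pooled or bilinearly upsampled to that scale, passed through a 3x3
#' convolution to 64 channels, concatenated (5 x 64 = 320 channels) and fused
#' by a 3x3 convolution keeping 320 channels. Only the full-resolution layer
#' feeds the sigmoid head; coarser aggregation layers are retained as side
#' branches (deep supervision itself is out of scope) and are included in
#' complexity totals.
#'
#' @param config an [arch_config()].
#' @return a validated `network_spec`.
#' @export
build_unet3plus <- function(config = arch_config()) {
  net <- network_spec("unet3plus", config$input_shape)
  enc <- unet_encoder(net, config)
  net <- enc$net
  tap_scales <- 2^(seq_len(config$depth) - 1)
  width <- config$base_channels
  last <- NULL
  for (s in rev(seq_len(config$depth - 1))) {
    r <- add_aggregation(net, paste0("de", s), enc$taps, tap_scales,
                         scale = 2^(s - 1), width = width)
    net <- r$net
    last <- r
  }
  net <- net_add(net, "head", "conv", last$agg, kernel = 1L,
                 out_channels = config$output_channels, bias = TRUE,
                 batchnorm = FALSE, activation = "sigmoid")
  net <- net_set_output(net, "head")
  net$last_fusion <- list(left = last$left, right = last$agg, taps = enc$taps)
  validate_network(net)
  net
}

#' Build the ablation encoders
#'
#' Three encoder structures sharing a single full-scale aggregation decoder
#' head: variant `"A"` uses the contracting (U-Net encoder) path and emits
#' its five multi-scale taps; variant `"C"` uses the complete U-Net
#' (contracting + expanding) and taps the bottleneck plus the four decoder
#' stage outputs; variant `"B"` is a best-effort reconstruction of "the
#' expanding path used as an encoder": the input is pooled to the coarsest
#' scale, mapped to the widest channel count, and processed coarse-to-fine
#' with learned (transposed-convolution) upsampling, tapping every scale.
#'
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param config an [arch_config()].
#' @return a validated `network_spec`.
#' @export
build_ablation_encoder <- function(variant = c("A", "B", "C"),
                                   config = arch_config()) {
  variant <- match.arg(variant)
  chs <- config$base_channels * 2L^(seq_len(config$depth) - 1L)
  net <- network_spec(paste0("encoder-", tolower(variant)), config$input_shape)
  if (variant == "A") {
    enc <- unet_encoder(net, config)
    net <- enc$net; taps <- enc$taps
    tap_scales <- 2^(seq_len(config$depth) - 1)
  } else if (variant == "C") {
    enc <- unet_encoder(net, config)
    net <- enc$net
    from <- enc$taps[config$depth]
    taps <- c(enc$taps[config$depth])
    tap_scales <- 2^(config$depth - 1)
    for (s in rev(seq_len(config$depth - 1))) {
      did <- paste0("deconv", s)
      net <- net_add(net, did, "deconv", from, kernel = 2L, out_channels = chs[s])
      kid <- paste0("skip", s)
      net <- net_add(net, kid, "concat", c(enc$taps[s], did))
      net <- add_stage(net, paste0("dec", s), kid, "conv", chs[s])
      from <- paste0("dec", s, "_b2")
      taps <- c(taps, from)
      tap_scales <- c(tap_scales, 2^(s - 1))
    }
  } else {
    down <- 2L^(config$depth - 1L)
    net <- net_add(net, "shrink", "maxpool", "input", factor = down)
    net <- add_stage(net, paste0("exp", config$depth), "shrink", "conv",
                     chs[config$depth])
    from <- paste0("exp", config$depth, "_b2")
    taps <- c(from)
    tap_scales <- 2^(config$depth - 1)
    for (s in rev(seq_len(config$depth - 1))) {
      did <- paste0("updeconv", s)
      net <- net_add(net, did, "deconv", from, kernel = 2L, out_channels = chs[s])
      net <- add_stage(net, paste0("exp", s), did, "conv", chs[s])
      from <- paste0("exp", s, "_b2")
      taps <- c(taps, from)
      tap_scales <- c(tap_scales, 2^(s - 1))
    }
  }
  r <- add_aggregation(net, "de1", taps, tap_scales, scale = 1,
                       width = config$base_channels)
  net <- r$net
  net <- net_add(net, "head", "conv", r$agg, kernel = 1L,
                 out_channels = config$output_channels, bias = TRUE,
                 batchnorm = FALSE, activation = "sigmoid")
  net <- net_set_output(net, "head")
  net$last_fusion <- list(left = r$left, right = r$agg, taps = taps)
  validate_network(net)
  net
}

#' List available architecture builders
#'
#' @return character vector of names accepted by [build_network()].
#' @export
list_networks <- function() {
  c("half-unet", "half-unet-dagger", "half-unet-star-u", "half-unet-star-d",
    "unet", "unet3plus", "encoder-a", "encoder-b", "encoder-c")
}

#' Build a network by name
#'
#' @param name one of [list_networks()].
#' @param config an [arch_config()].
#' @return a validated `network_spec`.
#' @export
build_network <- function(name, config = arch_config()) {
  switch(name,
    "half-unet" = build_half_unet(config),
    "half-unet-dagger" = build_half_unet_dagger(config),
    "half-unet-star-u" = build_half_unet_star(config, "upsample_conv"),
    "half-unet-star-d" = build_half_unet_star(config, "deconv"),
    "unet" = build_unet(config),
    "unet3plus" = build_unet3plus(config),
    "encoder-a" = build_ablation_encoder("A", config),
    "encoder-b" = build_ablation_encoder("B", config),
    "encoder-c" = build_ablation_encoder("C", config),
    stop("unknown architecture '", name, "'; available: ",
         paste(list_networks(), collapse = ", "))
  )
}

#' Split off a network's last feature-fusion sub-network
#'
#' Divides the final fusion stage into its fusion part ("left": upsampling,
#' transposed convolutions or channel-unifying convolutions plus the
#' add/concat node) and its convolution part ("right": the single
#' convolution or Ghost module immediately after the fusion), each returned
#' as a standalone `network_spec` whose inputs carry the shapes inferred
#' from the parent network.
#'
#' @param net a `network_spec` built by one of the builders that tag their
#'   last fusion (Half-UNet family, U-Net, UNet3+, ablation encoders).
#' @return list with elements `left` and `right`.
#' @export
extract_last_fusion <- function(net) {
  lf <- net$last_fusion
  if (is.null(lf))
    stop("network '", net$name, "' does not tag a last-fusion stage")
  left_out <- lf$left[length(lf$left)]  # the add/concat node
  left <- subnetwork(net, lf$left, paste0(net$name, "_left"), left_out)
  right <- subnetwork(net, lf$right, paste0(net$name, "_right"), lf$right)
  list(left = left, right = right)
}

#' Channel total entering a network's last fusion
#'
#' Sum of the channel counts of the (resampled) feature maps feeding the
#' last feature-fusion stage, before any channel unification.
#'
#' @param net a `network_spec` with a tagged last fusion.
#' @return integer channel count.
#' @export
last_fusion_input_channels <- function(net) {
  lf <- net$last_fusion
  if (is.null(lf)) stop("network '", net$name, "' does not tag a last fusion")
  shapes <- network_shapes(net)
  sum(vapply(lf$taps, function(id) shapes[[id]][1], integer(1)))
}
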