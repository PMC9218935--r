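#' Analytic parameter and FLOP counts for single layers
#'
#' Closed-form accounting for the building blocks. For a `K x K` convolution
#' with `Cin` input and `Cout` output channels the parameter count is
#' `(K^2 * Cin + 1) * Cout` (the `+1` is the bias) and the FLOP count on an
#' `Hout x Wout` output is `2 * K^2 * Cin * Cout * Hout * Wout` (two
#' operations per multiply-accumulate). A Ghost module with ratio `s = 2` and
#' cheap kernel equal to its primary kernel costs
#' `[K^2 * (Cin + 1) + 2] * Cout / 2` parameters and
#' `2 * K^2 * (Cin + 1) * (Cout / 2) * Hout * Wout` FLOPs — the primary
#' convolution produces `Cout/2` intrinsic maps and the depthwise cheap
#' operation the remaining `Cout/2`. A transposed convolution's FLOPs scale
#' with its input (not output) size: `2 * K^2 * Cin * Cout * Hin * Win`.
#'
#' Accounting rules: bias, batchnorm, activation, pooling, interpolation and
#' elementwise addition contribute zero FLOPs; batchnorm contributes 2
#' learnable parameters per channel (scale and shift); running statistics are
#' not counted.
#'
#' @param spec a [conv_spec()], [ghost_spec()] or [deconv_spec()].
#' @return a count (numeric scalar).
#' @export
conv_params <- function(spec) {
  p <- (spec$kernel^2 * spec$in_channels + as.integer(spec$bias)) *
    spec$out_channels
  if (isTRUE(spec$batchnorm)) p <- p + 2 * spec$out_channels
  p
}

#' @rdname conv_params
#' @export
conv_flops <- function(spec) {
  stopifnot(!is.null(spec$out_h), !is.null(spec$out_w))
  2 * spec$kernel^2 * spec$in_channels * spec$out_channels *
    spec$out_h * spec$out_w
}

#' @rdname conv_params
#' @export
ghost_params <- function(spec) {
  ch <- spec$out_channels %/% spec$ratio
  primary <- (spec$kernel^2 * spec$in_channels + as.integer(spec$bias)) * ch
  cheap <- (spec$cheap_kernel^2 + as.integer(spec$bias)) * ch
  p <- primary + cheap
  if (isTRUE(spec$batchnorm)) p <- p + 2 * spec$out_channels
  p
}

#' @rdname conv_params
#' @export
ghost_flops <- function(spec) {
  stopifnot(!is.null(spec$out_h), !is.null(spec$out_w))
  ch <- spec$out_channels %/% spec$ratio
  hw <- spec$out_h * spec$out_w
  2 * spec$kernel^2 * spec$in_channels * ch * hw +
    2 * spec$cheap_kernel^2 * ch * hw
}

#' @rdname conv_params
#' @export
deconv_params <- function(spec) {
  (spec$kernel^2 * spec$in_channels + as.integer(spec$bias)) * spec$out_channels
}

#' @rdname conv_params
#' @export
deconv_flops <- function(spec) {
  stopifnot(!is.null(spec$in_h), !is.null(spec$in_w))
  2 * spec$kernel^2 * spec$in_channels * spec$out_channels *
    spec$in_h * spec$in_w
}

#' Round half away from zero
#'
#' Plain commercial rounding (0.005 -> 0.01), used for the human-readable
#' K/M/G complexity figures.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Format a count in K/M/G units
#'
#' @param x numeric count.
#' @param unit `"auto"` picks the largest of K/M/G not exceeding the value;
#'   otherwise one of `"K"`, `"M"`, `"G"`.
#' @param digits decimal places (round half up).
#' @return character, e.g. `"0.21 M"`.
#' @export
format_count <- function(x, unit = "auto", digits = 2) {
  scale <- c(K = 1e3, M = 1e6, G = 1e9)
  pick <- function(v) {
    if (unit != "auto") return(unit)
    if (v >= 1e9) "G" else if (v >= 1e6) "M" else if (v >= 1e3) "K" else ""
  }
  vapply(x, function(v) {
    u <- pick(v)
    if (u == "") return(format(v))
    sprintf(paste0("%.", digits, "f %s"), round_half_up(v / scale[[u]], digits), u)
  }, character(1))
}

node_counts <- function(node, in_shape, out_shape) {
  kind <- node$kind
  if (kind == "conv") {
    spec <- conv_spec(node$kernel, in_shape[1], node$out_channels,
                      bias = node$bias, batchnorm = node$batchnorm,
                      out_h = out_shape[2], out_w = out_shape[3])
    c(params = conv_params(spec), flops = conv_flops(spec))
  } else if (kind == "ghost") {
    spec <- ghost_spec(node$kernel, in_shape[1], node$out_channels,
                       ratio = node$ratio, cheap_kernel = node$cheap_kernel,
                       bias = node$bias, batchnorm = node$batchnorm,
                       out_h = out_shape[2], out_w = out_shape[3])
    c(params = ghost_params(spec), flops = ghost_flops(spec))
  } else if (kind == "deconv") {
    spec <- deconv_spec(node$kernel, in_shape[1], node$out_channels,
                        bias = node$bias, in_h = in_shape[2], in_w = in_shape[3])
    c(params = deconv_params(spec), flops = deconv_flops(spec))
  } else {
    c(params = 0, flops = 0)
  }
}

#' Analytic complexity report for a whole network
#'
#' Traverses the graph, resolves every layer's spatial dimensions from the
#' input shape and dispatches to the per-layer counters. Pooling, bilinear
#' upsampling, addition, concatenation and activations contribute zero to
#' both totals. All nodes are counted, including side branches.
#'
#' @param net a `network_spec`.
#' @param input_shape optional `c(channels, height, width)` override for the
#'   primary input (parameter totals are invariant to it; FLOPs are not).
#' @return a `complexity_report`: data.frame of per-layer rows plus totals.
#' @export
count_network <- function(net, input_shape = NULL) {
  if (!is.null(input_shape)) {
    stopifnot(length(input_shape) == 3)
    ids <- net_input_ids(net)
    stopifnot(length(ids) == 1)
    net$nodes[[ids]]$shape <- as.integer(input_shape)
    net$input_shape <- as.integer(input_shape)
  }
  shapes <- network_shapes(net)
  rows <- lapply(net$nodes, function(node) {
    in_shape <- if (length(node$inputs)) shapes[[node$inputs[1]]] else NULL
    cnt <- node_counts(node, in_shape, shapes[[node$id]])
    data.frame(layer = node$id, kind = node$kind,
               params = unname(cnt["params"]), flops = unname(cnt["flops"]))
  })
  layers <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(list(network = net$name, layers = layers,
                 total_params = sum(layers$params),
                 total_flops = sum(layers$flops),
                 params_label = format_count(sum(layers$params), "M"),
                 flops_label = format_count(sum(layers$flops), "G")),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("complexity_report for '", x$network, "'\n", sep = "")
  nz <- x$layers[x$layers$params > 0 | x$layers$flops > 0, ]
  if (nrow(nz)) print(nz, row.names = FALSE)
  cat(sprintf("totals: %s params (%s), %s FLOPs (%s)\n",
              format(x$total_params, big.mark = ","), x$params_label,
              format(x$total_flops, big.mark = ","), x$flops_label))
  invisible(x)
}

#' Check analytic parameter counts against the runtime
#'
#' Instantiates the network's weight containers and enumerates every
#' learnable scalar; the result must equal the analytic total from
#' [count_network()].
#'
#' @param net a `network_spec`.
#' @return list with `analytic`, `enumerated` and `equal`.
#' @export
verify_against_runtime <- function(net) {
  analytic <- count_network(net)$total_params
  ini <- net_init(net, init = "zero")
  enumerated <- enumerate_params(ini$params)
  list(analytic = analytic, enumerated = enumerated,
       equal = analytic == enumerated)
}

#' Whole-network comparison table
#'
#' Builds the main architectures at the given input shape and tabulates
#' their total parameters and FLOPs, plus the FLOP multiple relative to the
#' cheapest network.
#'
#' @param input_shape `c(channels, height, width)`.
#' @param networks architecture names (see [list_networks()]).
#' @return data.frame with counts and formatted labels.
#' @export
networks_table <- function(input_shape = c(1, 128, 128),
                           networks = c("unet", "unet3plus",
                                        "half-unet-star-u", "half-unet-star-d",
                                        "half-unet-dagger", "half-unet")) {
  rows <- lapply(networks, function(nm) {
    rep <- count_network(build_network(nm, arch_config(input_shape = input_shape)))
    data.frame(architecture = nm, params = rep$total_params,
               flops = rep$total_flops, params_label = rep$params_label)
  })
  out <- do.call(rbind, rows)
  out$flops_multiple <- round_half_up(out$flops / min(out$flops), 0)
  out
}

#' Last-fusion sub-network comparison table
#'
#' Splits the final feature-fusion stage of UNet3+, U-Net and Half-UNet into
#' its fusion ("left") and convolution ("right") parts and tabulates each
#' part's parameters and FLOPs.
#'
#' @param input_shape `c(channels, height, width)`.
#' @return data.frame with one row per sub-network part.
#' @export
fusion_table <- function(input_shape = c(1, 128, 128)) {
  cfg <- arch_config(input_shape = input_shape)
  nets <- list(`UNet3+` = build_unet3plus(cfg), `U-Net` = build_unet(cfg),
               `Half-UNet` = build_half_unet(cfg))
  rows <- lapply(names(nets), function(nm) {
    parts <- extract_last_fusion(nets[[nm]])
    do.call(rbind, lapply(c("left", "right"), function(side) {
      rep <- count_network(parts[[side]])
      data.frame(network = nm, part = side, params = rep$total_params,
                 flops = rep$total_flops,
                 params_label = rep$params_label, flops_label = rep$flops_label)
    }))
  })
  do.call(rbind, rows)
}
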