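#' Layer specifications
#'
#' Value objects describing the building blocks from which every architecture
#' in the package is assembled. They carry the shape information needed both
#' by the analytic complexity engine and by the runtime.
#'
#' `conv_spec()` describes a stride-1 "same"-padded square convolution;
#' `ghost_spec()` a Ghost module, which produces `out_channels / ratio`
#' intrinsic maps with a standard convolution and the remaining maps with a
#' cheap depthwise convolution applied to the intrinsic maps; `deconv_spec()`
#' a transposed convolution with stride equal to its kernel, so the output is
#' `kernel` times larger than the input.
#'
#' @param kernel square kernel size in pixels (odd for stride-1 convs).
#' @param in_channels,out_channels channel counts.
#' @param bias whether the convolution carries a bias term.
#' @param batchnorm whether a batch-normalization stage (2 learnable scalars
#'   per channel) follows.
#' @param relu whether a ReLU follows.
#' @param out_h,out_w output spatial size in pixels (needed for FLOP counts).
#' @param ratio reciprocal of the intrinsic-map proportion; only `ratio = 2`
#'   (half primary, half ghost maps) is supported.
#' @param cheap_kernel kernel of the depthwise cheap operation.
#' @param in_h,in_w input spatial size of a transposed convolution (its FLOPs
#'   scale with the input, not the output, size).
#' @return a classed list.
#' @export
conv_spec <- function(kernel, in_channels, out_channels, bias = TRUE,
                      batchnorm = FALSE, relu = FALSE,
                      out_h = NULL, out_w = NULL) {
  stopifnot(kernel >= 1, in_channels >= 1, out_channels >= 1)
  structure(list(kernel = as.integer(kernel),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 bias = bias, batchnorm = batchnorm, relu = relu,
                 out_h = out_h, out_w = out_w),
            class = c("conv_spec", "layer_spec"))
}

#' @rdname conv_spec
#' @export
ghost_spec <- function(kernel = 3L, in_channels, out_channels, ratio = 2L,
                       cheap_kernel = 3L, bias = TRUE, batchnorm = FALSE,
                       relu = FALSE, out_h = NULL, out_w = NULL) {
  if (ratio != 2L)
    stop("unsupported ghost ratio s = ", ratio, " (only s = 2 is supported)")
  if (out_channels %% ratio != 0L)
    stop("out_channels must be divisible by the ghost ratio")
  structure(list(kernel = as.integer(kernel),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 cheap_kernel = as.integer(cheap_kernel),
                 bias = bias, batchnorm = batchnorm, relu = relu,
                 out_h = out_h, out_w = out_w),
            class = c("ghost_spec", "layer_spec"))
}

#' @rdname conv_spec
#' @export
deconv_spec <- function(kernel, in_channels, out_channels, bias = TRUE,
                        in_h = NULL, in_w = NULL) {
  stopifnot(kernel >= 1, in_channels >= 1, out_channels >= 1)
  structure(list(kernel = as.integer(kernel), stride = as.integer(kernel),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 bias = bias, in_h = in_h, in_w = in_w),
            class = c("deconv_spec", "layer_spec"))
}

# promote (H,W) or (H,W,C) to (H,W,C,N); returns list(x, had_batch)
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be arrays")
  if (length(d) == 2) d <- c(d, 1L)
  if (length(d) == 3) {
    dim(x) <- c(d, 1L)
    return(list(x = x, batched = FALSE))
  }
  if (length(d) == 4) return(list(x = x, batched = TRUE))
  stop("feature maps must have 2-4 dimensions (H, W, C, N)")
}

unbatch <- function(y, batched) {
  if (!batched) dim(y) <- dim(y)[1:3]
  y
}

#' Initialize weights for a single block
#'
#' Kaiming (He) initialization scaled by the receptive fan-in, or all zeros.
#'
#' @param spec a `conv_spec`, `ghost_spec` or `deconv_spec`.
#' @param init `"kaiming"` or `"zero"`.
#' @return a nested list of numeric arrays (the block's weight container).
#' @export
block_weights <- function(spec, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  draw <- function(k, cin, cout) {
    n <- k * k * cin * cout
    w <- if (init == "zero") numeric(n) else rnorm(n, sd = sqrt(2 / (k * k * cin)))
    array(w, dim = c(k, k, cin, cout))
  }
  bn_part <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
  if (inherits(spec, "conv_spec")) {
    p <- list(w = draw(spec$kernel, spec$in_channels, spec$out_channels))
    if (spec$bias) p$b <- numeric(spec$out_channels)
    if (spec$batchnorm) p <- c(p, bn_part(spec$out_channels))
    p
  } else if (inherits(spec, "ghost_spec")) {
    ch <- spec$out_channels %/% spec$ratio
    primary <- list(w = draw(spec$kernel, spec$in_channels, ch))
    if (spec$bias) primary$b <- numeric(ch)
    if (spec$batchnorm) primary <- c(primary, bn_part(ch))
    dw <- if (init == "zero") numeric(spec$cheap_kernel^2 * ch) else
      rnorm(spec$cheap_kernel^2 * ch, sd = sqrt(2 / spec$cheap_kernel^2))
    cheap <- list(w = array(dw, dim = c(spec$cheap_kernel, spec$cheap_kernel, ch)))
    if (spec$bias) cheap$b <- numeric(ch)
    if (spec$batchnorm) cheap <- c(cheap, bn_part(ch))
    list(primary = primary, cheap = cheap)
  } else if (inherits(spec, "deconv_spec")) {
    p <- list(w = draw(spec$kernel, spec$in_channels, spec$out_channels))
    if (spec$bias) p$b <- numeric(spec$out_channels)
    p
  } else stop("unknown spec")
}

#' Forward operators on feature maps
#'
#' Reference forward semantics of the building blocks, operating on numeric
#' arrays laid out `(height, width, channels[, batch])`. `conv_forward()` is a
#' stride-1 "same"-padded convolution; `ghost_forward()` concatenates the
#' Ghost module's intrinsic maps (standard convolution) with its ghost maps
#' (depthwise convolution of the intrinsic maps); `deconv_forward()` is a
#' transposed convolution with stride = kernel; `maxpool2()` is 2x2/stride-2
#' max pooling; `bilinear_up()` is bilinear interpolation by an integer
#' factor. Batch normalization uses batch statistics when `train = TRUE`.
#'
#' @param x input feature map, `(H, W, C)` or `(H, W, C, N)` array.
#' @param spec the corresponding layer specification.
#' @param weights a weight container from [block_weights()].
#' @param train use batch statistics in any batch-normalization stage.
#' @return output feature map with the same array layout as the input.
#' @export
conv_forward <- function(x, spec, weights, train = TRUE) {
  fm <- as_feature_map(x)
  if (dim(fm$x)[3] != spec$in_channels)
    stop("channel mismatch: input has ", dim(fm$x)[3], " channels, spec expects ",
         spec$in_channels)
  y <- conv_stage_fwd(fm$x, weights, spec$bias, spec$batchnorm,
                      if (spec$relu) "relu" else "none", train)$y
  unbatch(y, fm$batched)
}

#' @rdname conv_forward
#' @export
ghost_forward <- function(x, spec, weights, train = TRUE) {
  fm <- as_feature_map(x)
  if (dim(fm$x)[3] != spec$in_channels)
    stop("channel mismatch: input has ", dim(fm$x)[3], " channels, spec expects ",
         spec$in_channels)
  act <- if (spec$relu) "relu" else "none"
  p <- conv_stage_fwd(fm$x, weights$primary, spec$bias, spec$batchnorm, act, train)$y
  g <- dw_stage_fwd(p, weights$cheap, spec$bias, spec$batchnorm, act, train)$y
  unbatch(cat_channels(list(p, g)), fm$batched)
}

#' @rdname conv_forward
#' @export
deconv_forward <- function(x, spec, weights) {
  fm <- as_feature_map(x)
  if (dim(fm$x)[3] != spec$in_channels)
    stop("channel mismatch: input has ", dim(fm$x)[3], " channels, spec expects ",
         spec$in_channels)
  unbatch(deconv_fwd(fm$x, weights$w, weights$b), fm$batched)
}

#' @rdname conv_forward
#' @param factor integer upsampling factor.
#' @export
maxpool2 <- function(x, factor = 2L) {
  fm <- as_feature_map(x)
  d <- dim(fm$x)
  if (d[1] %% factor != 0 || d[2] %% factor != 0)
    stop("spatial size ", d[1], "x", d[2], " not divisible by ", factor)
  unbatch(cpp_maxpool_fwd(fm$x, as.integer(factor))$y, fm$batched)
}

#' @rdname conv_forward
#' @export
bilinear_up <- function(x, factor = 2L) {
  fm <- as_feature_map(x)
  unbatch(cpp_bilinear_fwd(fm$x, as.integer(factor)), fm$batched)
}

#' Full-scale additive feature fusion
#'
#' Upsamples feature maps from every scale to the finest (largest) spatial
#' size by bilinear interpolation and fuses them by elementwise addition.
#' Addition, unlike concatenation, requires all inputs to share the same
#' channel count and introduces no learnable parameters and no FLOPs under
#' the package's accounting rules.
#'
#' @param features list of feature maps `(H, W, C[, N])` whose spatial sizes
#'   are integer-factor fractions of the largest one.
#' @return the fused feature map at the largest spatial size.
#' @export
full_scale_fusion <- function(features) {
  stopifnot(length(features) >= 1)
  fms <- lapply(features, as_feature_map)
  dims <- lapply(fms, function(f) dim(f$x))
  cs <- vapply(dims, `[`, numeric(1), 3)
  if (length(unique(cs)) != 1)
    stop("additive fusion requires equal channel counts, got: ",
         paste(cs, collapse = ", "))
  H <- max(vapply(dims, `[`, numeric(1), 1))
  out <- NULL
  for (f in fms) {
    d <- dim(f$x)
    if (H %% d[1] != 0)
      stop("spatial sizes must be integer fractions of the full size")
    up <- if (d[1] == H) f$x else cpp_bilinear_fwd(f$x, as.integer(H %/% d[1]))
    out <- if (is.null(out)) up else out + up
  }
  unbatch(out, fms[[1]]$batched)
}

cat_channels <- function(xs) cpp_concat_channels(xs)
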