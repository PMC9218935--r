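test_that("convolution parameter and FLOP formulas give the hand-derived counts", {
  expect_equal(conv_params(conv_spec(3, 64, 64)), 36928)
  expect_equal(conv_params(conv_spec(1, 64, 1)), 65)
  expect_equal(conv_params(conv_spec(2, 128, 64)), 32832)
  expect_equal(conv_params(conv_spec(3, 4, 8, bias = FALSE)), 288)
  expect_equal(conv_params(conv_spec(3, 4, 8, batchnorm = TRUE)),
               (9 * 4 + 1) * 8 + 16)

  expect_equal(conv_flops(conv_spec(3, 128, 64, out_h = 128, out_w = 128)),
               2415919104)
  expect_equal(conv_flops(conv_spec(3, 320, 320, out_h = 128, out_w = 128)),
               30198988800)
  expect_equal(conv_flops(conv_spec(3, 64, 64, out_h = 128, out_w = 128)),
               1207959552)
})

test_that("ghost module counts follow the half-primary/half-cheap decomposition", {
  expect_equal(ghost_params(ghost_spec(3, 64, 64)), 18784)
  expect_equal(ghost_params(ghost_spec(3, 1, 64)), 640)
  expect_equal(ghost_params(ghost_spec(3, 1, 2)), 20)
  # 18,784 = 18,464 primary + 320 cheap
  expect_equal(conv_params(conv_spec(3, 64, 32)), 18464)
  expect_equal((3^2 + 1) * 32, 320)
  expect_equal(ghost_params(ghost_spec(3, 64, 64)), 18464 + 320)

  g <- ghost_spec(3, 64, 64, out_h = 128, out_w = 128)
  expect_equal(ghost_flops(g), 613416960)
  # decomposition: primary conv at Cout/2 plus depthwise maps
  expect_equal(conv_flops(conv_spec(3, 64, 32, out_h = 128, out_w = 128)),
               603979776)
  expect_equal(ghost_flops(g), 603979776 + 2 * 9 * 32 * 128 * 128)
  # halving both spatial dims quarters the FLOPs
  expect_equal(ghost_flops(ghost_spec(3, 64, 64, out_h = 64, out_w = 64)),
               613416960 / 4)
})

test_that("transposed-convolution FLOPs scale with the input size", {
  expect_equal(deconv_flops(deconv_spec(2, 128, 64, in_h = 64, in_w = 64)),
               268435456)
  expect_equal(deconv_flops(deconv_spec(2, 64, 32, in_h = 16, in_w = 16)),
               4194304)
  # all four U-Net decoder deconvs share Cin*Cout*Hin*Win at a fixed output
  net <- build_unet(arch_config())
  shapes <- network_shapes(net)
  ids <- grep("^deconv", names(net$nodes), value = TRUE)
  fl <- vapply(ids, function(id) {
    node <- net$nodes[[id]]
    s <- shapes[[node$inputs[1]]]
    deconv_flops(deconv_spec(node$kernel, s[1], node$out_channels,
                             in_h = s[2], in_w = s[3]))
  }, numeric(1))
  expect_equal(length(unique(fl)), 1L)
  expect_equal(unname(fl[1]), 268435456)
})

test_that("rounding and K/M/G formatting follow round-half-up at two decimals", {
  expect_equal(round_half_up(0.205, 2), 0.21)
  expect_equal(round_half_up(2.415919104, 2), 2.42)
  expect_equal(round_half_up(36.928, 2), 36.93)
  expect_equal(format_count(208865, "M"), "0.21 M")
  expect_equal(format_count(0, "M"), "0.00 M")
  expect_equal(format_count(18784), "18.78 K")
  expect_equal(format_count(613416960, "G"), "0.61 G")
  expect_equal(format_count(613416960), "613.42 M")
})

test_that("whole-network counting dispatches per layer and zero-costs fusion plumbing", {
  net <- network_spec("one-conv", c(1, 8, 8))
  net <- net_add(net, "c", "conv", "input", kernel = 1L, out_channels = 1L,
                 batchnorm = FALSE, activation = "none")
  net <- halfunet:::net_set_output(net, "c")
  rep <- count_network(net)
  expect_equal(rep$total_params, 2)  # 1 weight + 1 bias
  expect_equal(rep$total_flops, 2 * 1 * 1 * 1 * 8 * 8)

  pool_rows <- subset(count_network(build_half_unet(tiny_cfg()))$layers,
                      kind %in% c("maxpool", "bilinear_up", "add", "input"))
  expect_true(all(pool_rows$params == 0) && all(pool_rows$flops == 0))
})

test_that("analytic parameter totals equal brute-force weight enumeration for every builder", {
  for (nm in list_networks()) {
    v <- verify_against_runtime(build_network(nm, tiny_cfg()))
    expect_true(v$equal, label = paste0(nm, " analytic=", v$analytic,
                                        " enumerated=", v$enumerated))
  }
  # and at a second, deeper configuration
  for (nm in c("half-unet", "unet", "unet3plus")) {
    v <- verify_against_runtime(build_network(nm, tiny_cfg(size = 32, base = 6,
                                                           depth = 4)))
    expect_true(v$equal, label = nm)
  }
})

test_that("parameters are size-invariant and FLOPs are linear in pixel count", {
  for (nm in c("half-unet", "unet", "unet3plus", "half-unet-star-d")) {
    r1 <- count_network(build_network(nm, tiny_cfg(size = 16)))
    r2 <- count_network(build_network(nm, tiny_cfg(size = 32)))
    expect_equal(r1$total_params, r2$total_params, label = nm)
    expect_equal(r2$total_flops, 4 * r1$total_flops, label = nm)
  }
})

test_that("a ghost module never costs more than the conv it replaces", {
  # algebraically (K = d = 3): ghost = (Cout/2)(9 Cin + 11) vs
  # conv = (Cout/2)(18 Cin + 2) — strictly cheaper for Cin >= 2, equal at Cin = 1
  for (cin in c(2, 3, 16, 64, 200)) {
    for (cout in c(2, 8, 64, 256)) {
      expect_lt(ghost_params(ghost_spec(3, cin, cout)),
                conv_params(conv_spec(3, cin, cout)))
    }
  }
  for (cout in c(2, 8, 64))
    expect_equal(ghost_params(ghost_spec(3, 1, cout)),
                 conv_params(conv_spec(3, 1, cout)))
})
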