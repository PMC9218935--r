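test_that("every builder yields a valid graph that runs a forward pass", {
  set.seed(21)
  cfg <- tiny_cfg()
  x <- rand_fm(16, 16, 1, 2)
  for (nm in list_networks()) {
    net <- build_network(nm, cfg)
    expect_silent(validate_network(net))
    ini <- net_init(net)
    out <- net_forward(net, ini$params, ini$state, x, train = TRUE)$out
    expect_equal(dim(out), c(16, 16, 1, 2), label = nm)
    expect_true(all(is.finite(out)) && all(out > 0) && all(out < 1),
                label = paste(nm, "sigmoid output"))
  }
})

test_that("the calibrated builders reproduce the published complexity figures", {
  expect_equal(count_network(build_half_unet())$total_params, 208865)
  expect_equal(count_network(build_half_unet())$params_label, "0.21 M")
  expect_equal(count_network(build_half_unet_dagger())$params_label, "0.41 M")
  expect_equal(count_network(build_unet())$total_params, 31042369)
  expect_equal(count_network(build_unet())$params_label, "31.04 M")
  # starred variants: ordering is the primary check; the reconstruction also
  # lands on the printed values exactly
  pu <- count_network(build_half_unet_star(arch_config(), "upsample_conv"))
  pd <- count_network(build_half_unet_star(arch_config(), "deconv"))
  expect_gt(pd$total_params, pu$total_params)
  expect_gt(pu$total_flops, count_network(build_half_unet_dagger())$total_flops)
  expect_gt(pu$total_flops, pd$total_flops)
  expect_equal(pu$params_label, "20.03 M")
  expect_equal(pd$params_label, "38.09 M")
})

test_that("removing ghost modules (dagger) changes no tensor shape", {
  cfg <- tiny_cfg()
  s_ghost <- network_shapes(build_half_unet(cfg))
  s_conv <- network_shapes(build_half_unet_dagger(cfg))
  expect_identical(s_ghost, s_conv)
  p_ghost <- count_network(build_half_unet(cfg))$total_params
  p_conv <- count_network(build_half_unet_dagger(cfg))$total_params
  expect_gt(p_conv, p_ghost)
})

test_that("doubling encoders produce the 64..1024 channel sequence", {
  net <- build_half_unet_star(arch_config(), "deconv")
  shapes <- network_shapes(net)
  chs <- vapply(paste0("enc", 1:5, "_b2"), function(id) shapes[[id]][1],
                integer(1))
  expect_equal(unname(chs), c(64L, 128L, 256L, 512L, 1024L))
  expect_equal(unname(vapply(paste0("enc", 1:5, "_b2"),
                             function(id) network_shapes(build_unet(
                               arch_config()))[[id]][1], integer(1))),
               c(64L, 128L, 256L, 512L, 1024L))
})

test_that("full-scale aggregation layers concatenate 5 x 64 = 320 channels", {
  net <- build_unet3plus(arch_config())
  shapes <- network_shapes(net)
  agg_ids <- grep("_agg$", names(net$nodes), value = TRUE)
  expect_equal(length(agg_ids), 4L)
  for (id in agg_ids) expect_equal(shapes[[id]][1], 320L)
  cc_ids <- grep("_concat$", names(net$nodes), value = TRUE)
  for (id in cc_ids) expect_equal(shapes[[id]][1], 320L)
  expect_equal(last_fusion_input_channels(net), 1984L)
})

test_that("ablation encoders emit the expected taps and share the aggregation head", {
  cfg <- tiny_cfg()
  a <- build_ablation_encoder("A", cfg)
  b <- build_ablation_encoder("B", cfg)
  cc <- build_ablation_encoder("C", cfg)
  # A taps every downsample rate 1,2,4 (depth 3)
  shapes <- network_shapes(a)
  scales <- vapply(a$last_fusion$taps, function(id) 16L %/% shapes[[id]][2],
                   integer(1))
  expect_equal(sort(unname(scales)), c(1L, 2L, 4L))
  # C contains A's encoder as a subgraph
  enc_ids <- grep("^(enc|pool)", names(a$nodes), value = TRUE)
  expect_true(all(enc_ids %in% names(cc$nodes)))
  # all three produce full-resolution single-channel sigmoid output
  for (net in list(a, b, cc)) {
    expect_equal(network_shapes(net)[[net$output]], c(1L, 16L, 16L))
  }
  expect_error(build_ablation_encoder("D", cfg))
})

test_that("the last-fusion split isolates fusion and convolution parts", {
  hu <- extract_last_fusion(build_half_unet(arch_config()))
  expect_equal(count_network(hu$left)$total_params, 0)
  expect_equal(count_network(hu$left)$total_flops, 0)
  expect_equal(count_network(hu$right)$total_params, 18784 + 128)

  un <- extract_last_fusion(build_unet(arch_config()))
  dk <- un$left$nodes[["deconv1"]]
  expect_equal(dk$kind, "deconv")
  expect_equal(dk$kernel, 2L)
  expect_equal(network_shapes(un$left)[["in_dec2_b2"]], c(128L, 64L, 64L))
  expect_equal(count_network(un$left)$total_params, 32832)

  u3 <- extract_last_fusion(build_unet3plus(arch_config()))
  agg <- u3$right$nodes[["de1_agg"]]
  expect_equal(agg$out_channels, 320L)
  expect_equal(network_shapes(u3$right)[["in_de1_concat"]][1], 320L)
  # Eq-(1)-style count of the aggregation conv
  expect_equal(conv_params(conv_spec(3, 320, 320)), 921920)

  # the extracted left part executes as a standalone sub-network
  set.seed(22)
  huL <- extract_last_fusion(build_half_unet(tiny_cfg()))$left
  ins <- lapply(halfunet:::net_input_ids(huL), function(id) {
    s <- huL$nodes[[id]]$shape
    rand_fm(s[2], s[3], s[1], 1)
  })
  names(ins) <- halfunet:::net_input_ids(huL)
  ini <- net_init(huL)
  out <- net_forward(huL, ini$params, ini$state, ins)$out
  expect_equal(dim(out), c(16, 16, 4, 1))
})

test_that("unknown architecture names are rejected with the list of valid names", {
  expect_error(build_network("no-such-net"), "half-unet")
  expect_setequal(list_networks(),
                  c("half-unet", "half-unet-dagger", "half-unet-star-u",
                    "half-unet-star-d", "unet", "unet3plus",
                    "encoder-a", "encoder-b", "encoder-c"))
})
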