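test_that("generation is a pure function of config and seed", {
  cfg <- synthetic_config("nodule", image_size = 32, n_images = 4, seed = 9)
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_identical(m1$image, m2$image)
  expect_identical(m1$split, m2$split)
  for (f in c(m1$image, m1$mask)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed changes the pixels
  m3 <- generate_dataset(synthetic_config("nodule", image_size = 32,
                                          n_images = 4, seed = 10),
                         tempfile("gen3"))
  expect_false(identical(
    unname(tools::md5sum(file.path(attr(m3, "dir"), m3$image[1]))),
    unname(tools::md5sum(file.path(d1, m1$image[1])))))
})

test_that("in the noiseless case a mid-intensity threshold recovers each mask exactly", {
  for (regime in c("mass", "nodule")) {
    cfg <- synthetic_config(regime, n_images = 1, noise_sd = 0,
                            background_gradient = FALSE, seed = 4)
    smp <- render_synthetic(cfg, 1)
    got <- (smp$image > smp$thresholds[[1]]) * 1
    expect_equal(got, smp$mask, label = regime)
  }
  cfg <- synthetic_config("ventricle", image_size = 128, n_images = 1,
                          noise_sd = 0, background_gradient = FALSE, seed = 5)
  smp <- render_synthetic(cfg, 1)
  expect_equal((smp$image > smp$thresholds[["endocardium"]]) * 1,
               smp$masks$endocardium)
  expect_equal((smp$image > smp$thresholds[["epicardium"]]) * 1,
               smp$masks$epicardium)
  # endocardium is nested strictly inside epicardium
  expect_true(all(smp$masks$epicardium >= smp$masks$endocardium))
  expect_gt(sum(smp$masks$epicardium), sum(smp$masks$endocardium))
})

test_that("mask foreground area stays inside the analytic radius bounds", {
  cfg <- synthetic_config("mass", image_size = 64, n_images = 1, seed = 6)
  for (i in 1:8) {
    smp <- render_synthetic(cfg, i)
    area <- sum(smp$mask)
    lo <- pi * cfg$radius_range[1]^2
    hi <- pi * cfg$radius_range[2]^2
    # discretization of the exact ellipse can move area by a few boundary px
    expect_gt(area, 0.8 * lo)
    expect_lt(area, 1.2 * hi)
  }
})

test_that("raster pairs round-trip losslessly", {
  img <- round(matrix(runif(64), 8, 8) * 255) / 255
  msk <- matrix(0, 8, 8); msk[3, 5] <- 1   # single foreground pixel
  ip <- tempfile(fileext = ".png"); mp <- tempfile(fileext = ".png")
  write_pair(img, msk, ip, mp)
  back <- read_pair(ip, mp)
  expect_identical(back$image, img)
  expect_identical(back$mask, msk)

  # 16-bit TIFF path
  img16 <- round(matrix(runif(64), 8, 8) * 65535) / 65535
  it <- tempfile(fileext = ".tif"); mt <- tempfile(fileext = ".tif")
  write_pair(img16, msk, it, mt, bits = 16)
  back16 <- read_pair(it, mt)
  expect_equal(back16$image, img16, tolerance = 1e-12)

  # reading a non-binary mask is a validation error
  bad <- tempfile(fileext = ".png")
  png::writePNG(matrix(runif(64), 8, 8), bad)
  expect_error(read_pair(ip, bad), "not binary")
  expect_error(write_pair(img, matrix(0.5, 8, 8), ip, mp), "binary")
})

test_that("manifests enforce existence and split disjointness at 7:3", {
  ds <- tiny_dataset(n = 10)
  man <- read_manifest(file.path(ds$dir, "manifest.json"))
  expect_equal(nrow(man), 10)
  expect_equal(sum(man$split == "train"), 7)
  expect_equal(sum(man$split == "test"), 3)
  expect_length(intersect(man$image[man$split == "train"],
                          man$image[man$split == "test"]), 0)
  bad <- man
  bad$split[1] <- setdiff(c("train", "test"), bad$split[1])[1]
  p <- file.path(ds$dir, "bad.json")
  write_manifest(rbind(man, bad), p)
  expect_error(read_manifest(p), "not disjoint")
})

test_that("augmentation emits exactly ten records per training image", {
  ds <- tiny_dataset(regime = "mass", size = 32, n = 5, seed = 8)
  n_train <- sum(ds$man$split == "train")
  aug <- augment_dataset(ds$man)
  expect_equal(sum(aug$split == "train"), 10 * n_train)
  expect_equal(sum(aug$split == "test"), sum(ds$man$split == "test"))
  expect_equal(sum(aug$provenance == "augmented"), 9 * n_train)
  # every augmented pair exists and stays binary
  arr <- load_manifest_arrays(aug, "train")
  expect_true(all(arr$y %in% c(0, 1)))
})

test_that("rotations and flips satisfy the dihedral-group identities", {
  set.seed(41)
  img <- matrix(runif(256), 16, 16)
  expect_equal(rotate_image(rotate_image(img, 180), 180), img)
  expect_equal(flip_image(flip_image(img, "horizontal"), "horizontal"), img)
  expect_equal(flip_image(flip_image(img, "vertical"), "vertical"), img)
  # horizontal then vertical flip equals a 180-degree rotation
  expect_equal(flip_image(flip_image(img, "horizontal"), "vertical"),
               rotate_image(img, 180))
  # four quarter-turns compose to the identity
  r <- img
  for (k in 1:4) r <- rotate_image(r, 90)
  expect_equal(r, img)
  # 90-multiples preserve mask area exactly
  msk <- matrix(0, 16, 16); msk[3:7, 5:11] <- 1
  for (a in c(90, 180, 270))
    expect_equal(sum(rotate_image(msk, a, "nearest")), sum(msk))
})

test_that("45-degree rotations preserve mask area within interpolation tolerance", {
  cfg <- synthetic_config("mass", image_size = 64, n_images = 1, seed = 12)
  for (i in 1:4) {
    msk <- render_synthetic(cfg, i)$mask
    for (a in c(45, 135, 225, 315)) {
      rot <- (rotate_image(msk, a, "nearest") >= 0.5) * 1
      expect_lt(abs(sum(rot) - sum(msk)) / sum(msk), 0.05,
                label = paste("angle", a, "sample", i))
    }
  }
})
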