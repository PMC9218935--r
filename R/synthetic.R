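#' Synthetic dataset configuration
#'
#' Describes a synthetic binary-segmentation dataset emulating one of three
#' regimes: `"mass"` — a single soft-edged bright ellipse with a textured
#' interior on a noisy background (mammographic-mass-like, default 128x128);
#' `"nodule"` — one to three small bright discs (lung-nodule-like, default
#' 64x64); `"ventricle"` — a nested disc/annulus structure producing two
#' ground-truth masks, the inner disc (endocardium) and the outer disc
#' (epicardium) (cardiac-MRI-like, default 256x256). Masks are the exact
#' generating geometry. All objects are placed inside the inscribed circle
#' so 45-degree rotations never clip foreground. Generation is a pure
#' function of the configuration (including its seed).
#'
#' @param regime `"mass"`, `"nodule"` or `"ventricle"`.
#' @param image_size square image side in pixels (regime default if `NULL`).
#' @param n_images number of image/mask pairs.
#' @param object_count_range integer range of object counts (nodule regime).
#' @param radius_range object radius (semi-axis) range in pixels.
#' @param foreground_contrast peak foreground intensity above background, in
#'   `[0, 1]` intensity units.
#' @param noise_sd Gaussian pixel-noise standard deviation, intensity units.
#' @param background_gradient add a gentle linear intensity ramp.
#' @param target which mask is the training target in the ventricle regime.
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(regime = c("mass", "nodule", "ventricle"),
                             image_size = NULL, n_images = 100L,
                             object_count_range = c(1L, 3L),
                             radius_range = NULL,
                             foreground_contrast = 0.45, noise_sd = 0.04,
                             background_gradient = TRUE,
                             target = c("endocardium", "epicardium"),
                             seed = 1L) {
  regime <- match.arg(regime)
  target <- match.arg(target)
  if (is.null(image_size))
    image_size <- switch(regime, mass = 128L, nodule = 64L, ventricle = 256L)
  if (is.null(radius_range))
    radius_range <- switch(regime,
      mass = round(image_size * c(0.09, 0.2)),
      nodule = round(image_size * c(0.05, 0.11)),
      ventricle = round(image_size * c(0.16, 0.27)))
  stopifnot(noise_sd >= 0, n_images >= 1,
            foreground_contrast > 0, foreground_contrast <= 1)
  if (max(radius_range) >= image_size / 2 - 2)
    stop("radius_range does not fit inside the image")
  structure(list(regime = regime, image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 object_count_range = as.integer(object_count_range),
                 radius_range = radius_range,
                 foreground_contrast = foreground_contrast,
                 noise_sd = noise_sd,
                 background_gradient = isTRUE(background_gradient),
                 target = target, seed = as.integer(seed)),
            class = "synthetic_config")
}

BG_BASE <- 0.25

# soft edge crossing 0.5 exactly on the geometric boundary q = 1
soft_step <- function(q, width = 0.3) {
  pmin(pmax(0.5 + (1 - q) / width, 0), 1)
}

# random position such that a disc of `radius` stays inside the inscribed
# circle with a 2-px margin (rotation-safe)
place_centre <- function(size, radius) {
  lim <- size / 2 - radius - 2
  repeat {
    p <- runif(2, -lim, lim)
    if (sqrt(sum(p^2)) <= lim) return(p + (size + 1) / 2)
  }
}

#' Render one synthetic sample
#'
#' Deterministic given `config` and `index`. Returns the unquantized image,
#' the target mask, all masks, and the exact mid-intensity threshold(s) that
#' recover each mask in the noiseless case.
#'
#' @param config a [synthetic_config()].
#' @param index 1-based sample index.
#' @return list with `image`, `mask`, `masks` (named list), `thresholds`.
#' @export
render_synthetic <- function(config, index = 1L) {
  set.seed((config$seed * 1000003L + index) %% .Machine$integer.max)
  n <- config$image_size
  yy <- matrix(seq_len(n), n, n)          # row (y) coordinate
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  ctr <- config$foreground_contrast
  bg <- matrix(BG_BASE, n, n)
  if (config$background_gradient)
    bg <- bg + 0.06 * (xx - (n + 1) / 2) / n + 0.04 * (yy - (n + 1) / 2) / n

  if (config$regime == "mass") {
    ab <- runif(2, config$radius_range[1], config$radius_range[2])
    cen <- place_centre(n, max(ab))
    th <- runif(1, 0, pi)
    u <- cos(th) * (xx - cen[2]) + sin(th) * (yy - cen[1])
    v <- -sin(th) * (xx - cen[2]) + cos(th) * (yy - cen[1])
    q <- (u / ab[1])^2 + (v / ab[2])^2
    s <- soft_step(q)
    tex <- 0.1 * ctr * sin(u / 3 + runif(1, 0, 2 * pi)) *
      sin(v / 4 + runif(1, 0, 2 * pi)) * (q < 0.7)
    img <- bg + ctr * s + tex
    masks <- list(mass = q < 1)
    thr <- c(mass = BG_BASE + ctr / 2)
  } else if (config$regime == "nodule") {
    k <- sample(seq(config$object_count_range[1],
                    config$object_count_range[2]), 1)
    s <- matrix(0, n, n)
    q_any <- matrix(Inf, n, n)
    for (i in seq_len(k)) {
      r <- runif(1, config$radius_range[1], config$radius_range[2])
      cen <- place_centre(n, r)
      q <- ((xx - cen[2])^2 + (yy - cen[1])^2) / r^2
      s <- pmax(s, soft_step(q))
      q_any <- pmin(q_any, q)
    }
    img <- bg + ctr * s
    masks <- list(nodule = q_any < 1)
    thr <- c(nodule = BG_BASE + ctr / 2)
  } else {
    ro <- runif(1, config$radius_range[1], config$radius_range[2])
    ri <- ro * runif(1, 0.5, 0.68)
    cen <- place_centre(n, ro)
    r2 <- (xx - cen[2])^2 + (yy - cen[1])^2
    s_epi <- soft_step(r2 / ro^2, width = 0.15)
    s_endo <- soft_step(r2 / ri^2, width = 0.15)
    img <- bg + 0.5 * ctr * s_epi + 0.5 * ctr * s_endo
    masks <- list(endocardium = r2 < ri^2, epicardium = r2 < ro^2)
    thr <- c(endocardium = BG_BASE + 0.75 * ctr,
             epicardium = BG_BASE + 0.25 * ctr)
  }
  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(n * n, sd = config$noise_sd), n, n)
  img <- pmin(pmax(img, 0), 1)
  masks <- lapply(masks, function(m) { storage.mode(m) <- "double"; m })
  target <- if (config$regime == "ventricle") config$target else names(masks)[1]
  list(image = img, mask = masks[[target]], masks = masks, thresholds = thr)
}

#' Generate a synthetic dataset on disk
#'
#' Renders `n_images` samples, quantizes them to 8-bit PNG, writes paired
#' binary masks (stored as 0/255 single-channel PNGs), assigns disjoint
#' train/test splits by a seeded permutation, and writes a JSON manifest.
#' Byte-identical for identical configurations.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @param split_ratio named fractions summing to 1, default 7:3 train:test.
#' @return the manifest data.frame (columns `image`, `mask`, `split`,
#'   `provenance`, paths relative to `dir`), with `dir` attached as an
#'   attribute.
#' @export
generate_dataset <- function(config, dir,
                             split_ratio = c(train = 0.7, test = 0.3)) {
  stopifnot(abs(sum(split_ratio) - 1) < 1e-8)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- config$n_images
  set.seed(config$seed)
  perm <- sample.int(n)
  n_train <- round(split_ratio[["train"]] * n)
  split <- rep("test", n)
  split[perm[seq_len(n_train)]] <- "train"
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- render_synthetic(config, i)
    img_rel <- sprintf("images/img_%04d.png", i)
    msk_rel <- sprintf("masks/img_%04d_mask.png", i)
    write_pair(smp$image, smp$mask, file.path(dir, img_rel),
               file.path(dir, msk_rel))
    if (config$regime == "ventricle") {
      for (nm in names(smp$masks)) {
        extra <- sprintf("masks/img_%04d_mask_%s.png", i, substr(nm, 1, 4))
        png::writePNG(smp$masks[[nm]], file.path(dir, extra))
      }
    }
    rows[[i]] <- data.frame(image = img_rel, mask = msk_rel,
                            split = split[i], provenance = "original")
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "dir") <- dir
  write_manifest(manifest, file.path(dir, "manifest.json"),
                 config = config)
  manifest
}

#' Read and write image/mask pairs
#'
#' Grayscale rasters, 8-bit PNG (default) or 8/16-bit TIFF chosen by file
#' extension. Images are quantized to the target bit depth on write, so a
#' write/read round trip of an already-quantized array is bit-identical.
#' Masks are stored as 0/255 (or 0/65535) single-channel images and
#' interpreted as 0/1; reading a non-binary mask is an error.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param mask binary numeric matrix.
#' @param image_path,mask_path output paths (`.png`, `.tif`/`.tiff`).
#' @param bits bit depth for TIFF output (8 or 16; PNG is written 8-bit).
#' @return `read_pair()`: list with `image` and `mask` matrices.
#' @export
write_pair <- function(image, mask, image_path, mask_path, bits = 8L) {
  if (!all(mask %in% c(0, 1))) stop("mask must be strictly binary")
  write_gray(image, image_path, bits)
  write_gray(mask, mask_path, bits)
  invisible(NULL)
}

#' @rdname write_pair
#' @export
read_pair <- function(image_path, mask_path) {
  image <- read_gray(image_path)
  mask <- read_gray(mask_path)
  if (!all(mask %in% c(0, 1)))
    stop("mask file '", mask_path, "' is not binary")
  list(image = image, mask = mask)
}

is_tiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

write_gray <- function(x, path, bits = 8L) {
  levels <- 2^bits - 1
  q <- round(x * levels) / levels
  if (is_tiff(path)) {
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bits))
  } else {
    png::writePNG(q, path)
  }
  invisible(path)
}

read_gray <- function(path) {
  x <- if (is_tiff(path)) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' Dataset manifests
#'
#' A manifest is a data.frame with columns `image`, `mask`, `split`
#' (`"train"`/`"test"`) and `provenance` (`"original"`/`"augmented"`), with
#' paths relative to the dataset directory. `read_manifest()` validates that
#' every referenced file exists and that no image appears in more than one
#' split.
#'
#' @param manifest the manifest data.frame.
#' @param path JSON file path.
#' @param config optional generating [synthetic_config()] stored alongside.
#' @return `read_manifest()`: the manifest with attribute `dir`.
#' @export
write_manifest <- function(manifest, path, config = NULL) {
  payload <- list(records = manifest)
  if (!is.null(config)) payload$config <- unclass(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  manifest <- as.data.frame(payload$records)
  dir <- dirname(path)
  missing <- !file.exists(file.path(dir, c(manifest$image, manifest$mask)))
  if (any(missing)) stop("manifest references missing files")
  by_img <- split(manifest$split, manifest$image)
  if (any(vapply(by_img, function(s) length(unique(s)), integer(1)) > 1))
    stop("manifest splits are not disjoint")
  attr(manifest, "dir") <- dir
  manifest
}

#' Load a manifest split into arrays
#'
#' @param manifest a manifest data.frame with attribute `dir` (from
#'   [generate_dataset()] or [read_manifest()]).
#' @param split which split to load.
#' @return list with `x` images and `y` masks, both `(H, W, 1, N)` arrays.
#' @export
load_manifest_arrays <- function(manifest, split = "train") {
  dir <- attr(manifest, "dir")
  if (is.null(dir)) stop("manifest has no 'dir' attribute")
  rec <- manifest[manifest$split == split, , drop = FALSE]
  if (!nrow(rec)) stop("no records in split '", split, "'")
  pairs <- lapply(seq_len(nrow(rec)), function(i)
    read_pair(file.path(dir, rec$image[i]), file.path(dir, rec$mask[i])))
  d <- dim(pairs[[1]]$image)
  x <- array(0, c(d[1], d[2], 1, nrow(rec)))
  y <- array(0, c(d[1], d[2], 1, nrow(rec)))
  for (i in seq_along(pairs)) {
    x[, , 1, i] <- pairs[[i]]$image
    y[, , 1, i] <- pairs[[i]]$mask
  }
  list(x = x, y = y)
}

#' Geometric transforms for paired augmentation
#'
#' `rotate_image()` rotates clockwise about the image centre on a fixed
#' canvas with zero fill outside the source; multiples of 90 degrees use
#' exact array permutations, other angles inverse-map with bilinear (images)
#' or nearest-neighbour (masks) interpolation. `flip_image()` mirrors
#' horizontally (left-right) or vertically (up-down).
#'
#' @param img numeric matrix (square for non-90-multiple rotations).
#' @param angle clockwise rotation in degrees.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param direction `"horizontal"` or `"vertical"`.
#' @return the transformed matrix.
#' @export
rotate_image <- function(img, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  a <- angle %% 360
  H <- nrow(img); W <- ncol(img)
  if (a == 0) return(img)
  if (a %% 90 == 0) {
    return(switch(as.character(a),
      "90"  = t(img[H:1, , drop = FALSE]),
      "180" = img[H:1, W:1, drop = FALSE],
      "270" = t(img)[W:1, , drop = FALSE]))
  }
  if (H != W) stop("non-90-degree rotation requires a square image")
  th <- a * pi / 180
  c0 <- (H + 1) / 2
  dy <- matrix(seq_len(H) - c0, H, W)
  dx <- matrix(seq_len(W) - c0, H, W, byrow = TRUE)
  sx <- cos(th) * dx + sin(th) * dy + c0
  sy <- -sin(th) * dx + cos(th) * dy + c0
  if (interp == "nearest") {
    si <- round(sy); sj <- round(sx)
    ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
    out <- matrix(0, H, W)
    out[ok] <- img[cbind(si[ok], sj[ok])]
    return(out)
  }
  i0 <- floor(sy); j0 <- floor(sx)
  ai <- sy - i0; aj <- sx - j0
  pick <- function(ii, jj) {
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- matrix(0, H, W)
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v
  }
  (1 - ai) * (1 - aj) * pick(i0, j0) + (1 - ai) * aj * pick(i0, j0 + 1) +
    ai * (1 - aj) * pick(i0 + 1, j0) + ai * aj * pick(i0 + 1, j0 + 1)
}

#' @rdname rotate_image
#' @export
flip_image <- function(img, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (direction == "horizontal") img[, ncol(img):1, drop = FALSE]
  else img[nrow(img):1, , drop = FALSE]
}

augment_transforms <- function() {
  c(list(identity),
    lapply(seq(45, 315, by = 45), function(a)
      function(img, interp) rotate_image(img, a, interp)),
    list(function(img, interp) flip_image(img, "horizontal"),
         function(img, interp) flip_image(img, "vertical")))
}

#' Ten-fold training-set augmentation
#'
#' For every original training record, emits the original plus seven
#' clockwise rotations (45, 90, ..., 315 degrees), one horizontal flip and
#' one vertical flip — ten records per image. The identical transform is
#' applied to image and mask; images are interpolated bilinearly, masks with
#' nearest neighbour and re-binarized at 0.5. Test-split records are left
#' untouched.
#'
#' @param manifest a manifest with attribute `dir`.
#' @param dir dataset directory (defaults to the manifest's).
#' @return the augmented manifest (original + augmented records), written
#'   back to `manifest.json` in `dir`.
#' @export
augment_dataset <- function(manifest, dir = attr(manifest, "dir")) {
  if (is.null(dir)) stop("dataset directory unknown")
  tr <- manifest[manifest$split == "train" &
                   manifest$provenance == "original", , drop = FALSE]
  tfs <- augment_transforms()
  new_rows <- list()
  for (i in seq_len(nrow(tr))) {
    pr <- read_pair(file.path(dir, tr$image[i]), file.path(dir, tr$mask[i]))
    if (nrow(pr$image) != ncol(pr$image))
      stop("augmentation requires square images")
    stem <- sub("\\.png$", "", basename(tr$image[i]))
    for (k in seq_along(tfs)[-1]) {
      f <- tfs[[k]]
      img_t <- f(pr$image, "bilinear")
      msk_t <- as.numeric(f(pr$mask, "nearest") >= 0.5)
      dim(msk_t) <- dim(pr$mask)
      img_rel <- sprintf("images/%s_aug%d.png", stem, k - 1)
      msk_rel <- sprintf("masks/%s_aug%d_mask.png", stem, k - 1)
      write_pair(pmin(pmax(img_t, 0), 1), msk_t,
                 file.path(dir, img_rel), file.path(dir, msk_rel))
      new_rows[[length(new_rows) + 1]] <-
        data.frame(image = img_rel, mask = msk_rel, split = "train",
                   provenance = "augmented")
    }
  }
  out <- rbind(manifest, do.call(rbind, new_rows))
  attr(out, "dir") <- dir
  write_manifest(out, file.path(dir, "manifest.json"))
  out
}
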