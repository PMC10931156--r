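# Canonical membrane geometry, in pixels. A 3 cm x 3 cm membrane with a
# 6 mm spot pitch maps to 20 px pitch (~6.7 px/mm); an extra band above
# the grid carries the white and black calibration labels.
#' Canonical array geometry
#'
#' Pixel layout of a rendered membrane: image size, the 5 x 5 grid of
#' spot centers (row-major from top-left), spot and sampling radii, and
#' the white/black calibration label boxes with their 8-bit reference
#' values (200 and 30 counts; matte labels safely below sensor
#' saturation).
#'
#' @param pitch_px Spot pitch in pixels (6 mm). Default 20.
#' @return A list describing the layout.
#' @export
array_layout <- function(pitch_px = 20L) {
  p <- pitch_px
  H <- as.integer(7.5 * p); W <- as.integer(6 * p)
  centers <- cbind(
    row = rep(as.integer(2.15 * p) + p * (0:4), each = 5L),
    col = rep(p + p * (0:4), times = 5L))
  list(
    H = H, W = W,
    spot_centers = centers,
    spot_radius = 0.35 * p,
    sampling_radius = 0.25 * p,
    white_patch_box = c(r0 = as.integer(0.35 * p), r1 = as.integer(1.35 * p),
                        c0 = as.integer(0.45 * p), c1 = as.integer(1.45 * p)),
    black_patch_box = c(r0 = as.integer(0.35 * p), r1 = as.integer(1.35 * p),
                        c0 = as.integer(4.55 * p), c1 = as.integer(5.55 * p)),
    patch_radius = 0.3 * p,
    reference_white = 200, reference_black = 30,
    background_rgb = c(235, 232, 228)
  )
}

box_center <- function(box) c((box["r0"] + box["r1"]) / 2,
                              (box["c0"] + box["c1"]) / 2)

# Smooth membrane texture: coarse Gaussian field bilinearly upsampled.
membrane_texture <- function(H, W, seed, amplitude = 3) {
  with_seed(derive_seed(seed, "texture"), {
    coarse <- matrix(rnorm(8 * 7, 0, amplitude), 8, 7)
    ri <- seq(1, 8, length.out = H); ci <- seq(1, 7, length.out = W)
    r0 <- pmin(floor(ri), 7); c0 <- pmin(floor(ci), 6)
    fr <- ri - r0; fc <- ci - c0
    a <- coarse[cbind(rep(r0, W), rep(c0, each = H))]
    b <- coarse[cbind(rep(r0 + 1, W), rep(c0, each = H))]
    cc <- coarse[cbind(rep(r0, W), rep(c0 + 1, each = H))]
    dd <- coarse[cbind(rep(r0 + 1, W), rep(c0 + 1, each = H))]
    m <- a * (1 - rep(fr, W)) * (1 - rep(fc, each = H)) +
      b * rep(fr, W) * (1 - rep(fc, each = H)) +
      cc * (1 - rep(fr, W)) * rep(fc, each = H) +
      dd * rep(fr, W) * rep(fc, each = H)
    matrix(m, H, W)
  })
}

# Per-spot pre/post drift realizing a configured blank total-ED
# distribution: per-spot ED magnitudes are drawn so the 25-spot sum has
# the requested mean and sd, then oriented uniformly in RGB space.
blank_drift <- function(seed, mean_total = 47.75, sd_total = 2) {
  if (mean_total <= 0) return(matrix(0, 25L, 3L))
  with_seed(derive_seed(seed, "blank-drift"), {
    eds <- pmax(rnorm(25L, mean_total / 25, sd_total / 5), 0)
    dirs <- matrix(rnorm(75L), 25L, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    dirs * eds
  })
}

#' Render a sensor-array image
#'
#' Draws the 25 dye spots (baseline color plus the gas-induced shift from
#' [simulate_delta()] plus optional per-spot drift) as filled disks on a
#' textured membrane, together with the white and black calibration
#' labels, then applies the scene perturbation: channel gains, geometric
#' warp, additive noise, and clipping to [0, 255]. Pixel values are kept
#' as continuous counts; quantization to 8 bits happens only on PNG
#' export.
#'
#' @param library A [make_dye_library()] object.
#' @param gas Gas mixture (named ppm vector); `NULL` for an unexposed array.
#' @param scene A [scene_params()] object.
#' @param seed Integer seed for scene noise.
#' @param drift Optional 25 x 3 matrix of per-spot RGB drift (counts),
#'   e.g. from the blank-drift model.
#' @param layout Geometry from [array_layout()].
#' @param meta Optional named list stored as image metadata
#'   (fruit, stage, timestamp_h, ...).
#' @return An object of class `array_image`: pixels (H x W x 3 array of
#'   counts), transformed spot centers and patch centers, patch boxes,
#'   ground-truth spot colors, the scene, and metadata.
#' @export
render_array_image <- function(library, gas = NULL, scene = canonical_scene(),
                               seed = 1L, drift = NULL,
                               layout = array_layout(), meta = list()) {
  stopifnot(inherits(library, "dye_library"), inherits(scene, "scene_params"))
  H <- layout$H; W <- layout$W
  delta <- if (is.null(gas)) matrix(0, 25L, 3L) else simulate_delta(library, gas)
  spot_rgb <- as.matrix(library$spec[, c("R", "G", "B")]) + delta
  if (!is.null(drift)) {
    stopifnot(identical(dim(drift), c(25L, 3L)))
    spot_rgb <- spot_rgb + drift
  }
  spot_rgb <- clip255(spot_rgb)

  tex <- membrane_texture(H, W, scene$background_seed)
  img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- layout$background_rgb[ch] + tex

  fill_box <- function(box, value) {
    for (ch in 1:3) img[box["r0"]:box["r1"], box["c0"]:box["c1"], ch] <<- value
  }
  fill_box(layout$white_patch_box, layout$reference_white)
  fill_box(layout$black_patch_box, layout$reference_black)

  rows <- matrix(rep(1:H, W), H, W)
  cols <- matrix(rep(1:W, each = H), H, W)
  for (i in 1:25) {
    ctr <- layout$spot_centers[i, ]
    mask <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= layout$spot_radius^2
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[mask] <- spot_rgb[i, ch]
      img[, , ch] <- plane
    }
  }

  for (ch in 1:3) img[, , ch] <- img[, , ch] * scene$illumination_gain[ch]

  M <- scene_homography(scene)
  identity_warp <- scene$rotation_deg == 0 && scene$perspective == 0
  if (!identity_warp) img <- warp_image(img, M)
  center <- c((H + 1) / 2, (W + 1) / 2)
  tf <- function(rc) if (identity_warp) rc else transform_rc(M, rc, center)
  spot_centers <- tf(layout$spot_centers)

  if (scene$noise_sd > 0) {
    img <- img + with_seed(derive_seed(seed, "pixel-noise"),
                           array(rnorm(H * W * 3L, 0, scene$noise_sd),
                                 dim = c(H, W, 3L)))
  }
  img <- clip255(img)

  structure(list(
    pixels = img,
    spot_centers = spot_centers,
    patch_centers = list(
      white = drop(tf(rbind(box_center(layout$white_patch_box)))),
      black = drop(tf(rbind(box_center(layout$black_patch_box))))),
    white_patch_box = layout$white_patch_box,
    black_patch_box = layout$black_patch_box,
    patch_radius = layout$patch_radius,
    sampling_radius = layout$sampling_radius,
    reference_white = layout$reference_white,
    reference_black = layout$reference_black,
    truth = list(spot_rgb = spot_rgb, delta = delta, drift = drift),
    scene = scene, meta = meta), class = "array_image")
}

#' @export
print.array_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("array_image %dx%d, 25 spots, gains (%.2f, %.2f, %.2f)\n",
              d[1], d[2], x$scene$illumination_gain[1],
              x$scene$illumination_gain[2], x$scene$illumination_gain[3]))
  if (length(x$meta)) utils::str(x$meta, give.attr = FALSE)
  invisible(x)
}

#' Bilinear image resize
#'
#' @param img H x W x 3 numeric array.
#' @param side Output side length in pixels (square output).
#' @return side x side x 3 array.
#' @export
resize_image <- function(img, side) {
  d <- dim(img); H <- d[1]; W <- d[2]
  ri <- seq(1, H, length.out = side); ci <- seq(1, W, length.out = side)
  r0 <- pmin(floor(ri), H - 1L); c0 <- pmin(floor(ci), W - 1L)
  fr <- ri - r0; fc <- ci - c0
  out <- array(0, dim = c(side, side, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    a <- plane[cbind(rep(r0, side), rep(c0, each = side))]
    b <- plane[cbind(rep(r0 + 1, side), rep(c0, each = side))]
    cc <- plane[cbind(rep(r0, side), rep(c0 + 1, each = side))]
    dd <- plane[cbind(rep(r0 + 1, side), rep(c0 + 1, each = side))]
    m <- a * (1 - rep(fr, side)) * (1 - rep(fc, each = side)) +
      b * rep(fr, side) * (1 - rep(fc, each = side)) +
      cc * (1 - rep(fr, side)) * rep(fc, each = side) +
      dd * rep(fr, side) * rep(fc, each = side)
    out[, , ch] <- matrix(m, side, side)
  }
  out
}

#' Preprocess an image for the classifier
#'
#' Resizes to a square `side x side` raster. At paper scale the network
#' input side is 255 pixels, which is the default here.
#'
#' @param image An `array_image` or an H x W x 3 array.
#' @param side Target side in pixels. Default 255.
#' @return side x side x 3 array of counts.
#' @export
preprocess_image <- function(image, side = 255L) {
  img <- if (inherits(image, "array_image")) image$pixels else image
  stopifnot(length(dim(img)) == 3L, side >= 2L)
  resize_image(img, as.integer(side))
}

#' Write an array image (or raw raster) as PNG
#' @param image `array_image` or H x W x 3 array of counts in [0, 255].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  img <- if (inherits(image, "array_image")) image$pixels else image
  png::writePNG(clip01(img / 255), path)
  invisible(path)
}

#' Read a PNG as a raster of 8-bit counts
#' @param path PNG file path.
#' @return H x W x 3 numeric array in [0, 255].
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}
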