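#' Spot sampling grid
#'
#' The 25 spot centers (row-major from top-left) and the disk radius used
#' to average pixel values at each spot. Centers must be pairwise
#' separated by more than twice the sampling radius so disks never
#' overlap.
#'
#' @param centers 25 x 2 matrix of (row, col) pixel coordinates.
#' @param sampling_radius Disk radius in pixels.
#' @return An object of class `spot_grid`.
#' @export
spot_grid <- function(centers, sampling_radius) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 25L, ncol(centers) == 2L, sampling_radius >= 0)
  if (nrow(centers) > 1L) {
    dmin <- min(dist(centers))
    if (dmin <= 2 * sampling_radius)
      stop("spot centers closer than twice the sampling radius")
  }
  structure(list(centers = centers, sampling_radius = sampling_radius),
            class = "spot_grid")
}

# Grid implied by an image's metadata (transformed centers).
grid_of <- function(image) {
  spot_grid(image$spot_centers, image$sampling_radius)
}

#' Locate the spot grid in an image without metadata
#'
#' Template fit for rasters whose spot coordinates are unknown: slides
#' the canonical 5 x 5 lattice over integer translations and keeps the
#' offset maximizing the mean color saturation (max minus min channel)
#' of the disk means — dye spots are saturated, the membrane background
#' is nearly neutral. The score is flat wherever the sampling disk stays
#' inside the spot, so the offset is recovered up to the slack between
#' the sampling and spot radii (2 px at the default geometry); spot
#' colors are exact within that slack.
#'
#' @param pixels H x W x 3 array of counts.
#' @param layout Canonical geometry from [array_layout()].
#' @param search Maximum absolute translation searched, in pixels.
#' @return A [spot_grid()]; the chosen (row, col) offset is attached as
#'   attribute `"offset"`.
#' @export
fit_spot_grid <- function(pixels, layout = array_layout(), search = 6L) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  best <- NULL; best_score <- -Inf
  for (dr in -search:search) for (dc in -search:search) {
    centers <- sweep(layout$spot_centers, 2, c(dr, dc), "+")
    if (any(centers[, 1] < 1 | centers[, 1] > H |
            centers[, 2] < 1 | centers[, 2] > W)) next
    rgb <- t(vapply(1:25, function(i)
      disk_mean_rgb(pixels, centers[i, ], layout$sampling_radius),
      numeric(3)))
    score <- mean(apply(rgb, 1, max) - apply(rgb, 1, min))
    if (score > best_score) { best_score <- score; best <- c(dr, dc) }
  }
  if (is.null(best)) stop("no lattice placement fits inside the raster")
  g <- spot_grid(sweep(layout$spot_centers, 2, best, "+"),
                 layout$sampling_radius)
  attr(g, "offset") <- best
  g
}

disk_mean_rgb <- function(pixels, center, radius) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(H, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(W, ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  mask <- outer((rr - center[1])^2, (cc - center[2])^2, "+") <= radius^2
  if (!any(mask)) { # degenerate radius: nearest single pixel
    return(pixels[round(center[1]), round(center[2]), ])
  }
  vapply(1:3, function(ch) mean(pixels[rr, cc, ch][mask]), numeric(1))
}

#' Mean RGB of each spot
#'
#' Averages pixel values over a disk of the grid's sampling radius at
#' each of the 25 spot centers, in row-major grid order. A radius of 0
#' degenerates to the single nearest pixel.
#'
#' @param image An `array_image` or an H x W x 3 array.
#' @param grid A [spot_grid()]; defaults to the grid recorded in the
#'   image metadata.
#' @return 25 x 3 matrix of mean (R, G, B) counts.
#' @export
extract_spot_rgb <- function(image, grid = NULL) {
  pixels <- if (inherits(image, "array_image")) image$pixels else image
  if (is.null(grid)) {
    if (!inherits(image, "array_image"))
      stop("a spot_grid is required for plain rasters")
    grid <- grid_of(image)
  }
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  if (any(grid$centers[, 1] < 1 | grid$centers[, 1] > H |
          grid$centers[, 2] < 1 | grid$centers[, 2] > W))
    stop("spot center outside the raster")
  out <- t(vapply(1:25, function(i)
    disk_mean_rgb(pixels, grid$centers[i, ], grid$sampling_radius),
    numeric(3)))
  colnames(out) <- c("R", "G", "B")
  out
}

#' Fit a two-point color calibration
#'
#' Per-channel affine map (gain, offset) that sends the measured mean of
#' the black label to `reference_black` and the white label to
#' `reference_white`, correcting illumination before color extraction.
#'
#' @param image An `array_image` with calibration labels.
#' @param reference_black,reference_white Target counts; default to the
#'   references recorded in the image (30 and 200).
#' @return An object of class `calibration_map` with `gain`, `offset`,
#'   and the references.
#' @export
fit_calibration <- function(image, reference_black = NULL,
                            reference_white = NULL) {
  stopifnot(inherits(image, "array_image"))
  if (is.null(reference_black)) reference_black <- image$reference_black
  if (is.null(reference_white)) reference_white <- image$reference_white
  w <- disk_mean_rgb(image$pixels, image$patch_centers$white, image$patch_radius)
  b <- disk_mean_rgb(image$pixels, image$patch_centers$black, image$patch_radius)
  if (any(w <= b))
    stop("degenerate lighting: white label not brighter than black label")
  gain <- (reference_white - reference_black) / (w - b)
  offset <- reference_black - gain * b
  structure(list(gain = gain, offset = offset,
                 reference_black = reference_black,
                 reference_white = reference_white,
                 measured_black = b, measured_white = w),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("calibration: gain (%.3f, %.3f, %.3f) offset (%.1f, %.1f, %.1f)\n",
              x$gain[1], x$gain[2], x$gain[3],
              x$offset[1], x$offset[2], x$offset[3]))
  invisible(x)
}

#' Apply a calibration map to an image
#'
#' @param image An `array_image`.
#' @param map A [fit_calibration()] result.
#' @return The calibrated `array_image` (pixels clipped to [0, 255]).
#' @export
apply_calibration <- function(image, map) {
  stopifnot(inherits(image, "array_image"), inherits(map, "calibration_map"))
  for (ch in 1:3)
    image$pixels[, , ch] <- map$gain[ch] * image$pixels[, , ch] + map$offset[ch]
  image$pixels <- clip255(image$pixels)
  image
}

#' Calibrate an image against its black/white labels
#'
#' Convenience wrapper: [fit_calibration()] followed by
#' [apply_calibration()].
#' @inheritParams fit_calibration
#' @return The calibrated `array_image`.
#' @export
calibrate_image <- function(image, reference_black = NULL,
                            reference_white = NULL) {
  apply_calibration(image,
                    fit_calibration(image, reference_black, reference_white))
}

#' Per-spot color differentials and ED response
#'
#' Subtracts pre-exposure from post-exposure spot colors and derives the
#' Euclidean distance response `ED = sqrt(dR^2 + dG^2 + dB^2)` per spot,
#' plus a total array response (sum over spots by default; root sum of
#' squares available).
#'
#' @param pre_rgb,post_rgb 25 x 3 matrices of spot colors (counts).
#' @param total One of `"sum"` (default) or `"rss"` -- how per-spot EDs
#'   aggregate into the total.
#' @return An object of class `delta_signature`: `delta_rgb` (25 x 3,
#'   signed), `ed_per_spot` (25), `total_ed` (scalar).
#' @export
delta_signature <- function(pre_rgb, post_rgb, total = c("sum", "rss")) {
  total <- match.arg(total)
  pre_rgb <- as.matrix(pre_rgb); post_rgb <- as.matrix(post_rgb)
  if (!all(dim(pre_rgb) == c(25L, 3L)) || !all(dim(post_rgb) == c(25L, 3L)))
    stop("pre and post spot colors must both be 25 x 3")
  d <- post_rgb - pre_rgb
  ed <- sqrt(rowSums(d^2))
  tot <- if (total == "sum") sum(ed) else sqrt(sum(ed^2))
  structure(list(delta_rgb = d, ed_per_spot = ed, total_ed = tot,
                 total_rule = total),
            class = "delta_signature")
}

#' @export
print.delta_signature <- function(x, ...) {
  cat(sprintf("delta_signature: total ED %.2f (%s of 25 spots), max spot ED %.2f\n",
              x$total_ed, x$total_rule, max(x$ed_per_spot)))
  invisible(x)
}

#' Signature of a pre/post image pair
#'
#' Calibrates both images against their black/white labels (optional),
#' extracts spot colors, and forms the [delta_signature()].
#'
#' @param pre,post `array_image` objects.
#' @param calibrate Calibrate both images first? Default `TRUE`.
#' @param total Total-ED aggregation rule.
#' @return A `delta_signature`.
#' @export
pair_signature <- function(pre, post, calibrate = TRUE,
                           total = c("sum", "rss")) {
  if (calibrate) {
    pre <- calibrate_image(pre)
    post <- calibrate_image(post)
  }
  delta_signature(extract_spot_rgb(pre), extract_spot_rgb(post),
                  total = match.arg(total))
}

#' Render a color differential map
#'
#' Expands per-spot |dRGB| from the `in_range` window (default 3-10
#' counts) onto `out_range` (default 0-255) and lays the 25 spots out as
#' 5 x 5 color tiles. Magnitudes below the window floor clip to the
#' output floor, above the ceiling to the output ceiling.
#'
#' @param sig A [delta_signature()].
#' @param in_range Input window, default `c(3, 10)`.
#' @param out_range Output range, default `c(0, 255)`.
#' @param tile_px Tile side in pixels. Default 20.
#' @return (5 * tile_px) square x 3 array of counts.
#' @export
render_differential_map <- function(sig, in_range = c(3, 10),
                                    out_range = c(0, 255), tile_px = 20L) {
  stopifnot(inherits(sig, "delta_signature"), in_range[1] < in_range[2])
  a <- abs(sig$delta_rgb)
  scaled <- (a - in_range[1]) / (in_range[2] - in_range[1])
  vals <- round(out_range[1] + clip01(scaled) * (out_range[2] - out_range[1]))
  side <- 5L * tile_px
  out <- array(0, dim = c(side, side, 3L))
  for (i in 1:25) {
    r <- (i - 1L) %/% 5L; c <- (i - 1L) %% 5L
    out[r * tile_px + 1:tile_px, c * tile_px + 1:tile_px, ] <-
      rep(vals[i, ], each = tile_px * tile_px)
  }
  out
}

#' Write a delta signature as CSV
#' @param sig A `delta_signature`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signature_csv <- function(sig, path) {
  df <- data.frame(spot_id = 1:25, dR = sig$delta_rgb[, 1],
                   dG = sig$delta_rgb[, 2], dB = sig$delta_rgb[, 3],
                   ED = sig$ed_per_spot)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
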