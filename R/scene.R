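#' Photographic scene parameters
#'
#' A scene perturbation is a per-channel illumination gain, a small
#' rigid-plus-perspective geometric distortion, and additive Gaussian
#' pixel noise. The canonical scene (all gains 1, zero rotation,
#' perspective and noise) is the identity of the perturbation model.
#'
#' @param illumination_gain Length-3 positive multiplicative gains (R, G, B).
#' @param rotation_deg In-plane rotation in degrees.
#' @param perspective Perspective magnitude (dimensionless, ~0-0.005).
#' @param noise_sd Additive Gaussian noise standard deviation, 8-bit counts.
#' @param background_seed Integer seed for the membrane background texture.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(illumination_gain = c(1, 1, 1), rotation_deg = 0,
                         perspective = 0, noise_sd = 0,
                         background_seed = 1L) {
  stopifnot(length(illumination_gain) == 3L, all(illumination_gain > 0),
            noise_sd >= 0)
  structure(list(illumination_gain = as.numeric(illumination_gain),
                 rotation_deg = as.numeric(rotation_deg),
                 perspective = as.numeric(perspective),
                 noise_sd = as.numeric(noise_sd),
                 background_seed = as.integer(background_seed)),
            class = "scene_params")
}

#' @rdname scene_params
#' @export
canonical_scene <- function() scene_params()

#' Draw a random photographic scene
#'
#' `"low"` emulates controlled flatbed-scanner capture (tiny gain and
#' noise variation); `"paper"` emulates hand-held capture under
#' arbitrarily transformed light and angles (log-normal channel gains
#' with sd 0.25, rotations up to ~10 degrees, mild perspective, noise
#' sd 3 counts).
#'
#' @param seed Integer seed.
#' @param level `"low"` or `"paper"`.
#' @return A [scene_params()] object.
#' @export
random_scene <- function(seed, level = c("low", "paper")) {
  level <- match.arg(level)
  with_seed(derive_seed(seed, paste0("scene-", level)), {
    if (level == "low") {
      scene_params(illumination_gain = exp(rnorm(3, 0, 0.02)),
                   rotation_deg = runif(1, -1, 1), perspective = 0,
                   noise_sd = 0.5,
                   background_seed = sample.int(1e6, 1))
    } else {
      scene_params(illumination_gain = exp(rnorm(3, 0, 0.25)),
                   rotation_deg = runif(1, -10, 10),
                   perspective = runif(1, 0, 0.003), noise_sd = 3,
                   background_seed = sample.int(1e6, 1))
    }
  })
}

is_canonical_scene <- function(scene) {
  all(scene$illumination_gain == 1) && scene$rotation_deg == 0 &&
    scene$perspective == 0 && scene$noise_sd == 0
}

# Forward 3x3 homography for a scene, acting on centered (x = col,
# y = row) coordinates: rotation followed by a mild perspective division.
scene_homography <- function(scene) {
  th <- scene$rotation_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  P <- rbind(c(1, 0, 0), c(0, 1, 0),
             c(scene$perspective, scene$perspective / 2, 1))
  P %*% R
}

# Apply homography M to points given as an n x 2 (row, col) matrix.
transform_rc <- function(M, rc, center) {
  xy <- cbind(rc[, 2] - center[2], rc[, 1] - center[1], 1)
  q <- xy %*% t(M)
  cbind(q[, 2] / q[, 3] + center[1], q[, 1] / q[, 3] + center[2])
}

# Inverse-map bilinear warp of an H x W x 3 image under homography M.
warp_image <- function(img, M, fill = 60) {
  d <- dim(img); H <- d[1]; W <- d[2]
  center <- c((H + 1) / 2, (W + 1) / 2)
  Minv <- solve(M)
  grid <- cbind(rep(1:H, times = W), rep(1:W, each = H))
  src <- transform_rc(Minv, grid, center)
  sr <- src[, 1]; sc <- src[, 2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inside <- r0 >= 1 & r0 < H & c0 >= 1 & c0 < W
  out <- array(fill, dim = d)
  idx <- function(r, c) (c - 1L) * H + r
  for (ch in 1:3) {
    plane <- img[, , ch]
    v <- rep(fill, H * W)
    r0i <- r0[inside]; c0i <- c0[inside]
    fri <- fr[inside]; fci <- fc[inside]
    v[inside] <-
      plane[idx(r0i, c0i)] * (1 - fri) * (1 - fci) +
      plane[idx(r0i + 1, c0i)] * fri * (1 - fci) +
      plane[idx(r0i, c0i + 1)] * (1 - fri) * fci +
      plane[idx(r0i + 1, c0i + 1)] * fri * fci
    out[, , ch] <- matrix(v, H, W)
  }
  out
}
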