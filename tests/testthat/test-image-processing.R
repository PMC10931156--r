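test_that("two-point calibration solves the affine map exactly", {
  lib <- test_library(1)
  # an image already at the references yields the identity map
  img <- render_array_image(lib, NULL)
  cal <- fit_calibration(img)
  expect_equal(unname(cal$gain), rep(1, 3), tolerance = 1e-10)
  expect_equal(unname(cal$offset), rep(0, 3), tolerance = 1e-8)
  # textbook 2-point solution: measured (10, 200) onto targets (0, 255)
  img2 <- img
  img2$pixels <- img2$pixels * (190 / 170) + (10 - 30 * 190 / 170)
  cal2 <- fit_calibration(img2, reference_black = 0, reference_white = 255)
  expect_equal(unname(cal2$gain), rep(255 / 190, 3), tolerance = 1e-9)
  expect_equal(unname(cal2$offset), rep(-10 * 255 / 190, 3), tolerance = 1e-7)
})

test_that("degenerate lighting (white <= black) errors", {
  lib <- test_library(1)
  img <- render_array_image(lib, NULL)
  img$pixels[] <- 100
  expect_error(fit_calibration(img), "degenerate")
})

test_that("calibration is idempotent and undoes a known channel gain", {
  lib <- test_library(1)
  base <- render_array_image(lib, NULL)
  base_rgb <- extract_spot_rgb(base)
  cal1 <- calibrate_image(base)
  cal2 <- fit_calibration(cal1)
  expect_equal(unname(cal2$gain), rep(1, 3), tolerance = 1e-6)

  sc <- scene_params(illumination_gain = c(1.15, 0.9, 1.05))
  tinted <- render_array_image(lib, NULL, scene = sc)
  fixed <- calibrate_image(tinted)
  expect_lt(max(abs(extract_spot_rgb(fixed) - base_rgb)), 2)
})

test_that("total ED is invariant to an invertible gain after calibration", {
  lib <- test_library(1)
  drift <- ripenose:::blank_drift(21)
  pre0 <- render_array_image(lib, NULL)
  post0 <- render_array_image(lib, NULL, drift = drift)
  sig0 <- pair_signature(pre0, post0, calibrate = FALSE)
  # gains kept within the sensor's dynamic range (no channel saturates)
  for (g in list(c(1.1, 1, 0.9), c(0.92, 1.08, 1))) {
    sc <- scene_params(illumination_gain = g)
    pre <- render_array_image(lib, NULL, scene = sc)
    post <- render_array_image(lib, NULL, scene = sc, drift = drift)
    expect_lt(max(post$truth$spot_rgb) * max(g), 255)
    sig <- pair_signature(pre, post, calibrate = TRUE)
    expect_lt(max(abs(sig$ed_per_spot - sig0$ed_per_spot)), 2)
    expect_equal(sig$total_ed, sig0$total_ed, tolerance = 0.05)
  }
})

test_that("spot extraction averages disks in grid order", {
  lib <- test_library(1)
  img <- render_array_image(lib, NULL)
  # constant field: every spot mean equals that color
  img$pixels[, , 1] <- 12; img$pixels[, , 2] <- 34; img$pixels[, , 3] <- 56
  rgb <- extract_spot_rgb(img)
  expect_equal(rgb, matrix(rep(c(12, 34, 56), each = 25), 25),
               ignore_attr = TRUE)
  # radius 0 degenerates to a single pixel
  g0 <- spot_grid(img$spot_centers, 0)
  rgb0 <- extract_spot_rgb(img, g0)
  expect_equal(unname(rgb0[1, ]), c(12, 34, 56))
  # centers outside the raster error
  bad <- img
  bad$spot_centers[1, ] <- c(-5, 10)
  expect_error(extract_spot_rgb(bad), "outside")
  # grids with overlapping disks are rejected
  expect_error(spot_grid(matrix(rep(c(5, 5), 25), 25, byrow = TRUE), 4),
               "closer")
})

test_that("delta signatures implement ED = sqrt(dR^2+dG^2+dB^2)", {
  pre <- matrix(100, 25, 3)
  expect_equal(delta_signature(pre, pre)$total_ed, 0)
  post <- pre; post[7, ] <- post[7, ] + c(3, 4, 0)
  sig <- delta_signature(pre, post)
  expect_equal(sig$ed_per_spot[7], 5)
  expect_equal(sig$total_ed, 5)
  post[7, ] <- pre[7, ] + c(1, 2, 2)
  expect_equal(delta_signature(pre, post)$ed_per_spot[7], 3)
  expect_error(delta_signature(pre[1:10, ], post), "25 x 3")
  # root-sum-of-squares aggregation option
  post2 <- pre; post2[1, 1] <- 103; post2[2, 2] <- 104
  expect_equal(delta_signature(pre, post2, total = "rss")$total_ed, 5)
})

test_that("ED is invariant to consistent grid permutations", {
  set.seed(7)
  pre <- matrix(runif(75, 50, 200), 25)
  post <- pre + matrix(rnorm(75, 0, 5), 25)
  perm <- sample(25)
  s1 <- delta_signature(pre, post)
  s2 <- delta_signature(pre[perm, ], post[perm, ])
  expect_equal(s2$total_ed, s1$total_ed)
  expect_equal(s2$ed_per_spot, s1$ed_per_spot[perm])
})

test_that("differential map expands |delta| from 3-10 onto 0-255", {
  pre <- matrix(100, 25, 3)
  post <- pre
  post[1, 1] <- 110    # |d| = 10 -> 255
  post[2, 1] <- 103    # |d| = 3  -> 0
  post[3, 1] <- 106.5  # |d| = 6.5 -> 128
  post[4, 1] <- 100.5  # below window -> 0
  post[5, 1] <- 180    # above window -> 255
  post[6, 1] <- 90     # negative shift, |d| = 10 -> 255
  m <- render_differential_map(delta_signature(pre, post), tile_px = 4L)
  tile <- function(i, ch) m[(i - 1) %/% 5 * 4 + 1, ((i - 1) %% 5) * 4 + 1, ch]
  expect_equal(tile(1, 1), 255)
  expect_equal(tile(2, 1), 0)
  expect_equal(tile(3, 1), 128)
  expect_equal(tile(4, 1), 0)
  expect_equal(tile(5, 1), 255)
  expect_equal(tile(6, 1), 255)
  expect_equal(dim(m), c(20L, 20L, 3L))
})

test_that("template grid fit recovers a translated lattice without metadata", {
  lib <- test_library(1)
  img <- render_array_image(lib, NULL)
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  # shift the whole raster by (3, -2) and refit from pixels alone
  shifted <- array(ripenose:::array_layout()$background_rgb[1],
                   dim = dim(img$pixels))
  shifted[4:H, 1:(W - 2), ] <- img$pixels[1:(H - 3), 3:W, ]
  g <- fit_spot_grid(shifted)
  # alignment is recovered up to the slack between sampling radius (5)
  # and spot radius (7); colors are exact within that slack
  expect_true(all(abs(attr(g, "offset") - c(3, -2)) <= 2))
  expect_lt(max(abs(extract_spot_rgb(shifted, g) - img$truth$spot_rgb)), 1.5)
})

test_that("PNG round-trip preserves pixel counts to 8-bit precision", {
  lib <- test_library(1)
  img <- render_array_image(lib, NULL)
  path <- tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- read_image_png(path)
  expect_lt(max(abs(back - img$pixels)), 0.51)
})
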