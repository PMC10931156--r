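test_that("dye library has the fixed class census and is seed-deterministic", {
  lib <- test_library(1)
  census <- table(lib$spec$dye_class)
  expect_equal(unname(census[c("aldehyde_ketone", "solvatochromic", "redox",
                               "lewis_acidic", "ph_indicator")]),
               c(2L, 3L, 3L, 3L, 14L), ignore_attr = TRUE)
  expect_equal(nrow(lib$spec), 25L)
  expect_true(all(lib$spec$R >= 0 & lib$spec$R <= 255))

  expect_identical(make_dye_library(0), make_dye_library(0))
  l0 <- make_dye_library(0); l1 <- make_dye_library(1)
  expect_true(any(l0$spec[, c("R", "G", "B")] != l1$spec[, c("R", "G", "B")]))
})

test_that("every VOC has enough strong responders above the floor", {
  lib <- test_library(1)
  mags <- sqrt(apply(lib$max_delta^2, c(1, 2), sum))
  for (v in voc_names())
    expect_gte(sum(mags[, v] >= lib$strong_floor), 5L)
})

test_that("simulate_delta follows a clipped Hill dose-response", {
  lib <- test_library(1)
  expect_equal(simulate_delta(lib, gas_mixture()), matrix(0, 25, 3),
               ignore_attr = TRUE)
  # half-saturation halves the maximum shift
  d1 <- simulate_delta(lib, gas_mixture("ethanol" = lib$half_sat[7, "ethanol"]),
                       dye = 7)
  expect_equal(unname(d1), unname(lib$max_delta[7, "ethanol", ] / 2),
               tolerance = 1e-12)
  # saturation limit
  dinf <- simulate_delta(lib, gas_mixture("ethanol" = 1e12), dye = 7)
  expect_equal(unname(dinf), unname(lib$max_delta[7, "ethanol", ]),
               tolerance = 1e-6)
  expect_error(simulate_delta(lib, c("ethanol" = -5)), ">= 0")
})

test_that("response magnitude is monotone in concentration for all dyes", {
  lib <- test_library(1)
  grid <- c(0, 1, 5, 10, 50, 100, 500, 1000, 5000)
  for (v in c("trans-2-hexenal", "(+)-limonene", "ethyl acetate")) {
    mags <- sapply(grid, function(cc) {
      d <- simulate_delta(lib, gas_mixture(setNames(cc, v)))
      sqrt(rowSums(d^2))
    })
    expect_true(all(diff(t(mags)) >= -1e-9))
  }
})

test_that("rendered arrays have 25 spots and exact canonical colors", {
  lib <- test_library(1)
  img <- render_array_image(lib, gas_mixture("benzaldehyde" = 200))
  expect_equal(nrow(img$spot_centers), 25L)
  expect_equal(dim(img$pixels)[3], 3L)
  # canonical scene, zero noise: spot means equal ground truth
  got <- extract_spot_rgb(img)
  expect_lt(max(abs(got - img$truth$spot_rgb)), 1)
  # illumination gain doubles the white patch red channel, clipped at 255
  sc <- scene_params(illumination_gain = c(2, 1, 1))
  img2 <- render_array_image(lib, NULL, scene = sc)
  w <- ripenose:::disk_mean_rgb(img2$pixels, img2$patch_centers$white,
                                img2$patch_radius)
  expect_equal(unname(w[1]), min(2 * img2$reference_white, 255))
  expect_equal(unname(w[2]), img2$reference_white)
})

test_that("scene warp tracks spot centers through rotation", {
  lib <- test_library(1)
  sc <- scene_params(rotation_deg = 7, perspective = 0.001)
  img <- render_array_image(lib, NULL, scene = sc)
  # extracted colors at transformed centers still match baselines closely
  got <- extract_spot_rgb(img)
  expect_lt(max(abs(got - img$truth$spot_rgb)), 3)
})

test_that("blank total-ED distribution matches the configured statistics", {
  lib <- test_library(1)
  pr <- generate_dose_response_images(lib, "trans-2-hexenal", 0,
                                      replicates = 100, seed = 3)
  totals <- vapply(pr$records, function(r)
    pair_signature(r$pre, r$post, calibrate = FALSE)$total_ed, numeric(1))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 47.75), 3 * se)
  expect_equal(sd(totals), 2, tolerance = 0.35)
})

test_that("zero-noise generator gives zero ED at zero concentration", {
  lib <- test_library(1)
  pr <- generate_dose_response_images(lib, "ethanol", 0, replicates = 2,
                                      seed = 1, blank_mean = 0, blank_sd = 0)
  sig <- pair_signature(pr$records[[1]]$pre, pr$records[[1]]$post,
                        calibrate = FALSE)
  expect_equal(sig$total_ed, 0)
})

test_that("mean total ED is non-decreasing in concentration", {
  lib <- test_library(1)
  pr <- generate_dose_response_images(lib, "trans-2-hexenal",
                                      c(0, 10, 50, 250, 1000),
                                      replicates = 3, seed = 5)
  s <- measure_dose_response(pr)
  expect_true(all(diff(s$total_ed) > 0))
  expect_error(generate_dose_response_images(lib, "ethanol", numeric(0)),
               "empty")
  expect_error(generate_dose_response_images(lib, "ethanol", c(10, 5)),
               "ascending")
})

test_that("stage labels follow the half-open day intervals", {
  expect_equal(stage_label("banana", c(0, 1.9, 2, 5.9, 6, 8)),
               c("unripe", "unripe", "ripe", "ripe", "overripe", "overripe"))
  expect_equal(stage_label("mango", c(2.9, 3, 7.9, 8, 10)),
               c("unripe", "ripe", "ripe", "overripe", "overripe"))
  expect_equal(stage_label("peach", c(1.9, 2, 6.9, 7)),
               c("unripe", "ripe", "ripe", "overripe"))
  expect_error(stage_label("banana", 9), "outside")
  expect_length(ripeness_classes(), 10L)
})

test_that("emission curves are non-negative and rise with storage time", {
  for (fr in fruit_names()) {
    traj <- ripeness_trajectory(fr)
    e0 <- emissions_at(traj, 0); e1 <- emissions_at(traj, traj$span)
    expect_true(all(e0 >= 0))
    expect_true(all(e1 > e0))
  }
  # batch redraw changes parameters deterministically
  t1 <- ripeness_trajectory("banana", batch_seed = 9)
  t2 <- ripeness_trajectory("banana", batch_seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1$pars, ripeness_trajectory("banana")$pars))
})

test_that("ripeness dataset manifest has 10 classes, 17:3 split, 12 h grid", {
  lib <- test_library(1)
  ds <- generate_ripeness_dataset(lib, n_images_per_class = 2, seed = 4)
  m <- ds$manifest
  expect_setequal(unique(m$class_label), ripeness_classes())
  expect_equal(nrow(m), 20L)
  expect_equal(sum(m$split == "train"), 17L)
  expect_equal(sum(m$split == "val"), 3L)
  expect_true(all(m$timestamp_h %% 12 == 0))
  # banana at 96 h (4 days) is ripe
  expect_equal(stage_label("banana", 96 / 24), "ripe")
  # determinism: identical manifests for identical seeds
  ds2 <- generate_ripeness_dataset(lib, n_images_per_class = 2, seed = 4)
  expect_identical(ds$manifest, ds2$manifest)
  # and bit-identical rasters
  i1 <- render_dataset_image(ds, 3, lib)
  i2 <- render_dataset_image(ds2, 3, lib)
  expect_identical(i1$pixels, i2$pixels)
})

test_that("test batch redraws trajectories (batch shift)", {
  lib <- test_library(1)
  ds <- generate_ripeness_dataset(lib, 2, seed = 4)
  ts <- generate_ripeness_dataset(lib, 2, seed = 4, batch = "test")
  expect_true(all(ts$manifest$split == "test"))
  expect_false(identical(ds$trajectories$banana$pars,
                         ts$trajectories$banana$pars))
})

test_that("timestamps always agree with the labeled stage", {
  lib <- test_library(1)
  ds <- generate_ripeness_dataset(lib, 5, seed = 8)
  m <- ds$manifest[ds$manifest$class_label != "blank", ]
  expect_true(all(mapply(function(f, t, s) stage_label(f, t / 24) == s,
                         m$fruit, m$timestamp_h, m$stage)))
})
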