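#' Random train/validation split at a fixed ratio
#'
#' Seeded random partition at `ratio` (default 17:3). Sizes that do not
#' divide evenly round toward the training set.
#'
#' @param n Number of items, or a manifest data frame.
#' @param ratio Length-2 integer ratio, default `c(17, 3)`.
#' @param seed Integer seed.
#' @return Character vector (`"train"`/`"val"`) of length `n`.
#' @export
split_dataset <- function(n, ratio = c(17, 3), seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(n >= 1L, length(ratio) == 2L, all(ratio > 0))
  n_train <- min(n, ceiling(n * ratio[1] / sum(ratio)))
  out <- rep("val", n)
  idx <- with_seed(derive_seed(seed, "split"), sample.int(n, n_train))
  out[idx] <- "train"
  out
}

scene_from_row <- function(row) {
  scene_params(illumination_gain = c(row$gain_r, row$gain_g, row$gain_b),
               rotation_deg = row$rotation_deg,
               perspective = row$perspective, noise_sd = row$noise_sd,
               background_seed = row$background_seed)
}

#' Generate a labeled ripeness image dataset manifest
#'
#' Emulates the fruit-in-a-box experiment: arrays are photographed every
#' 12 h over each fruit's storage span under randomized illumination and
#' angles, and labeled with one of the ten classes (fruit x stage, plus
#' blank for unreacted arrays). Pixels are not stored in the manifest;
#' [render_dataset_image()] re-renders any image deterministically from
#' its recorded seed and scene.
#'
#' @param library A [make_dye_library()] object.
#' @param n_images_per_class Images per class (>= 1).
#' @param seed Integer seed.
#' @param scene_level `"low"` (controlled capture) or `"paper"`
#'   (arbitrary light and angles).
#' @param batch `"train"` uses the nominal fruit batch and splits rows
#'   into train/val at `split_ratio`; `"test"` re-draws the emission
#'   trajectories to emulate a different fruit batch and marks all rows
#'   `"test"`.
#' @param split_ratio Train:validation ratio. Default `c(17, 3)`.
#' @param layout Geometry from [array_layout()].
#' @param blank_mean,blank_sd Per-array drift calibration (counts).
#' @return An object of class `ripeness_dataset` with elements
#'   `manifest` (data frame), `trajectories`, `classes`, and the
#'   generation configuration.
#' @export
generate_ripeness_dataset <- function(library, n_images_per_class = 20L,
                                      seed = 1L,
                                      scene_level = c("low", "paper"),
                                      batch = c("train", "test"),
                                      split_ratio = c(17, 3),
                                      layout = array_layout(),
                                      blank_mean = 47.75, blank_sd = 2) {
  stopifnot(inherits(library, "dye_library"), n_images_per_class >= 1L)
  scene_level <- match.arg(scene_level)
  batch <- match.arg(batch)
  classes <- ripeness_classes()
  batch_seed <- if (batch == "test") derive_seed(seed, "test-batch") else NULL
  trajectories <- setNames(
    lapply(fruit_names(), ripeness_trajectory, batch_seed = batch_seed),
    fruit_names())

  rows <- list()
  for (cls in classes) {
    if (cls == "blank") {
      fruit <- NA_character_; stage <- NA_character_
      t_grid <- 0
    } else {
      parts <- strsplit(cls, "_")[[1L]]
      fruit <- parts[1L]; stage <- parts[2L]
      span_d <- fruit_stage_table()$span[fruit_stage_table()$fruit == fruit]
      grid_h <- seq(0, span_d * 24, by = 12)
      t_grid <- grid_h[stage_label(fruit, grid_h / 24) == stage]
    }
    ts <- with_seed(derive_seed(seed, paste0("times-", batch, "-", cls)),
                    sample(t_grid, n_images_per_class, replace = TRUE))
    for (i in seq_len(n_images_per_class)) {
      img_seed <- derive_seed(seed, sprintf("img-%s-%s-%d", batch, cls, i))
      sc <- random_scene(img_seed, scene_level)
      rows[[length(rows) + 1L]] <- data.frame(
        class_label = cls, fruit = fruit, stage = stage,
        timestamp_h = ts[i], image_seed = img_seed,
        gain_r = sc$illumination_gain[1], gain_g = sc$illumination_gain[2],
        gain_b = sc$illumination_gain[3], rotation_deg = sc$rotation_deg,
        perspective = sc$perspective, noise_sd = sc$noise_sd,
        background_seed = sc$background_seed, batch = batch,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$split <- if (batch == "test") "test"
                    else split_dataset(nrow(manifest), split_ratio, seed)
  manifest <- cbind(id = seq_len(nrow(manifest)), manifest)
  structure(list(manifest = manifest, trajectories = trajectories,
                 classes = classes, library_seed = library$seed,
                 scene_level = scene_level, batch = batch,
                 split_ratio = split_ratio, layout = layout,
                 blank_mean = blank_mean, blank_sd = blank_sd, seed = seed),
            class = "ripeness_dataset")
}

#' @export
print.ripeness_dataset <- function(x, ...) {
  cat(sprintf("ripeness_dataset: %d images, %d classes, batch '%s', scenes '%s'\n",
              nrow(x$manifest), length(x$classes), x$batch, x$scene_level))
  print(table(x$manifest$split))
  invisible(x)
}

#' Re-render one dataset image from its manifest row
#'
#' @param dataset A [generate_ripeness_dataset()] object.
#' @param i Row index into the manifest.
#' @param library The `dye_library` used to generate the dataset.
#' @return An `array_image`.
#' @export
render_dataset_image <- function(dataset, i, library) {
  stopifnot(inherits(dataset, "ripeness_dataset"))
  row <- dataset$manifest[i, ]
  gas <- if (is.na(row$fruit)) NULL else
    gas_mixture(emissions_at(dataset$trajectories[[row$fruit]],
                             row$timestamp_h / 24))
  drift <- blank_drift(row$image_seed, dataset$blank_mean, dataset$blank_sd)
  render_array_image(library, gas = gas, scene = scene_from_row(row),
                     seed = row$image_seed, drift = drift,
                     layout = dataset$layout,
                     meta = list(class_label = row$class_label,
                                 fruit = row$fruit, stage = row$stage,
                                 timestamp_h = row$timestamp_h))
}

#' Render dataset images as a classifier input tensor
#'
#' Renders (a subset of) the manifest and resizes every image to a
#' square `side` raster.
#'
#' @param dataset A `ripeness_dataset`.
#' @param library Its `dye_library`.
#' @param side Input side in pixels (desk default 32; paper scale 255).
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @param indices Optional explicit manifest row indices.
#' @return A list `x` (side x side x 3 x N array of counts), `y`
#'   (integer class index), `classes`, `indices`.
#' @export
render_manifest_images <- function(dataset, library, side = 32L,
                                   split = NULL, indices = NULL) {
  if (is.null(indices)) {
    indices <- seq_len(nrow(dataset$manifest))
    if (!is.null(split))
      indices <- indices[dataset$manifest$split %in% split]
  }
  n <- length(indices)
  x <- array(0, dim = c(side, side, 3L, n))
  for (j in seq_len(n)) {
    img <- render_dataset_image(dataset, indices[j], library)
    x[, , , j] <- preprocess_image(img, side)
  }
  y <- match(dataset$manifest$class_label[indices], dataset$classes)
  list(x = x, y = y, classes = dataset$classes, indices = indices)
}

#' Total ED of dataset images against the unreacted reference array
#'
#' The reference is the canonical-scene render of the unreacted library
#' (the stored time-zero photo of the membrane design). Each dataset
#' image is optionally calibrated against its black/white labels before
#' spot extraction.
#'
#' @param dataset A `ripeness_dataset`.
#' @param library Its `dye_library`.
#' @param indices Manifest row indices (default all).
#' @param calibrate Calibrate images first. Default `TRUE`.
#' @return Numeric vector of total EDs.
#' @export
dataset_total_ed <- function(dataset, library, indices = NULL,
                             calibrate = TRUE) {
  if (is.null(indices)) indices <- seq_len(nrow(dataset$manifest))
  ref <- render_array_image(library, gas = NULL, layout = dataset$layout)
  ref_rgb <- extract_spot_rgb(ref)
  vapply(indices, function(i) {
    img <- render_dataset_image(dataset, i, library)
    if (calibrate) img <- calibrate_image(img)
    delta_signature(ref_rgb, extract_spot_rgb(img))$total_ed
  }, numeric(1))
}

#' Write a dataset manifest as CSV
#' @param dataset A `ripeness_dataset`.
#' @param path Output CSV path.
#' @param image_dir Optional directory recorded in the `path` column.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(dataset, path, image_dir = "images") {
  m <- dataset$manifest
  m$path <- file.path(image_dir, sprintf("img_%05d.png", m$id))
  m$seed <- dataset$seed
  cols <- c("path", "fruit", "stage", "class_label", "timestamp_h", "split",
            "seed", "image_seed", "gain_r", "gain_g", "gain_b",
            "rotation_deg", "perspective", "noise_sd", "background_seed",
            "batch")
  write.csv(m[, cols], path, row.names = FALSE)
  invisible(path)
}
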