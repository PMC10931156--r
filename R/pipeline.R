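#' Default pipeline configuration
#'
#' A single nested list drives every stage; all randomness derives from
#' the one top-level seed. `demo = TRUE` shrinks problem sizes for a
#' quick end-to-end run.
#'
#' @param seed Top-level seed.
#' @param demo Use small demo sizes.
#' @return Named list (serializable to YAML unchanged).
#' @export
default_config <- function(seed = 1L, demo = FALSE) {
  list(
    seed = as.integer(seed),
    generator = list(
      vocs = if (demo) c("trans-2-hexenal", "benzaldehyde") else voc_names(),
      concentrations = c(0, 5, 10, 25, 50, 100, 250, 500, 1000),
      replicates = 3L,
      n_images_per_class = if (demo) 12L else 100L,
      scene_level = "paper",
      blank_mean = 47.75, blank_sd = 2),
    model = list(input_side = 32L, stem_stride = 2L,
                 spp_levels = c(1L, 2L, 4L), paper_scale = FALSE),
    train = list(epochs = if (demo) 2L else 15L, batch_size = 32L),
    compare = list(n_per_class = if (demo) 5L else 20L,
                   n_calibration = if (demo) 3L else 10L)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage_marker <- function(outdir, name) file.path(outdir, name, ".done")

stage_fresh <- function(outdir, name, config, force) {
  mk <- stage_marker(outdir, name)
  hash <- paste(deparse(config), collapse = "")
  if (!force && file.exists(mk) && identical(readLines(mk, warn = FALSE)[1],
                                             digest_chr(hash)))
    return(FALSE)
  dir.create(file.path(outdir, name), recursive = TRUE, showWarnings = FALSE)
  TRUE
}

stage_done <- function(outdir, name, config) {
  hash <- paste(deparse(config), collapse = "")
  writeLines(digest_chr(hash), stage_marker(outdir, name))
}

digest_chr <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147480009
  as.character(h)
}

#' Compare ED reference-range and DCNN classification
#'
#' Draws a seeded evaluation set of `n_per_class` fresh images per class
#' under the training-batch conditions, classifies each image twice --
#' by the total-ED reference ranges built from `n_calibration` seeded
#' calibration samples per class, and by the trained network -- and
#' reports both accuracies on the identical draw.
#'
#' @param library The `dye_library`.
#' @param model A trained `dcnn_model`.
#' @param config Pipeline configuration (for scene level and sizes).
#' @param seed Integer seed for the draws.
#' @return Data frame with columns `method` and `accuracy` (%), with the
#'   two [eval_report()]s attached as attribute `"reports"`.
#' @export
compare_ed_vs_dcnn <- function(library, model, config = default_config(),
                               seed = config$seed) {
  npc <- config$compare$n_per_class
  ncal <- config$compare$n_calibration
  lvl <- config$generator$scene_level
  cal <- generate_ripeness_dataset(
    library, n_images_per_class = ncal, seed = derive_seed(seed, "ed-cal"),
    scene_level = lvl, blank_mean = config$generator$blank_mean,
    blank_sd = config$generator$blank_sd)
  cal_ed <- dataset_total_ed(cal, library)
  ranges <- build_reference_ranges(split(cal_ed, cal$manifest$class_label))

  ev <- generate_ripeness_dataset(
    library, n_images_per_class = npc, seed = derive_seed(seed, "ed-eval"),
    scene_level = lvl, blank_mean = config$generator$blank_mean,
    blank_sd = config$generator$blank_sd)
  truth <- match(ev$manifest$class_label, ev$classes)

  ed_pred_lab <- classify_by_ed(dataset_total_ed(ev, library), ranges)
  ed_pred <- match(ed_pred_lab, ev$classes)
  ed_acc <- 100 * mean(!is.na(ed_pred) & ed_pred == truth)
  ed_pred[is.na(ed_pred)] <- ((truth[is.na(ed_pred)]) %% length(ev$classes)) + 1L
  ed_rep <- eval_report(truth, ed_pred, ev$classes)

  tensors <- render_manifest_images(ev, library, side = model$config$input_side)
  dc_pred <- predict(model, tensors$x)
  dc_rep <- eval_report(truth, dc_pred, ev$classes)

  out <- data.frame(method = c("ed_reference_range", "dcnn"),
                    accuracy = c(ed_acc, dc_rep$accuracy))
  attr(out, "reports") <- list(ed = ed_rep, dcnn = dc_rep)
  out
}

#' Run the end-to-end pipeline
#'
#' Stage graph: `simulate` (dye library, dose-response image pairs,
#' dataset manifests) -> `process` (signatures, differential maps) ->
#' `lod` and `hca` (ED statistics) -> `train` -> `eval` -> `gradcam` ->
#' `compare`. Each stage writes its artifacts under a stage-named
#' subdirectory of `outdir`; a completed stage is skipped on re-run with
#' an identical configuration unless `force = TRUE`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param outdir Output directory.
#' @param stages Character vector of stages, or `"full"`.
#' @param force Re-run stages even if up to date.
#' @return A run report (list of per-stage timings, artifact paths and
#'   headline metrics), also written to `outdir/run_report.json`.
#' @export
run_pipeline <- function(config = default_config(demo = TRUE),
                         outdir = "ripenose_run", stages = "full",
                         force = FALSE) {
  all_stages <- c("simulate", "process", "lod", "hca", "train", "eval",
                  "gradcam", "compare")
  if (identical(stages, "full")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  library <- make_dye_library(seed)
  report <- list(seed = seed, stages = list(), metrics = list())

  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- expr
    report$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    value
  }
  need <- function(name) {
    if (!file.exists(stage_marker(outdir, name)))
      stop("stage '", name, "' has not been run yet; run it first")
  }

  gen <- config$generator
  pairs_cache <- NULL
  dose_pairs <- function() {
    if (is.null(pairs_cache))
      pairs_cache <<- lapply(setNames(gen$vocs, gen$vocs), function(v)
        generate_dose_response_images(
          library, v, gen$concentrations, replicates = gen$replicates,
          seed = derive_seed(seed, paste0("dose-", v)),
          blank_mean = gen$blank_mean, blank_sd = gen$blank_sd))
    pairs_cache
  }

  if ("simulate" %in% stages && stage_fresh(outdir, "simulate", config, force)) {
    timed("simulate", {
      sdir <- file.path(outdir, "simulate")
      write.csv(library$spec, file.path(sdir, "dye_library.csv"),
                row.names = FALSE)
      for (v in gen$vocs) {
        pr <- dose_pairs()[[v]]
        vd <- file.path(sdir, gsub("[^a-z0-9]+", "_", v))
        dir.create(vd, showWarnings = FALSE)
        for (rec in pr$records) {
          base <- sprintf("c%g_r%d", rec$conc, rec$replicate)
          write_image_png(rec$pre, file.path(vd, paste0(base, "_pre.png")))
          write_image_png(rec$post, file.path(vd, paste0(base, "_post.png")))
        }
      }
      ds <- generate_ripeness_dataset(
        library, gen$n_images_per_class, seed = seed,
        scene_level = gen$scene_level, blank_mean = gen$blank_mean,
        blank_sd = gen$blank_sd)
      ts <- generate_ripeness_dataset(
        library, max(2L, gen$n_images_per_class %/% 5L), seed = seed,
        scene_level = gen$scene_level, batch = "test",
        blank_mean = gen$blank_mean, blank_sd = gen$blank_sd)
      write_manifest_csv(ds, file.path(sdir, "manifest_trainval.csv"))
      write_manifest_csv(ts, file.path(sdir, "manifest_test.csv"))
      saveRDS(list(dataset = ds, test_dataset = ts),
              file.path(sdir, "datasets.rds"))
      stage_done(outdir, "simulate", config)
    })
  }

  series <- NULL
  if (any(c("process", "lod") %in% stages)) {
    need("simulate")
    series <- lapply(dose_pairs(), measure_dose_response)
  }

  if ("process" %in% stages && stage_fresh(outdir, "process", config, force)) {
    timed("process", {
      pdir <- file.path(outdir, "process")
      for (v in names(series)) {
        pr <- dose_pairs()[[v]]
        tag <- gsub("[^a-z0-9]+", "_", v)
        for (rec in pr$records) {
          sig <- pair_signature(rec$pre, rec$post, calibrate = FALSE)
          base <- sprintf("%s_c%g_r%d", tag, rec$conc, rec$replicate)
          write_signature_csv(sig, file.path(pdir, paste0(base, ".csv")))
        }
        top <- pr$records[[length(pr$records)]]
        sig <- pair_signature(top$pre, top$post, calibrate = FALSE)
        write_image_png(render_differential_map(sig),
                        file.path(pdir, paste0(tag, "_diffmap.png")))
      }
      stage_done(outdir, "process", config)
    })
  }

  if ("lod" %in% stages && stage_fresh(outdir, "lod", config, force)) {
    timed("lod", {
      lods <- vapply(series, function(s) as.numeric(estimate_lod(s)),
                     numeric(1))
      tab <- data.frame(voc = names(series), lod_ppm = lods)
      write.csv(tab, file.path(outdir, "lod", "lod_table.csv"),
                row.names = FALSE)
      report$metrics$lod <- setNames(as.list(lods), names(series))
      stage_done(outdir, "lod", config)
    })
  }

  if ("hca" %in% stages && stage_fresh(outdir, "hca", config, force)) {
    timed("hca", {
      em <- simulate_voc_ed_matrix(seed)
      lk <- hca_ward(em$means)
      write_linkage_csv(lk, file.path(outdir, "hca", "linkage.csv"))
      sr27 <- cluster_success_rate(lk, em$condition, k = 27L)
      sr9 <- cluster_success_rate(lk, em$voc, k = 9L)
      report$metrics$hca_success_rate_k27 <- sr27
      report$metrics$hca_success_rate_k9 <- sr9
      try({
        grDevices::png(file.path(outdir, "hca", "dendrogram.png"),
                       width = 900, height = 500)
        plot(lk$hclust, main = "Ward linkage of VOC fingerprints",
             xlab = "", sub = "")
        grDevices::dev.off()
      }, silent = TRUE)
      stage_done(outdir, "hca", config)
    })
  }

  model <- NULL
  load_datasets <- function() readRDS(file.path(outdir, "simulate",
                                                "datasets.rds"))
  if ("train" %in% stages && stage_fresh(outdir, "train", config, force)) {
    need("simulate")
    timed("train", {
      dsl <- load_datasets()
      mcfg <- dcnn_config(input_side = config$model$input_side,
                          stem_stride = config$model$stem_stride,
                          spp_levels = config$model$spp_levels,
                          paper_scale = isTRUE(config$model$paper_scale))
      model <- build_model(mcfg, seed = seed)
      tensors <- render_manifest_images(dsl$dataset, library,
                                        side = mcfg$input_side,
                                        split = "train")
      tensors$classes <- dsl$dataset$classes
      model <- train_dcnn(model, tensors, epochs = config$train$epochs,
                          batch_size = config$train$batch_size, seed = seed)
      saveRDS(model, file.path(outdir, "train", "model.rds"))
      jsonlite::write_json(
        list(config = unclass(model$config),
             blocks = model$plan$blocks, final_C = model$plan$final_C,
             feature_dim = model$plan$feat_dim, n_params = n_params(model)),
        file.path(outdir, "train", "architecture.json"),
        auto_unbox = TRUE, digits = NA)
      write.csv(model$history, file.path(outdir, "train", "history.csv"),
                row.names = FALSE)
      stage_done(outdir, "train", config)
    })
  }
  load_model <- function() {
    if (is.null(model)) {
      need("train")
      model <<- readRDS(file.path(outdir, "train", "model.rds"))
    }
    model
  }

  if ("eval" %in% stages && stage_fresh(outdir, "eval", config, force)) {
    need("simulate")
    timed("eval", {
      m <- load_model()
      dsl <- load_datasets()
      for (what in c("val", "test")) {
        ds <- if (what == "val") dsl$dataset else dsl$test_dataset
        te <- render_manifest_images(ds, library, side = m$config$input_side,
                                     split = if (what == "val") "val" else "test")
        te$classes <- ds$classes
        rep_ <- evaluate_model(m, te)
        write_eval_report(rep_, file.path(outdir, "eval",
                                          paste0(what, ".json")))
        report$metrics[[paste0(what, "_accuracy")]] <- rep_$accuracy
        report$metrics[[paste0(what, "_macro_f1")]] <- rep_$macro_f1
      }
      stage_done(outdir, "eval", config)
    })
  }

  if ("gradcam" %in% stages && stage_fresh(outdir, "gradcam", config, force)) {
    need("simulate")
    timed("gradcam", {
      m <- load_model()
      dsl <- load_datasets()
      idx <- which(dsl$dataset$manifest$split == "val")[1:3]
      for (i in idx) {
        img <- render_dataset_image(dsl$dataset, i, library)
        cls <- match(dsl$dataset$manifest$class_label[i], dsl$dataset$classes)
        cam <- grad_cam(m, img, cls)
        cam_rgb <- preprocess_image(img, m$config$input_side)
        heat <- cam / max(cam, 1e-9)
        cam_rgb[, , 1] <- clip255(cam_rgb[, , 1] + 120 * heat)
        write_image_png(cam_rgb, file.path(outdir, "gradcam",
                                           sprintf("cam_%03d.png", i)))
      }
      stage_done(outdir, "gradcam", config)
    })
  }

  if ("compare" %in% stages && stage_fresh(outdir, "compare", config, force)) {
    timed("compare", {
      m <- load_model()
      cmp <- compare_ed_vs_dcnn(library, m, config, seed = seed)
      write.csv(cmp, file.path(outdir, "compare", "ed_vs_dcnn.csv"),
                row.names = FALSE)
      report$metrics$ed_accuracy <- cmp$accuracy[cmp$method == "ed_reference_range"]
      report$metrics$dcnn_accuracy <- cmp$accuracy[cmp$method == "dcnn"]
      stage_done(outdir, "compare", config)
    })
  }

  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
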