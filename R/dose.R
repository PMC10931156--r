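#' Generate pre/post image pairs across a concentration series
#'
#' For each concentration and replicate, renders a pre-exposure (blank)
#' image and a post-exposure image of the same membrane under the same
#' scene. Post-exposure spots carry the gas-induced shift plus a small
#' stochastic per-spot drift calibrated so that the blank (zero
#' concentration) total-ED distribution has the configured mean and
#' standard deviation (defaults 47.75 and 2 counts, i.e. 3 sigma = 6).
#'
#' @param library A [make_dye_library()] object.
#' @param voc VOC name (one of [voc_names()]).
#' @param concentrations Ascending concentrations in ppm (may include 0).
#' @param replicates Replicates per concentration (>= 1).
#' @param seed Integer seed.
#' @param scene A [scene_params()]; flatbed-scanner capture is canonical.
#' @param blank_mean,blank_sd Blank total-ED calibration (counts). Set
#'   `blank_mean = 0` for a noise-free generator.
#' @param layout Geometry from [array_layout()].
#' @return An object of class `dose_response_images`: a list of records
#'   `(conc, replicate, pre, post)` plus the configuration.
#' @export
generate_dose_response_images <- function(library, voc, concentrations,
                                          replicates = 3L, seed = 1L,
                                          scene = canonical_scene(),
                                          blank_mean = 47.75, blank_sd = 2,
                                          layout = array_layout()) {
  stopifnot(inherits(library, "dye_library"), replicates >= 1L)
  if (length(concentrations) == 0L) stop("empty concentration list")
  if (is.unsorted(concentrations)) stop("concentrations must be ascending")
  voc <- match.arg(voc, voc_names())
  records <- list()
  k <- 0L
  for (ci in seq_along(concentrations)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      child <- derive_seed(seed, sprintf("dose-%d-%d", ci, r))
      drift <- blank_drift(child, blank_mean, blank_sd)
      conc <- concentrations[ci]
      gas <- gas_mixture(setNames(conc, voc))
      pre <- render_array_image(library, gas = NULL, scene = scene,
                                seed = child, layout = layout,
                                meta = list(voc = voc, conc = conc,
                                            replicate = r, phase = "pre"))
      post <- render_array_image(library, gas = gas, scene = scene,
                                 seed = child + 1L, drift = drift,
                                 layout = layout,
                                 meta = list(voc = voc, conc = conc,
                                             replicate = r, phase = "post"))
      records[[k]] <- list(conc = conc, replicate = r, pre = pre, post = post)
    }
  }
  structure(list(records = records, voc = voc,
                 concentrations = concentrations, replicates = replicates,
                 blank_mean = blank_mean, blank_sd = blank_sd, seed = seed),
            class = "dose_response_images")
}

#' Construct a dose-response series
#'
#' @param voc VOC name.
#' @param concentrations Ascending tested concentrations (ppm).
#' @param total_ed Replicate-averaged total ED per concentration.
#' @param per_spot_ed Optional length(concentrations) x 25 matrix of
#'   replicate-averaged per-spot EDs.
#' @param blank_mean,blank_sd Blank-control total-ED statistics.
#' @return An object of class `dose_response_series`.
#' @export
dose_response_series <- function(voc, concentrations, total_ed,
                                 per_spot_ed = NULL,
                                 blank_mean = 47.75, blank_sd = 2) {
  stopifnot(length(concentrations) == length(total_ed), blank_sd >= 0)
  if (!is.null(per_spot_ed)) {
    per_spot_ed <- as.matrix(per_spot_ed)
    stopifnot(nrow(per_spot_ed) == length(concentrations),
              ncol(per_spot_ed) == 25L)
  }
  structure(list(voc = voc, concentrations = as.numeric(concentrations),
                 total_ed = as.numeric(total_ed), per_spot_ed = per_spot_ed,
                 blank_mean = blank_mean, blank_sd = blank_sd),
            class = "dose_response_series")
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("dose-response of %s over %d concentrations; blank %.2f +/- %.2f\n",
              x$voc, length(x$concentrations), x$blank_mean, x$blank_sd))
  print(data.frame(ppm = x$concentrations, total_ed = round(x$total_ed, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Measure a dose-response series from image pairs
#'
#' Extracts the [pair_signature()] of every pre/post pair and averages
#' replicates at each concentration. Blank statistics are taken from the
#' replicates at zero concentration when at least two are present,
#' otherwise from the generator's configured values.
#'
#' @param pairs A [generate_dose_response_images()] object.
#' @param calibrate Calibrate images against their labels first.
#' @param total Total-ED aggregation rule.
#' @return A [dose_response_series()].
#' @export
measure_dose_response <- function(pairs, calibrate = FALSE,
                                  total = c("sum", "rss")) {
  stopifnot(inherits(pairs, "dose_response_images"))
  total <- match.arg(total)
  sigs <- lapply(pairs$records, function(rec)
    pair_signature(rec$pre, rec$post, calibrate = calibrate, total = total))
  concs <- vapply(pairs$records, `[[`, numeric(1), "conc")
  totals <- vapply(sigs, `[[`, numeric(1), "total_ed")
  per_spot <- t(vapply(sigs, `[[`, numeric(25), "ed_per_spot"))
  uc <- sort(unique(concs))
  tot_mean <- vapply(uc, function(cc) mean(totals[concs == cc]), numeric(1))
  spot_mean <- t(vapply(uc, function(cc)
    colMeans(per_spot[concs == cc, , drop = FALSE]), numeric(25)))
  if (sum(concs == 0) >= 2L) {
    bm <- mean(totals[concs == 0]); bs <- sd(totals[concs == 0])
  } else {
    bm <- pairs$blank_mean; bs <- pairs$blank_sd
  }
  dose_response_series(pairs$voc, uc, tot_mean, spot_mean,
                       blank_mean = bm, blank_sd = bs)
}

#' Expected noise-free total ED of a VOC at given concentrations
#'
#' Closed-form deterministic response of a library (no drift, no scene):
#' the sum over spots of the Euclidean norm of the Hill-saturating RGB
#' shift. Useful for planting and recovering detection thresholds.
#'
#' @param library A `dye_library`.
#' @param voc VOC name.
#' @param conc Concentration(s) in ppm.
#' @return Numeric vector of total EDs.
#' @export
expected_total_ed <- function(library, voc, conc) {
  vapply(conc, function(cc) {
    d <- simulate_delta(library, gas_mixture(setNames(cc, voc)))
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
}

#' Synthetic VOC-by-concentration ED matrix for clustering
#'
#' Builds the 27-condition ED response matrix (9 VOCs x 3 concentrations
#' x 25 per-spot EDs) the way the gas-rig experiment produces it: each
#' condition's mean per-spot ED pattern comes from the dye library's
#' saturating responses, and replicate rows add Gaussian noise whose
#' standard deviation is the minimum between-condition mean separation
#' divided by `separation` (default 10, i.e. separation is 10x the
#' within-condition noise sd).
#'
#' @param seed Integer seed (also seeds the default library).
#' @param library Optional `dye_library`; defaults to
#'   `make_dye_library(seed)`.
#' @param concentrations Three tested concentrations (ppm).
#' @param replicates Replicates per condition. Default 3.
#' @param separation Ratio of minimum between-condition mean separation
#'   to noise sd. Default 10.
#' @return A list with `means` (27 x 25 replicate-averaged matrix),
#'   `true_means` (the noise-free condition patterns), `replicates`
#'   (27 * replicates x 25), `condition`, `voc`, `conc` labels, and
#'   `noise_sd`.
#' @export
simulate_voc_ed_matrix <- function(seed = 1L, library = NULL,
                                   concentrations = c(100, 500, 1000),
                                   replicates = 3L, separation = 10) {
  if (is.null(library)) library <- make_dye_library(seed)
  stopifnot(length(concentrations) == 3L, replicates >= 1L, separation > 0)
  vocs <- voc_names()
  cond <- expand.grid(conc = concentrations, voc = vocs,
                      stringsAsFactors = FALSE)[, c("voc", "conc")]
  mu <- t(mapply(function(v, cc) {
    d <- simulate_delta(library, gas_mixture(setNames(cc, v)))
    sqrt(rowSums(d^2))
  }, cond$voc, cond$conc))
  rownames(mu) <- paste(cond$voc, cond$conc, sep = "@")
  noise_sd <- min(dist(mu)) / separation
  reps <- with_seed(derive_seed(seed, "ed-matrix-noise"), {
    do.call(rbind, lapply(seq_len(nrow(mu)), function(i)
      matrix(rep(mu[i, ], each = replicates), replicates, 25L,
             byrow = FALSE) +
        matrix(rnorm(replicates * 25L, 0, noise_sd), replicates, 25L)))
  })
  rep_cond <- rep(rownames(mu), each = replicates)
  means <- do.call(rbind, lapply(rownames(mu), function(lb)
    colMeans(reps[rep_cond == lb, , drop = FALSE])))
  rownames(means) <- rownames(mu)
  list(means = means, true_means = mu, replicates = reps,
       condition = rownames(mu),
       voc = cond$voc, conc = cond$conc, rep_condition = rep_cond,
       rep_voc = rep(cond$voc, each = replicates), noise_sd = noise_sd)
}
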