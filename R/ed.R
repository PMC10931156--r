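#' Limit of detection by the blank + 3 sigma rule
#'
#' The LOD is the smallest tested concentration whose (replicate-
#' averaged) total ED exceeds the blank mean plus three blank standard
#' deviations. Returns `NA` when no tested concentration crosses the
#' threshold ("not reached").
#'
#' @param series A [dose_response_series()].
#' @param blank_mean,blank_sd Optional overrides of the series' blank
#'   statistics.
#' @param spot Optional dye id (1-25): estimate a per-dye LOD from that
#'   spot's ED column instead of the total. The caller must then supply
#'   blank statistics on the single-spot scale.
#' @return LOD in ppm, or `NA_real_` if not reached. The detection
#'   threshold is attached as attribute `"threshold"`.
#' @export
estimate_lod <- function(series, blank_mean = NULL, blank_sd = NULL,
                         spot = NULL) {
  stopifnot(inherits(series, "dose_response_series"))
  if (is.unsorted(series$concentrations))
    stop("concentrations must be sorted ascending")
  bm <- if (is.null(blank_mean)) series$blank_mean else blank_mean
  bs <- if (is.null(blank_sd)) series$blank_sd else blank_sd
  if (is.null(bm) || is.null(bs)) stop("blank statistics are required")
  ed <- if (is.null(spot)) series$total_ed else {
    if (is.null(series$per_spot_ed)) stop("series lacks per-spot EDs")
    stopifnot(spot >= 1L, spot <= 25L)
    series$per_spot_ed[, spot]
  }
  thr <- bm + 3 * bs
  above <- which(ed > thr)
  lod <- if (length(above)) series$concentrations[min(above)] else NA_real_
  structure(lod, threshold = thr)
}

#' Rank dyes by sensitivity to a VOC
#'
#' Orders dyes by their per-spot ED at the highest tested concentration,
#' descending; ties break toward the lower dye id.
#'
#' @param series A [dose_response_series()] carrying `per_spot_ed`.
#' @param k Number of dyes to return (<= 25). Default 8.
#' @return Integer vector of dye ids (1-25), most sensitive first.
#' @export
rank_sensitive_dyes <- function(series, k = 8L) {
  stopifnot(inherits(series, "dose_response_series"), k <= 25L, k >= 1L)
  if (is.null(series$per_spot_ed)) stop("series lacks per-spot EDs")
  top <- series$per_spot_ed[nrow(series$per_spot_ed), ]
  order(-top, seq_along(top))[seq_len(k)]
}

#' Build per-class ED reference ranges
#'
#' The reference range of each ripeness class is the min-max interval of
#' its calibration samples' total EDs.
#'
#' @param labeled_eds Named list: class label -> numeric vector of total
#'   EDs (at least one sample per class; two or more recommended).
#' @return An object of class `reference_ranges` (data frame with
#'   `class`, `lo`, `hi`).
#' @export
build_reference_ranges <- function(labeled_eds) {
  stopifnot(is.list(labeled_eds), length(labeled_eds) >= 1L)
  if (any(!vapply(labeled_eds, length, 1L)))
    stop("every class needs at least one ED sample")
  df <- data.frame(class = names(labeled_eds),
                   lo = vapply(labeled_eds, min, numeric(1)),
                   hi = vapply(labeled_eds, max, numeric(1)),
                   n = vapply(labeled_eds, length, integer(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(df, class = c("reference_ranges", "data.frame"))
}

#' Classify samples by ED reference range
#'
#' Assigns each total ED to the class whose reference interval contains
#' it. If several intervals contain it the narrowest wins and the call
#' is flagged ambiguous; if none contains it the call is
#' `"out_of_range"`.
#'
#' @param total_ed Numeric vector of total EDs.
#' @param ranges A [build_reference_ranges()] object.
#' @return Character vector of class labels (or `"out_of_range"`), with
#'   a logical attribute `"ambiguous"`.
#' @export
classify_by_ed <- function(total_ed, ranges) {
  stopifnot(inherits(ranges, "reference_ranges"))
  width <- ranges$hi - ranges$lo
  out <- character(length(total_ed))
  amb <- logical(length(total_ed))
  for (i in seq_along(total_ed)) {
    hit <- which(total_ed[i] >= ranges$lo & total_ed[i] <= ranges$hi)
    if (length(hit) == 0L) {
      out[i] <- "out_of_range"
    } else {
      if (length(hit) > 1L) {
        amb[i] <- TRUE
        hit <- hit[order(width[hit], hit)][1L]
      }
      out[i] <- ranges$class[hit]
    }
  }
  structure(out, ambiguous = amb)
}

#' Ward-linkage hierarchical clustering of ED fingerprints
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances between per-spot ED rows (one row per sample or
#' condition).
#'
#' @param m Numeric matrix, n samples x 25 per-spot EDs (n >= 2).
#' @param labels Optional sample labels; default row names.
#' @return An object of class `linkage_result` wrapping the merge tree:
#'   `merge`, `height`, `labels`, `method`, and the underlying `hclust`.
#' @export
hca_ward <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(m))) stop("non-finite entries in the ED matrix")
  h <- hclust(dist(m), method = "ward.D2")
  if (!is.null(labels)) h$labels <- labels
  structure(list(merge = h$merge, height = h$height, labels = h$labels,
                 method = "ward", n = nrow(m), hclust = h),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("Ward linkage over %d samples (%d merges)\n", x$n, x$n - 1L))
  invisible(x)
}

#' Cut a linkage tree into k clusters
#' @param linkage A [hca_ward()] result.
#' @param k Number of clusters.
#' @return Integer cluster assignment per sample.
#' @export
cut_linkage <- function(linkage, k) {
  stopifnot(inherits(linkage, "linkage_result"), k >= 1L, k <= linkage$n)
  cutree(linkage$hclust, k = k)
}

#' Clustering success rate against known labels
#'
#' Cuts the tree into `k` clusters and scores the fraction of samples
#' whose cluster is label-pure (every member shares the sample's label).
#' With `k = n` every singleton is pure and the rate is 1 by definition.
#'
#' @param linkage A [hca_ward()] result.
#' @param true_labels Label per sample.
#' @param k Number of clusters to cut.
#' @return Fraction in [0, 1].
#' @export
cluster_success_rate <- function(linkage, true_labels, k) {
  stopifnot(length(true_labels) == linkage$n)
  cl <- cut_linkage(linkage, k)
  pure <- vapply(seq_along(cl), function(i) {
    members <- true_labels[cl == cl[i]]
    all(members == true_labels[i])
  }, logical(1))
  mean(pure)
}

#' Export a linkage tree as a flat merge table
#' @param linkage A `linkage_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_linkage_csv <- function(linkage, path) {
  df <- data.frame(step = seq_along(linkage$height),
                   left = linkage$merge[, 1], right = linkage$merge[, 2],
                   height = linkage$height)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
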