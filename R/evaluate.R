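#' Classification report: confusion matrix, accuracy, macro F1
#'
#' Builds the K x K confusion matrix (rows = truth, columns =
#' prediction), overall accuracy in percent, per-class precision `p`
#' and recall `r`, and the macro F1 score, where each class's
#' `F1 = 2pr / (p + r)` and is defined as 0 when `p + r = 0`.
#'
#' @param truth Integer true labels (1..K).
#' @param pred Integer predicted labels (1..K).
#' @param classes Class names (length K), or an integer K.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(truth, pred, classes) {
  if (length(classes) == 1L && is.numeric(classes))
    classes <- as.character(seq_len(classes))
  K <- length(classes)
  stopifnot(length(truth) == length(pred), all(truth %in% seq_len(K)),
            all(pred %in% seq_len(K)))
  confusion <- matrix(0L, K, K, dimnames = list(truth = classes,
                                                pred = classes))
  for (i in seq_along(truth))
    confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  report_from_confusion(confusion)
}

#' @rdname eval_report
#' @param confusion K x K confusion-count matrix (rows = truth).
#' @export
report_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  tp <- diag(confusion)
  precision <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  recall <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = confusion,
                 accuracy = 100 * sum(tp) / sum(confusion),
                 precision = precision, recall = recall, f1 = f1,
                 macro_f1 = mean(f1), n = sum(confusion)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% on %d samples, macro F1 %.4f\n",
              x$accuracy, x$n, x$macro_f1))
  invisible(x)
}

#' Evaluate a classifier on labeled data
#'
#' @param model A trained `dcnn_model`.
#' @param data List with `x`, `y` and optionally `classes`.
#' @return An [eval_report()].
#' @export
evaluate_model <- function(model, data) {
  if (length(data$y) == 0L) stop("empty evaluation split")
  pred <- predict(model, data$x)
  classes <- if (!is.null(data$classes)) data$classes
             else model$config$num_classes
  eval_report(data$y, pred, classes)
}

#' Write an eval report as JSON (+ CSV confusion matrix)
#' @param report An `eval_report`.
#' @param path Output JSON path; the confusion matrix goes to the same
#'   path with extension `.confusion.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(accuracy = report$accuracy,
                            macro_f1 = report$macro_f1,
                            precision = report$precision,
                            recall = report$recall, f1 = report$f1,
                            n = report$n),
                       path, auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(report$confusion),
            sub("\\.json$", ".confusion.csv", path))
  invisible(path)
}

#' Grad-CAM class relevance map
#'
#' Gradient-weighted class activation mapping on the final dense block's
#' feature maps: channel weights are the spatially averaged gradients of
#' the target class score, the weighted sum is rectified and bilinearly
#' upsampled to the input extent.
#'
#' @param model A trained `dcnn_model` (at least one training epoch).
#' @param image side x side x 3 array of counts, or an `array_image`
#'   (resized automatically).
#' @param target_class Integer class index (1..num_classes).
#' @return side x side non-negative relevance matrix with attribute
#'   `"target_class"`.
#' @export
grad_cam <- function(model, image, target_class) {
  stopifnot(inherits(model, "dcnn_model"),
            target_class >= 1L, target_class <= model$config$num_classes)
  if (model$trained_epochs == 0L)
    stop("grad_cam requires a trained model")
  side <- model$config$input_side
  img <- if (inherits(image, "array_image")) preprocess_image(image, side)
         else image
  if (!all(dim(img)[1:2] == side)) img <- resize_image(img, side)
  X <- input_to_cube(img)
  fw <- forward_dcnn(model, X, training = FALSE)
  cfg <- model$config
  A <- fw$cache$final_act
  H <- fw$cache$final_H
  C <- dim(A)[1]
  dlog <- matrix(0, cfg$num_classes, 1L)
  dlog[target_class, 1L] <- 1
  dF <- t(model$params$fc_W) %*% dlog
  dA <- array(0, dim = dim(A))
  off <- 0L
  for (lv in cfg$spp_levels) {
    rows <- C * lv * lv
    dpo <- dF[off + seq_len(rows), , drop = FALSE]
    dim(dpo) <- c(C, lv * lv, 1L)
    dA <- dA + adaptive_avgpool_bw(dpo, H, H, lv)
    off <- off + rows
  }
  w <- rowMeans(matrix(dA, C))
  cam <- matrix(colSums(matrix(A, C) * w), H, H)
  cam <- pmax(cam, 0)
  up <- resize_image(array(rep(cam, 3L), c(H, H, 3L)), side)[, , 1L]
  structure(up, target_class = target_class)
}
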