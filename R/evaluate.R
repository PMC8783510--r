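# Localization / segmentation metrics and the layer x threshold grid search.
#
# IoU is computed between the predicted chalk mask and the polygon-derived
# ground-truth mask. Two aggregate accuracies are reported over the chalky
# images: GT-known localization accuracy (fraction with IoU >= 0.5,
# independent of the classifier) and localization accuracy (label correct
# AND IoU >= 0.5). The IoU >= 0.5 cutoff is applied inclusively for both.

#' Intersection-over-union of two masks
#'
#' @param pred,truth logical matrices of equal dimensions; `truth` must be
#'   non-empty (a chalky ground truth always has chalk pixels).
#' @return numeric in `[0, 1]`.
#' @export
iou <- function(pred, truth) {
  assert_that(identical(dim(pred), dim(truth)),
              "pred and truth must have equal dimensions")
  assert_that(any(truth), "truth mask must be non-empty")
  sum(pred & truth) / sum(pred | truth)
}

#' Average IoU as a percentage
#'
#' @param ious non-empty numeric vector of per-image IoU values.
#' @return mean IoU x 100, rounded half-up to 2 decimals.
#' @export
average_iou <- function(ious) {
  assert_that(length(ious) > 0, "ious must be non-empty")
  round_half_up(100 * mean(ious))
}

#' GT-known localization accuracy
#'
#' Fraction of ground-truth chalky images whose IoU with the truth mask is
#' at least 0.5, independent of the classifier's prediction.
#'
#' @param ious non-empty numeric vector of per-image IoU values.
#' @return list with `percent` (2-decimal, half-up), `numerator`,
#'   `denominator`.
#' @export
gt_known_loc_acc <- function(ious) {
  assert_that(length(ious) > 0, "ious must be non-empty")
  num <- sum(ious >= 0.5)
  list(percent = round_half_up(100 * num / length(ious)),
       numerator = num, denominator = length(ious))
}

#' Localization accuracy
#'
#' Fraction of ground-truth chalky images for which both the predicted
#' label is correct and the IoU is at least 0.5. Never exceeds the
#' GT-known localization accuracy on the same images.
#'
#' @param ious per-image IoU values.
#' @param pred_labels,true_labels aligned label vectors; all `true_labels`
#'   must be `"chalky"`.
#' @return list with `percent`, `numerator`, `denominator`.
#' @export
loc_acc <- function(ious, pred_labels, true_labels) {
  assert_that(length(ious) == length(pred_labels) &&
                length(ious) == length(true_labels) && length(ious) > 0,
              "ious, pred_labels and true_labels must align and be non-empty")
  assert_that(all(true_labels == "chalky"),
              "localization accuracy is defined over chalky ground truth")
  num <- sum(pred_labels == true_labels & ious >= 0.5)
  list(percent = round_half_up(100 * num / length(ious)),
       numerator = num, denominator = length(ious))
}

#' Grid search over heatmap layers and binarization thresholds
#'
#' For each (layer, T) cell, computes chalky-class heatmaps for the given
#' grains, binarizes at T, and records the average IoU against the truth
#' masks (truth masks are brought to the model input resolution by
#' nearest-neighbour resampling). The best cell attains the matrix maximum;
#' ties break toward the lower layer index, then the lower threshold.
#'
#' @param handle trained `chalk_cnn`.
#' @param grains list of grain images (chalky ones).
#' @param truth_masks list of logical ground-truth chalk masks, aligned
#'   with `grains` (any resolution; resized to the model input).
#' @param layers character vector of layer names.
#' @param thresholds numeric vector of thresholds (percent of max).
#' @param method CAM variant.
#' @return list of class `grid_result`: `avg_iou` (|layers| x |thresholds|
#'   matrix, percent), `best_layer`, `best_T`, `ious` (per-cell list).
#' @export
grid_search_iou <- function(handle, grains, truth_masks,
                            layers = handle$layer_names,
                            thresholds = seq(10, 80, by = 10),
                            method = "gradcam") {
  assert_that(length(grains) == length(truth_masks) && length(grains) > 0,
              "grains and truth_masks must align and be non-empty")
  assert_that(length(layers) > 0 && length(thresholds) > 0,
              "layers and thresholds must be non-empty")
  cam_fun <- switch(method,
                    "gradcam" = gradcam_heatmap,
                    "gradcam++" = gradcampp_heatmap,
                    "scorecam" = scorecam_heatmap,
                    ck_stop(sprintf("unknown CAM method '%s'", method),
                            class = "chalkcam_config_error"))
  tm <- lapply(truth_masks, function(m) resize_nearest(m, handle$input_size))
  avg <- matrix(NA_real_, length(layers), length(thresholds),
                dimnames = list(layers, paste0("T", thresholds)))
  cell_ious <- list()
  for (li in seq_along(layers)) {
    hms <- lapply(grains, function(g)
      cam_fun(handle, g, class = "chalky", layer = layers[li]))
    for (ti in seq_along(thresholds)) {
      ious_ <- vapply(seq_along(grains), function(i)
        iou(binarize_heatmap(hms[[i]], thresholds[ti]), tm[[i]]), 0)
      avg[li, ti] <- average_iou(ious_)
      cell_ious[[paste(layers[li], thresholds[ti], sep = "_")]] <- ious_
    }
  }
  best <- c(1L, 1L)
  for (li in seq_along(layers)) for (ti in seq_along(thresholds))
    if (avg[li, ti] > avg[best[1], best[2]]) best <- c(li, ti)
  structure(list(avg_iou = avg,
                 best_layer = layers[best[1]],
                 best_T = thresholds[best[2]],
                 ious = cell_ious),
            class = "grid_result")
}

#' Per-group mean and standard error of chalkiness phenotypes
#'
#' Aggregates chalkiness records by grouping keys (e.g. genotype x panicle
#' x treatment) and reports per-group mean and SEM (= sd / sqrt(n)) of the
#' chalk-area percentage and the ChalkyScore. Groups of one record report
#' SEM as `NA`; empty groups are never emitted.
#'
#' @param records data.frame of chalkiness records including the columns in
#'   `group_keys` plus `chalky_score` and `chalk_area_percent`.
#' @param group_keys character vector of grouping column names.
#' @return data.frame with the keys, `n`, and mean/SEM columns for both
#'   phenotypes.
#' @export
aggregate_by_group <- function(records, group_keys) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "records must be a non-empty data.frame")
  missing_keys <- setdiff(group_keys, names(records))
  assert_that(length(missing_keys) == 0,
              sprintf("unknown group key(s): %s",
                      paste(missing_keys, collapse = ", ")))
  assert_that(all(c("chalky_score", "chalk_area_percent") %in% names(records)),
              "records must have chalky_score and chalk_area_percent")
  sem <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  groups <- split(records, records[group_keys], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    cbind(g[1, group_keys, drop = FALSE],
          data.frame(n = nrow(g),
                     mean_chalk_area_percent = mean(g$chalk_area_percent),
                     sem_chalk_area_percent = sem(g$chalk_area_percent),
                     mean_chalky_score = mean(g$chalky_score),
                     sem_chalky_score = sem(g$chalky_score)))
  }))
  rownames(out) <- NULL
  out
}
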