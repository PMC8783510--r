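# From heatmap to phenotype: binary chalk mask, ChalkyScore, chalk-area %.
#
# Both quantities are defined relative to the heatmap's per-image maximum,
# which makes them invariant to positive rescaling of the heatmap and pins
# the ChalkyScore to [0, 1]: 0 = no chalkiness, 1 = severe chalkiness over
# the whole grain surface.

#' Binarize a heatmap at a percentage of its maximum
#'
#' Pixels whose value is at least `T`% of the per-image maximum heatmap
#' value form the chalk mask. An all-zero heatmap yields an empty mask.
#'
#' @param heatmap a `chalk_heatmap` (its `final`, input-resolution map is
#'   used) or a nonnegative numeric matrix.
#' @param T threshold as percent of the per-image maximum, in (0, 100].
#' @return logical matrix.
#' @export
binarize_heatmap <- function(heatmap, T = 60) {
  h <- if (inherits(heatmap, "chalk_heatmap")) heatmap$final else heatmap
  assert_that(is.matrix(h) && is.numeric(h), "heatmap must be numeric")
  assert_that(is_number(T) && T > 0 && T <= 100, "T must be in (0, 100]")
  mx <- max(h)
  if (mx <= 0) return(matrix(FALSE, nrow(h), ncol(h)))
  h >= (T / 100) * mx
}

#' ChalkyScore of a grain
#'
#' Mean of the max-normalized heatmap over the grain-foreground pixels:
#' `(1/Z) * sum over GrainArea of H_final / max(H_final)`. An all-zero
#' heatmap scores 0.
#'
#' @param heatmap a `chalk_heatmap` or numeric matrix (input resolution).
#' @param grain a `grain_mask` (see [grain_area_mask()]) or logical matrix
#'   of the same dimensions as the heatmap.
#' @return numeric in `[0, 1]`.
#' @export
chalk_score <- function(heatmap, grain) {
  h <- if (inherits(heatmap, "chalk_heatmap")) heatmap$final else heatmap
  m <- if (inherits(grain, "grain_mask")) grain$mask else grain
  assert_that(is.matrix(h), "heatmap must be a matrix")
  assert_that(identical(dim(h), dim(m)),
              "heatmap and grain mask dimensions must match")
  Z <- sum(m)
  assert_that(Z > 0, "grain mask is empty (Z = 0)")
  mx <- max(h)
  if (mx <= 0) return(0)
  sum(h[m]) / mx / Z
}

#' Chalk area as a percentage of grain area
#'
#' `100 * |chalk mask intersect grain mask| / Z`.
#'
#' @param mask logical chalk mask (e.g. from [binarize_heatmap()]).
#' @param grain a `grain_mask` or logical matrix, same dimensions.
#' @return percentage in `[0, 100]`.
#' @export
chalk_area_percent <- function(mask, grain) {
  m <- if (inherits(grain, "grain_mask")) grain$mask else grain
  assert_that(identical(dim(mask), dim(m)),
              "mask and grain mask dimensions must match")
  Z <- sum(m)
  assert_that(Z > 0, "grain mask is empty (Z = 0)")
  100 * sum(mask & m) / Z
}

#' Quantify chalkiness for a batch of grains
#'
#' For each grain: predict the label, compute the chalky-class heatmap at
#' the given layer, binarize it at threshold `T`, and derive ChalkyScore
#' and chalk-area percentage over the grain foreground (computed by
#' [grain_area_mask()] and brought to the model input resolution). When
#' `gate_on_prediction` is `TRUE` (the default use of the pipeline),
#' grains predicted non-chalky receive score 0, area 0 and an empty mask.
#'
#' @param handle trained `chalk_cnn`.
#' @param grains list of grain images (`grain_image` objects or arrays).
#' @param layer layer used for the heatmap.
#' @param T binarization threshold (percent of max).
#' @param gate_on_prediction zero out grains predicted non-chalky.
#' @param method CAM variant: `"gradcam"`, `"gradcam++"` or `"scorecam"`.
#' @return data.frame with columns `grain_id`, `label`, `chalky_score`,
#'   `chalk_area_percent`, `layer`, `threshold`; the binary chalk masks are
#'   attached as the `masks` attribute (one per row).
#' @export
quantify_batch <- function(handle, grains, layer = "block2", T = 60,
                           gate_on_prediction = TRUE, method = "gradcam") {
  assert_that(inherits(handle, "chalk_cnn") && handle$trained,
              "handle must be a trained chalk_cnn")
  cam_fun <- switch(method,
                    "gradcam" = gradcam_heatmap,
                    "gradcam++" = gradcampp_heatmap,
                    "scorecam" = scorecam_heatmap,
                    ck_stop(sprintf("unknown CAM method '%s'", method),
                            class = "chalkcam_config_error"))
  rows <- vector("list", length(grains))
  masks <- vector("list", length(grains))
  for (i in seq_along(grains)) {
    g <- grains[[i]]
    id <- if (inherits(g, "grain_image") && !is.null(g$id)) g$id
          else sprintf("grain%04d", i)
    pred <- predict(handle, g)
    if (gate_on_prediction && pred$label == "non-chalky") {
      masks[[i]] <- matrix(FALSE, handle$input_size[1], handle$input_size[2])
      rows[[i]] <- data.frame(grain_id = id, label = pred$label,
                              chalky_score = 0, chalk_area_percent = 0,
                              layer = layer, threshold = T,
                              stringsAsFactors = FALSE)
      next
    }
    gm <- grain_area_mask(g)
    gm_rs <- resize_nearest(gm$mask, handle$input_size)
    hm <- cam_fun(handle, g, class = "chalky", layer = layer)
    mask <- binarize_heatmap(hm, T) & gm_rs
    masks[[i]] <- mask
    rows[[i]] <- data.frame(
      grain_id = id, label = pred$label,
      chalky_score = chalk_score(hm, gm_rs),
      chalk_area_percent = chalk_area_percent(mask, gm_rs),
      layer = layer, threshold = T, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "masks") <- masks
  out
}
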