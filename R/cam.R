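# Class-activation heatmaps.
#
# For a trained classifier, a target class c and a named layer with feature
# maps f^k (k = 1..K, N spatial positions each), Grad-CAM weights each map
# by the spatial mean of the exact gradient of the class logit y^c:
#   w_k = (1/N) sum_ij d y^c / d f^k_ij
# and the heatmap is ReLU(sum_k w_k f^k), upsampled to the input resolution
# by corner-aligned bilinear interpolation. Gradients are taken with respect
# to the logit, never the softmax probability. The chalky class is the class
# of interest throughout.

heatmap_obj <- function(raw, input_size, layer, class_index, method) {
  final <- resize_bilinear(raw, input_size)
  final[final < 0] <- 0
  structure(list(raw = raw, final = final, layer_name = layer,
                 class_index = class_index, method = method),
            class = "chalk_heatmap")
}

#' @export
print.chalk_heatmap <- function(x, ...) {
  cat(sprintf("<chalk_heatmap> %s @ %s, raw %dx%d -> final %dx%d, max %.4g\n",
              x$method, x$layer_name, nrow(x$raw), ncol(x$raw),
              nrow(x$final), ncol(x$final), max(x$final)))
  invisible(x)
}

resolve_class <- function(handle, class) {
  if (is.character(class)) {
    idx <- handle$class_index_map[class]
    assert_that(!is.na(idx), sprintf("unknown class '%s'", class))
    unname(idx)
  } else {
    assert_that(class %in% c(0, 1), "class index must be 0 or 1")
    as.integer(class)
  }
}

# feature stack and logit-gradient of class c at a layer, by exact backprop
cam_grads <- function(handle, image, class, layer) {
  i <- layer_index(handle, layer)
  c_idx <- resolve_class(handle, class)
  fw <- net_forward(handle, prepare_input(handle, image), want_cache = TRUE)
  dlogits <- numeric(2)
  dlogits[c_idx + 1] <- 1
  bw <- net_backward(handle, fw, dlogits, want_param_grads = FALSE)
  list(maps = fw$features[[i]], grads = bw$dfeat[[i]],
       layer_idx = i, class_index = c_idx, fw = fw)
}

#' Grad-CAM feature-map weights
#'
#' @param handle a trained `chalk_cnn`.
#' @param image grain image.
#' @param class class of interest: `"chalky"` (default), `"non-chalky"`,
#'   or a 0/1 index.
#' @param layer layer name from `handle$layer_names`.
#' @return list of class `cam_weights`: `w` (length-K numeric),
#'   `class_index`, `layer_name`.
#' @export
gradcam_weights <- function(handle, image, class = "chalky", layer) {
  g <- cam_grads(handle, image, class, layer)
  K <- dim(g$grads)[3]
  w <- colMeans(matrix(g$grads, ncol = K))
  structure(list(w = w, class_index = g$class_index, layer_name = layer),
            class = "cam_weights")
}

#' Grad-CAM heatmap
#'
#' `ReLU(sum_k w_k f^k)` with the Grad-CAM weights of
#' [gradcam_weights()], bilinearly upsampled to the model input size.
#' Nonnegative everywhere by construction.
#'
#' @inheritParams gradcam_weights
#' @return object of class `chalk_heatmap` with `raw` (feature-resolution)
#'   and `final` (input-resolution) maps.
#' @export
gradcam_heatmap <- function(handle, image, class = "chalky", layer) {
  g <- cam_grads(handle, image, class, layer)
  K <- dim(g$grads)[3]
  w <- colMeans(matrix(g$grads, ncol = K))
  raw <- weighted_map_sum(g$maps, w)
  heatmap_obj(raw, handle$input_size, layer, g$class_index, "gradcam")
}

weighted_map_sum <- function(maps, w) {
  d <- dim(maps)
  raw <- matrix(matrix(maps, ncol = d[3]) %*% w, d[1], d[2])
  raw[raw < 0] <- 0
  raw
}

#' Grad-CAM++ heatmap
#'
#' Extension of Grad-CAM with pixel-wise weighting coefficients
#' `alpha_ij = g_ij^2 / (2 g_ij^2 + sum(f) g_ij^3)` (0/0 treated as 0),
#' where `g` is the exact logit gradient; the map weight is
#' `sum_ij alpha_ij ReLU(g_ij)`. Designed to spread credit over larger or
#' repeated class regions.
#'
#' @inheritParams gradcam_weights
#' @return a `chalk_heatmap`.
#' @export
gradcampp_heatmap <- function(handle, image, class = "chalky", layer) {
  g <- cam_grads(handle, image, class, layer)
  d <- dim(g$grads)
  K <- d[3]
  w <- numeric(K)
  for (k in seq_len(K)) {
    gk <- g$grads[, , k]
    fk <- g$maps[, , k]
    denom <- 2 * gk^2 + sum(fk) * gk^3
    alpha <- ifelse(denom == 0, 0, gk^2 / denom)
    w[k] <- sum(alpha * pmax(gk, 0))
  }
  raw <- weighted_map_sum(g$maps, w)
  heatmap_obj(raw, handle$input_size, layer, g$class_index, "gradcam++")
}

#' Score-CAM heatmap
#'
#' Gradient-free variant: each feature map is upsampled to the input size,
#' min-max normalized to `[0, 1]` and used to mask the input image; the
#' class-c logit of the masked input is the map's score, and scores are
#' softmax-normalized across maps to give the weights. A constant
#' activation map is ill-defined under min-max normalization and receives
#' weight zero.
#'
#' @inheritParams gradcam_weights
#' @param batch number of masked forward passes evaluated per chunk (kept
#'   for interface compatibility; evaluation is sequential).
#' @return a `chalk_heatmap`.
#' @export
scorecam_heatmap <- function(handle, image, class = "chalky", layer,
                             batch = 16) {
  i <- layer_index(handle, layer)
  c_idx <- resolve_class(handle, class)
  x <- prepare_input(handle, image)
  fw <- net_forward(handle, x)
  maps <- fw$features[[i]]
  K <- dim(maps)[3]
  scores <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    if (diff(range(maps[, , k])) == 0) next  # constant map: zero weight
    up <- resize_bilinear(maps[, , k], handle$input_size)
    rng <- range(up)
    if (diff(rng) == 0) next
    mask <- (up - rng[1]) / diff(rng)
    masked <- x * array(rep(mask, 3), c(dim(mask), 3L))
    scores[k] <- net_forward(handle, masked)$logits[c_idx + 1]
  }
  w <- numeric(K)
  live <- !is.na(scores)
  if (any(live)) {
    s <- scores[live]
    e <- exp(s - max(s))
    w[live] <- e / sum(e)
  }
  raw <- weighted_map_sum(maps, w)
  heatmap_obj(raw, handle$input_size, layer, c_idx, "scorecam")
}
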