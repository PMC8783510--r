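#' Bilinear resize with corner-aligned sampling
#'
#' Resamples a matrix to a new size by bilinear interpolation. Output sample
#' positions are corner-aligned: output pixel (1, 1) coincides with input
#' pixel (1, 1) and the last output pixel with the last input pixel, so
#' corner values are preserved exactly. This is the interpolation used to
#' upsample class-activation heatmaps to the model input resolution, and the
#' convention is fixed so results are bit-reproducible.
#'
#' @param m numeric matrix.
#' @param out_dim integer vector `c(rows, cols)` of the output size.
#' @return numeric matrix of dimension `out_dim`.
#' @export
#' @examples
#' resize_bilinear(matrix(c(0, 0, 0, 4), 2, 2), c(4, 4))
resize_bilinear <- function(m, out_dim) {
  assert_that(is.matrix(m) && is.numeric(m), "m must be a numeric matrix")
  assert_that(length(out_dim) == 2 && all(out_dim >= 1),
              "out_dim must be two positive integers")
  ho <- as.integer(out_dim[1]); wo <- as.integer(out_dim[2])
  hi <- nrow(m); wi <- ncol(m)
  # source coordinates (1-based, corner aligned); degenerate axes map to 1
  src <- function(n_out, n_in) {
    if (n_out == 1 || n_in == 1) rep(1, n_out)
    else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  ys <- src(ho, hi); xs <- src(wo, wi)
  y0 <- pmin(floor(ys), hi - if (hi > 1) 1 else 0); y1 <- pmin(y0 + 1, hi)
  x0 <- pmin(floor(xs), wi - if (wi > 1) 1 else 0); x1 <- pmin(x0 + 1, wi)
  fy <- ys - y0; fx <- xs - x0
  # outer-product blend of the four neighbor grids
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y1, x0, drop = FALSE]
  m01 <- m[y0, x1, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, ho, wo); wx <- matrix(fx, ho, wo, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m10 * wy * (1 - wx) +
    m01 * (1 - wy) * wx + m11 * wy * wx
}

#' Nearest-neighbour resize
#'
#' Used to bring binary ground-truth masks to the model input resolution
#' without introducing fractional values.
#'
#' @inheritParams resize_bilinear
#' @return matrix of dimension `out_dim`, values drawn from `m`.
#' @export
resize_nearest <- function(m, out_dim) {
  assert_that(is.matrix(m), "m must be a matrix")
  ho <- as.integer(out_dim[1]); wo <- as.integer(out_dim[2])
  yi <- pmin(pmax(round((seq_len(ho) - 0.5) * nrow(m) / ho + 0.5), 1), nrow(m))
  xi <- pmin(pmax(round((seq_len(wo) - 0.5) * ncol(m) / wo + 0.5), 1), ncol(m))
  m[yi, xi, drop = FALSE]
}
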