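# Plate-to-grain cropping: grayscale conversion, Canny-style edge detection,
# per-grain bounding boxes, crops, and the grain foreground mask used as the
# denominator of the chalkiness score.

#' Read an image file as a 0-255 RGB array
#'
#' Reads TIFF/JPEG/PNG via EBImage and returns the package's internal
#' representation: a `[H, W, 3]` array indexed `[row = y, col = x]` with
#' values in 0-255. Grayscale files are replicated across channels.
#'
#' @param path image file path.
#' @return numeric array `[H, W, 3]`.
#' @export
read_image <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              class = "chalkcam_io_error")
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- as.array(img) * 255
  if (length(d) == 2) {
    a <- array(rep(t(a), 3), c(d[2], d[1], 3L))
  } else {
    a <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  }
  a
}

#' Write a 0-255 RGB array to an image file
#'
#' @param pixels `[H, W, 3]` array, 0-255.
#' @param path output path; format chosen from the extension.
#' @export
write_image <- function(pixels, path) {
  assert_that(is.array(pixels) && length(dim(pixels)) == 3,
              "pixels must be an [H, W, 3] array")
  img <- EBImage::Image(aperm(pixels, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Convert an RGB raster to grayscale
#'
#' Standard Rec. 601 luminance weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param image `[H, W, 3]` array or a `grain_image`.
#' @return numeric matrix `[H, W]`.
#' @export
to_grayscale <- function(image) {
  if (inherits(image, "grain_image")) image <- image$pixels
  assert_that(is.array(image) && length(dim(image)) == 3 &&
                dim(image)[3] == 3,
              "image must have exactly 3 channels")
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (!is.matrix(g)) g <- matrix(g, dim(image)[1], dim(image)[2])
  g
}

#' Detect per-grain bounding boxes in a plate scan
#'
#' Canny-style detection: Gaussian smoothing, Sobel gradient magnitude,
#' two-level hysteresis thresholding (weak edges kept only when connected to
#' a strong edge), morphological closing so broken contours label as one
#' component, and one bounding box per connected component of sufficient
#' area. The two thresholds default to 0.67 and 1.33 times the median gray
#' value of the image and can be overridden.
#'
#' @param gray single-channel numeric matrix (0-255).
#' @param sigma Gaussian smoothing radius in pixels.
#' @param low,high hysteresis thresholds on gradient magnitude; `NULL` means
#'   auto (0.67 / 1.33 x median gray value).
#' @param min_area minimum component area (pixels) for a box to be kept;
#'   default 200 suits 800 dpi-equivalent scans.
#' @param close_iter iterations of 3x3 morphological closing.
#' @return data.frame with columns `x0, y0, x1, y1` (0-based, half-open),
#'   sorted top-to-bottom then left-to-right; zero rows for a blank image.
#' @export
detect_grain_boxes <- function(gray, sigma = 1.4, low = NULL, high = NULL,
                               min_area = 200, close_iter = 2) {
  assert_that(is.matrix(gray) && is.numeric(gray),
              "gray must be a single-channel numeric matrix")
  med <- median(gray)
  if (is.null(low)) low <- 0.67 * med
  if (is.null(high)) high <- 1.33 * med
  gs <- as.matrix(EBImage::gblur(gray, sigma = sigma,
                                 boundary = "replicate"))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(gs, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(gs, t(kx), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  weak <- mag >= low
  if (!any(weak)) return(empty_boxes())
  lab <- EBImage::bwlabel(weak)
  strong_labels <- unique(lab[mag >= high & lab > 0])
  if (length(strong_labels) == 0) return(empty_boxes())
  edges <- matrix(lab %in% strong_labels, nrow(gray), ncol(gray))
  brush <- EBImage::makeBrush(3, "box")
  for (i in seq_len(close_iter)) edges <- EBImage::closing(edges, brush)
  lab2 <- EBImage::bwlabel(edges)
  n <- max(lab2)
  if (n == 0) return(empty_boxes())
  boxes <- lapply(seq_len(n), function(l) {
    w <- which(lab2 == l, arr.ind = TRUE)
    if (nrow(w) < min_area) return(NULL)
    refine_box(gray, min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
  })
  boxes <- do.call(rbind, boxes)
  if (is.null(boxes)) return(empty_boxes())
  boxes <- boxes[order(boxes$y0, boxes$x0), , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

# Edge contours (smoothed, closed) overshoot the grain outline by a few
# pixels; tighten each candidate box to the Otsu foreground it contains so
# boxes enclose the grain foreground, not its halo.
refine_box <- function(gray, r0, r1, c0, c1) {
  loose <- data.frame(x0 = c0 - 1L, y0 = r0 - 1L, x1 = c1, y1 = r1)
  sub <- gray[r0:r1, c0:c1, drop = FALSE]
  rng <- diff(range(sub))
  if (rng < 1) return(loose)
  thr <- EBImage::otsu(sub / 255) * 255
  fg <- sub > thr
  if (!any(fg)) return(loose)
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  fg <- lab == which.max(areas)
  rr <- range(which(rowSums(fg) > 0))
  cc <- range(which(colSums(fg) > 0))
  data.frame(x0 = c0 + cc[1] - 2L, y0 = r0 + rr[1] - 2L,
             x1 = c0 + cc[2] - 1L, y1 = r0 + rr[2] - 1L)
}

empty_boxes <- function() {
  data.frame(x0 = integer(0), y0 = integer(0),
             x1 = integer(0), y1 = integer(0))
}

#' Crop individual grains from a plate image
#'
#' Crops the regions of interest defined by `boxes`, optionally padded.
#' Boxes touching the plate border count as truncated grains and are
#' dropped when `exclude_truncated` is `TRUE` (truncated grains cannot be
#' phenotyped reliably). Crop identifiers are deterministic:
#' `<plate>_<y0>_<x0>` of the unpadded box.
#'
#' @param image `[H, W, 3]` plate array.
#' @param boxes data.frame from [detect_grain_boxes()] (0-based half-open).
#' @param exclude_truncated drop boxes that touch the image border.
#' @param pad pixels of padding added on each side (clipped to the image).
#' @param plate_id identifier used in crop ids.
#' @return list of `grain_image` objects; attribute `n_truncated` counts
#'   the dropped truncated grains.
#' @export
crop_grains <- function(image, boxes, exclude_truncated = TRUE, pad = 0,
                        plate_id = "plate") {
  assert_that(is.array(image) && length(dim(image)) == 3,
              "image must be an [H, W, 3] array")
  H <- dim(image)[1]; W <- dim(image)[2]
  assert_that(is.data.frame(boxes) &&
                all(c("x0", "y0", "x1", "y1") %in% names(boxes)),
              "boxes must have columns x0, y0, x1, y1")
  if (nrow(boxes) > 0)
    assert_that(all(boxes$x1 > boxes$x0) && all(boxes$y1 > boxes$y0),
                "boxes must satisfy x1 > x0 and y1 > y0")
  out <- list(); n_trunc <- 0L
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    truncated <- b$x0 <= 0 || b$y0 <= 0 || b$x1 >= W || b$y1 >= H
    if (truncated && exclude_truncated) {
      n_trunc <- n_trunc + 1L
      next
    }
    x0 <- max(b$x0 - pad, 0); y0 <- max(b$y0 - pad, 0)
    x1 <- min(b$x1 + pad, W); y1 <- min(b$y1 + pad, H)
    out[[length(out) + 1]] <- structure(
      list(pixels = image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE],
           source_plate = plate_id,
           box = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
           truncated = truncated,
           id = sprintf("%s_%04d_%04d", plate_id, b$y0, b$x0)),
      class = "grain_image")
  }
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Grain foreground mask of a cropped grain image
#'
#' Foreground via Otsu thresholding of the grayscale crop, keeping the
#' largest connected component with holes filled — a robust parameter-free
#' default for high-contrast scans. `Z` is the grain-area pixel count used
#' as the denominator of the chalkiness score.
#'
#' @param grain a `grain_image` or `[H, W, 3]` array.
#' @return list of class `grain_mask` with `mask` (logical matrix) and `Z`.
#' @export
grain_area_mask <- function(grain) {
  g <- to_grayscale(grain)
  rng <- diff(range(g))
  if (rng < 1) {
    # (near-)uniform crop: all-bright counts as all grain, all-dark has none
    if (mean(g) >= 64) {
      mask <- matrix(TRUE, nrow(g), ncol(g))
      return(structure(list(mask = mask, Z = length(mask)),
                       class = "grain_mask"))
    }
    ck_stop("crop contains no foreground (all background)",
            class = "chalkcam_empty_mask_error")
  }
  thr <- EBImage::otsu(g / 255) * 255
  fg <- g > thr
  if (!any(fg))
    ck_stop("crop contains no foreground (all background)",
            class = "chalkcam_empty_mask_error")
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  mask <- lab == which.max(areas)
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  structure(list(mask = mask, Z = sum(mask)), class = "grain_mask")
}
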