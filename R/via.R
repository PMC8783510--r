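# VGG Image Annotator (VIA) polygon annotations and rasterization.
#
# Chalk-area ground truth is exchanged as VIA v2 JSON: a dict keyed by
# "<filename>-<size>", each entry holding `filename`, `size` and a list of
# `regions` whose `shape_attributes` carry `all_points_x` / `all_points_y`
# for polygons. v1-style exports (a plain list of entries) are tolerated by
# key sniffing. Polygons are ordered (x, y) vertex matrices in pixel
# coordinates.

#' Read polygon annotations from a VIA JSON file
#'
#' Parses polygon regions; regions of any other shape (rect, circle, ...)
#' are skipped with a warning. Images with zero polygon regions yield an
#' annotation with an empty polygon list.
#'
#' @param path VIA v2 project/export JSON (v1 region lists tolerated).
#' @return list of `polygon_annotation` objects: `image_id` plus
#'   `polygons`, a list of n x 2 matrices with columns `x`, `y`.
#' @export
read_via_annotations <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              class = "chalkcam_io_error")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    ck_stop(sprintf("malformed VIA JSON in '%s': %s",
                                    path, conditionMessage(e)),
                            class = "chalkcam_parse_error"))
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  lapply(unname(doc), function(entry) {
    polys <- list()
    for (reg in entry$regions) {
      sa <- reg$shape_attributes
      if (is.null(sa$name) || sa$name != "polygon") {
        warning(sprintf("skipping non-polygon region (shape '%s') in '%s'",
                        if (is.null(sa$name)) "?" else sa$name,
                        entry$filename), call. = FALSE)
        next
      }
      polys[[length(polys) + 1]] <-
        cbind(x = unlist(sa$all_points_x), y = unlist(sa$all_points_y))
    }
    structure(list(image_id = entry$filename, polygons = polys),
              class = "polygon_annotation")
  })
}

#' Write polygon annotations as VIA v2 JSON
#'
#' @param annotations list of entries with `image_id` and `polygons`
#'   (n x 2 matrices, columns x then y).
#' @param path output file.
#' @export
write_via_annotations <- function(annotations, path) {
  entries <- list()
  for (a in annotations) {
    regions <- lapply(a$polygons, function(p) {
      list(shape_attributes = list(name = "polygon",
                                   all_points_x = as.numeric(p[, 1]),
                                   all_points_y = as.numeric(p[, 2])),
           region_attributes = list(label = "chalky"))
    })
    entries[[paste0(a$image_id, "--1")]] <-
      list(filename = a$image_id, size = -1L, regions = regions,
           file_attributes = list())
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel `(row i, col j)` (0-based) is set iff its center
#' `(x = j + 0.5, y = i + 0.5)` lies inside the polygon under the even-odd
#' rule; geometry outside the image is effectively clipped because only
#' in-image pixel centers are tested.
#'
#' @param polygon n x 2 matrix of vertices (x, y), n >= 3.
#' @param dims `c(H, W)` of the output mask.
#' @return logical `H x W` matrix.
#' @export
rasterize_polygon <- function(polygon, dims) {
  polygon <- as.matrix(polygon)
  assert_that(is.numeric(polygon) && ncol(polygon) == 2 &&
                nrow(polygon) >= 3,
              "polygon must be an n x 2 vertex matrix with n >= 3")
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  px <- rep(seq_len(W) - 0.5, each = H)   # column-major pixel centers
  py <- rep(seq_len(H) - 0.5, times = W)
  inside <- rep(FALSE, H * W)
  n <- nrow(polygon)
  xv <- polygon[, 1]; yv <- polygon[, 2]
  j <- n
  for (i in seq_len(n)) {
    # edge (j -> i): toggle points whose horizontal ray crosses it
    crosses <- ((yv[i] > py) != (yv[j] > py))
    if (any(crosses)) {
      xint <- xv[i] + (py[crosses] - yv[i]) * (xv[j] - xv[i]) /
        (yv[j] - yv[i])
      hit <- crosses
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
    j <- i
  }
  matrix(inside, H, W)
}

#' Trace a binary mask outline as a polygon
#'
#' Marching-squares contour of the mask at level 0.5, decimated to at most
#' `max_vertices` vertices — the synthetic stand-in for a manually clicked
#' annotation polygon. The largest contour is returned.
#'
#' @param mask logical matrix.
#' @param max_vertices maximum number of polygon vertices.
#' @return n x 2 matrix of (x, y) vertices in pixel coordinates, or `NULL`
#'   for an empty mask.
#' @export
mask_to_polygon <- function(mask, max_vertices = 100) {
  if (!any(mask)) return(NULL)
  H <- nrow(mask); W <- ncol(mask)
  # pad so contours of blobs touching the mask edge still close
  z <- matrix(0, H + 2, W + 2)
  z[2:(H + 1), 2:(W + 1)] <- mask * 1
  # contourLines expects z[i, j] at (x[i], y[j]); our rows are y, so pass t()
  cl <- contourLines(x = seq_len(W + 2) - 1.5, y = seq_len(H + 2) - 1.5,
                     z = t(z), levels = 0.5)
  if (length(cl) == 0) return(NULL)
  lens <- vapply(cl, function(c_) length(c_$x), 0)
  best <- cl[[which.max(lens)]]
  poly <- cbind(x = best$x, y = best$y)
  if (nrow(poly) > max_vertices) {
    keep <- unique(round(seq(1, nrow(poly), length.out = max_vertices)))
    poly <- poly[keep, , drop = FALSE]
  }
  poly
}
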