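# Synthetic grain/plate generator.
#
# Emulates the statistical structure the pipeline assumes: elliptical grains
# at a bright gray level on a near-black background, optionally carrying one
# soft-boundary chalk blob (a blurred bright elliptical patch), arranged on
# plates without touching. Every generated object carries exact ground truth
# (grain mask, chalk mask, chalk polygon, bounding box), so the cropper, the
# classifier, the CAM engine and the evaluation metrics are all testable
# without real scans.
#
# Conventions used throughout the package: rasters are numeric matrices or
# arrays indexed [row = y, col = x]; RGB images are [H, W, 3] arrays with
# values in 0..255; bounding boxes are 0-based, half-open [x0,x1) x [y0,y1).

#' Specification of one synthetic grain
#'
#' @param grain_axes pixel lengths (major, minor) of the grain ellipse.
#' @param grain_intensity mean foreground gray level (0-255). Kept at >= 120
#'   against a background of ~10 so edge detection is well-posed.
#' @param chalk_present logical; does the grain carry a chalk blob?
#' @param chalk_fraction target fraction of grain area covered by the chalk
#'   blob, in `[0, 1)`; must be 0 when `chalk_present` is `FALSE`.
#' @param chalk_peak peak added brightness of the chalk blob.
#' @param blur_sigma pixels of Gaussian smoothing giving the chalk its soft
#'   boundary.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param rng_seed integer seed making the grain reproducible.
#' @return an object of class `grain_spec`.
#' @export
grain_spec <- function(grain_axes = c(80, 40), grain_intensity = 140,
                       chalk_present = FALSE, chalk_fraction = 0,
                       chalk_peak = 60, blur_sigma = 2, noise_sd = 3,
                       rng_seed = 1L) {
  assert_that(length(grain_axes) == 2 && all(grain_axes > 0),
              "grain_axes must be two positive lengths")
  assert_that(is_number(grain_intensity) && grain_intensity > 0 &&
                grain_intensity <= 255, "grain_intensity must be in (0, 255]")
  assert_that(isTRUE(chalk_present) || isFALSE(chalk_present),
              "chalk_present must be TRUE or FALSE")
  assert_that(is_number(chalk_fraction) && chalk_fraction >= 0 &&
                chalk_fraction < 1, "chalk_fraction must be in [0, 1)")
  if (!chalk_present)
    assert_that(chalk_fraction == 0,
                "chalk_fraction must be 0 when chalk_present is FALSE")
  assert_that(is_number(chalk_peak) && chalk_peak > 0,
              "chalk_peak must be positive")
  assert_that(is_number(blur_sigma) && blur_sigma > 0,
              "blur_sigma must be positive")
  assert_that(is_number(noise_sd) && noise_sd >= 0,
              "noise_sd must be non-negative")
  structure(list(grain_axes = as.numeric(grain_axes),
                 grain_intensity = grain_intensity,
                 chalk_present = chalk_present,
                 chalk_fraction = chalk_fraction,
                 chalk_peak = chalk_peak, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "grain_spec")
}

#' Layout of a synthetic plate
#'
#' @param plate_size pixels `c(H, W)` of the plate scan.
#' @param n_grains number of grains per plate (plates typically hold 25-30).
#' @param min_gap minimum pixel gap between grain bounding boxes.
#' @param allow_border_truncation logical; when `TRUE` the first grain is
#'   deliberately placed straddling the plate border, to exercise the
#'   truncation-exclusion policy of the cropper.
#' @param rng_seed integer seed for grain placement and plate noise.
#' @return an object of class `plate_layout`.
#' @export
plate_layout <- function(plate_size = c(1200, 1200), n_grains = 25,
                         min_gap = 12, allow_border_truncation = FALSE,
                         rng_seed = 1L) {
  assert_that(length(plate_size) == 2 && all(plate_size >= 64),
              "plate_size must be two dimensions >= 64")
  assert_that(is_count(n_grains), "n_grains must be a non-negative count")
  assert_that(is_number(min_gap) && min_gap >= 1, "min_gap must be >= 1")
  structure(list(plate_size = as.integer(plate_size),
                 n_grains = as.integer(n_grains),
                 min_gap = as.integer(min_gap),
                 allow_border_truncation = isTRUE(allow_border_truncation),
                 rng_seed = as.integer(rng_seed)),
            class = "plate_layout")
}

# background gray level of synthetic scans
SYNTH_BACKGROUND <- 10

# Render one grain tile (grayscale, no noise). The chalk blob is an ellipse
# similar to the grain outline scaled by sqrt(chalk_fraction) so large blobs
# still fit inside the grain; its binary support is defined at half of the
# blurred peak, which gives an unambiguous ground truth for a soft-boundary
# object.
render_grain <- function(spec) {
  a <- spec$grain_axes[1] / 2  # semi-major (x)
  b <- spec$grain_axes[2] / 2  # semi-minor (y)
  margin <- ceiling(3 * spec$blur_sigma + 4)
  H <- ceiling(2 * b) + 2 * margin
  W <- ceiling(2 * a) + 2 * margin
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  grain_mask <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
  img <- matrix(SYNTH_BACKGROUND, H, W)
  img[grain_mask] <- spec$grain_intensity
  chalk_mask <- matrix(FALSE, H, W)
  if (spec$chalk_present && spec$chalk_fraction > 0) {
    s <- sqrt(spec$chalk_fraction)       # blob is the grain ellipse scaled by s
    ra <- s * a; rb <- s * b
    # blob center uniform in the grain shrunk so the blob stays inside
    shrink <- 1 - s
    theta <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
    bx <- cx + rho * cos(theta) * a * shrink * 0.9
    by <- cy + rho * sin(theta) * b * shrink * 0.9
    blob <- ((xx - bx) / ra)^2 + ((yy - by) / rb)^2 <= 1
    bright <- EBImage::gblur(blob * spec$chalk_peak, sigma = spec$blur_sigma)
    bright <- as.matrix(bright)
    img <- img + bright * grain_mask
    chalk_mask <- (bright >= spec$chalk_peak / 2) & grain_mask
  }
  list(image = img, grain_mask = grain_mask, chalk_mask = chalk_mask)
}

#' Generate one synthetic grain image with ground truth
#'
#' Renders an elliptical grain on a near-black background; when
#' `spec$chalk_present`, a Gaussian-blurred bright blob is added inside the
#' grain and its half-peak support becomes the binary chalk ground truth.
#' Identical spec (including seed) yields identical output.
#'
#' @param spec a [grain_spec()].
#' @return a list with elements `image` (a `grain_image`: RGB array
#'   `[H, W, 3]`, 0-255) and `truth` (a `grain_truth` with `label`,
#'   `grain_mask`, `chalk_mask`, `chalk_polygon`).
#' @export
generate_grain <- function(spec) {
  assert_that(inherits(spec, "grain_spec"), "spec must be a grain_spec")
  with_seed_(spec$rng_seed, {
    r <- render_grain(spec)
    img <- r$image
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    img <- round(clip01(img))
    chalky <- spec$chalk_present && any(r$chalk_mask)
    poly <- if (chalky) mask_to_polygon(r$chalk_mask) else NULL
    list(
      image = structure(
        list(pixels = array(img, c(dim(img), 3L)),
             source_plate = NA_character_,
             box = c(x0 = 0L, y0 = 0L, x1 = ncol(img), y1 = nrow(img)),
             truncated = FALSE,
             id = sprintf("grain_seed%d", spec$rng_seed)),
        class = "grain_image"),
      truth = structure(
        list(label = if (chalky) "chalky" else "non-chalky",
             grain_mask = r$grain_mask,
             chalk_mask = r$chalk_mask,
             chalk_polygon = poly),
        class = "grain_truth")
    )
  })
}

#' Sample a set of grain specifications
#'
#' Draws grain geometry and intensity from ranges typical of 800-dpi rice
#' scans at desk scale; half the grains are chalky by default, with chalk
#' fractions uniform in 0.2-0.5.
#'
#' @param n number of specs.
#' @param p_chalky probability a grain is chalky.
#' @param chalk_fraction_range range the chalk fraction is drawn from.
#' @param seed master seed; per-grain seeds are derived from it.
#' @return list of [grain_spec()] objects.
#' @export
sample_grain_specs <- function(n, p_chalky = 0.5,
                               chalk_fraction_range = c(0.2, 0.5),
                               seed = 1L) {
  assert_that(is_count(n), "n must be a count")
  with_seed_(seed, {
    seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      chalky <- runif(1) < p_chalky
      grain_spec(
        grain_axes = c(runif(1, 70, 90), runif(1, 36, 46)),
        grain_intensity = runif(1, 130, 150),
        chalk_present = chalky,
        chalk_fraction = if (chalky)
          runif(1, chalk_fraction_range[1], chalk_fraction_range[2]) else 0,
        chalk_peak = runif(1, 50, 70),
        blur_sigma = 2, noise_sd = 3, rng_seed = seeds[i])
    })
  })
}

#' Generate a synthetic plate scan
#'
#' Places the rendered grains at random positions such that their tight
#' bounding boxes are separated by at least `layout$min_gap` pixels and do
#' not touch the plate border; when `layout$allow_border_truncation` is
#' `TRUE`, the first grain is placed straddling the border instead. Returned
#' boxes exactly enclose each grain's foreground.
#'
#' @param layout a [plate_layout()]; `layout$n_grains` must equal
#'   `length(grain_specs)`.
#' @param grain_specs list of [grain_spec()].
#' @param max_tries placement retries per grain before a capacity error.
#' @return list with `image` (RGB plate array) and `grains`, a list of
#'   entries `box` (0-based half-open, clipped to the plate), `truth`
#'   (a `grain_truth` in plate-local crop coordinates) and `truncated`.
#' @export
generate_plate <- function(layout, grain_specs, max_tries = 300) {
  assert_that(inherits(layout, "plate_layout"), "layout must be a plate_layout")
  assert_that(length(grain_specs) == layout$n_grains,
              "length(grain_specs) must equal layout$n_grains")
  H <- layout$plate_size[1]; W <- layout$plate_size[2]
  plate <- matrix(SYNTH_BACKGROUND, H, W)
  grains <- list()
  if (layout$n_grains == 0) {
    return(list(image = array(round(plate), c(H, W, 3L)), grains = grains))
  }
  with_seed_(layout$rng_seed, {
    tiles <- lapply(grain_specs, function(s) with_seed_(s$rng_seed,
                                                        render_grain(s)))
    placed <- matrix(numeric(0), 0, 4)  # accepted boxes x0,y0,x1,y1 (0-based)
    gap <- layout$min_gap
    for (i in seq_along(tiles)) {
      t_i <- tiles[[i]]
      rr <- range(which(rowSums(t_i$grain_mask) > 0))
      cc <- range(which(colSums(t_i$grain_mask) > 0))
      th <- rr[2] - rr[1] + 1; tw <- cc[2] - cc[1] + 1
      ok <- FALSE
      if (layout$allow_border_truncation && i == 1) {
        # straddle the left border: clip about 40% of the tile width
        cut <- max(1, floor(tw * 0.4))
        y0 <- floor(runif(1, 2, H - th - 2))
        box <- c(0, y0, tw - cut, y0 + th)
        ok <- TRUE
        src_cols <- (cc[1] + cut):cc[2]
        src_rows <- rr[1]:rr[2]
        dst_rows <- (y0 + 1):(y0 + th)
        dst_cols <- 1:(tw - cut)
        truncated <- TRUE
      } else {
        for (try in seq_len(max_tries)) {
          x0 <- floor(runif(1, 2, W - tw - 2))
          y0 <- floor(runif(1, 2, H - th - 2))
          box <- c(x0, y0, x0 + tw, y0 + th)
          if (nrow(placed) == 0 ||
              all(box[1] >= placed[, 3] + gap | placed[, 1] >= box[3] + gap |
                  box[2] >= placed[, 4] + gap | placed[, 2] >= box[4] + gap)) {
            ok <- TRUE; break
          }
        }
        if (!ok)
          ck_stop(sprintf(
            "could not place grain %d after %d tries; plate too crowded",
            i, max_tries), class = "chalkcam_capacity_error")
        src_rows <- rr[1]:rr[2]; src_cols <- cc[1]:cc[2]
        dst_rows <- (box[2] + 1):box[4]; dst_cols <- (box[1] + 1):box[3]
        truncated <- FALSE
      }
      sub_mask <- t_i$grain_mask[src_rows, src_cols, drop = FALSE]
      sub_img <- t_i$image[src_rows, src_cols, drop = FALSE]
      sub_chalk <- t_i$chalk_mask[src_rows, src_cols, drop = FALSE]
      tgt <- plate[dst_rows, dst_cols, drop = FALSE]
      tgt[sub_mask] <- sub_img[sub_mask]
      plate[dst_rows, dst_cols] <- tgt
      placed <- rbind(placed, box)
      chalky <- any(sub_chalk)
      grains[[i]] <- list(
        box = c(x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4]),
        truth = structure(list(
          label = if (chalky) "chalky" else "non-chalky",
          grain_mask = sub_mask, chalk_mask = sub_chalk,
          chalk_polygon = if (chalky) mask_to_polygon(sub_chalk) else NULL),
          class = "grain_truth"),
        truncated = truncated)
    }
    noise_sd <- mean(vapply(grain_specs, `[[`, numeric(1), "noise_sd"))
    if (noise_sd > 0)
      plate <- plate + matrix(rnorm(length(plate), 0, noise_sd), H, W)
    plate <- round(clip01(plate))
    list(image = array(plate, c(H, W, 3L)), grains = grains)
  })
}

#' Generate a synthetic chalkiness dataset on disk
#'
#' Renders `n_plates` plates, crops every (non-truncated) grain using its
#' ground-truth box, writes per-grain PNG crops, a CSV manifest and a VIA v2
#' JSON annotation file holding the chalk polygons of chalky grains (in crop
#' coordinates). Grains are split into train/dev/test sets at `split_ratio`;
#' no grain appears in two splits.
#'
#' @param n_plates number of plates.
#' @param layout [plate_layout()] used for every plate (its seed is
#'   re-derived per plate from `seed`).
#' @param split_ratio length-3 ratio summing to 1 (train, dev, test).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; plate and grain seeds are derived from it.
#' @param p_chalky,chalk_fraction_range passed to [sample_grain_specs()].
#' @return invisibly, a list with `manifest` (data.frame: path, label,
#'   split, plate, box_x0..box_y1), `truths` (per-grain `grain_truth` list,
#'   same order), `manifest_path`, `via_path`.
#' @export
generate_dataset <- function(n_plates, layout = plate_layout(),
                             split_ratio = c(0.5, 0.25, 0.25),
                             out_dir, seed = 1L, p_chalky = 0.5,
                             chalk_fraction_range = c(0.2, 0.5)) {
  assert_that(is_count(n_plates) && n_plates > 0, "n_plates must be a count")
  assert_that(length(split_ratio) == 3 && abs(sum(split_ratio) - 1) < 1e-8,
              "split_ratio must be three fractions summing to 1")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) ck_stop(sprintf("cannot create out_dir '%s'", out_dir),
                     class = "chalkcam_io_error")
  }
  crop_dir <- file.path(out_dir, "crops")
  dir.create(crop_dir, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 2 * n_plates)
  rows <- list(); truths <- list(); annos <- list()
  k <- 0
  for (p in seq_len(n_plates)) {
    lay <- layout
    lay$rng_seed <- seeds[2 * p - 1]
    specs <- sample_grain_specs(lay$n_grains, p_chalky = p_chalky,
                                chalk_fraction_range = chalk_fraction_range,
                                seed = seeds[2 * p])
    pl <- generate_plate(lay, specs)
    plate_id <- sprintf("plate%03d", p)
    for (g in pl$grains) {
      if (g$truncated) next
      k <- k + 1
      b <- g$box
      crop <- pl$image[(b["y0"] + 1):b["y1"], (b["x0"] + 1):b["x1"], ,
                       drop = FALSE]
      fname <- sprintf("%s_%04d_%04d.png", plate_id, b["y0"], b["x0"])
      path <- file.path(crop_dir, fname)
      write_image(crop, path)
      rows[[k]] <- data.frame(
        path = file.path("crops", fname), label = g$truth$label,
        split = NA_character_, plate = plate_id,
        box_x0 = b[["x0"]], box_y0 = b[["y0"]],
        box_x1 = b[["x1"]], box_y1 = b[["y1"]],
        stringsAsFactors = FALSE)
      truths[[k]] <- g$truth
      if (g$truth$label == "chalky")
        annos[[length(annos) + 1]] <- list(
          image_id = fname,
          polygons = list(g$truth$chalk_polygon))
    }
  }
  manifest <- do.call(rbind, rows)
  # disjoint split assignment: shuffled indices cut at the ratio boundaries
  n <- nrow(manifest)
  idx <- with_seed_(seed + 1L, sample.int(n))
  n_train <- round(split_ratio[1] * n)
  n_dev <- round(split_ratio[2] * n)
  split <- rep("test", n)
  split[idx[seq_len(n_train)]] <- "train"
  split[idx[n_train + seq_len(min(n_dev, n - n_train))]] <- "dev"
  manifest$split <- split
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  via_path <- file.path(out_dir, "annotations.json")
  write_via_annotations(annos, via_path)
  invisible(list(manifest = manifest, truths = truths,
                 manifest_path = manifest_path, via_path = via_path))
}
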