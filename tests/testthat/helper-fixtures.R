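# Shared fixtures, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_image <- function(h = 64, w = 64, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), c(h, w, 3)))
}

# independent oracle for Grad-CAM weights: central finite differences of the
# class logit along the all-ones direction of each feature map, which equals
# the spatial sum of the per-pixel gradients (and /N gives their average)
fd_gradcam_weights <- function(handle, image, layer, class_index = 1,
                               eps = 1e-3) {
  li <- match(layer, handle$layer_names)
  fw <- chalkcam:::net_forward(handle,
                               chalkcam:::prepare_input(handle, image))
  f <- fw$features[[li]]
  N <- prod(dim(f)[1:2])
  vapply(seq_len(dim(f)[3]), function(k) {
    fp <- f; fp[, , k] <- fp[, , k] + eps
    fm <- f; fm[, , k] <- fm[, , k] - eps
    zp <- chalkcam:::forward_from_layer(handle, li, fp)[class_index + 1]
    zm <- chalkcam:::forward_from_layer(handle, li, fm)[class_index + 1]
    (zp - zm) / (2 * eps) / N
  }, 0)
}

# brute-force even-odd point-in-polygon test for a single point
point_in_polygon_eo <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xint <- poly[i, 1] + (py - poly[i, 2]) * (poly[j, 1] - poly[i, 1]) /
        (poly[j, 2] - poly[i, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# random simple (star-shaped) polygon: sorted angles, random radii
random_simple_polygon <- function(n_vertices, cx, cy, r_max) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.2 * r_max, r_max)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# small in-memory synthetic grain set as a training manifest
small_grain_manifest <- function(n = 80, seed = 11,
                                 split = c(0.75, 0.25, 0)) {
  specs <- sample_grain_specs(n, seed = seed)
  gs <- lapply(specs, generate_grain)
  labels <- vapply(gs, function(g) g$truth$label, "")
  sp <- withr::with_seed(seed + 1, sample(rep(
    c("train", "dev", "test"),
    c(round(split[1] * n), round(split[2] * n),
      n - round(split[1] * n) - round(split[2] * n)))))
  manifest <- data.frame(label = labels, split = sp)
  manifest$image <- I(lapply(gs, function(g) g$image$pixels))
  attr(manifest, "grains") <- gs
  manifest
}

# one small trained model shared across test files (trains once per run)
.fixture_env <- new.env(parent = emptyenv())

cached_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    manifest <- small_grain_manifest()
    handle <- build_backbone("tiny", input_size = c(32, 32), seed = 7)
    .fixture_env$model <- train_classifier(
      handle, manifest,
      train_config(max_epochs = 10, rng_seed = 7))
    .fixture_env$manifest <- manifest
  }
  list(model = .fixture_env$model, manifest = .fixture_env$manifest)
}
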