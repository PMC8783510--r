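test_that("corner-aligned bilinear upsampling matches the closed form", {
  up <- resize_bilinear(matrix(c(0, 0, 0, 4), 2, 2), c(4, 4))
  # closed form: f(r, c) = 4 * (r-1)/3 * (c-1)/3
  expected <- outer(0:3, 0:3, function(r, c) 4 * (r / 3) * (c / 3))
  expect_equal(up, expected)
  expect_equal(up[4, 4], 4)  # corner preserved exactly
  expect_equal(up[1, 1], 0)
  # identity when sizes match
  m <- matrix(runif(12), 3, 4)
  expect_equal(resize_bilinear(m, c(3, 4)), m)
})

test_that("a feature map summed into the logit has weight 1, unconnected maps 0", {
  h <- build_backbone("tiny", seed = 2)
  # y_chalky = N * GAP(map 1) = sum over map 1; no path from other maps
  h$params$Wh[] <- 0
  h$params$Wh[2, 1] <- 64   # N = 8 x 8 positions in block3
  w <- gradcam_weights(h, rand_image(seed = 4), "chalky", "block3")$w
  expect_equal(w[1], 1, tolerance = 1e-12)
  expect_equal(w[-1], rep(0, 31))
})

test_that("Grad-CAM weights equal finite-difference gradient averages", {
  h <- build_backbone("tiny", seed = 5)
  img <- rand_image(seed = 6)
  for (layer in h$layer_names) {
    w <- gradcam_weights(h, img, "chalky", layer)$w
    fd <- fd_gradcam_weights(h, img, layer, class_index = 1)
    expect_lte(max(abs(w - fd)), 1e-3)
  }
  expect_error(gradcam_weights(h, img, "chalky", "block9"),
               class = "chalkcam_config_error")
})

test_that("an everywhere-negative weighted sum yields an all-zero heatmap", {
  h <- build_backbone("tiny", seed = 3)
  h$params$Wh[2, ] <- -1   # every gradient path negative
  h$params$bh[] <- 0
  hm <- gradcam_heatmap(h, rand_image(seed = 7), "chalky", "block3")
  expect_true(all(hm$raw == 0))
  expect_true(all(hm$final == 0))
})

test_that("scaling the logits scales the Grad-CAM heatmap exactly", {
  h <- build_backbone("tiny", seed = 8)
  img <- rand_image(seed = 9)
  hm1 <- gradcam_heatmap(h, img, "chalky", "block2")
  h2 <- h
  h2$params$Wh <- 2 * h$params$Wh
  h2$params$bh <- 2 * h$params$bh
  hm2 <- gradcam_heatmap(h2, img, "chalky", "block2")
  expect_equal(hm2$raw, 2 * hm1$raw, tolerance = 1e-12)
})

test_that("Grad-CAM++ reduces to the feature map on a single-map toy", {
  h <- build_backbone("tiny", channels = c(4, 4, 1), seed = 10)
  h$params$Wh[] <- 0
  h$params$Wh[2, 1] <- 1   # uniform positive gradients on the single map
  img <- rand_image(seed = 11)
  hpp <- gradcampp_heatmap(h, img, "chalky", "block3")
  f <- feature_maps(h, img, "block3")$maps[, , 1]
  expect_gt(max(hpp$raw), 0)
  expect_equal(hpp$raw / max(hpp$raw), f / max(f), tolerance = 1e-9)
  hg <- gradcam_heatmap(h, img, "chalky", "block3")
  expect_equal(which.max(hpp$raw), which.max(hg$raw))
})

test_that("zero gradients give zero heatmaps for both gradient methods", {
  h <- build_backbone("tiny", seed = 12)
  h$params$Wh[2, ] <- 0   # chalky logit disconnected
  img <- rand_image(seed = 13)
  expect_true(all(gradcam_heatmap(h, img, "chalky", "block2")$final == 0))
  expect_true(all(gradcampp_heatmap(h, img, "chalky", "block2")$final == 0))
})

test_that("Score-CAM weights are uniform for a constant-logit model and zero for constant maps", {
  h <- build_backbone("tiny", seed = 14)
  h$params$Wh[] <- 0
  h$params$bh <- c(0.3, 0.7)   # model ignores its input
  img <- rand_image(seed = 15)
  hm <- scorecam_heatmap(h, img, "chalky", "block2")
  f <- feature_maps(h, img, "block2")$maps
  K <- dim(f)[3]
  live <- vapply(seq_len(K), function(k) diff(range(f[, , k])) > 0, TRUE)
  expected <- Reduce(`+`, lapply(which(live), function(k) f[, , k])) /
    sum(live)
  expected[expected < 0] <- 0
  expect_equal(hm$raw, expected, tolerance = 1e-9)

  # constant activation maps are ill-posed under min-max: zero weight
  hc <- build_backbone("tiny", seed = 16)
  hc$params$W1[] <- 0
  hc$params$b1[] <- 1   # block1 maps constant
  hmc <- scorecam_heatmap(hc, img, "chalky", "block1")
  expect_true(all(hmc$final == 0))
})

test_that("heatmaps are nonnegative at input resolution for every method and layer", {
  fx <- cached_trained_model()
  h <- fx$model
  grains <- attr(fx$manifest, "grains")
  chalky <- which(vapply(grains, function(g) g$truth$label, "") == "chalky")
  img <- grains[[chalky[1]]]$image
  for (fun in list(gradcam_heatmap, gradcampp_heatmap, scorecam_heatmap)) {
    for (layer in h$layer_names) {
      hm <- fun(h, img, "chalky", layer)
      expect_true(all(hm$final >= 0))
      expect_true(all(hm$raw >= 0))
      expect_equal(dim(hm$final), h$input_size)
    }
  }
})

test_that("Score-CAM localizes the chalk blob on a trained model", {
  fx <- cached_trained_model()
  h <- fx$model
  grains <- attr(fx$manifest, "grains")
  chalky <- which(vapply(grains, function(g) g$truth$label, "") == "chalky")
  g <- grains[[chalky[1]]]
  hm <- scorecam_heatmap(h, g$image, "chalky", "block1")
  tm <- resize_nearest(g$truth$chalk_mask, h$input_size)
  dil <- as.matrix(EBImage::dilate(tm * 1, EBImage::makeBrush(9, "box"))) > 0
  am <- which(hm$final == max(hm$final), arr.ind = TRUE)[1, ]
  expect_true(dil[am[1], am[2]])
})
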