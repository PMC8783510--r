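test_that("IoU matches the published worked example and basic identities", {
  # masks engineered to |intersection| = 5167 and |union| = 6370
  u <- matrix(FALSE, 80, 80)
  truth <- u; truth[1:5700] <- TRUE
  pred <- u; pred[534:6370] <- TRUE
  expect_equal(sum(pred & truth), 5167)
  expect_equal(sum(pred | truth), 6370)
  expect_equal(iou(pred, truth), 5167 / 6370)
  expect_equal(round(iou(pred, truth), 4), 0.8111)
  expect_equal(iou(truth, truth), 1)
  expect_equal(iou(pred, truth), iou(truth, pred))  # symmetric
  disj <- u; disj[6000:6300] <- TRUE
  expect_equal(iou(disj, truth), 0)
  expect_error(iou(pred, u), class = "chalkcam_validation_error")
})

test_that("average IoU is the rounded mean in percent", {
  expect_equal(average_iou(1), 100)
  expect_equal(average_iou(c(0.5, 0.7)), 60)
  withr::with_seed(23, {
    x <- runif(166)
    # brute-force summation oracle
    s <- 0; for (v in x) s <- s + v
    expect_equal(average_iou(x), round_half_up(100 * s / 166),
                 tolerance = 1e-9)
  })
  expect_error(average_iou(numeric(0)), class = "chalkcam_validation_error")
})

test_that("localization accuracies reproduce the printed fraction arithmetic", {
  r <- gt_known_loc_acc(c(rep(1, 140), rep(0, 26)))
  expect_equal(r$percent, 84.34)
  expect_equal(r$numerator, 140)
  expect_equal(r$denominator, 166)
  expect_equal(gt_known_loc_acc(rep(1, 10))$percent, 100)
  # inclusive >= 0.5 rule
  r2 <- gt_known_loc_acc(c(0.6, 0.5, 0.49, 0.2))
  expect_equal(r2$numerator, 2)
  expect_equal(r2$percent, 50)

  ious <- c(rep(1, 140), rep(0, 26))
  pred <- c(rep("chalky", 138), rep("non-chalky", 28))
  la <- loc_acc(ious, pred, rep("chalky", 166))
  expect_equal(la$percent, 83.13)
  expect_equal(la$numerator, 138)
  # all labels wrong -> 0 regardless of IoU
  expect_equal(loc_acc(rep(1, 5), rep("non-chalky", 5),
                       rep("chalky", 5))$percent, 0)
  # all labels right -> reduces to GT-known
  expect_equal(loc_acc(ious, rep("chalky", 166), rep("chalky", 166))$percent,
               gt_known_loc_acc(ious)$percent)
})

test_that("localization accuracy never exceeds GT-known accuracy", {
  withr::with_seed(29, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      ious <- runif(n)
      pred <- sample(c("chalky", "non-chalky"), n, replace = TRUE)
      expect_lte(loc_acc(ious, pred, rep("chalky", n))$percent,
                 gt_known_loc_acc(ious)$percent)
    }
  })
})

test_that("the grid search returns a full matrix whose best cell is maximal", {
  fx <- cached_trained_model()
  h <- fx$model
  grains <- attr(fx$manifest, "grains")
  chalky <- which(vapply(grains, function(g) g$truth$label, "") == "chalky")
  sel <- chalky[1:6]
  imgs <- lapply(grains[sel], function(g) g$image)
  masks <- lapply(grains[sel], function(g) g$truth$chalk_mask)
  thresholds <- c(30, 50, 70)
  gr <- grid_search_iou(h, imgs, masks, thresholds = thresholds)
  expect_equal(dim(gr$avg_iou), c(3, 3))
  expect_false(anyNA(gr$avg_iou))
  expect_equal(gr$avg_iou[gr$best_layer, paste0("T", gr$best_T)],
               max(gr$avg_iou))
  # tie-break: first (lowest layer index, lowest T) cell attaining the max
  best <- which(t(gr$avg_iou) == max(gr$avg_iou), arr.ind = TRUE)[1, ]
  expect_equal(gr$best_layer, rownames(gr$avg_iou)[best[2]])
  expect_equal(gr$best_T, thresholds[best[1]])
  # single-cell grid: that cell is best
  g1 <- grid_search_iou(h, imgs, masks, layers = "block1", thresholds = 50)
  expect_equal(g1$best_layer, "block1")
  expect_equal(g1$best_T, 50)
})

test_that("a threshold bracketing the blob half-peak dominates the grid", {
  # grains whose chalk is a sharp half-peak-defined blob: the truth mask is
  # recovered best at an intermediate threshold, not at the extremes
  fx <- cached_trained_model()
  h <- fx$model
  grains <- attr(fx$manifest, "grains")
  chalky <- which(vapply(grains, function(g) g$truth$label, "") == "chalky")
  sel <- chalky[1:8]
  imgs <- lapply(grains[sel], function(g) g$image)
  masks <- lapply(grains[sel], function(g) g$truth$chalk_mask)
  gr <- grid_search_iou(h, imgs, masks, layers = "block1",
                        thresholds = c(5, 95, 50))
  expect_equal(gr$best_T, 50)
})

test_that("group aggregation reports mean, SEM and n per non-empty group", {
  records <- data.frame(
    genotype = c("A", "A", "A", "B"),
    treatment = c("CNT", "CNT", "CNT", "HNT"),
    chalky_score = c(0.1, 0.2, 0.3, 0.5),
    chalk_area_percent = c(10, 20, 30, 50))
  out <- aggregate_by_group(records, c("genotype", "treatment"))
  expect_equal(nrow(out), 2)  # empty combinations never emitted
  a <- out[out$genotype == "A", ]
  expect_equal(a$n, 3)
  expect_equal(a$mean_chalk_area_percent, 20)
  expect_equal(a$sem_chalk_area_percent, 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(round(a$sem_chalk_area_percent, 4), 5.7735)
  b <- out[out$genotype == "B", ]
  expect_equal(b$n, 1)
  expect_true(is.na(b$sem_chalky_score))  # SEM undefined for n = 1
  expect_error(aggregate_by_group(records, "panicle"),
               class = "chalkcam_validation_error")
})
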