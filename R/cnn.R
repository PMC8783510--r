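# Small convolutional classifier with exact backpropagation.
#
# The class-activation engine needs (a) the feature maps of any named
# convolutional block and (b) exact gradients of a chosen logit with respect
# to those maps. Both are provided by this hand-written network: three
# conv(3x3, pad 1) -> ReLU -> maxpool(2x2) blocks (8/16/32 channels by
# default), global average pooling, and a 2-logit linear head. Convolutions
# are evaluated as im2col matrix products with index matrices precomputed
# per layer, which keeps a full forward+backward pass on a 64x64 image in
# the low milliseconds in plain R.
#
# Tensors are [H, W, C] arrays; a "feature stack" of block k is its
# post-pool output (8/16/32 maps at 32/16/8 spatial resolution for 64x64
# input).

make_conv_geom <- function(H, W, Cin) {
  Hp <- H + 2L; Wp <- W + 2L
  r_i <- rep(seq_len(H), times = W)
  r_j <- rep(seq_len(W), each = H)
  off <- expand.grid(di = 0:2, dj = 0:2, ci = seq_len(Cin))
  M <- matrix(0L, H * W, nrow(off))
  for (q in seq_len(nrow(off))) {
    M[, q] <- (r_i + off$di[q]) + (r_j + off$dj[q] - 1L) * Hp +
      (off$ci[q] - 1L) * Hp * Wp
  }
  list(H = H, W = W, Cin = Cin, Hp = Hp, Wp = Wp, M = M)
}

conv_forward <- function(x, geom, W_, b) {
  P <- array(0, c(geom$Hp, geom$Wp, geom$Cin))
  P[2:(geom$Hp - 1), 2:(geom$Wp - 1), ] <- x
  X <- matrix(P[geom$M], nrow(geom$M))
  Z <- X %*% W_
  Z <- Z + rep(b, each = nrow(Z))
  A <- Z
  A[A < 0] <- 0
  list(A = A, X = X, Z = Z)
}

conv_backward <- function(dA, cache, W_, geom, want_param_grads = TRUE) {
  dZ <- dA
  dZ[cache$Z <= 0] <- 0
  dW <- if (want_param_grads) crossprod(cache$X, dZ) else NULL
  db <- if (want_param_grads) colSums(dZ) else NULL
  dXcol <- dZ %*% t(W_)
  dP <- numeric(geom$Hp * geom$Wp * geom$Cin)
  for (q in seq_len(ncol(geom$M))) {
    idx <- geom$M[, q]
    dP[idx] <- dP[idx] + dXcol[, q]
  }
  dPa <- array(dP, c(geom$Hp, geom$Wp, geom$Cin))
  list(dW = dW, db = db,
       dx = dPa[2:(geom$Hp - 1), 2:(geom$Wp - 1), , drop = FALSE])
}

maxpool_forward <- function(A) {
  d <- dim(A); H <- d[1]; W <- d[2]
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, W, 2); ce <- seq(2, W, 2)
  s1 <- A[ro, co, , drop = FALSE]; s2 <- A[re, co, , drop = FALSE]
  s3 <- A[ro, ce, , drop = FALSE]; s4 <- A[re, ce, , drop = FALSE]
  P <- pmax(s1, s2, s3, s4)
  am <- array(4L, dim(P))
  am[P == s3] <- 3L; am[P == s2] <- 2L; am[P == s1] <- 1L  # ties -> lowest
  list(P = P, am = am, in_dim = d)
}

maxpool_backward <- function(dP, cache) {
  d <- cache$in_dim
  dA <- array(0, d)
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  rows <- list(ro, re, ro, re); cols <- list(co, co, ce, ce)
  for (q in 1:4)
    dA[rows[[q]], cols[[q]], ] <- dP * (cache$am == q)
  dA
}

#' Build a chalkiness classification backbone
#'
#' The `"tiny"` backbone is a CPU-trainable network: three blocks of
#' 3x3 convolution (8, 16, 32 channels), ReLU and 2x2 max pooling, followed
#' by global average pooling and a 2-logit head (class 0 = non-chalky,
#' class 1 = chalky). Its three inspectable layers (`block1`..`block3`)
#' expose feature stacks of 32x32x8, 16x16x16 and 8x8x32 for 64x64 input.
#' No pretrained weight sets ship with the package.
#'
#' @param name backbone identifier; only `"tiny"` is available.
#' @param pretrained must be `FALSE`; kept as an explicit argument so the
#'   interface mirrors backbones that do have published weights.
#' @param input_size `c(H, W)` the input image is resized to; both must be
#'   divisible by 8.
#' @param channels channel counts of the three blocks.
#' @param seed seed for weight initialization (He-scaled normal).
#' @return an object of class `chalk_cnn`.
#' @export
build_backbone <- function(name = "tiny", pretrained = FALSE,
                           input_size = c(64, 64), channels = c(8, 16, 32),
                           seed = 0L) {
  if (!identical(name, "tiny"))
    ck_stop(sprintf("unknown backbone '%s' (available: tiny)", name),
            class = "chalkcam_config_error")
  if (isTRUE(pretrained))
    ck_stop("no pretrained weights are available for the tiny backbone",
            class = "chalkcam_config_error")
  assert_that(length(input_size) == 2 && all(input_size %% 8 == 0) &&
                all(input_size >= 16),
              "input_size must be divisible by 8 and >= 16")
  assert_that(length(channels) == 3 && all(channels >= 1),
              "channels must give three positive counts")
  input_size <- as.integer(input_size)
  channels <- as.integer(channels)
  in_ch <- c(3L, channels[1], channels[2])
  H <- input_size[1]; W <- input_size[2]
  geoms <- list()
  for (l in 1:3) {
    geoms[[l]] <- make_conv_geom(H, W, in_ch[l])
    H <- H %/% 2L; W <- W %/% 2L
  }
  params <- with_seed_(seed, {
    p <- list()
    for (l in 1:3) {
      fan_in <- 9 * in_ch[l]
      p[[paste0("W", l)]] <- matrix(rnorm(fan_in * channels[l],
                                          sd = sqrt(2 / fan_in)),
                                    fan_in, channels[l])
      p[[paste0("b", l)]] <- numeric(channels[l])
    }
    p$Wh <- matrix(rnorm(2 * channels[3], sd = sqrt(2 / channels[3])),
                   2, channels[3])
    p$bh <- numeric(2)
    p
  })
  structure(list(backbone_name = name, input_size = input_size,
                 channels = channels,
                 layer_names = paste0("block", 1:3),
                 class_index_map = c("non-chalky" = 0L, "chalky" = 1L),
                 params = params, geoms = geoms,
                 trained = FALSE, log = NULL, config = NULL),
            class = "chalk_cnn")
}

#' @export
print.chalk_cnn <- function(x, ...) {
  cat(sprintf("<chalk_cnn> backbone '%s', input %dx%d, blocks %s, %s\n",
              x$backbone_name, x$input_size[1], x$input_size[2],
              paste(x$channels, collapse = "/"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

layer_index <- function(handle, layer) {
  i <- match(layer, handle$layer_names)
  if (is.na(i))
    ck_stop(sprintf("unknown layer '%s' (available: %s)", layer,
                    paste(handle$layer_names, collapse = ", ")),
            class = "chalkcam_config_error")
  i
}

# resize an RGB array (or grain_image) to the model input size, 0-255
prepare_input <- function(handle, image) {
  if (inherits(image, "grain_image")) image <- image$pixels
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3L))
  assert_that(is.array(image) && length(dim(image)) == 3,
              "image must be an [H, W, 3] array")
  d <- dim(image)
  if (d[1] == handle$input_size[1] && d[2] == handle$input_size[2])
    return(image)
  out <- array(0, c(handle$input_size, 3L))
  for (ch in 1:3)
    out[, , ch] <- resize_bilinear(image[, , ch], handle$input_size)
  out
}

# full forward pass; img is a [H, W, 3] array at input size, 0-255.
# Inputs are centered (x/255 - 0.5): with all-positive inputs the
# first-layer gradients are strongly correlated across filters and SGD
# crawls; centering removes that.
net_forward <- function(handle, img, want_cache = FALSE) {
  x <- img / 255 - 0.5
  feats <- vector("list", 3)
  caches <- if (want_cache) vector("list", 3) else NULL
  p <- handle$params
  for (l in 1:3) {
    cf <- conv_forward(x, handle$geoms[[l]], p[[paste0("W", l)]],
                       p[[paste0("b", l)]])
    A_arr <- array(cf$A, c(handle$geoms[[l]]$H, handle$geoms[[l]]$W,
                           handle$channels[l]))
    pf <- maxpool_forward(A_arr)
    feats[[l]] <- pf$P
    if (want_cache) caches[[l]] <- list(conv = cf, pool = pf)
    x <- pf$P
  }
  hw <- prod(dim(x)[1:2])
  g <- colMeans(matrix(x, hw, handle$channels[3]))
  logits <- as.vector(p$Wh %*% g + p$bh)
  names(logits) <- names(handle$class_index_map)
  list(logits = logits, features = feats, g = g, caches = caches)
}

# backward pass from a gradient on the logits; returns parameter gradients
# (optionally) and gradients w.r.t. each block's post-pool feature stack
net_backward <- function(handle, fw, dlogits, want_param_grads = TRUE) {
  p <- handle$params
  grads <- list()
  if (want_param_grads) {
    grads$Wh <- dlogits %o% fw$g
    grads$bh <- dlogits
  }
  dg <- as.vector(crossprod(p$Wh, dlogits))
  f3 <- fw$features[[3]]
  hw <- prod(dim(f3)[1:2])
  dP <- array(rep(dg / hw, each = hw), dim(f3))
  dfeat <- vector("list", 3)
  dfeat[[3]] <- dP
  for (l in 3:1) {
    dA_arr <- maxpool_backward(dP, fw$caches[[l]]$pool)
    dA <- matrix(dA_arr, ncol = handle$channels[l])
    cb <- conv_backward(dA, fw$caches[[l]]$conv, p[[paste0("W", l)]],
                        handle$geoms[[l]], want_param_grads)
    if (want_param_grads) {
      grads[[paste0("W", l)]] <- cb$dW
      grads[[paste0("b", l)]] <- cb$db
    }
    dP <- cb$dx
    if (l > 1) dfeat[[l - 1]] <- dP
  }
  list(grads = grads, dfeat = dfeat)
}

# forward pass resumed from a (possibly perturbed) feature stack of a layer
forward_from_layer <- function(handle, layer_idx, fmap) {
  p <- handle$params
  x <- fmap
  if (layer_idx < 3) {
    for (l in (layer_idx + 1):3) {
      cf <- conv_forward(x, handle$geoms[[l]], p[[paste0("W", l)]],
                         p[[paste0("b", l)]])
      A_arr <- array(cf$A, c(handle$geoms[[l]]$H, handle$geoms[[l]]$W,
                             handle$channels[l]))
      x <- maxpool_forward(A_arr)$P
    }
  }
  hw <- prod(dim(x)[1:2])
  g <- colMeans(matrix(x, hw, handle$channels[3]))
  as.vector(p$Wh %*% g + p$bh)
}

#' Feature maps of a named layer
#'
#' @param handle a `chalk_cnn`.
#' @param image grain image (any size; resized to the model input).
#' @param layer one of `handle$layer_names`.
#' @return list of class `feature_stack`: `maps` (array `[Hf, Wf, K]`),
#'   `layer_name`, `K`, `N` (spatial positions per map).
#' @export
feature_maps <- function(handle, image, layer) {
  i <- layer_index(handle, layer)
  fw <- net_forward(handle, prepare_input(handle, image))
  maps <- fw$features[[i]]
  structure(list(maps = maps, layer_name = layer,
                 K = dim(maps)[3], N = prod(dim(maps)[1:2])),
            class = "feature_stack")
}

#' Training configuration
#'
#' @param batch_size minibatch size for gradient descent.
#' @param learning_rate positive step size.
#' @param max_epochs number of epochs to run; the checkpoint with the best
#'   development-set chalky F1 is retained.
#' @param momentum SGD momentum coefficient.
#' @param rng_seed seed controlling initial shuffling and batching.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, learning_rate = 0.05,
                         max_epochs = 30, momentum = 0.9, rng_seed = 0L) {
  assert_that(is_count(batch_size) && batch_size > 0,
              "batch_size must be a positive count")
  assert_that(is_number(learning_rate) && learning_rate > 0,
              "learning_rate must be positive")
  assert_that(is_count(max_epochs) && max_epochs > 0,
              "max_epochs must be a positive count")
  assert_that(is_number(momentum) && momentum >= 0 && momentum < 1,
              "momentum must be in [0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 momentum = momentum, rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

# resolve a manifest (data.frame with label/split plus either an `image`
# list-column or a `path` column) into in-memory inputs at model resolution
manifest_inputs <- function(handle, manifest, base_dir = NULL) {
  assert_that(is.data.frame(manifest) &&
                all(c("label", "split") %in% names(manifest)),
              "manifest needs columns label and split")
  imgs <- if ("image" %in% names(manifest)) {
    manifest$image
  } else {
    assert_that("path" %in% names(manifest),
                "manifest needs an image list-column or a path column")
    paths <- manifest$path
    if (!is.null(base_dir)) paths <- file.path(base_dir, paths)
    lapply(paths, read_image)
  }
  lapply(imgs, function(im) prepare_input(handle, im))
}

#' Train the chalky/non-chalky classifier
#'
#' Minibatch stochastic gradient descent with momentum on the softmax
#' cross-entropy loss. After each epoch the model is evaluated on the
#' development split and the parameters with the best chalky F1 are
#' retained as the returned checkpoint. Training is reproducible under
#' `config$rng_seed`.
#'
#' @param handle an untrained or trained `chalk_cnn`.
#' @param manifest data.frame with columns `label` (chalky / non-chalky),
#'   `split` (train / dev / test) and either `path` or an `image`
#'   list-column of RGB arrays.
#' @param config a [train_config()].
#' @param base_dir optional directory that `manifest$path` is relative to.
#' @param verbose print per-epoch progress.
#' @return the trained `chalk_cnn`; `$log` holds a data.frame with
#'   per-epoch `epoch`, `train_loss`, `dev_accuracy`, `dev_f1_chalky`, and
#'   `$best_epoch` the retained epoch.
#' @export
train_classifier <- function(handle, manifest, config = train_config(),
                             base_dir = NULL, verbose = FALSE) {
  assert_that(inherits(handle, "chalk_cnn"), "handle must be a chalk_cnn")
  assert_that(inherits(config, "train_config"), "config must be a train_config")
  inputs <- manifest_inputs(handle, manifest, base_dir)
  tr <- which(manifest$split == "train")
  dv <- which(manifest$split == "dev")
  assert_that(length(tr) > 0 && length(dv) > 0,
              "manifest must contain train and dev splits")
  y <- unname(handle$class_index_map[manifest$label])
  if (any(is.na(y)))
    ck_stop("labels must be 'chalky' or 'non-chalky'",
            class = "chalkcam_data_error")
  if (length(unique(y[tr])) < 2)
    ck_stop("training split must contain both classes",
            class = "chalkcam_data_error")
  p <- handle$params
  vel <- lapply(p, function(w) w * 0)
  best <- list(f1 = -Inf, params = p, epoch = 0L)
  log <- vector("list", config$max_epochs)
  with_seed_(config$rng_seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1, length(ord))]
        acc <- NULL
        bl <- 0
        for (i in batch) {
          handle$params <- p
          fw <- net_forward(handle, inputs[[i]], want_cache = TRUE)
          z <- fw$logits
          m <- max(z)
          pr <- exp(z - m) / sum(exp(z - m))
          bl <- bl + (log(sum(exp(z - m))) + m - z[y[i] + 1])
          dlogits <- pr
          dlogits[y[i] + 1] <- dlogits[y[i] + 1] - 1
          bw <- net_backward(handle, fw, dlogits)
          acc <- if (is.null(acc)) bw$grads
          else mapply(`+`, acc, bw$grads, SIMPLIFY = FALSE)
        }
        nb <- length(batch)
        for (nm in names(p)) {
          vel[[nm]] <- config$momentum * vel[[nm]] -
            config$learning_rate * acc[[nm]] / nb
          p[[nm]] <- p[[nm]] + vel[[nm]]
        }
        losses <- c(losses, bl / nb)
      }
      handle$params <- p
      dev_pred <- vapply(dv, function(i) {
        z <- net_forward(handle, inputs[[i]])$logits
        if (z[2] > z[1]) "chalky" else "non-chalky"
      }, character(1))
      rep_ <- classification_metrics(dev_pred, manifest$label[dv])
      f1 <- rep_$per_class$f1[rep_$per_class$class == "chalky"]
      log[[epoch]] <- data.frame(epoch = epoch,
                                 train_loss = mean(losses),
                                 dev_accuracy = rep_$accuracy,
                                 dev_f1_chalky = f1)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  dev acc %.2f  dev F1 %.2f",
                        epoch, mean(losses), rep_$accuracy, f1))
      if (f1 > best$f1) best <- list(f1 = f1, params = p, epoch = epoch)
    }
  })
  handle$params <- best$params
  handle$trained <- TRUE
  handle$config <- config
  handle$best_epoch <- best$epoch
  handle$log <- do.call(rbind, log)
  handle
}

#' Predict the label of a grain image
#'
#' Returns the predicted class and the raw (pre-softmax) logits, which the
#' CAM engine backpropagates. Equal logits break toward non-chalky (the
#' lower class index).
#'
#' @param object a trained `chalk_cnn`.
#' @param grain grain image (array or `grain_image`).
#' @param ... unused.
#' @return list with `label` and named `logits`.
#' @export
predict.chalk_cnn <- function(object, grain, ...) {
  fw <- net_forward(object, prepare_input(object, grain))
  z <- fw$logits
  list(label = if (z[2] > z[1]) "chalky" else "non-chalky", logits = z)
}

#' Predict labels for a list of grain images
#'
#' @param handle a trained `chalk_cnn`.
#' @param grains list of grain images.
#' @return data.frame with `label`, `logit_nonchalky`, `logit_chalky`.
#' @export
predict_batch <- function(handle, grains) {
  res <- lapply(grains, function(g) predict(handle, g))
  data.frame(label = vapply(res, `[[`, character(1), "label"),
             logit_nonchalky = vapply(res, function(r) r$logits[1], 0),
             logit_chalky = vapply(res, function(r) r$logits[2], 0))
}

#' Save / load a model checkpoint
#'
#' @param handle a `chalk_cnn`.
#' @param path checkpoint file path.
#' @return `load_model` returns the `chalk_cnn`.
#' @export
save_model <- function(handle, path) {
  assert_that(inherits(handle, "chalk_cnn"), "handle must be a chalk_cnn")
  saveRDS(handle, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  h <- readRDS(path)
  assert_that(inherits(h, "chalk_cnn"), "checkpoint is not a chalk_cnn")
  h
}
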