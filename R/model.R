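# The feature-merging classifier: a CNN backbone extracts features from the
# spectrogram image, a sigmoid squashes them to [0, 1], the scaled
# handcrafted features are concatenated, and a single fully connected
# sigmoid unit produces the anomaly score. Exposed in the classic R
# modelling idiom: fusion_fit() returns a classed object with predict /
# print / summary / plot methods.

#' Configuration of the feature-merging classifier
#'
#' @param backbone CNN block: `"tiny-test"` (two small conv blocks, for
#'   desk-scale work), `"vgg16"`, `"vgg19"`, `"resnet18"` or `"resnet34"`.
#'   All backbones end in global average pooling, so the merge uses the
#'   post-pooling feature vector (16-dim for tiny-test, 512-dim otherwise)
#'   and any input size downsampling to at least 1 pixel is accepted.
#' @param input_mode `"gray"` (1-channel) or `"rgb"` (3-channel) input.
#' @param n_handcrafted Number of handcrafted features merged in: 9 for
#'   rhythm models, 11 for heartbeat models.
#' @param dropout_rate Dropout applied to the merged feature vector during
#'   training.
#' @param lr_init,lr_decay,decay_every Learning-rate schedule: start at
#'   `lr_init` (default 0.1) and multiply by `lr_decay` (default 0.5,
#'   i.e. 50% decay) every `decay_every` epochs.
#' @param early_stop_patience Stop when validation accuracy strictly
#'   decreases this many consecutive epochs (default 2).
#' @param batch_size,max_epochs Minibatch size and epoch cap.
#' @param momentum SGD momentum.
#' @param clip_norm Global gradient-norm clip (stabilizes the 0.1 LR).
#' @param val_frac Fraction of the training data held out as the inner
#'   validation split (default 20%).
#' @param seed Integer seed covering initialization, the inner split,
#'   shuffling and dropout.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(backbone = c("tiny-test", "vgg16", "vgg19",
                                       "resnet18", "resnet34"),
                          input_mode = c("gray", "rgb"),
                          n_handcrafted = 9, dropout_rate = 0.5,
                          lr_init = 0.1, lr_decay = 0.5, decay_every = 10,
                          early_stop_patience = 2, batch_size = 32,
                          max_epochs = 30, momentum = 0.9, clip_norm = 5,
                          val_frac = 0.2, seed = 1L) {
  backbone <- match.arg(backbone)
  input_mode <- match.arg(input_mode)
  stopifnot(lr_init > 0, lr_decay > 0, lr_decay < 1,
            dropout_rate >= 0, dropout_rate < 1,
            n_handcrafted %in% c(9, 11) || n_handcrafted > 0)
  structure(list(backbone = backbone, input_mode = input_mode,
                 n_handcrafted = as.integer(n_handcrafted),
                 dropout_rate = dropout_rate, lr_init = lr_init,
                 lr_decay = lr_decay, decay_every = decay_every,
                 early_stop_patience = early_stop_patience,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 clip_norm = clip_norm, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "fusion_config")
}

#' Build an untrained feature-merging network
#'
#' Graph: backbone(image) -> global-average-pooled feature vector ->
#' elementwise sigmoid -> concatenate with the scaled handcrafted features
#' -> dropout -> one fully connected unit -> sigmoid score in `[0, 1]`.
#' Grayscale mode adapts the first convolution to 1-channel input.
#'
#' @param config A [fusion_config()].
#' @return List with `backbone`, `head` (the final dense layer) and
#'   `merged_dim`.
#' @export
build_fusion_net <- function(config) {
  stopifnot(inherits(config, "fusion_config"))
  set.seed(config$seed)
  cin <- if (config$input_mode == "gray") 1L else 3L
  bb <- .build_backbone(config$backbone, cin)
  merged_dim <- bb$out_dim + config$n_handcrafted
  head <- .dense_layer(merged_dim, 1L)
  list(backbone = bb, head = head, merged_dim = merged_dim)
}

# forward pass; images: (H, W, C, N) in [0,1]; feats: (p, N) scaled.
# returns scores plus caches for backprop when training = TRUE
.fusion_forward <- function(net, images, feats, config, training = FALSE) {
  bf <- .backbone_forward(net$backbone, images)
  fimg <- .sigmoid(bf$out)                    # (D, N) in [0,1]
  merged <- rbind(fimg, feats)
  drop_mask <- NULL
  if (training && config$dropout_rate > 0) {
    drop_mask <- matrix(runif(length(merged)) >= config$dropout_rate,
                        nrow(merged), ncol(merged)) / (1 - config$dropout_rate)
    merged <- merged * drop_mask
  }
  z <- net$head$W %*% merged + net$head$b
  scores <- as.numeric(.sigmoid(z))
  list(scores = scores,
       cache = list(bf = bf, fimg = fimg, merged = merged,
                    drop_mask = drop_mask))
}

.fusion_backward <- function(net, cache, scores, y, config) {
  n <- length(y)
  dz <- matrix((scores - y) / n, nrow = 1)    # BCE + sigmoid
  grads_head <- list(W = dz %*% t(cache$merged), b = sum(dz))
  dmerged <- t(net$head$W) %*% dz
  if (!is.null(cache$drop_mask)) dmerged <- dmerged * cache$drop_mask
  D <- nrow(cache$fimg)
  dfimg <- dmerged[seq_len(D), , drop = FALSE] *
    cache$fimg * (1 - cache$fimg)
  grads_bb <- .backbone_backward(net$backbone, dfimg, cache$bf$caches)
  list(head = grads_head, bb = grads_bb)
}

# learning rate at a given epoch: lr_init halved every decay_every epochs
.lr_at <- function(epoch, config) {
  config$lr_init * config$lr_decay^floor((epoch - 1) / config$decay_every)
}

# early stopping: validation accuracy strictly decreased in `patience`
# consecutive epochs (e.g. accs .8 .9 .85 .8 stops after epoch 4)
.should_stop <- function(val_accs, patience = 2) {
  length(val_accs) > patience &&
    all(diff(tail(val_accs, patience + 1)) < 0)
}

.bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# normalize image input to an (H, W, C, N) array in [0, 1]
.image_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) {
    return(if (max(images) > 1) images / 255 else images)
  }
  stopifnot(is.list(images), length(images) >= 1)
  arrs <- lapply(images, function(im) {
    a <- if (inherits(im, "spectro_image")) im$pixels else im
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
    if (max(a) > 1) a / 255 else a
  })
  d <- dim(arrs[[1]])
  out <- array(0, c(d, length(arrs)))
  for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
  out
}

#' Fit the feature-merging classifier
#'
#' Trains with minibatch SGD (momentum, gradient-norm clipping) on binary
#' cross-entropy. 80% of the supplied data trains the network and 20% is
#' an inner validation split; the learning rate starts at `lr_init` and
#' halves every `decay_every` epochs; training stops early when validation
#' accuracy strictly decreases in `early_stop_patience` consecutive
#' epochs. The min-max feature scaler is learned here, on the training
#' data only, and stored in the fitted object.
#'
#' @param images Spectrogram images: a list of [render_spectrogram()]
#'   outputs / matrices, or an `(H, W, C, N)` array.
#' @param features Numeric matrix of handcrafted features, one row per
#'   item, in schema order.
#' @param labels Integer 0/1 labels (1 = abnormal).
#' @param config A [fusion_config()].
#' @return Object of class `ecg_fusion` with elements `net`, `scaler`,
#'   `config` and `history` (per-epoch loss/accuracy data frame).
#' @export
fusion_fit <- function(images, features, labels, config = fusion_config()) {
  x <- .image_batch(images)
  n <- dim(x)[4]
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == n, length(labels) == n)
  if (n == 0) stop("empty training set")
  if (ncol(features) != config$n_handcrafted) {
    stop("feature matrix has ", ncol(features), " columns; config expects ",
         config$n_handcrafted)
  }

  scaler <- fit_scaler(features)
  feats <- t(apply_scaler(scaler, features))  # (p, N)

  net <- build_fusion_net(config)             # seeds RNG
  val_n <- max(1L, round(config$val_frac * n))
  val_idx <- sample(n, val_n)
  tr_idx <- setdiff(seq_len(n), val_idx)

  state <- list()
  hist <- list()
  prev_acc <- c()
  for (epoch in seq_len(config$max_epochs)) {
    lr <- .lr_at(epoch, config)
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
      xb <- x[, , , bi, drop = FALSE]
      fb <- feats[, bi, drop = FALSE]
      yb <- labels[bi]
      fw <- .fusion_forward(net, xb, fb, config, training = TRUE)
      gr <- .fusion_backward(net, fw$cache, fw$scores, yb, config)
      st <- .sgd_step(net$backbone, net$head, gr$bb, gr$head, state, lr,
                      config$momentum, config$clip_norm)
      net$backbone <- st$bb; net$head <- st$head; state <- st$state
      ep_loss <- ep_loss + .bce(fw$scores, yb) * length(bi)
      ep_correct <- ep_correct + sum(classify_score(fw$scores) == yb)
    }
    vw <- .fusion_forward(net, x[, , , val_idx, drop = FALSE],
                          feats[, val_idx, drop = FALSE], config)
    val_acc <- mean(classify_score(vw$scores) == labels[val_idx])
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / length(ord),
      train_acc = ep_correct / length(ord),
      val_loss = .bce(vw$scores, labels[val_idx]),
      val_acc = val_acc
    )
    prev_acc <- c(prev_acc, val_acc)
    if (.should_stop(prev_acc, config$early_stop_patience)) break
  }

  structure(list(net = net, scaler = scaler, config = config,
                 history = do.call(rbind, hist),
                 feature_names = colnames(features)),
            class = "ecg_fusion")
}

#' Predict anomaly scores or labels from a fitted classifier
#'
#' @param object An `ecg_fusion` model.
#' @param images,features New data in the same formats as [fusion_fit()].
#' @param type `"score"` for raw sigmoid outputs in `[0, 1]`, `"label"`
#'   for thresholded 0/1 labels.
#' @param ... Unused.
#' @return Numeric scores or integer labels.
#' @export
predict.ecg_fusion <- function(object, images, features,
                               type = c("score", "label"), ...) {
  type <- match.arg(type)
  x <- .image_batch(images)
  features <- as.matrix(features)
  feats <- t(apply_scaler(object$scaler, features))
  fw <- .fusion_forward(object$net, x, feats, object$config)
  if (type == "score") fw$scores else classify_score(fw$scores)
}

#' @export
print.ecg_fusion <- function(x, ...) {
  h <- x$history
  cat(sprintf("Feature-merging ECG classifier (%s, %s, %d handcrafted features)\n",
              x$config$backbone, x$config$input_mode, x$config$n_handcrafted))
  cat(sprintf("  trained %d epochs; final val accuracy %.3f\n",
              nrow(h), h$val_acc[nrow(h)]))
  invisible(x)
}

#' @export
summary.ecg_fusion <- function(object, ...) {
  cat("Feature-merging ECG classifier\n")
  cat("  backbone:      ", object$config$backbone, "\n")
  cat("  input mode:    ", object$config$input_mode, "\n")
  cat("  merged dim:    ", object$net$merged_dim, "(=",
      object$net$backbone$out_dim, "CNN +", object$config$n_handcrafted,
      "handcrafted )\n")
  cat("  LR schedule:   ", object$config$lr_init, "x",
      object$config$lr_decay, "every", object$config$decay_every, "epochs\n")
  print(object$history)
  invisible(object)
}

#' @export
plot.ecg_fusion <- function(x, ...) {
  h <- x$history
  plot.default(h$epoch, h$train_loss, type = "l", xlab = "epoch",
               ylab = "binary cross-entropy",
               ylim = range(c(h$train_loss, h$val_loss)), ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", legend = c("training", "validation"), lty = c(1, 2),
         bty = "n")
  invisible(x)
}

#' Threshold an anomaly score into a binary label
#'
#' The decision rule sends scores of exactly 0.5 to normal:
#' label = 0 (normal) if `x <= 0.5`, 1 (abnormal) if `x > 0.5`.
#'
#' @param x Scores in `[0, 1]` (vectorized).
#' @return Integer 0/1 labels.
#' @export
classify_score <- function(x) {
  if (any(x < 0 | x > 1)) stop("scores must lie in [0, 1]")
  as.integer(x > 0.5)
}

#' Fuse the two per-lead scores into one decision
#'
#' `y = y1 + y2 - 0.5`, labeled abnormal when `y >= 0.5` (equivalently
#' `y1 + y2 >= 1`), so a single confident lead can dominate. Note the
#' fused boundary `y = 0.5` maps to abnormal while the single-lead
#' boundary `x = 0.5` maps to normal; both rules are applied exactly as
#' defined.
#'
#' @param y1,y2 Per-lead scores in `[0, 1]` (vectorized).
#' @return Data frame with `y1`, `y2`, fused score `y` in `[-0.5, 1.5]`,
#'   and `label`.
#' @export
fuse_leads <- function(y1, y2) {
  if (any(y1 < 0 | y1 > 1) || any(y2 < 0 | y2 > 1)) {
    stop("per-lead scores must lie in [0, 1]")
  }
  y <- y1 + y2 - 0.5
  data.frame(y1 = y1, y2 = y2, y = y, label = as.integer(y >= 0.5))
}
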