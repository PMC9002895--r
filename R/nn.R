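# Minimal convolutional-network engine in base R. Batches are arrays with
# dim (H, W, C, N); convolutions are im2col + GEMM so BLAS does the heavy
# lifting. Only what the feature-merging classifier needs is implemented:
# conv / relu / 2x2 maxpool / residual block / global average pool /
# dense / sigmoid / dropout, each with forward and backward passes.

.conv_layer <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  fan_in <- k * k * cin
  list(type = "conv",
       W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), nrow = cout),
       b = numeric(cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       cin = as.integer(cin), cout = as.integer(cout))
}

.dense_layer <- function(din, dout) {
  list(type = "dense",
       W = matrix(rnorm(dout * din, sd = sqrt(1 / din)), nrow = dout),
       b = numeric(dout))
}

.pad4 <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

.im2col <- function(xp, k, s, hout, wout) {
  d <- dim(xp)
  C <- d[3]; N <- d[4]
  cols <- array(0, c(hout, wout, k * k * C, N))
  for (ki in seq_len(k)) {
    rows <- seq(ki, by = s, length.out = hout)
    for (kj in seq_len(k)) {
      cc <- seq(kj, by = s, length.out = wout)
      f <- ki + (kj - 1L) * k + (seq_len(C) - 1L) * k * k
      cols[, , f, ] <- xp[rows, cc, , , drop = FALSE]
    }
  }
  X <- aperm(cols, c(3, 1, 2, 4))
  dim(X) <- c(k * k * C, hout * wout * N)
  X
}

.conv_forward <- function(layer, x) {
  d <- dim(x)
  k <- layer$k; s <- layer$stride; p <- layer$pad
  hout <- (d[1] + 2 * p - k) %/% s + 1L
  wout <- (d[2] + 2 * p - k) %/% s + 1L
  xp <- .pad4(x, p)
  X <- .im2col(xp, k, s, hout, wout)
  out <- layer$W %*% X + layer$b
  dim(out) <- c(layer$cout, hout, wout, d[4])
  list(out = aperm(out, c(2, 3, 1, 4)),
       cache = list(X = X, in_dim = d, hout = hout, wout = wout))
}

.conv_backward <- function(layer, dout, cache) {
  d <- cache$in_dim
  k <- layer$k; s <- layer$stride; p <- layer$pad
  hout <- cache$hout; wout <- cache$wout
  N <- d[4]
  dmat <- aperm(dout, c(3, 1, 2, 4))
  dim(dmat) <- c(layer$cout, hout * wout * N)
  dW <- dmat %*% t(cache$X)
  db <- rowSums(dmat)
  dX <- t(layer$W) %*% dmat
  dim(dX) <- c(k * k * layer$cin, hout, wout, N)
  dcols <- aperm(dX, c(2, 3, 1, 4))
  dxp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], N))
  for (ki in seq_len(k)) {
    rows <- seq(ki, by = s, length.out = hout)
    for (kj in seq_len(k)) {
      cc <- seq(kj, by = s, length.out = wout)
      f <- ki + (kj - 1L) * k + (seq_len(layer$cin) - 1L) * k * k
      dxp[rows, cc, , ] <- dxp[rows, cc, , , drop = FALSE] +
        dcols[, , f, , drop = FALSE]
    }
  }
  dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
        else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

.pool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  i1 <- seq(1L, by = 2L, length.out = h2)
  j1 <- seq(1L, by = 2L, length.out = w2)
  s <- list(x[i1, j1, , , drop = FALSE], x[i1 + 1L, j1, , , drop = FALSE],
            x[i1, j1 + 1L, , , drop = FALSE],
            x[i1 + 1L, j1 + 1L, , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4)
  for (q in 1:4) {
    masks[[q]] <- (s[[q]] == m) & !taken
    taken <- taken | masks[[q]]
  }
  list(out = m, cache = list(masks = masks, in_dim = d, h2 = h2, w2 = w2))
}

.pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  h2 <- cache$h2; w2 <- cache$w2
  i1 <- seq(1L, by = 2L, length.out = h2)
  j1 <- seq(1L, by = 2L, length.out = w2)
  dx <- array(0, d)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (q in 1:4) {
    dx[i1 + offs[[q]][1], j1 + offs[[q]][2], , ] <-
      dout * cache$masks[[q]]
  }
  dx
}

.gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(xm), d[3], d[4])
  list(out = out, cache = list(in_dim = d))
}

.gap_backward <- function(dout, cache) {
  d <- cache$in_dim
  hw <- d[1] * d[2]
  dx <- array(rep(as.vector(dout) / hw, each = hw), d)
  dx
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.res_block <- function(cin, cout, stride = 1L) {
  list(type = "resblock",
       conv1 = .conv_layer(cin, cout, 3L, stride),
       conv2 = .conv_layer(cout, cout, 3L, 1L),
       proj = if (stride != 1L || cin != cout)
                .conv_layer(cin, cout, 1L, stride, pad = 0L))
}

.resblock_forward <- function(layer, x) {
  f1 <- .conv_forward(layer$conv1, x)
  a1 <- pmax(f1$out, 0)
  f2 <- .conv_forward(layer$conv2, a1)
  sh <- if (!is.null(layer$proj)) .conv_forward(layer$proj, x)
        else list(out = x, cache = NULL)
  z <- f2$out + sh$out
  out <- pmax(z, 0)
  list(out = out,
       cache = list(c1 = f1$cache, a1pos = a1 > 0, c2 = f2$cache,
                    sh = sh$cache, zpos = z > 0))
}

.resblock_backward <- function(layer, dout, cache) {
  dz <- dout * cache$zpos
  b2 <- .conv_backward(layer$conv2, dz, cache$c2)
  da1 <- b2$dx * cache$a1pos
  b1 <- .conv_backward(layer$conv1, da1, cache$c1)
  grads <- list(conv1 = b1$grads, conv2 = b2$grads)
  if (!is.null(layer$proj)) {
    bp <- .conv_backward(layer$proj, dz, cache$sh)
    dx <- b1$dx + bp$dx
    grads$proj <- bp$grads
  } else {
    dx <- b1$dx + dz
  }
  list(dx = dx, grads = grads)
}

# ---- backbone builders ----------------------------------------------------

.backbone_tiny <- function(cin) {
  list(layers = list(.conv_layer(cin, 8L, 3L), list(type = "relu"),
                     list(type = "pool"),
                     .conv_layer(8L, 16L, 3L), list(type = "relu"),
                     list(type = "pool"),
                     list(type = "gap")),
       out_dim = 16L)
}

.backbone_vgg <- function(cin, cfg) {
  layers <- list()
  c_prev <- cin
  for (item in cfg) {
    if (identical(item, "M")) {
      layers <- c(layers, list(list(type = "pool")))
    } else {
      layers <- c(layers, list(.conv_layer(c_prev, as.integer(item), 3L),
                               list(type = "relu")))
      c_prev <- as.integer(item)
    }
  }
  list(layers = c(layers, list(list(type = "gap"))), out_dim = 512L)
}

.backbone_resnet <- function(cin, blocks) {
  layers <- list(.conv_layer(cin, 64L, 7L, 2L, 3L), list(type = "relu"),
                 list(type = "pool"))
  chans <- c(64L, 128L, 256L, 512L)
  c_prev <- 64L
  for (stage in seq_along(blocks)) {
    for (b in seq_len(blocks[stage])) {
      stride <- if (b == 1L && stage > 1L) 2L else 1L
      layers <- c(layers, list(.res_block(c_prev, chans[stage], stride)))
      c_prev <- chans[stage]
    }
  }
  list(layers = c(layers, list(list(type = "gap"))), out_dim = 512L)
}

.build_backbone <- function(backbone, cin) {
  switch(backbone,
    "tiny-test" = .backbone_tiny(cin),
    vgg16 = .backbone_vgg(cin, list(64, 64, "M", 128, 128, "M",
                                    256, 256, 256, "M", 512, 512, 512, "M",
                                    512, 512, 512, "M")),
    vgg19 = .backbone_vgg(cin, list(64, 64, "M", 128, 128, "M",
                                    256, 256, 256, 256, "M",
                                    512, 512, 512, 512, "M",
                                    512, 512, 512, 512, "M")),
    resnet18 = .backbone_resnet(cin, c(2L, 2L, 2L, 2L)),
    resnet34 = .backbone_resnet(cin, c(3L, 4L, 6L, 3L)),
    stop("unknown backbone: ", backbone)
  )
}

.backbone_forward <- function(bb, x) {
  caches <- vector("list", length(bb$layers))
  for (i in seq_along(bb$layers)) {
    ly <- bb$layers[[i]]
    r <- switch(ly$type,
      conv = .conv_forward(ly, x),
      relu = list(out = pmax(x, 0), cache = x > 0),
      pool = .pool_forward(x),
      resblock = .resblock_forward(ly, x),
      gap = .gap_forward(x),
      stop("unknown layer: ", ly$type)
    )
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

.backbone_backward <- function(bb, dout, caches) {
  grads <- vector("list", length(bb$layers))
  for (i in rev(seq_along(bb$layers))) {
    ly <- bb$layers[[i]]
    r <- switch(ly$type,
      conv = .conv_backward(ly, dout, caches[[i]]),
      relu = list(dx = dout * caches[[i]], grads = NULL),
      pool = list(dx = .pool_backward(dout, caches[[i]]), grads = NULL),
      resblock = .resblock_backward(ly, dout, caches[[i]]),
      gap = list(dx = .gap_backward(dout, caches[[i]]), grads = NULL)
    )
    dout <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots for parameter-free layers
  }
  grads
}

# flatten trainable parameters to a named list of matrices for SGD state
.layer_params <- function(ly) {
  switch(ly$type,
    conv = list(W = "W", b = "b"),
    dense = list(W = "W", b = "b"),
    resblock = NULL,                     # handled recursively
    NULL)
}

.sgd_step <- function(bb, head, grads_bb, grads_head, state, lr, momentum,
                      clip) {
  # global gradient-norm clipping keeps the large initial LR stable
  sq <- 0
  walk <- function(g) {
    for (gi in g) {
      if (is.list(gi)) walk(gi) else sq <<- sq + sum(gi^2)
    }
  }
  walk(grads_bb); walk(grads_head)
  scale <- if (sq > clip^2) clip / sqrt(sq) else 1

  upd <- function(layer, grad, key) {
    for (nm in c("W", "b")) {
      k <- paste0(key, ".", nm)
      v <- state[[k]]
      if (is.null(v)) v <- 0
      v <- momentum * v - lr * scale * grad[[nm]]
      state[[k]] <<- v
      layer[[nm]] <- layer[[nm]] + v
    }
    layer
  }
  for (i in seq_along(bb$layers)) {
    ly <- bb$layers[[i]]
    if (ly$type == "conv") {
      bb$layers[[i]] <- upd(ly, grads_bb[[i]], paste0("L", i))
    } else if (ly$type == "resblock") {
      for (part in c("conv1", "conv2", "proj")) {
        if (!is.null(ly[[part]]) && !is.null(grads_bb[[i]][[part]])) {
          ly[[part]] <- upd(ly[[part]], grads_bb[[i]][[part]],
                            paste0("L", i, ".", part))
        }
      }
      bb$layers[[i]] <- ly
    }
  }
  head <- upd(head, grads_head, "head")
  list(bb = bb, head = head, state = state)
}
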