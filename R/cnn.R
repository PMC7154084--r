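#' Small CNN configuration
#'
#' A compact convolutional classifier for scalogram rasters: a stack of
#' conv-ReLU blocks (the first with a large 11x11 kernel and stride 4,
#' suited to the blob-like energy features of scalograms; subsequent blocks
#' 3x3), 2x2 max-pooling between blocks, and a fully-connected softmax head
#' over the classes. Trained with Adam at a fixed base learning rate, a
#' higher learning rate on the freshly initialised head, minibatches of 64,
#' gradient clipping, and early stopping with patience counted in
#' validation events (validation every `validation_freq` iterations).
#'
#' @param input_size `c(H, W)` raster size in pixels (3 colour channels
#'   assumed).
#' @param n_classes number of output classes (default 5).
#' @param conv_channels output channels per conv block.
#' @param first_kernel,first_stride kernel size and stride of block 1.
#' @param learning_rate Adam base step size (default 1e-4).
#' @param head_lr_multiplier learning-rate factor for the FC head
#'   (default 20).
#' @param minibatch minibatch size (default 64).
#' @param max_epochs epoch cap (default 60).
#' @param validation_freq run validation every this many iterations.
#' @param patience validation events of rising loss tolerated (default 6).
#' @param clip_norm global gradient-norm clip (default 1).
#' @param seed RNG seed (initialisation and shuffling).
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(input_size = c(96, 96), n_classes = 5,
                       conv_channels = c(16, 32, 32, 32),
                       first_kernel = 11, first_stride = 4,
                       learning_rate = 1e-4, head_lr_multiplier = 20,
                       minibatch = 64, max_epochs = 60, validation_freq = 6,
                       patience = 6, clip_norm = 1, seed = 1) {
  assert_count(minibatch, "minibatch")
  assert_scalar(learning_rate, "learning_rate", lower = 1e-12)
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 conv_channels = as.integer(conv_channels),
                 first_kernel = as.integer(first_kernel),
                 first_stride = as.integer(first_stride),
                 learning_rate = learning_rate,
                 head_lr_multiplier = head_lr_multiplier,
                 minibatch = as.integer(minibatch),
                 max_epochs = as.integer(max_epochs),
                 validation_freq = as.integer(validation_freq),
                 patience = as.integer(patience),
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "cnn_config")
}

# linear indices of all k x k x Cin patches in a (Hp, Wp, Cin) array,
# one column per output position (column-major over the Ho x Wo grid)
conv_index <- function(Hp, Wp, Cin, k, stride) {
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  off <- as.vector(outer(outer(seq_len(k), (seq_len(k) - 1) * Hp, `+`),
                         (seq_len(Cin) - 1) * Hp * Wp, `+`))
  base <- as.vector(outer(seq(1L, by = stride, length.out = Ho),
                          (seq(1L, by = stride, length.out = Wo) - 1L) * Hp, `+`))
  list(idx = outer(off, base, `+`) - 1L, Ho = Ho, Wo = Wo)
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# build layer list from the config; every layer records its input geometry
cnn_build <- function(cfg) {
  H <- cfg$input_size[1]; W <- cfg$input_size[2]; Cin <- 3L
  layers <- list()
  nb <- length(cfg$conv_channels)
  for (i in seq_len(nb)) {
    k <- if (i == 1) cfg$first_kernel else 3L
    stride <- if (i == 1) cfg$first_stride else 1L
    pad <- if (i == 1) 0L else 1L
    Cout <- cfg$conv_channels[i]
    geom <- conv_index(H + 2 * pad, W + 2 * pad, Cin, k, stride)
    fan_in <- k * k * Cin
    layers[[length(layers) + 1L]] <- list(
      type = "conv", k = k, stride = stride, pad = pad,
      Cin = Cin, Cout = Cout, Hin = H, Win = W,
      Ho = geom$Ho, Wo = geom$Wo, idx = geom$idx,
      W = matrix(rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)), fan_in, Cout),
      b = rep(0, Cout), head = FALSE)
    H <- geom$Ho; W <- geom$Wo; Cin <- Cout
    layers[[length(layers) + 1L]] <- list(type = "relu")
    if (i < nb && H >= 2 && W >= 2) {
      # no fields: a pool layer must not partially match `$W`
      layers[[length(layers) + 1L]] <- list(type = "pool")
      H <- H %/% 2L; W <- W %/% 2L
    }
  }
  D <- H * W * Cin
  layers[[length(layers) + 1L]] <- list(
    type = "fc", D = D, K = cfg$n_classes,
    W = matrix(rnorm(D * cfg$n_classes, sd = sqrt(2 / D)), D, cfg$n_classes),
    b = rep(0, cfg$n_classes), head = TRUE)
  layers
}

conv_fwd <- function(layer, x) {
  xp <- pad_array(x, layer$pad)
  B <- dim(x)[4]
  P <- layer$Ho * layer$Wo
  npix <- prod(dim(xp)[1:3])
  Xcol <- matrix(0, nrow(layer$idx), P * B)
  xv <- as.vector(xp)
  for (b in seq_len(B)) {
    Xcol[, (b - 1L) * P + seq_len(P)] <- xv[layer$idx + (b - 1L) * npix]
  }
  out <- crossprod(Xcol, layer$W)
  out <- sweep(out, 2, layer$b, `+`)
  y <- array(0, c(layer$Ho, layer$Wo, layer$Cout, B))
  for (b in seq_len(B)) {
    y[, , , b] <- array(out[(b - 1L) * P + seq_len(P), ],
                        c(layer$Ho, layer$Wo, layer$Cout))
  }
  list(y = y, cache = list(Xcol = Xcol, B = B, dimxp = dim(xp)[1:3]))
}

conv_bwd <- function(layer, cache, dy) {
  B <- cache$B
  P <- layer$Ho * layer$Wo
  dY <- matrix(0, P * B, layer$Cout)
  for (b in seq_len(B)) {
    dY[(b - 1L) * P + seq_len(P), ] <- matrix(dy[, , , b], P, layer$Cout)
  }
  dW <- cache$Xcol %*% dY
  db <- colSums(dY)
  dXcol <- layer$W %*% t(dY)
  npix <- prod(cache$dimxp[1:3])
  dxp <- numeric(npix * B)
  offs <- (seq_len(B) - 1L) * npix
  for (r in seq_len(nrow(layer$idx))) {
    # for a fixed kernel offset, target positions are distinct, so the
    # vectorised accumulate is race-free
    tgt <- as.vector(outer(layer$idx[r, ], offs, `+`))
    dxp[tgt] <- dxp[tgt] + as.vector(dXcol[r, ])
  }
  dxp <- array(dxp, c(cache$dimxp, B))
  if (layer$pad > 0) {
    dxp <- dxp[layer$pad + seq_len(layer$Hin), layer$pad + seq_len(layer$Win), , ,
               drop = FALSE]
  }
  list(dx = dxp, dW = dW, db = db)
}

pool_fwd <- function(layer, x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  s <- lapply(1:4, function(q) {
    dh <- (q - 1) %% 2; dw <- (q - 1) %/% 2
    x[2 * seq_len(H2) - 1 + dh, 2 * seq_len(W2) - 1 + dw, , , drop = FALSE]
  })
  m <- cbind(as.vector(s[[1]]), as.vector(s[[2]]),
             as.vector(s[[3]]), as.vector(s[[4]]))
  choice <- max.col(m, ties.method = "first")
  y <- array(m[cbind(seq_len(nrow(m)), choice)], c(H2, W2, d[3], d[4]))
  list(y = y, cache = list(dimx = d, H2 = H2, W2 = W2, choice = choice))
}

pool_bwd <- function(layer, cache, dy) {
  d <- cache$dimx
  H2 <- cache$H2; W2 <- cache$W2
  dx <- array(0, d)
  # linear index of the chosen input cell for every output cell
  grid <- expand.grid(h = seq_len(H2), w = seq_len(W2),
                      c = seq_len(d[3]), b = seq_len(d[4]))
  dh <- (cache$choice - 1) %% 2
  dw <- (cache$choice - 1) %/% 2
  lin <- (2 * grid$h - 1 + dh) +
    (2 * grid$w - 1 + dw - 1) * d[1] +
    (grid$c - 1) * d[1] * d[2] +
    (grid$b - 1) * d[1] * d[2] * d[3]
  dx[lin] <- as.vector(dy)
  dx
}

cnn_forward <- function(layers, x, keep_cache = TRUE) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$type == "conv") {
      r <- conv_fwd(lay, x)
      x <- r$y
      if (keep_cache) caches[[li]] <- r$cache
    } else if (lay$type == "relu") {
      if (keep_cache) caches[[li]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (lay$type == "pool") {
      r <- pool_fwd(lay, x)
      x <- r$y
      if (keep_cache) caches[[li]] <- r$cache
    } else if (lay$type == "fc") {
      B <- dim(x)[4]
      xf <- matrix(x, ncol = B)        # D x B
      if (keep_cache) caches[[li]] <- list(xf = xf, dimx = dim(x))
      x <- t(crossprod(xf, lay$W)) + lay$b   # K x B
      x <- t(x)                               # B x K logits
    }
  }
  list(logits = x, caches = caches)
}

cnn_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dy <- dlogits                                 # B x K
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    if (lay$type == "fc") {
      cache <- caches[[li]]
      grads[[li]] <- list(dW = cache$xf %*% dy, db = colSums(dy))
      dx <- lay$W %*% t(dy)                     # D x B
      dy <- array(dx, cache$dimx)
    } else if (lay$type == "pool") {
      dy <- pool_bwd(lay, caches[[li]], dy)
    } else if (lay$type == "relu") {
      dy <- dy * caches[[li]]$mask
    } else if (lay$type == "conv") {
      r <- conv_bwd(lay, caches[[li]], dy)
      grads[[li]] <- list(dW = r$dW, db = r$db)
      dy <- r$dx
    }
  }
  grads
}

cnn_loss_grad <- function(layers, x, yi, K) {
  fw <- cnn_forward(layers, x)
  p <- softmax_rows(fw$logits)
  B <- nrow(p)
  yh <- matrix(0, B, K); yh[cbind(seq_len(B), yi)] <- 1
  loss <- xent_loss(p, yh)
  grads <- cnn_backward(layers, fw$caches, (p - yh) / B)
  list(loss = loss, grads = grads)
}

cnn_eval <- function(layers, x, yi, K, batch = 64) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    fw <- cnn_forward(layers, x[, , , idx, drop = FALSE], keep_cache = FALSE)
    p <- softmax_rows(fw$logits)
    yh <- matrix(0, length(idx), K); yh[cbind(seq_along(idx), yi[idx])] <- 1
    loss <- loss + xent_loss(p, yh) * length(idx)
    correct <- correct + sum(max.col(p) == yi[idx])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Train the small CNN
#'
#' Trains on labelled image arrays with Adam, minibatches, global-norm
#' gradient clipping and early stopping on validation loss (patience
#' counted in validation events, validation run every
#' `cfg$validation_freq` iterations). The best-validation snapshot is
#' returned. If a split manifest is given, the function verifies that no
#' augmented image is in a different split from its parent and raises a
#' hard error on leakage.
#'
#' @param x training images, `H x W x 3 x N` array in `[0, 1]`.
#' @param y training labels.
#' @param cfg a [cnn_config()].
#' @param val_x,val_y validation images and labels.
#' @param manifest optional tibble with columns `id`, `parent_id`, `split`
#'   covering the training/validation images, audited for split leakage.
#' @return object of class `cnn_model`: layers with trained weights, the
#'   config, class levels and the validation history.
#' @export
train_cnn <- function(x, y, cfg, val_x, val_y, manifest = NULL) {
  if (!is.null(manifest)) audit_split_leakage(manifest)
  d <- dim(x)
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2] || d[3] != 3) {
    abort(sprintf("images must be %d x %d x 3, got %d x %d x %d.",
                  cfg$input_size[1], cfg$input_size[2], d[1], d[2], d[3]))
  }
  lev <- sort(unique(c(y, val_y)))
  if (length(setdiff(lev, unique(y)))) {
    abort("every class must be present in the training labels.")
  }
  yi <- match(y, lev); vi <- match(val_y, lev)
  K <- cfg$n_classes
  withr::with_seed(cfg$seed, {
    layers <- cnn_build(cfg)
    adam <- list()
    t_step <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- list(loss = Inf, layers = layers, event = 0L)
    hist <- list()
    rises <- 0L; prev_val <- Inf; event <- 0L; iter <- 0L
    n <- d[4]
    stop_now <- FALSE
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = cfg$minibatch)) {
        idx <- ord[start:min(start + cfg$minibatch - 1, n)]
        iter <- iter + 1L
        lg <- cnn_loss_grad(layers, x[, , , idx, drop = FALSE], yi[idx], K)
        # global-norm gradient clipping
        gn <- sqrt(sum(map_dbl(seq_along(layers), function(li) {
          g <- lg$grads[[li]]
          if (is.null(g)) 0 else sum(g$dW^2) + sum(g$db^2)
        })))
        scale <- if (gn > cfg$clip_norm) cfg$clip_norm / gn else 1
        t_step <- t_step + 1
        for (li in seq_along(layers)) {
          g <- lg$grads[[li]]
          if (is.null(g)) next
          lr <- cfg$learning_rate *
            (if (isTRUE(layers[[li]]$head)) cfg$head_lr_multiplier else 1)
          key <- as.character(li)
          st <- adam[[key]] %||% list(mW = 0 * g$dW, vW = 0 * g$dW,
                                      mb = 0 * g$db, vb = 0 * g$db)
          st$mW <- b1 * st$mW + (1 - b1) * g$dW * scale
          st$vW <- b2 * st$vW + (1 - b2) * (g$dW * scale)^2
          st$mb <- b1 * st$mb + (1 - b1) * g$db * scale
          st$vb <- b2 * st$vb + (1 - b2) * (g$db * scale)^2
          corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
          layers[[li]]$W <- layers[[li]]$W -
            lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
          layers[[li]]$b <- layers[[li]]$b -
            lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
          adam[[key]] <- st
        }
        if (iter %% cfg$validation_freq == 0) {
          event <- event + 1L
          ev <- cnn_eval(layers, val_x, vi, K, cfg$minibatch)
          hist[[event]] <- tibble(event = event, epoch = epoch,
                                  iteration = iter, train_loss = lg$loss,
                                  val_loss = ev$loss,
                                  val_accuracy = ev$accuracy)
          if (ev$loss < best$loss) {
            best <- list(loss = ev$loss, layers = layers, event = event)
          }
          rises <- if (ev$loss > prev_val) rises + 1L else 0L
          prev_val <- ev$loss
          if (rises > cfg$patience) { stop_now <- TRUE; break }
        }
      }
      if (stop_now) break
    }
    # final validation so the best snapshot can never trail the last state
    ev <- cnn_eval(layers, val_x, vi, K, cfg$minibatch)
    event <- event + 1L
    hist[[event]] <- tibble(event = event, epoch = NA_integer_,
                            iteration = iter, train_loss = NA_real_,
                            val_loss = ev$loss, val_accuracy = ev$accuracy)
    if (ev$loss < best$loss) best <- list(loss = ev$loss, layers = layers,
                                          event = event)
    structure(list(layers = best$layers, cfg = cfg, levels = lev,
                   history = bind_rows(hist), best_event = best$event,
                   val_loss = best$loss),
              class = "cnn_model")
  })
}

# hard error if any augmented image sits in a different split from its parent
audit_split_leakage <- function(manifest) {
  m <- as_tibble(manifest)
  kids <- m[!is.na(m$parent_id), ]
  if (!nrow(kids)) return(invisible(TRUE))
  parents <- m[match(kids$parent_id, m$id), ]
  bad <- which(!is.na(parents$split) & kids$split != parents$split)
  if (length(bad)) {
    abort(sprintf("split leakage: augmented trial(s) %s not in their parent's split.",
                  paste(utils::head(kids$id[bad], 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  n <- dim(newdata)[4]
  K <- object$cfg$n_classes
  p <- matrix(0, n, K)
  for (start in seq(1, n, by = object$cfg$minibatch)) {
    idx <- start:min(start + object$cfg$minibatch - 1, n)
    fw <- cnn_forward(object$layers, newdata[, , , idx, drop = FALSE],
                      keep_cache = FALSE)
    p[idx, ] <- softmax_rows(fw$logits)
  }
  colnames(p) <- as.character(object$levels)
  if (type == "prob") p else object$levels[max.col(p)]
}

#' @export
print.cnn_model <- function(x, ...) {
  nconv <- sum(vapply(x$layers, function(l) l$type == "conv", logical(1)))
  cat(sprintf("<cnn_model> %d conv blocks -> fc %d-way; best validation event %d (val loss %.4f)\n",
              nconv, x$cfg$n_classes, x$best_event, x$val_loss))
  invisible(x)
}
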