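#' Shallow ANN configuration
#'
#' A single-hidden-layer network: sigmoid hidden units (default 256),
#' softmax output over the classes, trained with minibatch stochastic
#' gradient descent on the cross-entropy loss. Training stops at
#' `max_epochs` or once the validation loss has risen for more than
#' `patience` consecutive epochs; the best-validation snapshot is returned.
#'
#' @param input_dim feature dimension.
#' @param hidden_nodes hidden layer width (default 256).
#' @param n_classes number of output classes (default 5).
#' @param learning_rate SGD step size (default 0.01; the tuning grid in the
#'   protocol is 0.1, 0.01, 0.001, 0.0001).
#' @param max_epochs epoch cap (default 100).
#' @param patience epochs of rising validation loss tolerated (default 6).
#' @param minibatch minibatch size (default 16).
#' @param standardize z-score features using training-set statistics.
#' @param seed RNG seed for initialisation and shuffling.
#' @return list of class `ann_config`.
#' @export
ann_config <- function(input_dim, hidden_nodes = 256, n_classes = 5,
                       learning_rate = 0.01, max_epochs = 100, patience = 6,
                       minibatch = 16, standardize = TRUE, seed = 1) {
  assert_count(input_dim, "input_dim")
  assert_count(hidden_nodes, "hidden_nodes")
  assert_count(n_classes, "n_classes")
  assert_scalar(learning_rate, "learning_rate", lower = 1e-12)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_nodes = as.integer(hidden_nodes),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 minibatch = as.integer(minibatch),
                 standardize = standardize, seed = as.integer(seed)),
            class = "ann_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

xent_loss <- function(p, y_onehot) -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))

ann_forward <- function(model, x) {
  h <- 1 / (1 + exp(-(x %*% model$W1 + matrix(model$b1, nrow(x),
                                              length(model$b1), byrow = TRUE))))
  p <- softmax_rows(h %*% model$W2 + matrix(model$b2, nrow(x),
                                            length(model$b2), byrow = TRUE))
  list(h = h, p = p)
}

#' Train the shallow ANN
#'
#' @param x training feature matrix (`n x input_dim`), e.g. the numeric part
#'   of a [feature_table()].
#' @param y training labels (all configured classes must be present).
#' @param cfg an [ann_config()].
#' @param val_x,val_y held-out validation set, disjoint from training, used
#'   for early stopping and snapshot selection.
#' @return object of class `ann_model` with the weight matrices, the
#'   training history (per-epoch train/validation loss and accuracy), the
#'   config snapshot and the class levels.
#' @export
train_ann <- function(x, y, cfg, val_x, val_y) {
  x <- as.matrix(x); val_x <- as.matrix(val_x)
  if (ncol(x) != cfg$input_dim) {
    abort(sprintf("feature dimension %d does not match cfg$input_dim = %d.",
                  ncol(x), cfg$input_dim))
  }
  lev <- sort(unique(c(y, val_y)))
  if (length(lev) < cfg$n_classes || length(setdiff(lev, unique(y)))) {
    abort("every configured class must be present in the training labels.")
  }
  yi <- match(y, lev); vi <- match(val_y, lev)
  K <- cfg$n_classes
  onehot <- function(i) {
    m <- matrix(0, length(i), K); m[cbind(seq_along(i), i)] <- 1; m
  }
  withr::with_seed(cfg$seed, {
    if (cfg$standardize) {
      mu <- colMeans(x)
      sg <- apply(x, 2, stats::sd); sg[sg < 1e-12] <- 1
    } else {
      mu <- rep(0, ncol(x)); sg <- rep(1, ncol(x))
    }
    xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
    vs <- sweep(sweep(val_x, 2, mu), 2, sg, "/")
    d <- cfg$input_dim; H <- cfg$hidden_nodes
    r1 <- sqrt(6 / (d + H)); r2 <- sqrt(6 / (H + K))
    model <- list(W1 = matrix(runif(d * H, -r1, r1), d, H), b1 = rep(0, H),
                  W2 = matrix(runif(H * K, -r2, r2), H, K), b2 = rep(0, K),
                  mu = mu, sg = sg, levels = lev, cfg = cfg)
    yt <- onehot(yi); yv <- onehot(vi)
    best <- list(loss = Inf, model = model, epoch = 0L)
    hist <- list()
    rises <- 0L
    prev_val <- Inf
    n <- nrow(xs)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = cfg$minibatch)) {
        idx <- ord[start:min(start + cfg$minibatch - 1, n)]
        xb <- xs[idx, , drop = FALSE]; yb <- yt[idx, , drop = FALSE]
        fw <- ann_forward(model, xb)
        dz2 <- (fw$p - yb) / nrow(xb)
        dW2 <- crossprod(fw$h, dz2); db2 <- colSums(dz2)
        dh <- dz2 %*% t(model$W2) * fw$h * (1 - fw$h)
        dW1 <- crossprod(xb, dh); db1 <- colSums(dh)
        lr <- cfg$learning_rate
        model$W1 <- model$W1 - lr * dW1; model$b1 <- model$b1 - lr * db1
        model$W2 <- model$W2 - lr * dW2; model$b2 <- model$b2 - lr * db2
      }
      ptr <- ann_forward(model, xs)$p
      pv <- ann_forward(model, vs)$p
      tl <- xent_loss(ptr, yt); vl <- xent_loss(pv, yv)
      hist[[epoch]] <- tibble(
        epoch = epoch, train_loss = tl,
        train_accuracy = mean(max.col(ptr) == yi),
        val_loss = vl, val_accuracy = mean(max.col(pv) == vi))
      if (vl < best$loss) best <- list(loss = vl, model = model, epoch = epoch)
      rises <- if (vl > prev_val) rises + 1L else 0L
      prev_val <- vl
      if (rises > cfg$patience) break
    }
    out <- best$model
    out$history <- bind_rows(hist)
    out$best_epoch <- best$epoch
    out$val_loss <- best$loss
    structure(out, class = "ann_model")
  })
}

#' @export
predict.ann_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sg, "/")
  p <- ann_forward(object, x)$p
  colnames(p) <- as.character(object$levels)
  if (type == "prob") p else object$levels[max.col(p)]
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d-%d-%d sigmoid network; best epoch %d (val loss %.4f)\n",
              x$cfg$input_dim, x$cfg$hidden_nodes, x$cfg$n_classes,
              x$best_epoch, x$val_loss))
  invisible(x)
}
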