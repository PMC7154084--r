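test_that("the shallow ANN separates well-separated Gaussian classes", {
  d <- gaussian_classes(100, 10, gap = 5, seed = 31)
  idx <- withr::with_seed(31, sample(200))
  tr <- idx[1:140]; va <- idx[141:170]; te <- idx[171:200]
  cfg <- ann_config(input_dim = 10, n_classes = 2, hidden_nodes = 32,
                    seed = 1)
  fit <- train_ann(d$x[tr, ], d$y[tr], cfg, d$x[va, ], d$y[va])
  acc <- mean(predict(fit, d$x[te, ], type = "class") == d$y[te])
  expect_gte(acc, 0.95)
  # probability contract
  p <- predict(fit, d$x[te, ])
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  # early stopping: returned snapshot never trails the final epoch
  expect_lte(fit$val_loss, fit$history$val_loss[nrow(fit$history)])
  expect_lte(nrow(fit$history), cfg$max_epochs)
})

test_that("the ANN is chance-level on shuffled labels and solves XOR", {
  d <- gaussian_classes(100, 10, gap = 5, seed = 32)
  idx <- withr::with_seed(32, sample(200))
  tr <- idx[1:140]; va <- idx[141:170]; te <- idx[171:200]
  cfg <- ann_config(input_dim = 10, n_classes = 2, hidden_nodes = 32,
                    seed = 2)
  # average over independent shuffles: the pooled test count gives the
  # binomial null its proper resolution
  accs <- vapply(1:3, function(s) {
    y_shuf <- withr::with_seed(99 + s, sample(d$y))
    fit <- train_ann(d$x[tr, ], y_shuf[tr], cfg, d$x[va, ], y_shuf[va])
    mean(predict(fit, d$x[te, ], type = "class") == y_shuf[te])
  }, numeric(1))
  ci <- stats::qbinom(c(0.025, 0.975), 90, 0.5) / 90
  expect_gte(mean(accs), ci[1])
  expect_lte(mean(accs), ci[2])

  # XOR: beyond any linear decision rule
  xor_d <- withr::with_seed(33, {
    n <- 400
    x <- matrix(runif(2 * n, -1, 1), n)
    y <- 1L + as.integer(sign(x[, 1]) == sign(x[, 2]))
    list(x = x + rnorm(2 * n, sd = 0.05), y = y)
  })
  idx <- withr::with_seed(33, sample(400))
  tr <- idx[1:280]; va <- idx[281:340]; te <- idx[341:400]
  cfg2 <- ann_config(input_dim = 2, n_classes = 2, hidden_nodes = 16,
                     learning_rate = 0.1, max_epochs = 200, seed = 3)
  fit2 <- train_ann(xor_d$x[tr, ], xor_d$y[tr], cfg2,
                    xor_d$x[va, ], xor_d$y[va])
  expect_gte(mean(predict(fit2, xor_d$x[te, ], type = "class") ==
                    xor_d$y[te]), 0.9)
})

test_that("a missing class in the training labels is an error", {
  d <- gaussian_classes(20, 4, gap = 3, seed = 34)
  cfg <- ann_config(input_dim = 4, n_classes = 2, seed = 1)
  only1 <- d$y == 1
  expect_error(train_ann(d$x[only1, ], d$y[only1], cfg, d$x, d$y),
               "present")
  expect_error(train_ann(d$x[, 1:3], d$y, cfg, d$x[, 1:3], d$y), "input_dim")
})

test_that("hidden-width sweep shows accuracy that rises then plateaus", {
  d <- withr::with_seed(35, {
    n <- 80; dd <- 30
    x <- rbind(matrix(rnorm(n * dd), n), matrix(rnorm(n * dd, mean = 0.45), n))
    list(x = x, y = rep(1:2, each = n))
  })
  widths <- c(8, 64, 256)
  accs <- vapply(1:2, function(s) {
    idx <- withr::with_seed(40 + s, sample(160))
    tr <- idx[1:112]; va <- idx[113:136]; te <- idx[137:160]
    vapply(widths, function(w) {
      cfg <- ann_config(input_dim = 30, n_classes = 2, hidden_nodes = w,
                        max_epochs = 60, seed = s)
      fit <- train_ann(d$x[tr, ], d$y[tr], cfg, d$x[va, ], d$y[va])
      mean(predict(fit, d$x[te, ], type = "class") == d$y[te])
    }, numeric(1))
  }, numeric(length(widths)))
  m <- rowMeans(accs)
  # non-decreasing-then-flat within noise
  expect_gte(m[2], m[1] - 0.05)
  expect_gte(m[3], m[2] - 0.05)
})

test_that("CNN gradients match finite differences on a tiny network", {
  cfg <- cnn_config(input_size = c(12, 12), n_classes = 3,
                    conv_channels = c(2, 3), first_kernel = 3,
                    first_stride = 2, seed = 5)
  withr::with_seed(5, {
    layers <- megdecode:::cnn_build(cfg)
    x <- array(runif(12 * 12 * 3 * 2), c(12, 12, 3, 2))
    yi <- c(1L, 3L)
    lg <- megdecode:::cnn_loss_grad(layers, x, yi, 3)
    eps <- 1e-6
    for (li in seq_along(layers)) {
      if (is.null(layers[[li]]$W)) next
      for (probe in 1:5) {
        i <- sample(length(layers[[li]]$W), 1)
        lp <- layers; lp[[li]]$W[i] <- lp[[li]]$W[i] + eps
        lm <- layers; lm[[li]]$W[i] <- lm[[li]]$W[i] - eps
        num <- (megdecode:::cnn_loss_grad(lp, x, yi, 3)$loss -
                  megdecode:::cnn_loss_grad(lm, x, yi, 3)$loss) / (2 * eps)
        expect_lt(abs(num - lg$grads[[li]]$dW[i]) / max(1e-6, abs(num)),
                  1e-4)
      }
    }
  })
})

test_that("the small CNN separates blob-position classes and is chance on shuffled labels", {
  d <- blob_images(100, px = 48, seed = 36)
  idx <- withr::with_seed(36, sample(200))
  tr <- idx[1:140]; va <- idx[141:170]; te <- idx[171:200]
  cfg <- cnn_config(input_size = c(48, 48), n_classes = 2,
                    conv_channels = c(8, 16), max_epochs = 20, seed = 2)
  fit <- train_cnn(d$images[, , , tr], d$y[tr], cfg,
                   d$images[, , , va], d$y[va])
  expect_gte(mean(predict(fit, d$images[, , , te], type = "class") ==
                    d$y[te]), 0.95)
  p <- predict(fit, d$images[, , , te])
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  # best snapshot never trails the final validation state
  expect_lte(fit$val_loss, fit$history$val_loss[nrow(fit$history)])

  # chance calibration pooled over independent shuffles (a single small
  # test set is noisier than the plain binomial null)
  acc_s <- vapply(1:3, function(s) {
    y_shuf <- withr::with_seed(36 + s, sample(d$y))
    cfg_s <- cnn_config(input_size = c(48, 48), n_classes = 2,
                        conv_channels = c(8, 16), max_epochs = 4,
                        seed = 2 + s)
    fit_s <- train_cnn(d$images[, , , tr], y_shuf[tr], cfg_s,
                       d$images[, , , va], y_shuf[va])
    mean(predict(fit_s, d$images[, , , te], type = "class") == y_shuf[te])
  }, numeric(1))
  ci <- stats::qbinom(c(0.025, 0.975), 90, 0.5) / 90
  expect_gte(mean(acc_s), ci[1])
  expect_lte(mean(acc_s), ci[2])
})

test_that("CNN training is deterministic under a fixed seed", {
  d <- blob_images(20, px = 24, seed = 38)
  cfg <- cnn_config(input_size = c(24, 24), n_classes = 2,
                    conv_channels = c(4), first_kernel = 5, first_stride = 2,
                    max_epochs = 3, minibatch = 8, validation_freq = 2,
                    seed = 7)
  a <- train_cnn(d$images[, , , 1:30], d$y[1:30], cfg,
                 d$images[, , , 31:40], d$y[31:40])
  b <- train_cnn(d$images[, , , 1:30], d$y[1:30], cfg,
                 d$images[, , , 31:40], d$y[31:40])
  expect_identical(a$history, b$history)
  expect_identical(a$layers, b$layers)
})

test_that("split leakage between augmented children and parents is a hard error", {
  manifest <- tibble::tibble(
    id = c("t1", "t2", "t1_s100", "t2_s100"),
    parent_id = c(NA, NA, "t1", "t2"),
    split = c("train", "test", "train", "train"))
  expect_error(megdecode:::audit_split_leakage(manifest), "leakage")
  ok <- manifest
  ok$split[4] <- "test"
  expect_true(megdecode:::audit_split_leakage(ok))

  d <- blob_images(4, px = 24, seed = 39)
  cfg <- cnn_config(input_size = c(24, 24), n_classes = 2,
                    conv_channels = c(2), first_kernel = 5, first_stride = 2,
                    max_epochs = 1, minibatch = 4, seed = 1)
  expect_error(
    train_cnn(d$images[, , , 1:4], d$y[1:4], cfg,
              d$images[, , , 5:8], d$y[5:8], manifest = manifest),
    "leakage")
})

test_that("cross-entropy aggregation matches hand arithmetic and breaks ties low", {
  # hand computation: 3 sensors, K = 2
  p1 <- c(0.9, 0.6, 0.2)
  probs <- cbind(p1, 1 - p1)
  colnames(probs) <- NULL
  res <- aggregate_trial(probs)
  hand1 <- mean(-log(p1))
  hand2 <- mean(-log(1 - p1))
  expect_equal(unname(res$scores), c(hand1, hand2))
  expect_equal(res$class, 1L)
  expect_false(res$tie)

  # consensus one-hot-ish sensors pick that class
  oneish <- matrix(rep(c(0.01, 0.01, 0.97, 0.01), 5), 5, 4, byrow = TRUE)
  expect_equal(aggregate_trial(oneish)$class, 3L)

  # uniform probabilities tie towards the first class, flagged
  unif <- matrix(0.25, 4, 4)
  resu <- aggregate_trial(unif)
  expect_equal(resu$class, 1L)
  expect_true(resu$tie)

  # permutation invariance over sensors
  shuf <- probs[c(3, 1, 2), ]
  expect_equal(aggregate_trial(shuf)$scores, res$scores)

  expect_error(aggregate_trial(matrix(c(0.5, 0.2), 1)), "sum to 1")

  # epsilon floor keeps exact zeros finite
  z <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_true(all(is.finite(aggregate_trial(z)$scores)))

  # arithmetic-mean alternative agrees on the argmax here
  expect_equal(aggregate_trial(probs, method = "mean_prob")$class, 1L)
})

test_that("ANN agrees with an independent classifier on the same task", {
  skip_if_not_installed("nnet")
  d <- gaussian_classes(60, 6, gap = 3, seed = 44)
  idx <- withr::with_seed(44, sample(120))
  tr <- idx[1:84]; va <- idx[85:102]; te <- idx[103:120]
  cfg <- ann_config(input_dim = 6, n_classes = 2, hidden_nodes = 16, seed = 1)
  ours <- train_ann(d$x[tr, ], d$y[tr], cfg, d$x[va, ], d$y[va])
  acc_ours <- mean(predict(ours, d$x[te, ], type = "class") == d$y[te])
  ref <- nnet::nnet(d$x[tr, ], class.ind <- stats::model.matrix(
    ~ factor(d$y[tr]) - 1), size = 16, softmax = TRUE, trace = FALSE,
    maxit = 200)
  acc_ref <- mean(max.col(predict(ref, d$x[te, ])) == d$y[te])
  expect_lt(abs(acc_ours - acc_ref), 0.15)
})
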