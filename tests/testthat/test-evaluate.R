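test_that("stratified splits honour the 70/15/15 ratios and determinism", {
  info <- tibble::tibble(id = sprintf("t%03d", 1:500),
                         label = rep(1:5, each = 100), subject = 1L)
  plan <- split_data(info, n_repeats = 3, seed = 5)
  for (r in 1:3) {
    counts <- table(plan$assignment$split[plan$assignment$rep == r])
    expect_equal(unname(counts["train"]), 350)
    expect_equal(unname(counts["validation"]), 75)
    expect_equal(unname(counts["test"]), 75)
  }
  # stratification: per class within one trial of the target
  asg <- dplyr::left_join(plan$assignment, info, by = "id")
  strat <- dplyr::count(asg[asg$rep == 1 & asg$split == "test", ], label)
  expect_true(all(abs(strat$n - 15) <= 1))

  expect_identical(split_data(info, n_repeats = 3, seed = 5)$assignment,
                   plan$assignment)
  expect_false(identical(split_data(info, n_repeats = 3, seed = 6)$assignment,
                         plan$assignment))
  expect_warning(split_data(tibble::tibble(id = c("a", "b"),
                                           label = c(1L, 2L), subject = 1L)),
                 "stratif")
})

test_that("augmented trials always inherit their parent's split", {
  cfg <- tiny_config()
  aug <- augment_shift(generate_dataset(cfg), c(100, 200))
  plan <- split_data(aug, n_repeats = 2, seed = 3)
  asg <- dplyr::left_join(plan$assignment,
                          aug$info[, c("id", "parent_id")], by = "id")
  expect_equal(nrow(asg), 2 * length(aug))   # every trial assigned per repeat
  kids <- asg[!is.na(asg$parent_id), ]
  parents <- asg[is.na(asg$parent_id), ]
  joined <- dplyr::inner_join(
    kids, parents, by = c("parent_id" = "id", "rep" = "rep"),
    suffix = c("_kid", "_par"))
  expect_equal(nrow(joined), nrow(kids))     # exhaustive audit over all pairs
  expect_true(all(joined$split_kid == joined$split_par))
})

test_that("confusion tallies match a brute-force loop and report both accuracy flavours", {
  withr::with_seed(51, {
    truth <- sample(0:3, 200, replace = TRUE)
    pred <- ifelse(runif(200) < 0.6, truth, sample(0:3, 200, replace = TRUE))
    cs <- confusion_and_accuracy(truth, pred, labels = 0:3)
    manual <- matrix(0L, 4, 4)
    for (i in seq_along(truth)) {
      manual[truth[i] + 1, pred[i] + 1] <- manual[truth[i] + 1, pred[i] + 1] + 1L
    }
    expect_equal(unname(cs$confusion), manual)
    expect_equal(cs$overall_accuracy, 100 * mean(truth == pred))
    # overall equals the row-count-weighted mean of per-class accuracies
    expect_equal(cs$overall_accuracy,
                 sum(cs$per_class$accuracy * cs$per_class$n) /
                   sum(cs$per_class$n))
  })

  perfect <- confusion_and_accuracy(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(diag(perfect$confusion) == 1))
  expect_equal(perfect$average_accuracy, 100)
  expect_error(confusion_and_accuracy(integer(), integer()), "empty")
})

test_that("one-vs-rest AUC matches the Mann-Whitney concordance count", {
  # 6-point toy example, worked by exhaustive pairwise concordance
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  truth <- c(1, 1, 2, 1, 2, 2)
  scores <- cbind(s, 1 - s)
  auc <- roc_auc_ovr(scores, truth, labels = c(1, 2))
  pos <- s[truth == 1]; neg <- s[truth == 2]
  conc <- sum(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))) / (length(pos) * length(neg))
  expect_equal(auc$per_class$auc[1], conc)

  # perfect separation
  perf <- roc_auc_ovr(cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8)),
                      c(1, 1, 2, 2), labels = c(1, 2))
  expect_equal(perf$per_class$auc, c(1, 1))

  # label-independent scores: macro AUC near 1/2
  withr::with_seed(52, {
    n <- 2000
    sc <- matrix(runif(3 * n), n)
    sc <- sc / rowSums(sc)
    truth <- sample(1:3, n, replace = TRUE)
    null_auc <- roc_auc_ovr(sc, truth, labels = 1:3)
    expect_lt(abs(null_auc$macro_auc - 0.5), 0.03)
  })

  # absent class is flagged as undefined
  expect_warning(partial <- roc_auc_ovr(cbind(c(0.9, 0.1), c(0.1, 0.9)),
                                        c(1, 1), labels = c(1, 2)),
                 "undefined")
  expect_true(is.na(partial$per_class$auc[2]))
})

test_that("our AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    n <- 300
    s <- c(rnorm(n / 2, 1), rnorm(n / 2))
    truth <- rep(c(1, 2), each = n / 2)
    ours <- roc_auc_ovr(cbind(s, -s), truth, labels = c(1, 2))
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(truth == 1, s, direction = "<"))))
    expect_equal(ours$per_class$auc[1], ref, tolerance = 1e-9)
  })
})

test_that("the exact binomial chance level behaves as the distribution dictates", {
  # single trial: no accuracy is significant, threshold caps at 100%
  expect_equal(chance_level(1, 5), 100)
  # large n: converges to 100/K
  expect_lt(chance_level(1e6, 5), 20.2)
  expect_gte(chance_level(1e6, 5), 20)
  # always at least 100/K and non-increasing in n
  ns <- c(10, 30, 60, 100, 300, 1000)
  th <- vapply(ns, chance_level, numeric(1), n_classes = 5)
  expect_true(all(th >= 20))
  expect_true(all(diff(th) <= 1e-9))
  # the exact threshold is itself unlikely under the null...
  th300 <- chance_level(300, 5)
  k <- th300 / 100 * 300
  expect_lte(stats::pbinom(k - 1, 300, 0.2, lower.tail = FALSE), 0.05)
  # ...and one trial fewer is not
  expect_gt(stats::pbinom(k - 2, 300, 0.2, lower.tail = FALSE), 0.05)
  expect_error(chance_level(100, 5, alpha = 1.5), "alpha")
  expect_error(chance_level(100, 1), "n_classes")
})

test_that("method comparisons reproduce the textbook paired t statistic", {
  # 4-element hand example
  a <- c(80, 85, 90, 88)
  b <- c(75, 82, 84, 86)
  d <- a - b
  t_hand <- mean(d) / (stats::sd(d) / sqrt(4))
  res <- compare_methods(a, b)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 3)

  # identical arrays: zero difference everywhere -> t = 0, p = 1, flagged
  same <- compare_methods(c(70, 75.001, 80), c(70, 75.001, 80))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$flag, "zero-variance")

  # constant positive offset with tiny noise: decisive
  withr::with_seed(54, {
    b8 <- rnorm(8, 80, 1)
    a8 <- b8 + 5 + rnorm(8, sd = 0.01)
    expect_lt(compare_methods(a8, b8)$p_value, 0.001)
  })

  # one-sample against chance, one-tailed
  acc <- c(55, 60, 58, 62)
  vs <- compare_methods(acc, chance = 30)
  tt <- stats::t.test(acc, mu = 30, alternative = "greater")
  expect_equal(vs$p_value, tt$p.value)
  expect_equal(vs$alternative, "greater")

  expect_error(compare_methods(a), "supply")
  expect_error(compare_methods(a, b[1:2]), "equal length")
})

test_that("pairwise comparison table carries a Holm-adjusted column", {
  withr::with_seed(55, {
    acc <- data.frame(ann = rnorm(6, 80, 2), st = rnorm(6, 88, 2),
                      sst = rnorm(6, 92, 2))
    out <- compare_all_methods(acc)
    expect_equal(nrow(out), 3)
    expect_true(all(out$p_holm >= out$p_value - 1e-12))
  })
})

test_that("run_pipeline validates its inputs and reports the declared structure", {
  cfg <- tiny_config()
  ds <- generate_dataset(cfg)
  expect_error(run_pipeline(ds, "production", "svm"), "valid options")
  expect_error(run_pipeline(ds, "sleep", "ann"), "valid options")
  empty <- ds[0]
  expect_error(run_pipeline(empty, "production", "ann"), "empty")

  rep1 <- run_pipeline(ds, "production", "ann", n_repeats = 1, seed = 2,
                       ann_opts = list(hidden_nodes = 8, max_epochs = 10))
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1$accuracy), 1)
  expect_true(all(rep1$accuracy$accuracy >= 0 & rep1$accuracy$accuracy <= 100))
  g <- glance(rep1)
  expect_true(all(c("mean_accuracy", "chance_level", "macro_auc") %in%
                    names(g)))
  expect_equal(sum(rep1$confusion$confusion), sum(rep1$accuracy$n_test))
})
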