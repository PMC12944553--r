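test_that("fusion concatenates blocks in canonical order with bookkeeping", {
  n <- 6
  fa <- matrix(rnorm(n * 35), n); df <- matrix(rnorm(n * 128), n)
  ac <- matrix(rnorm(n * 88), n)
  full <- fuse_features(fa, df, ac)
  expect_equal(ncol(full), 251)
  expect_equal(attr(full, "blocks"),
               list(fauf = 1:35, dflgf = 36:163, acoustic = 164:251))
  expect_equal(full[, 1:35], fa)

  vis <- fuse_features(fauf = fa, dflgf = df,
                       channels = c("fauf", "dflgf"))
  expect_equal(ncol(vis), 163)
  aco <- fuse_features(acoustic = ac, channels = "acoustic")
  expect_equal(ncol(aco), 88)

  expect_error(fuse_features(fa, df[, 1:100], ac), "128")
  expect_error(fuse_features(fa, df[1:3, ], ac), "disagree")
  expect_error(fuse_features(fauf = NULL, dflgf = df, acoustic = ac),
               "missing")
})

test_that("the fused network has the printed layer sizes and counts", {
  set.seed(12)
  x <- matrix(rnorm(60 * 251), 60)
  y <- factor(rep(c("control", "mild", "moderate", "severe"), 15))
  net <- vacp_net(x, y, epochs = 3)
  expect_equal(net$dims, c(251, 128, 64, 32, 4))
  expect_equal(net$n_parameters, 42724)
  expect_equal(count_parameters(gcn_encoder(), net), 42724 + 4816)
})

test_that("training is deterministic and fits separable data", {
  set.seed(14)
  x <- rbind(matrix(rnorm(40 * 10, 0), 40),
             matrix(rnorm(40 * 10, 4), 40))
  y <- factor(rep(c("a", "b"), each = 40))
  n1 <- vacp_net(x, y, epochs = 30, seed = 5)
  n2 <- vacp_net(x, y, epochs = 30, seed = 5)
  expect_identical(n1$weights, n2$weights)
  expect_equal(mean(predict(n1, x) == y), 1)
  probs <- predict(n1, x, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, 80), tolerance = 1e-9)
  expect_error(vacp_net(x, factor(rep("a", 80))), "single class")
})

test_that("stratified splits hold out a fifth of every class", {
  y <- factor(rep(c("a", "b", "c", "d"), each = 25))
  for (s in 0:4) {
    sp <- vacp:::stratified_split(y, 0.2, seed = s)
    expect_equal(unname(table(y[sp$test])), rep(5L, 4), ignore_attr = TRUE)
    expect_length(intersect(sp$train, sp$test), 0)
  }
})

test_that("evaluation reports per-split metrics and a stochastic confusion", {
  set.seed(16)
  x <- do.call(rbind, lapply(0:3, function(k)
    matrix(rnorm(30 * 8, 5 * k), 30)))
  y <- factor(rep(c("control", "mild", "moderate", "severe"), each = 30),
              levels = c("control", "mild", "moderate", "severe"))
  ev <- evaluate_model(x, y, classifier_spec("dnn", epochs = 30))
  expect_equal(nrow(ev$per_split), 5)
  expect_equal(ev$split_seeds, 0:4)
  expect_equal(unname(rowSums(ev$confusion)), rep(1, 4), tolerance = 1e-9)
  # well-separated classes: near-perfect accuracy, diagonal confusion
  expect_gt(ev$mean_accuracy, 0.95)
  expect_gt(min(diag(ev$confusion)), 0.8)
  # macro-F1 equals accuracy for a diagonal confusion on balanced data
  expect_equal(ev$mean_f1, ev$mean_accuracy, tolerance = 0.05)
  expect_lte(ev$mean_f1, 1)

  # bit-for-bit reproducibility under the same seeds
  ev2 <- evaluate_model(x, y, classifier_spec("dnn", epochs = 30))
  expect_identical(ev$per_split, ev2$per_split)
  expect_identical(ev$confusion, ev2$confusion)

  sparse <- c(1:4, 31:34, 61:64, 91:94)  # four samples per class
  expect_error(evaluate_model(x[sparse, ], y[sparse],
                              classifier_spec("dnn")), "at least 5")
})

test_that("macro F1 averages per-class harmonic scores", {
  truth <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  pred <- factor(c("a", "b", "b", "b"), levels = c("a", "b"))
  # class a: P=1, R=0.5, F1=2/3; class b: P=2/3, R=1, F1=0.8
  expect_equal(vacp:::macro_f1(truth, pred), mean(c(2 / 3, 0.8)))
})

test_that("baseline classifiers train through the common interface", {
  set.seed(18)
  x <- rbind(matrix(rnorm(40 * 6, 0), 40), matrix(rnorm(40 * 6, 3), 40))
  y <- factor(rep(c("a", "b"), each = 40))
  for (kind in c("svm", "random_forest")) {
    fit <- train_classifier(x, y, classifier_spec(kind))
    expect_s3_class(fit, "vacp_classifier")
    expect_gt(mean(predict(fit, x) == y), 0.9)
  }
})

test_that("identical feature copies in two channels yield no fusion gain", {
  set.seed(20)
  x <- do.call(rbind, lapply(0:3, function(k)
    matrix(rnorm(20 * 35, 1.2 * k), 20)))
  y <- factor(rep(c("control", "mild", "moderate", "severe"), each = 20),
              levels = c("control", "mild", "moderate", "severe"))
  spec <- classifier_spec("dnn", epochs = 40)
  single <- evaluate_model(x, y, spec)$mean_accuracy
  dup <- evaluate_model(cbind(x, x), y, spec)$mean_accuracy
  expect_lt(abs(dup - single), 0.1)
})
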