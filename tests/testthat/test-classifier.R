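test_that("the feature-length trace reproduces the published layer shapes", {
  tr <- model_feature_trace(classifier_config())
  expect_identical(tr$conv_lengths, c(25L, 25L, 11L, 9L, 7L, 3L, 1L))
  expect_identical(tr$flatten_width, 64L)
  expect_identical(tr$dense_units, c(8L, 4L, 1L))
  m <- build_model(classifier_config())
  expect_identical(ncol(m$weights$Wd3), 1L) # scalar probability output
})

test_that("configurations that collapse the stack or break contracts error", {
  expect_error(model_feature_trace(classifier_config(input_len = 8)), "collapses")
  expect_error(classifier_config(val_fraction = 0), "val_fraction")
  expect_error(classifier_config(conv_filters = c(8, 8)), "conv_filters")
})

test_that("weight initialization is a deterministic function of the seed", {
  m1 <- build_model(classifier_config(seed = 5))
  m2 <- build_model(classifier_config(seed = 5))
  m3 <- build_model(classifier_config(seed = 6))
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("backpropagated gradients match finite differences", {
  cfg <- classifier_config(conv_filters = c(2L, 2L, 2L, 2L, 3L),
                           dense_units = c(3L, 2L), dropout_rate = 0, seed = 3)
  model <- build_model(cfg)
  set.seed(1)
  # move zero-initialized biases off the ReLU kink, where the two-sided
  # finite difference and the subgradient legitimately disagree
  for (nm in grep("^b", names(model$weights), value = TRUE))
    model$weights[[nm]] <- rnorm(length(model$weights[[nm]]), 0, 0.05)
  X <- matrix(rnorm(6 * 27), 6, 27)
  y <- c(0, 1, 1, 0, 1, 0)
  fw <- ppgthreat:::nn_forward(model, X, train = FALSE)
  g <- ppgthreat:::nn_backward(model, fw, y)
  loss_at <- function(m) {
    p <- ppgthreat:::nn_forward(m, X, train = FALSE)$prob
    ppgthreat:::bce_loss(p, y)
  }
  eps <- 1e-6
  for (nm in c("Wc1", "Wc3", "Wc5", "bc2", "Wd1", "Wd3", "bd3")) {
    w <- model$weights[[nm]]
    idx <- seq_len(min(4, length(w)))
    for (i in idx) {
      mp <- model; mp$weights[[nm]][i] <- w[i] + eps
      mm <- model; mm$weights[[nm]][i] <- w[i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]][i]), num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("the validation split is stratified, disjoint and a function of the seed", {
  y <- rep(c(0L, 1L), c(120, 80))
  s1 <- stratified_split(y, 0.2, seed = 9)
  s2 <- stratified_split(y, 0.2, seed = 9)
  s3 <- stratified_split(y, 0.2, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1$val, s3$val))
  expect_length(intersect(s1$train, s1$val), 0)
  expect_setequal(c(s1$train, s1$val), seq_along(y))
  expect_equal(sum(y[s1$val] == 0), 24L) # floor(120 * 0.2)
  expect_equal(sum(y[s1$val] == 1), 16L)
})

test_that("training separates linearly separable pulse classes", {
  ps <- separable_pulses(n_per_class = 300, shift = 2, seed = 11)
  cfg <- classifier_config(seed = 2)
  m <- train_classifier(build_model(cfg), ps, cfg)
  expect_true(m$trained)
  expect_lte(nrow(m$history), 30L)
  pr <- predict_pulse(m, ps)
  expect_gt(mean(pr$label == ps$label), 0.95)
})

test_that("held-out accuracy on the separable benchmark exceeds 0.9 across seeds", {
  for (s in 1:5) {
    tr <- separable_pulses(n_per_class = 250, shift = 2, seed = 100 + s)
    te <- separable_pulses(n_per_class = 80, shift = 2, seed = 200 + s)
    cfg <- classifier_config(seed = s, max_epochs = 15)
    m <- train_classifier(build_model(cfg), tr, cfg)
    pr <- predict_pulse(m, te)
    expect_gt(mean(pr$label == te$label), 0.9, label = sprintf("seed %d", s))
  }
})

test_that("randomly shuffled labels give chance-level validation accuracy", {
  ps <- separable_pulses(n_per_class = 300, shift = 2, seed = 17)
  set.seed(5)
  ps$label <- sample(ps$label)
  cfg <- classifier_config(seed = 4, max_epochs = 10)
  m <- train_classifier(build_model(cfg), ps, cfg)
  expect_gt(utils::tail(m$history$val_acc, 1), 0.4)
  expect_lt(utils::tail(m$history$val_acc, 1), 0.6)
})

test_that("training is bit-reproducible for a fixed seed and data", {
  ps <- separable_pulses(n_per_class = 120, shift = 2, seed = 19)
  cfg <- classifier_config(seed = 8, max_epochs = 4)
  m1 <- train_classifier(build_model(cfg), ps, cfg)
  m2 <- train_classifier(build_model(cfg), ps, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("prediction contracts hold: probabilities, thresholds, arity", {
  ps <- separable_pulses(n_per_class = 120, shift = 3, seed = 21)
  cfg <- classifier_config(seed = 1, max_epochs = 6)
  m <- train_classifier(build_model(cfg), ps, cfg)
  # probability stays in [0, 1] even for wild inputs
  wild <- matrix(rnorm(20 * 27, 0, 1e4), 20, 27)
  pw <- predict_pulse(m, wild)
  expect_true(all(pw$prob >= 0 & pw$prob <= 1))
  # a pulse deep inside the class-1 manifold is labeled 1
  deep <- ps$values[which(ps$label == 1L)[1], , drop = FALSE] + 1
  expect_equal(predict_pulse(m, deep)$label, 1L)
  # threshold semantics: at 1.0 nothing is labeled 1 unless prob is exactly 1
  m100 <- m; m100$cfg$decision_threshold <- 1.0
  pr <- predict_pulse(m100, ps)
  expect_true(all(pr$label[pr$prob < 1] == 0L))
  expect_error(predict_pulse(m, rnorm(12)), "length")
})

test_that("training refuses single-class or unlabeled input", {
  ps <- separable_pulses(n_per_class = 100, seed = 23)
  only1 <- ps[ps$label == 1L]
  cfg <- classifier_config(seed = 1)
  expect_error(train_classifier(build_model(cfg), only1, cfg), "single class")
  na_ps <- ps; na_ps$label <- rep(NA_integer_, n_pulses(ps))
  expect_error(train_classifier(build_model(cfg), na_ps, cfg), "labeled")
})
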