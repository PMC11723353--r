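# The mixture fits below use shape_normalize = FALSE because the simulated
# clusters live on an abstract unit scale, not on an ADC-count pulse scale.
plain_settings <- function(...) {
  gmm_settings(shape_normalize = FALSE, n_restarts = 3, ...)
}

test_that("EM recovers the parameters of a well-separated two-component mixture", {
  ps <- two_cluster_pulses(n1 = 500, n2 = 500, sep = 10, seed = 7)
  m <- fit_class_gmm(ps, plain_settings(seed = 2), class_label = 0L)
  expect_equal(sort(m$weights), c(0.5, 0.5), tolerance = 0.05)
  # means back on the data scale, within 0.5 SD of truth per dimension
  mu <- sweep(sweep(m$means, 2, m$normalization$scale, "*"),
              2, m$normalization$center, "+")
  lo <- which.min(mu[, 1]); hi <- 3 - lo
  expect_true(all(abs(mu[lo, ] - 0) < 0.5))
  expect_true(all(abs(mu[hi, ] - 10) < 0.5))
})

test_that("the majority-weight component is designated normal", {
  ps <- two_cluster_pulses(n1 = 800, n2 = 200, sep = 10, seed = 3)
  m <- fit_class_gmm(ps, plain_settings(seed = 4), class_label = 1L)
  expect_equal(max(m$weights), 0.8, tolerance = 0.05)
  expect_equal(m$normal_component, which.max(m$weights))
  # the normal component's mean must be the big (origin) cluster
  mu_n <- m$means[m$normal_component, ] * m$normalization$scale + m$normalization$center
  expect_lt(mean(mu_n), 2)
})

test_that("degenerate and undersized inputs fail loudly", {
  same <- pulse_set(matrix(1, 100, 27), "w", 0L, 14L)
  expect_error(fit_class_gmm(same, plain_settings()), "degenerate")
  few <- two_cluster_pulses(n1 = 20, n2 = 20)
  expect_error(fit_class_gmm(few, plain_settings()), "at least")
  mixed <- two_cluster_pulses()
  mixed$label <- rep(c(0L, 1L), length.out = n_pulses(mixed))
  expect_error(fit_class_gmm(mixed, plain_settings()), "more than one class")
})

test_that("pulses at the component means classify to their components", {
  ps <- two_cluster_pulses(n1 = 700, n2 = 300, sep = 10, seed = 9)
  m <- fit_class_gmm(ps, plain_settings(seed = 1), class_label = 0L)
  mu <- sweep(sweep(m$means, 2, m$normalization$scale, "*"),
              2, m$normalization$center, "+")
  expect_equal(classify_pulse(m, mu[m$normal_component, ]), "normal")
  expect_equal(classify_pulse(m, mu[3 - m$normal_component, ]), "anomalous")
  # posterior responsibilities over the two components sum to one
  r <- ppgthreat:::normal_responsibility(m, ps$values)
  expect_true(all(r >= 0 & r <= 1))
  expect_error(classify_pulse(m, rnorm(5)), "length")
})

test_that("EM log-likelihood is non-decreasing along the winning trace", {
  ps <- two_cluster_pulses(seed = 15)
  m <- fit_class_gmm(ps, plain_settings(seed = 5), class_label = 0L)
  tr <- m$fit_meta$loglik_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) > -1e-8))
})

test_that("our EM agrees with an independent mixture implementation", {
  suppressMessages(library(mclust)) # Mclust resolves helpers by name
  ps <- two_cluster_pulses(n1 = 400, n2 = 200, sep = 8, seed = 23)
  m <- fit_class_gmm(ps, plain_settings(covariance_type = "full", seed = 6),
                     class_label = 0L)
  X <- ppgthreat:::apply_normalization(ps$values, m$normalization)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ours <- classify_pulse(m, ps$values) == "normal"
  theirs <- ref$classification == which.max(ref$parameters$pro)
  expect_gt(max(mean(ours == theirs), mean(ours != theirs)), 0.98)
  expect_equal(sort(m$weights), sort(ref$parameters$pro), tolerance = 0.03)
})

test_that("training selection keeps exactly each class's own normal group", {
  p0 <- two_cluster_pulses(n1 = 600, n2 = 200, sep = 8, seed = 31)
  p0$label <- rep(0L, n_pulses(p0))
  p1 <- two_cluster_pulses(n1 = 550, n2 = 250, sep = 8, seed = 32)
  p1$label <- rep(1L, n_pulses(p1))
  m0 <- fit_class_gmm(p0, plain_settings(seed = 7), class_label = 0L)
  m1 <- fit_class_gmm(p1, plain_settings(seed = 8), class_label = 1L)
  ft <- filter_training(p0, p1, m0, m1)
  v1 <- classify_pulse(m1, p1)
  expect_identical(ft$kept1$values, p1$values[v1 == "normal", , drop = FALSE])
  expect_lte(n_pulses(ft$kept0), n_pulses(p0))
  expect_lte(n_pulses(ft$kept1), n_pulses(p1))
  expect_equal(ft$report$retention_1, mean(v1 == "normal"))
  expect_error(filter_training(p1, p0, m0, m1), "labels do not match")
})

test_that("test filtering removes exactly the pulses both models call anomalous", {
  p0 <- two_cluster_pulses(n1 = 600, n2 = 200, sep = 8, seed = 41)
  p1 <- two_cluster_pulses(n1 = 550, n2 = 250, sep = 8, seed = 42)
  p0$label <- rep(0L, n_pulses(p0))
  p1$label <- rep(1L, n_pulses(p1))
  m0 <- fit_class_gmm(p0, plain_settings(seed = 9), class_label = 0L)
  m1 <- fit_class_gmm(p1, plain_settings(seed = 10), class_label = 1L)
  test_pulses <- bind_pulses(p0[1:100], p1[1:100])
  v0 <- classify_pulse(m0, test_pulses)
  v1 <- classify_pulse(m1, test_pulses)
  res <- filter_test(test_pulses, m0, m1)
  expect_identical(res$keep, v0 == "normal" | v1 == "normal")
  expect_equal(res$report$removal_fraction, mean(!res$keep))
  # empty input passes through
  empty <- filter_test(test_pulses[0], m0, m1)
  expect_equal(n_pulses(empty$kept), 0L)
  # a pulse kept for training under its own model is never test-removed
  ft <- filter_training(p0, p1, m0, m1)
  kept_tr <- bind_pulses(ft$kept0, ft$kept1)
  expect_true(all(filter_test(kept_tr, m0, m1)$keep))
})

test_that("on ambiguously labeled synthetic data the filter targets non-responders", {
  # default-condition dataset whose subject draws leave the two physiologies
  # separable; the class-1 anomalous group must be enriched in non-responder
  # provenance and retention must be materially below 1
  cfg <- synth_config(seed = 101)
  ds <- generate_dataset(cfg)
  prep <- preprocess_dataset(ds, filter_config())
  pulses <- prep$pulses
  nonresp <- stats::setNames(ds$manifest$is_nonresponder, ds$manifest$window_id)
  gmm_norm <- compute_normalization(
    ppgthreat:::shape_normalize_values(pulses$values))
  p1 <- pulses[pulses$label == 1L]
  m1 <- fit_class_gmm(p1, gmm_settings(seed = 1), gmm_norm, class_label = 1L)
  removed <- classify_pulse(m1, p1) == "anomalous"
  expect_lt(mean(!removed), 0.95)
  enrichment <- mean(nonresp[p1$window_id][removed]) /
    mean(nonresp[p1$window_id][!removed])
  expect_gte(enrichment, 2)
})

test_that("PCA projection behaves as a centered eigen-decomposition", {
  # rank-1 data: a line in 27-dim space
  set.seed(2)
  dir27 <- rnorm(27)
  X <- outer(rnorm(50), dir27)
  pr <- pca_project(X, 2)
  expect_equal(pr$explained_variance[1], 1, tolerance = 1e-10)
  # centering: scores average to the origin
  ps <- two_cluster_pulses(seed = 51)
  pr2 <- pca_project(ps, 3)
  expect_equal(unname(colMeans(pr2$scores)), rep(0, 3), tolerance = 1e-8)
  expect_true(all(diff(pr2$explained_variance) <= 1e-12))
  expect_error(pca_project(ps$values[1, , drop = FALSE], 2), "at least")
})
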