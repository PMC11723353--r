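# Mixture-model label-noise filtering. One 2-component full-covariance
# Gaussian mixture is fitted per class over 27-dimensional pulses; the
# majority-weight component is designated "normal" (label-consistent), the
# other "anomalous" (ambiguous). Training keeps a class's pulses that are
# normal under that class's own model; at test time a pulse is removed only
# when both class models call it anomalous (indiscernible).

#' EM settings for class mixture models
#'
#' @param n_restarts number of k-means-seeded EM restarts; the best final
#'   log-likelihood wins.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the change in per-observation mean
#'   log-likelihood.
#' @param reg diagonal regularization added to each covariance (data are
#'   standardized before fitting, so this is on unit scale).
#' @param covariance_type `"tied"` (default: one pooled full covariance
#'   shared by both components) or `"full"` (per-component). With
#'   per-component covariances and strongly clustered subjects, EM can
#'   maximize likelihood by collapsing one component onto a single subject's
#'   tight pulse cluster; tying the covariance removes that failure mode and
#'   keeps the split on the normal-versus-anomalous axis.
#' @param min_pulses minimum pulses required to fit a class model.
#' @param shape_normalize if `TRUE` (default), each pulse is divided by its
#'   maximum absolute value before standardization, so the mixture judges
#'   waveform shape rather than subject-specific gain (wrist-PPG amplitude
#'   is dominated by contact pressure and skin optics, not affective state).
#' @param seed RNG seed controlling initialization.
#' @return a `gmm_settings` list.
#' @export
gmm_settings <- function(n_restarts = 10L, max_iter = 200L, tol = 1e-4,
                         reg = 1e-6, covariance_type = c("tied", "full"),
                         min_pulses = 50L, shape_normalize = TRUE,
                         seed = 1L) {
  list(n_restarts = check_positive_int(n_restarts, "n_restarts"),
       max_iter = check_positive_int(max_iter, "max_iter"),
       tol = check_nonneg(tol, "tol"),
       reg = check_nonneg(reg, "reg"),
       covariance_type = match.arg(covariance_type),
       min_pulses = check_positive_int(min_pulses, "min_pulses"),
       shape_normalize = isTRUE(shape_normalize),
       seed = as.integer(seed))
}

# Per-pulse peak normalization: unit maximum absolute amplitude.
shape_normalize_values <- function(values) {
  mx <- apply(abs(values), 1, max)
  mx[mx < 1e-12] <- 1
  values / mx
}

#' Per-dimension standardization statistics
#'
#' Computed once on the pooled training pulses and shared between the
#' mixture models and the pulse classifier, so both operate in the same
#' normalized space (raw ~10^4-count amplitudes would dominate conditioning).
#'
#' @param values numeric matrix, pulses in rows.
#' @return list with `center` and `scale` vectors (zero SDs replaced by 1).
#' @export
compute_normalization <- function(values) {
  ctr <- colMeans(values)
  scl <- apply(values, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = as.numeric(ctr), scale = as.numeric(scl))
}

apply_normalization <- function(values, norm) {
  sweep(sweep(values, 2, norm$center, "-"), 2, norm$scale, "/")
}

# Log-density of rows of X under N(mu, sigma), via Cholesky.
dmvnorm_log <- function(X, mu, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

em_once <- function(X, z0, settings) {
  n <- nrow(X); d <- ncol(X)
  tied <- settings$covariance_type %||% "tied"
  resp <- cbind(z0, 1 - z0)
  loglik_trace <- numeric(0)
  prev <- -Inf
  w <- c(0.5, 0.5); mu <- list(); sig <- list()
  for (iter in seq_len(settings$max_iter)) {
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-8)
    w <- nk / n
    for (k in 1:2) {
      mu[[k]] <- colSums(X * resp[, k]) / nk[k]
      Xc <- sweep(X, 2, mu[[k]], "-")
      sig[[k]] <- crossprod(Xc * resp[, k], Xc)
    }
    if (tied == "tied") {
      S <- (sig[[1]] + sig[[2]]) / n + diag(settings$reg, d)
      sig[[1]] <- sig[[2]] <- S
    } else {
      for (k in 1:2) sig[[k]] <- sig[[k]] / nk[k] + diag(settings$reg, d)
    }
    # E step
    lp <- cbind(log(w[1]) + dmvnorm_log(X, mu[[1]], sig[[1]]),
                log(w[2]) + dmvnorm_log(X, mu[[2]], sig[[2]]))
    lse <- logsumexp2(lp[, 1], lp[, 2])
    resp <- exp(lp - lse)
    ll <- mean(lse)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(prev) && abs(ll - prev) < settings$tol) break
    prev <- ll
  }
  list(weights = w, means = mu, covariances = sig,
       loglik = ll, iterations = length(loglik_trace),
       loglik_trace = loglik_trace)
}

#' Fit a 2-component Gaussian mixture for one class of pulses
#'
#' Pulses are standardized with `normalization` (computed from the input if
#' not supplied), then a 2-component full-covariance mixture is fitted by EM
#' with k-means initialization and multiple restarts. The component with the
#' larger mixture weight is designated `normal_component` (ties broken by
#' smaller covariance determinant): the method presumes correctly-responding
#' subjects are the majority, so the minority component captures ambiguous,
#' likely-mislabeled pulses.
#'
#' @param pulses a [pulse_set()] containing a single class's pulses.
#' @param settings a [gmm_settings()].
#' @param normalization optional shared statistics from
#'   [compute_normalization()].
#' @param class_label the class these pulses belong to (0/1); taken from the
#'   pulse labels when `NULL`.
#' @return a `gmm_class_model`: `class_label`, `weights`, `means` (2 x d),
#'   `covariances` (list of two d x d matrices), `normal_component`,
#'   `normalization`, `fit_meta` (seed, log-likelihood, iterations, trace,
#'   convergence flag).
#' @export
fit_class_gmm <- function(pulses, settings = gmm_settings(),
                          normalization = NULL, class_label = NULL) {
  X0 <- if (inherits(pulses, "pulse_set")) pulses$values else as.matrix(pulses)
  if (is.null(class_label)) {
    labs <- unique(stats::na.omit(if (inherits(pulses, "pulse_set")) pulses$label else integer(0)))
    if (length(labs) > 1L)
      stop("fit_class_gmm(): pulses contain more than one class", call. = FALSE)
    class_label <- if (length(labs) == 1L) labs else NA_integer_
  }
  if (nrow(X0) < settings$min_pulses)
    stop(sprintf("fit_class_gmm(): need at least %d pulses, got %d",
                 settings$min_pulses, nrow(X0)), call. = FALSE)
  if (all(apply(X0, 2, stats::sd) < 1e-12))
    stop("fit_class_gmm(): degenerate input (all pulses identical)", call. = FALSE)
  if (settings$shape_normalize) X0 <- shape_normalize_values(X0)
  if (is.null(normalization)) normalization <- compute_normalization(X0)
  X <- apply_normalization(X0, normalization)

  best <- NULL
  for (r in seq_len(settings$n_restarts)) {
    set.seed(derive_seed(settings$seed, 11L, r))
    km <- tryCatch(stats::kmeans(X, centers = 2L, nstart = 1L, iter.max = 25L),
                   error = function(e) NULL)
    z0 <- if (is.null(km)) as.numeric(stats::runif(nrow(X)) < 0.5)
          else as.numeric(km$cluster == 1L)
    fit <- tryCatch(em_once(X, z0, settings), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("fit_class_gmm(): EM failed in every restart (degenerate data?)", call. = FALSE)

  # majority-weight component is "normal"; tie -> smaller covariance determinant
  nc <- if (abs(best$weights[1] - best$weights[2]) > 1e-9) {
    which.max(best$weights)
  } else {
    which.min(vapply(best$covariances, function(S) determinant(S)$modulus, numeric(1)))
  }
  structure(list(class_label = class_label,
                 weights = best$weights,
                 means = rbind(best$means[[1]], best$means[[2]]),
                 covariances = best$covariances,
                 normal_component = as.integer(nc),
                 normalization = normalization,
                 shape_normalize = settings$shape_normalize,
                 fit_meta = list(seed = settings$seed, loglik = best$loglik,
                                 iterations = best$iterations,
                                 loglik_trace = best$loglik_trace,
                                 converged = best$iterations < settings$max_iter)),
            class = "gmm_class_model")
}

#' @export
print.gmm_class_model <- function(x, ...) {
  cat(sprintf("gmm_class_model (class %s): weights %.3f/%.3f, normal component %d, loglik %.3f\n",
              x$class_label, x$weights[1], x$weights[2], x$normal_component,
              x$fit_meta$loglik))
  invisible(x)
}

# Posterior responsibility of the designated normal component, per pulse.
normal_responsibility <- function(model, values) {
  if (!inherits(model, "gmm_class_model"))
    stop("classify_pulse(): model is not a fitted gmm_class_model", call. = FALSE)
  values <- as.matrix(values)
  if (isTRUE(model$shape_normalize)) values <- shape_normalize_values(values)
  X <- apply_normalization(values, model$normalization)
  lp1 <- log(model$weights[1]) + dmvnorm_log(X, model$means[1, ], model$covariances[[1]])
  lp2 <- log(model$weights[2]) + dmvnorm_log(X, model$means[2, ], model$covariances[[2]])
  lse <- logsumexp2(lp1, lp2)
  resp <- cbind(exp(lp1 - lse), exp(lp2 - lse))
  resp[, model$normal_component]
}

#' Classify pulses as normal or anomalous under one class model
#'
#' A pulse is "normal" when the posterior responsibility of the designated
#' normal component is at least 0.5 (hard assignment).
#'
#' @param model a fitted `gmm_class_model`.
#' @param pulse a [pulse_set()], or a numeric matrix/vector of pulse values.
#' @return character vector of `"normal"` / `"anomalous"`, one per pulse.
#' @export
classify_pulse <- function(model, pulse) {
  vals <- if (inherits(pulse, "pulse_set")) pulse$values else rbind(pulse)
  if (ncol(vals) != ncol(model$means))
    stop(sprintf("classify_pulse(): pulse length %d, model expects %d",
                 ncol(vals), ncol(model$means)), call. = FALSE)
  ifelse(normal_responsibility(model, vals) >= 0.5, "normal", "anomalous")
}

#' Select trainable pulses for both classes
#'
#' Under the default `"own_normal"` rule, a class-c training pulse is kept
#' iff it is normal under class c's own model, i.e. only the normal groups
#' from each class enter training. The alternative `"both_abnormal"` rule
#' removes a pulse only when both models call it anomalous.
#'
#' @param pulses0,pulses1 [pulse_set()]s of class-0 and class-1 training pulses.
#' @param model0,model1 the corresponding fitted `gmm_class_model`s.
#' @param rule `"own_normal"` (default) or `"both_abnormal"`.
#' @return list with `kept0`, `kept1` (subsets of the inputs) and `report`
#'   (per-class retention fractions and counts).
#' @export
filter_training <- function(pulses0, pulses1, model0, model1,
                            rule = c("own_normal", "both_abnormal")) {
  rule <- match.arg(rule)
  if (!is.na(model0$class_label) && !all(stats::na.omit(pulses0$label) == model0$class_label))
    stop("filter_training(): pulses0 labels do not match model0's class", call. = FALSE)
  if (!is.na(model1$class_label) && !all(stats::na.omit(pulses1$label) == model1$class_label))
    stop("filter_training(): pulses1 labels do not match model1's class", call. = FALSE)
  keep_rule <- function(p, own, other) {
    if (n_pulses(p) == 0) return(logical(0))
    if (rule == "own_normal") classify_pulse(own, p) == "normal"
    else classify_pulse(own, p) == "normal" | classify_pulse(other, p) == "normal"
  }
  k0 <- keep_rule(pulses0, model0, model1)
  k1 <- keep_rule(pulses1, model1, model0)
  list(kept0 = pulses0[k0], kept1 = pulses1[k1],
       report = list(rule = rule,
                     n_in_0 = n_pulses(pulses0), n_kept_0 = sum(k0),
                     n_in_1 = n_pulses(pulses1), n_kept_1 = sum(k1),
                     retention_0 = if (n_pulses(pulses0)) mean(k0) else NA_real_,
                     retention_1 = if (n_pulses(pulses1)) mean(k1) else NA_real_))
}

#' Remove indiscernible test pulses
#'
#' Under the default `"both_abnormal"` rule a test pulse is removed iff it is
#' anomalous under both class models — neither class claims it, so it cannot
#' be discerned. The `"own_normal"` alternative requires labels and keeps a
#' pulse iff normal under its own class's model.
#'
#' @param pulses a [pulse_set()].
#' @param model0,model1 fitted `gmm_class_model`s for classes 0 and 1.
#' @param rule `"both_abnormal"` (default) or `"own_normal"`.
#' @return list with `kept` (a `pulse_set`), `keep` (logical vector) and
#'   `report` (removal fraction and counts).
#' @export
filter_test <- function(pulses, model0, model1,
                        rule = c("both_abnormal", "own_normal")) {
  rule <- match.arg(rule)
  if (n_pulses(pulses) == 0) {
    return(list(kept = pulses, keep = logical(0),
                report = list(rule = rule, n_in = 0L, n_kept = 0L,
                              removal_fraction = NA_real_)))
  }
  if (rule == "both_abnormal") {
    keep <- classify_pulse(model0, pulses) == "normal" |
            classify_pulse(model1, pulses) == "normal"
  } else {
    if (anyNA(pulses$label))
      stop("filter_test(): own_normal rule requires pulse labels", call. = FALSE)
    v0 <- classify_pulse(model0, pulses) == "normal"
    v1 <- classify_pulse(model1, pulses) == "normal"
    keep <- ifelse(pulses$label == 0L, v0, v1)
  }
  list(kept = pulses[keep], keep = keep,
       report = list(rule = rule, n_in = n_pulses(pulses), n_kept = sum(keep),
                     removal_fraction = 1 - mean(keep)))
}

#' Project pulses onto principal components (diagnostics)
#'
#' Centered linear PCA projection of pulse vectors, used to visualize how the
#' mixture filtering separates the classes in two dimensions.
#'
#' @param pulses a [pulse_set()] or numeric matrix.
#' @param n_components number of components to return.
#' @return list with `scores` (n x n_components), `explained_variance`
#'   (variance fractions, non-increasing) and `rotation`.
#' @export
pca_project <- function(pulses, n_components = 2L) {
  X <- if (inherits(pulses, "pulse_set")) pulses$values else as.matrix(pulses)
  if (nrow(X) < max(2L, n_components))
    stop("pca_project(): need at least as many pulses as components (>= 2)", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}
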