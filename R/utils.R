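# Internal helpers: validation, seed derivation, numerics.

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop_cfg(name, "must be a positive integer")
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_cfg(name, "must be a nonnegative number")
  as.numeric(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_cfg(name, "must lie in [0, 1]")
  as.numeric(x)
}

#' Derive a reproducible sub-stream seed
#'
#' Combines a root seed with integer keys (subject index, window index,
#' stage tags ...) into a deterministic 31-bit seed, so every random draw in
#' the package has its own stream independent of generation order.
#'
#' @param root integer root seed.
#' @param ... integer keys identifying the sub-stream.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(root, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(root) %% m
  for (k in c(...)) {
    h <- (h * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

# Stable hash of an R object for run manifests: md5 of its canonical JSON.
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically safe binary cross-entropy.
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
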