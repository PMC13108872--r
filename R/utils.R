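# Internal helpers shared across modules.

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range R requires for set.seed().
deriveSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629) + 1L
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotMatrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

# Column variances without the overhead of apply().
colVars <- function(x, center = colMeans(x)) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  colSums(sweep(x, 2L, center, "-")^2) / (n - 1L)
}

# Squared Euclidean cross-distance matrix between the rows of a and b.
crossDist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
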