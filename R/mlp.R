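# Internal MLP machinery for the noise-prediction network.
#
# Architecture (tabular DDPM backbone): the input is the concatenation
# [x_t || time embedding || condition embeddings]; each hidden layer is
# linear -> batch normalization -> ReLU, and the sinusoidal time embedding
# is re-concatenated with every hidden layer's output before the next
# linear map. A final linear layer maps back to the target dimension.
# Conditioning vectors enter through per-modality linear projections whose
# output block is zeroed exactly when the modality is masked.
#
# Everything is plain double-precision matrix algebra; parameters live in a
# flat named list so the Adam update is a simple loop over names.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

mlpInit <- function(targetDim, conditionDims, config, seed) {
  H <- config$hiddenSize
  L <- config$nHiddenLayers
  td <- config$timeEmbedDim
  cd <- config$condEmbedDim
  k <- length(conditionDims)
  inDim <- targetDim + td + k * cd
  params <- list()
  withSeed(seed, {
    for (m in names(conditionDims)) {
      params[[paste0("proj.", m)]] <-
        matrix(stats::rnorm(conditionDims[[m]] * cd, sd = 1 / sqrt(conditionDims[[m]])),
               conditionDims[[m]], cd)
    }
    prev <- inDim
    for (l in seq_len(L)) {
      params[[paste0("L", l, ".W")]] <- matrix(stats::rnorm(prev * H, sd = sqrt(2 / prev)), prev, H)
      params[[paste0("L", l, ".b")]] <- rep(0, H)
      params[[paste0("L", l, ".gamma")]] <- rep(1, H)
      params[[paste0("L", l, ".beta")]] <- rep(0, H)
      prev <- H + td
    }
    params[["out.W"]] <- matrix(stats::rnorm(prev * targetDim, sd = sqrt(1 / prev)), prev, targetDim)
    params[["out.b"]] <- rep(0, targetDim)
  })
  running <- list()
  for (l in seq_len(L)) {
    running[[paste0("L", l, ".mean")]] <- rep(0, H)
    running[[paste0("L", l, ".var")]] <- rep(1, H)
  }
  list(params = params, running = running,
       meta = list(targetDim = targetDim, conditionDims = conditionDims,
                   L = L, H = H, timeDim = td, condDim = cd))
}

#' Sinusoidal time embedding
#'
#' Standard transformer-style positional encoding of the diffusion
#' timestep: interleaved sine/cosine pairs over geometrically spaced
#' frequencies `10000^(-k/(dim/2))`, k = 1..dim/2. All components lie in
#' \[-1, 1\] and t = 0 maps to alternating (0, 1).
#'
#' @param t non-negative timestep (scalar or vector).
#' @param dim embedding size (even).
#' @return a length-`dim` vector, or a matrix with one row per element of
#'   `t`.
#' @export
timeEmbedding <- function(t, dim) {
  if (dim %% 2L != 0L || dim < 2L) stop("'dim' must be a positive even number")
  if (any(t < 0)) stop("'t' must be non-negative")
  half <- dim %/% 2L
  freqs <- 10000^(-(seq_len(half) / half))
  ang <- outer(as.numeric(t), freqs)            # n x half
  out <- matrix(0, length(t), dim)
  out[, seq(1L, dim, by = 2L)] <- sin(ang)
  out[, seq(2L, dim, by = 2L)] <- cos(ang)
  if (length(t) == 1L) drop(out) else out
}

# Build the concatenated condition-embedding block. conditions: named list
# of matrices (or NULL entries); presentMask: named logical. Absent
# modalities contribute an exact zero block regardless of stored values.
condEmbed <- function(params, meta, n, conditions, presentMask) {
  mods <- names(meta$conditionDims)
  k <- length(mods)
  if (k == 0L) return(matrix(numeric(0), n, 0L))
  out <- matrix(0, n, k * meta$condDim)
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    if (isTRUE(presentMask[[m]])) {
      C <- conditions[[m]]
      if (is.null(C)) stop(sprintf("modality '%s' flagged present but has no values", m))
      if (ncol(C) != meta$conditionDims[[m]]) {
        stop(sprintf("modality '%s' has %d columns, expected %d",
                     m, ncol(C), meta$conditionDims[[m]]))
      }
      cols <- ((i - 1L) * meta$condDim + 1L):(i * meta$condDim)
      out[, cols] <- C %*% params[[paste0("proj.", m)]]
    }
  }
  out
}

# Forward pass. t: scalar or per-row vector of timesteps. Returns the
# prediction and (when train = TRUE) the caches needed for backprop, plus
# updated running statistics.
mlpForward <- function(net, X, t, conditions, presentMask, train = FALSE) {
  params <- net$params; meta <- net$meta
  n <- nrow(X)
  TE <- timeEmbedding(t, meta$timeDim)
  if (is.null(dim(TE))) TE <- matrix(TE, n, meta$timeDim, byrow = TRUE)
  CE <- condEmbed(params, meta, n, conditions, presentMask)
  h <- cbind(X, TE, CE)
  cache <- if (train) list(TE = TE, CE = CE, inputs = list()) else NULL
  running <- net$running
  for (l in seq_len(meta$L)) {
    W <- params[[paste0("L", l, ".W")]]
    z <- sweep(h %*% W, 2L, params[[paste0("L", l, ".b")]], "+")
    if (train) {
      mu <- colMeans(z)
      v <- colSums(sweep(z, 2L, mu, "-")^2) / n      # population variance
      running[[paste0("L", l, ".mean")]] <-
        (1 - BN_MOMENTUM) * running[[paste0("L", l, ".mean")]] + BN_MOMENTUM * mu
      running[[paste0("L", l, ".var")]] <-
        (1 - BN_MOMENTUM) * running[[paste0("L", l, ".var")]] + BN_MOMENTUM * v * n / max(n - 1, 1)
    } else {
      mu <- running[[paste0("L", l, ".mean")]]
      v <- running[[paste0("L", l, ".var")]]
    }
    inv <- 1 / sqrt(v + BN_EPS)
    zn <- sweep(sweep(z, 2L, mu, "-"), 2L, inv, "*")
    o <- sweep(sweep(zn, 2L, params[[paste0("L", l, ".gamma")]], "*"),
               2L, params[[paste0("L", l, ".beta")]], "+")
    a <- pmax(o, 0)
    if (train) {
      cache$inputs[[l]] <- list(h = h, zn = zn, inv = inv, mask = o > 0)
    }
    h <- cbind(a, TE)
  }
  pred <- sweep(h %*% params[["out.W"]], 2L, params[["out.b"]], "+")
  if (train) cache$hOut <- h
  list(pred = pred, cache = cache, running = running)
}

# Backward pass for the MSE-on-noise objective. dPred: gradient of the loss
# w.r.t. the prediction. Returns the flat gradient list (same names as
# params); projections of masked modalities get zero gradient.
mlpBackward <- function(net, fwd, dPred, conditions, presentMask) {
  params <- net$params; meta <- net$meta
  cache <- fwd$cache
  grads <- list()
  H <- meta$H; td <- meta$timeDim
  grads[["out.W"]] <- crossprod(cache$hOut, dPred)
  grads[["out.b"]] <- colSums(dPred)
  dh <- dPred %*% t(params[["out.W"]])
  for (l in meta$L:1) {
    da <- dh[, seq_len(H), drop = FALSE]           # drop the TE block
    ci <- cache$inputs[[l]]
    do <- da * ci$mask
    grads[[paste0("L", l, ".gamma")]] <- colSums(do * ci$zn)
    grads[[paste0("L", l, ".beta")]] <- colSums(do)
    dzn <- sweep(do, 2L, params[[paste0("L", l, ".gamma")]], "*")
    n <- nrow(do)
    s1 <- colSums(dzn)
    s2 <- colSums(dzn * ci$zn)
    dz <- sweep(dzn * n, 2L, s1, "-")
    dz <- dz - sweep(ci$zn, 2L, s2, "*")
    dz <- sweep(dz, 2L, ci$inv / n, "*")
    grads[[paste0("L", l, ".W")]] <- crossprod(ci$h, dz)
    grads[[paste0("L", l, ".b")]] <- colSums(dz)
    dh <- dz %*% t(params[[paste0("L", l, ".W")]])
  }
  # dh now spans [X || TE || CE]; only the CE block carries parameters.
  mods <- names(meta$conditionDims)
  offset <- meta$targetDim + td
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    nm <- paste0("proj.", m)
    if (isTRUE(presentMask[[m]])) {
      cols <- (offset + (i - 1L) * meta$condDim + 1L):(offset + i * meta$condDim)
      grads[[nm]] <- crossprod(conditions[[m]], dh[, cols, drop = FALSE])
    } else {
      grads[[nm]] <- params[[nm]] * 0
    }
  }
  grads
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

# --- plain dense network (no BN, no time injection) for autoencoders ------

denseInit <- function(dims, seed) {
  params <- list()
  withSeed(seed, {
    for (i in seq_len(length(dims) - 1L)) {
      params[[paste0("W", i)]] <-
        matrix(stats::rnorm(dims[i] * dims[i + 1L], sd = sqrt(1 / dims[i])),
               dims[i], dims[i + 1L])
      params[[paste0("b", i)]] <- rep(0, dims[i + 1L])
    }
  })
  params
}

# tanh on all but the last layer
denseForward <- function(params, X, nLayers) {
  acts <- vector("list", nLayers + 1L)
  acts[[1L]] <- X
  h <- X
  for (i in seq_len(nLayers)) {
    h <- sweep(h %*% params[[paste0("W", i)]], 2L, params[[paste0("b", i)]], "+")
    if (i < nLayers) h <- tanh(h)
    acts[[i + 1L]] <- h
  }
  list(out = h, acts = acts)
}

denseBackward <- function(params, fwd, dOut, nLayers) {
  grads <- list()
  dh <- dOut
  for (i in nLayers:1) {
    if (i < nLayers) dh <- dh * (1 - fwd$acts[[i + 1L]]^2)
    grads[[paste0("W", i)]] <- crossprod(fwd$acts[[i]], dh)
    grads[[paste0("b", i)]] <- colSums(dh)
    dh <- dh %*% t(params[[paste0("W", i)]])
  }
  grads
}
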