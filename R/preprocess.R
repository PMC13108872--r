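#' Read / write a modality table
#'
#' Delimited text with a header row and a leading sample-ID column; missing
#' entries are empty fields or "NA". Returns a numeric matrix with sample
#' IDs as rownames.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return numeric samples x features matrix.
#' @export
readModalityTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("sample IDs must be unique")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname readModalityTable
#' @param x numeric matrix with sample-ID rownames.
#' @param idColumn name for the leading ID column.
#' @export
writeModalityTable <- function(x, path, sep = "\t", idColumn = "sample_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' RNA-seq: recover counts and renormalize to log2(CPM + 1)
#'
#' Input values are on the log2(count + 1) scale. Per sample, counts are
#' recovered as `2^v - 1`, scaled to counts per million, and re-logged, so
#' the output is invariant to library-size differences.
#'
#' @param x samples x genes matrix of log2(count + 1) values (>= 0).
#' @return matrix of log2(CPM + 1) values.
#' @export
rnaseqTransform <- function(x) {
  stopifnotMatrix(x)
  if (any(x < 0, na.rm = TRUE)) stop("log2(count+1) values must be non-negative")
  counts <- 2^x - 1
  lib <- rowSums(counts, na.rm = TRUE)
  if (any(lib == 0)) {
    stop(sprintf("sample(s) with all-zero counts: %s",
                 paste(rownames(counts)[lib == 0], collapse = ", ")))
  }
  cpm <- counts / lib * 1e6
  log2(cpm + 1)
}

#' Low-expression gene filter
#'
#' Keeps genes with CPM strictly greater than `cpmThreshold` in at least
#' `minFraction` of samples. Input is on the log2(CPM + 1) scale as
#' produced by [rnaseqTransform()].
#'
#' @param x samples x genes matrix of log2(CPM + 1) values.
#' @param cpmThreshold CPM cutoff (strict, default 1).
#' @param minFraction minimum fraction of samples (inclusive, default 0.2).
#' @return character vector of retained gene names (or column indices when
#'   unnamed).
#' @export
filterLowExpression <- function(x, cpmThreshold = 1.0, minFraction = 0.20) {
  stopifnotMatrix(x)
  cpm <- 2^x - 1
  frac <- colMeans(cpm > cpmThreshold, na.rm = TRUE)
  keep <- frac >= minFraction
  if (is.null(colnames(x))) which(keep) else colnames(x)[keep]
}

#' Copy-number transform: clipped log2 ratio to the diploid state
#'
#' Absolute copy-number values are mapped to `log2(v / 2)` and clipped to
#' \[-2, 2\]. Zero copies are undefined under the log transform and become
#' missing.
#'
#' @param x samples x genes matrix of absolute copy numbers (>= 0).
#' @param clip symmetric clipping bound (default 2).
#' @return matrix of clipped log2 ratios with NA where input was 0.
#' @export
cnaTransform <- function(x, clip = 2) {
  stopifnotMatrix(x)
  if (any(x < 0, na.rm = TRUE)) stop("copy-number values must be non-negative")
  out <- log2(x / 2)
  out[!is.na(x) & x == 0] <- NA_real_
  pmin(pmax(out, -clip), clip)
}

#' Median-center a protein-array table
#'
#' Subtracts, for each protein, the median expression across all samples
#' (missing entries ignored), removing sample-independent offsets.
#'
#' @param x samples x proteins matrix.
#' @return median-centered matrix.
#' @export
rppaCenter <- function(x) {
  stopifnotMatrix(x)
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop(sprintf("feature(s) with no observed values: %s",
                 paste(colnames(x)[is.na(med)], collapse = ", ")))
  }
  sweep(x, 2L, med, "-")
}

#' Drop features with excessive missingness
#'
#' Removes features whose missing fraction is strictly greater than
#' `maxMissingFraction` (default 10%).
#'
#' @param x samples x features matrix.
#' @param maxMissingFraction exclusive upper bound on the missing fraction.
#' @return the filtered matrix.
#' @export
dropSparseFeatures <- function(x, maxMissingFraction = 0.10) {
  stopifnotMatrix(x)
  frac <- colMeans(is.na(x))
  x[, frac <= maxMissingFraction, drop = FALSE]
}

#' Impute missing entries
#'
#' `method = "median"` fills each feature with its median over the training
#' rows (all rows when `trainIds` is NULL). `method = "knn"` fills each
#' missing entry with the mean of that feature over the `k` nearest
#' samples, by Euclidean distance over co-observed features, considering
#' only neighbors with the feature observed.
#'
#' @param x samples x features matrix with NA for missing entries.
#' @param method `"knn"` or `"median"`.
#' @param k neighbor count for KNN (default 5).
#' @param trainIds optional row IDs on which medians / neighbor pools are
#'   computed, to keep held-out rows out of the fitted statistics.
#' @return complete matrix.
#' @export
imputeMissing <- function(x, method = c("knn", "median"), k = 5L,
                          trainIds = NULL) {
  method <- match.arg(method)
  stopifnotMatrix(x)
  pool <- if (is.null(trainIds)) seq_len(nrow(x)) else match(trainIds, rownames(x))
  if (anyNA(pool)) stop("trainIds not found among rownames")
  nObs <- colSums(!is.na(x[pool, , drop = FALSE]))
  if (any(nObs == 0L)) {
    stop(sprintf("feature(s) with no observed values: %s",
                 paste(colnames(x)[nObs == 0L], collapse = ", ")))
  }
  if (method == "median") {
    med <- apply(x[pool, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      x[miss, j] <- med[[j]]
    }
    return(x)
  }
  # knn
  incomplete <- which(rowSums(is.na(x)) > 0L)
  for (i in incomplete) {
    cand <- setdiff(pool, i)
    xi <- x[i, ]
    d2 <- vapply(cand, function(r) {
      co <- !is.na(xi) & !is.na(x[r, ])
      if (!any(co)) return(Inf)
      mean((xi[co] - x[r, co])^2)
    }, numeric(1))
    for (j in which(is.na(xi))) {
      ok <- cand[!is.na(x[cand, j]) & is.finite(d2)]
      if (length(ok) == 0L) stop("no neighbor with the feature observed")
      ord <- ok[order(d2[match(ok, cand)])]
      nb <- ord[seq_len(min(k, length(ord)))]
      x[i, j] <- mean(x[nb, j])
    }
  }
  x
}

#' Stratified cohort split with a complete-profiles-only test set
#'
#' Allocates each stratum (cancer type) to train/validation/test at the
#' given fractions using largest-remainder rounding within the stratum.
#' The test quota is drawn exclusively from samples whose profiles are
#' complete (all modalities available); a stratum with too few complete
#' samples gets its quota reduced with a warning, the shortfall going to
#' the training set.
#'
#' @param ids character sample IDs.
#' @param typeLabels per-sample stratum labels.
#' @param fractions train/val/test fractions summing to 1.
#' @param complete per-sample logical: all modalities available.
#' @param seed integer seed; the split is deterministic given it.
#' @return list with `train`, `val`, `test` ID vectors and `strata`, the
#'   named label vector.
#' @export
stratifiedSplit <- function(ids, typeLabels, fractions = c(0.80, 0.05, 0.15),
                            complete = rep(TRUE, length(ids)), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (length(ids) != length(typeLabels) || length(ids) != length(complete)) {
    stop("ids, typeLabels and complete must be aligned")
  }
  train <- character(); val <- character(); test <- character()
  withSeed(seed, {
    for (s in sort(unique(as.character(typeLabels)))) {
      sidx <- which(as.character(typeLabels) == s)
      ns <- length(sidx)
      quota <- floor(fractions * ns)
      rem <- fractions * ns - quota
      for (j in order(rem, decreasing = TRUE)[seq_len(ns - sum(quota))]) {
        quota[j] <- quota[j] + 1L
      }
      compl <- sidx[complete[sidx]]
      if (length(compl) < quota[3L]) {
        warning(sprintf(
          "stratum '%s': only %d complete samples for a test quota of %d; quota reduced",
          s, length(compl), quota[3L]))
        quota[1L] <- quota[1L] + (quota[3L] - length(compl))
        quota[3L] <- length(compl)
      }
      testIdx <- if (quota[3L] > 0L) sample(compl, quota[3L]) else integer(0)
      restIdx <- sample(setdiff(sidx, testIdx))
      valIdx <- restIdx[seq_len(min(quota[2L], length(restIdx)))]
      trainIdx <- setdiff(restIdx, valIdx)
      train <- c(train, ids[trainIdx])
      val <- c(val, ids[valIdx])
      test <- c(test, ids[testIdx])
    }
  })
  list(train = train, val = val, test = test,
       strata = stats::setNames(as.character(typeLabels), ids))
}

#' Fit a per-modality embedding to the shared latent space
#'
#' Standardizes features (center/scale fit on the training table only) and
#' learns either a PCA basis (top `latentDim` orthonormal components) or a
#' small symmetric autoencoder (one tanh hidden layer per side, linear
#' latent and output, Adam on reconstruction MSE with early stopping on a
#' validation table).
#'
#' @param train samples x features training matrix (no missing values).
#' @param modality modality name.
#' @param latentDim latent dimensionality (default 32).
#' @param method `"pca"` or `"autoencoder"`.
#' @param val optional validation matrix for autoencoder early stopping; a
#'   10% tail split of `train` is used when omitted.
#' @param hiddenSize,learningRate,maxEpochs,patience,batchSize autoencoder
#'   training settings.
#' @param seed integer seed.
#' @return an [EmbeddingModel-class].
#' @export
fitEmbedding <- function(train, modality, latentDim = 32L,
                         method = c("pca", "autoencoder"), val = NULL,
                         hiddenSize = 64L, learningRate = 1e-3,
                         maxEpochs = 500L, patience = 20L, batchSize = 64L,
                         seed = 1L) {
  method <- match.arg(method)
  stopifnotMatrix(train)
  if (anyNA(train)) stop("training table must be complete (impute first)")
  center <- colMeans(train)
  scl <- sqrt(colVars(train, center))
  if (all(scl == 0)) stop("degenerate (zero-variance) training table")
  scl[scl == 0] <- 1
  Z <- sweep(sweep(train, 2L, center, "-"), 2L, scl, "/")
  latentDim <- as.integer(latentDim)
  if (method == "pca") {
    if (latentDim >= ncol(train)) {
      stop("latentDim must be smaller than the feature count for PCA")
    }
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    fit <- list(rotation = pc$rotation[, seq_len(latentDim), drop = FALSE])
  } else {
    D <- ncol(Z)
    if (is.null(val)) {
      nv <- max(2L, floor(0.1 * nrow(Z)))
      vidx <- seq(nrow(Z) - nv + 1L, nrow(Z))
      Zv <- Z[vidx, , drop = FALSE]
      Zt <- Z[-vidx, , drop = FALSE]
    } else {
      Zv <- sweep(sweep(val, 2L, center, "-"), 2L, scl, "/")
      Zt <- Z
    }
    dims <- c(D, hiddenSize, latentDim, hiddenSize, D)
    params <- denseInit(dims, deriveSeed(seed, 1L))
    opt <- adamInit(params)
    best <- Inf; bestParams <- params; bad <- 0L
    withSeed(deriveSeed(seed, 2L), {
      for (epoch in seq_len(maxEpochs)) {
        idx <- sample.int(nrow(Zt))
        for (start in seq(1L, nrow(Zt), by = batchSize)) {
          rows <- idx[start:min(start + batchSize - 1L, nrow(Zt))]
          fwd <- denseForward(params, Zt[rows, , drop = FALSE], 4L)
          resid <- fwd$out - Zt[rows, , drop = FALSE]
          grads <- denseBackward(params, fwd, 2 * resid / length(resid), 4L)
          upd <- adamStep(params, grads, opt, learningRate)
          params <- upd$params; opt <- upd$state
        }
        vmse <- mean((denseForward(params, Zv, 4L)$out - Zv)^2)
        if (vmse < best - 1e-9) { best <- vmse; bestParams <- params; bad <- 0L }
        else { bad <- bad + 1L; if (bad >= patience) break }
      }
    })
    fit <- list(params = bestParams, hiddenSize = hiddenSize, valMSE = best)
  }
  new("EmbeddingModel", modality = modality, method = method,
      latentDim = latentDim, center = center, scale = scl, fit = fit)
}

#' @rdname fitEmbedding
#' @param model an [EmbeddingModel-class].
#' @param x samples x features matrix to encode.
#' @return `encodeLatent()` returns a samples x latentDim matrix.
#' @export
encodeLatent <- function(model, x) {
  Z <- sweep(sweep(x, 2L, model@center, "-"), 2L, model@scale, "/")
  out <- if (model@method == "pca") {
    Z %*% model@fit$rotation
  } else {
    denseForward(model@fit$params, Z, 2L)$out
  }
  rownames(out) <- rownames(x)
  out
}

#' @rdname fitEmbedding
#' @param latent samples x latentDim matrix to decode.
#' @return `decodeLatent()` returns a reconstruction on the original
#'   feature scale.
#' @export
decodeLatent <- function(model, latent) {
  Z <- if (model@method == "pca") {
    latent %*% t(model@fit$rotation)
  } else {
    p <- model@fit$params
    dec <- list(W1 = p$W3, b1 = p$b3, W2 = p$W4, b2 = p$b4)
    denseForward(dec, latent, 2L)$out
  }
  out <- sweep(sweep(Z, 2L, model@scale, "*"), 2L, model@center, "+")
  rownames(out) <- rownames(latent)
  out
}

#' Train-fit latent scaler
#'
#' Per-feature standardization of latent tables, fit on the training rows
#' and applied everywhere, so the terminal diffusion distribution N(0, I)
#' matches the data scale.
#'
#' @param train latent matrix of training samples.
#' @return list with `center`, `scale` and functions `apply(x)` /
#'   `invert(x)`.
#' @export
latentScaler <- function(train) {
  center <- colMeans(train)
  scl <- sqrt(colVars(train, center))
  scl[scl == 0] <- 1
  list(
    center = center, scale = scl,
    apply = function(x) sweep(sweep(x, 2L, center, "-"), 2L, scl, "/"),
    invert = function(x) sweep(sweep(x, 2L, scl, "*"), 2L, center, "+")
  )
}
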