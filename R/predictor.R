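#' Construct a conditioning set
#'
#' Bundles per-modality conditioning matrices with presence flags. Entries
#' given as `NULL` (or flagged absent) contribute an exact zero block to
#' any network that consumes the set, so whatever values they may carry are
#' never used.
#'
#' @param values named list of numeric matrices (samples x latent dim);
#'   `NULL` entries mark absent modalities.
#' @param present optional named logical overriding the default
#'   `!is.null(...)` presence.
#' @return a [ConditionSet-class].
#' @examples
#' cs <- conditionSet(list(rnaseq = matrix(rnorm(8), 2), cna = NULL))
#' conditionPresent(cs)
#' @export
conditionSet <- function(values, present = NULL) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("'values' must be a named list")
  }
  if (is.null(present)) {
    present <- !vapply(values, is.null, logical(1))
  } else {
    present <- present[names(values)]
  }
  new("ConditionSet", values = values, present = present)
}

#' @rdname conditionSet
#' @param conditions a [ConditionSet-class].
#' @export
conditionPresent <- function(conditions) conditions@present

#' @rdname conditionSet
#' @param modality modality name.
#' @export
conditionValues <- function(conditions, modality) conditions@values[[modality]]

setMethod("show", "ConditionSet", function(object) {
  p <- object@present
  cat(sprintf("ConditionSet: %s\n", paste(
    sprintf("%s[%s]", names(p), ifelse(p, "present", "absent")), collapse = ", ")))
})

#' Noise-predictor training configuration
#'
#' Defaults sit at the small end of the architecture search space used for
#' the full-scale models (4-7 hidden layers, hidden size 256-1024, time
#' embedding 64-128, condition embedding 8-32, learning rate 1e-4 to 1e-3,
#' batch 64-128); desk-scale runs shrink them further.
#'
#' @param nHiddenLayers,hiddenSize,timeEmbedDim,condEmbedDim architecture.
#' @param learningRate,batchSize optimizer settings (Adam).
#' @param maxEpochs training cap; early stopping usually triggers first.
#' @param patience number of validation evaluations without improvement
#'   before stopping.
#' @param evalInterval epochs between validation-generation evaluations.
#' @return a named list of class-free configuration values.
#' @export
predictorConfig <- function(nHiddenLayers = 4L, hiddenSize = 256L,
                            timeEmbedDim = 64L, condEmbedDim = 16L,
                            learningRate = 1e-3, batchSize = 128L,
                            maxEpochs = 20000L, patience = 10L,
                            evalInterval = 100L) {
  cfg <- list(
    nHiddenLayers = as.integer(nHiddenLayers), hiddenSize = as.integer(hiddenSize),
    timeEmbedDim = as.integer(timeEmbedDim), condEmbedDim = as.integer(condEmbedDim),
    learningRate = learningRate, batchSize = as.integer(batchSize),
    maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
    evalInterval = as.integer(evalInterval)
  )
  if (any(vapply(cfg, function(x) length(x) != 1L || is.na(x) || x <= 0, logical(1)))) {
    stop("all configuration values must be positive scalars")
  }
  if (cfg$timeEmbedDim %% 2L != 0L) stop("timeEmbedDim must be even")
  cfg
}

#' Project and concatenate conditioning modalities
#'
#' Applies each modality's linear projection to its conditioning matrix and
#' concatenates the blocks in the fixed order of `projections`. Absent
#' modalities contribute an exact zero block, implementing the masking
#' strategy that lets one network serve any subset of inputs.
#'
#' @param conditions a [ConditionSet-class].
#' @param projections named list of projection matrices (inputDim x
#'   embedDim), one per modality the model was built with; the list order
#'   is the concatenation order.
#' @return an n x (k * embedDim) matrix.
#' @export
projectConditions <- function(conditions, projections) {
  mods <- names(projections)
  unknown <- setdiff(names(conditions@present)[conditions@present], mods)
  if (length(unknown)) {
    stop(sprintf("unknown condition modality: %s", paste(unknown, collapse = ", ")))
  }
  embDim <- unique(vapply(projections, ncol, integer(1)))
  if (length(embDim) != 1L) stop("all projections must share the embedding dimension")
  n <- NA_integer_
  for (m in mods) {
    if (is.matrix(conditions@values[[m]])) { n <- nrow(conditions@values[[m]]); break }
  }
  if (is.na(n)) n <- 1L   # fully absent set: a single all-zero row
  out <- matrix(0, n, length(mods) * embDim)
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    if (isTRUE(conditions@present[[m]])) {
      out[, ((i - 1L) * embDim + 1L):(i * embDim)] <-
        conditions@values[[m]] %*% projections[[m]]
    }
  }
  out
}

# Split a ConditionSet (or NULL) into the value list / presence mask the
# low-level network expects, restricted to the checkpoint's modalities.
resolveConditions <- function(condMods, conditions, masked) {
  present <- stats::setNames(rep(FALSE, length(condMods)), condMods)
  values <- stats::setNames(vector("list", length(condMods)), condMods)
  if (!is.null(conditions)) {
    extra <- setdiff(names(conditions@present), condMods)
    if (length(extra)) {
      stop(sprintf("condition modality not recognized by this model: %s",
                   paste(extra, collapse = ", ")))
    }
    for (m in intersect(names(conditions@present), condMods)) {
      if (isTRUE(conditions@present[[m]])) {
        present[[m]] <- TRUE
        values[[m]] <- conditions@values[[m]]
      }
    }
  }
  if (!masked && !all(present)) {
    stop(sprintf("single-condition model requires modality '%s' to be present",
                 paste(condMods[!present], collapse = ", ")))
  }
  list(values = values, present = present)
}

#' Predict the noise component with a trained checkpoint
#'
#' Runs the MLP in evaluation mode (batch normalization uses the stored
#' running statistics), so the output is deterministic in its inputs.
#'
#' @param checkpoint a [NoisePredictor-class].
#' @param xt noisy latent matrix (n x D).
#' @param t scalar timestep or per-row vector.
#' @param conditions a [ConditionSet-class], or NULL for a fully masked
#'   (unconditional) call to a masked model.
#' @return predicted-noise matrix with the shape of `xt`.
#' @export
predictNoise <- function(checkpoint, xt, t, conditions = NULL) {
  stopifnotMatrix(xt)
  if (ncol(xt) != checkpoint@targetDim) {
    stop(sprintf("xt has %d columns, model expects %d", ncol(xt), checkpoint@targetDim))
  }
  rc <- resolveConditions(checkpoint@conditionModalities, conditions, checkpoint@masked)
  net <- list(params = checkpoint@params$weights,
              running = checkpoint@params$running,
              meta = checkpoint@params$meta)
  mlpForward(net, xt, t, rc$values, rc$present, train = FALSE)$pred
}

# ---------------------------------------------------------------------------
# Training

alignTables <- function(tables, mods) {
  ids <- rownames(tables[[mods[[1L]]]])
  for (m in mods) {
    tab <- tables[[m]]
    if (is.null(tab)) stop(sprintf("modality '%s' missing from the data", m))
    if (!is.null(rownames(tab)) && !is.null(ids) && !identical(rownames(tab), ids)) {
      if (!setequal(rownames(tab), ids)) {
        stop(sprintf("modality '%s' is not aligned on sample IDs", m))
      }
      tables[[m]] <- tab[ids, , drop = FALSE]
    }
  }
  tables
}

# Full reverse-diffusion generation from a raw net (training internals).
generateFromNet <- function(net, n, D, schedule, condValues, presentMask, seed) {
  fun <- function(xt, t, conditions) {
    mlpForward(net, xt, t, condValues, presentMask, train = FALSE)$pred
  }
  ddpmSample(fun, schedule, n, D, conditions = NULL, seed = seed)
}

trainDDPM <- function(train, val, target, condMods, config, schedule, seed,
                      masked = FALSE, subsetSampler = NULL, verbose = FALSE) {
  mods <- c(target, condMods)
  train <- alignTables(train, mods)
  val <- alignTables(val, mods)
  X <- train[[target]]
  if (is.null(X) || nrow(X) == 0L) stop("empty training data")
  D <- ncol(X)
  conditionDims <- stats::setNames(
    vapply(condMods, function(m) ncol(train[[m]]), integer(1)), condMods)
  net <- mlpInit(D, conditionDims, config, deriveSeed(seed, 1L))
  opt <- adamInit(net$params)
  T <- schedule@steps
  n <- nrow(X)
  valX <- val[[target]]
  valCond <- stats::setNames(lapply(condMods, function(m) val[[m]]), condMods)
  valPresent <- stats::setNames(rep(TRUE, length(condMods)), condMods)
  valSeed <- deriveSeed(seed, 2L)

  bestMSE <- Inf
  bestNet <- NULL
  badEvals <- 0L
  log <- list()
  withSeed(deriveSeed(seed, 3L), {
    for (epoch in seq_len(config$maxEpochs)) {
      idx <- sample.int(n)
      epochLoss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batchSize)) {
        rows <- idx[start:min(start + config$batchSize - 1L, n)]
        if (length(rows) < 2L) next  # batch norm needs >= 2 rows
        x0 <- X[rows, , drop = FALSE]
        tIdx <- sample.int(T, length(rows), replace = TRUE)
        eps <- matrix(stats::rnorm(length(rows) * D), length(rows), D)
        xt <- qSample(x0, tIdx, eps, schedule)
        presentMods <- if (!masked) condMods
          else if (is.null(subsetSampler)) condMods[stats::runif(length(condMods)) < 0.5]
          else subsetSampler(condMods)
        presentMask <- stats::setNames(condMods %in% presentMods, condMods)
        condValues <- stats::setNames(
          lapply(condMods, function(m) train[[m]][rows, , drop = FALSE]), condMods)
        fwd <- mlpForward(net, xt, tIdx, condValues, presentMask, train = TRUE)
        net$running <- fwd$running
        resid <- fwd$pred - eps
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        }
        epochLoss <- epochLoss + loss; nb <- nb + 1L
        grads <- mlpBackward(net, fwd, 2 * resid / length(resid), condValues, presentMask)
        upd <- adamStep(net$params, grads, opt, config$learningRate)
        net$params <- upd$params; opt <- upd$state
      }
      if (epoch %% config$evalInterval == 0L || epoch == config$maxEpochs) {
        gen <- generateFromNet(net, nrow(valX), D, schedule, valCond, valPresent, valSeed)
        mse <- mean((gen - valX)^2)
        log[[length(log) + 1L]] <- data.frame(
          epoch = epoch, trainLoss = epochLoss / max(nb, 1L), valMSE = mse)
        if (verbose) message(sprintf("epoch %d: train %.4f val-gen MSE %.4f",
                                     epoch, epochLoss / max(nb, 1L), mse))
        if (mse < bestMSE - 1e-12) {
          bestMSE <- mse; bestNet <- net; badEvals <- 0L
        } else {
          badEvals <- badEvals + 1L
          if (badEvals >= config$patience) break
        }
      }
    }
  })
  if (is.null(bestNet)) bestNet <- net
  new("NoisePredictor",
    params = list(weights = bestNet$params, running = bestNet$running,
                  meta = bestNet$meta),
    config = config, targetModality = target,
    conditionModalities = condMods, conditionDims = conditionDims,
    targetDim = as.integer(D), masked = masked, bestValMSE = bestMSE,
    scheduleRef = scheduleDescriptor(schedule),
    trainingLog = do.call(rbind, log)
  )
}

#' Train a single-condition diffusion model
#'
#' Fits the noise-prediction MLP for one ordered (condition -> target)
#' modality pair by minimizing the MSE between true and predicted noise at
#' uniformly sampled timesteps. Every `evalInterval` epochs the model
#' generates fully denoised samples for the validation set (conditioned on
#' the real validation conditions) and the MSE against the real targets
#' drives early stopping; the best checkpoint is returned.
#'
#' @param train,val named lists of latent matrices (rownames are sample
#'   IDs) containing at least the target and condition modalities.
#' @param target,condition modality names.
#' @param config a [predictorConfig()].
#' @param schedule a [NoiseSchedule-class].
#' @param seed integer seed fixing initialization, batching and noise.
#' @param verbose print per-evaluation progress.
#' @return a [NoisePredictor-class].
#' @export
trainSingleCondition <- function(train, val, target, condition, config,
                                 schedule, seed = 1L, verbose = FALSE) {
  trainDDPM(train, val, target, condition, config, schedule, seed,
            masked = FALSE, verbose = verbose)
}

#' Train a multi-condition diffusion model with subset masking
#'
#' Like [trainSingleCondition()] but conditions on several modalities at
#' once. Each training batch draws a random subset of the conditioning
#' modalities (by default uniform over all subsets, including the empty
#' set) and masks the rest to zero, so the trained network handles any
#' availability pattern — including fully unconditional generation.
#' Validation generation and early stopping always use the full condition
#' set.
#'
#' @inheritParams trainSingleCondition
#' @param conditions character vector of conditioning modality names.
#' @param subsetSampler optional `function(modalities)` returning the
#'   subset to keep for a batch; `NULL` for the default uniform sampler.
#'   A degenerate sampler `function(m) m` reproduces single-condition
#'   training exactly (given the same seed).
#' @return a [NoisePredictor-class] with `masked = TRUE`.
#' @export
trainMultiCondition <- function(train, val, target, conditions, config,
                                schedule, seed = 1L, subsetSampler = NULL,
                                verbose = FALSE) {
  trainDDPM(train, val, target, conditions, config, schedule, seed,
            masked = TRUE, subsetSampler = subsetSampler, verbose = verbose)
}

#' Validation-generation mean squared error
#'
#' Runs one full reverse-diffusion generation per validation sample,
#' conditioned on the real validation conditions, and returns the MSE
#' against the real targets — the quantity used for early stopping and for
#' the inverse-MSE ensemble weights.
#'
#' @param checkpoint a [NoisePredictor-class].
#' @param val named list of latent matrices with the target and condition
#'   modalities.
#' @param schedule a [NoiseSchedule-class]; defaults to the checkpoint's
#'   training schedule.
#' @param seed integer seed for the generation noise stream.
#' @return scalar MSE.
#' @export
validationGenerationMSE <- function(checkpoint, val, schedule = NULL, seed = 1L) {
  if (is.null(schedule)) schedule <- scheduleFromDescriptor(checkpoint@scheduleRef)
  mods <- c(checkpoint@targetModality, checkpoint@conditionModalities)
  val <- alignTables(val, mods)
  target <- val[[checkpoint@targetModality]]
  cs <- conditionSet(stats::setNames(
    lapply(checkpoint@conditionModalities, function(m) val[[m]]),
    checkpoint@conditionModalities))
  gen <- ddpmSample(checkpoint, schedule, nrow(target), checkpoint@targetDim,
                    conditions = cs, seed = seed)
  mean((gen - target)^2)
}

setMethod("show", "NoisePredictor", function(object) {
  cat(sprintf(
    "NoisePredictor: %s | %s -> %s (D = %d)\n  best validation generation MSE: %.4g (%d evaluations)\n",
    if (object@masked) "multi-condition (masked)" else "single-condition",
    if (length(object@conditionModalities))
      paste(object@conditionModalities, collapse = " + ") else "<unconditional>",
    object@targetModality, object@targetDim, object@bestValMSE,
    nrow(object@trainingLog)
  ))
})

#' Save / load a noise-predictor checkpoint
#'
#' A checkpoint directory holds the opaque weights blob plus plain-text
#' metadata (configuration, modalities, best validation MSE, schedule
#' descriptor) and the training log as a TSV. `loadCheckpoint()` restores a
#' predictor whose outputs are bit-identical to the saved one.
#'
#' @param checkpoint a [NoisePredictor-class].
#' @param dir directory to create/read.
#' @return `saveCheckpoint()` returns `dir` invisibly; `loadCheckpoint()`
#'   returns the restored [NoisePredictor-class].
#' @export
saveCheckpoint <- function(checkpoint, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(checkpoint@params, file.path(dir, "weights.rds"))
  meta <- list(
    config = checkpoint@config,
    targetModality = checkpoint@targetModality,
    conditionModalities = as.list(checkpoint@conditionModalities),
    conditionDims = as.list(checkpoint@conditionDims),
    targetDim = checkpoint@targetDim,
    masked = checkpoint@masked,
    bestValMSE = checkpoint@bestValMSE,
    schedule = checkpoint@scheduleRef
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(checkpoint@trainingLog, file.path(dir, "training_log.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  params <- readRDS(file.path(dir, "weights.rds"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  log <- utils::read.delim(file.path(dir, "training_log.tsv"))
  new("NoisePredictor",
    params = params,
    config = as.list(meta$config),
    targetModality = meta$targetModality,
    conditionModalities = as.character(unlist(meta$conditionModalities)),
    conditionDims = stats::setNames(as.integer(unlist(meta$conditionDims)),
                                    names(meta$conditionDims)),
    targetDim = as.integer(meta$targetDim),
    masked = as.logical(meta$masked),
    bestValMSE = as.numeric(meta$bestValMSE),
    scheduleRef = as.list(meta$schedule),
    trainingLog = log
  )
}
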