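#' Inverse-MSE ensemble weights
#'
#' Member weights are set inversely proportional to each single-condition
#' model's validation reconstruction MSE:
#' \eqn{w_i = (1/\mathrm{mse}_i) / \sum_j (1/\mathrm{mse}_j)}.
#'
#' @param valMses strictly positive per-member validation MSEs.
#' @return non-negative weights summing to one.
#' @export
computeWeights <- function(valMses) {
  valMses <- as.numeric(valMses)
  if (length(valMses) == 0L || any(!is.finite(valMses)) || any(valMses <= 0)) {
    stop("validation MSEs must be strictly positive")
  }
  inv <- 1 / valMses
  inv / sum(inv)
}

#' Consensus noise vector
#'
#' Element-wise weighted average \eqn{\epsilon_{consensus} = \sum_i w_i\,
#' \epsilon_{\theta_i}} of the member noise predictions.
#'
#' @param predictions list of equally shaped noise matrices.
#' @param weights valid weight vector (see [computeWeights()]).
#' @return the consensus matrix.
#' @export
consensusNoise <- function(predictions, weights) {
  if (length(predictions) != length(weights)) {
    stop("one weight per prediction required")
  }
  dims <- lapply(predictions, dim)
  if (length(unique(dims)) != 1L) stop("predictions must share a common shape")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to one")
  }
  out <- predictions[[1L]] * weights[[1L]]
  for (i in seq_along(predictions)[-1L]) {
    out <- out + predictions[[i]] * weights[[i]]
  }
  out
}

# Per-sample weighted mean pairwise cosine distance between member
# predictions. Returns a length-n vector. Pairs involving a zero-norm
# prediction get distance 0 (treated as non-conflicting).
pairwiseCoherence <- function(predictions, weights) {
  k <- length(predictions)
  n <- nrow(predictions[[1L]])
  if (k < 2L) return(rep(0, n))
  norms <- lapply(predictions, function(p) sqrt(rowSums(p^2)))
  num <- rep(0, n); den <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      dot <- rowSums(predictions[[i]] * predictions[[j]])
      nn <- norms[[i]] * norms[[j]]
      d <- ifelse(nn > 0, 1 - dot / nn, 0)
      w <- weights[[i]] * weights[[j]]
      num <- num + w * d
      den <- den + w
    }
  }
  if (den > 0) num / den else rep(0, n)
}

#' Coherence distance of a set of noise predictions
#'
#' Weighted mean over pairs i < j of the pairwise cosine distance
#' \eqn{d_{ij} = 1 - \epsilon_{\theta_i}\cdot\epsilon_{\theta_j} /
#' (\lVert\epsilon_{\theta_i}\rVert \lVert\epsilon_{\theta_j}\rVert)},
#' with pair weight proportional to \eqn{w_i w_j}. Distances are computed
#' per sample (row) and averaged over the batch; the result lies in
#' \[0, 2\]. A single member gives 0.
#'
#' @inheritParams consensusNoise
#' @return scalar mean coherence distance.
#' @export
coherenceDistance <- function(predictions, weights) {
  mean(pairwiseCoherence(predictions, weights))
}

#' Assemble a Coherent Denoising ensemble
#'
#' @param members list of single-condition [NoisePredictor-class] objects
#'   (or plain predictor functions for analytic members).
#' @param conditionModalities one conditioning modality name per member;
#'   inferred from checkpoints when omitted.
#' @param valMses per-member validation MSEs used to derive inverse-MSE
#'   weights; inferred from checkpoints when omitted.
#' @param weights explicit weights overriding `valMses`.
#' @return a [CoherentEnsemble-class].
#' @export
coherentEnsemble <- function(members, conditionModalities = NULL,
                             valMses = NULL, weights = NULL) {
  if (is(members, "NoisePredictor") || is.function(members)) members <- list(members)
  if (is.null(conditionModalities)) {
    conditionModalities <- vapply(members, function(m) {
      if (is(m, "NoisePredictor")) {
        if (length(m@conditionModalities) != 1L) {
          stop("ensemble members must be single-condition models")
        }
        m@conditionModalities
      } else {
        stop("supply 'conditionModalities' for function members")
      }
    }, character(1))
  }
  if (is.null(weights)) {
    if (is.null(valMses)) {
      valMses <- vapply(members, function(m) {
        if (is(m, "NoisePredictor")) m@bestValMSE else NA_real_
      }, numeric(1))
      if (anyNA(valMses)) stop("supply 'valMses' or 'weights' for function members")
    }
    weights <- computeWeights(valMses)
  }
  new("CoherentEnsemble", members = members,
      conditionModalities = as.character(conditionModalities),
      weights = as.numeric(weights))
}

#' @rdname coherentEnsemble
#' @param ensemble a [CoherentEnsemble-class].
#' @export
ensembleWeights <- function(ensemble) {
  stats::setNames(ensemble@weights, ensemble@conditionModalities)
}

setMethod("show", "CoherentEnsemble", function(object) {
  cat(sprintf("CoherentEnsemble with %d member(s):\n", length(object@members)))
  for (i in seq_along(object@members)) {
    cat(sprintf("  %s (w = %.3f)\n", object@conditionModalities[[i]],
                object@weights[[i]]))
  }
})

# One member's noise prediction. `condValue` is a matrix or NULL; for
# checkpoints it is wrapped in a present ConditionSet.
memberPredict <- function(member, modality, xt, t, condValue) {
  if (is.function(member)) {
    member(xt, t, condValue)
  } else {
    cs <- conditionSet(stats::setNames(list(condValue), modality))
    predictNoise(member, xt, t, cs)
  }
}

# Shared reverse loop for an ensemble: runs all members at every step,
# aggregates with consensusNoise and records per-sample coherence.
ensembleReverse <- function(ensemble, condValues, n, D, schedule, seed) {
  T <- schedule@steps
  dist <- matrix(0, T, n)
  x <- withSeed(seed, {
    x <- matrix(stats::rnorm(n * D), n, D)
    for (t in T:1) {
      preds <- lapply(seq_along(ensemble@members), function(i) {
        memberPredict(ensemble@members[[i]], ensemble@conditionModalities[[i]],
                      x, t, condValues[[i]])
      })
      dist[t, ] <- pairwiseCoherence(preds, ensemble@weights)
      epsHat <- consensusNoise(preds, ensemble@weights)
      z <- if (t > 1) matrix(stats::rnorm(n * D), n, D) else NULL
      x <- reverseStep(x, t, epsHat, z, schedule)
    }
    x
  })
  list(x = x, dist = dist)
}

#' Coherent Denoising: consensus sampling with coherence-based rejection
#'
#' Runs the reverse diffusion loop using the weighted-average consensus of
#' all member noise predictions at every step, while monitoring the
#' weighted mean pairwise cosine distance between the member predictions.
#' A sample trajectory is rejected when that distance exceeds `threshold`
#' for strictly more than `maxFraction` of the T steps; rejected samples
#' are retried with a fresh, deterministically re-seeded noise stream up to
#' `maxRetries` times, after which the trajectory with the smallest
#' incoherent fraction is kept and flagged as not accepted.
#'
#' @param ensemble a [CoherentEnsemble-class].
#' @param conditions a [ConditionSet-class] holding a present value matrix
#'   for every member's conditioning modality (rows define the batch).
#' @param schedule a [NoiseSchedule-class].
#' @param seed integer seed; retries advance it deterministically.
#' @param threshold coherence distance above which a step counts as
#'   incoherent (default 1, i.e. orthogonal predictions).
#' @param maxFraction largest tolerated fraction of incoherent steps
#'   (default 0.05); the comparison is strict, so a trajectory at exactly
#'   `maxFraction` is accepted.
#' @param maxRetries retries per rejected sample (default 5).
#' @param targetDim latent dimension of the generated modality; inferred
#'   from checkpoint members, required for function-only ensembles.
#' @return a [GenerationResult-class].
#' @export
coherentSample <- function(ensemble, conditions, schedule, seed = 1L,
                           threshold = 1.0, maxFraction = 0.05,
                           maxRetries = 5L, targetDim = NULL) {
  mods <- ensemble@conditionModalities
  missing <- mods[!vapply(mods, function(m)
    isTRUE(conditions@present[[m]]), logical(1))]
  if (length(missing)) {
    stop(sprintf("condition modality missing from the condition set: %s",
                 paste(missing, collapse = ", ")))
  }
  condValues <- lapply(mods, function(m) conditions@values[[m]])
  n <- nrow(condValues[[1L]])
  D <- targetDim
  if (is.null(D)) {
    for (m in ensemble@members) {
      if (is(m, "NoisePredictor")) { D <- m@targetDim; break }
    }
    if (is.null(D)) stop("supply 'targetDim' for a function-only ensemble")
  }
  T <- schedule@steps

  samples <- matrix(NA_real_, n, D)
  dist <- matrix(NA_real_, T, n)
  incFrac <- rep(NA_real_, n)
  accepted <- rep(FALSE, n)
  retries <- rep(0L, n)
  bestFrac <- rep(Inf, n)
  active <- seq_len(n)
  for (attempt in 0:maxRetries) {
    if (length(active) == 0L) break
    sub <- lapply(condValues, function(v) v[active, , drop = FALSE])
    runSeed <- if (attempt == 0L) seed else deriveSeed(seed, attempt)
    run <- ensembleReverse(ensemble, sub, length(active), D, schedule, runSeed)
    frac <- colMeans(run$dist > threshold)
    improve <- frac < bestFrac[active]
    upd <- active[improve]
    samples[upd, ] <- run$x[improve, , drop = FALSE]
    dist[, upd] <- run$dist[, improve, drop = FALSE]
    incFrac[upd] <- frac[improve]
    bestFrac[upd] <- frac[improve]
    ok <- frac <= maxFraction            # strict ">" rejects, "<=" accepts
    accepted[active[ok]] <- TRUE
    retries[active] <- attempt
    active <- active[!ok]
  }
  new("GenerationResult",
    samples = samples, accepted = accepted, retriesUsed = retries,
    perStepDistance = dist, incoherentFraction = incFrac,
    threshold = threshold, maxFraction = maxFraction
  )
}

setMethod("show", "GenerationResult", function(object) {
  cat(sprintf(
    "GenerationResult: %d sample(s), %d accepted, mean incoherent fraction %.3f (threshold %.2f, max %.2f)\n",
    nrow(object@samples), sum(object@accepted),
    mean(object@incoherentFraction), object@threshold, object@maxFraction
  ))
})

#' @describeIn coherentSample generated samples of a result.
#' @param result a [GenerationResult-class].
#' @export
generatedSamples <- function(result) result@samples

#' @describeIn coherentSample per-sample acceptance flags.
#' @export
isAccepted <- function(result) result@accepted

#' @describeIn coherentSample per-step coherence diagnostics, averaged over
#'   the batch.
#' @export
stepDiagnostics <- function(result) {
  list(perStepDistance = rowMeans(result@perStepDistance),
       incoherentFraction = result@incoherentFraction,
       threshold = result@threshold, maxFraction = result@maxFraction)
}

#' Conditional sampling with a multi-condition model
#'
#' Standard reverse diffusion with the (possibly partial, possibly empty)
#' masked condition set fed to the network at every step.
#'
#' @param checkpoint a masked multi-condition [NoisePredictor-class].
#' @param conditions a [ConditionSet-class] over any subset of the model's
#'   modalities; NULL for fully unconditional generation.
#' @param schedule a [NoiseSchedule-class].
#' @param n number of samples; inferred from the first present condition
#'   when omitted.
#' @param seed integer seed.
#' @return generated n x D matrix.
#' @export
multiConditionSample <- function(checkpoint, conditions = NULL, schedule = NULL,
                                 n = NULL, seed = 1L) {
  if (!checkpoint@masked) stop("checkpoint is not a multi-condition (masked) model")
  if (is.null(schedule)) schedule <- scheduleFromDescriptor(checkpoint@scheduleRef)
  if (is.null(n)) {
    if (is.null(conditions) || !any(conditions@present)) {
      stop("supply 'n' for fully unconditional generation")
    }
    n <- nrow(conditions@values[[which(conditions@present)[[1L]]]])
  }
  ddpmSample(checkpoint, schedule, n, checkpoint@targetDim,
             conditions = conditions, seed = seed)
}

#' Unconditional generation probe
#'
#' Probes what a model can generate without any informative input, the
#' regime used to assess memorization of the training distribution. For a
#' Coherent Denoising ensemble every member receives an all-zero condition
#' value (single-condition members have no masking pathway, so the zero
#' vector is injected as the condition itself); rejection sampling is
#' disabled. For a masked multi-condition model all modalities are masked.
#'
#' @param model a [CoherentEnsemble-class] or masked
#'   [NoisePredictor-class].
#' @param schedule a [NoiseSchedule-class].
#' @param n number of samples.
#' @param seed integer seed.
#' @return generated n x D matrix.
#' @export
unconditionalProbe <- function(model, schedule, n, seed = 1L) {
  if (is(model, "CoherentEnsemble")) {
    condValues <- lapply(seq_along(model@members), function(i) {
      m <- model@members[[i]]
      d <- if (is(m, "NoisePredictor")) m@conditionDims[[model@conditionModalities[[i]]]]
           else 1L
      matrix(0, n, d)
    })
    member1 <- model@members[[1L]]
    D <- if (is(member1, "NoisePredictor")) member1@targetDim
         else stop("function members need checkpoint members to infer D")
    ensembleReverse(model, condValues, n, D, schedule, seed)$x
  } else if (is(model, "NoisePredictor")) {
    if (!model@masked) stop("single-condition checkpoints are probed through an ensemble")
    multiConditionSample(model, conditions = NULL, schedule = schedule,
                         n = n, seed = seed)
  } else {
    stop("unsupported model type")
  }
}
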