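# Modality generators: the pluggable objects the experiment harnesses use
# to complete a missing modality. A generator is a function
#   function(target, conditions, ids, seed) -> matrix
# where `conditions` is a named list of real latent matrices for the
# available modalities (rows aligned with `ids`) and the returned matrix
# has one row per id, in order.

#' Oracle generator returning the real data
#'
#' Used for the exact harness identities: parity deltas vanish and
#' completion gain exactly cancels the ablation drop when the "generated"
#' data is the real data itself.
#'
#' @param cohort a [SyntheticCohort-class].
#' @return a generator function.
#' @export
realDataGenerator <- function(cohort) {
  force(cohort)
  function(target, conditions, ids, seed = 1L) {
    cohort@latents[[target]][ids, , drop = FALSE]
  }
}

#' Truth-based conditional sampler for synthetic cohorts
#'
#' Uses the stored generative ground truth: the shared factor is estimated
#' from the available modalities by least squares against the true shared
#' loadings, and the target modality is re-drawn with a fresh private
#' factor and observation noise. This is the model-free posterior-style
#' sampler the synthetic cohort makes possible, and deliberately carries
#' the irreducible private-factor variability of the target modality.
#'
#' @param cohort a [SyntheticCohort-class].
#' @return a generator function.
#' @export
truthConditionalGenerator <- function(cohort) {
  force(cohort)
  truth <- cohort@truth
  cfg <- cohort@config
  function(target, conditions, ids, seed = 1L) {
    mods <- intersect(names(conditions), modalityNames(cohort))
    if (length(mods) == 0L) stop("need at least one conditioning modality")
    Astack <- do.call(rbind, truth$loadingsShared[mods])
    Y <- do.call(cbind, lapply(mods, function(m) conditions[[m]][ids, , drop = FALSE]))
    # least squares via SVD pseudo-inverse: stays defined when the stacked
    # condition dimensionality is below the shared-factor dimension
    sv <- svd(Astack)
    keep <- sv$d > max(dim(Astack)) * .Machine$double.eps * sv$d[1L]
    sHat <- Y %*% sv$u[, keep, drop = FALSE] %*%
      (t(sv$v[, keep, drop = FALSE]) / sv$d[keep])
    At <- truth$loadingsShared[[target]]
    Bt <- truth$loadingsPrivate[[target]]
    d <- cfg$modalityDims[[target]]
    withSeed(seed, {
      u <- matrix(stats::rnorm(length(ids) * cfg$privateDim,
                               sd = cfg$privateSignalSd[[target]]),
                  length(ids), cfg$privateDim)
      e <- matrix(stats::rnorm(length(ids) * d, sd = cfg$noiseSd), length(ids), d)
      out <- sHat %*% t(At) + u %*% t(Bt) + e
      rownames(out) <- ids
      out
    })
  }
}

#' Wrap a diffusion model as a modality generator
#'
#' Produces a generator backed by a masked multi-condition checkpoint or a
#' Coherent Denoising ensemble. When `scalers` (a named list of
#' [latentScaler()] objects covering the target and condition modalities)
#' is supplied, conditions are standardized before entering the model and
#' generated samples are mapped back to the cohort's latent scale. For an
#' ensemble, only members whose conditioning modality is available are
#' used, with weights renormalized; best-effort (rejected) trajectories
#' are returned like accepted ones.
#'
#' @param model a masked [NoisePredictor-class] or
#'   [CoherentEnsemble-class].
#' @param schedule a [NoiseSchedule-class].
#' @param scalers optional named list of [latentScaler()] objects.
#' @param threshold,maxFraction,maxRetries rejection settings for the
#'   ensemble path (see [coherentSample()]).
#' @return a generator function.
#' @export
diffusionGenerator <- function(model, schedule, scalers = NULL,
                               threshold = 1.0, maxFraction = 0.05,
                               maxRetries = 5L) {
  force(model); force(schedule); force(scalers)
  scaleIn <- function(m, x) if (is.null(scalers)) x else scalers[[m]]$apply(x)
  scaleOut <- function(m, x) if (is.null(scalers)) x else scalers[[m]]$invert(x)
  function(target, conditions, ids, seed = 1L) {
    condList <- lapply(names(conditions), function(m)
      scaleIn(m, conditions[[m]][ids, , drop = FALSE]))
    names(condList) <- names(conditions)
    out <- if (is(model, "CoherentEnsemble")) {
      keep <- which(model@conditionModalities %in% names(condList))
      if (length(keep) == 0L) stop("no ensemble member matches the available modalities")
      sub <- coherentEnsemble(model@members[keep],
                              conditionModalities = model@conditionModalities[keep],
                              weights = model@weights[keep] / sum(model@weights[keep]))
      cs <- conditionSet(condList[sub@conditionModalities])
      generatedSamples(coherentSample(sub, cs, schedule, seed = seed,
                                      threshold = threshold,
                                      maxFraction = maxFraction,
                                      maxRetries = maxRetries))
    } else {
      usable <- intersect(names(condList), model@conditionModalities)
      cs <- conditionSet(condList[usable])
      multiConditionSample(model, cs, schedule, n = length(ids), seed = seed)
    }
    out <- scaleOut(target, out)
    rownames(out) <- ids
    out
  }
}
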