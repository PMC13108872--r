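#' @import methods
NULL

#' Variance schedule of a denoising diffusion process
#'
#' Holds the per-step noise variances \eqn{\beta_t}, the retention factors
#' \eqn{\alpha_t = 1 - \beta_t} and the cumulative signal retention
#' \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s} that define both the forward
#' (noising) and reverse (denoising) processes. Construct with
#' [makeSchedule()].
#'
#' @slot steps total number of diffusion steps T.
#' @slot betas,alphas,alphaBars length-T numeric vectors.
#' @slot kind schedule family name (currently `"linear"`).
#' @slot betaStart,betaEnd endpoints of the beta progression, kept so a
#'   schedule can be serialized as a small descriptor and rebuilt exactly.
#' @export
setClass("NoiseSchedule",
  representation(
    steps = "integer", betas = "numeric", alphas = "numeric",
    alphaBars = "numeric", kind = "character",
    betaStart = "numeric", betaEnd = "numeric"
  )
)

setValidity("NoiseSchedule", function(object) {
  msg <- character()
  T <- object@steps
  if (length(T) != 1L || is.na(T) || T < 1L) msg <- c(msg, "steps must be a positive integer")
  for (nm in c("betas", "alphas", "alphaBars")) {
    if (length(slot(object, nm)) != T) msg <- c(msg, sprintf("%s must have length %d", nm, T))
  }
  if (length(msg) == 0L) {
    b <- object@betas
    if (any(b <= 0 | b >= 1)) msg <- c(msg, "every beta_t must lie in (0,1)")
    if (max(abs(object@alphas - (1 - b))) > 1e-12) msg <- c(msg, "alphas must equal 1 - betas")
    ab <- object@alphaBars
    if (max(abs(ab - cumprod(object@alphas))) > 1e-12) {
      msg <- c(msg, "alphaBars must be the cumulative product of alphas")
    }
    if (any(ab <= 0 | ab >= 1)) msg <- c(msg, "every alphaBar_t must lie in (0,1)")
    if (T > 1L && any(diff(ab) >= 0)) msg <- c(msg, "alphaBars must be strictly decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Named per-modality conditioning vectors with presence masks
#'
#' The conditioning input of a diffusion model: one latent matrix per
#' modality (rows are samples) together with a presence flag. Absent
#' modalities contribute an exact zero block to the network input, so their
#' stored values (if any) are never used. Construct with [conditionSet()].
#'
#' @slot values named list of numeric matrices (may hold a placeholder for
#'   absent modalities).
#' @slot present named logical vector, one flag per modality.
#' @export
setClass("ConditionSet",
  representation(values = "list", present = "logical")
)

setValidity("ConditionSet", function(object) {
  msg <- character()
  if (is.null(names(object@present)) || any(!nzchar(names(object@present)))) {
    msg <- c(msg, "presence flags must be named by modality")
  }
  if (!setequal(names(object@values), names(object@present))) {
    msg <- c(msg, "values and presence flags must cover the same modalities")
  }
  for (nm in names(object@present)) {
    if (isTRUE(object@present[[nm]]) && !is.matrix(object@values[[nm]])) {
      msg <- c(msg, sprintf("present modality '%s' must carry a matrix of values", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Trained noise-prediction network
#'
#' Checkpoint of an MLP noise predictor \eqn{\epsilon_\theta(x_t, t, C)}:
#' parameters, architecture configuration, the modalities it conditions on,
#' the best validation generation MSE reached during training, and the full
#' training log. Produced by [trainSingleCondition()] and
#' [trainMultiCondition()]; serialized with [saveCheckpoint()].
#'
#' @slot params flat named list of parameter matrices (treated as opaque).
#' @slot config [predictorConfig()] list used for training.
#' @slot targetModality name of the modality this model generates.
#' @slot conditionModalities names of the conditioning modalities (possibly
#'   empty for a purely unconditional model).
#' @slot conditionDims named integer vector of conditioning latent dims.
#' @slot targetDim latent dimension of the target modality.
#' @slot masked whether the model was trained with subset masking (a
#'   multi-condition model) and therefore accepts absent modalities.
#' @slot bestValMSE minimum validation generation MSE over training.
#' @slot scheduleRef descriptor of the schedule used for training.
#' @slot trainingLog data.frame with columns epoch, trainLoss, valMSE.
#' @export
setClass("NoisePredictor",
  representation(
    params = "list", config = "list", targetModality = "character",
    conditionModalities = "character", conditionDims = "integer",
    targetDim = "integer", masked = "logical", bestValMSE = "numeric",
    scheduleRef = "list", trainingLog = "data.frame"
  )
)

setValidity("NoisePredictor", function(object) {
  msg <- character()
  if (!setequal(names(object@conditionDims), object@conditionModalities)) {
    msg <- c(msg, "conditionDims must be named by the condition modalities")
  }
  log <- object@trainingLog
  if (nrow(log) > 0L && length(object@bestValMSE) == 1L && is.finite(object@bestValMSE)) {
    vals <- log$valMSE[is.finite(log$valMSE)]
    if (length(vals) && object@bestValMSE > min(vals) + 1e-12) {
      msg <- c(msg, "bestValMSE must equal the minimum of the training log")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Coherent Denoising ensemble specification
#'
#' A set of single-condition diffusion models over the same target modality,
#' with normalized non-negative weights (typically inverse validation MSE,
#' see [computeWeights()]). Members may also be plain prediction functions
#' `function(xt, t, cond)`, which is how closed-form oracles are plugged in.
#' Construct with [coherentEnsemble()].
#'
#' @slot members list of [NoisePredictor-class] objects or functions.
#' @slot conditionModalities one conditioning modality per member.
#' @slot weights normalized member weights \eqn{w_i}.
#' @export
setClass("CoherentEnsemble",
  representation(
    members = "list", conditionModalities = "character", weights = "numeric"
  )
)

setValidity("CoherentEnsemble", function(object) {
  msg <- character()
  n <- length(object@members)
  if (n < 1L) msg <- c(msg, "ensemble needs at least one member")
  if (length(object@weights) != n) msg <- c(msg, "one weight per member required")
  if (length(object@conditionModalities) != n) {
    msg <- c(msg, "one condition modality per member required")
  }
  if (anyDuplicated(object@conditionModalities)) {
    msg <- c(msg, "condition modalities must be distinct")
  }
  if (length(object@weights) == n && n >= 1L) {
    if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-12) msg <- c(msg, "weights must sum to one")
  }
  targets <- unique(vapply(object@members, function(m) {
    if (is(m, "NoisePredictor")) m@targetModality else NA_character_
  }, character(1)))
  targets <- targets[!is.na(targets)]
  if (length(targets) > 1L) msg <- c(msg, "all members must target the same modality")
  if (length(msg)) msg else TRUE
})

#' Result of a Coherent Denoising generation
#'
#' @slot samples generated latent matrix (one row per requested sample).
#' @slot accepted per-sample flag: TRUE if the returned trajectory passed the
#'   coherence-based rejection rule, FALSE for best-effort trajectories kept
#'   after exhausting the retries.
#' @slot retriesUsed per-sample count of discarded trajectories.
#' @slot perStepDistance T x n matrix of weighted mean pairwise cosine
#'   distances between member noise predictions, for the returned
#'   trajectories.
#' @slot incoherentFraction per-sample fraction of steps whose coherence
#'   distance exceeded the threshold.
#' @slot threshold,maxFraction the rejection-rule parameters used.
#' @export
setClass("GenerationResult",
  representation(
    samples = "matrix", accepted = "logical", retriesUsed = "integer",
    perStepDistance = "matrix", incoherentFraction = "numeric",
    threshold = "numeric", maxFraction = "numeric"
  )
)

#' Synthetic multimodal cohort
#'
#' A generated cohort with per-modality latent tables, a cluster (tumor-type
#' like) label, an ordinal stage label, survival outcomes, per-modality
#' availability flags and the full generative ground truth (factors,
#' loadings and noise), so that every latent table can be reconstructed
#' exactly from the stored truth. Construct with [generateCohort()].
#'
#' @slot latents named list of n x d latent matrices, rownames are sample IDs.
#' @slot typeLabel factor of cluster labels.
#' @slot stageLabel integer ordinal stage in 1..stageLevels.
#' @slot survivalTime,survivalEvent numeric follow-up time and 0/1 event flag.
#' @slot available named list of per-sample logical availability flags.
#' @slot truth list with the generative components (see [generateCohort()]).
#' @slot config the [cohortConfig()] list used.
#' @export
setClass("SyntheticCohort",
  representation(
    latents = "list", typeLabel = "factor", stageLabel = "integer",
    survivalTime = "numeric", survivalEvent = "integer",
    available = "list", truth = "list", config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  n <- length(object@typeLabel)
  for (nm in names(object@latents)) {
    if (nrow(object@latents[[nm]]) != n) {
      msg <- c(msg, sprintf("latent table '%s' must have %d rows", nm, n))
    }
  }
  if (!setequal(names(object@available), names(object@latents))) {
    msg <- c(msg, "availability flags must cover every modality")
  }
  for (nm in names(object@available)) {
    if (length(object@available[[nm]]) != n) {
      msg <- c(msg, sprintf("availability for '%s' must have length %d", nm, n))
    }
  }
  if (length(object@survivalTime) != n || length(object@survivalEvent) != n ||
      length(object@stageLabel) != n) {
    msg <- c(msg, "labels and outcomes must have one entry per sample")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted per-modality embedding model
#'
#' Maps a preprocessed feature table to the shared low-dimensional latent
#' space, either by PCA or by a small symmetric autoencoder. The per-feature
#' standardization is fit exclusively on training samples and stored with
#' the model. Construct with [fitEmbedding()].
#'
#' @slot modality modality name.
#' @slot method `"pca"` or `"autoencoder"`.
#' @slot latentDim latent dimensionality (32 in the full-scale pipeline).
#' @slot center,scale per-feature standardization parameters (train-fit).
#' @slot fit method-specific fitted state (rotation matrix or network
#'   parameters).
#' @export
setClass("EmbeddingModel",
  representation(
    modality = "character", method = "character", latentDim = "integer",
    center = "numeric", scale = "numeric", fit = "list"
  )
)
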