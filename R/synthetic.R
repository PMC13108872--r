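#' Synthetic multimodal cohort configuration
#'
#' Describes a cohort with cluster (tumor-type like) structure, a signal
#' shared across modalities plus modality-private signal, per-modality
#' missingness, ordinal stage labels and survival outcomes. One modality
#' ("cna" by default) carries a dominant private factor, emulating the
#' regime where its information is largely uncorrelated with the other
#' modalities and therefore poorly reconstructible from them.
#'
#' Each sample draws a type k and a shared factor
#' \eqn{s \sim N(c_k, \sigma_s^2 I)}; modality m observes
#' \eqn{A_m s + B_m u_m + e_m} with private factor
#' \eqn{u_m \sim N(0, \sigma_{p,m}^2 I)} and noise
#' \eqn{e_m \sim N(0, \sigma_e^2 I)}. Stage is an ordinal threshold model
#' on a linear score of s; survival is exponential proportional hazards
#' with a per-type baseline rate, administratively censored at `horizon`.
#' Missingness is independent per modality (MCAR).
#'
#' @param nSamples cohort size.
#' @param nTypes number of clusters (default 6; the full-scale regime has
#'   20).
#' @param modalityDims named integer vector of latent dims (default four
#'   modalities at 8, the desk-scale counterpart of 32).
#' @param sharedDim,privateDim dimensionality of the shared and private
#'   factors.
#' @param typeScale standard deviation of the cluster centers.
#' @param sharedSignalSd within-cluster sd of the shared factor.
#' @param privateSignalSd named per-modality sd of the private factor; the
#'   "cna"-like modality defaults to a dominant 2.0 versus 0.5 elsewhere.
#' @param noiseSd observation noise sd.
#' @param missingRates named per-modality missingness fractions; defaults
#'   mirror the availability pattern of a large pan-cancer cohort (about
#'   14/6/32/25% missing for cna/rnaseq/rppa/wsi).
#' @param stageLevels,stageEffect ordinal stage levels and the strength of
#'   the shared-factor effect on stage.
#' @param survivalBaseline per-type baseline hazard rates (recycled).
#' @param survivalEffect log-hazard coefficient of the shared-factor score.
#' @param horizon administrative censoring time.
#' @param completeFraction fraction of samples reserved as fully observed
#'   (never hit by missingness), usable as a complete test pool.
#' @param seed integer seed.
#' @return a named configuration list.
#' @export
cohortConfig <- function(nSamples = 2000L, nTypes = 6L,
                         modalityDims = c(cna = 8L, rnaseq = 8L, rppa = 8L, wsi = 8L),
                         sharedDim = 4L, privateDim = 2L,
                         typeScale = 1.5, sharedSignalSd = 0.5,
                         privateSignalSd = NULL, noiseSd = 0.3,
                         missingRates = NULL,
                         stageLevels = 4L, stageEffect = 1.0,
                         survivalBaseline = NULL, survivalEffect = 0.5,
                         horizon = 30, completeFraction = 0,
                         seed = 1L) {
  modalityDims <- unlist(modalityDims)
  if (!is.null(privateSignalSd)) privateSignalSd <- unlist(privateSignalSd)
  if (!is.null(missingRates)) missingRates <- unlist(missingRates)
  if (!is.null(survivalBaseline)) survivalBaseline <- unlist(survivalBaseline)
  mods <- names(modalityDims)
  if (is.null(mods)) stop("modalityDims must be named")
  if (is.null(privateSignalSd)) {
    privateSignalSd <- stats::setNames(rep(0.5, length(mods)), mods)
    if ("cna" %in% mods) privateSignalSd[["cna"]] <- 2.0
  }
  if (is.null(missingRates)) {
    defaults <- c(cna = 0.14, rnaseq = 0.06, rppa = 0.32, wsi = 0.25)
    missingRates <- stats::setNames(
      ifelse(mods %in% names(defaults), defaults[mods], 0.1), mods)
  }
  if (is.null(survivalBaseline)) {
    survivalBaseline <- seq(0.02, 0.10, length.out = nTypes)
  }
  cfg <- list(
    nSamples = as.integer(nSamples), nTypes = as.integer(nTypes),
    modalityDims = modalityDims, sharedDim = as.integer(sharedDim),
    privateDim = as.integer(privateDim), typeScale = typeScale,
    sharedSignalSd = sharedSignalSd,
    privateSignalSd = privateSignalSd[mods], noiseSd = noiseSd,
    missingRates = missingRates[mods], stageLevels = as.integer(stageLevels),
    stageEffect = stageEffect,
    survivalBaseline = rep_len(survivalBaseline, nTypes),
    survivalEffect = survivalEffect, horizon = horizon,
    completeFraction = completeFraction, seed = as.integer(seed)
  )
  if (cfg$nTypes < 2L) stop("nTypes must be at least 2")
  if (any(unlist(cfg[c("sharedSignalSd", "noiseSd")]) <= 0)) {
    stop("signal and noise standard deviations must be positive")
  }
  if (any(cfg$missingRates < 0 | cfg$missingRates >= 1)) {
    stop("missing rates must lie in [0, 1)")
  }
  cfg
}

#' Generate a synthetic multimodal cohort
#'
#' Draws a cohort under the generative model documented in
#' [cohortConfig()]. All generative components (cluster centers, loading
#' matrices, factors and noise) are stored in the `truth` slot, so every
#' latent table is reproduced exactly by
#' `shared %*% t(A) + private %*% t(B) + noise` and oracle checks can
#' invert the generative map.
#'
#' @param config a [cohortConfig()] list.
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(config) {
  cfg <- config
  mods <- names(cfg$modalityDims)
  n <- cfg$nSamples; q <- cfg$sharedDim; p <- cfg$privateDim
  withSeed(cfg$seed, {
    centers <- matrix(stats::rnorm(cfg$nTypes * q, sd = cfg$typeScale), cfg$nTypes, q)
    A <- lapply(mods, function(m)
      matrix(stats::rnorm(cfg$modalityDims[[m]] * q, sd = 1 / sqrt(q)),
             cfg$modalityDims[[m]], q))
    B <- lapply(mods, function(m)
      matrix(stats::rnorm(cfg$modalityDims[[m]] * p, sd = 1 / sqrt(p)),
             cfg$modalityDims[[m]], p))
    names(A) <- names(B) <- mods
    type <- sample.int(cfg$nTypes, n, replace = TRUE)
    shared <- centers[type, , drop = FALSE] +
      matrix(stats::rnorm(n * q, sd = cfg$sharedSignalSd), n, q)
    private <- list(); noise <- list(); latents <- list()
    for (m in mods) {
      d <- cfg$modalityDims[[m]]
      private[[m]] <- matrix(stats::rnorm(n * p, sd = cfg$privateSignalSd[[m]]), n, p)
      noise[[m]] <- matrix(stats::rnorm(n * d, sd = cfg$noiseSd), n, d)
      latents[[m]] <- shared %*% t(A[[m]]) + private[[m]] %*% t(B[[m]]) + noise[[m]]
    }
    stageW <- stats::rnorm(q); stageW <- stageW / sqrt(sum(stageW^2))
    stageScore <- cfg$stageEffect * drop(shared %*% stageW) + stats::rlogis(n)
    breaks <- stats::quantile(stageScore, probs = seq(0, 1, length.out = cfg$stageLevels + 1L))
    breaks[1L] <- -Inf; breaks[length(breaks)] <- Inf
    stage <- as.integer(cut(stageScore, breaks, labels = FALSE, include.lowest = TRUE))
    survW <- stats::rnorm(q); survW <- survW / sqrt(sum(survW^2))
    linpred <- cfg$survivalEffect * drop(shared %*% survW)
    rate <- cfg$survivalBaseline[type] * exp(linpred)
    rawTime <- stats::rexp(n, rate)
    event <- as.integer(rawTime <= cfg$horizon)
    time <- pmin(rawTime, cfg$horizon)
    reserved <- if (cfg$completeFraction > 0) {
      sample.int(n, ceiling(cfg$completeFraction * n))
    } else integer(0)
    available <- list()
    for (m in mods) {
      avail <- stats::runif(n) >= cfg$missingRates[[m]]
      avail[reserved] <- TRUE
      available[[m]] <- avail
    }
    ids <- sprintf("S%05d", seq_len(n))
    for (m in mods) {
      dimnames(latents[[m]]) <- list(ids, paste0(m, seq_len(cfg$modalityDims[[m]])))
    }
    new("SyntheticCohort",
      latents = latents,
      typeLabel = factor(paste0("T", type), levels = paste0("T", seq_len(cfg$nTypes))),
      stageLabel = stage, survivalTime = time, survivalEvent = event,
      available = available,
      truth = list(centers = centers, loadingsShared = A, loadingsPrivate = B,
                   sharedFactor = shared, privateFactors = private,
                   noise = noise, stageWeights = stageW, stageScore = stageScore,
                   survWeights = survW, linearPredictor = linpred,
                   reservedComplete = ids[reserved]),
      config = cfg
    )
  })
}

#' @rdname generateCohort
#' @param cohort a [SyntheticCohort-class].
#' @export
modalityNames <- function(cohort) names(cohort@latents)

#' @rdname generateCohort
#' @param modality modality name; all modalities when NULL.
#' @export
cohortLatents <- function(cohort, modality = NULL) {
  if (is.null(modality)) cohort@latents else cohort@latents[[modality]]
}

#' @rdname generateCohort
#' @export
sampleIds <- function(cohort) rownames(cohort@latents[[1L]])

#' @rdname generateCohort
#' @export
typeLabels <- function(cohort) cohort@typeLabel

#' @rdname generateCohort
#' @export
stageLabels <- function(cohort) cohort@stageLabel

#' @rdname generateCohort
#' @export
survivalOutcomes <- function(cohort) {
  data.frame(id = sampleIds(cohort), time = cohort@survivalTime,
             event = cohort@survivalEvent)
}

#' @rdname generateCohort
#' @export
availability <- function(cohort, modality = NULL) {
  if (is.null(modality)) cohort@available else cohort@available[[modality]]
}

#' @rdname generateCohort
#' @export
cohortTruth <- function(cohort) cohort@truth

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d samples, %d types, modalities: %s\n",
    length(object@typeLabel), nlevels(object@typeLabel),
    paste(sprintf("%s(d=%d, %.0f%% avail)", names(object@latents),
                  vapply(object@latents, ncol, integer(1)),
                  100 * vapply(object@available, mean, numeric(1))),
          collapse = ", ")))
})

#' Add missingness to a cohort copy
#'
#' Marks modalities unavailable per the requested pattern without touching
#' the original cohort: `TRUE` removes a modality everywhere, a fraction in
#' (0, 1) removes a seeded random subset of samples.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param pattern named list/vector: modality -> TRUE or removal fraction.
#' @param seed integer seed for fractional removal.
#' @return a degraded copy of the cohort.
#' @export
degradeCohort <- function(cohort, pattern, seed = 1L) {
  unknown <- setdiff(names(pattern), modalityNames(cohort))
  if (length(unknown)) {
    stop(sprintf("unknown modality: %s", paste(unknown, collapse = ", ")))
  }
  out <- cohort
  n <- length(cohort@typeLabel)
  withSeed(seed, {
    for (m in names(pattern)) {
      p <- pattern[[m]]
      if (isTRUE(p)) {
        out@available[[m]] <- rep(FALSE, n)
      } else if (is.numeric(p) && p >= 0 && p <= 1) {
        drop <- sample.int(n, round(p * n))
        avail <- out@available[[m]]
        avail[drop] <- FALSE
        out@available[[m]] <- avail
      } else {
        stop("pattern entries must be TRUE or a fraction in [0, 1]")
      }
    }
  })
  out
}

#' Relabel a cohort with a partly modality-private outcome
#'
#' Builds a binary label whose signal is carried by the shared factor for
#' most samples but, within a minority subgroup of cluster types, by the
#' private factor of one modality — the regime where a specific tumor
#' type's outcome hinges on information only that modality carries. Only
#' the real data of that modality can resolve the subgroup's labels, so
#' informed (counterfactual-variance driven) acquisition of real data
#' should beat random acquisition.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param modality the modality whose private factor carries the subgroup
#'   signal.
#' @param fracInformative target fraction of samples in the private-signal
#'   subgroup (default 0.25); whole cluster types are assigned to the
#'   subgroup until the fraction is reached.
#' @param effect strength of the private-factor effect (default 4).
#' @param seed integer seed.
#' @return list with `label` (factor), `informative` (logical flag per
#'   sample), `informativeTypes` (the subgroup's type levels) and `score`
#'   (the latent score).
#' @export
privateSignalLabels <- function(cohort, modality, fracInformative = 0.25,
                                effect = 4, seed = 1L) {
  truth <- cohort@truth
  n <- length(cohort@typeLabel)
  u <- truth$privateFactors[[modality]]
  withSeed(seed, {
    w <- stats::rnorm(ncol(truth$sharedFactor)); w <- w / sqrt(sum(w^2))
    v <- stats::rnorm(ncol(u)); v <- v / sqrt(sum(v^2))
    typeOrder <- sample(levels(cohort@typeLabel))
    counts <- table(cohort@typeLabel)[typeOrder]
    nTake <- which(cumsum(counts) >= fracInformative * n)[1L]
    informativeTypes <- typeOrder[seq_len(nTake)]
    informative <- cohort@typeLabel %in% informativeTypes
    score <- drop(truth$sharedFactor %*% w) +
      effect * informative * drop(u %*% v)
    label <- factor(ifelse(score > stats::median(score), "high", "low"))
    list(label = label, informative = informative,
         informativeTypes = informativeTypes, score = score)
  })
}

#' Export / read a cohort as delimited tables
#'
#' Writes one TSV per modality plus a labels table (type, stage, survival)
#' and an availability table, in the layout the preprocessing readers
#' consume, so the full pipeline can be driven end-to-end from fixtures.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory.
#' @return `exportCohort()` returns `dir` invisibly; `readCohortDir()`
#'   returns a list with `latents`, `labels` and `available`.
#' @export
exportCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in modalityNames(cohort)) {
    writeModalityTable(cohort@latents[[m]], file.path(dir, paste0(m, ".tsv")))
  }
  labels <- data.frame(
    sample_id = sampleIds(cohort), type = as.character(cohort@typeLabel),
    stage = cohort@stageLabel, time = cohort@survivalTime,
    event = cohort@survivalEvent)
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  avail <- data.frame(sample_id = sampleIds(cohort),
                      lapply(cohort@available, as.integer))
  utils::write.table(avail, file.path(dir, "availability.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname exportCohort
#' @export
readCohortDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  special <- c("labels.tsv", "availability.tsv")
  latents <- list()
  for (f in files[!basename(files) %in% special]) {
    latents[[sub("\\.tsv$", "", basename(f))]] <- readModalityTable(f)
  }
  labels <- utils::read.delim(file.path(dir, "labels.tsv"))
  avail <- utils::read.delim(file.path(dir, "availability.tsv"))
  list(latents = latents, labels = labels,
       available = lapply(avail[-1L], function(x) as.logical(x)))
}
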