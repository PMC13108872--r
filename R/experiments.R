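#' Experiment configuration
#'
#' @param nRuns independent generation runs per condition (default 10).
#' @param nTrees trees / boosting rounds for the downstream models
#'   (default 500).
#' @param seed master seed; all run seeds derive from it.
#' @return a named list.
#' @export
experimentConfig <- function(nRuns = 10L, nTrees = 500L, seed = 1L) {
  if (nRuns < 1L) stop("nRuns must be at least 1")
  list(nRuns = as.integer(nRuns), nTrees = as.integer(nTrees),
       seed = as.integer(seed))
}

taskLabels <- function(cohort, task) {
  switch(task,
    type = cohort@typeLabel,
    stage = factor(cohort@stageLabel),
    stop(sprintf("unknown task '%s'", task)))
}

genericNames <- function(features) {
  colnames(features) <- paste0("V", seq_len(ncol(features)))
  features
}

trainForestClassifier <- function(features, labels, nTrees, seed) {
  df <- data.frame(genericNames(features), check.names = FALSE)
  df$.label <- factor(labels)
  ranger::ranger(dependent.variable.name = ".label", data = df,
                 num.trees = nTrees, probability = TRUE, seed = seed,
                 num.threads = 1L)
}

predictForestLabels <- function(model, features) {
  probs <- stats::predict(model,
                          data.frame(genericNames(features), check.names = FALSE),
                          num.threads = 1L)$predictions
  factor(colnames(probs)[max.col(probs, ties.method = "first")],
         levels = colnames(probs))
}

#' Classifier parity between real and generated data
#'
#' Trains one single-modality classifier per modality on real training
#' data (tumor-type and stage tasks) and compares its performance on the
#' real test set against `nRuns` seeded synthetic test sets per generator,
#' each produced by generating the target modality conditioned on the
#' remaining real modalities.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param split a [stratifiedSplit()] result.
#' @param generators named list of generator functions (see
#'   [realDataGenerator()]).
#' @param tasks subset of `c("type", "stage")`.
#' @param config an [experimentConfig()].
#' @return data.frame of [metricReport()] rows.
#' @export
parityExperiment <- function(cohort, split, generators,
                             tasks = c("type", "stage"),
                             config = experimentConfig()) {
  mods <- modalityNames(cohort)
  ids <- sampleIds(cohort)
  rows <- list()
  for (task in tasks) {
    y <- stats::setNames(taskLabels(cohort, task), ids)
    for (m in mods) {
      clf <- trainForestClassifier(cohort@latents[[m]][split$train, , drop = FALSE],
                                   y[split$train], config$nTrees,
                                   deriveSeed(config$seed, 11L))
      yTest <- y[split$test]
      realPred <- predictForestLabels(clf, cohort@latents[[m]][split$test, , drop = FALSE])
      rows[[length(rows) + 1L]] <- metricReport(
        "macroF1", macroF1(yTest, realPred), target = m, method = "real", context = task)
      rows[[length(rows) + 1L]] <- metricReport(
        "balancedAccuracy", balancedAccuracy(yTest, realPred),
        target = m, method = "real", context = task)
      conditions <- cohort@latents[setdiff(mods, m)]
      for (g in names(generators)) {
        f1s <- numeric(config$nRuns); bas <- numeric(config$nRuns)
        for (r in seq_len(config$nRuns)) {
          synth <- generators[[g]](m, conditions, split$test,
                                   seed = deriveSeed(config$seed, 100L + r))
          pred <- predictForestLabels(clf, synth)
          f1s[r] <- macroF1(yTest, pred)
          bas[r] <- balancedAccuracy(yTest, pred)
        }
        rows[[length(rows) + 1L]] <- metricReport(
          "macroF1", f1s, target = m, method = g, context = task)
        rows[[length(rows) + 1L]] <- metricReport(
          "balancedAccuracy", bas, target = m, method = g, context = task)
      }
    }
  }
  do.call(rbind, rows)
}

concatFeatures <- function(latents, ids, mods) {
  out <- do.call(cbind, lapply(mods, function(m) {
    x <- latents[[m]][ids, , drop = FALSE]
    colnames(x) <- paste0(m, ".", seq_len(ncol(x)))
    x
  }))
  rownames(out) <- ids
  out
}

trainXgbClassifier <- function(features, labels, nTrees, seed) {
  labels <- factor(labels)
  dtrain <- xgboost::xgb.DMatrix(features, label = as.integer(labels) - 1L)
  booster <- withSeed(seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nlevels(labels),
                  max_depth = 4, eta = 0.1, nthread = 1),
    data = dtrain, nrounds = nTrees, verbose = 0))
  list(booster = booster, levels = levels(labels))
}

predictXgbProbs <- function(model, features) {
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(features))
  if (is.null(dim(p))) {
    p <- matrix(p, ncol = length(model$levels), byrow = TRUE)
  }
  colnames(p) <- model$levels
  p
}

predictXgbLabels <- function(model, features) {
  p <- predictXgbProbs(model, features)
  factor(model$levels[max.col(p, ties.method = "first")], levels = model$levels)
}

trainXgbSurvival <- function(features, times, events, nTrees, seed) {
  lab <- ifelse(events == 1, times, -times)  # survival:cox convention
  dtrain <- xgboost::xgb.DMatrix(features, label = lab)
  withSeed(seed, xgboost::xgb.train(
    params = list(objective = "survival:cox", max_depth = 3, eta = 0.05,
                  nthread = 1),
    data = dtrain, nrounds = nTrees, verbose = 0))
}

#' Ablation versus synthetic completion of missing modalities
#'
#' Trains multimodal downstream models (a gradient-boosted classifier for
#' stage and a boosted proportional-hazards model for survival, both with
#' native missing-value routing) on the full training data, then evaluates
#' the test set under each missing-data pattern three ways: full real
#' data, ablated (missing features flagged as NA) and completed by each
#' generator. A label-only baseline (same classifier on a one-hot tumor
#' type encoding) isolates the signal beyond the dominant type signature.
#' "drop" is full minus ablated; "gain" is completed minus ablated.
#'
#' @param cohort,split,generators,config as in [parityExperiment()].
#' @param patterns named list of character vectors: modalities removed in
#'   each scenario.
#' @param tasks subset of `c("stage", "survival")`.
#' @return data.frame with one row per (task, pattern, method).
#' @export
completionExperiment <- function(cohort, split, patterns, generators,
                                 tasks = c("stage", "survival"),
                                 config = experimentConfig()) {
  mods <- modalityNames(cohort)
  ids <- sampleIds(cohort)
  trainX <- concatFeatures(cohort@latents, split$train, mods)
  testX <- concatFeatures(cohort@latents, split$test, mods)
  stage <- stats::setNames(factor(cohort@stageLabel), ids)
  time <- stats::setNames(cohort@survivalTime, ids)
  event <- stats::setNames(cohort@survivalEvent, ids)
  type <- stats::setNames(cohort@typeLabel, ids)

  models <- list()
  if ("stage" %in% tasks) {
    models$stage <- trainXgbClassifier(trainX, stage[split$train], config$nTrees,
                                       deriveSeed(config$seed, 21L))
    oneHot <- function(f) {
      m <- stats::model.matrix(~ 0 + f)
      colnames(m) <- levels(f)
      m
    }
    models$labelOnly <- trainXgbClassifier(oneHot(type[split$train]),
                                           stage[split$train], config$nTrees,
                                           deriveSeed(config$seed, 22L))
    labelOnlyPred <- predictXgbLabels(models$labelOnly, oneHot(type[split$test]))
  }
  if ("survival" %in% tasks) {
    models$survival <- trainXgbSurvival(trainX, time[split$train],
                                        event[split$train], config$nTrees,
                                        deriveSeed(config$seed, 23L))
  }
  score <- function(task, X) {
    if (task == "stage") {
      macroF1(stage[split$test], predictXgbLabels(models$stage, X))
    } else {
      risk <- stats::predict(models$survival, xgboost::xgb.DMatrix(X))
      concordanceIndex(time[split$test], event[split$test], risk)
    }
  }
  maskPattern <- function(X, removed) {
    for (m in removed) X[, grep(paste0("^", m, "\\."), colnames(X))] <- NA_real_
    X
  }
  completed <- function(removed, g, seed) {
    X <- testX
    conditions <- cohort@latents[setdiff(mods, removed)]
    for (m in removed) {
      synth <- generators[[g]](m, conditions, split$test, seed = deriveSeed(seed, match(m, mods)))
      X[, grep(paste0("^", m, "\\."), colnames(X))] <- synth
    }
    X
  }
  rows <- list()
  for (task in tasks) {
    full <- score(task, testX)
    rows[[length(rows) + 1L]] <- data.frame(
      task = task, pattern = "none", method = "full", value = full,
      sd = NA_real_, nRuns = 1L)
    if (task == "stage") {
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, pattern = "none", method = "labelOnly",
        value = macroF1(stage[split$test], labelOnlyPred), sd = NA_real_, nRuns = 1L)
    }
    for (p in names(patterns)) {
      removed <- patterns[[p]]
      if (length(removed) == 0L) {
        abl <- full
      } else {
        abl <- score(task, maskPattern(testX, removed))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, pattern = p, method = "ablated", value = abl,
        sd = NA_real_, nRuns = 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, pattern = p, method = "drop", value = full - abl,
        sd = NA_real_, nRuns = 1L)
      for (g in names(generators)) {
        vals <- vapply(seq_len(config$nRuns), function(r) {
          X <- if (length(removed) == 0L) testX
               else completed(removed, g, deriveSeed(config$seed, 300L + r))
          score(task, X)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          task = task, pattern = p, method = paste0("completed:", g),
          value = mean(vals), sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
          nRuns = length(vals))
        rows[[length(rows) + 1L]] <- data.frame(
          task = task, pattern = p, method = paste0("gain:", g),
          value = mean(vals) - abl, sd = NA_real_, nRuns = length(vals))
      }
    }
  }
  do.call(rbind, rows)
}

#' Unconditional-generation privacy probe
#'
#' Generates `n` samples without any informative conditioning from both a
#' Coherent Denoising ensemble (zero-vector conditions) and a masked
#' multi-condition model (fully masked conditions), `nRuns` times each,
#' and scores manifold-coverage F1 and energy distance against the real
#' reference set. A model that cannot reproduce the reference manifold
#' without input (coverage 0, high energy distance) is the
#' privacy-preserving outcome.
#'
#' @param ensemble a [CoherentEnsemble-class].
#' @param multiModel a masked [NoisePredictor-class].
#' @param reference real latent matrix of the target modality (training
#'   manifold).
#' @param schedule a [NoiseSchedule-class].
#' @param n samples per probe (default: nrow(reference)).
#' @param nRuns probe repetitions.
#' @param seed master seed.
#' @param k neighborhood size for coverage.
#' @return data.frame of [metricReport()] rows (coverage F1 and energy
#'   distance per model).
#' @export
privacyProbeExperiment <- function(ensemble, multiModel, reference, schedule,
                                   n = nrow(reference), nRuns = 10L,
                                   seed = 1L, k = 5L) {
  probes <- list(coherentDenoising = ensemble, multiCondition = multiModel)
  rows <- list()
  for (nm in names(probes)) {
    f1 <- numeric(nRuns); ed <- numeric(nRuns)
    for (r in seq_len(nRuns)) {
      gen <- unconditionalProbe(probes[[nm]], schedule, n,
                                seed = deriveSeed(seed, 500L + r))
      f1[r] <- manifoldCoverage(reference, gen, k = k)[["f1"]]
      ed[r] <- energyDistance(reference, gen)
    }
    rows[[length(rows) + 1L]] <- metricReport("coverageF1", f1, method = nm)
    rows[[length(rows) + 1L]] <- metricReport("energyDistance", ed, method = nm)
  }
  do.call(rbind, rows)
}

#' Counterfactual variance scores for data-acquisition prioritization
#'
#' For each profile with the target modality considered missing: generate
#' `nVersions` versions of it with different seeds, run the classifier on
#' each completed profile, and score the average across-version variance
#' of the class probabilities. A high score flags prediction instability —
#' the real data likely carries signal not redundant with the available
#' modalities. Deterministic generators and classifiers that ignore the
#' target modality both score exactly 0.
#'
#' @param predictProb function mapping a named list of modality matrices
#'   to an n x classes probability matrix.
#' @param conditions named list of real matrices for the available
#'   modalities.
#' @param target the missing modality name.
#' @param generator a generator function.
#' @param ids sample IDs (rows of the condition matrices).
#' @param nVersions generated versions per profile (default 10).
#' @param seed master seed.
#' @return data.frame with columns id, score and nVersions.
#' @export
counterfactualVarianceScores <- function(predictProb, conditions, target,
                                         generator, ids, nVersions = 10L,
                                         seed = 1L) {
  probs <- vector("list", nVersions)
  for (v in seq_len(nVersions)) {
    synth <- generator(target, conditions, ids, seed = deriveSeed(seed, 700L + v))
    features <- c(lapply(conditions, function(x) x[ids, , drop = FALSE]),
                  stats::setNames(list(synth), target))
    probs[[v]] <- predictProb(features)
  }
  mean_ <- Reduce(`+`, probs) / nVersions
  ss <- Reduce(`+`, lapply(probs, function(p) (p - mean_)^2))
  score <- rowMeans(ss / (nVersions - 1))
  data.frame(id = ids, score = unname(score), nVersions = nVersions)
}

#' Informed versus random data-acquisition curves
#'
#' For each acquisition fraction, replaces the hidden target modality with
#' real data for the selected subset — either in descending
#' counterfactual-variance order (informed; ties broken by sample ID) or
#' in random order (one ordering per run) — generates the remainder, and
#' evaluates macro F1. Reports the curves and the area under each
#' (trapezoid over the fraction grid).
#'
#' @param predictLabel function mapping a named list of modality matrices
#'   to predicted labels.
#' @param y true labels for `ids`.
#' @param conditions named list of real matrices for the available
#'   modalities.
#' @param target hidden modality name.
#' @param realTarget the real matrix of the hidden modality.
#' @param generator a generator function.
#' @param scores data.frame from [counterfactualVarianceScores()].
#' @param ids sample IDs.
#' @param fractions acquisition grid (default 0, 0.1, ..., 1).
#' @param nRuns random orderings / generation seeds (default 10).
#' @param seed master seed.
#' @return list with `curves` (strategy, run, fraction, f1) and `areas`
#'   (strategy, run, area).
#' @export
prioritizationCurves <- function(predictLabel, y, conditions, target,
                                 realTarget, generator, scores, ids,
                                 fractions = seq(0, 1, by = 0.1),
                                 nRuns = 10L, seed = 1L) {
  n <- length(ids)
  ord <- scores$id[order(-scores$score, scores$id)]
  evalSubset <- function(acquired, genSeed) {
    synth <- generator(target, conditions, ids, seed = genSeed)
    X <- synth
    if (length(acquired)) {
      X[match(acquired, ids), ] <- realTarget[acquired, , drop = FALSE]
    }
    features <- c(lapply(conditions, function(x) x[ids, , drop = FALSE]),
                  stats::setNames(list(X), target))
    macroF1(y, predictLabel(features))
  }
  curves <- list()
  for (r in seq_len(nRuns)) {
    genSeed <- deriveSeed(seed, 900L + r)
    randomOrder <- withSeed(deriveSeed(seed, 950L + r), sample(ids))
    for (f in fractions) {
      kAcq <- round(f * n)
      inf <- evalSubset(utils::head(ord, kAcq), genSeed)
      rnd <- evalSubset(utils::head(randomOrder, kAcq), genSeed)
      curves[[length(curves) + 1L]] <- data.frame(
        strategy = c("informed", "random"), run = r, fraction = f,
        f1 = c(inf, rnd))
    }
  }
  curves <- do.call(rbind, curves)
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  areas <- do.call(rbind, lapply(split(curves, curves[c("strategy", "run")]), function(d) {
    d <- d[order(d$fraction), ]
    data.frame(strategy = d$strategy[1L], run = d$run[1L],
               area = trap(d$fraction, d$f1))
  }))
  rownames(areas) <- NULL
  list(curves = curves, areas = areas)
}
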