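# Shared fixtures. Trained models are expensive, so they are built once
# per test run and cached; every consumer states the fixture's conditions
# through these helpers rather than re-deriving them.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# Short schedule for desk-scale runs: alphaBar_T ~ 7e-3 at T = 200.
testSchedule <- function() makeSchedule(200L, 1e-4, 0.05)

clusterMatrix <- function(n, centers, sd, seed) {
  withr::with_seed(seed, {
    type <- sample.int(nrow(centers), n, replace = TRUE)
    x <- centers[type, , drop = FALSE] +
      matrix(rnorm(n * ncol(centers), sd = sd), n, ncol(centers))
    rownames(x) <- sprintf("S%04d", seq_len(n))
    attr(x, "type") <- type
    x
  })
}

# Copy task: 2-D latent, 3 clusters, n = 600, condition identical to the
# target; a conditional model that works must reproduce its condition.
copyTaskFixture <- function() {
  cached("copyTask", function() {
    centers <- matrix(c(-2, -2, 0, 2, 2, -1), 3, 2, byrow = TRUE)
    lat <- clusterMatrix(600, centers, sd = 0.3, seed = 101)
    train <- list(a = lat[1:500, ], b = lat[1:500, ])
    val <- list(a = lat[501:600, ], b = lat[501:600, ])
    sch <- testSchedule()
    cfg <- predictorConfig(
      nHiddenLayers = 2L, hiddenSize = 64L, timeEmbedDim = 32L,
      condEmbedDim = 16L, learningRate = 1e-3, batchSize = 128L,
      maxEpochs = 800L, patience = 5L, evalInterval = 100L)
    ckpt <- trainSingleCondition(train, val, "a", "b", cfg, sch, seed = 3L)
    list(train = train, val = val, schedule = sch, config = cfg,
         checkpoint = ckpt)
  })
}

# Privacy-asymmetry scenario: well-separated clustered cohort, 6 types,
# 2 modalities, n = 2000; one single-condition model (the ensemble) and
# one masked multi-condition model trained on identical data.
privacyFixture <- function() {
  cached("privacy", function() {
    cfg <- cohortConfig(
      nSamples = 2000L, nTypes = 6L, typeScale = 3,
      modalityDims = c(m1 = 8L, m2 = 8L),
      privateSignalSd = c(m1 = 0.4, m2 = 0.4),
      sharedSignalSd = 0.4, noiseSd = 0.2,
      missingRates = c(m1 = 0, m2 = 0), seed = 11L)
    cohort <- generateCohort(cfg)
    split <- stratifiedSplit(sampleIds(cohort), typeLabels(cohort), seed = 5L)
    scalers <- lapply(cohortLatents(cohort), function(x)
      latentScaler(x[split$train, , drop = FALSE]))
    lat <- lapply(names(scalers), function(m)
      scalers[[m]]$apply(cohortLatents(cohort, m)))
    names(lat) <- names(scalers)
    trainT <- lapply(lat, function(x) x[split$train, , drop = FALSE])
    valT <- lapply(lat, function(x) x[split$val, , drop = FALSE])
    sch <- testSchedule()
    pcfg <- predictorConfig(
      nHiddenLayers = 3L, hiddenSize = 128L, timeEmbedDim = 32L,
      condEmbedDim = 16L, learningRate = 1e-3, batchSize = 128L,
      maxEpochs = 400L, patience = 4L, evalInterval = 50L)
    single <- trainSingleCondition(trainT, valT, "m1", "m2", pcfg, sch, seed = 21L)
    multi <- trainMultiCondition(trainT, valT, "m1", "m2", pcfg, sch, seed = 22L)
    list(cohort = cohort, split = split, scalers = scalers, schedule = sch,
         trainT = trainT, valT = valT, single = single, multi = multi,
         ensemble = coherentEnsemble(list(single)))
  })
}

# Small three-modality cohort shared by the experiment harness tests.
experimentCohort <- function() {
  cached("experimentCohort", function() {
    cohort <- generateCohort(cohortConfig(
      nSamples = 900L, nTypes = 3L,
      modalityDims = c(cna = 5L, rnaseq = 5L, rppa = 5L),
      privateSignalSd = c(cna = 2.0, rnaseq = 0.4, rppa = 0.4),
      missingRates = c(cna = 0, rnaseq = 0, rppa = 0), seed = 55L))
    split <- stratifiedSplit(sampleIds(cohort), typeLabels(cohort), seed = 56L)
    list(cohort = cohort, split = split)
  })
}

# Prioritization scenario: three modalities; a minority of cluster types
# carry label signal only in m1's private factor.
prioritizationFixture <- function() {
  cached("prioritization", function() {
    cfg <- cohortConfig(
      nSamples = 1500L, nTypes = 4L,
      modalityDims = c(m1 = 6L, m2 = 6L, m3 = 6L),
      privateSignalSd = c(m1 = 1.5, m2 = 0.4, m3 = 0.4),
      missingRates = c(m1 = 0, m2 = 0, m3 = 0), seed = 7L)
    cohort <- generateCohort(cfg)
    labels <- privateSignalLabels(cohort, "m1", fracInformative = 0.3,
                                  effect = 6, seed = 8L)
    split <- stratifiedSplit(sampleIds(cohort), typeLabels(cohort), seed = 9L)
    lat <- cohortLatents(cohort)
    y <- stats::setNames(labels$label, sampleIds(cohort))
    concat <- function(featureList) {
      do.call(cbind, lapply(names(lat), function(m) {
        x <- featureList[[m]]
        colnames(x) <- paste0(m, ".", seq_len(ncol(x)))
        x
      }))
    }
    clf <- ranger::ranger(
      y = y[split$train],
      x = data.frame(concat(lapply(lat, function(x) x[split$train, ])),
                     check.names = FALSE),
      num.trees = 300, probability = TRUE, seed = 1, num.threads = 1)
    predictProb <- function(featureList) {
      stats::predict(clf, data.frame(concat(featureList), check.names = FALSE),
                     num.threads = 1)$predictions
    }
    predictLabel <- function(featureList) {
      p <- predictProb(featureList)
      factor(colnames(p)[max.col(p, ties.method = "first")], levels = levels(y))
    }
    list(cohort = cohort, labels = labels, split = split, y = y,
         predictProb = predictProb, predictLabel = predictLabel,
         generator = truthConditionalGenerator(cohort))
  })
}
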