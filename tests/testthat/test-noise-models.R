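# The MLP noise-predictor contract: time embedding, condition masking,
# training loops and checkpointing.

tinyTables <- function(seed = 77, n = 120, d = 3) {
  withr::with_seed(seed, {
    mk <- function() {
      x <- matrix(rnorm(n * d), n, d)
      rownames(x) <- sprintf("S%03d", seq_len(n))
      x
    }
    list(a = mk(), b = mk(), c = mk())
  })
}

tinyConfig <- function(...) {
  base <- list(nHiddenLayers = 2L, hiddenSize = 16L, timeEmbedDim = 8L,
               condEmbedDim = 4L, learningRate = 1e-3, batchSize = 32L,
               maxEpochs = 20L, patience = 2L, evalInterval = 10L)
  do.call(predictorConfig, utils::modifyList(base, list(...)))
}

test_that("time embedding follows the sinusoidal convention", {
  expect_equal(timeEmbedding(0, 8L), rep(c(0, 1), 4))
  expect_equal(timeEmbedding(10000, 2L), c(sin(1), cos(1)))
  e <- timeEmbedding(c(3, 17, 123), 16L)
  expect_identical(dim(e), c(3L, 16L))
  expect_true(all(e >= -1 & e <= 1))
  expect_error(timeEmbedding(1, 7L), "even")
  expect_error(timeEmbedding(-1, 4L), "non-negative")
})

test_that("condition projection zeroes absent modalities exactly", {
  proj <- list(a = diag(3), b = matrix(1, 2, 3))
  # all absent: exact zero vector of length k * embDim
  cs <- conditionSet(list(a = NULL, b = NULL))
  expect_equal(projectConditions(cs, proj), matrix(0, 1, 6))
  # absent modality values never influence the output
  v <- matrix(c(1, 2, 3), 1)
  cs1 <- conditionSet(list(a = v, b = matrix(99, 1, 2)),
                      present = c(a = TRUE, b = FALSE))
  cs2 <- conditionSet(list(a = v, b = matrix(-5, 1, 2)),
                      present = c(a = TRUE, b = FALSE))
  expect_identical(projectConditions(cs1, proj), projectConditions(cs2, proj))
  # identity projection passes the value through
  expect_equal(projectConditions(cs1, proj)[, 1:3], drop(v))
  expect_equal(projectConditions(cs1, proj)[, 4:6], rep(0, 3))
  # unknown modality is rejected
  cs3 <- conditionSet(list(z = v))
  expect_error(projectConditions(cs3, proj), "unknown")
})

test_that("training returns a usable checkpoint and an honest log", {
  tabs <- tinyTables()
  train <- lapply(tabs, function(x) x[1:100, ])
  val <- lapply(tabs, function(x) x[101:120, ])
  sch <- makeSchedule(20L, 1e-3, 0.1)
  ck <- trainSingleCondition(train, val, "a", "b", tinyConfig(), sch, seed = 5L)
  expect_s4_class(ck, "NoisePredictor")
  expect_equal(ck@bestValMSE, min(ck@trainingLog$valMSE))
  expect_true(validObject(ck))
  # deterministic evaluation mode
  xt <- matrix(rnorm(15), 5, 3)
  cs <- conditionSet(list(b = val$b[1:5, ]))
  expect_identical(predictNoise(ck, xt, 3L, cs), predictNoise(ck, xt, 3L, cs))
  # seeded initialization is reproducible end to end
  ck2 <- trainSingleCondition(train, val, "a", "b", tinyConfig(), sch, seed = 5L)
  expect_identical(predictNoise(ck2, xt, 3L, cs), predictNoise(ck, xt, 3L, cs))
  # empty training data aborts
  expect_error(trainSingleCondition(lapply(train, function(x) x[0, , drop = FALSE]),
                                    val, "a", "b", tinyConfig(), sch, seed = 1L),
               "empty")
})

test_that("training loss decreases over the first hundred epochs", {
  tabs <- tinyTables(seed = 31, n = 80, d = 2)
  train <- lapply(tabs, function(x) x[1:64, ])
  val <- lapply(tabs, function(x) x[65:80, ])
  sch <- makeSchedule(20L, 1e-3, 0.1)
  cfg <- tinyConfig(maxEpochs = 100L, evalInterval = 20L, patience = 100L)
  ck <- trainSingleCondition(train, val, "a", "b", cfg, sch, seed = 2L)
  log <- ck@trainingLog
  expect_lt(log$trainLoss[nrow(log)], log$trainLoss[1L])
})

test_that("masked modalities cannot influence a multi-condition model", {
  tabs <- tinyTables()
  train <- lapply(tabs, function(x) x[1:100, ])
  val <- lapply(tabs, function(x) x[101:120, ])
  sch <- makeSchedule(20L, 1e-3, 0.1)
  ck <- trainMultiCondition(train, val, "a", c("b", "c"), tinyConfig(), sch,
                            seed = 6L)
  xt <- matrix(rnorm(15), 5, 3)
  base <- conditionSet(list(b = val$b[1:5, ], c = matrix(0, 5, 3)),
                       present = c(b = TRUE, c = FALSE))
  pert <- conditionSet(list(b = val$b[1:5, ], c = matrix(1e6, 5, 3)),
                       present = c(b = TRUE, c = FALSE))
  expect_identical(predictNoise(ck, xt, 7L, base), predictNoise(ck, xt, 7L, pert))
  # fully masked call works (unconditional mode) and is deterministic
  g1 <- multiConditionSample(ck, NULL, sch, n = 4L, seed = 3L)
  g2 <- multiConditionSample(ck, NULL, sch, n = 4L, seed = 3L)
  expect_identical(g1, g2)
  # unknown modality rejected
  bad <- conditionSet(list(zzz = val$b[1:5, ]))
  expect_error(predictNoise(ck, xt, 7L, bad), "not recognized")
})

test_that("degenerate subset sampling reproduces single-condition training", {
  tabs <- tinyTables()
  train <- lapply(tabs, function(x) x[1:100, ])
  val <- lapply(tabs, function(x) x[101:120, ])
  sch <- makeSchedule(20L, 1e-3, 0.1)
  single <- trainSingleCondition(train, val, "a", "b", tinyConfig(), sch, seed = 9L)
  multi <- trainMultiCondition(train, val, "a", "b", tinyConfig(), sch, seed = 9L,
                               subsetSampler = function(mods) mods)
  expect_equal(multi@trainingLog, single@trainingLog)
  xt <- matrix(rnorm(9), 3, 3)
  cs <- conditionSet(list(b = val$b[1:3, ]))
  expect_identical(predictNoise(multi, xt, 11L, cs), predictNoise(single, xt, 11L, cs))
})

test_that("checkpoints round-trip through save/load bit-identically", {
  fx <- copyTaskFixture()
  dir <- withr::local_tempdir()
  saveCheckpoint(fx$checkpoint, dir)
  back <- loadCheckpoint(dir)
  xt <- matrix(rnorm(10), 5, 2)
  cs <- conditionSet(list(b = fx$val$b[1:5, ]))
  expect_identical(predictNoise(back, xt, 40L, cs),
                   predictNoise(fx$checkpoint, xt, 40L, cs))
  expect_equal(back@bestValMSE, fx$checkpoint@bestValMSE)
  expect_equal(back@conditionModalities, fx$checkpoint@conditionModalities)
  expect_equal(back@trainingLog$valMSE, fx$checkpoint@trainingLog$valMSE)
})

test_that("conditional generation solves the copy task", {
  fx <- copyTaskFixture()
  gen <- ddpmSample(fx$checkpoint, fx$schedule, 100L, 2L,
                    conditionSet(list(b = fx$val$b)), seed = 9L)
  expect_gt(rSquared(fx$val$a, gen), 0.9)
})

test_that("validation-generation MSE is seeded and beats the data variance", {
  fx <- copyTaskFixture()
  m1 <- validationGenerationMSE(fx$checkpoint, fx$val, fx$schedule, seed = 4L)
  m2 <- validationGenerationMSE(fx$checkpoint, fx$val, fx$schedule, seed = 4L)
  expect_identical(m1, m2)
  # a working conditional model is far below the mean-predictor error
  expect_lt(m1, 0.1 * mean(apply(fx$val$a, 2, var)))
})

test_that("the oracle's generation MSE approaches the analytic floor", {
  # independent generations of N(mu, S) against real draws have expected
  # squared error 2 * mean(diag(S)) per entry
  sch <- makeSchedule(1000L)
  S0 <- diag(c(1, 2))
  pred <- gaussianOraclePredictor(c(0, 0), S0, sch)
  gen <- ddpmSample(pred, sch, 1500L, 2L, seed = 8L)
  real <- withr::with_seed(15, cbind(rnorm(1500, sd = 1), rnorm(1500, sd = sqrt(2))))
  expect_equal(mean((gen - real)^2), 2 * mean(diag(S0)), tolerance = 0.1)
})
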