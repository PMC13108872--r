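# Experiment harnesses: oracle identities, counterfactual scores,
# prioritization curves and the CLI surface.

test_that("parity with the oracle generator reproduces the real scores", {
  ec <- experimentCohort()
  res <- parityExperiment(ec$cohort, ec$split,
                          list(oracle = realDataGenerator(ec$cohort)),
                          tasks = "type",
                          config = experimentConfig(nRuns = 2L, nTrees = 100L))
  for (m in modalityNames(ec$cohort)) {
    f1 <- res[res$metric == "macroF1" & res$target == m, ]
    expect_equal(f1$value[f1$method == "oracle"], f1$value[f1$method == "real"])
    expect_equal(f1$sd[f1$method == "oracle"], 0)
  }
})

test_that("truth-conditional generation preserves the predictive signal", {
  # high-shared-signal regime: the type signature lives in the shared
  # factor, so resampling a modality's private part leaves classifier
  # performance nearly unchanged for shared-dominated modalities
  cohort <- generateCohort(cohortConfig(
    nSamples = 900L, nTypes = 3L, typeScale = 2,
    modalityDims = c(cna = 5L, rnaseq = 5L, rppa = 5L),
    privateSignalSd = c(cna = 2.0, rnaseq = 0.3, rppa = 0.3),
    noiseSd = 0.2,
    missingRates = c(cna = 0, rnaseq = 0, rppa = 0), seed = 57L))
  split <- stratifiedSplit(sampleIds(cohort), typeLabels(cohort), seed = 58L)
  res <- parityExperiment(
    cohort, split, list(truthCond = truthConditionalGenerator(cohort)),
    tasks = "type", config = experimentConfig(nRuns = 2L, nTrees = 100L))
  f1 <- res[res$metric == "macroF1" & res$target == "rnaseq", ]
  gap <- abs(f1$value[f1$method == "truthCond"] - f1$value[f1$method == "real"])
  expect_lt(gap, 0.1)
})

test_that("completion with the oracle generator cancels the drop exactly", {
  ec <- experimentCohort()
  res <- completionExperiment(
    ec$cohort, ec$split,
    patterns = list(none = character(0), two = c("rnaseq", "rppa")),
    generators = list(oracle = realDataGenerator(ec$cohort)),
    tasks = c("stage", "survival"),
    config = experimentConfig(nRuns = 2L, nTrees = 80L))
  for (task in c("stage", "survival")) {
    r <- res[res$task == task, ]
    # empty pattern: no drop, no gain
    expect_equal(r$value[r$pattern == "none" & r$method == "drop"], 0)
    expect_equal(r$value[r$pattern == "none" & r$method == "gain:oracle"], 0)
    # real-data completion restores the full score exactly
    drop2 <- r$value[r$pattern == "two" & r$method == "drop"]
    gain2 <- r$value[r$pattern == "two" & r$method == "gain:oracle"]
    expect_equal(gain2, drop2)
    expect_equal(r$value[r$pattern == "two" & r$method == "completed:oracle"],
                 r$value[r$pattern == "none" & r$method == "full"])
  }
  # removing informative modalities actually costs performance
  stage <- res[res$task == "stage", ]
  expect_gt(stage$value[stage$pattern == "two" & stage$method == "drop"], 0)
})

test_that("counterfactual variance scores obey their exact identities", {
  fx <- prioritizationFixture()
  testIds <- fx$split$test[1:60]
  lat <- cohortLatents(fx$cohort)
  conds <- lapply(lat[c("m2", "m3")], function(x) x[testIds, , drop = FALSE])
  # deterministic generator: zero score for every profile
  det <- function(target, conditions, ids, seed) {
    matrix(0, length(ids), 6, dimnames = list(ids, NULL))
  }
  s0 <- counterfactualVarianceScores(fx$predictProb, conds, "m1", det,
                                     testIds, nVersions = 5L, seed = 1L)
  expect_equal(s0$score, rep(0, 60))
  # classifier that ignores the target modality: zero score
  ignoring <- function(featureList) {
    n <- nrow(featureList$m2)
    matrix(0.5, n, 2, dimnames = list(NULL, c("high", "low")))
  }
  s1 <- counterfactualVarianceScores(ignoring, conds, "m1", fx$generator,
                                     testIds, nVersions = 5L, seed = 1L)
  expect_equal(s1$score, rep(0, 60))
  # stochastic generator: positive scores matching a brute-force
  # recomputation from the stored probability vectors
  nV <- 6L
  s2 <- counterfactualVarianceScores(fx$predictProb, conds, "m1",
                                     fx$generator, testIds,
                                     nVersions = nV, seed = 2L)
  expect_gt(max(s2$score), 0)
  probs <- lapply(seq_len(nV), function(v) {
    synth <- fx$generator("m1", conds, testIds,
                          seed = coherentgen:::deriveSeed(2L, 700L + v))
    fx$predictProb(c(conds, list(m1 = synth)))
  })
  i <- which.max(s2$score)
  perClass <- vapply(1:2, function(cl)
    var(vapply(probs, function(p) p[i, cl], numeric(1))), numeric(1))
  expect_equal(s2$score[i], mean(perClass), tolerance = 1e-12)
})

test_that("prioritization curves meet their endpoint identities", {
  fx <- prioritizationFixture()
  testIds <- fx$split$test
  lat <- cohortLatents(fx$cohort)
  conds <- lapply(lat[c("m2", "m3")], function(x) x[testIds, , drop = FALSE])
  scores <- counterfactualVarianceScores(fx$predictProb, conds, "m1",
                                         fx$generator, testIds,
                                         nVersions = 10L, seed = 3L)
  pc <- prioritizationCurves(fx$predictLabel, fx$y[testIds], conds, "m1",
                             lat$m1[testIds, ], fx$generator, scores, testIds,
                             fractions = c(0, 0.5, 1), nRuns = 2L, seed = 4L)
  full <- macroF1(fx$y[testIds], fx$predictLabel(
    c(conds, list(m1 = lat$m1[testIds, ]))))
  atOne <- pc$curves[pc$curves$fraction == 1, ]
  expect_true(all(atOne$f1 == full))
  atZero <- pc$curves[pc$curves$fraction == 0, ]
  # both strategies coincide at zero acquisition (same generation seed)
  byRun <- split(atZero, atZero$run)
  for (d in byRun) expect_equal(d$f1[1], d$f1[2])
})

test_that("informed prioritization dominates random acquisition", {
  fx <- prioritizationFixture()
  testIds <- fx$split$test
  lat <- cohortLatents(fx$cohort)
  conds <- lapply(lat[c("m2", "m3")], function(x) x[testIds, , drop = FALSE])
  scores <- counterfactualVarianceScores(fx$predictProb, conds, "m1",
                                         fx$generator, testIds,
                                         nVersions = 10L, seed = 3L)
  # scores flag the subgroup whose labels need the real modality
  informative <- fx$labels$informative[match(testIds, sampleIds(fx$cohort))]
  expect_gt(cor(scores$score, as.numeric(informative)), 0.3)
  pc <- prioritizationCurves(fx$predictLabel, fx$y[testIds], conds, "m1",
                             lat$m1[testIds, ], fx$generator, scores, testIds,
                             nRuns = 10L, seed = 4L)
  wide <- merge(pc$areas[pc$areas$strategy == "informed", c("run", "area")],
                pc$areas[pc$areas$strategy == "random", c("run", "area")],
                by = "run", suffixes = c(".informed", ".random"))
  expect_gte(sum(wide$area.informed >= wide$area.random), 9L)
})

test_that("the CLI drives simulate -> train -> generate end to end", {
  d <- withr::local_tempdir()
  w <- function(x, f) { yaml::write_yaml(x, f <- file.path(d, f)); f }
  simCfg <- w(list(nSamples = 150L, nTypes = 2L,
                   modalityDims = list(m1 = 3L, m2 = 3L),
                   missingRates = list(m1 = 0, m2 = 0)), "sim.yaml")
  expect_equal(cliMain(c("simulate", "--config", simCfg, "--seed", "7",
                         "--out", file.path(d, "sim"))), 0L)
  trCfg <- w(list(cohortDir = file.path(d, "sim"), target = "m1",
                  conditions = "m2", mode = "single",
                  schedule = list(steps = 30L, betaStart = 1e-3, betaEnd = 0.1),
                  predictor = list(nHiddenLayers = 2L, hiddenSize = 16L,
                                   timeEmbedDim = 8L, condEmbedDim = 4L,
                                   maxEpochs = 20L, patience = 2L,
                                   evalInterval = 10L)), "train.yaml")
  expect_equal(cliMain(c("train", "--config", trCfg, "--seed", "5",
                         "--out", file.path(d, "model"))), 0L)
  gnCfg <- w(list(checkpoint = file.path(d, "model", "checkpoint"),
                  cohortDir = file.path(d, "sim")), "gen.yaml")
  expect_equal(cliMain(c("generate", "--config", gnCfg, "--seed", "5",
                         "--out", file.path(d, "gen"))), 0L)
  gen <- readModalityTable(file.path(d, "gen", "generated.tsv"))
  expect_identical(dim(gen), c(150L, 3L))
})

test_that("the CLI round-trips simulate -> evaluate with a stable manifest", {
  outDir <- withr::local_tempdir()
  cfgFile <- file.path(outDir, "sim.yaml")
  yaml::write_yaml(list(nSamples = 120L, nTypes = 2L,
                        modalityDims = list(m1 = 3L, m2 = 3L),
                        missingRates = list(m1 = 0, m2 = 0)), cfgFile)
  simDir <- file.path(outDir, "sim")
  expect_equal(cliMain(c("simulate", "--config", cfgFile, "--seed", "7",
                         "--out", simDir)), 0L)
  expect_true(file.exists(file.path(simDir, "m1.tsv")))
  evalCfg <- file.path(outDir, "eval.yaml")
  yaml::write_yaml(list(real = file.path(simDir, "m1.tsv"),
                        generated = file.path(simDir, "m1.tsv")), evalCfg)
  evalDir <- file.path(outDir, "eval")
  expect_equal(cliMain(c("evaluate", "--config", evalCfg, "--out", evalDir)), 0L)
  metrics <- read.delim(file.path(evalDir, "metrics.tsv"))
  expect_equal(metrics$value[metrics$metric == "rSquared"], 1)
  # identical reruns produce identical manifests and outputs
  simDir2 <- file.path(outDir, "sim2")
  cliMain(c("simulate", "--config", cfgFile, "--seed", "7", "--out", simDir2))
  expect_identical(readLines(file.path(simDir, "run_manifest.json")),
                   readLines(file.path(simDir2, "run_manifest.json")))
  expect_identical(readLines(file.path(simDir, "m1.tsv")),
                   readLines(file.path(simDir2, "m1.tsv")))
  # invalid config keys fail loudly with a nonzero status
  badCfg <- file.path(outDir, "bad.yaml")
  yaml::write_yaml(list(nonsenseKey = 1), badCfg)
  expect_message(
    status <- cliMain(c("simulate", "--config", badCfg, "--out", outDir)),
    "nonsenseKey")
  expect_equal(status, 1L)
  expect_message(status2 <- cliMain("frobnicate"), "unknown subcommand")
  expect_equal(status2, 1L)
})
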