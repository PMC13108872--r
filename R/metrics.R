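#' Coefficient of determination for reconstructed tables
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, pooled over all samples x features,
#' with the total sum of squares taken about the real table's per-feature
#' means. A generator that returns the per-feature mean therefore scores
#' exactly 0 (the mean-predictor baseline) and worse generators score
#' negative.
#'
#' @param real,generated aligned numeric matrices.
#' @return scalar R squared.
#' @export
rSquared <- function(real, generated) {
  stopifnotMatrix(real); stopifnotMatrix(generated)
  if (!all(dim(real) == dim(generated))) stop("shapes must agree")
  ssTot <- sum(sweep(real, 2L, colMeans(real), "-")^2)
  if (ssTot == 0) stop("real table has zero total variance")
  1 - sum((generated - real)^2) / ssTot
}

#' Across-run output variance as a percentage of real variance
#'
#' For each sample and feature, the variance across the generated runs is
#' computed, averaged over the whole table, and expressed as a percentage
#' of the real table's mean per-feature variance. Runs that are i.i.d.
#' with the real per-feature variance calibrate to ~100%.
#'
#' @param runs list of >= 2 generated matrices, aligned with `real`.
#' @param real the real data matrix.
#' @return percentage (0 means all runs identical).
#' @export
outputVariancePct <- function(runs, real) {
  if (length(runs) < 2L) stop("need at least two generated runs")
  stopifnotMatrix(real)
  for (r in runs) {
    if (!all(dim(r) == dim(real))) stop("all runs must match the real shape")
  }
  R <- length(runs)
  mean_ <- Reduce(`+`, runs) / R
  ss <- Reduce(`+`, lapply(runs, function(x) (x - mean_)^2))
  perCell <- ss / (R - 1)
  realVar <- mean(colVars(real))
  if (realVar == 0) stop("real table has zero variance")
  100 * mean(perCell) / realVar
}

#' Energy distance between two sample sets
#'
#' Un-rooted V-statistic
#' \eqn{2\,\overline{\lVert a-b\rVert} - \overline{\lVert a-a'\rVert} -
#' \overline{\lVert b-b'\rVert}} over all ordered pairs (diagonals
#' included). Zero iff the two finite sets are equal as multisets; lower
#' means more similar distributions.
#'
#' @param A,B numeric matrices with equal column counts.
#' @return scalar energy distance.
#' @export
energyDistance <- function(A, B) {
  stopifnotMatrix(A); stopifnotMatrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("sets must be non-empty")
  if (ncol(A) != ncol(B)) stop("dimension mismatch")
  2 * mean(sqrt(crossDist2(A, B))) -
    mean(sqrt(crossDist2(A, A))) -
    mean(sqrt(crossDist2(B, B)))
}

#' k-NN manifold precision, recall and F1
#'
#' Precision: fraction of generated points lying within the k-NN radius
#' (distance to the k-th nearest neighbor, self excluded) of at least one
#' real point. Recall: the symmetric quantity with the roles swapped. F1
#' is their harmonic mean (0 when both vanish). This is the k-NN manifold
#' estimate commonly used to score generative coverage.
#'
#' @param real,generated sample sets (rows) of equal dimension.
#' @param k neighborhood size (default 5); must be smaller than either set.
#' @return named vector with precision, recall and f1.
#' @export
manifoldCoverage <- function(real, generated, k = 5L) {
  stopifnotMatrix(real); stopifnotMatrix(generated)
  if (k >= nrow(real) || k >= nrow(generated)) {
    stop("k must be smaller than both set sizes")
  }
  radius <- function(X) {
    d2 <- crossDist2(X, X)
    diag(d2) <- Inf
    apply(d2, 1L, function(r) sqrt(sort(r, partial = k)[k]))
  }
  covered <- function(points, ref, refRadius) {
    d <- sqrt(crossDist2(points, ref))
    inside <- sweep(d, 2L, refRadius, "<=")
    mean(apply(inside, 1L, any))
  }
  precision <- covered(generated, real, radius(real))
  recall <- covered(real, generated, radius(generated))
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

confusionStats <- function(y, yHat) {
  y <- as.character(y); yHat <- as.character(yHat)
  if (length(y) == 0L || length(y) != length(yHat)) {
    stop("labels must be non-empty and aligned")
  }
  classes <- sort(union(unique(y), unique(yHat)))
  stats <- lapply(classes, function(cl) {
    tp <- sum(y == cl & yHat == cl)
    fp <- sum(y != cl & yHat == cl)
    fn <- sum(y == cl & yHat != cl)
    list(tp = tp, fp = fp, fn = fn, support = sum(y == cl))
  })
  names(stats) <- classes
  stats
}

#' Macro F1 score
#'
#' Unweighted mean of per-class F1 over the union of observed and
#' predicted classes; a class with no true positives (including classes
#' predicted but absent from the truth) contributes 0.
#'
#' @param y,yHat true and predicted labels.
#' @return scalar macro F1.
#' @export
macroF1 <- function(y, yHat) {
  st <- confusionStats(y, yHat)
  f1 <- vapply(st, function(s) {
    den <- 2 * s$tp + s$fp + s$fn
    if (den == 0) 0 else 2 * s$tp / den
  }, numeric(1))
  mean(f1)
}

#' Balanced accuracy
#'
#' Mean per-class recall over the classes present in the truth.
#'
#' @inheritParams macroF1
#' @return scalar balanced accuracy.
#' @export
balancedAccuracy <- function(y, yHat) {
  st <- confusionStats(y, yHat)
  st <- st[vapply(st, function(s) s$support > 0L, logical(1))]
  mean(vapply(st, function(s) s$tp / s$support, numeric(1)))
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (an earlier observed event versus a longer
#' survivor) where the higher risk score belongs to the shorter survival;
#' ties in risk count one half.
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param riskScores higher = predicted shorter survival.
#' @return scalar C-index.
#' @export
concordanceIndex <- function(times, events, riskScores) {
  if (length(times) != length(events) || length(times) != length(riskScores)) {
    stop("inputs must be aligned")
  }
  fit <- survival::concordance(
    survival::Surv(times, events) ~ riskScores, reverse = TRUE)
  n <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (n == 0) stop("no comparable pairs")
  unname(fit$concordance)
}

#' Assemble a metric-report row
#'
#' One row per (metric, context) combination, mirroring the tabular
#' layouts used to report reconstruction fidelity, parity and privacy
#' results. Dispersion is only present when more than one run was pooled.
#'
#' @param metric metric name.
#' @param values per-run values (length >= 1).
#' @param target target modality tag.
#' @param method generative method tag.
#' @param context free-form extra tag (conditioning set, task, ...).
#' @return one-row data.frame.
#' @export
metricReport <- function(metric, values, target = NA_character_,
                         method = NA_character_, context = NA_character_) {
  data.frame(
    metric = metric, value = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
    nRuns = length(values), target = target, method = method,
    context = context, stringsAsFactors = FALSE)
}
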