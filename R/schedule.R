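#' Build a diffusion variance schedule
#'
#' Creates the fixed variance schedule \eqn{\{\beta_t\}_{t=1}^T} of a
#' denoising diffusion probabilistic model together with the derived
#' retention factors \eqn{\alpha_t = 1-\beta_t} and cumulative products
#' \eqn{\bar\alpha_t}. The default (T = 1000, linear \eqn{\beta} from 1e-4
#' to 0.02) is the standard DDPM choice; short schedules used in examples
#' and tests raise `betaEnd` so that \eqn{\bar\alpha_T} stays close to zero
#' and generation can start from pure noise.
#'
#' @param steps number of diffusion steps T (positive integer).
#' @param betaStart,betaEnd endpoints of the beta progression; must satisfy
#'   `0 < betaStart <= betaEnd < 1`.
#' @param kind schedule family; currently only `"linear"` (arithmetic
#'   progression from `betaStart` to `betaEnd`).
#' @return a [NoiseSchedule-class] object.
#' @examples
#' sch <- makeSchedule(1000)
#' alphaBars(sch)[1000]  # ~4e-5: essentially pure noise at t = T
#' @export
makeSchedule <- function(steps = 1000L, betaStart = 1e-4, betaEnd = 0.02,
                         kind = c("linear")) {
  kind <- match.arg(kind)
  if (length(steps) != 1L || is.na(steps) || steps < 1 || steps != round(steps)) {
    stop("'steps' must be a positive integer")
  }
  steps <- as.integer(steps)
  if (!(betaStart > 0 && betaStart <= betaEnd && betaEnd < 1)) {
    stop("need 0 < betaStart <= betaEnd < 1")
  }
  betas <- if (steps == 1L) betaStart else seq(betaStart, betaEnd, length.out = steps)
  alphas <- 1 - betas
  new("NoiseSchedule",
    steps = steps, betas = betas, alphas = alphas, alphaBars = cumprod(alphas),
    kind = kind, betaStart = betaStart, betaEnd = betaEnd
  )
}

#' @describeIn makeSchedule number of steps T.
#' @param schedule a [NoiseSchedule-class].
#' @export
nSteps <- function(schedule) schedule@steps

#' @describeIn makeSchedule the beta_t vector.
#' @export
betas <- function(schedule) schedule@betas

#' @describeIn makeSchedule the alpha_t vector.
#' @export
alphas <- function(schedule) schedule@alphas

#' @describeIn makeSchedule the cumulative signal retention alphaBar_t.
#' @export
alphaBars <- function(schedule) schedule@alphaBars

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf(
    "NoiseSchedule: %s, T = %d, beta in [%g, %g], alphaBar_T = %.3g\n",
    object@kind, object@steps, object@betaStart, object@betaEnd,
    object@alphaBars[object@steps]
  ))
})

#' Serialize a schedule to a reconstruction descriptor
#'
#' Schedules are stored as the small set of constructor arguments, never as
#' raw arrays, so a reloaded schedule is rebuilt bit-identically.
#'
#' @param schedule a [NoiseSchedule-class].
#' @return named list with fields steps, kind, betaStart, betaEnd.
#' @export
scheduleDescriptor <- function(schedule) {
  list(steps = schedule@steps, kind = schedule@kind,
       betaStart = schedule@betaStart, betaEnd = schedule@betaEnd)
}

#' @rdname scheduleDescriptor
#' @param descriptor a list as returned by [scheduleDescriptor()].
#' @export
scheduleFromDescriptor <- function(descriptor) {
  makeSchedule(descriptor$steps, descriptor$betaStart, descriptor$betaEnd,
               descriptor$kind)
}

#' Forward diffusion: sample x_t directly from x_0
#'
#' Computes \eqn{x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,
#' \epsilon} row-wise, the closed-form marginal of the forward noising
#' process.
#'
#' @param x0 clean latent matrix (n x D).
#' @param t integer timestep indices in 1..T, length 1 or n.
#' @param eps standard-normal noise matrix, same shape as `x0`.
#' @param schedule a [NoiseSchedule-class].
#' @return the noised matrix x_t.
#' @export
qSample <- function(x0, t, eps, schedule) {
  stopifnotMatrix(x0); stopifnotMatrix(eps)
  if (!all(dim(x0) == dim(eps))) stop("x0 and eps must have the same shape")
  n <- nrow(x0)
  if (!(length(t) == 1L || length(t) == n)) stop("t must have length 1 or nrow(x0)")
  if (any(t < 1 | t > schedule@steps)) stop("timestep indices out of 1..T")
  ab <- schedule@alphaBars[t]
  x0 * sqrt(ab) + eps * sqrt(1 - ab)
}

#' One reverse (denoising) transition
#'
#' Computes the posterior mean
#' \eqn{\mu_\theta = (x_t - \beta_t/\sqrt{1-\bar\alpha_t}\,\hat\epsilon)
#' / \sqrt{\alpha_t}} and, for t > 1, adds transition noise with standard
#' deviation \eqn{\sqrt{\beta_t}}. The final step t = 1 returns the mean
#' alone, so generation ends at the posterior mean.
#'
#' @param xt current latent matrix.
#' @param t scalar timestep in 1..T.
#' @param epsHat predicted noise matrix, same shape as `xt`.
#' @param z standard-normal draw for the transition noise; ignored at t = 1
#'   and may then be NULL.
#' @param schedule a [NoiseSchedule-class].
#' @return the matrix at step t - 1.
#' @export
reverseStep <- function(xt, t, epsHat, z, schedule) {
  stopifnotMatrix(xt); stopifnotMatrix(epsHat)
  if (!all(dim(xt) == dim(epsHat))) stop("xt and epsHat must have the same shape")
  if (length(t) != 1L || t < 1 || t > schedule@steps) stop("t must be a scalar in 1..T")
  beta <- schedule@betas[t]
  ab <- schedule@alphaBars[t]
  mu <- (xt - epsHat * (beta / sqrt(1 - ab))) / sqrt(schedule@alphas[t])
  if (t > 1) {
    stopifnotMatrix(z)
    if (!all(dim(z) == dim(xt))) stop("z must match the shape of xt")
    mu + sqrt(beta) * z
  } else {
    mu
  }
}

# Normalize a predictor (NoisePredictor or plain function) to a function
# f(xt, t, conditionSet) returning a noise matrix.
asNoiseFun <- function(predictor) {
  if (is.function(predictor)) return(predictor)
  if (is(predictor, "NoisePredictor")) {
    return(function(xt, t, conditions) predictNoise(predictor, xt, t, conditions))
  }
  stop("predictor must be a function or a NoisePredictor")
}

#' Generate samples by iterating the reverse diffusion process
#'
#' Draws \eqn{x_T \sim N(0, I)} and applies [reverseStep()] for
#' t = T, ..., 1 using the supplied noise predictor. The entire noise
#' stream is fixed by `seed`, so the output is a pure function of
#' (predictor, schedule, condition, seed).
#'
#' @param predictor a [NoisePredictor-class] or a function
#'   `function(xt, t, conditions)` returning a predicted-noise matrix.
#' @param schedule a [NoiseSchedule-class].
#' @param n number of samples to generate (n = 0 gives an empty matrix).
#' @param D latent dimension.
#' @param conditions a [ConditionSet-class] or NULL for unconditional use.
#' @param seed integer seed fixing the noise stream.
#' @return an n x D matrix of generated samples.
#' @export
ddpmSample <- function(predictor, schedule, n, D, conditions = NULL, seed = 1L) {
  if (n == 0L) return(matrix(numeric(0), 0L, D))
  fun <- asNoiseFun(predictor)
  T <- schedule@steps
  withSeed(seed, {
    x <- matrix(stats::rnorm(n * D), n, D)
    for (t in T:1) {
      epsHat <- tryCatch(fun(x, t, conditions), error = function(e) {
        stop(sprintf("noise predictor failed at step t = %d: %s", t,
                     conditionMessage(e)), call. = FALSE)
      })
      z <- if (t > 1) matrix(stats::rnorm(n * D), n, D) else NULL
      x <- reverseStep(x, t, epsHat, z, schedule)
    }
    x
  })
}

#' Exact noise predictor for Gaussian data (test oracle)
#'
#' For data distributed as \eqn{N(\mu_0, \Sigma_0)}, the posterior-mean
#' noise given \eqn{x_t} has the closed form
#' \eqn{E[\epsilon \mid x_t] = \sqrt{1-\bar\alpha_t}\,
#' (\bar\alpha_t \Sigma_0 + (1-\bar\alpha_t) I)^{-1}
#' (x_t - \sqrt{\bar\alpha_t}\,\mu_0)}. Used as an analytically known
#' stand-in for a trained network when validating the sampling machinery.
#'
#' @param mu0 mean vector of the data distribution.
#' @param Sigma0 covariance matrix (symmetric positive-definite).
#' @param schedule a [NoiseSchedule-class].
#' @return a predictor function `function(xt, t, conditions)`.
#' @export
gaussianOraclePredictor <- function(mu0, Sigma0, schedule) {
  D <- length(mu0)
  Sigma0 <- as.matrix(Sigma0)
  if (!isTRUE(all.equal(Sigma0, t(Sigma0), tolerance = 1e-8))) {
    stop("Sigma0 must be symmetric")
  }
  ev <- eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma0 must be positive-definite")
  I <- diag(D)
  function(xt, t, conditions = NULL) {
    ab <- schedule@alphaBars[t]
    M <- solve(ab * Sigma0 + (1 - ab) * I)
    sqrt(1 - ab) * (sweep(xt, 2L, sqrt(ab) * mu0, "-") %*% M)
  }
}
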