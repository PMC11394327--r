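# Mathematical core of the conditional diffusion model, independent of
# any network: the noise schedule gamma_0..gamma_T with per-step
# retention factors alpha_t, the piecewise-uniform noise-level sampler,
# the variance-preserving closed-form noising, the epsilon-prediction
# loss, and the Gaussian reverse-step parameterization.
#
# Conventions: gamma_t is the cumulative noise VARIANCE at step t, so
# 1 - gamma_t = (1 - gamma_0) * prod_{s<=t} alpha_s (the familiar
# 1 - gamma_t = prod alpha_s when gamma_0 = 0), the forward step is
# y_t = sqrt(alpha_t) y_{t-1} + sqrt(1 - alpha_t) eps, and the closed
# form is y_t = sqrt(1 - gamma_t) y_0 + sqrt(gamma_t) eps, which is
# variance-preserving: (1 - gamma) + gamma = 1.

#' Diffusion configuration
#'
#' @param T number of diffusion steps (benchmark-scale default 2000;
#'   desk-scale runs use far fewer).
#' @param gamma_min,gamma_max endpoints of the cumulative-noise schedule,
#'   with `0 <= gamma_min < gamma_max <= 1`.
#' @return a `diffusion_config` list.
#' @export
diffusion_config <- function(T = 2000L, gamma_min = 1e-4, gamma_max = 0.98) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (!(gamma_min >= 0 && gamma_min < gamma_max && gamma_max <= 1))
    stop("need 0 <= gamma_min < gamma_max <= 1", call. = FALSE)
  structure(list(T = as.integer(T), gamma_min = gamma_min,
                 gamma_max = gamma_max),
            class = "diffusion_config")
}

#' Build a noise schedule
#'
#' Places `T + 1` cumulative noise levels gamma_0..gamma_T linearly on
#' `[gamma_min, gamma_max]` and derives the per-step retention factors
#' from the consistency relation `alpha_t = (1 - gamma_t)/(1 - gamma_{t-1})`,
#' so that `1 - gamma_t = (1 - gamma_0) * prod_{s<=t} alpha_s` holds by
#' construction (the textbook `1 - gamma_t = prod alpha_s` when
#' `gamma_0 = 0`).
#'
#' @param config a [diffusion_config()].
#' @return a `noise_schedule` list with fields `T`, `gamma` (length
#'   `T + 1`), `alpha` (length `T`).
#' @examples
#' sch <- make_schedule(diffusion_config(T = 4, gamma_min = 0, gamma_max = 1))
#' sch$gamma
#' @export
make_schedule <- function(config) {
  stopifnot(inherits(config, "diffusion_config"))
  gamma <- seq(config$gamma_min, config$gamma_max, length.out = config$T + 1L)
  alpha <- (1 - gamma[-1L]) / (1 - gamma[-length(gamma)])
  structure(list(T = config$T, gamma = gamma, alpha = alpha,
                 config = config),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat("noise schedule: T =", x$T, " gamma in [",
      format(x$gamma[1L]), ",", format(x$gamma[length(x$gamma)]), "]\n")
  invisible(x)
}

#' Sample a noise level from the piecewise-uniform schedule density
#'
#' Draws a step index t uniformly on {1..T}, then a level gamma uniformly
#' within the piece `(gamma_{t-1}, gamma_t]` — the mixture density
#' `p(gamma) = sum_t (1/T) U(gamma_{t-1}, gamma_t)`. Uses the current RNG
#' state; seed at the caller.
#'
#' @param schedule a `noise_schedule`.
#' @return list with `t` (step index) and `gamma` (noise level).
#' @export
sample_gamma <- function(schedule) {
  t <- sample.int(schedule$T, 1L)
  lo <- schedule$gamma[t]; hi <- schedule$gamma[t + 1L]
  list(t = t, gamma = lo + (hi - lo) * stats::runif(1))
}

#' CDF of the piecewise-uniform noise-level density
#'
#' Closed form used to check the sampler: within piece t the CDF rises
#' linearly from `(t-1)/T` to `t/T`.
#'
#' @param q quantile vector.
#' @param schedule a `noise_schedule`.
#' @return CDF values in [0, 1].
#' @export
pgamma_schedule <- function(q, schedule) {
  g <- schedule$gamma; T <- schedule$T
  sapply(q, function(x) {
    if (x <= g[1L]) return(0)
    if (x >= g[T + 1L]) return(1)
    t <- findInterval(x, g, rightmost.closed = TRUE)  # piece index
    (t - 1) / T + (x - g[t]) / (T * (g[t + 1L] - g[t]))
  })
}

#' One forward diffusion step
#'
#' Draws from `q(y_t | y_{t-1}) = N(sqrt(alpha_t) y_{t-1}, (1 - alpha_t) I)`:
#' returns `sqrt(alpha_t) * y_prev + sqrt(1 - alpha_t) * eps` with
#' standard-normal `eps`. Uses the current RNG state.
#'
#' @param y_prev image array (internal [-1,1] scale).
#' @param alpha_t retention factor in (0, 1].
#' @return noised array of the same shape.
#' @export
forward_step <- function(y_prev, alpha_t) {
  if (alpha_t <= 0 || alpha_t > 1) stop("alpha_t must be in (0, 1]", call. = FALSE)
  if (alpha_t == 1) return(y_prev)
  eps <- array(stats::rnorm(length(y_prev)), dim(y_prev))
  sqrt(alpha_t) * y_prev + sqrt(1 - alpha_t) * eps
}

#' Closed-form noising at cumulative level gamma
#'
#' `y_t = sqrt(1 - gamma) * y0 + sqrt(gamma) * eps`. For independent
#' unit-variance `y0` and `eps` the output has unit variance for every
#' gamma — the variance-preserving property the training loop relies on.
#'
#' @param y0 clean image array.
#' @param gamma cumulative noise level in [0, 1].
#' @param eps noise field of the same shape as `y0`.
#' @return noised array.
#' @export
noised_image <- function(y0, gamma, eps) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  if (!identical(dim(y0), dim(eps)) || length(y0) != length(eps))
    stop("y0 and eps must share shape", call. = FALSE)
  sqrt(1 - gamma) * y0 + sqrt(gamma) * eps
}

#' Epsilon-prediction training loss
#'
#' Mean squared error between the predicted and the true noise field,
#' averaged over all elements so the loss is scale-free across image
#' sizes and batch shapes.
#'
#' @param predicted_noise,eps arrays of identical shape.
#' @return non-negative scalar.
#' @export
training_loss <- function(predicted_noise, eps) {
  if (length(predicted_noise) != length(eps) ||
      !identical(dim(predicted_noise), dim(eps)))
    stop("predicted_noise and eps must share shape", call. = FALSE)
  mean((predicted_noise - eps)^2)
}

#' Gaussian reverse-step parameters
#'
#' Mean and variance of `p(y_{t-1} | y_t, x)` under the fixed-variance
#' parameterization: `mu = (y_t - (1 - alpha_t)/sqrt(gamma_t) * eps_hat) /
#' sqrt(alpha_t)` and `sigma2 = 1 - alpha_t`.
#'
#' @param y_t current noisy image.
#' @param predicted_noise network estimate of the noise field.
#' @param schedule a `noise_schedule`.
#' @param t step index in 1..T.
#' @return list with `mu` (array) and `sigma2` (scalar).
#' @export
posterior_step_params <- function(y_t, predicted_noise, schedule, t) {
  if (t < 1 || t > schedule$T) stop("t must be in 1..T", call. = FALSE)
  alpha_t <- schedule$alpha[t]
  gamma_t <- schedule$gamma[t + 1L]
  mu <- (y_t - (1 - alpha_t) / sqrt(gamma_t) * predicted_noise) / sqrt(alpha_t)
  list(mu = mu, sigma2 = 1 - alpha_t)
}
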