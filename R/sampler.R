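# Inference: iterative refinement from pure noise, conditioned on the
# hairy image. Two modes are first class because the printed additive
# update (residual mode) and the Gaussian posterior (ancestral mode) are
# different readings of the same reverse process; ancestral is the
# default as it matches the epsilon-prediction training objective.

#' Sampler configuration
#'
#' @param mode `"ancestral"` (Gaussian posterior step, default) or
#'   `"residual"` (additive update `y_{t-1} = f(y_t, x, t) + y_t`).
#' @param T_infer number of refinement iterations (>= 0); `NULL` uses the
#'   schedule's training T. Benchmark-scale runs use 2000; quick previews
#'   use as few as 10.
#' @param seed integer seed for the initial noise and the ancestral
#'   noise draws.
#' @param trajectory keep the per-step trajectory.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(mode = c("ancestral", "residual"), T_infer = NULL,
                           seed = 1L, trajectory = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(T_infer) && T_infer < 0) stop("T_infer must be >= 0", call. = FALSE)
  structure(list(mode = mode, T_infer = T_infer, seed = as.integer(seed),
                 trajectory = isTRUE(trajectory)),
            class = "sampler_config")
}

#' One residual refinement step
#'
#' The printed additive update: the network output is added to the
#' current iterate with no rescaling, `y_{t-1} = f(y_t, x, t) + y_t`.
#'
#' @param params a `denoiser_params`.
#' @param y_t current iterate (internal scale).
#' @param x conditioning image (internal scale).
#' @param schedule a `noise_schedule` supplying the step's noise level.
#' @param t step index (>= 1).
#' @return the next iterate `y_{t-1}`.
#' @export
refine_step <- function(params, y_t, x, schedule, t) {
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  predict_noise(params, x, y_t, schedule$gamma[t + 1L]) + y_t
}

#' One ancestral (Gaussian posterior) step
#'
#' Draws `y_{t-1} ~ N(mu, sigma2 I)` with the mean and variance from
#' [posterior_step_params()]; the final step (t = 1) returns the mean
#' without noise. Uses the current RNG state.
#'
#' @inheritParams refine_step
#' @return the next iterate `y_{t-1}`.
#' @export
ancestral_step <- function(params, y_t, x, schedule, t) {
  eps_hat <- predict_noise(params, x, y_t, schedule$gamma[t + 1L])
  pp <- posterior_step_params(y_t, eps_hat, schedule, t)
  if (t == 1L || pp$sigma2 <= 0) return(pp$mu)
  pp$mu + sqrt(pp$sigma2) * array(stats::rnorm(length(pp$mu)), dim(pp$mu))
}

#' Remove hair from an image by iterative refinement
#'
#' Initializes `y_T` from a standard normal, applies `T_infer` reverse
#' steps in the configured mode conditioned on the hairy image `x`, and
#' maps the result back to [0, 1] with clipping. When `T_infer` differs
#' from the training T, the cumulative-noise schedule is re-knotted over
#' the same gamma range with `T_infer` pieces. Pure function of
#' `(params, x, config)`.
#'
#' @param params a `denoiser_params` (trained, or an oracle for testing).
#' @param x hairy image on the external [0, 1] scale.
#' @param schedule the training `noise_schedule`.
#' @param config a [sampler_config()].
#' @return list with `y0` (dehaired [0, 1] image) and, if requested,
#'   `trajectory` (list of length `T_infer + 1` of internal-scale
#'   iterates, initialization first).
#' @export
dehair <- function(params, x, schedule, config = sampler_config()) {
  check_raster(x, range = c(0, 1), what = "x")
  T_infer <- if (is.null(config$T_infer)) schedule$T else as.integer(config$T_infer)
  if (T_infer != schedule$T) {
    cf <- schedule$config
    schedule <- make_schedule(diffusion_config(T = max(T_infer, 1L),
                                               gamma_min = cf$gamma_min,
                                               gamma_max = cf$gamma_max))
  }
  x_int <- to_internal(x)
  with_seed(config$seed, {
    y <- array(stats::rnorm(length(x_int)), dim(x_int))
    traj <- if (config$trajectory) list(y) else NULL
    step_fun <- if (config$mode == "residual") refine_step else ancestral_step
    for (t in rev(seq_len(T_infer))) {
      y <- step_fun(params, y, x_int, schedule, t)
      if (config$trajectory) traj[[length(traj) + 1L]] <- y
    }
    list(y0 = clip_image(to_external(y), 0, 1), trajectory = traj)
  })
}
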