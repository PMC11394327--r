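# Training loop: sample a pair, sample a noise level from the schedule,
# noise the clean image, predict the noise conditioned on the hairy
# image, take the mean-squared-error gradient, and apply an Adam update.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4, the benchmark
#'   setting; tiny desk-scale models train faster with larger rates).
#' @param iterations number of optimizer steps.
#' @param batch_size pairs per step.
#' @param seed integer seed covering data order, noise levels and noise
#'   draws.
#' @param checkpoint_every write a checkpoint every this many steps
#'   (`Inf` to disable).
#' @param checkpoint_path directory for checkpoints.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, iterations = 20000L,
                         batch_size = 8L, seed = 1L,
                         checkpoint_every = Inf, checkpoint_path = NULL) {
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 checkpoint_every = checkpoint_every,
                 checkpoint_path = checkpoint_path),
            class = "train_config")
}

#' Initialize Adam optimizer state
#' @param n number of parameters.
#' @return an `adam_state` list (first/second moment vectors, step count).
#' @export
adam_init <- function(n) {
  structure(list(m = numeric(n), v = numeric(n), t = 0L,
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
            class = "adam_state")
}

#' One Adam update
#' @param state an `adam_state`.
#' @param grad gradient vector.
#' @param lr learning rate.
#' @return list with `delta` (parameter increment) and updated `state`.
#' @export
adam_update <- function(state, grad, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(delta = -lr * mhat / (sqrt(vhat) + state$eps), state = state)
}

# Loss and parameter gradient for one (x, y0) pair at one noise level.
pair_loss_grad <- function(params, x_int, y0_int, gamma, eps, want_grad = TRUE) {
  cfg <- params$config
  x3 <- as_hwc(x_int, cfg$image_channels)
  y3 <- as_hwc(y0_int, cfg$image_channels)
  e3 <- as_hwc(eps, cfg$image_channels)
  y_t <- noised_image(y3, gamma, e3)
  fwd <- unet_forward(params$theta, cfg, x3, y_t, gamma)
  loss <- training_loss(fwd$out, e3)
  if (!want_grad) return(list(loss = loss))
  dOut <- 2 * (fwd$out - e3) / length(e3)
  list(loss = loss,
       grad = unet_backward(params$theta, cfg, fwd$cache, dOut))
}

#' One training step
#'
#' Executes one full inner iteration of the training algorithm on a
#' mini-batch: per pair, sample a noise level from the schedule's
#' piecewise-uniform density, draw standard-normal noise, form the noised
#' image, evaluate the epsilon-prediction loss and its gradient, then
#' apply a single Adam update with the batch-mean gradient. Images in the
#' batch are on the external [0, 1] scale and are mapped to [-1, 1]
#' internally. Uses the current RNG state; seed at the caller.
#'
#' @param params a `denoiser_params`.
#' @param batch non-empty list of [paired_sample()] objects.
#' @param schedule a `noise_schedule`.
#' @param opt_state an `adam_state` (created if `NULL`).
#' @param learning_rate Adam step size; 0 leaves parameters unchanged.
#' @return list `(params, opt_state, loss)` with the batch-mean loss.
#' @export
train_step <- function(params, batch, schedule, opt_state = NULL,
                       learning_rate = 1e-4) {
  if (length(batch) == 0L) stop("batch must be non-empty", call. = FALSE)
  flat <- flatten_params(params)
  if (is.null(opt_state)) opt_state <- adam_init(length(flat))
  gsum <- numeric(length(flat))
  loss <- 0
  for (p in batch) {
    sg <- sample_gamma(schedule)
    x_int <- to_internal(p$hairy)
    y0_int <- to_internal(p$clean)
    eps <- array(stats::rnorm(length(y0_int)), dim(y0_int))
    lg <- pair_loss_grad(params, x_int, y0_int, sg$gamma, eps,
                         want_grad = learning_rate > 0)
    loss <- loss + lg$loss
    if (learning_rate > 0)
      gsum <- gsum + unlist(lg$grad, use.names = FALSE)
  }
  loss <- loss / length(batch)
  if (!is.finite(loss))
    stop("non-finite training loss (", loss, ") at optimizer step ",
         opt_state$t + 1L, call. = FALSE)
  if (learning_rate > 0) {
    up <- adam_update(opt_state, gsum / length(batch), learning_rate)
    opt_state <- up$state
    params$theta <- relist_params(flat + up$delta, params)
  }
  params$step <- params$step + 1L
  list(params = params, opt_state = opt_state, loss = loss)
}

resolve_pairs <- function(data) {
  if (inherits(data, "dataset_manifest")) {
    ids <- data$train_ids
    if (length(ids) == 0L) ids <- unlist(data$classes, use.names = FALSE)
    lapply(ids, function(id) load_pair(data, id))
  } else if (is.list(data) && all(vapply(data, inherits, logical(1), "paired_sample"))) {
    data
  } else stop("data must be a dataset_manifest or a list of paired_sample",
              call. = FALSE)
}

#' Train the conditional denoiser
#'
#' Runs the configured number of Adam iterations over random mini-batches
#' of training pairs (the train split of a manifest, or an in-memory pair
#' list). Fully seeded: initialization, data order, noise levels and noise
#' draws all derive from the configured seeds, and a run resumed from a
#' checkpoint reproduces the uninterrupted run exactly.
#'
#' @param data a `dataset_manifest` with a train split, or a list of
#'   [paired_sample()] objects.
#' @param config a [train_config()].
#' @param diffusion a [diffusion_config()].
#' @param denoiser a [denoiser_config()].
#' @param init_seed seed for parameter initialization.
#' @param resume path to a checkpoint to resume from.
#' @return a `denoiser_params` with attributes `losses` (per-iteration
#'   loss vector) and `schedule`.
#' @export
train <- function(data, config = train_config(),
                  diffusion = diffusion_config(),
                  denoiser = denoiser_config(),
                  init_seed = 1L, resume = NULL) {
  pairs <- resolve_pairs(data)
  if (length(pairs) == 0L) stop("empty training set", call. = FALSE)
  schedule <- make_schedule(diffusion)
  losses <- numeric(0)
  start_iter <- 1L
  if (is.null(resume)) {
    params <- init_denoiser(denoiser, seed = init_seed)
    opt_state <- adam_init(length(flatten_params(params)))
    with_seed(config$seed, rng <- get(".Random.seed", envir = globalenv()))
  } else {
    ck <- load_checkpoint(resume, config = denoiser)
    params <- ck$params
    opt_state <- ck$opt_state
    rng <- ck$rng
    losses <- ck$losses
    start_iter <- ck$iteration + 1L
  }
  old_rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv()))
  assign(".Random.seed", rng, envir = globalenv())
  for (it in start_iter:config$iterations) {
    idx <- sample.int(length(pairs), min(config$batch_size, length(pairs)),
                      replace = length(pairs) < config$batch_size)
    st <- train_step(params, pairs[idx], schedule, opt_state,
                     learning_rate = config$learning_rate)
    params <- st$params
    opt_state <- st$opt_state
    losses <- c(losses, st$loss)
    if (is.finite(config$checkpoint_every) &&
        it %% config$checkpoint_every == 0L &&
        !is.null(config$checkpoint_path)) {
      dir.create(config$checkpoint_path, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(params, opt_state,
                      file.path(config$checkpoint_path,
                                sprintf("ckpt_%06d.rds", it)),
                      schedule = schedule, iteration = it, losses = losses,
                      rng = get(".Random.seed", envir = globalenv()))
    }
  }
  attr(params, "losses") <- losses
  attr(params, "schedule") <- schedule
  params
}

CHECKPOINT_VERSION <- 1L

#' Save / load a training checkpoint
#'
#' The checkpoint embeds the parameters, optimizer state, denoiser config,
#' noise schedule, RNG state and loss history, plus a digest of the
#' payload; loading verifies the digest (tampered files are rejected) and,
#' if `config` is supplied, that the embedded config matches it.
#'
#' @param params a `denoiser_params`.
#' @param opt_state an `adam_state`.
#' @param path checkpoint file path.
#' @param schedule,iteration,losses,rng training state to embed.
#' @return `save_checkpoint` returns `path` invisibly.
#' @export
save_checkpoint <- function(params, opt_state, path, schedule = NULL,
                            iteration = 0L, losses = numeric(0), rng = NULL) {
  payload <- list(version = CHECKPOINT_VERSION, params = params,
                  opt_state = opt_state, schedule = schedule,
                  iteration = iteration, losses = losses, rng = rng)
  raw <- serialize(payload, NULL)
  saveRDS(list(digest = digest_raw(raw), payload = raw), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config if non-`NULL`, a [denoiser_config()] the checkpoint must
#'   match.
#' @export
load_checkpoint <- function(path, config = NULL) {
  x <- tryCatch(readRDS(path),
                error = function(e) stop("cannot read checkpoint '", path, "'",
                                         call. = FALSE))
  if (!is.list(x) || !all(c("digest", "payload") %in% names(x)) ||
      !identical(digest_raw(x$payload), x$digest))
    stop("checkpoint '", path, "' is corrupt or has been tampered with",
         call. = FALSE)
  payload <- unserialize(x$payload)
  if (!identical(payload$version, CHECKPOINT_VERSION))
    stop("checkpoint version ", payload$version, " does not match ",
         CHECKPOINT_VERSION, call. = FALSE)
  if (!is.null(config) && !identical(unclass(payload$params$config),
                                     unclass(config)))
    stop("checkpoint config does not match the requested denoiser config",
         call. = FALSE)
  payload
}

# md5 of a raw vector via a temporary file (tools::md5sum is file-based).
digest_raw <- function(raw) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}
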