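# Modelling front-end: one fitting function returning a classed object
# with the usual print / summary / coef / predict / plot / simulate /
# residuals methods, wrapping the lower-level train / dehair machinery.

#' Fit a conditional diffusion dehairing model
#'
#' Trains the conditional U-Net noise predictor on paired hairy /
#' hair-free images and returns a fitted model object. The training data
#' may be a `dataset_manifest` (its train split is used) or an in-memory
#' list of [paired_sample()] objects.
#'
#' @param data training pairs (manifest or list of `paired_sample`).
#' @param diffusion a [diffusion_config()]; T controls how finely the
#'   forward corruption is discretized.
#' @param denoiser a [denoiser_config()] describing the U-Net.
#' @param control a [train_config()] (iterations, learning rate, batch
#'   size, seeds).
#' @param init_seed seed for parameter initialization.
#' @param keep_data store the training pairs in the object (needed by
#'   [residuals.dermadiff()]).
#' @return an object of class `dermadiff`.
#' @examples
#' \donttest{
#' pairs <- lapply(1:4, function(i) {
#'   clean <- make_lesion_texture(i, c(16, 16))
#'   hairy <- synth_line_hair(clean, n_lines = 4, seed = i,
#'                            length_range = c(3, 7))
#'   paired_sample(hairy, clean, "nv", paste0("s", i))
#' })
#' fit <- dermadiff(pairs,
#'                  diffusion = diffusion_config(T = 10),
#'                  control = train_config(iterations = 5, seed = 1))
#' print(fit)
#' }
#' @export
dermadiff <- function(data,
                      diffusion = diffusion_config(),
                      denoiser = denoiser_config(),
                      control = train_config(),
                      init_seed = 1L, keep_data = TRUE) {
  cl <- match.call()
  pairs <- resolve_pairs(data)
  params <- train(pairs, config = control, diffusion = diffusion,
                  denoiser = denoiser, init_seed = init_seed)
  structure(list(params = params,
                 schedule = attr(params, "schedule"),
                 losses = attr(params, "losses"),
                 diffusion = diffusion,
                 denoiser = denoiser,
                 control = control,
                 n_train = length(pairs),
                 image_dim = dim(pairs[[1L]]$clean),
                 data = if (keep_data) pairs else NULL,
                 call = cl),
            class = "dermadiff")
}

#' @export
print.dermadiff <- function(x, ...) {
  cat("Conditional diffusion dehairing model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d training pairs of %s, T = %d, %d parameters\n",
              x$n_train, paste(x$image_dim, collapse = "x"),
              x$schedule$T, length(flatten_params(x$params))))
  n <- length(x$losses)
  if (n > 0)
    cat(sprintf("  %d iterations; loss %.4f (first) -> %.4f (last)\n",
                n, x$losses[1L], x$losses[n]))
  invisible(x)
}

#' @export
summary.dermadiff <- function(object, window = 100L, ...) {
  n <- length(object$losses)
  w <- min(window, n)
  out <- list(call = object$call,
              n_train = object$n_train,
              image_dim = object$image_dim,
              T = object$schedule$T,
              n_params = length(flatten_params(object$params)),
              iterations = n,
              loss_first_window = mean(object$losses[seq_len(w)]),
              loss_last_window = mean(object$losses[(n - w + 1L):n]))
  class(out) <- "summary.dermadiff"
  out
}

#' @export
print.summary.dermadiff <- function(x, ...) {
  cat("Conditional diffusion dehairing model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  training pairs: %d (%s)\n", x$n_train,
              paste(x$image_dim, collapse = "x")))
  cat(sprintf("  diffusion steps T: %d   parameters: %d\n", x$T, x$n_params))
  cat(sprintf("  iterations: %d   mean loss first/last window: %.4f / %.4f\n",
              x$iterations, x$loss_first_window, x$loss_last_window))
  invisible(x)
}

#' @export
coef.dermadiff <- function(object, ...) flatten_params(object$params)

#' Dehair new images with a fitted model
#'
#' @param object a fitted `dermadiff` model.
#' @param newdata a single [0, 1] image array or a list of them.
#' @param mode,steps,seed sampler settings (see [sampler_config()]);
#'   `steps = NULL` uses the training T.
#' @param trajectory keep per-step iterates.
#' @param ... unused.
#' @return a dehaired image (single input) or list of images.
#' @export
predict.dermadiff <- function(object, newdata, mode = c("ancestral", "residual"),
                              steps = NULL, seed = 1L, trajectory = FALSE, ...) {
  mode <- match.arg(mode)
  single <- !is.list(newdata)
  imgs <- if (single) list(newdata) else newdata
  out <- lapply(seq_along(imgs), function(i) {
    r <- dehair(object$params, imgs[[i]], object$schedule,
                sampler_config(mode = mode, T_infer = steps,
                               seed = seed + i - 1L, trajectory = trajectory))
    if (trajectory) r else r$y0
  })
  if (single) out[[1L]] else out
}

#' Restoration residuals on the training pairs
#'
#' Dehaired-minus-clean pixel residuals for the stored training pairs;
#' requires the model to have been fitted with `keep_data = TRUE`.
#'
#' @param object a fitted `dermadiff` model.
#' @param n_pairs number of training pairs to evaluate (restoration is
#'   iterative and costs `T` network passes per image).
#' @param seed,steps sampler settings.
#' @param ... unused.
#' @return list of residual arrays.
#' @export
residuals.dermadiff <- function(object, n_pairs = min(4L, object$n_train),
                                seed = 1L, steps = NULL, ...) {
  if (is.null(object$data))
    stop("model was fitted with keep_data = FALSE", call. = FALSE)
  pairs <- object$data[seq_len(n_pairs)]
  restored <- predict(object, lapply(pairs, `[[`, "hairy"),
                      steps = steps, seed = seed)
  lapply(seq_along(pairs), function(i) restored[[i]] - pairs[[i]]$clean)
}

#' Draw repeated stochastic restorations
#'
#' The sampler is stochastic (initial noise and ancestral draws), so
#' repeated restorations of the same image with different seeds form a
#' sample from the model's posterior over hair-free images.
#'
#' @param object a fitted `dermadiff` model.
#' @param nsim number of restorations.
#' @param seed base seed; draw i uses `seed + i - 1`.
#' @param newdata hairy image to restore (default: first stored training
#'   image).
#' @param steps sampler iterations.
#' @param ... unused.
#' @return list of `nsim` dehaired images.
#' @export
simulate.dermadiff <- function(object, nsim = 1L, seed = 1L, newdata = NULL,
                               steps = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data))
      stop("supply newdata or fit with keep_data = TRUE", call. = FALSE)
    newdata <- object$data[[1L]]$hairy
  }
  lapply(seq_len(nsim), function(i)
    predict(object, newdata, steps = steps, seed = seed + i - 1L))
}

#' Plot the training loss curve
#'
#' @param x a fitted `dermadiff` model.
#' @param window running-mean window.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dermadiff <- function(x, window = 25L, ...) {
  l <- x$losses
  graphics::plot(seq_along(l), l, type = "l", col = "grey70",
                 xlab = "iteration", ylab = "epsilon-prediction loss", ...)
  if (length(l) >= window) {
    rm <- stats::filter(l, rep(1 / window, window), sides = 1)
    graphics::lines(seq_along(l), rm, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
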