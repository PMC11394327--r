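# Image-quality metrics (PSNR, SSIM, LPIPS with an injectable feature
# extractor) and confusion-matrix classification metrics, plus per-class
# report tables.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` in decibels; identical images (MSE = 0)
#' return `Inf`.
#'
#' @param reference,test image arrays of identical shape.
#' @param max_value maximum possible pixel value (1 for [0, 1] images,
#'   255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, max_value = 1) {
  if (!identical(dim(reference), dim(test)))
    stop("reference and test must share shape", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Structural similarity index
#'
#' Mean over sliding windows of the per-window similarity
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`,
#' with uniform window weighting and the conventional stabilizers
#' `C1 = (0.01 MAX)^2`, `C2 = (0.03 MAX)^2`. Multichannel images are
#' averaged over channels. Symmetric in its arguments and bounded in
#' [-1, 1], equal to 1 exactly for identical inputs.
#'
#' @param x,y image arrays of identical shape.
#' @param window square window side (default 8); capped at the image size.
#' @param max_value dynamic range maximum.
#' @param C1,C2 stabilizing constants.
#' @return scalar SSIM.
#' @export
ssim <- function(x, y, window = 8L, max_value = 1,
                 C1 = (0.01 * max_value)^2, C2 = (0.03 * max_value)^2) {
  if (!identical(dim(x), dim(y))) stop("x and y must share shape", call. = FALSE)
  if (length(dim(x)) == 3L) {
    return(mean(vapply(seq_len(dim(x)[3L]), function(k)
      ssim(x[, , k], y[, , k], window, max_value, C1, C2), numeric(1))))
  }
  H <- nrow(x); W <- ncol(x)
  w <- min(window, H, W)
  n <- w * w
  # sliding-window sums via cumulative sums over rows then columns
  win_sum <- function(m) {
    cs <- apply(rbind(0, apply(m, 2L, cumsum)), 1L, cumsum)  # transposed
    cs <- t(cs)
    cs <- cbind(0, cs)
    rows <- (w + 1L):(H + 1L); cols <- (w + 1L):(W + 1L)
    cs[rows, cols] - cs[rows - w, cols] - cs[rows, cols - w] +
      cs[rows - w, cols - w]
  }
  sx <- win_sum(x); sy <- win_sum(y)
  sxx <- win_sum(x * x); syy <- win_sum(y * y); sxy <- win_sum(x * y)
  mx <- sx / n; my <- sy / n
  vx <- sxx / n - mx^2; vy <- syy / n - my^2
  cxy <- sxy / n - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Identity feature extractor
#'
#' Single layer returning the image itself with unit weight; under this
#' extractor [lpips()] reduces exactly to the mean squared pixel
#' difference, a useful calibration point.
#' @return a `feature_extractor`.
#' @export
identity_extractor <- function() {
  structure(list(layers = list(function(img) as_hwc(img, n_channels(img))),
                 weights = 1),
            class = "feature_extractor")
}

#' Fixed-seed random convolution feature extractor
#'
#' A stack of random 3x3 convolutions with ReLU between layers, generated
#' deterministically from a seed. It needs no pretrained weights and
#' serves as the default perceptual backend at desk scale; a pretrained
#' network can be plugged in through the same interface (a list of
#' image -> H x W x C feature maps plus per-layer weights).
#'
#' @param seed integer seed.
#' @param n_layers number of convolution layers.
#' @param channels feature channels per layer.
#' @param weights per-layer weights (default uniform `1/n_layers`).
#' @return a `feature_extractor`.
#' @export
random_conv_extractor <- function(seed = 42L, n_layers = 3L, channels = 8L,
                                  weights = rep(1 / n_layers, n_layers)) {
  convs <- with_seed(seed, {
    cins <- c(NA, rep(channels, n_layers - 1L))
    lapply(seq_len(n_layers), function(l)
      list(gray = init_conv3(if (l == 1L) 1L else channels, channels),
           rgb = if (l == 1L) init_conv3(3L, channels) else NULL))
  })
  layer_fun <- function(l) {
    force(l)
    function(img) {
      X <- as_hwc(img, n_channels(img))
      for (k in seq_len(l)) {
        Wb <- if (k == 1L && dim(X)[3L] == 3L) convs[[k]]$rgb else convs[[k]]$gray
        X <- conv3_fwd(X, Wb$W, Wb$b)$Y
        if (k < l) X <- pmax(X, 0)
      }
      X
    }
  }
  structure(list(layers = lapply(seq_len(n_layers), layer_fun),
                 weights = weights),
            class = "feature_extractor")
}

#' Learned-perceptual-style image patch similarity
#'
#' Weighted sum over extractor layers of the spatially averaged squared
#' feature difference:
#' `sum_l (1 / (H_l W_l)) sum_{h,w} w_l || F_l(I1)_{h,w} - F_l(I2)_{h,w} ||^2`.
#' Zero iff all features coincide; with the identity extractor it equals
#' the mean squared pixel difference.
#'
#' @param i1,i2 image arrays accepted by the extractor.
#' @param extractor a `feature_extractor` (see [random_conv_extractor()],
#'   [identity_extractor()]).
#' @return non-negative scalar.
#' @export
lpips <- function(i1, i2, extractor = random_conv_extractor()) {
  stopifnot(inherits(extractor, "feature_extractor"))
  total <- 0
  for (l in seq_along(extractor$layers)) {
    F1 <- extractor$layers[[l]](i1)
    F2 <- extractor$layers[[l]](i2)
    if (!identical(dim(F1), dim(F2)))
      stop("extractor produced mismatched feature shapes", call. = FALSE)
    d <- dim(F1)
    total <- total + extractor$weights[l] * sum((F1 - F2)^2) / (d[1L] * d[2L])
  }
  total
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from
#' one-vs-rest confusion counts. Denominator-zero cases yield `NaN`
#' (undefined-metric sentinel). The metrics are invariant under uniform
#' scaling of all four counts.
#'
#' @param TP,FP,FN,TN non-negative counts.
#' @return named list of the five metrics.
#' @examples
#' classification_metrics(TP = 9, FP = 1, FN = 1, TN = 89)
#' @export
classification_metrics <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  total <- TP + FP + FN + TN
  ratio <- function(a, b) if (b == 0) NaN else a / b
  precision <- ratio(TP, TP + FP)
  recall <- ratio(TP, TP + FN)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    NaN else 2 * precision * recall / (precision + recall)
  list(accuracy = ratio(TP + TN, total),
       precision = precision,
       recall = recall,
       specificity = ratio(TN, TN + FP),
       f1 = f1)
}

#' Multiclass metrics by one-vs-rest macro averaging
#'
#' Reduces a K-class confusion matrix to per-class one-vs-rest counts,
#' computes the five metrics per class, and macro-averages them.
#'
#' @param confusion K x K matrix, rows = true class, columns = predicted.
#' @return list with `per_class` (data frame) and `macro` (named list).
#' @export
multiclass_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  K <- nrow(confusion)
  total <- sum(confusion)
  rows <- lapply(seq_len(K), function(k) {
    TP <- confusion[k, k]
    FN <- sum(confusion[k, ]) - TP
    FP <- sum(confusion[, k]) - TP
    TN <- total - TP - FN - FP
    c(list(class = if (is.null(rownames(confusion))) as.character(k)
           else rownames(confusion)[k]),
      classification_metrics(TP, FP, FN, TN))
  })
  per_class <- do.call(rbind, lapply(rows, as.data.frame))
  macro <- as.list(colMeans(per_class[, -1L]))
  list(per_class = per_class, macro = macro)
}

#' Mean cross-entropy loss
#'
#' Mean over samples of `-sum_i y_i log(p_i)`; probabilities are floored
#' at `eps` to keep the loss finite when the true class receives zero
#' mass.
#'
#' @param labels one-hot matrix (samples x classes) or a single vector.
#' @param probabilities matching matrix of class probabilities (rows on
#'   the simplex).
#' @param eps probability floor.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(labels, probabilities, eps = 1e-12) {
  y <- rbind(labels); p <- rbind(probabilities)
  if (!identical(dim(y), dim(p)))
    stop("labels and probabilities must share shape", call. = FALSE)
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6))
    stop("probabilities must be non-negative and sum to 1 per sample",
         call. = FALSE)
  mean(-rowSums(y * log(pmax(p, eps))))
}

#' Per-class image-quality report
#'
#' Computes PSNR, SSIM and LPIPS for every (clean, restored) pair, then
#' a per-class mean and an `Average` row equal to the arithmetic mean of
#' the class rows — the layout of the standard dehairing benchmark
#' tables.
#'
#' @param pairs list of lists with elements `clean`, `restored`, `label`
#'   (label from [LESION_CLASSES]).
#' @param extractor LPIPS backend; `NULL` for the default fixed-seed
#'   random extractor.
#' @param max_value PSNR/SSIM dynamic range maximum.
#' @param file optional CSV path to write the report to.
#' @return `metric_report` data frame with columns
#'   `class, n, psnr, ssim, lpips`.
#' @export
evaluate_pairs <- function(pairs, extractor = NULL, max_value = 1,
                           file = NULL) {
  if (length(pairs) == 0L) stop("pairs must be non-empty", call. = FALSE)
  if (is.null(extractor)) extractor <- random_conv_extractor()
  labs <- vapply(pairs, function(p) p$label, character(1))
  bad <- setdiff(unique(labs), LESION_CLASSES)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  vals <- t(vapply(pairs, function(p) c(
    psnr = psnr(p$clean, p$restored, max_value),
    ssim = ssim(p$clean, p$restored, max_value = max_value),
    lpips = lpips(p$clean, p$restored, extractor)), numeric(3)))
  classes <- intersect(LESION_CLASSES, unique(labs))
  rows <- lapply(classes, function(cl) {
    i <- labs == cl
    data.frame(class = cl, n = sum(i), psnr = mean(vals[i, "psnr"]),
               ssim = mean(vals[i, "ssim"]), lpips = mean(vals[i, "lpips"]))
  })
  rep <- do.call(rbind, rows)
  avg <- data.frame(class = "Average", n = sum(rep$n),
                    psnr = mean(rep$psnr), ssim = mean(rep$ssim),
                    lpips = mean(rep$lpips))
  out <- rbind(rep, avg)
  class(out) <- c("metric_report", "data.frame")
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
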