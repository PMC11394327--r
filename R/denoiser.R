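# Conditional U-Net noise predictor f(x, y_t, gamma) with hand-written
# forward and backward passes. Tensors are arrays (H, W, C). Convolutions
# use im2col so the inner loop is a single matrix multiply; at desk scale
# (16-64 px, a few channels) base R linear algebra is fast enough.
#
# Architecture: channel-wise concatenation of the conditioning image x
# and the noisy image y_t at the input; a 3x3 stem; encoder stages of
# ResNet blocks (3x3 conv -> +noise-level bias -> ReLU -> 3x3 conv, with
# identity or 1x1-projected skip) separated by 2x2 mean-pool; a mirrored
# decoder with nearest-neighbor upsampling and concatenated encoder skip
# features; a 3x3 output head. The noise level gamma enters every block
# through a sinusoidal embedding mapped by a per-block linear layer to a
# per-channel bias.

#' Denoiser configuration
#'
#' @param image_channels channels of the images (1 or 3).
#' @param base_channels width of the first stage.
#' @param channel_mults integer multiplier per resolution stage; the
#'   number of stages is `length(channel_mults)` and inputs must be
#'   divisible by `2^(stages - 1)`.
#' @param blocks_per_stage ResNet blocks per stage.
#' @param time_embed_dim even length of the sinusoidal noise-level
#'   embedding.
#' @return a `denoiser_config` list.
#' @export
denoiser_config <- function(image_channels = 1L, base_channels = 8L,
                            channel_mults = c(1L, 2L),
                            blocks_per_stage = 1L, time_embed_dim = 16L) {
  if (length(channel_mults) < 1L || any(channel_mults < 1))
    stop("channel_mults must be positive integers", call. = FALSE)
  if (blocks_per_stage < 1L) stop("blocks_per_stage must be >= 1", call. = FALSE)
  if (time_embed_dim %% 2L != 0L) stop("time_embed_dim must be even", call. = FALSE)
  if (!image_channels %in% c(1L, 3L)) stop("image_channels must be 1 or 3", call. = FALSE)
  structure(list(image_channels = as.integer(image_channels),
                 base_channels = as.integer(base_channels),
                 channel_mults = as.integer(channel_mults),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 time_embed_dim = as.integer(time_embed_dim)),
            class = "denoiser_config")
}

stage_channels <- function(cfg) cfg$base_channels * cfg$channel_mults

## ---- primitive layers -------------------------------------------------

# Zero-pad H and W by 1 on each side.
pad1 <- function(X) {
  d <- dim(X)
  out <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L]))
  out[2:(d[1L] + 1L), 2:(d[2L] + 1L), ] <- X
  out
}

# im2col for 3x3 kernels on a padded input: rows grouped as
# (offset o in 1..9) x (input channel k), columns are output pixels in
# column-major (h, w) order.
im2col3 <- function(Xp, H, W) {
  Cin <- dim(Xp)[3L]
  cols <- matrix(0, 9L * Cin, H * W)
  for (o in 0:8) {
    dy <- o %/% 3L; dx <- o %% 3L
    patch <- Xp[(dy + 1L):(dy + H), (dx + 1L):(dx + W), , drop = FALSE]
    cols[(o * Cin + 1L):((o + 1L) * Cin), ] <- t(matrix(patch, H * W, Cin))
  }
  cols
}

# Scatter-add of column gradients back to the padded input.
col2im3 <- function(dcols, H, W, Cin) {
  dXp <- array(0, c(H + 2L, W + 2L, Cin))
  for (o in 0:8) {
    dy <- o %/% 3L; dx <- o %% 3L
    g <- array(t(dcols[(o * Cin + 1L):((o + 1L) * Cin), , drop = FALSE]),
               c(H, W, Cin))
    dXp[(dy + 1L):(dy + H), (dx + 1L):(dx + W), ] <-
      dXp[(dy + 1L):(dy + H), (dx + 1L):(dx + W), , drop = FALSE] + g
  }
  dXp
}

# 3x3 same convolution. W is (Cout x 9*Cin), b length Cout.
conv3_fwd <- function(X, Wm, b) {
  d <- dim(X); H <- d[1L]; W_ <- d[2L]
  cols <- im2col3(pad1(X), H, W_)
  Y <- Wm %*% cols + b
  list(Y = array(t(Y), c(H, W_, nrow(Wm))), cols = cols, H = H, W = W_,
       Cin = d[3L])
}

conv3_bwd <- function(cache, Wm, dY) {
  H <- cache$H; W_ <- cache$W
  dYm <- t(matrix(dY, H * W_, dim(dY)[3L]))
  dW <- dYm %*% t(cache$cols)
  db <- rowSums(dYm)
  dXp <- col2im3(t(Wm) %*% dYm, H, W_, cache$Cin)
  list(dX = dXp[2:(H + 1L), 2:(W_ + 1L), , drop = FALSE], dW = dW, db = db)
}

# 1x1 convolution (channel projection).
conv1_fwd <- function(X, Wm, b) {
  d <- dim(X)
  Xm <- t(matrix(X, d[1L] * d[2L], d[3L]))
  Y <- Wm %*% Xm + b
  list(Y = array(t(Y), c(d[1L], d[2L], nrow(Wm))), Xm = Xm, H = d[1L], W = d[2L])
}

conv1_bwd <- function(cache, Wm, dY) {
  dYm <- t(matrix(dY, cache$H * cache$W, dim(dY)[3L]))
  list(dX = array(t(t(Wm) %*% dYm), c(cache$H, cache$W, ncol(Wm))),
       dW = dYm %*% t(cache$Xm), db = rowSums(dYm))
}

# 2x2 mean pooling, stride 2 (H, W even).
pool_fwd <- function(X) {
  d <- dim(X)
  (X[seq(1L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE] +
   X[seq(2L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE] +
   X[seq(1L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE] +
   X[seq(2L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE]) / 4
}

pool_bwd <- function(dY) {
  d <- dim(dY)
  dX <- array(0, c(2L * d[1L], 2L * d[2L], d[3L]))
  g <- dY / 4
  dX[seq(1L, 2L * d[1L], 2L), seq(1L, 2L * d[2L], 2L), ] <- g
  dX[seq(2L, 2L * d[1L], 2L), seq(1L, 2L * d[2L], 2L), ] <- g
  dX[seq(1L, 2L * d[1L], 2L), seq(2L, 2L * d[2L], 2L), ] <- g
  dX[seq(2L, 2L * d[1L], 2L), seq(2L, 2L * d[2L], 2L), ] <- g
  dX
}

# Nearest-neighbor x2 upsampling.
upsample_fwd <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

upsample_bwd <- function(dY) {
  d <- dim(dY)
  dY[seq(1L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE] +
    dY[seq(2L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE] +
    dY[seq(1L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE] +
    dY[seq(2L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE]
}

#' Sinusoidal embedding of a noise level
#'
#' Maps a scalar gamma in [0, 1] to a length-`dim` vector of sines and
#' cosines at geometrically spaced frequencies; this is the conditioning
#' signal injected into every ResNet block.
#'
#' @param gamma scalar noise level.
#' @param dim even embedding length.
#' @return numeric vector of length `dim`.
#' @export
time_embedding <- function(gamma, dim = 16L) {
  half <- dim %/% 2L
  freqs <- exp(seq(log(1), log(1000), length.out = half))
  c(sin(gamma * freqs), cos(gamma * freqs))
}

## ---- ResNet block -----------------------------------------------------

resblock_fwd <- function(X, p, emb) {
  c1 <- conv3_fwd(X, p$c1$W, p$c1$b)
  tb <- as.vector(p$t$W %*% emb + p$t$b)            # per-channel bias
  h2 <- sweep(c1$Y, 3L, tb, "+")
  h3 <- pmax(h2, 0)
  c2 <- conv3_fwd(h3, p$c2$W, p$c2$b)
  if (is.null(p$skip)) {
    out <- c2$Y + X
    sk <- NULL
  } else {
    sk <- conv1_fwd(X, p$skip$W, p$skip$b)
    out <- c2$Y + sk$Y
  }
  list(Y = out, c1 = c1, c2 = c2, sk = sk, relu_mask = (h2 > 0), emb = emb)
}

resblock_bwd <- function(cache, p, dY) {
  b2 <- conv3_bwd(cache$c2, p$c2$W, dY)
  dh2 <- b2$dX * cache$relu_mask
  dtb <- apply(dh2, 3L, sum)
  b1 <- conv3_bwd(cache$c1, p$c1$W, dh2)
  # assemble in the same field order as init_resblock so that the
  # unlist()ed gradient aligns with the unlist()ed parameters
  g <- list(c1 = list(W = b1$dW, b = b1$db),
            t = list(W = outer(dtb, cache$emb), b = dtb),
            c2 = list(W = b2$dW, b = b2$db))
  if (is.null(p$skip)) {
    dX <- b1$dX + dY
  } else {
    bs <- conv1_bwd(cache$sk, p$skip$W, dY)
    g$skip <- list(W = bs$dW, b = bs$db)
    dX <- b1$dX + bs$dX
  }
  list(dX = dX, grads = g)
}

init_conv3 <- function(Cin, Cout) {
  list(W = matrix(stats::rnorm(Cout * 9L * Cin, 0, sqrt(2 / (9L * Cin))),
                  Cout, 9L * Cin),
       b = numeric(Cout))
}

init_conv1 <- function(Cin, Cout) {
  list(W = matrix(stats::rnorm(Cout * Cin, 0, sqrt(2 / Cin)), Cout, Cin),
       b = numeric(Cout))
}

init_resblock <- function(Cin, Cout, E) {
  # skip entry is present only when a projection is needed: relist()
  # cannot faithfully round-trip NULL placeholders
  p <- list(c1 = init_conv3(Cin, Cout),
            t = list(W = matrix(stats::rnorm(Cout * E, 0, 0.01), Cout, E),
                     b = numeric(Cout)),
            c2 = init_conv3(Cout, Cout))
  if (Cin != Cout) p$skip <- init_conv1(Cin, Cout)
  p
}

#' Initialize denoiser parameters
#'
#' He-normal initialization of every convolution; deterministic for a
#' fixed seed. The parameter structure is fully determined by the config,
#' so checkpoints round-trip exactly.
#'
#' @param config a [denoiser_config()].
#' @param seed integer seed.
#' @return a `denoiser_params` object.
#' @export
init_denoiser <- function(config, seed = 1L) {
  stopifnot(inherits(config, "denoiser_config"))
  ch <- stage_channels(config)
  S <- length(ch)
  E <- config$time_embed_dim
  B <- config$blocks_per_stage
  with_seed(seed, {
    params <- list(stem = init_conv3(2L * config$image_channels, ch[1L]))
    params$enc <- lapply(seq_len(S), function(s) {
      lapply(seq_len(B), function(b) {
        cin <- if (b == 1L && s > 1L) ch[s - 1L] else ch[s]
        init_resblock(cin, ch[s], E)
      })
    })
    if (S > 1L) {
      params$dec <- lapply(seq_len(S - 1L), function(i) {
        s <- S - i  # decoder works from the bottom up: stage S-1 .. 1
        lapply(seq_len(B), function(b) {
          cin <- if (b == 1L) ch[s + 1L] + ch[s] else ch[s]
          init_resblock(cin, ch[s], E)
        })
      })
    } else params$dec <- list()
    # zero-initialized output head: the untrained net predicts zero noise,
    # which stabilizes early optimization (standard for diffusion models)
    params$final <- list(W = matrix(0, config$image_channels, 9L * ch[1L]),
                         b = numeric(config$image_channels))
    structure(list(theta = params, config = config, step = 0L),
              class = "denoiser_params")
  })
}

#' @export
print.denoiser_params <- function(x, ...) {
  cat("conditional U-Net denoiser:", length(unlist(x$theta)), "parameters,",
      length(x$config$channel_mults), "stage(s), trained", x$step, "step(s)\n")
  invisible(x)
}

# Full forward pass with caches for backprop. x and y_t are (H, W, C).
unet_forward <- function(theta, cfg, x, y_t, gamma) {
  S <- length(cfg$channel_mults)
  B <- cfg$blocks_per_stage
  emb <- time_embedding(gamma, cfg$time_embed_dim)
  inp <- array(c(x, y_t), c(dim(x)[1L], dim(x)[2L], 2L * cfg$image_channels))
  stem <- conv3_fwd(inp, theta$stem$W, theta$stem$b)
  h <- stem$Y
  enc_caches <- vector("list", S)
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    stage_caches <- vector("list", B)
    for (b in seq_len(B)) {
      rc <- resblock_fwd(h, theta$enc[[s]][[b]], emb)
      h <- rc$Y
      stage_caches[[b]] <- rc
    }
    enc_caches[[s]] <- stage_caches
    if (s < S) {
      skips[[s]] <- h
      h <- pool_fwd(h)
    }
  }
  dec_caches <- if (S > 1L) vector("list", S - 1L) else list()
  for (i in seq_len(max(S - 1L, 0L))) {
    s <- S - i
    h <- upsample_fwd(h)
    h <- array(c(h, skips[[s]]),
               c(dim(h)[1L], dim(h)[2L], dim(h)[3L] + dim(skips[[s]])[3L]))
    stage_caches <- vector("list", B)
    for (b in seq_len(B)) {
      rc <- resblock_fwd(h, theta$dec[[i]][[b]], emb)
      h <- rc$Y
      stage_caches[[b]] <- rc
    }
    dec_caches[[i]] <- stage_caches
  }
  fin <- conv3_fwd(h, theta$final$W, theta$final$b)
  list(out = fin$Y,
       cache = list(stem = stem, enc = enc_caches, dec = dec_caches,
                    fin = fin, S = S, B = B))
}

unet_backward <- function(theta, cfg, cache, dOut) {
  S <- cache$S; B <- cache$B
  ch <- stage_channels(cfg)
  bf <- conv3_bwd(cache$fin, theta$final$W, dOut)
  gfinal <- list(W = bf$dW, b = bf$db)
  dh <- bf$dX
  dskips <- vector("list", S)
  gdec <- if (S > 1L) vector("list", S - 1L) else list()
  for (i in rev(seq_len(max(S - 1L, 0L)))) {
    s <- S - i
    gdec[[i]] <- vector("list", B)
    for (b in rev(seq_len(B))) {
      rb <- resblock_bwd(cache$dec[[i]][[b]], theta$dec[[i]][[b]], dh)
      gdec[[i]][[b]] <- rb$grads
      dh <- rb$dX
    }
    # split the concat gradient: first ch[s+1] channels to the upsampled
    # path, the rest to the encoder skip
    cu <- ch[s + 1L]
    dskips[[s]] <- dh[, , (cu + 1L):dim(dh)[3L], drop = FALSE]
    dh <- upsample_bwd(dh[, , seq_len(cu), drop = FALSE])
  }
  genc <- vector("list", S)
  for (s in rev(seq_len(S))) {
    if (s < S) dh <- pool_bwd(dh) + dskips[[s]]
    genc[[s]] <- vector("list", B)
    for (b in rev(seq_len(B))) {
      rb <- resblock_bwd(cache$enc[[s]][[b]], theta$enc[[s]][[b]], dh)
      genc[[s]][[b]] <- rb$grads
      dh <- rb$dX
    }
  }
  bs <- conv3_bwd(cache$stem, theta$stem$W, dh)
  # field order must mirror init_denoiser's theta for flat alignment
  list(stem = list(W = bs$dW, b = bs$db), enc = genc, dec = gdec,
       final = gfinal)
}

as_hwc <- function(img, C) {
  if (length(dim(img)) == 2L) array(img, c(dim(img), 1L)) else img
}

# Nearest-neighbor resize to (H, W).
resize_nn <- function(img, H, W) {
  d <- dim(img)
  ri <- pmin(pmax(round(seq(0.5, d[1L] - 0.5, length.out = H) + 0.5), 1L), d[1L])
  ci <- pmin(pmax(round(seq(0.5, d[2L] - 0.5, length.out = W) + 0.5), 1L), d[2L])
  if (length(d) == 2L) img[ri, ci] else img[ri, ci, , drop = FALSE]
}

#' Predict the noise field with the conditional denoiser
#'
#' Evaluates f(x, y_t, gamma): the conditioning image `x` is resized
#' (nearest neighbor) to the spatial size of `y_t` if needed, concatenated
#' channel-wise, and passed through the U-Net. If the spatial size is not
#' divisible by `2^(stages - 1)` the input is padded reflectively and the
#' output cropped back. Deterministic given (params, inputs).
#'
#' @param params a `denoiser_params`.
#' @param x conditioning (hairy) image, internal [-1, 1] scale.
#' @param y_t noisy image, same channel count.
#' @param gamma noise level in [0, 1].
#' @return predicted noise field with the shape of `y_t`.
#' @export
predict_noise <- function(params, x, y_t, gamma) {
  stopifnot(inherits(params, "denoiser_params"))
  cfg <- params$config
  y3 <- as_hwc(y_t, cfg$image_channels)
  H <- dim(y3)[1L]; W <- dim(y3)[2L]
  x3 <- as_hwc(x, cfg$image_channels)
  if (!identical(dim(x3)[1:2], dim(y3)[1:2]))
    x3 <- as_hwc(resize_nn(x3, H, W), cfg$image_channels)
  if (dim(x3)[3L] != dim(y3)[3L])
    stop("x and y_t must have the same channel count", call. = FALSE)
  div <- 2L^(length(cfg$channel_mults) - 1L)
  padH <- (div - H %% div) %% div
  padW <- (div - W %% div) %% div
  if (padH > 0L || padW > 0L) {
    x3 <- pad_reflect(x3, padH, padW)
    y3 <- pad_reflect(y3, padH, padW)
  }
  out <- unet_forward(params$theta, cfg, x3, y3, gamma)$out
  out <- out[seq_len(H), seq_len(W), , drop = FALSE]
  if (length(dim(y_t)) == 2L) out[, , 1L] else out
}

# Reflective padding on the bottom/right.
pad_reflect <- function(X, padH, padW) {
  d <- dim(X)
  ri <- c(seq_len(d[1L]), rev(seq_len(d[1L])))[seq_len(d[1L] + padH)]
  ci <- c(seq_len(d[2L]), rev(seq_len(d[2L])))[seq_len(d[2L] + padW)]
  X[ri, ci, , drop = FALSE]
}

#' Flatten denoiser parameters to a numeric vector
#'
#' Used by the optimizer and by finite-difference checks; `relist_params`
#' restores the nested structure.
#'
#' @param params a `denoiser_params` (or bare nested theta list).
#' @return numeric vector.
#' @export
flatten_params <- function(params) {
  theta <- if (inherits(params, "denoiser_params")) params$theta else params
  unlist(theta, use.names = FALSE)
}

#' @rdname flatten_params
#' @param flat numeric vector from [flatten_params()].
#' @param skeleton object providing the nested structure.
#' @export
relist_params <- function(flat, skeleton) {
  theta <- if (inherits(skeleton, "denoiser_params")) skeleton$theta else skeleton
  utils::relist(flat, skeleton = theta)
}
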