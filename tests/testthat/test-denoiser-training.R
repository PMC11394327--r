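test_that("denoiser initialization is seeded with config-determined shapes", {
  cfg <- tiny_denoiser_cfg()
  p1 <- init_denoiser(cfg, seed = 3)
  p2 <- init_denoiser(cfg, seed = 3)
  expect_identical(flatten_params(p1), flatten_params(p2))
  expect_false(identical(flatten_params(p1),
                         flatten_params(init_denoiser(cfg, seed = 4))))

  # parameter count oracle for a 1-stage config from shape arithmetic:
  # stem 3x3 (2 -> c), one ResNet block (two 3x3 convs c -> c plus the
  # noise-level linear E -> c), output head 3x3 (c -> 1)
  c1 <- denoiser_config(base_channels = 4, channel_mults = 1, time_embed_dim = 8)
  pc <- length(flatten_params(init_denoiser(c1, seed = 1)))
  c_ <- 4; E <- 8
  expected <- (9 * 2 * c_ + c_) +                 # stem
    (9 * c_ * c_ + c_) + (E * c_ + c_) + (9 * c_ * c_ + c_) +  # block
    (9 * c_ * 1 + 1)                              # head
  expect_equal(pc, expected)
})

test_that("noise prediction is deterministic with shape-preserving output", {
  p <- init_denoiser(tiny_denoiser_cfg(), seed = 1)
  set.seed(2)
  x <- matrix(runif(256, -1, 1), 16, 16)
  y <- matrix(rnorm(256), 16, 16)
  o1 <- predict_noise(p, x, y, 0.3)
  o2 <- predict_noise(p, x, y, 0.3)
  expect_identical(o1, o2)
  expect_identical(dim(o1), dim(y))
  expect_true(all(is.finite(o1)))
  # conditioning image is resized to the noisy image's grid
  xs <- matrix(runif(64, -1, 1), 8, 8)
  expect_identical(dim(predict_noise(p, xs, y, 0.3)), dim(y))
  # odd sizes go through declared reflective padding + crop
  y_odd <- matrix(rnorm(15 * 17), 15, 17)
  x_odd <- matrix(runif(15 * 17, -1, 1), 15, 17)
  expect_identical(dim(predict_noise(p, x_odd, y_odd, 0.3)), dim(y_odd))
})

test_that("analytic gradients match central finite differences", {
  p <- init_denoiser(tiny_denoiser_cfg(), seed = 5)
  set.seed(6)
  x <- array(runif(256, -1, 1), c(16, 16, 1))
  y0 <- array(runif(256, -1, 1), c(16, 16, 1))
  eps <- array(rnorm(256), c(16, 16, 1))
  lg <- dermadiff:::pair_loss_grad(p, x, y0, 0.4, eps)
  ganal <- unlist(lg$grad, use.names = FALSE)
  flat <- flatten_params(p)
  expect_length(ganal, length(flat))
  h <- 1e-5
  idx <- sample(length(flat), 25)
  for (i in idx) {
    fp <- flat; fp[i] <- flat[i] + h
    pm <- p; pm$theta <- relist_params(fp, p)
    l1 <- dermadiff:::pair_loss_grad(pm, x, y0, 0.4, eps, want_grad = FALSE)$loss
    fp[i] <- flat[i] - h
    pm$theta <- relist_params(fp, p)
    l0 <- dermadiff:::pair_loss_grad(pm, x, y0, 0.4, eps, want_grad = FALSE)$loss
    fd <- (l1 - l0) / (2 * h)
    expect_lt(abs(fd - ganal[i]) / max(abs(fd), abs(ganal[i]), 1e-8), 1e-4)
  }
})

test_that("a zero learning rate leaves parameters untouched", {
  p <- init_denoiser(tiny_denoiser_cfg(), seed = 1)
  sch <- make_schedule(diffusion_config(T = 10))
  batch <- lapply(1:2, make_noise_pair)
  set.seed(3)
  st <- train_step(p, batch, sch, learning_rate = 0)
  expect_identical(flatten_params(st$params), flatten_params(p))
  expect_true(is.finite(st$loss))
  expect_error(train_step(p, list(), sch), "non-empty")
})

test_that("repeated steps on one fixed batch drive the loss down", {
  p <- init_denoiser(tiny_denoiser_cfg(), seed = 2)
  sch <- make_schedule(diffusion_config(T = 10))
  batch <- lapply(1:4, make_noise_pair)
  opt <- NULL
  losses <- numeric(50)
  set.seed(4)
  for (k in 1:50) {
    st <- train_step(p, batch, sch, opt, learning_rate = 5e-3)
    p <- st$params; opt <- st$opt_state; losses[k] <- st$loss
  }
  expect_lt(losses[50], losses[1])
  expect_lt(mean(losses[41:50]), mean(losses[1:10]))
})

test_that("training runs its budget and is reproducible from a checkpoint", {
  pairs <- lapply(1:4, make_noise_pair)
  cfgD <- diffusion_config(T = 10)
  cfgN <- tiny_denoiser_cfg()
  ckdir <- tempfile("ck")
  p_full <- train(pairs,
                  config = train_config(iterations = 10, learning_rate = 1e-3,
                                        batch_size = 2, seed = 7,
                                        checkpoint_every = 5,
                                        checkpoint_path = ckdir),
                  diffusion = cfgD, denoiser = cfgN, init_seed = 1)
  expect_length(attr(p_full, "losses"), 10L)
  expect_false(identical(flatten_params(p_full),
                         flatten_params(init_denoiser(cfgN, 1))))
  # resume from the midpoint checkpoint reproduces the full run exactly
  ck <- file.path(ckdir, "ckpt_000005.rds")
  expect_true(file.exists(ck))
  p_res <- train(pairs,
                 config = train_config(iterations = 10, learning_rate = 1e-3,
                                       batch_size = 2, seed = 7),
                 diffusion = cfgD, denoiser = cfgN, resume = ck)
  expect_identical(flatten_params(p_res), flatten_params(p_full))
  expect_equal(attr(p_res, "losses"), attr(p_full, "losses"))
  expect_error(train(list(), config = train_config(iterations = 1)), "empty|manifest")
})

test_that("checkpoints round-trip exactly and reject tampering", {
  p <- init_denoiser(tiny_denoiser_cfg(), seed = 9)
  opt <- adam_init(length(flatten_params(p)))
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(p, opt, tf)
  ck <- load_checkpoint(tf)
  expect_identical(flatten_params(ck$params), flatten_params(p))
  # config guard
  expect_error(load_checkpoint(tf, config = denoiser_config(base_channels = 16)),
               "config")
  # tampering is detected via the embedded digest
  x <- readRDS(tf)
  x$payload[100] <- as.raw(bitwXor(as.integer(x$payload[100]), 255L))
  saveRDS(x, tf)
  expect_error(load_checkpoint(tf), "tampered|corrupt")
})
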