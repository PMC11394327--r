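test_that("psnr follows the closed form and decreases with error", {
  a <- matrix(0.5, 8, 8)
  expect_identical(psnr(a, a), Inf)
  # uniform error with MSE = 0.01 at MAX = 1 gives exactly 20 dB
  expect_equal(psnr(a, a + 0.1), 20)
  # loop-computed MSE oracle
  set.seed(1)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(psnr(x, y), 10 * log10(1 / (acc / 64)))
  # 8-bit scale
  expect_equal(psnr(a * 255, (a + 0.1) * 255, max_value = 255),
               10 * log10(255^2 / (25.5^2)))
  # strict monotonicity on an error ladder
  ladder <- sapply(c(0.02, 0.05, 0.1, 0.2), function(d) psnr(a, a + d))
  expect_true(all(diff(ladder) < 0))
  expect_error(psnr(a, matrix(0, 2, 2)), "shape")
})

test_that("ssim is 1 for identical images, symmetric, bounded, and matches
          the luminance-only closed form on constants", {
  img <- make_lesion_texture(4, c(32, 32))
  expect_equal(ssim(img, img), 1)
  # constant images: variances and covariance vanish, leaving
  # (2ab + C1) / (a^2 + b^2 + C1) * (C2 / C2)
  a <- 0.3; b <- 0.7
  C1 <- 0.01^2
  expect_equal(ssim(matrix(a, 16, 16), matrix(b, 16, 16)),
               (2 * a * b + C1) / (a^2 + b^2 + C1))
  set.seed(2)
  x <- matrix(runif(256), 16, 16)
  y <- clip_image(x + rnorm(256, 0, 0.1))
  expect_equal(ssim(x, y), ssim(y, x))
  expect_true(abs(ssim(x, y)) <= 1)
  # independent sliding-window loop oracle
  w <- 8; H <- 16; W <- 16; C1 <- 0.01^2; C2 <- 0.03^2
  vals <- c()
  for (r in 1:(H - w + 1)) for (c_ in 1:(W - w + 1)) {
    px <- x[r:(r + w - 1), c_:(c_ + w - 1)]
    py <- y[r:(r + w - 1), c_:(c_ + w - 1)]
    mx <- mean(px); my <- mean(py)
    vx <- mean(px^2) - mx^2; vy <- mean(py^2) - my^2
    cxy <- mean(px * py) - mx * my
    vals <- c(vals, (2 * mx * my + C1) * (2 * cxy + C2) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  expect_equal(ssim(x, y), mean(vals))
})

test_that("lpips reduces to MSE under the identity extractor and is
          zero for identical features", {
  img1 <- make_lesion_texture(5, c(16, 16))
  img2 <- make_lesion_texture(6, c(16, 16))
  ex <- random_conv_extractor(seed = 1)
  expect_equal(lpips(img1, img1, ex), 0)
  # zero layer weights: zero distance
  ex0 <- random_conv_extractor(seed = 1, weights = c(0, 0, 0))
  expect_equal(lpips(img1, img2, ex0), 0)
  # identity extractor with unit weight: mean squared pixel difference
  expect_equal(lpips(img1, img2, identity_extractor()),
               mean((img1 - img2)^2))
  expect_gt(lpips(img1, img2, ex), 0)
  # deterministic backend
  expect_equal(lpips(img1, img2, random_conv_extractor(seed = 1)),
               lpips(img1, img2, random_conv_extractor(seed = 1)))
})

test_that("classification metrics match hand arithmetic and scale invariance", {
  m <- classification_metrics(TP = 9, FP = 1, FN = 1, TN = 89)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$specificity, 89 / 90)
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$f1, 0.9)
  # perfect classifier
  perf <- classification_metrics(10, 0, 0, 90)
  expect_true(all(unlist(perf) == 1))
  # F1 harmonic-mean oracle and scaling invariance on random counts
  set.seed(3)
  for (k in 1:10) {
    cts <- sample(1:50, 4)
    mm <- classification_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(mm$f1, 2 * mm$precision * mm$recall / (mm$precision + mm$recall))
    ms <- classification_metrics(3 * cts[1], 3 * cts[2], 3 * cts[3], 3 * cts[4])
    expect_equal(unlist(mm), unlist(ms))
  }
  # undefined-metric sentinel
  expect_true(is.nan(classification_metrics(0, 0, 5, 5)$precision))
})

test_that("multiclass reduction conserves counts one-vs-rest", {
  cm <- matrix(c(50, 3, 2,
                 4, 45, 1,
                 0, 2, 43), 3, 3, byrow = TRUE)
  res <- multiclass_metrics(cm)
  expect_equal(nrow(res$per_class), 3L)
  # per-class TP+FP+FN+TN always totals the grand count
  expect_equal(res$per_class$accuracy[1],
               (50 + sum(cm[-1, -1])) / sum(cm))
  expect_equal(res$macro$recall, mean(res$per_class$recall))
})

test_that("cross entropy has its closed forms and floors zero probabilities", {
  y <- diag(3)
  expect_equal(cross_entropy(y, y + 0), 0, tolerance = 1e-10)
  K <- 5
  yu <- matrix(0, 1, K); yu[1, 2] <- 1
  pu <- matrix(1 / K, 1, K)
  expect_equal(cross_entropy(yu, pu), log(K))
  # loop oracle
  set.seed(4)
  p <- matrix(runif(12), 3, 4); p <- p / rowSums(p)
  yl <- t(sapply(1:3, function(i) as.numeric(seq_len(4) == i)))
  acc <- 0
  for (i in 1:3) for (j in 1:4) acc <- acc - yl[i, j] * log(p[i, j])
  expect_equal(cross_entropy(yl, p), acc / 3)
  # zero probability at the true label stays finite
  pz <- matrix(c(0, 1, 0, 0), 1, 4)
  yz <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_true(is.finite(cross_entropy(yz, pz)))
  expect_error(cross_entropy(yz, matrix(0.3, 1, 4)), "sum to 1")
})

test_that("per-class report means match hand computation with an Average row", {
  mk <- function(cl, d, i) {
    clean <- make_lesion_texture(i, c(16, 16))
    list(clean = clean, restored = clip_image(clean + d), label = cl)
  }
  pairs <- list(mk("mel", 0.1, 1), mk("mel", 0.1, 2),
                mk("nv", 0.2, 3), mk("nv", 0.2, 4))
  rep <- evaluate_pairs(pairs, extractor = identity_extractor())
  expect_equal(rep$class, c("mel", "nv", "Average"))
  # per-class means match direct recomputation
  expect_equal(rep$psnr[1], mean(c(psnr(pairs[[1]]$clean, pairs[[1]]$restored),
                                   psnr(pairs[[2]]$clean, pairs[[2]]$restored))))
  # the Average row is the arithmetic mean of the class rows
  expect_equal(rep$psnr[3], mean(rep$psnr[1:2]), tolerance = 1e-6)
  expect_equal(rep$ssim[3], mean(rep$ssim[1:2]), tolerance = 1e-6)
  expect_equal(rep$lpips[3], mean(rep$lpips[1:2]), tolerance = 1e-6)
  # identical pair: infinite PSNR sentinel, SSIM 1, LPIPS 0
  idp <- list(list(clean = pairs[[1]]$clean, restored = pairs[[1]]$clean,
                   label = "df"))
  r1 <- evaluate_pairs(idp, extractor = identity_extractor())
  expect_identical(r1$psnr[1], Inf)
  expect_equal(r1$ssim[1], 1)
  expect_equal(r1$lpips[1], 0)
  expect_error(evaluate_pairs(list(list(clean = 1, restored = 1,
                                        label = "zz"))), "unknown")
  # CSV serialization round-trips the table
  tf <- tempfile(fileext = ".csv")
  evaluate_pairs(pairs, extractor = identity_extractor(), file = tf)
  expect_equal(utils::read.csv(tf)$class, c("mel", "nv", "Average"))
})
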