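# Procedural stand-ins for dermoscopic images and hair masks, plus the
# paired-directory dataset convention (Data_Skin_with_Hair /
# Data_Skin_without_Hair with seven diagnostic-class subdirectories).

#' The seven diagnostic lesion classes
#'
#' Class vocabulary used throughout the dataset layout: actinic keratoses
#' (akiec), basal cell carcinoma (bcc), benign keratosis (bkl),
#' dermatofibroma (df), melanoma (mel), melanocytic nevi (nv) and vascular
#' lesions (vasc).
#' @export
LESION_CLASSES <- c("akiec", "bcc", "bkl", "df", "mel", "nv", "vasc")

DIR_HAIRY <- "Data_Skin_with_Hair"
DIR_CLEAN <- "Data_Skin_without_Hair"

#' Generate a procedural lesion-like texture
#'
#' Deterministic surrogate for a dermoscopic photograph: a smooth
#' skin-toned background (coarse random field, bilinearly upsampled) with
#' one darker elliptical blob whose boundary falls off smoothly. Intended
#' for desk-scale tests; it reproduces only the gross structure of a real
#' lesion image (smoothness plus a dark blob), not its color statistics.
#'
#' @param seed integer seed; the output is a pure function of
#'   `(seed, size, channels)`.
#' @param size integer vector `c(H, W)`, both at least 16.
#' @param channels 1 (grayscale matrix) or 3 (RGB array).
#' @return image array with values in [0, 1].
#' @examples
#' img <- make_lesion_texture(1, c(32, 32))
#' range(img)
#' @export
make_lesion_texture <- function(seed, size, channels = 1L) {
  if (length(size) != 2L || any(size < 16))
    stop("size must be c(H, W) with H, W >= 16", call. = FALSE)
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3", call. = FALSE)
  H <- as.integer(size[1L]); W <- as.integer(size[2L])
  with_seed(seed, {
    base_tone <- runif(1, 0.55, 0.75)
    coarse <- matrix(runif(16, -1, 1), 4, 4)
    field <- bilinear_upsample(coarse, H, W)
    bg <- base_tone + 0.05 * field

    cy <- runif(1, 0.35, 0.65) * H
    cx <- runif(1, 0.35, 0.65) * W
    ay <- runif(1, 0.18, 0.32) * H
    ax <- runif(1, 0.18, 0.32) * W
    theta <- runif(1, 0, pi)
    contrast <- runif(1, 0.15, 0.35)
    soft <- 0.12  # boundary softness relative to the ellipse radius

    yy <- matrix(seq_len(H) - 0.5, H, W) - cy
    xx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
    u <- (cos(theta) * xx + sin(theta) * yy) / ax
    v <- (-sin(theta) * xx + cos(theta) * yy) / ay
    r <- sqrt(u^2 + v^2)
    blob <- 1 / (1 + exp((r - 1) / soft))  # ~1 inside the ellipse, ~0 outside
    gray <- clip_image(bg - contrast * blob, 0, 1)

    if (channels == 1L) gray
    else {
      out <- array(0, c(H, W, 3L))
      # reddish skin cast: attenuate green/blue slightly
      out[, , 1L] <- gray
      out[, , 2L] <- clip_image(gray * 0.85, 0, 1)
      out[, , 3L] <- clip_image(gray * 0.8, 0, 1)
      out
    }
  })
}

bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  ys <- seq(1, h, length.out = H)
  xs <- seq(1, w, length.out = W)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  fy <- ys - y0; fx <- xs - x0
  a <- m[cbind(rep(y0, W), rep(x0, each = H))]
  b <- m[cbind(rep(y0, W), rep(x0 + 1L, each = H))]
  c_ <- m[cbind(rep(y0 + 1L, W), rep(x0, each = H))]
  d <- m[cbind(rep(y0 + 1L, W), rep(x0 + 1L, each = H))]
  fy <- rep(fy, W); fx <- rep(fx, each = H)
  matrix(a * (1 - fy) * (1 - fx) + b * (1 - fy) * fx +
           c_ * fy * (1 - fx) + d * fy * fx, H, W)
}

#' Generate a procedural binary hair mask
#'
#' Draws `n_strands` thin curved strands on a blank canvas: each strand
#' is confined to its own vertical band, starts near the top, and walks
#' strictly downward with its heading perturbed by a random walk scaled
#' by `curvature` (clamped to stay downward). Because unit steps keep
#' consecutive pixels 8-adjacent, each strand is one connected component,
#' and bands are separated, so the mask has exactly `n_strands`
#' components whenever the band width `W / n_strands` is at least about
#' 4 pixels. Entries are exactly 0 (background) and 1 (hair), the mask
#' convention of the overlay arithmetic.
#'
#' @param seed integer seed.
#' @param size integer vector `c(H, W)`.
#' @param n_strands number of strands (>= 0).
#' @param curvature standard deviation of the per-step heading change in
#'   radians; 0 gives straight strands.
#' @return H x W matrix with entries in {0, 1}.
#' @export
make_procedural_hair_mask <- function(seed, size, n_strands = 8L,
                                      curvature = 0.08) {
  if (length(size) != 2L || any(size < 1))
    stop("size must be c(H, W) with positive entries", call. = FALSE)
  if (n_strands < 0) stop("n_strands must be >= 0", call. = FALSE)
  H <- as.integer(size[1L]); W <- as.integer(size[2L])
  mask <- matrix(0, H, W)
  if (n_strands == 0L) return(mask)
  with_seed(seed, {
    for (i in seq_len(n_strands)) {
      # band [lo, hi): one vertical band per strand, with a >= 1.5 px
      # margin on each side so 8-connectivity cannot join neighbours
      band_w <- W / n_strands
      lo <- (i - 1) * band_w + min(1.5, band_w / 2 - 0.1)
      hi <- i * band_w - min(1.5, band_w / 2 - 0.1)
      x <- stats::runif(1, lo, max(lo, hi))
      y <- stats::runif(1, 0, max(0.15 * H - 1, 0.5))
      ang <- pi / 2 + stats::runif(1, -0.35, 0.35)
      len <- round(stats::runif(1, 0.5, 0.85) * min(H, W))
      for (s in seq_len(len)) {
        r <- floor(y); c_ <- floor(x)
        if (r >= 0 && r < H && c_ >= 0 && c_ < W) mask[r + 1L, c_ + 1L] <- 1
        ang <- ang + stats::rnorm(1, 0, curvature)
        # keep the heading strictly downward: y increases every step, so
        # a strand never re-enters the canvas after leaving it
        ang <- min(max(ang, pi / 2 - 0.6), pi / 2 + 0.6)
        x <- min(max(x + cos(ang), lo), max(lo, hi))
        y <- y + sin(ang)
      }
    }
  })
  mask
}

#' Construct a paired sample
#'
#' Bundles a hairy/clean image pair with its diagnostic class label and a
#' unique id; this is the training unit of the dehairing model.
#'
#' @param hairy,clean image arrays of identical dimensions, values in [0,1].
#' @param label one of [LESION_CLASSES].
#' @param id unique sample identifier.
#' @return a `paired_sample` list.
#' @export
paired_sample <- function(hairy, clean, label, id) {
  if (!identical(dim(hairy), dim(clean)))
    stop("hairy and clean images must share dimensions", call. = FALSE)
  if (!label %in% LESION_CLASSES)
    stop("unknown class label '", label, "'", call. = FALSE)
  structure(list(hairy = hairy, clean = clean, label = label, id = as.character(id)),
            class = "paired_sample")
}

#' Write paired samples into the two-root directory layout
#'
#' Materializes pairs as 8-bit PNGs under
#' `<root>/Data_Skin_with_Hair/<class>/<id>.png` and
#' `<root>/Data_Skin_without_Hair/<class>/<id>.png`, creating all fourteen
#' class subdirectories, and returns a manifest describing the layout.
#'
#' @param pairs list of [paired_sample()] objects with unique ids.
#' @param root dataset root directory (created if absent).
#' @return a `dataset_manifest` with empty split assignment.
#' @export
build_dermahair_layout <- function(pairs, root) {
  ids <- vapply(pairs, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids in pairs", call. = FALSE)
  for (cls in LESION_CLASSES) {
    dir.create(file.path(root, DIR_HAIRY, cls), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(root, DIR_CLEAN, cls), recursive = TRUE, showWarnings = FALSE)
  }
  classes <- stats::setNames(vector("list", length(LESION_CLASSES)), LESION_CLASSES)
  for (p in pairs) {
    if (!inherits(p, "paired_sample")) stop("pairs must be paired_sample objects", call. = FALSE)
    fn <- paste0(p$id, ".png")
    write_image(p$hairy, file.path(root, DIR_HAIRY, p$label, fn))
    write_image(p$clean, file.path(root, DIR_CLEAN, p$label, fn))
    classes[[p$label]] <- c(classes[[p$label]], p$id)
  }
  new_manifest(root = root, classes = classes)
}

new_manifest <- function(root, classes, train_ids = character(),
                         test_ids = character(), seed = NA_integer_) {
  structure(list(root = root, classes = classes,
                 train_ids = train_ids, test_ids = test_ids, seed = seed),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  n <- vapply(x$classes, length, integer(1))
  cat("dataset manifest at", x$root, "\n")
  cat("  per class:", paste(names(n), n, sep = "=", collapse = " "), "\n")
  cat("  split:", length(x$train_ids), "train /", length(x$test_ids), "test\n")
  invisible(x)
}

#' Reserve a per-class test split
#'
#' Draws exactly `n_test` ids from every class into the test set (the
#' benchmark convention is 100 per class, 700 test images over the seven
#' classes); all remaining ids form the training set. Deterministic for a
#' fixed seed.
#'
#' @param manifest a `dataset_manifest`.
#' @param n_test test images per class.
#' @param seed integer seed.
#' @return manifest with `train_ids` / `test_ids` filled in.
#' @export
split_per_class <- function(manifest, n_test = 100L, seed = 1L) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  train <- character(); test <- character()
  with_seed(seed, {
    for (cls in names(manifest$classes)) {
      ids <- manifest$classes[[cls]]
      if (length(ids) < n_test)
        stop("class '", cls, "' has ", length(ids),
             " samples, fewer than n_test = ", n_test, call. = FALSE)
      pick <- if (n_test > 0) sample(ids, n_test) else character()
      test <- c(test, pick)
      train <- c(train, setdiff(ids, pick))
    }
  })
  manifest$train_ids <- train
  manifest$test_ids <- test
  manifest$seed <- as.integer(seed)
  manifest
}

#' Serialize / restore a dataset manifest as JSON
#' @param manifest a `dataset_manifest`.
#' @param path JSON file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest.
#' @export
write_manifest <- function(manifest, path) {
  x <- unclass(manifest)
  if (is.na(x$seed)) x$seed <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- lapply(x$classes, as.character)
  new_manifest(root = x$root, classes = classes,
               train_ids = as.character(unlist(x$train_ids)),
               test_ids = as.character(unlist(x$test_ids)),
               seed = if (is.null(x$seed) || is.na(x$seed)) NA_integer_
                      else as.integer(x$seed))
}

#' Load one paired sample from a materialized layout
#' @param manifest a `dataset_manifest`.
#' @param id sample id present in the manifest.
#' @return a [paired_sample()].
#' @export
load_pair <- function(manifest, id) {
  cls <- NULL
  for (k in names(manifest$classes))
    if (id %in% manifest$classes[[k]]) { cls <- k; break }
  if (is.null(cls)) stop("id '", id, "' not in manifest", call. = FALSE)
  fn <- paste0(id, ".png")
  paired_sample(hairy = read_image(file.path(manifest$root, DIR_HAIRY, cls, fn)),
                clean = read_image(file.path(manifest$root, DIR_CLEAN, cls, fn)),
                label = cls, id = id)
}
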