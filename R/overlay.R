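# Two synthetic hair-degradation generators:
#  (1) mask-overlay arithmetic: invert a binary hair mask, add it to the
#      image, subtract one — the closed form is simply img - mask, with
#      an unbounded intermediate that is exposed for inspection;
#  (2) self-supervised line synthesis: draw many short 45-degree diagonal
#      segments with random start, length and direction, imitating hair
#      without any annotated mask.

check_binary_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stop(what, " must be an H x W matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop(what, " must be strictly binary (entries 0 or 1)", call. = FALSE)
  invisible(mask)
}

#' Invert a binary hair mask
#'
#' Flips 1 (hair) and 0 (background): `-1 * (mask - 1)`. The inverted mask
#' is the quantity added to the image in the overlay arithmetic, so that
#' the later subtraction of one darkens exactly the hair pixels.
#'
#' @param mask H x W matrix with entries in {0, 1}.
#' @return matrix of the same shape with entries flipped.
#' @examples
#' normalize_hair_mask(matrix(c(1, 0, 0, 1), 2, 2))
#' @export
normalize_hair_mask <- function(mask) {
  check_binary_mask(mask)
  -1 * (mask - 1)
}

#' Add the inverted mask to an image (unbounded intermediate)
#' @param img H x W numeric matrix.
#' @param normalized_mask inverted hair mask of the same shape.
#' @return elementwise sum; values may exceed [0, 1].
#' @export
merge_images <- function(img, normalized_mask) {
  if (!identical(dim(img), dim(normalized_mask)))
    stop("img and normalized_mask must share dimensions", call. = FALSE)
  img + normalized_mask
}

#' Subtract one from a merged image (unbounded result)
#' @param merged output of [merge_images()].
#' @return `merged - 1`, unclipped; hair pixels end up at `img - 1`.
#' @export
postprocess_merged <- function(merged) merged - 1

#' Superimpose a binary hair mask on an image
#'
#' Composes the three overlay steps (invert mask, add, subtract one).
#' Algebraically the unclipped result is exactly `img - mask`, broadcast
#' over channels for RGB input: background pixels are bit-identical to the
#' input and hair pixels are shifted down by one (negative for in-range
#' input). The rendered variant clips to [0, 1], turning hair pixels black.
#'
#' @param img image array in [0, 1] (matrix or H x W x C).
#' @param mask H x W binary hair mask.
#' @param clip if `TRUE` (default) include the [0,1]-clipped rendering in
#'   the result.
#' @return an `overlay_result` list with elements `normalized_mask`,
#'   `merged`, `final_unclipped` (both unbounded) and `final_clipped`.
#' @examples
#' img <- matrix(c(0.3, 0.5, 0.6, 0.8), 2, 2)   # column-major
#' m <- matrix(c(1, 0, 0, 1), 2, 2)
#' add_mask_hair(img, m)$final_unclipped
#' @export
add_mask_hair <- function(img, mask, clip = TRUE) {
  check_raster(img, range = c(0, 1), what = "img")
  check_binary_mask(mask)
  d <- dim(img)
  if (!identical(d[1:2], dim(mask)))
    stop("img and mask must share height and width", call. = FALSE)
  nm <- normalize_hair_mask(mask)
  merged <- per_channel(img, function(ch) merge_images(ch, nm))
  final <- per_channel(merged, postprocess_merged)
  structure(list(normalized_mask = nm,
                 merged = merged,
                 final_unclipped = final,
                 final_clipped = if (clip) clip_image(final, 0, 1) else NULL),
            class = "overlay_result")
}

#' Sample one random diagonal line specification
#'
#' Draws, in this fixed order, an integer x start uniform on [0, W], an
#' integer y start uniform on [0, H], an integer length uniform on
#' `length_range`, and a direction d uniform on {-1, +1}; the endpoints are
#' `x_end = x_start + d * length`, `y_end = y_start + length`, so every
#' line is a 45-degree diagonal running downward. Endpoints may fall
#' outside the canvas; rasterization clips them. Uses the current RNG
#' state (seed at the caller, e.g. in [synth_line_hair()]).
#'
#' @param W,H canvas width and height in pixels.
#' @param length_range integer interval `c(lo, hi)` for the line length;
#'   default `c(10, 30)`.
#' @return a `line_spec` list with fields `x_start`, `y_start`, `length`,
#'   `d`, `x_end`, `y_end` (0-based pixel coordinates).
#' @export
sample_line <- function(W, H, length_range = c(10L, 30L)) {
  if (W < 1 || H < 1) stop("W and H must be >= 1", call. = FALSE)
  lo <- as.integer(length_range[1L]); hi <- as.integer(length_range[2L])
  if (lo > hi) stop("length_range must satisfy lo <= hi", call. = FALSE)
  x_start <- sample(0:W, 1L)
  y_start <- sample(0:H, 1L)
  len <- if (lo == hi) lo else sample(lo:hi, 1L)
  d <- sample(c(-1L, 1L), 1L)
  structure(list(x_start = x_start, y_start = y_start, length = len, d = d,
                 x_end = x_start + d * len, y_end = y_start + len),
            class = "line_spec")
}

#' Rasterize a line segment onto an image
#'
#' Walks the Bresenham path from `(x_start, y_start)` to `(x_end, y_end)`
#' and sets every on-canvas pixel to `color`; out-of-canvas portions are
#' clipped, all other pixels are untouched. Coordinates are 0-based with x
#' as column and y as row.
#'
#' @param img image array.
#' @param line a `line_spec` from [sample_line()] (or a list with the same
#'   fields).
#' @param color pixel value written on the path (default 0, black).
#' @param width stroke width in pixels (default 1).
#' @return the image with the segment drawn.
#' @export
rasterize_line <- function(img, line, color = 0, width = 1L) {
  d <- dim(img); H <- d[1L]; W <- d[2L]
  pts <- bresenham(line$x_start, line$y_start, line$x_end, line$y_end)
  half <- (width - 1L) %/% 2L
  for (i in seq_len(nrow(pts))) {
    for (ox in -half:(width - 1L - half)) {
      x <- pts[i, 1L] + ox; y <- pts[i, 2L]
      if (x >= 0 && x < W && y >= 0 && y < H) {
        if (length(d) == 2L) img[y + 1L, x + 1L] <- color
        else img[y + 1L, x + 1L, ] <- color
      }
    }
  }
  img
}

# Integer Bresenham walk; returns a matrix of (x, y) pairs inclusive of
# both endpoints.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- max(dx, dy) + 1L
  out <- matrix(0L, n, 2L)
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    if (x == x1 && y == y1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  out
}

#' Draw random hair-like line segments on an image
#'
#' The self-supervised degradation generator: samples `n_lines` diagonal
#' segments with [sample_line()] and rasterizes each onto a copy of the
#' input. Deterministic for a fixed seed; the input is not mutated and
#' pixels not covered by any segment are bit-identical to the input.
#'
#' @param img image array in [0, 1].
#' @param n_lines number of segments (default 1000, sized for 256-px
#'   canvases; scale down for small fixtures).
#' @param seed integer seed.
#' @param length_range integer length interval, default `c(10, 30)`.
#' @param color stroke value, default 0 (dark hair).
#' @param width stroke width in pixels.
#' @param return_lines also return the sampled `line_spec`s.
#' @return the degraded image, or if `return_lines` a list
#'   `(image, lines)`.
#' @export
synth_line_hair <- function(img, n_lines = 1000L, seed = 1L,
                            length_range = c(10L, 30L), color = 0,
                            width = 1L, return_lines = FALSE) {
  check_raster(img, range = c(0, 1), what = "img")
  d <- dim(img); H <- d[1L]; W <- d[2L]
  out <- img
  lines <- vector("list", n_lines)
  with_seed(seed, {
    for (i in seq_len(n_lines)) {
      ln <- sample_line(W = W, H = H, length_range = length_range)
      lines[[i]] <- ln
      out <- rasterize_line(out, ln, color = color, width = width)
    }
  })
  if (return_lines) list(image = out, lines = lines) else out
}
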