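#' @keywords internal
"_PACKAGE"

# Images are plain numeric arrays, H x W (grayscale) or H x W x C with
# C in {1, 3}. Coordinates are 0-based (row, column), origin top-left.
# The external value range is [0, 1]; the diffusion core works in [-1, 1].

#' Validate a raster image array
#'
#' Checks that `img` is a finite numeric array of dimension H x W or
#' H x W x C with C in {1, 3}, and optionally that its values lie in a
#' declared range. Intermediate images produced by the overlay arithmetic
#' may carry an unbounded range; pass `range = NULL` for those.
#'
#' @param img numeric matrix or 3-d array.
#' @param range length-2 numeric interval the values must lie in, or `NULL`
#'   to skip the range check.
#' @param what name used in error messages.
#' @return `img`, invisibly, after validation.
#' @export
check_raster <- function(img, range = c(0, 1), what = "img") {
  if (!is.numeric(img)) stop(what, " must be numeric", call. = FALSE)
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop(what, " must be an H x W or H x W x C array", call. = FALSE)
  if (length(d) == 3L && !(d[3L] %in% c(1L, 3L)))
    stop(what, " must have 1 or 3 channels, got ", d[3L], call. = FALSE)
  if (d[1L] < 1L || d[2L] < 1L)
    stop(what, " must have positive height and width", call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (!is.null(range)) {
    if (min(img) < range[1L] || max(img) > range[2L])
      stop(what, " has values outside [", range[1L], ", ", range[2L], "]",
           call. = FALSE)
  }
  invisible(img)
}

#' Number of channels of an image array
#' @param img image array.
#' @return 1 for a matrix, otherwise the third dimension.
#' @export
n_channels <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) 1L else d[3L]
}

# Apply f(matrix) to each channel, preserving shape.
per_channel <- function(img, f) {
  d <- dim(img)
  if (length(d) == 2L) return(f(img))
  out <- img
  for (k in seq_len(d[3L])) out[, , k] <- f(img[, , k])
  out
}

#' Map an image between the external [0,1] and internal [-1,1] ranges
#'
#' The diffusion core operates on the symmetric range [-1, 1] so that
#' standard-normal noise has a comparable scale to the signal; images
#' enter through `to_internal()` and leave through `to_external()`.
#'
#' @param img image array.
#' @return rescaled array of the same shape.
#' @export
to_internal <- function(img) 2 * img - 1

#' @rdname to_internal
#' @export
to_external <- function(img) (img + 1) / 2

#' Clip an image to a range
#' @param img image array.
#' @param lo,hi clipping bounds.
#' @return array with values clamped to `[lo, hi]`.
#' @export
clip_image <- function(img, lo = 0, hi = 1) pmin(pmax(img, lo), hi)

#' Read a PNG image as a [0,1] raster array
#'
#' Decodes an 8- or 16-bit PNG to a numeric array scaled to [0, 1]. An
#' alpha channel, if present, is dropped. Grayscale files yield an
#' H x W matrix; color files an H x W x 3 array.
#'
#' @param path path to a PNG file.
#' @return numeric image array in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'",
                               call. = FALSE)
  img <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop("cannot decode PNG '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3L] == 2L) img <- img[, , 1L]              # gray + alpha
    else if (d[3L] == 4L) img <- img[, , 1:3]        # rgb + alpha
    else if (d[3L] == 1L) img <- img[, , 1L]
  }
  img
}

#' Write a [0,1] raster image as an 8-bit PNG
#'
#' Quantizes with round-half-up to integers 0..255 so that a write/read
#' round trip is exact at 8-bit resolution. Out-of-range input is a
#' contract violation: callers clip explicitly first (see [clip_image()]),
#' there is no silent clipping here.
#'
#' @param img image array with values in [0, 1].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_raster(img, range = c(0, 1), what = "img")
  q <- floor(img * 255 + 0.5) / 255  # round-half-up at 8 bits
  png::writePNG(q, target = path)
  invisible(path)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
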