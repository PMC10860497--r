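#' 8-bit RGB raster images
#'
#' `morphstim` represents every frame and composite image as a plain integer
#' array of dimension `height x width x 3` (row-major, origin at the top-left,
#' channel order R, G, B), with values in `[0, 255]`. These helpers construct
#' and validate such arrays and move them to and from PNG/JPEG files.
#'
#' @param width,height Canvas size in pixels.
#' @param fill Length-3 integer RGB triple used to fill the canvas.
#' @returns An integer array of dim `c(height, width, 3)`.
#' @examples
#' img <- new_image_rgb(4, 3, fill = c(200, 150, 20))
#' dim(img)
#' @export
new_image_rgb <- function(width, height, fill = c(0L, 0L, 0L)) {
  fill <- check_rgb8(fill)
  arr <- array(0L, dim = c(height, width, 3L))
  arr[, , 1L] <- fill[1L]
  arr[, , 2L] <- fill[2L]
  arr[, , 3L] <- fill[3L]
  arr
}

# validate an RGB triple, return as integer
check_rgb8 <- function(x, what = "color") {
  if (length(x) != 3L || anyNA(x) || any(x < 0) || any(x > 255)) {
    stop(sprintf("%s must be three channel values in [0, 255]", what),
         call. = FALSE)
  }
  as.integer(round(x))
}

assert_image_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop(sprintf("%s must be a height x width x 3 array", what), call. = FALSE)
  }
  invisible(img)
}

assert_same_dims <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("image dimension mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(NULL)
}

#' Read and write raster images
#'
#' PNG is handled natively (bit-exact round trips); JPEG is read and written
#' through EBImage when available. Reading a JPEG emits a warning because
#' lossy compression relaxes the pixel-exact guarantees the validator relies
#' on.
#'
#' @param path File path; the extension selects the format.
#' @param img Integer `height x width x 3` RGB array.
#' @param quality JPEG quality (ignored for PNG).
#' @returns `read_image_rgb()` returns an integer RGB array;
#'   `write_image_rgb()` returns `path` invisibly.
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
    if (dim(px)[3L] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
    if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]
    return(array(as.integer(round(px * 255)), dim = dim(px)))
  }
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    warning("JPEG input: pixel values are lossy; bit-exact checks are relaxed",
            call. = FALSE)
    im <- EBImage::readImage(path)
    px <- EBImage::imageData(im)      # width x height (x channels)
    if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
    if (dim(px)[3L] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
    px <- aperm(px[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
    return(array(as.integer(round(px * 255)), dim = dim(px)))
  }
  stop(sprintf("unsupported raster extension '.%s'", ext), call. = FALSE)
}

#' @rdname read_image_rgb
#' @export
write_image_rgb <- function(img, path, quality = 95) {
  assert_image_rgb(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("writing JPEG requires the EBImage package", call. = FALSE)
    }
    px <- aperm(img, c(2L, 1L, 3L)) / 255
    EBImage::writeImage(EBImage::Image(px, colormode = "Color"), path,
                        quality = quality)
  } else {
    stop(sprintf("unsupported raster extension '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

# half-up rounding on non-negative values (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
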