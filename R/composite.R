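#' Parse and format composite-image filenames
#'
#' Composite sets follow the naming convention
#' `Img<id>_<Color>[_<quickState>...].<ext>`: the stem splits on
#' underscores into an `Img`-prefixed integer id, a color label, and one
#' state token per quick-change feature, in feature order. A video with one
#' slow change and `k` quick changes therefore needs `2^(k+1)` files.
#'
#' @param filename A file name (directories are ignored). Recognized raster
#'   extensions: png, jpg, jpeg.
#' @returns `parse_composite_name()` returns a list with `image_id`
#'   (integer), `color_label` (string) and `quick_states` (character vector,
#'   possibly empty). `format_composite_name()` returns a file name string.
#' @examples
#' parse_composite_name("Img3_Orange_Left.jpg")
#' format_composite_name(1, "Yellow", character(), "png")
#' @export
parse_composite_name <- function(filename) {
  filename <- basename(filename)
  ext <- tolower(tools::file_ext(filename))
  if (!ext %in% c("png", "jpg", "jpeg")) {
    stop(sprintf("'%s': unrecognized raster extension '%s'", filename, ext),
         call. = FALSE)
  }
  stem <- tools::file_path_sans_ext(filename)
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  if (length(tokens) < 2L) {
    stop(sprintf("'%s': expected at least 'Img<digits>_<Color>', got %d token(s)",
                 filename, length(tokens)), call. = FALSE)
  }
  if (any(!nzchar(tokens))) {
    stop(sprintf("'%s': empty token at position %d", filename,
                 which(!nzchar(tokens))[1L]), call. = FALSE)
  }
  if (!grepl("^Img[0-9]+$", tokens[1L])) {
    stop(sprintf("'%s': first token '%s' must match 'Img<digits>'",
                 filename, tokens[1L]), call. = FALSE)
  }
  list(image_id = as.integer(sub("^Img", "", tokens[1L])),
       color_label = tokens[2L],
       quick_states = if (length(tokens) > 2L) tokens[-(1:2)] else character(0))
}

#' @rdname parse_composite_name
#' @param image_id Integer scene id.
#' @param color_label Color label token.
#' @param quick_states Character vector of state tokens (feature order).
#' @param ext File extension without the dot.
#' @export
format_composite_name <- function(image_id, color_label, quick_states = character(),
                                  ext = "png") {
  paste0(paste(c(sprintf("Img%d", as.integer(image_id)), color_label,
                 quick_states), collapse = "_"), ".", ext)
}

# stem used as the key into a composite set's image map
composite_stem <- function(color_label, quick_states) {
  paste(c(color_label, quick_states), collapse = "_")
}

#' Load a complete composite image set from a directory
#'
#' Scans `dir` for composite files of one scene, checks that exactly two
#' color labels are staged, that the combination grid is complete
#' (`2^(k+1)` images for `k` features), that per-position state domains are
#' consistent, and that all images share one canvas size, then reads every
#' image into memory.
#'
#' @param dir Directory holding one generation run (flat layout).
#' @param image_id Integer scene id to load.
#' @param start_color Optional color label to treat as the morph's start
#'   color; the other label becomes the end color. Defaults to the
#'   alphabetically first label. (The direction of the slow fade is a run
#'   configuration, not a property of the files.)
#' @returns A `composite_set` list: `image_id`, `width`, `height`,
#'   `color_labels` (start, end), `feature_state_domains` (list of label
#'   pairs, one per feature position), and `images` (named by file stem).
#' @export
load_composite_set <- function(dir, image_id, start_color = NULL) {
  files <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  keys <- lapply(files, function(f) tryCatch(parse_composite_name(f),
                                             error = function(e) NULL))
  keep <- !vapply(keys, is.null, logical(1))
  files <- files[keep]; keys <- keys[keep]
  keep <- vapply(keys, function(k) k$image_id == as.integer(image_id), logical(1))
  files <- files[keep]; keys <- keys[keep]
  if (length(files) == 0L) {
    stop(sprintf("no composite files for Img%d in '%s'", image_id, dir),
         call. = FALSE)
  }
  colors <- unique(vapply(keys, `[[`, "", "color_label"))
  if (length(colors) != 2L) {
    stop(sprintf(
      "found %d color label(s) (%s) for Img%d; stage exactly one pair of colors per input folder",
      length(colors), paste(colors, collapse = ", "), image_id), call. = FALSE)
  }
  k_states <- vapply(keys, function(k) length(k$quick_states), integer(1))
  if (length(unique(k_states)) != 1L) {
    stop("inconsistent number of quick-state tokens across filenames", call. = FALSE)
  }
  k <- k_states[1L]
  domains <- vector("list", k)
  if (k > 0L) {
    for (pos in seq_len(k)) {
      labs <- sort(unique(vapply(keys, function(x) x$quick_states[pos], "")))
      if (length(labs) != 2L) {
        stop(sprintf("state token position %d has %d label(s) (%s); expected exactly 2",
                     pos, length(labs), paste(labs, collapse = ", ")), call. = FALSE)
      }
      domains[[pos]] <- labs
    }
  }
  # completeness: every color x state combination must be present exactly once
  grid <- expand.grid(c(list(color = colors), domains),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  want <- vapply(seq_len(nrow(grid)), function(r)
    composite_stem(grid[r, 1L], if (k > 0L) as.character(grid[r, -1L]) else character(0)),
    "")
  have <- vapply(keys, function(x) composite_stem(x$color_label, x$quick_states), "")
  if (anyDuplicated(have)) {
    stop(sprintf("duplicate composite keys: %s",
                 paste(unique(have[duplicated(have)]), collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(want, have)
  if (length(missing) > 0L) {
    stop(sprintf("incomplete composite set for Img%d: missing %s",
                 image_id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  images <- stats::setNames(
    lapply(file.path(dir, files), read_image_rgb), have)
  dims <- vapply(images, function(im) dim(im)[1:2], integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    stop("composite images have mixed dimensions", call. = FALSE)
  }
  if (is.null(start_color)) start_color <- sort(colors)[1L]
  if (!start_color %in% colors) {
    stop(sprintf("start_color '%s' not among staged labels (%s)",
                 start_color, paste(colors, collapse = ", ")), call. = FALSE)
  }
  structure(list(image_id = as.integer(image_id),
                 width = dims[2, 1L], height = dims[1, 1L],
                 color_labels = c(start_color, setdiff(colors, start_color)),
                 feature_state_domains = domains,
                 images = images),
            class = "composite_set")
}

#' @export
print.composite_set <- function(x, ...) {
  k <- length(x$feature_state_domains)
  cat(sprintf("<composite_set> Img%d: %dx%d px, colors %s -> %s, %d feature(s), %d images\n",
              x$image_id, x$width, x$height,
              x$color_labels[1L], x$color_labels[2L], k, length(x$images)))
  invisible(x)
}

# fetch an image from the set by (color label, state vector)
set_image <- function(set, color_label, quick_states) {
  key <- composite_stem(color_label, quick_states)
  img <- set$images[[key]]
  if (is.null(img)) stop(sprintf("composite set has no image '%s'", key),
                         call. = FALSE)
  img
}
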