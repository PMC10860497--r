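#' Describe a quick-change feature of a synthetic scene
#'
#' A quick-change feature is a small scene element that can be toggled
#' between exactly two states (e.g. an arrow tilted left vs. right, an
#' object present vs. absent, a bar horizontal vs. vertical). In the
#' finished stimulus each feature flips once, quickly, at a random moment
#' during the slow color morph.
#'
#' @param name Feature label (used in filenames; no underscores).
#' @param bbox Pixel bounding box `c(x0, y0, x1, y1)`, 1-based inclusive.
#' @param states Character vector of exactly two state labels. Labels must
#'   be non-empty and contain no underscore (they become filename tokens).
#' @param glyph Which built-in glyph renders the feature: `"arrow"` maps
#'   state 1/2 to left/right orientation, `"bar"` to horizontal/vertical,
#'   `"dots"` to present/absent.
#' @param color RGB triple the glyph is drawn in.
#' @returns A `quick_feature` list.
#' @export
quick_feature <- function(name, bbox, states = c("Left", "Right"),
                          glyph = c("arrow", "bar", "dots"),
                          color = c(40L, 40L, 40L)) {
  glyph <- match.arg(glyph)
  check_state_labels(states)
  bbox <- check_bbox(bbox)
  structure(list(name = as.character(name), bbox = bbox,
                 states = as.character(states), glyph = glyph,
                 color = check_rgb8(color, "feature color")),
            class = "quick_feature")
}

check_state_labels <- function(states) {
  if (length(states) != 2L || anyDuplicated(states) ||
      any(!nzchar(states)) || any(grepl("_", states, fixed = TRUE))) {
    stop("feature states must be two distinct, non-empty, underscore-free labels",
         call. = FALSE)
  }
  invisible(states)
}

check_bbox <- function(bbox) {
  bbox <- as.integer(bbox)
  if (length(bbox) != 4L || bbox[3L] < bbox[1L] || bbox[4L] < bbox[2L]) {
    stop("bbox must be c(x0, y0, x1, y1) with positive area", call. = FALSE)
  }
  bbox
}

#' Parametric description of a synthetic change-blindness scene
#'
#' A scene has a uniform background, one large central "slow-change" region
#' whose fill color is swapped between generation runs (this is the element
#' that slowly fades in the final video), and zero or more small
#' quick-change features. An optional deterministic luminance texture is
#' applied inside the slow region so that, as in hand-drawn cartoon scenes,
#' its pixels do not all share one value while the region mean stays within
#' +/-1 of the nominal color.
#'
#' @param width,height Canvas size in pixels (default 480 x 480).
#' @param background_color RGB triple for everything outside the slow
#'   region and the feature glyphs.
#' @param slow_region Shape descriptor: a list with `shape` (`"ellipse"` or
#'   `"round_rect"`), `bbox` (pixel rectangle, strictly inside the canvas)
#'   and, for rounded rectangles, `corner_radius` in pixels.
#' @param texture_amplitude Integer 0-32; peak luminance modulation applied
#'   inside the slow region. The texture is a pure function of
#'   `(render_seed, pixel coordinates)`.
#' @param features List of [quick_feature()] objects with pairwise disjoint
#'   bounding boxes (they may overlap the slow region).
#' @param render_seed Integer seed for the texture hash.
#' @returns A `scene_spec` list.
#' @seealso [render_scene()], [emit_composite_set()], [demo_scene_spec()]
#' @export
scene_spec <- function(width = 480, height = 480,
                       background_color = c(235L, 235L, 230L),
                       slow_region = list(shape = "ellipse",
                                          bbox = c(90L, 90L, 390L, 390L)),
                       texture_amplitude = 0L,
                       features = list(),
                       render_seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width > 0, height > 0)
  slow_region$bbox <- check_bbox(slow_region$bbox)
  if (!slow_region$shape %in% c("ellipse", "round_rect")) {
    stop("slow_region$shape must be 'ellipse' or 'round_rect'", call. = FALSE)
  }
  bb <- slow_region$bbox
  if (bb[1L] <= 1L || bb[2L] <= 1L || bb[3L] >= width || bb[4L] >= height) {
    stop("slow_region bbox must lie strictly inside the canvas", call. = FALSE)
  }
  texture_amplitude <- as.integer(texture_amplitude)
  if (texture_amplitude < 0L || texture_amplitude > 32L) {
    stop("texture_amplitude must be in 0..32", call. = FALSE)
  }
  features <- lapply(features, function(f) {
    if (!inherits(f, "quick_feature")) stop("features must be quick_feature objects",
                                            call. = FALSE)
    if (any(f$bbox[c(1L, 2L)] < 1L) || f$bbox[3L] > width || f$bbox[4L] > height) {
      stop(sprintf("feature '%s' bbox lies outside the canvas", f$name),
           call. = FALSE)
    }
    f
  })
  if (length(features) > 1L) {
    for (i in seq_len(length(features) - 1L)) {
      for (j in (i + 1L):length(features)) {
        if (boxes_overlap(features[[i]]$bbox, features[[j]]$bbox)) {
          stop(sprintf("feature bboxes '%s' and '%s' overlap",
                       features[[i]]$name, features[[j]]$name), call. = FALSE)
        }
      }
    }
  }
  structure(list(width = width, height = height,
                 background_color = check_rgb8(background_color, "background"),
                 slow_region = slow_region,
                 texture_amplitude = texture_amplitude,
                 features = features,
                 render_seed = as.integer(render_seed)),
            class = "scene_spec")
}

boxes_overlap <- function(a, b) {
  a[1L] <= b[3L] && b[1L] <= a[3L] && a[2L] <= b[4L] && b[2L] <= a[4L]
}

# logical height x width mask of the slow-change region
slow_region_mask <- function(spec) {
  bb <- spec$slow_region$bbox
  w <- spec$width; h <- spec$height
  x <- matrix(rep(seq_len(w), each = h), nrow = h)
  y <- matrix(rep(seq_len(h), times = w), nrow = h)
  if (spec$slow_region$shape == "ellipse") {
    cx <- (bb[1L] + bb[3L]) / 2; cy <- (bb[2L] + bb[4L]) / 2
    rx <- (bb[3L] - bb[1L]) / 2; ry <- (bb[4L] - bb[2L]) / 2
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  } else {
    r <- spec$slow_region$corner_radius %||% 0
    inside <- x >= bb[1L] & x <= bb[3L] & y >= bb[2L] & y <= bb[4L]
    if (r > 0) {
      xc <- pmin(pmax(x, bb[1L] + r), bb[3L] - r)
      yc <- pmin(pmax(y, bb[2L] + r), bb[4L] - r)
      inside & ((x - xc)^2 + (y - yc)^2 <= r^2)
    } else inside
  }
}

# deterministic per-pixel hash in [0, 1): pure function of (seed, x, y)
texture_hash <- function(x, y, seed) {
  v <- sin(x * 12.9898 + y * 78.233 + seed * 0.54531) * 43758.5453
  v - floor(v)
}

#' Render one composite version of a synthetic scene
#'
#' Produces the scene with the slow-change region filled in `color` and each
#' quick-change feature drawn in the requested state. Rendering is fully
#' deterministic: two calls with identical arguments give bit-identical
#' images, and all pixels outside the slow region and the feature boxes
#' depend on neither `color` nor `quick_states`.
#'
#' @param spec A [scene_spec()].
#' @param color RGB triple for the slow-change region. With
#'   `texture_amplitude = 0` every region pixel equals `color` exactly; with
#'   texture, a zero-mean luminance offset is added per pixel (keep channels
#'   within `[amplitude, 255 - amplitude]` so clipping cannot bias the mean).
#' @param quick_states Character vector of state labels, one per feature, in
#'   feature order.
#' @returns An integer `height x width x 3` RGB array.
#' @export
render_scene <- function(spec, color, quick_states = character()) {
  stopifnot(inherits(spec, "scene_spec"))
  color <- check_rgb8(color)
  if (length(quick_states) != length(spec$features)) {
    stop(sprintf("expected %d quick states, got %d",
                 length(spec$features), length(quick_states)), call. = FALSE)
  }
  img <- new_image_rgb(spec$width, spec$height, fill = spec$background_color)
  mask <- slow_region_mask(spec)
  n_in <- sum(mask)
  if (n_in > 0L) {
    off <- 0
    if (spec$texture_amplitude > 0L) {
      w <- spec$width; h <- spec$height
      x <- matrix(rep(seq_len(w), each = h), nrow = h)
      y <- matrix(rep(seq_len(h), times = w), nrow = h)
      hh <- texture_hash(x[mask], y[mask], spec$render_seed)
      off <- round_half_up(abs((hh - 0.5) * 2 * spec$texture_amplitude)) *
        sign(hh - 0.5)
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- pmin(255L, pmax(0L, as.integer(color[ch] + off)))
      img[, , ch] <- plane
    }
  }
  for (k in seq_along(spec$features)) {
    f <- spec$features[[k]]
    si <- match(quick_states[[k]], f$states)
    if (is.na(si)) {
      stop(sprintf("unknown state '%s' for feature '%s' (valid: %s)",
                   quick_states[[k]], f$name,
                   paste(f$states, collapse = ", ")), call. = FALSE)
    }
    img <- draw_glyph(img, f, si)
  }
  img
}

# paint a feature glyph for state index 1 or 2 inside its bbox
draw_glyph <- function(img, f, state_index) {
  bb <- f$bbox
  bw <- bb[3L] - bb[1L] + 1L; bh <- bb[4L] - bb[2L] + 1L
  u <- matrix(rep((seq_len(bw) - 0.5) / bw, each = bh), nrow = bh)
  v <- matrix(rep((seq_len(bh) - 0.5) / bh, times = bw), nrow = bh)
  m <- switch(f$glyph,
    arrow = if (state_index == 1L) abs(v - 0.5) <= 0.5 * u
            else                   abs(v - 0.5) <= 0.5 * (1 - u),
    bar   = if (state_index == 1L) abs(v - 0.5) <= 0.16
            else                   abs(u - 0.5) <= 0.16,
    dots  = if (state_index == 1L) {
              cx <- c(0.30, 0.70, 0.48); cy <- c(0.32, 0.42, 0.74)
              r2 <- 0.14^2
              Reduce(`|`, lapply(1:3, function(i)
                (u - cx[i])^2 + (v - cy[i])^2 <= r2))
            } else matrix(FALSE, bh, bw)
  )
  rows <- bb[2L]:bb[4L]; cols <- bb[1L]:bb[3L]
  for (ch in 1:3) {
    patch <- img[rows, cols, ch]
    patch[m] <- f$color[ch]
    img[rows, cols, ch] <- patch
  }
  img
}

#' Write the full composite image set for a scene
#'
#' Renders and saves one image per combination of slow-change color and
#' quick-change state vector: `2 * 2^k` files for `k` binary features, named
#' `Img<id>_<Color>[_<state>...].<fmt>` so that [load_composite_set()] (and
#' the original pipeline's conventions) can enumerate them.
#'
#' @param spec A [scene_spec()].
#' @param image_id Integer scene identifier used in filenames.
#' @param colors Named list of exactly two RGB triples; names are the color
#'   labels, list order is start color then end color.
#' @param out_dir Output directory (created if needed).
#' @param fmt `"png"` (default; bit-exact) or `"jpg"`.
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @returns Character vector of written paths, sorted lexicographically.
#' @examples
#' \donttest{
#' spec <- demo_scene_spec(n_features = 1, width = 64, height = 64)
#' paths <- emit_composite_set(spec, 1,
#'   colors = list(Yellow = c(230, 200, 40), Orange = c(230, 130, 30)),
#'   out_dir = tempfile())
#' basename(paths)  # 4 files
#' }
#' @export
emit_composite_set <- function(spec, image_id, colors, out_dir, fmt = "png",
                               overwrite = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (length(colors) != 2L || is.null(names(colors)) || any(!nzchar(names(colors)))) {
    stop("colors must be a named list of exactly two RGB triples", call. = FALSE)
  }
  check_state_labels(names(colors))  # same lexical rules as state tokens
  if (!fmt %in% c("png", "jpg")) stop("fmt must be 'png' or 'jpg'", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grids <- state_grid(spec$features)
  paths <- character(0)
  for (cl in names(colors)) {
    for (r in seq_len(nrow(grids))) {
      states <- as.character(grids[r, ])
      fn <- format_composite_name(image_id, cl, states, ext = fmt)
      paths <- c(paths, file.path(out_dir, fn))
    }
  }
  exists_already <- file.exists(paths)
  if (any(exists_already) && !overwrite) {
    stop(sprintf("refusing to overwrite %d existing file(s) in '%s'; set overwrite = TRUE",
                 sum(exists_already), out_dir), call. = FALSE)
  }
  i <- 0L
  for (cl in names(colors)) {
    for (r in seq_len(nrow(grids))) {
      i <- i + 1L
      img <- render_scene(spec, colors[[cl]], as.character(grids[r, ]))
      write_image_rgb(img, paths[i])
    }
  }
  sort(paths)
}

# all combinations of feature states, one column per feature, in feature order
state_grid <- function(features) {
  if (length(features) == 0L) return(data.frame(row.names = 1L))
  expand.grid(lapply(features, function(f) f$states),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' A ready-made demonstration scene
#'
#' Builds a canonical synthetic scene: a large central ellipse (the
#' slow-change element) with mild texture, plus up to three quick-change
#' features in the corners (an arrow, a bar, and a dot cluster).
#'
#' @param n_features Number of quick-change features, 0-3.
#' @param width,height Canvas size in pixels.
#' @param texture_amplitude Luminance texture amplitude inside the region.
#' @param render_seed Texture seed.
#' @returns A [scene_spec()].
#' @export
demo_scene_spec <- function(n_features = 3, width = 480, height = 480,
                            texture_amplitude = 8, render_seed = 1L) {
  stopifnot(n_features >= 0, n_features <= 3)
  sx <- function(p) as.integer(round(p * width))
  sy <- function(p) as.integer(round(p * height))
  feats <- list(
    quick_feature("rocket", bbox = c(sx(0.04), sy(0.04), sx(0.24), sy(0.20)),
                  states = c("Left", "Right"), glyph = "arrow"),
    quick_feature("antenna", bbox = c(sx(0.76), sy(0.04), sx(0.96), sy(0.20)),
                  states = c("Flat", "Tall"), glyph = "bar",
                  color = c(70L, 40L, 120L)),
    quick_feature("birds", bbox = c(sx(0.76), sy(0.80), sx(0.96), sy(0.96)),
                  states = c("Here", "Gone"), glyph = "dots",
                  color = c(120L, 30L, 30L))
  )
  scene_spec(width = width, height = height,
             slow_region = list(shape = "ellipse",
                                bbox = c(sx(0.20), sy(0.20), sx(0.80), sy(0.80))),
             texture_amplitude = texture_amplitude,
             features = feats[seq_len(n_features)],
             render_seed = render_seed)
}

#' Read and write scene specifications as JSON
#'
#' @param spec A [scene_spec()].
#' @param path JSON file path.
#' @returns `read_scene_spec()` returns a [scene_spec()];
#'   `write_scene_spec()` returns `path` invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- unclass(spec)
  x$features <- lapply(x$features, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  feats <- lapply(x$features, function(f)
    quick_feature(f$name, unlist(f$bbox), unlist(f$states), f$glyph,
                  unlist(f$color)))
  scene_spec(width = x$width, height = x$height,
             background_color = unlist(x$background_color),
             slow_region = list(shape = x$slow_region$shape,
                                bbox = unlist(x$slow_region$bbox),
                                corner_radius = x$slow_region$corner_radius),
             texture_amplitude = x$texture_amplitude,
             features = feats,
             render_seed = x$render_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
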