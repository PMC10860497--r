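#' Build a composite set in memory from a synthetic scene
#'
#' Renders every color x quick-state combination of a [scene_spec()]
#' directly into a `composite_set`, skipping the round trip through image
#' files. Pixel-identical to [emit_composite_set()] followed by
#' [load_composite_set()] (PNG path).
#'
#' @param spec A [scene_spec()].
#' @param image_id Integer scene id.
#' @param colors Named list of exactly two RGB triples (start, then end).
#' @returns A `composite_set`.
#' @export
build_composite_set <- function(spec, image_id, colors) {
  stopifnot(inherits(spec, "scene_spec"), length(colors) == 2L)
  grids <- state_grid(spec$features)
  images <- list()
  for (cl in names(colors)) {
    for (r in seq_len(nrow(grids))) {
      states <- as.character(grids[r, ])
      images[[composite_stem(cl, states)]] <- render_scene(spec, colors[[cl]],
                                                           states)
    }
  }
  structure(list(image_id = as.integer(image_id),
                 width = spec$width, height = spec$height,
                 color_labels = names(colors),
                 feature_state_domains = lapply(spec$features, `[[`, "states"),
                 images = images),
            class = "composite_set")
}

#' Generate one slow-change stimulus video
#'
#' Runs the full pipeline for one composite set: draws the quick-change
#' schedule from `config$seed`, assembles the 20 s frame sequence (lead +
#' slow color morph with embedded quick changes + tail, plus the optional
#' fixation overlay), streams it into the encoder, and writes a JSON
#' manifest sidecar (`<out_path>.json`) that fully determines regeneration.
#'
#' @param set A `composite_set` ([load_composite_set()] or
#'   [build_composite_set()]).
#' @param out_path Output video path (`.avi`).
#' @param config A [morph_config()]; `quick_change_count` must equal the
#'   set's feature count.
#' @param codec `"lossless"` (default) or `"lossy"`.
#' @param start_rgb,end_rgb Optional nominal RGB of the slow-change colors,
#'   echoed into the manifest for colorimetry checks.
#' @param feature_bboxes Optional data frame (`x0`, `y0`, `x1`, `y1`) of
#'   quick-feature boxes, echoed into the manifest so the validator can
#'   exclude them from the slow-change mask.
#' @returns Invisibly, the manifest list (also written to
#'   `<out_path>.json`).
#' @export
generate_stimulus <- function(set, out_path, config = morph_config(),
                              codec = c("lossless", "lossy"),
                              start_rgb = NULL, end_rgb = NULL,
                              feature_bboxes = NULL) {
  codec <- match.arg(codec)
  stopifnot(inherits(set, "composite_set"), inherits(config, "morph_config"))
  k <- length(set$feature_state_domains)
  if (config$quick_change_count != k) {
    stop(sprintf("config$quick_change_count (%d) must match the set's %d feature(s)",
                 config$quick_change_count, k), call. = FALSE)
  }
  schedule <- schedule_quick_changes(config, features = as.character(seq_len(k)))
  from_states <- vapply(set$feature_state_domains, `[`, "", 1L)
  to_states <- vapply(set$feature_state_domains, `[`, "", 2L)
  gen <- overlaid_generator(
    frame_generator(set, schedule, config, from_states, to_states), config)
  info <- encode_video(gen, out_path, codec = codec,
                       fps = config$fps, n_frames = config$n_total)
  sched_out <- schedule
  if (k > 0) {
    sched_out$from_state <- from_states[schedule$feature_index]
    sched_out$to_state <- to_states[schedule$feature_index]
  }
  manifest <- list(
    manifest_version = 1L,
    tool = paste0("morphstim ", as.character(utils::packageVersion("morphstim"))),
    config = config_echo(config),
    image_id = set$image_id,
    width = info$width, height = info$height,
    color_labels = set$color_labels,
    start_rgb = start_rgb, end_rgb = end_rgb,
    from_states = as.list(from_states), to_states = as.list(to_states),
    feature_bboxes = feature_bboxes,
    schedule = sched_out,
    codec = info$codec, lossless = info$lossless,
    frame_checksums = if (info$lossless) info$frame_checksums)
  write_manifest(manifest, paste0(out_path, ".json"))
  invisible(manifest)
}

config_echo <- function(config) {
  e <- unclass(config)
  e$overlay <- if (!is.null(e$overlay)) unclass(e$overlay)
  e
}

config_from_echo <- function(e) {
  ov <- if (!is.null(e$overlay)) {
    fixation_overlay(e$overlay$mark_radius_px, e$overlay$crosshair_width_px,
                     e$overlay$crosshair_flash_s)
  }
  morph_config(fps = e$fps, lead_s = e$lead_s, morph_s = e$morph_s,
               tail_s = e$tail_s, quick_change_count = e$quick_change_count,
               quick_change_duration_s = e$quick_change_duration_s,
               min_gap_s = e$min_gap_s, seed = e$seed, overlay = ov)
}

#' Regenerate a stimulus from its manifest
#'
#' Rebuilds a video from the composite inputs plus the manifest sidecar,
#' using the recorded schedule (not a fresh draw). In lossless mode the
#' regenerated frames are bit-identical to the originals, which the
#' recorded per-frame checksums verify.
#'
#' @param set The `composite_set` the original run used.
#' @param manifest Manifest list or path to the JSON sidecar.
#' @param out_path Output video path.
#' @returns Invisibly, the [encode_video()] info for the regenerated file;
#'   an error is raised if recorded checksums do not match.
#' @export
regenerate_stimulus <- function(set, manifest, out_path) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  config <- config_from_echo(manifest$config)
  from_states <- unlist(manifest$from_states) %||% character(0)
  to_states <- unlist(manifest$to_states) %||% character(0)
  schedule <- manifest$schedule
  gen <- overlaid_generator(
    frame_generator(set, schedule, config, from_states, to_states), config)
  info <- encode_video(gen, out_path,
                       codec = if (isTRUE(manifest$lossless)) "lossless" else "lossy",
                       fps = config$fps, n_frames = config$n_total)
  if (isTRUE(manifest$lossless) && !is.null(manifest$frame_checksums)) {
    if (!identical(unname(unlist(manifest$frame_checksums)),
                   unname(info$frame_checksums))) {
      stop("regenerated frames do not match the manifest checksums", call. = FALSE)
    }
  }
  invisible(info)
}

# stable polynomial string hash mod 2^31 - 1, for per-cell seed derivation
string_hash31 <- function(s) {
  h <- 17
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- (h * 131 + b) %% 2147483647   # stays well inside double precision
  }
  h
}

#' Derive a per-cell seed from a master seed
#'
#' Battery cells get independent, stable seeds: hashing the cell label
#' together with the master seed means adding or reordering cells never
#' perturbs the schedules of existing ones.
#'
#' @param master_seed Integer master seed.
#' @param ... Cell identifiers (scene id, color-pair label, ...), combined
#'   into the hashed label.
#' @returns An integer seed in `[0, 2^31)`.
#' @export
cell_seed <- function(master_seed, ...) {
  lab <- paste(c(as.character(master_seed), vapply(list(...), as.character, "")),
               collapse = "|")
  as.integer(string_hash31(lab))
}

#' Generate a full stimulus battery
#'
#' Produces one video per (scene, color pair) cell — e.g. 11 scenes x 5
#' color pairs = 55 videos — with per-cell seeds derived from the master
#' seed, and writes an index CSV. A failing cell is reported in the index
#' and does not abort the batch.
#'
#' @param scenes Named list of [scene_spec()] objects; names are scene ids
#'   (integer-like strings or integers).
#' @param color_pairs Named list of color pairs; each element is a named
#'   list of two RGB triples (start, then end), the element name labels the
#'   pair.
#' @param out_dir Output directory.
#' @param config Base [morph_config()]; each cell replaces `seed` (derived
#'   per cell) and `quick_change_count` (the scene's own feature count).
#' @param master_seed Master seed for [cell_seed()].
#' @param codec Passed to [generate_stimulus()].
#' @returns A tibble index (also written to `out_dir/index.csv`): scene,
#'   color pair, seed, video path, status.
#' @export
generate_battery <- function(scenes, color_pairs, out_dir,
                             config = morph_config(), master_seed = 1L,
                             codec = "lossless") {
  stopifnot(length(scenes) >= 1, length(color_pairs) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- tidyr::expand_grid(scene = names(scenes), pair = names(color_pairs))
  rows <- purrr::pmap(cells, function(scene, pair) {
    seed <- cell_seed(master_seed, scene, pair)
    sid <- suppressWarnings(as.integer(gsub("\\D", "", scene)))
    if (is.na(sid)) sid <- match(scene, names(scenes))
    path <- file.path(out_dir, sprintf("Img%d_%s.avi", sid, pair))
    status <- tryCatch({
      spec <- scenes[[scene]]
      # each scene brings its own feature count (1-3 quick changes per video)
      cfg <- morph_config(fps = config$fps, lead_s = config$lead_s,
                          morph_s = config$morph_s, tail_s = config$tail_s,
                          quick_change_count = length(spec$features),
                          quick_change_duration_s = config$quick_change_duration_s,
                          min_gap_s = config$min_gap_s, seed = seed,
                          overlay = config$overlay)
      set <- build_composite_set(spec, sid, color_pairs[[pair]])
      bbs <- if (length(spec$features) > 0) {
        do.call(rbind, lapply(spec$features, function(f)
          data.frame(x0 = f$bbox[1L], y0 = f$bbox[2L],
                     x1 = f$bbox[3L], y1 = f$bbox[4L])))
      }
      generate_stimulus(set, path, cfg, codec = codec,
                        start_rgb = as.list(color_pairs[[pair]][[1L]]),
                        end_rgb = as.list(color_pairs[[pair]][[2L]]),
                        feature_bboxes = bbs)
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    tibble::tibble(scene = scene, pair = pair, seed = seed,
                   video = path, status = status)
  })
  index <- dplyr::bind_rows(rows)
  readr::write_csv(index, file.path(out_dir, "index.csv"))
  index
}

#' The five standard slow-change color pairs
#'
#' The standardized color-pair palette used for validation batteries: two
#' pairs adjacent on the color wheel (yellow-orange, purple-blue), two
#' distant pairs (purple-orange, blue-yellow), and a non-standard variant.
#'
#' @returns A named list of color pairs suitable for [generate_battery()].
#' @export
standard_color_pairs <- function() {
  yellow <- c(233, 212, 80); orange <- c(227, 134, 61)
  purple <- c(118, 74, 155); blue <- c(73, 111, 189)
  list(
    YellowOrange = list(Yellow = yellow, Orange = orange),
    PurpleBlue   = list(Purple = purple, Blue = blue),
    PurpleOrange = list(Purple = purple, Orange = orange),
    BlueYellow   = list(Blue = blue, Yellow = yellow),
    PurpleOrangeNS = list(Plum = c(104, 62, 138), Amber = c(214, 126, 44)))
}
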