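#' Timing configuration for a slow-change stimulus
#'
#' Holds every timing parameter of the generated video. The defaults give
#' the standard stimulus: 2 s of the unchanging initial frame, a 16 s slow
#' color morph rendered as 192 frames at 12 frames/s, and 2 s of the
#' unchanging final frame — a 20 s, 240-frame video — with each quick
#' change unfolding over 1 s (12 frames) at a random moment inside the
#' morph segment.
#'
#' @param fps Frames per second (default 12).
#' @param lead_s,morph_s,tail_s Durations in seconds of the lead bookend,
#'   the morph segment, and the tail bookend (defaults 2, 16, 2).
#' @param quick_change_count Number of quick changes, 0-3. 0 produces a
#'   stimulus with only the slow change.
#' @param quick_change_duration_s Duration of each quick change (default 1 s).
#' @param min_gap_s Minimum gap between quick-change windows (default 1 s).
#' @param seed Integer seed driving the random quick-change moments.
#' @param overlay Optional [fixation_overlay()] applied to the bookends.
#' @returns A `morph_config` list with the derived frame counts
#'   `n_lead`, `n_morph`, `n_tail`, `n_total` and `dur_frames`.
#' @export
morph_config <- function(fps = 12, lead_s = 2, morph_s = 16, tail_s = 2,
                         quick_change_count = 3, quick_change_duration_s = 1,
                         min_gap_s = 1, seed = 1L, overlay = NULL) {
  for (nm in c("lead_s", "morph_s", "tail_s", "quick_change_duration_s")) {
    v <- fps * get(nm)
    if (abs(v - round(v)) > 1e-9) {
      stop(sprintf("fps * %s must be an integer number of frames", nm),
           call. = FALSE)
    }
  }
  if (quick_change_count < 0 || quick_change_count > 3) {
    stop("quick_change_count must be in 0..3", call. = FALSE)
  }
  cfg <- list(fps = fps, lead_s = lead_s, morph_s = morph_s, tail_s = tail_s,
              quick_change_count = as.integer(quick_change_count),
              quick_change_duration_s = quick_change_duration_s,
              min_gap_s = min_gap_s, seed = as.integer(seed), overlay = overlay)
  cfg$n_lead <- as.integer(round(fps * lead_s))
  cfg$n_morph <- as.integer(round(fps * morph_s))
  cfg$n_tail <- as.integer(round(fps * tail_s))
  cfg$n_total <- cfg$n_lead + cfg$n_morph + cfg$n_tail
  cfg$dur_frames <- as.integer(round(fps * quick_change_duration_s))
  gap <- as.integer(round(fps * min_gap_s))
  if (quick_change_count * (cfg$dur_frames + gap) > cfg$n_morph) {
    stop(sprintf(
      "infeasible packing: %d * (%d + %d) frames > %d morph frames",
      quick_change_count, cfg$dur_frames, gap, cfg$n_morph), call. = FALSE)
  }
  structure(cfg, class = "morph_config")
}

# one interpolated frame: round(start + f*(end-start)), half-up, f = i/(n-1)
morph_frame <- function(start, end, i, n_frames) {
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  f <- i / (n_frames - 1)
  arr <- round_half_up(start + f * (end - start))
  storage.mode(arr) <- "integer"
  arr
}

#' Build a morph series between two composite images
#'
#' Creates the ordered series of frames in which the scene fades from the
#' start-color version to the end-color version by linearly interpolating
#' the two images' RGB values: frame `i` (0-based) is, per pixel and
#' channel, `round(start + (i/(n_frames-1)) * (end - start))` with half-up
#' rounding, so the first and last frames are pixel-exact copies of the
#' inputs.
#'
#' @param start,end Equal-sized integer RGB arrays (one fixed quick-change
#'   state, two colors).
#' @param n_frames Number of frames in the series (default 192, i.e. 16 s
#'   at 12 fps).
#' @returns A list of `n_frames` integer RGB arrays.
#' @export
build_morph_series <- function(start, end, n_frames = 192) {
  assert_image_rgb(start, "start"); assert_image_rgb(end, "end")
  assert_same_dims(start, end)
  lapply(seq_len(n_frames) - 1L, function(i) morph_frame(start, end, i, n_frames))
}

#' Randomly schedule the quick changes
#'
#' Draws one onset per quick-change feature, uniformly over all feasible
#' placements: every 1 s transition window must fit inside the morph
#' segment and windows must be separated by at least `min_gap_s`.
#' Events are assigned to features by a uniform random permutation.
#' The draw is a deterministic function of `config$seed`.
#'
#' @param config A [morph_config()]; `quick_change_count` events are drawn.
#' @param features Character vector of feature names (length must equal
#'   `quick_change_count`), or a composite set's feature positions.
#' @returns A tibble with one row per event: `feature_index`, `feature`,
#'   `from_state`, `to_state` (filled by [assemble_frames()] callers when
#'   state domains are known; here `NA`), `onset_frame` (0-based morph-frame
#'   index) and `duration_frames`, sorted by onset.
#' @export
schedule_quick_changes <- function(config, features = character()) {
  stopifnot(inherits(config, "morph_config"))
  m <- config$quick_change_count
  if (length(features) != m) {
    stop(sprintf("config asks for %d quick change(s) but %d feature(s) given",
                 m, length(features)), call. = FALSE)
  }
  if (m == 0L) {
    return(tibble::tibble(feature_index = integer(0), feature = character(0),
                          onset_frame = integer(0), duration_frames = integer(0)))
  }
  dur <- config$dur_frames
  gap <- as.integer(round(config$fps * config$min_gap_s))
  max_onset <- config$n_morph - dur          # onset in 0..max_onset
  onsets <- with_seed(config$seed, {
    repeat {
      cand <- sort(sample.int(max_onset + 1L, m, replace = FALSE) - 1L)
      if (m == 1L || all(diff(cand) >= dur + gap)) break
    }
    perm <- sample.int(m)
    list(cand = cand, perm = perm)
  })
  tibble::tibble(feature_index = onsets$perm,
                 feature = as.character(features)[onsets$perm],
                 onset_frame = onsets$cand,
                 duration_frames = dur)
}

# per-feature transition fraction at morph frame i given the schedule:
# 0 before the window, (j+1)/dur inside it, 1 after
feature_alpha <- function(schedule, n_features, i) {
  a <- numeric(n_features)
  for (r in seq_len(nrow(schedule))) {
    f <- schedule$feature_index[r]
    on <- schedule$onset_frame[r]; dur <- schedule$duration_frames[r]
    a[f] <- if (i < on) 0 else if (i >= on + dur) 1 else (i - on + 1) / dur
  }
  a
}

# compute assembled frame at 0-based morph index i directly from the set
assemble_morph_frame <- function(set, schedule, config, i,
                                 from_states, to_states) {
  k <- length(from_states)
  a <- feature_alpha(schedule, k, i)
  cur <- ifelse(a >= 1, to_states, from_states)
  mid <- which(a > 0 & a < 1)
  start_l <- set$color_labels[1L]; end_l <- set$color_labels[2L]
  frame_for <- function(states) {
    morph_frame(set_image(set, start_l, states), set_image(set, end_l, states),
                i, config$n_morph)
  }
  if (length(mid) == 0L) return(frame_for(cur))
  # windows are separated, so at most one feature is mid-transition
  pre <- cur; pre[mid] <- from_states[mid]
  post <- cur; post[mid] <- to_states[mid]
  alpha <- a[mid[1L]]
  arr <- round_half_up((1 - alpha) * frame_for(pre) + alpha * frame_for(post))
  storage.mode(arr) <- "integer"
  arr
}

#' Assemble the full stimulus frame sequence
#'
#' Steps through the slow color morph, at each step taking the morph frame
#' that corresponds to the current quick-change state combination, and
#' bookends the morph with the unchanging initial and final frames. During
#' a quick-change window the frame is a per-pixel linear cross-fade between
#' the pre-state and post-state morph series at the same morph index, with
#' the blend weight ramping linearly over the window — so the slow change
#' never pauses while a quick change unfolds.
#'
#' @param set A [load_composite_set()] result (or the in-memory set built by
#'   the generator).
#' @param schedule A [schedule_quick_changes()] tibble.
#' @param config A [morph_config()].
#' @param from_states,to_states Per-feature initial and final state labels;
#'   default to the first and second label of each feature's domain.
#' @returns A `frame_sequence`: list with `fps`, `frames` (list of integer
#'   RGB arrays of length `fps * (lead_s + morph_s + tail_s)`) and
#'   `annotations` (tibble with 0-based `frame`, `segment`
#'   (lead/morph/tail) and 0-based `morph_index`, `NA` outside the morph).
#' @export
assemble_frames <- function(set, schedule, config,
                            from_states = NULL, to_states = NULL) {
  stopifnot(inherits(config, "morph_config"))
  k <- length(set$feature_state_domains)
  if (config$quick_change_count != k) {
    stop(sprintf("config schedules %d quick change(s) but the set has %d feature(s)",
                 config$quick_change_count, k), call. = FALSE)
  }
  if (nrow(schedule) != k || (k > 0 && !setequal(schedule$feature_index, seq_len(k)))) {
    stop("schedule does not cover each feature exactly once", call. = FALSE)
  }
  if (is.null(from_states)) from_states <- vapply(set$feature_state_domains, `[`, "", 1L)
  if (is.null(to_states)) to_states <- vapply(set$feature_state_domains, `[`, "", 2L)
  gen <- frame_generator(set, schedule, config, from_states, to_states)
  frames <- lapply(seq_len(config$n_total) - 1L, gen)
  new_frame_sequence(frames, config)
}

# closure mapping 0-based sequence frame index -> assembled frame
frame_generator <- function(set, schedule, config, from_states, to_states) {
  force(set); force(schedule); force(config)
  function(t) {
    if (t < config$n_lead) {
      assemble_morph_frame(set, schedule, config, 0L, from_states, to_states)
    } else if (t < config$n_lead + config$n_morph) {
      assemble_morph_frame(set, schedule, config, t - config$n_lead,
                           from_states, to_states)
    } else {
      assemble_morph_frame(set, schedule, config, config$n_morph - 1L,
                           from_states, to_states)
    }
  }
}

new_frame_sequence <- function(frames, config) {
  ann <- tibble::tibble(
    frame = seq_along(frames) - 1L,
    segment = rep(c("lead", "morph", "tail"),
                  times = c(config$n_lead, config$n_morph, config$n_tail)),
    morph_index = c(rep(NA_integer_, config$n_lead),
                    seq_len(config$n_morph) - 1L,
                    rep(NA_integer_, config$n_tail)))
  structure(list(fps = config$fps, frames = frames, annotations = ann),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %g fps (%.1f s)\n",
              length(x$frames), d[2L], d[1L], x$fps, length(x$frames) / x$fps))
  invisible(x)
}

#' Fixation-mark overlay for the video bookends
#'
#' Describes the central white fixation dot shown during the unchanging
#' lead and tail segments, and the "cross hair" of four full-image lines
#' (horizontal, vertical, two diagonals, each 5 px wide) flashed when the
#' dot disappears at the start of the morph and reappears at its end.
#'
#' @param mark_radius_px Radius of the white fixation dot in pixels.
#' @param crosshair_width_px Line width of the cross-hair (default 5).
#' @param crosshair_flash_s How long the cross-hair is shown at each
#'   transition (default 0.5 s).
#' @returns A `fixation_overlay` list.
#' @export
fixation_overlay <- function(mark_radius_px = 6, crosshair_width_px = 5,
                             crosshair_flash_s = 0.5) {
  structure(list(mark_radius_px = mark_radius_px,
                 crosshair_width_px = crosshair_width_px,
                 crosshair_flash_s = crosshair_flash_s),
            class = "fixation_overlay")
}

# logical masks for the dot and the cross-hair on a h x w canvas
overlay_masks <- function(overlay, h, w) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  x <- matrix(rep(seq_len(w), each = h), nrow = h)
  y <- matrix(rep(seq_len(h), times = w), nrow = h)
  dot <- (x - cx)^2 + (y - cy)^2 <= overlay$mark_radius_px^2
  hw <- overlay$crosshair_width_px / 2
  cross <- abs(y - cy) <= hw | abs(x - cx) <= hw |
    abs((y - cy) - (x - cx)) / sqrt(2) <= hw |
    abs((y - cy) + (x - cx)) / sqrt(2) <= hw
  list(dot = dot, cross = cross)
}

paint_mask <- function(img, mask, color = c(255L, 255L, 255L)) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Apply the fixation overlay to a frame sequence
#'
#' Draws the white fixation dot on every lead and tail frame, and the
#' cross-hair on the final `crosshair_flash_s` of the lead and the first
#' `crosshair_flash_s` of the tail (the moments the dot disappears and
#' reappears). All other pixels, and all morph frames, are untouched.
#'
#' @param seq A `frame_sequence` from [assemble_frames()].
#' @param overlay A [fixation_overlay()], or `NULL` for a no-op.
#' @returns The overlaid `frame_sequence`.
#' @export
apply_fixation_overlay <- function(seq, overlay) {
  if (is.null(overlay)) return(seq)
  stopifnot(inherits(seq, "frame_sequence"), inherits(overlay, "fixation_overlay"))
  d <- dim(seq$frames[[1L]])
  masks <- overlay_masks(overlay, d[1L], d[2L])
  flash <- as.integer(round(seq$fps * overlay$crosshair_flash_s))
  ann <- seq$annotations
  lead_idx <- which(ann$segment == "lead")
  tail_idx <- which(ann$segment == "tail")
  cross_idx <- c(utils::tail(lead_idx, flash), utils::head(tail_idx, flash))
  for (t in c(lead_idx, tail_idx)) {
    img <- seq$frames[[t]]
    if (t %in% cross_idx) img <- paint_mask(img, masks$cross)
    img <- paint_mask(img, masks$dot)
    seq$frames[[t]] <- img
  }
  seq
}

# overlay-aware generator used by the streaming encoder
overlaid_generator <- function(gen, config) {
  if (is.null(config$overlay)) return(gen)
  ov <- config$overlay
  masks <- NULL
  flash <- as.integer(round(config$fps * ov$crosshair_flash_s))
  function(t) {
    img <- gen(t)
    in_lead <- t < config$n_lead
    in_tail <- t >= config$n_lead + config$n_morph
    if (!in_lead && !in_tail) return(img)
    if (is.null(masks)) {
      d <- dim(img)
      masks <<- overlay_masks(ov, d[1L], d[2L])
    }
    cross <- (in_lead && t >= config$n_lead - flash) ||
      (in_tail && t < config$n_lead + config$n_morph + flash)
    if (cross) img <- paint_mask(img, masks$cross)
    paint_mask(img, masks$dot)
  }
}
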