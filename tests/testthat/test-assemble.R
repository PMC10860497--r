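make_assembly <- function(n_features = 1, seed = 5, width = 48, height = 48,
                          texture = 8, overlay = NULL) {
  spec <- tiny_spec(n_features, width = width, height = height,
                    texture_amplitude = texture)
  set <- build_composite_set(spec, 1L, test_pair)
  cfg <- morph_config(quick_change_count = n_features, seed = seed,
                      overlay = overlay)
  sch <- schedule_quick_changes(cfg, features = as.character(seq_len(n_features)))
  list(spec = spec, set = set, cfg = cfg, sch = sch,
       seq = assemble_frames(set, sch, cfg))
}

test_that("the assembled sequence has lead + morph + tail structure", {
  a <- make_assembly(1)
  expect_length(a$seq$frames, a$cfg$n_total)
  expect_equal(as.vector(table(a$seq$annotations$segment)[c("lead", "morph", "tail")]),
               c(a$cfg$n_lead, a$cfg$n_morph, a$cfg$n_tail))
  # lead frames repeat morph frame 0 of the initial state
  start_img <- morphstim:::set_image(a$set, "Yellow", a$set$feature_state_domains[[1]][1])
  for (t in 1:a$cfg$n_lead) expect_identical(a$seq$frames[[t]], start_img)
  # tail frames repeat the final frame of the final state
  end_img <- morphstim:::set_image(a$set, "Orange", a$set$feature_state_domains[[1]][2])
  for (t in (a$cfg$n_total - a$cfg$n_tail + 1):a$cfg$n_total) {
    expect_identical(a$seq$frames[[t]], end_img)
  }
})

test_that("with no quick changes the sequence equals lead + morph series + tail", {
  spec <- tiny_spec(0, texture_amplitude = 8)
  set <- build_composite_set(spec, 1L, test_pair)
  cfg <- morph_config(quick_change_count = 0, seed = 2)
  seq <- assemble_frames(set, schedule_quick_changes(cfg, character()), cfg)
  series <- build_morph_series(set$images[["Yellow"]], set$images[["Orange"]],
                               cfg$n_morph)
  expected <- c(rep(series[1], cfg$n_lead), series, rep(series[cfg$n_morph], cfg$n_tail))
  expect_identical(seq$frames, expected)
})

test_that("outside quick-change windows and boxes, frames equal the pure morph", {
  a <- make_assembly(1, seed = 13)
  on <- a$sch$onset_frame; dur <- a$sch$duration_frames
  bb <- a$spec$features[[1]]$bbox
  dom <- a$set$feature_state_domains[[1]]
  pre_series_start <- morphstim:::set_image(a$set, "Yellow", dom[1])
  pre_series_end <- morphstim:::set_image(a$set, "Orange", dom[1])
  outside_box <- matrix(TRUE, a$spec$height, a$spec$width)
  outside_box[bb[2]:bb[4], bb[1]:bb[3]] <- FALSE
  for (i in c(0, on - 1, on + dur, a$cfg$n_morph - 1)) {
    frame <- a$seq$frames[[a$cfg$n_lead + i + 1]]
    states_now <- if (i >= on + dur) dom[2] else dom[1]
    oracle <- morphstim:::morph_frame(
      morphstim:::set_image(a$set, "Yellow", states_now),
      morphstim:::set_image(a$set, "Orange", states_now), i, a$cfg$n_morph)
    expect_identical(frame, oracle)
  }
  # during the window, pixels outside the feature bbox still equal the morph
  mid <- on + dur %/% 2
  frame <- a$seq$frames[[a$cfg$n_lead + mid + 1]]
  oracle <- morphstim:::morph_frame(pre_series_start, pre_series_end,
                                    mid, a$cfg$n_morph)
  for (ch in 1:3) {
    expect_true(all(frame[, , ch][outside_box] == oracle[, , ch][outside_box]))
  }
})

test_that("each feature flips exactly once, at its scheduled window", {
  a <- make_assembly(3, seed = 31)
  dom <- a$set$feature_state_domains
  for (r in seq_len(nrow(a$sch))) {
    f <- a$sch$feature_index[r]
    bb <- a$spec$features[[f]]$bbox
    on <- a$sch$onset_frame[r]; dur <- a$sch$duration_frames[r]
    probe <- function(i, states) {
      frame <- a$seq$frames[[a$cfg$n_lead + i + 1]]
      ref <- morphstim:::morph_frame(
        morphstim:::set_image(a$set, "Yellow", states),
        morphstim:::set_image(a$set, "Orange", states), i, a$cfg$n_morph)
      identical(frame[bb[2]:bb[4], bb[1]:bb[3], ],
                ref[bb[2]:bb[4], bb[1]:bb[3], ])
    }
    from <- vapply(dom, `[`, "", 1L); to <- from
    to[f] <- dom[[f]][2]
    # before the window: from-state pixels; from its last frame on: to-state
    expect_true(probe(on - 1, from) || on == 0)
    expect_true(probe(on + dur - 1, to))
    expect_true(probe(min(on + dur + 5, a$cfg$n_morph - 1), to))
  }
})

test_that("the slow change never pauses during quick changes", {
  a <- make_assembly(1, seed = 13, texture = 0)
  mask <- morphstim:::slow_region_mask(a$spec)
  bb <- a$spec$features[[1]]$bbox
  mask[bb[2]:bb[4], bb[1]:bb[3]] <- FALSE
  # green channel has the largest excursion; its region mean must advance
  # monotonically through the whole morph, windows included
  g <- vapply(a$seq$frames, function(f) mean(f[, , 2][mask]), numeric(1))
  morph_part <- g[(a$cfg$n_lead + 1):(a$cfg$n_lead + a$cfg$n_morph)]
  expect_true(all(diff(morph_part) <= 0))       # yellow -> orange: G falls
  expect_lt(morph_part[length(morph_part)], morph_part[1])
})

test_that("fixation overlay touches only mark and cross-hair pixels at the right times", {
  ov <- fixation_overlay(mark_radius_px = 3, crosshair_flash_s = 0.5)
  a <- make_assembly(1, seed = 7)
  plain <- a$seq
  marked <- apply_fixation_overlay(plain, ov)
  d <- dim(plain$frames[[1]])
  masks <- morphstim:::overlay_masks(ov, d[1], d[2])
  cx <- as.integer(round((d[2] + 1) / 2)); cy <- as.integer(round((d[1] + 1) / 2))
  n <- length(plain$frames)
  flash <- as.integer(a$cfg$fps * ov$crosshair_flash_s)

  expect_identical(apply_fixation_overlay(plain, NULL), plain)
  # center pixel white in bookends, scene-colored mid-morph
  expect_equal(as.vector(marked$frames[[1]][cy, cx, ]), c(255, 255, 255))
  expect_equal(as.vector(marked$frames[[n]][cy, cx, ]), c(255, 255, 255))
  mid <- a$cfg$n_lead + 96
  expect_identical(marked$frames[[mid]], plain$frames[[mid]])
  # diffs confined to the overlay geometry
  for (t in c(1, a$cfg$n_lead, a$cfg$n_lead + a$cfg$n_morph + 1, n)) {
    dm <- pmax(abs(marked$frames[[t]][, , 1] - plain$frames[[t]][, , 1]),
               abs(marked$frames[[t]][, , 2] - plain$frames[[t]][, , 2]),
               abs(marked$frames[[t]][, , 3] - plain$frames[[t]][, , 3]))
    allowed <- masks$dot
    if (t %in% c(a$cfg$n_lead - flash + seq_len(flash),
                 a$cfg$n_lead + a$cfg$n_morph + seq_len(flash))) {
      allowed <- allowed | masks$cross
    }
    expect_true(all(dm[!allowed] == 0))
  }
  # cross-hair present only in the flash windows
  probe_cross <- function(t) all(marked$frames[[t]][cy, , 2] == 255)
  expect_true(probe_cross(a$cfg$n_lead))            # last lead frame
  expect_false(probe_cross(1))                      # first lead frame: dot only
})

test_that("streamed generation matches materialized assembly bit for bit", {
  spec <- tiny_spec(2, texture_amplitude = 8)
  set <- build_composite_set(spec, 1L, test_pair)
  cfg <- morph_config(quick_change_count = 2, seed = 17,
                      overlay = fixation_overlay())
  sch <- schedule_quick_changes(cfg, features = c("1", "2"))
  seq <- apply_fixation_overlay(assemble_frames(set, sch, cfg), cfg$overlay)
  out <- tempfile(fileext = ".avi")
  generate_stimulus(set, out, cfg)
  dec <- decode_video(out)
  expect_identical(dec$frames, seq$frames)
})
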