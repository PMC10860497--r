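test_that("untextured slow region is an exact flat fill of the requested color", {
  spec <- tiny_spec(0, texture_amplitude = 0)
  img <- render_scene(spec, c(200, 150, 20))
  mask <- morphstim:::slow_region_mask(spec)
  for (ch in 1:3) {
    expect_true(all(img[, , ch][mask] == c(200, 150, 20)[ch]))
  }
  expect_equal(unname(region_mean_rgb(img, mask)), c(200, 150, 20))
})

test_that("textured region mean stays within one level of the nominal color", {
  spec <- tiny_spec(0, width = 96, height = 96, texture_amplitude = 8)
  mask <- morphstim:::slow_region_mask(spec)
  for (col in list(c(200, 150, 20), yellow, orange)) {
    img <- render_scene(spec, col)
    expect_true(all(abs(region_mean_rgb(img, mask) - col) <= 1))
    # texture actually varies the pixels
    expect_gt(length(unique(img[, , 1][mask])), 1)
  }
})

test_that("rendering is deterministic and texture is a pure function of seed and coords", {
  spec <- tiny_spec(2, texture_amplitude = 8)
  a <- render_scene(spec, yellow, c("Left", "Flat"))
  b <- render_scene(spec, yellow, c("Left", "Flat"))
  expect_identical(a, b)
  spec2 <- tiny_spec(2, texture_amplitude = 8, render_seed = 8L)
  c2 <- render_scene(spec2, yellow, c("Left", "Flat"))
  expect_false(identical(a, c2))
})

test_that("toggling one feature changes pixels only inside that feature's bbox", {
  spec <- tiny_spec(2, texture_amplitude = 8)
  a <- render_scene(spec, yellow, c("Left", "Flat"))
  b <- render_scene(spec, yellow, c("Right", "Flat"))
  dm <- pmax(abs(a[, , 1] - b[, , 1]), abs(a[, , 2] - b[, , 2]),
             abs(a[, , 3] - b[, , 3]))
  changed <- which(dm > 0, arr.ind = TRUE)
  bb <- spec$features[[1]]$bbox
  expect_gt(nrow(changed), 0)
  expect_true(all(changed[, "col"] >= bb[1] & changed[, "col"] <= bb[3]))
  expect_true(all(changed[, "row"] >= bb[2] & changed[, "row"] <= bb[4]))
})

test_that("all composite versions are co-registered outside region and feature boxes", {
  spec <- tiny_spec(2, texture_amplitude = 8)
  outside <- !morphstim:::slow_region_mask(spec)
  for (f in spec$features) {
    bb <- f$bbox
    outside[bb[2]:bb[4], bb[1]:bb[3]] <- FALSE
  }
  grid <- expand.grid(color = c("Yellow", "Orange"),
                      s1 = spec$features[[1]]$states,
                      s2 = spec$features[[2]]$states,
                      stringsAsFactors = FALSE)
  imgs <- lapply(seq_len(nrow(grid)), function(r)
    render_scene(spec, test_pair[[grid$color[r]]],
                 c(grid$s1[r], grid$s2[r])))
  ref <- imgs[[1]]
  for (img in imgs[-1]) {
    for (ch in 1:3) expect_true(all(img[, , ch][outside] == ref[, , ch][outside]))
  }
  # color isolation: fixed states, different colors -> diffs inside region only
  d <- pmax(abs(imgs[[1]][, , 1] - imgs[[2]][, , 1]),
            abs(imgs[[1]][, , 2] - imgs[[2]][, , 2]),
            abs(imgs[[1]][, , 3] - imgs[[2]][, , 3]))
  expect_true(all(d[!morphstim:::slow_region_mask(spec)] == 0))
})

test_that("emit_composite_set writes 2^(k+1) files for k = 0..3", {
  for (k in 0:3) {
    out <- tempfile()
    paths <- emit_composite_set(tiny_spec(k), 5L, test_pair, out)
    expect_length(paths, 2^(k + 1))
    expect_identical(paths, sort(paths))
    expect_true(all(file.exists(paths)))
  }
})

test_that("emit refuses to overwrite unless asked", {
  out <- tempfile()
  emit_composite_set(tiny_spec(1), 1L, test_pair, out)
  expect_error(emit_composite_set(tiny_spec(1), 1L, test_pair, out),
               "overwrite")
  expect_silent(emit_composite_set(tiny_spec(1), 1L, test_pair, out,
                                   overwrite = TRUE))
})

test_that("invalid geometry and state labels are rejected", {
  expect_error(render_scene(tiny_spec(1), yellow, "Sideways"), "unknown state")
  expect_error(render_scene(tiny_spec(1), yellow, character()), "expected 1")
  expect_error(scene_spec(width = 48, height = 48,
                          slow_region = list(shape = "ellipse",
                                             bbox = c(1, 10, 47, 40))),
               "strictly inside")
  expect_error(quick_feature("f", c(1, 1, 8, 8), states = c("a_b", "c")),
               "underscore")
  expect_error(quick_feature("f", c(1, 1, 8, 8), states = c("a", "a")),
               "distinct")
  big <- quick_feature("f", c(40, 40, 60, 60))
  expect_error(scene_spec(width = 48, height = 48,
                          slow_region = list(shape = "ellipse",
                                             bbox = c(10, 10, 40, 40)),
                          features = list(big)),
               "outside the canvas")
})

test_that("scene specs round-trip through JSON", {
  spec <- tiny_spec(3, texture_amplitude = 8)
  path <- tempfile(fileext = ".json")
  write_scene_spec(spec, path)
  back <- read_scene_spec(path)
  expect_identical(render_scene(back, yellow, c("Left", "Flat", "Here")),
                   render_scene(spec, yellow, c("Left", "Flat", "Here")))
})
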