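#' Derive the slow-change region mask from a composite pair
#'
#' Only the slow-change element differs between the start-color and
#' end-color versions of a scene (for fixed quick-change states), so the
#' set of pixels whose values differ between the two images recovers the
#' region. Quick-change feature boxes can be subtracted explicitly when the
#' two images happen to differ there too.
#'
#' @param start,end Equal-sized integer RGB arrays.
#' @param exclude_boxes List of pixel rectangles `c(x0, y0, x1, y1)` to
#'   drop from the mask (typically the feature bounding boxes).
#' @param tol Per-channel difference threshold: a pixel enters the mask
#'   when its maximum channel difference exceeds `tol`. Use 0 for lossless
#'   sources, ~8 for JPEG.
#' @returns A logical `height x width` matrix (the `RegionMask`).
#' @export
derive_region_mask <- function(start, end, exclude_boxes = list(), tol = 0) {
  assert_image_rgb(start); assert_image_rgb(end)
  assert_same_dims(start, end)
  diffmax <- pmax(abs(start[, , 1L] - end[, , 1L]),
                  abs(start[, , 2L] - end[, , 2L]),
                  abs(start[, , 3L] - end[, , 3L]))
  mask <- diffmax > tol
  for (bb in exclude_boxes) {
    bb <- check_bbox(bb)
    rows <- max(1L, bb[2L]):min(nrow(mask), bb[4L])
    cols <- max(1L, bb[1L]):min(ncol(mask), bb[3L])
    mask[rows, cols] <- FALSE
  }
  if (!any(mask)) stop("no changing pixels found: start and end images are identical within tol",
                       call. = FALSE)
  mask
}

#' Mean RGB over a pixel region
#'
#' Averages the RGB values across all pixels in the mask — the colorimetry
#' summary used to verify that a nominal color was realized consistently
#' (region means of the first and last video frames should match the
#' composite inputs).
#'
#' @param img Integer RGB array.
#' @param mask Logical `height x width` matrix; must select at least one
#'   pixel.
#' @returns Named numeric vector `c(R = , G = , B = )` of per-channel means.
#' @export
region_mean_rgb <- function(img, mask) {
  assert_image_rgb(img)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  c(R = mean(img[, , 1L][mask]),
    G = mean(img[, , 2L][mask]),
    B = mean(img[, , 3L][mask]))
}

# Exhaustive changepoint fit of the continuity-constrained flat-linear-flat
# model: y is flat at v0 up to frame b1 (0-based), linear from (b1, v0) to
# (b2, v1), and flat at v1 from b2 on, with v0/v1 the flat-segment means.
# Anchoring the line to the flat levels makes the breakpoints sharply
# identifiable: shifting a breakpoint by one frame stretches the whole line
# against the data. Ties break toward the longest linear segment.
fit_flat_linear_flat <- function(y) {
  n <- length(y)
  t0 <- seq_len(n) - 1
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y^2)); cty <- c(0, cumsum(t0 * y))
  seg <- function(cv, a, b) cv[b + 2L] - cv[a + 1L]    # sum over frames a..b
  best <- NULL
  for (b1 in 0:(n - 3L)) {
    m0 <- b1 + 1
    v0 <- seg(cy, 0L, b1) / m0
    sse0 <- seg(cy2, 0L, b1) - m0 * v0^2
    b2 <- (b1 + 2L):(n - 1L)
    m1 <- n - b2
    v1 <- (cy[n + 1L] - cy[b2 + 1L]) / m1
    sse1 <- (cy2[n + 1L] - cy2[b2 + 1L]) - m1 * v1^2
    # interior frames b1+1 .. b2-1, u = t - b1, line = v0 + s*u, s = (v1-v0)/L
    L <- b2 - b1
    m <- L - 1
    sy <- cy[b2 + 1L] - cy[b1 + 2L]
    sy2 <- cy2[b2 + 1L] - cy2[b1 + 2L]
    suy <- (cty[b2 + 1L] - cty[b1 + 2L]) - b1 * sy
    su <- m * L / 2
    su2 <- m * L * (2 * L - 1) / 6
    s <- (v1 - v0) / L
    sse_lin <- sy2 - 2 * (v0 * sy + s * suy) + m * v0^2 + 2 * v0 * s * su +
      s^2 * su2
    sse <- sse0 + sse1 + sse_lin
    j <- which.min(sse)
    cand <- which(sse <= sse[j] + 1e-9)
    j <- cand[length(cand)]                 # longest linear for this b1
    if (is.null(best) || sse[j] < best$sse - 1e-9 ||
        (sse[j] < best$sse + 1e-9 && L[j] > best$len)) {
      best <- list(b1 = b1, b2 = b2[j], sse = sse[j], len = L[j])
    }
  }
  best
}

# locate quick-change windows from frame-difference energy over the probe
# pixels (the abruptly changing pixels outside the slow-change mask)
recover_onsets <- function(frames, probe, morph_range, rel_threshold = 5,
                           abs_floor = 0.05) {
  n <- length(frames)
  if (!any(probe)) {
    return(tibble::tibble(onset_frame = integer(0), run_frames = integer(0)))
  }
  d <- numeric(n - 1L)
  out <- probe
  for (t in 2:n) {
    d[t - 1L] <- mean(abs(frames[[t]][, , 1L][out] - frames[[t - 1L]][, , 1L][out]) +
                      abs(frames[[t]][, , 2L][out] - frames[[t - 1L]][, , 2L][out]) +
                      abs(frames[[t]][, , 3L][out] - frames[[t - 1L]][, , 3L][out])) / 3
  }
  in_morph <- seq_along(d) %in% (morph_range[1L]:morph_range[2L])
  med <- stats::median(d[in_morph])
  mx <- max(d[in_morph])
  # detection criterion: any difference energy well above the morph baseline
  if (mx <= rel_threshold * med + abs_floor) {
    return(tibble::tibble(onset_frame = integer(0), run_frames = integer(0)))
  }
  # run segmentation: whichever cut is lower -- a multiple of the baseline,
  # or a fraction of the way to the strongest window -- so a whole 1 s
  # window forms one run both when windows dwarf the baseline and when the
  # weakest window is only a few times the baseline drift
  thr <- min(rel_threshold * med + abs_floor, med + 0.3 * (mx - med))
  hot <- d > thr & in_morph
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- tibble::tibble(onset_frame = starts[runs$values],  # d[i] = diff (i-1, i), 0-based frame i
                        run_frames = runs$lengths[runs$values])
  # quick changes are non-instantaneous (a window of many frames): discard
  # isolated spikes much shorter than the dominant window
  if (nrow(out) > 0L && max(out$run_frames) >= 3L) {
    out <- out[out$run_frames >= max(3, 0.3 * max(out$run_frames)), ]
  }
  out
}

#' Validate a generated stimulus video frame-by-frame
#'
#' Decodes the video and checks it against the structural contract of a
#' slow-change stimulus: an unchanging lead, a linear region-mean color
#' trajectory over the morph segment, an unchanging tail, and isolated
#' quick-change windows. Segment breakpoints are found by exhaustive search
#' over the flat-linear-flat changepoint model of the region-mean
#' trajectory; quick-change onsets are located from frame-to-frame
#' difference energy outside the slow-change mask.
#'
#' @param path Video path (AVI), or a decoded `frame_sequence`.
#' @param manifest Optional manifest (path or list from [read_manifest()]).
#'   When given, expected breakpoints, onsets and endpoint colors are
#'   compared and a pass/fail verdict per check is reported; feature boxes
#'   from the manifest are excluded from the region mask.
#' @param tol Per-channel tolerance for endpoint color checks (0 for
#'   lossless, 3 recommended for lossy video).
#' @param onset_tol Allowed onset deviation in frames (1 lossless, 2 lossy).
#' @param abrupt_tol Pixels whose value ever jumps by more than this between
#'   consecutive frames are excluded from the slow-change mask. A 255-level
#'   fade over 191 steps moves at most 2 levels per frame, while
#'   quick-change glyphs and fixation overlays jump by tens of levels, so
#'   the default of 4 cleanly separates the two without knowing the feature
#'   geometry.
#' @returns A `qc_report` list: `duration_s`, `fps`, `n_frames`,
#'   `breakpoints` (lead/morph/tail frame counts), per-channel `slope` and
#'   `r_squared` over the morph segment, `onsets` tibble, `start_rgb`,
#'   `end_rgb`, `trajectory` tibble, and a `checks` tibble with one row per
#'   enabled check. Non-monotone trajectories fail the `monotone` check
#'   with a diagnostic rather than raising an error.
#' @export
validate_video <- function(path, manifest = NULL, tol = 0, onset_tol = 1,
                           abrupt_tol = 4) {
  seq <- if (inherits(path, "frame_sequence")) path else decode_video(path)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  frames <- seq$frames
  n <- length(frames)
  exclude <- list()
  if (!is.null(manifest$feature_bboxes)) {
    exclude <- lapply(seq_len(nrow(manifest$feature_bboxes)), function(i)
      unlist(manifest$feature_bboxes[i, c("x0", "y0", "x1", "y1")]))
  }
  mask <- tryCatch(
    derive_region_mask(frames[[1L]], frames[[n]], exclude_boxes = exclude,
                       tol = tol),
    error = function(e) NULL)
  if (is.null(mask)) {
    checks <- tibble::tibble(
      check = "morph_segment_found", pass = FALSE,
      detail = "no morph segment found: first and last frames are identical within tol")
    return(structure(list(duration_s = n / seq$fps, fps = seq$fps, n_frames = n,
                          breakpoints = c(lead = NA_integer_, morph = NA_integer_,
                                          tail = NA_integer_),
                          slope = NULL, r_squared = NULL, onsets = NULL,
                          start_rgb = NULL, end_rgb = NULL, trajectory = NULL,
                          checks = checks, pass = FALSE),
                     class = "qc_report"))
  }
  # drop pixels that ever change abruptly (quick-change features, fixation
  # overlays): only gradually fading pixels belong to the slow-change mask
  abrupt <- matrix(FALSE, nrow(mask), ncol(mask))
  for (t in 2:n) {
    dmax <- pmax(abs(frames[[t]][, , 1L] - frames[[t - 1L]][, , 1L]),
                 abs(frames[[t]][, , 2L] - frames[[t - 1L]][, , 2L]),
                 abs(frames[[t]][, , 3L] - frames[[t - 1L]][, , 3L]))
    abrupt <- abrupt | (dmax > abrupt_tol)
  }
  mask <- mask & !abrupt
  if (!any(mask)) {
    checks <- tibble::tibble(
      check = "morph_segment_found", pass = FALSE,
      detail = "no gradually changing pixels: every changing pixel jumps abruptly")
    return(structure(list(duration_s = n / seq$fps, fps = seq$fps, n_frames = n,
                          breakpoints = c(lead = NA_integer_, morph = NA_integer_,
                                          tail = NA_integer_),
                          slope = NULL, r_squared = NULL, onsets = NULL,
                          start_rgb = NULL, end_rgb = NULL, trajectory = NULL,
                          checks = checks, pass = FALSE),
                     class = "qc_report"))
  }
  traj <- t(vapply(frames, region_mean_rgb, numeric(3), mask = mask))
  y <- rowMeans(traj)
  fit <- fit_flat_linear_flat(y)
  lead <- fit$b1; morph <- fit$b2 - fit$b1 + 1L; tail_n <- n - fit$b2 - 1L
  morph_idx <- (fit$b1 + 1L):(fit$b2 + 1L)
  tm <- morph_idx - 1
  slope <- numeric(3); r2 <- numeric(3)
  for (ch in 1:3) {
    yy <- traj[morph_idx, ch]
    if (stats::var(yy) < 1e-12) { slope[ch] <- 0; r2[ch] <- NA_real_; next }
    f <- stats::lm.fit(cbind(1, tm), yy)
    slope[ch] <- f$coefficients[2L]
    r2[ch] <- 1 - sum(f$residuals^2) / sum((yy - mean(yy))^2)
  }
  names(slope) <- names(r2) <- c("R", "G", "B")
  mono_dir <- sign(traj[fit$b2 + 1L, ] - traj[fit$b1 + 1L, ])
  dtraj <- apply(traj[morph_idx, , drop = FALSE], 2, diff)
  monotone <- all(vapply(1:3, function(ch)
    all(mono_dir[ch] * dtraj[, ch] >= -1e-9), logical(1)))
  onsets <- recover_onsets(frames, probe = abrupt,
                           morph_range = c(fit$b1 + 1L, fit$b2))
  start_rgb <- region_mean_rgb(frames[[1L]], mask)
  end_rgb <- region_mean_rgb(frames[[n]], mask)

  checks <- tibble::tibble(check = character(0), pass = logical(0),
                           detail = character(0))
  add <- function(check, pass, detail) {
    checks <<- dplyr::bind_rows(checks, tibble::tibble(
      check = check, pass = pass, detail = detail))
  }
  add("morph_segment_found", morph >= 2 && abs(y[fit$b2 + 1L] - y[fit$b1 + 1L]) > tol,
      sprintf("lead=%d morph=%d tail=%d", lead, morph, tail_n))
  add("monotone", monotone,
      if (monotone) "region means monotone over morph segment"
      else "non-monotone region-mean trajectory in morph segment")
  # judge linearity on the channel with the largest color excursion: in a
  # channel whose endpoints differ by only a few 8-bit levels, rounding
  # quantization dominates the trajectory and R^2 is uninformative
  best_ch <- which.max(abs(end_rgb - start_rgb))
  add("linear_fit", isTRUE(r2[best_ch] >= 0.999),
      sprintf("R^2 (R,G,B) = %s; judged on largest-excursion channel %s",
              paste(round(r2, 5), collapse = ", "), names(r2)[best_ch]))
  if (!is.null(manifest)) {
    cfg <- manifest$config
    add("breakpoints",
        lead == cfg$n_lead && morph == cfg$n_morph && tail_n == cfg$n_tail,
        sprintf("observed %d/%d/%d, expected %d/%d/%d",
                lead, morph, tail_n, cfg$n_lead, cfg$n_morph, cfg$n_tail))
    sched <- manifest$schedule
    exp_on <- sort(sched$onset_frame) + cfg$n_lead   # sequence frame index
    got_on <- sort(onsets$onset_frame)
    ok <- length(exp_on) == length(got_on) &&
      (length(exp_on) == 0L || all(abs(got_on - exp_on) <= onset_tol))
    add("quick_change_onsets", ok,
        sprintf("recovered [%s], expected [%s] (+/-%d)",
                paste(got_on, collapse = ","),
                paste(exp_on, collapse = ","), onset_tol))
    if (!is.null(manifest$start_rgb)) {
      ok_col <- all(abs(start_rgb - unlist(manifest$start_rgb)) <= tol + 1) &&
        all(abs(end_rgb - unlist(manifest$end_rgb)) <= tol + 1)
      add("endpoint_colors", ok_col,
          sprintf("start (%s) vs nominal (%s)",
                  paste(round(start_rgb, 1), collapse = ","),
                  paste(round(unlist(manifest$start_rgb), 1), collapse = ",")))
    }
    if (!is.null(manifest$frame_checksums) &&
        length(manifest$frame_checksums) == n) {
      sums <- vapply(frames, frame_checksum, "")
      add("frame_checksums", identical(sums, unlist(manifest$frame_checksums)),
          "md5 of decoded frames vs manifest")
    }
  }
  structure(list(duration_s = n / seq$fps, fps = seq$fps, n_frames = n,
                 breakpoints = c(lead = lead, morph = morph, tail = tail_n),
                 slope = slope, r_squared = r2,
                 onsets = onsets, start_rgb = start_rgb, end_rgb = end_rgb,
                 trajectory = tibble::tibble(
                   frame = seq_len(n) - 1L,
                   R = traj[, 1L], G = traj[, 2L], B = traj[, 3L]),
                 checks = checks, pass = all(checks$pass)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %.1f s @ %g fps (%d frames): lead %d / morph %d / tail %d\n",
              x$duration_s, x$fps, x$n_frames,
              x$breakpoints["lead"], x$breakpoints["morph"], x$breakpoints["tail"]))
  if (!is.null(x$start_rgb)) {
    cat(sprintf("  region mean %s -> %s, min R^2 %.5f\n",
                paste(round(x$start_rgb), collapse = ","),
                paste(round(x$end_rgb), collapse = ","),
                min(stats::na.omit(x$r_squared))))
  }
  status <- ifelse(x$checks$pass, "PASS", "FAIL")
  cat(sprintf("  [%s] %s: %s\n", status, x$checks$check, x$checks$detail), sep = "")
  cat(if (x$pass) "  overall: PASS\n" else "  overall: FAIL\n")
  invisible(x)
}

#' Tidy and summarize QC reports
#'
#' `tidy()` returns the per-check table; `glance()` a one-row summary.
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @returns A tibble.
#' @export
tidy.qc_report <- function(x, ...) x$checks

#' @rdname tidy.qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(duration_s = x$duration_s, fps = x$fps, n_frames = x$n_frames,
                 lead = x$breakpoints[["lead"]], morph = x$breakpoints[["morph"]],
                 tail = x$breakpoints[["tail"]],
                 n_onsets = if (is.null(x$onsets)) 0L else nrow(x$onsets),
                 min_r_squared = if (is.null(x$r_squared)) NA_real_
                                 else min(stats::na.omit(x$r_squared)),
                 pass = x$pass)
}

#' Plot the region-mean trajectory of a QC report
#'
#' Shows the per-channel mean color of the slow-change region across
#' frames, with the fitted lead/morph/tail breakpoints and recovered
#' quick-change onsets.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.qc_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectory, c("R", "G", "B"),
                              names_to = "channel", values_to = "mean")
  b <- object$breakpoints
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$mean,
                                     color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(b[["lead"]], b[["lead"]] + b[["morph"]]) - 0.5,
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_vline(data = object$onsets,
                        ggplot2::aes(xintercept = .data$onset_frame),
                        linetype = "dotted", color = "grey60") +
    ggplot2::scale_color_manual(values = c(R = "#c0392b", G = "#27ae60",
                                           B = "#2980b9")) +
    ggplot2::labs(x = "frame", y = "region mean (8-bit)",
                  title = "Slow-change region trajectory",
                  subtitle = "dashed: fitted segment breakpoints; dotted: recovered quick-change onsets") +
    ggplot2::theme_minimal()
}
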