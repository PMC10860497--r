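# morphstim

Tools for generating and validating **slow change blindness** video
stimuli, and for analysing the detection data such stimuli produce.

Slow change blindness is the failure of observers to notice a large visual
change that unfolds too slowly to produce an attention-grabbing transient —
for example, the central car in a cartoon street scene gradually fading
from yellow to orange over 16 seconds. Studying the phenomenon requires
many such videos, each pairing one *slow* change of interest with one to
three *quick* (1 s) changes. The quick changes give experimenters a
credible reason to ask "did you notice any changes?" after every trial
without revealing that a slow change occurred, and keep participants
engaged across repeated trials.

`morphstim` implements the full pipeline for R:

- **Scene synthesis** — procedural cartoon-like scenes with one large
  central colored region (the slow-change element, optionally textured so
  its pixels are not all identical) and small togglable features (arrow,
  bar, dot-cluster glyphs), rendered in every combination of color and
  feature state (`scene_spec()`, `render_scene()`, `emit_composite_set()`).
- **Composite set I/O** — the `Img#_Color_quickChangeState.{png,jpg}`
  naming convention: `2^(k+1)` co-registered images for `k` binary quick
  features (`parse_composite_name()`, `load_composite_set()`).
- **Morph engine** — for each quick-state combination, a *morph series*
  interpolating the two colors linearly in RGB:

  frame *i* of *n*, per pixel and channel:
  `round(start + (i/(n-1)) * (end - start))`

  By default 192 morph frames at 12 frames/s (a 16 s fade), bookended by
  2 s of the unchanging first and last frames: a 240-frame, 20 s video.
  Quick changes are scheduled at uniformly random feasible moments within
  the morph and realized as 12-frame cross-fades between the pre- and
  post-state series (`morph_config()`, `build_morph_series()`,
  `schedule_quick_changes()`, `assemble_frames()`), with an optional
  central fixation mark and full-image cross-hair for the bookends
  (`fixation_overlay()`).
- **Video encoding** — a built-in AVI muxer/demuxer: uncompressed RGB24
  (bit-exact round trips, the QC default) or MJPEG, plus a JSON manifest
  sidecar (config, schedule, per-frame md5 checksums) from which any
  stimulus can be regenerated bit-exactly (`encode_video()`,
  `decode_video()`, `generate_stimulus()`, `regenerate_stimulus()`,
  `generate_battery()`).
- **Quality control** — a frame-accurate validator that recovers the
  generation parameters from pixels: flat–linear–flat changepoint fit of
  the region-mean color trajectory (lead/morph/tail breakpoints), linearity
  R², quick-change onsets from frame-difference energy, endpoint
  colorimetry (`validate_video()`, `derive_region_mask()`,
  `region_mean_rgb()`; `tidy()`, `glance()`, `autoplot()` methods).
- **Detection statistics** — ingestion of manually coded trial responses
  and the analyses standard for such experiments: detection proportions,
  pooled two-proportion z test, paired t, one-way repeated-measures ANOVA,
  Pearson correlation — all returning tidy one-row tibbles
  (`read_responses()`, `detection_table()`, `detection_proportion()`,
  `two_proportion_z()`, `paired_t()`, `rm_anova_oneway()`, `pearson_r()`).

## Worked example

```r
library(morphstim)

# a demo scene: textured central ellipse + 3 quick-change features
spec <- demo_scene_spec(n_features = 3)                  # 480 x 480 canvas
set  <- build_composite_set(spec, image_id = 1,
                            colors = list(Yellow = c(233, 212, 80),
                                          Orange = c(227, 134, 61)))
set
#> <composite_set> Img1: 480x480 px, colors Yellow -> Orange, 3 feature(s), 16 images

cfg <- morph_config(seed = 42)           # 12 fps, 2 s + 16 s + 2 s, 3 quick changes
man <- generate_stimulus(set, "demo.avi", cfg)
man$schedule
#> # A tibble: 3 x 6
#>   feature_index feature onset_frame duration_frames from_state to_state
#>           <int> <chr>         <int>           <int> <chr>      <chr>
#> 1             1 1                73              12 Left       Right
#> 2             2 2               121              12 Flat       Tall
#> 3             3 3               145              12 Here       Gone

validate_video("demo.avi", manifest = "demo.avi.json")
#> <qc_report> 20.0 s @ 12 fps (240 frames): lead 24 / morph 192 / tail 24
#>   region mean 233,212,80 -> 227,134,61, min R^2 0.97
#>   [PASS] morph_segment_found: lead=24 morph=192 tail=24
#>   [PASS] monotone: region means monotone over morph segment
#>   [PASS] linear_fit: ... judged on largest-excursion channel G
#>   [PASS] breakpoints: observed 24/192/24, expected 24/192/24
#>   [PASS] quick_change_onsets: recovered [97,145,169], expected [97,145,169] (+/-1)
#>   [PASS] endpoint_colors: start (233,212,80) vs nominal (233,212,80)
#>   [PASS] frame_checksums: md5 of decoded frames vs manifest
#>   overall: PASS
```

The schedule shows each quick change's onset as a 0-based morph-frame
index (e.g. 73 ≙ 6.1 s into the fade, 8.1 s into the video); the QC report
confirms the decoded video has exactly 24 unchanging lead frames, a
192-frame linear color fade, 24 tail frames, and quick changes where the
manifest says they are. Counting statistics work the same way on coded
response tables:

```r
detection_proportion(4, 174)     #> 0.023  (4 detected slow changes in 174 trials)
rm_anova_oneway(matrix(runif(55), nrow = 11, ncol = 5))[, c("df1", "df2")]
#>     df1   df2
#>       4    40
```

A thin command-line front end (subcommands `synth`, `generate`, `batch`,
`validate`, `stats`) is installed at
`system.file("cli", "morphstim", package = "morphstim")`.

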