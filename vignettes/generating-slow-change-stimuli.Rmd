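---
title: "Generating and validating slow change blindness stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and validating slow change blindness stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphstim)
```

## The stimulus model

A slow-change stimulus is a short video of a static cartoon-like scene in
which one large, centrally located element — a car, a wall, a floor —
gradually fades from a start color to an end color, so slowly that
observers routinely fail to notice. To let experimenters ask about
"changes" on every trial without revealing the slow change, each video
also embeds one to three *quick changes*: small features (an object
added/removed, rotated, or altered) that flip state over one second at a
random moment during the fade.

The timing model, held by `morph_config()`, is:

| parameter | default | meaning |
|---|---|---|
| `fps` | 12 frames/s | constant video frame rate |
| `lead_s` | 2 s | unchanging first frame, repeated |
| `morph_s` | 16 s | the slow color fade (192 frames at defaults) |
| `tail_s` | 2 s | unchanging final frame, repeated |
| `quick_change_count` | 3 | number of quick changes (0–3) |
| `quick_change_duration_s` | 1 s | each quick change's transition window |
| `min_gap_s` | 1 s | minimum separation between windows |
| `seed` | — | drives the random quick-change moments |

giving a 20 s, 240-frame video. All products — `fps * lead_s` etc. — must
be integers so every segment is a whole number of frames.

The fade operates on co-registered *composite images*: for `k` binary
quick-change features, `2^(k+1)` renderings of the scene (two slow-change
colors x every feature-state combination), named
`Img<id>_<Color>[_<state>...]`. For each state combination the engine
builds a *morph series* by linear interpolation of the two images' 8-bit
RGB values: frame $i$ of $n$ is, per pixel and channel,

$$\mathrm{round}\!\left(\mathrm{start} + \tfrac{i}{n-1}(\mathrm{end} - \mathrm{start})\right),$$

computed in floating point and rounded half-up once at the end. The
inclusive-endpoint convention makes frames 0 and $n-1$ pixel-exact copies
of the inputs, which both the bookends and the validator rely on. As the
assembler steps through the fade it draws each frame from the series whose
state combination is current at that step, so the color morph never pauses
or repeats while a quick change unfolds.

## Quick-change scheduling and transitions

Onsets are drawn uniformly over all feasible placements: each 12-frame
window must lie inside the morph segment, and windows must be separated by
at least `min_gap_s` (rejection sampling, which preserves exact uniformity
over the feasible set; the separation default keeps each quick change
individually reportable). Events are assigned to features by a uniform
random permutation. The whole schedule is a deterministic function of the
seed, and the seed is recorded in the manifest.

How the original 1 s "non-instantaneous" transition is realized is a
genuinely open design point; we implement a per-pixel linear cross-fade
between the pre-state and post-state morph series across the window, with
weight $\alpha(j) = (j+1)/d$ for window frame $j$ of $d$. This is the
simplest mechanism consistent with frame selection from parallel series:
the final window frame coincides exactly with the post-state series, and
outside the feature's bounding box the cross-fade is the identity (both
series agree there), so the blend introduces no rounding artifacts
elsewhere.

For fixation-controlled designs, `fixation_overlay()` adds a white central
dot to every lead and tail frame, and a "cross hair" of four full-image
5 px lines (horizontal, vertical, two diagonals) flashed for a
configurable 0.5 s when the dot disappears at morph onset and reappears at
morph offset — a visible signal that free viewing may begin or should end.

## The synthetic scene generator

`scene_spec()` emulates the structure that matters for the pipeline, not
the aesthetics of licensed cartoon artwork: a uniform background, one
large central region (ellipse or rounded rectangle) whose fill color is
the slow-change element, and small feature glyphs (arrow left/right, bar
horizontal/vertical, dot cluster present/absent) with disjoint bounding
boxes. Because real scenes' colored regions are shaded rather than flat, a
deterministic luminance texture — a hash of `(render_seed, x, y)` scaled
to `texture_amplitude` (default 8 levels in the demo scene) — is added
inside the region. The texture is zero-mean by construction, so the
region's mean RGB stays within ±1 of the nominal color (provided channels
keep `amplitude` away from 0 and 255, so clipping cannot bias the mean),
which keeps colorimetry checks meaningful.

What the generator deliberately does **not** emulate: anti-aliased or
soft-edged contours, semantic scene content, JPEG provenance, and
correlated shading between the slow region and its surroundings. Tests
passing on these fixtures therefore establish the pipeline's frame
arithmetic, scheduling, encoding and recovery logic — not that any
particular artwork will produce change blindness in humans.

## Video containers and manifests

Stimuli are written to AVI by a built-in muxer with two payloads:
uncompressed RGB24 (the default; bit-exact `encode_video()` →
`decode_video()` round trips, which the test suite and validator exploit)
and MJPEG via EBImage for small deployable files. Constant frame rate is
enforced. Every generated video gets a JSON manifest echoing the full
configuration, color labels and nominal RGB, the realized schedule, the
codec, and per-frame md5 checksums (lossless runs), so
`regenerate_stimulus()` can rebuild the video bit-exactly and prove it did.

MJPEG uses chroma subsampling, so its error model is uneven: on smooth
content the per-channel error stays within ~3 levels, but at sharp
color edges (ubiquitous in cartoon scenes) individual pixels can deviate
by tens of levels even at maximum quality. Lossy-mode guarantees are
therefore stated on mean error and on region means (a boundary-diluted
statistic), and the validator's lossy tolerances (±3 on endpoint region
means, ±2 frames on onsets) assume a canvas large enough that region
boundaries are a small fraction of region area.

## The validator

`validate_video()` recovers generation parameters from pixels alone:

1. **Region mask.** Pixels whose values differ between the first and last
   frame, minus any feature boxes the manifest declares, minus every pixel
   that ever changes *abruptly* (more than `abrupt_tol = 4` levels between
   consecutive frames). A 255-level fade spread over 191 steps moves at
   most ~2 levels per frame, while quick-change glyphs and fixation
   overlays jump by tens of levels, so this separates slow from quick
   pixels without knowing the scene geometry.
2. **Breakpoints.** The per-frame mean RGB over the mask is fit with a
   continuity-constrained flat–linear–flat changepoint model by exhaustive
   search over integer breakpoint pairs (sequences are a few hundred
   frames; prefix sums make the search O(n²) and deterministic, ties
   broken toward the longest linear segment). Anchoring the line to the
   flat levels makes the breakpoints sharply identifiable even though
   rounding quantization duplicates the first/last morph frames; by
   convention the morph segment includes its endpoint copies of the
   bookend frames, so a default stimulus reports lead/morph/tail =
   24/192/24.
3. **Linearity.** Per-channel slope and R² over the morph segment. The
   pass criterion uses the channel with the largest color excursion: in a
   channel whose endpoints differ by only a few 8-bit levels, quantization
   dominates and R² is uninformative (the R channel of a yellow–orange
   fade moves 6 levels in 192 frames).
4. **Quick-change onsets.** Frame-to-frame mean absolute difference over
   the abrupt-pixel set. Events are declared when the peak exceeds 5x the
   morph-segment median (plus a small absolute floor of 0.05 for noiseless
   synthetic video whose baseline is exactly zero); runs are then cut at
   the lower of that level and 30% of the way from baseline to peak, so a
   whole window forms one run whether windows dwarf the baseline or barely
   clear it, and isolated spikes shorter than ~a third of the dominant
   window are discarded. On lossless self-generated stimuli, recovered
   onsets match the manifest to within one frame.

Non-monotone trajectories and missing morph segments are reported as
failed checks with diagnostics, never as exceptions, since the validator's
job includes judging malformed third-party stimuli.

## Statistics

The analysis functions mirror the standard battery for detection data.
`detection_proportion()` is plain count division (reported to 3 decimals,
matching convention). `two_proportion_z()` is the classical pooled z with
a two-sided normal p. `paired_t()` wraps `t.test(paired = TRUE)` and
defaults to one-sided (`a < b`), because the directional contrast —
adjacent color pairs yielding lower detection than distant ones — is the
typical use; the two-sided tail is a parameter away and the choice is
printed in the result. `rm_anova_oneway()` fits the within-subject ANOVA
through `aov()` with a subject error stratum, giving
$F = MS_\text{level}/MS_\text{level x subject}$ on
$((k-1), (k-1)(n-1))$ df — $(4, 40)$ for 11 images under 5 color
conditions. `pearson_r()` wraps `cor.test()` and adds $r^2$. Free-text
response *coding* is deliberately out of scope: it is a human judgment
task, so `read_responses()` ingests a coder-filled CSV and only validates
its consistency (codes may be true only on trials where a change was
reported at all). Every test is cross-checked in the suite against an
independently written sum-of-squares or formula oracle to 1e-10.

## Numerical conventions and degenerate inputs

* Frames and morph indices are 0-based in schedules, annotations and QC
  reports; transition windows are half-open `[onset, onset + duration)`.
* Rounding is half-up, applied once per pixel per frame; interpolation and
  cross-fade weights are computed in doubles.
* Equal start and end images yield a constant (still valid) morph series;
  validation of a constant video fails cleanly with "no morph segment".
* Zero-variance paired differences, pooled proportions of 0 or 1, constant
  correlation inputs, and a zero residual mean square with a nonzero level
  effect are degenerate-input errors; a zero level effect with zero
  residual reports F = 0.
* Battery cells derive their seeds by stable string hashing of
  `(master seed, scene id, pair label)`, so adding cells never perturbs
  existing ones; each scene contributes its own feature count (1–3 quick
  changes per video), as in a realistic battery.

## Problem sizes used by the tests

Pixel-exhaustive unit tests run on 48–64 px canvases; the acceptance
checks generate one full-size 480 x 480 default stimulus, a 55-video
battery (11 scenes x 5 standard color pairs) at 96 x 96, and 20
validator-recovery stimuli at 64 x 64 — sizes chosen so the full suite
exercises every code path, the battery check still covers all 55 cells,
and a complete run finishes in a couple of minutes on one core. Scheduler
uniformity is checked by chi-square goodness of fit over 10,000 seeded
draws against the 181 feasible onsets.

## Known limitations

* Only color changes in a single region are morphed; shape or position
  morphs would create implausible intermediate states and are out of
  scope, as is more than one slow-change region per stimulus.
* The MJPEG path's pointwise error at sharp edges (above) makes lossless
  AVI the only mode with bit-exact guarantees.
* Colorimetry checks assert self-consistency (video vs. its composite
  inputs), not agreement with any display-calibrated color standard.
* The validator assumes one slow region and non-overlapping quick-change
  windows; heavily overlapping third-party designs would need the
  windowing assumptions relaxed.
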