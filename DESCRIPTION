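Package: morphstim
Title: Generation and Validation of Slow Change Blindness Video Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A semi-automatic pipeline for creating slow change blindness
    video stimuli: cartoon-like scenes whose large central region fades
    between two colors over 16 seconds by linear RGB interpolation, with
    1-3 easily noticed 1-second "quick" feature changes embedded at random
    moments. Includes a procedural synthetic-scene renderer that emits the
    composite image sets the pipeline consumes, a parser for the
    Img#_Color_quickChangeState naming convention, a morph engine that
    assembles 20-second frame sequences (2 s lead, 16 s morph at 12 fps,
    2 s tail) with optional fixation-mark overlays, a built-in AVI
    encoder/decoder (lossless raw RGB and MJPEG) with reproducibility
    manifests, a frame-accurate validator that recovers generation
    parameters from pixels, and the detection-rate statistics used to
    analyse coded observer responses (proportions, paired t, one-way
    repeated-measures ANOVA, two-proportion z, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
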