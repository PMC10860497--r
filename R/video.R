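# --- Minimal AVI (RIFF) muxer/demuxer -------------------------------------
#
# Two codecs are supported, both standard AVI payloads:
#   * "rawrgb": uncompressed 24-bit BI_RGB DIB frames (BGR, bottom-up,
#     4-byte row stride) -> bit-exact round trips; the QC default.
#   * "mjpeg": one baseline JPEG per frame ('MJPG') via EBImage -> small
#     files for deployment, lossy.
# Constant frame rate only; a per-stream idx1 index is always written.

u32 <- function(x) {
  x <- ifelse(x > .Machine$integer.max, x - 4294967296, x)  # two's complement
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
fourcc <- function(s) charToRaw(s)

chunk <- function(id, data) {
  pad <- if (length(data) %% 2L == 1L) as.raw(0L) else raw(0)
  c(fourcc(id), u32(length(data)), data, pad)
}
riff_list <- function(type, data) chunk("LIST", c(fourcc(type), data))

# frame (h x w x 3 int array) -> DIB bytes: BGR, rows bottom-up, padded stride
pack_dib <- function(img) {
  d <- dim(img); h <- d[1L]; w <- d[2L]
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  core <- aperm(img[h:1, , 3:1, drop = FALSE], c(3L, 2L, 1L))  # (3, w, h)
  if (stride == w * 3L) return(as.raw(core))
  m <- matrix(0L, nrow = stride, ncol = h)
  m[seq_len(3L * w), ] <- core
  as.raw(as.vector(m))
}

unpack_dib <- function(bytes, w, h) {
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  m <- matrix(as.integer(bytes), nrow = stride, ncol = h)
  core <- array(m[seq_len(3L * w), ], dim = c(3L, w, h))
  arr <- aperm(core, c(3L, 2L, 1L))        # (h, w, 3), bottom-up BGR
  arr[h:1, , 3:1, drop = FALSE]
}

avi_headers <- function(w, h, fps, n_frames, codec, max_chunk) {
  raw_size <- ((w * 3L + 3L) %/% 4L) * 4L * h
  handler <- if (codec == "rawrgb") "DIB " else "MJPG"
  compression <- if (codec == "rawrgb") u32(0L) else fourcc("MJPG")
  avih <- c(u32(round(1e6 / fps)), u32(raw_size * ceiling(fps)), u32(0L),
            u32(0x10L),                       # AVIF_HASINDEX
            u32(n_frames), u32(0L), u32(1L), u32(max_chunk),
            u32(w), u32(h), u32(0L), u32(0L), u32(0L), u32(0L))
  strh <- c(fourcc("vids"), fourcc(handler), u32(0L), u16(0L), u16(0L),
            u32(0L), u32(1000L), u32(round(fps * 1000)), u32(0L),
            u32(n_frames), u32(max_chunk), u32(-1L), u32(0L),
            u16(0L), u16(0L), u16(w), u16(h))
  strf <- c(u32(40L), u32(w), u32(h), u16(1L), u16(24L), compression,
            u32(raw_size), u32(0L), u32(0L), u32(0L), u32(0L))
  riff_list("hdrl", c(chunk("avih", avih),
                      riff_list("strl", c(chunk("strh", strh),
                                          chunk("strf", strf)))))
}

#' Encode a frame sequence to an AVI video
#'
#' Writes the frames to a constant-frame-rate AVI using the package's
#' built-in muxer. `codec = "lossless"` stores uncompressed RGB frames and
#' round-trips bit-exactly through [decode_video()]; `codec = "lossy"`
#' stores one JPEG per frame (MJPEG; requires EBImage).
#'
#' @param seq A `frame_sequence`, a plain list of integer RGB frames, or a
#'   function `f(t)` returning the 0-based frame `t` (supply `n_frames` and
#'   `fps` in that case; this streams frames without materializing them).
#' @param path Output file path (conventionally `.avi`).
#' @param codec `"lossless"` (default) or `"lossy"`.
#' @param fps,n_frames Required only when `seq` is a generator function.
#' @param quality JPEG quality for the lossy codec.
#' @param checksums If `TRUE` (default for lossless), compute an md5
#'   checksum of each frame's raw RGB bytes for the manifest.
#' @returns Invisibly, a list with `path`, `codec`, `lossless`, `fps`,
#'   `n_frames`, `width`, `height` and `frame_checksums` (or `NULL`).
#' @export
encode_video <- function(seq, path, codec = c("lossless", "lossy"),
                         fps = NULL, n_frames = NULL, quality = 95,
                         checksums = NULL) {
  codec <- match.arg(codec)
  inner <- if (codec == "lossless") "rawrgb" else "mjpeg"
  if (inherits(seq, "frame_sequence")) {
    fps <- seq$fps; n_frames <- length(seq$frames)
    get_frame <- function(t) seq$frames[[t + 1L]]
  } else if (is.list(seq)) {
    if (is.null(fps)) stop("fps required for a plain frame list", call. = FALSE)
    n_frames <- length(seq)
    get_frame <- function(t) seq[[t + 1L]]
  } else if (is.function(seq)) {
    if (is.null(fps) || is.null(n_frames)) {
      stop("fps and n_frames are required with a frame generator", call. = FALSE)
    }
    get_frame <- function(t) seq(t)
  } else stop("seq must be a frame_sequence, list of frames, or generator",
              call. = FALSE)
  if (n_frames < 1L) stop("cannot encode an empty sequence", call. = FALSE)
  if (inner == "mjpeg" && !requireNamespace("EBImage", quietly = TRUE)) {
    stop("lossy (MJPEG) encoding requires the EBImage package; use codec = 'lossless'",
         call. = FALSE)
  }
  if (is.null(checksums)) checksums <- codec == "lossless"

  first <- get_frame(0L)
  assert_image_rgb(first, "frame")
  d <- dim(first); h <- d[1L]; w <- d[2L]
  tmp_jpg <- if (inner == "mjpeg") tempfile(fileext = ".jpg")
  sums <- if (checksums) character(n_frames)

  con <- file(path, "w+b")
  on.exit(close(con), add = TRUE)
  pos <- 0L
  put <- function(bytes) { writeBin(bytes, con); pos <<- pos + length(bytes) }
  put(c(fourcc("RIFF"), u32(0L), fourcc("AVI ")))
  hdr_pos <- pos
  put(avi_headers(w, h, fps, n_frames, inner, 0L))
  movi_pos <- pos
  put(c(fourcc("LIST"), u32(0L), fourcc("movi")))
  offsets <- integer(n_frames); sizes <- integer(n_frames)
  max_chunk <- 0L
  for (t in seq_len(n_frames) - 1L) {
    img <- if (t == 0L) first else get_frame(t)
    if (!identical(dim(img), d)) stop("frame dimensions changed mid-sequence",
                                      call. = FALSE)
    payload <- if (inner == "rawrgb") {
      pack_dib(img)
    } else {
      write_image_rgb(img, tmp_jpg, quality = quality)
      readBin(tmp_jpg, "raw", file.size(tmp_jpg))
    }
    if (checksums) sums[t + 1L] <- frame_checksum(img)
    offsets[t + 1L] <- pos - (movi_pos + 8L)   # from 'movi' fourcc
    sizes[t + 1L] <- length(payload)
    max_chunk <- max(max_chunk, length(payload))
    put(chunk(if (inner == "rawrgb") "00db" else "00dc", payload))
  }
  end_movi <- pos
  idx <- do.call(c, lapply(seq_len(n_frames), function(i)
    c(fourcc(if (inner == "rawrgb") "00db" else "00dc"),
      u32(0x10L), u32(offsets[i]), u32(sizes[i]))))
  put(chunk("idx1", idx))
  file_end <- pos
  # patch the deferred sizes
  seek(con, 4, origin = "start", rw = "write")
  writeBin(u32(file_end - 8L), con)
  seek(con, hdr_pos, origin = "start", rw = "write")
  writeBin(avi_headers(w, h, fps, n_frames, inner, max_chunk), con)
  seek(con, movi_pos + 4L, origin = "start", rw = "write")
  writeBin(u32(end_movi - movi_pos - 8L), con)
  invisible(list(path = path, codec = inner, lossless = codec == "lossless",
                 fps = fps, n_frames = n_frames, width = w, height = h,
                 frame_checksums = sums))
}

# md5 of the frame's raw RGB bytes (channel-major per pixel, row-major)
frame_checksum <- function(img) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(as.raw(aperm(img, c(3L, 2L, 1L))), tf)
  unname(tools::md5sum(tf))
}

read_u32 <- function(b, pos) {
  v <- as.numeric(b[pos]) + 256 * as.numeric(b[pos + 1L]) +
    65536 * as.numeric(b[pos + 2L]) + 16777216 * as.numeric(b[pos + 3L])
  v
}

#' Decode an AVI video into frames
#'
#' Reads an AVI written by [encode_video()] (or any constant-frame-rate AVI
#' with an uncompressed RGB24 or MJPEG video stream) back into 8-bit RGB
#' frames. Truncated files raise an error rather than returning a silent
#' short read.
#'
#' @param path AVI file path.
#' @returns A `frame_sequence` (without segment annotations) whose `fps`
#'   comes from the container's stream header.
#' @export
decode_video <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 24) stop("not a readable AVI file", call. = FALSE)
  b <- readBin(path, "raw", n)
  if (rawToChar(b[1:4]) != "RIFF" || rawToChar(b[9:12]) != "AVI ") {
    stop("not an AVI (RIFF) file", call. = FALSE)
  }
  declared <- read_u32(b, 5L)
  if (declared + 8 > n) stop("truncated AVI: file shorter than RIFF size",
                             call. = FALSE)
  w <- NULL; h <- NULL; fps <- NULL; codec <- NULL; n_frames <- NULL
  frames <- list()
  pos <- 13L
  parse_chunks <- function(pos, end) {
    while (pos + 8L <= end + 1L) {
      id <- rawToChar(b[pos:(pos + 3L)])
      sz <- read_u32(b, pos + 4L)
      body <- pos + 8L
      if (body + sz - 1L > n) stop("truncated AVI: chunk exceeds file",
                                   call. = FALSE)
      if (id == "LIST") {
        parse_chunks(body + 4L, body + sz - 1L)
      } else if (id == "avih") {
        if (is.null(fps)) fps <<- 1e6 / read_u32(b, body)
      } else if (id == "strh") {
        if (rawToChar(b[body:(body + 3L)]) == "vids") {
          scale <- read_u32(b, body + 20L); rate <- read_u32(b, body + 24L)
          if (scale > 0) fps <<- rate / scale
          n_frames <<- read_u32(b, body + 32L)
        }
      } else if (id == "strf") {
        w <<- read_u32(b, body + 4L); h <<- read_u32(b, body + 8L)
        comp <- read_u32(b, body + 16L)
        codec <<- if (comp == 0) "rawrgb"
                  else if (rawToChar(b[(body + 16L):(body + 19L)]) == "MJPG") "mjpeg"
                  else stop("unsupported AVI codec", call. = FALSE)
      } else if (id %in% c("00db", "00dc")) {
        payload <- b[body:(body + sz - 1L)]
        frames[[length(frames) + 1L]] <<- payload
      }
      pos <- body + sz + (sz %% 2L)
    }
  }
  parse_chunks(pos, min(n, declared + 8))
  if (is.null(w) || is.null(codec)) stop("no video stream header found",
                                         call. = FALSE)
  if (!is.null(n_frames) && length(frames) < n_frames) {
    stop(sprintf("truncated AVI: header declares %d frames, found %d",
                 n_frames, length(frames)), call. = FALSE)
  }
  decoded <- if (codec == "rawrgb") {
    lapply(frames, unpack_dib, w = as.integer(w), h = as.integer(h))
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("decoding MJPEG requires the EBImage package", call. = FALSE)
    }
    tmp <- tempfile(fileext = ".jpg")
    on.exit(unlink(tmp))
    lapply(frames, function(p) {
      writeBin(p, tmp)
      suppressWarnings(read_image_rgb(tmp))
    })
  }
  structure(list(fps = fps, frames = decoded, annotations = NULL),
            class = "frame_sequence")
}

#' Write and read stimulus manifests
#'
#' A manifest is the JSON sidecar written next to every generated video.
#' It echoes the full timing configuration, the scene/color inputs, the
#' realized quick-change schedule, the codec, and (for lossless runs) a
#' per-frame checksum list, so that [regenerate_stimulus()] can rebuild the
#' video bit-exactly from the manifest plus the composite images.
#'
#' @param manifest A `stimulus_manifest` list (built by
#'   [generate_stimulus()]).
#' @param path JSON path.
#' @returns `read_manifest()` returns the manifest list; `write_manifest()`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(m$schedule) && length(m$schedule) > 0) {
    m$schedule <- tibble::as_tibble(m$schedule)
  } else {
    m$schedule <- tibble::tibble(feature_index = integer(0), feature = character(0),
                                 onset_frame = integer(0), duration_frames = integer(0))
  }
  m
}
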