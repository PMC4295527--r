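#' Ordered stimulus frame sets
#'
#' A `frame_set` holds an ordered list of 2-D grayscale rasters with
#' intensities in \[0, 1\], all resized to a single common size so that
#' per-frame feature vectors have identical length across the stimulus set.
#'
#' @param frames list of numeric matrices (intensity rasters).
#' @param frame_ids optional character labels, one per frame.
#' @param common_size integer `(height, width)` all frames are resized to;
#'   defaults to the size of the first frame.
#' @return An object of class `frame_set` with elements `frames`,
#'   `frame_ids` and `common_size`.
#' @export
frame_set <- function(frames, frame_ids = NULL, common_size = NULL) {
  if (!is.list(frames) || length(frames) < 2)
    stop("a frame_set needs at least 2 frames")
  if (is.null(common_size)) common_size <- dim(frames[[1]])
  common_size <- as.integer(common_size)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (!all(is.finite(f))) stop("frame intensities must be finite")
    if (!identical(dim(f), common_size))
      f <- resize_bilinear(f, common_size[1], common_size[2])
    pmin(pmax(f, 0), 1)
  })
  if (is.null(frame_ids))
    frame_ids <- sprintf("frame_%04d", seq_along(frames))
  structure(list(frames = frames, frame_ids = as.character(frame_ids),
                 common_size = common_size),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d frames, %d x %d\n", length(x$frames),
              x$common_size[1], x$common_size[2]))
  invisible(x)
}

#' @export
length.frame_set <- function(x) length(x$frames)

#' Generate synthetic stimulus frames with scene-class structure
#'
#' Emulates a stimulus set of dynamic natural scenes with three visually
#' distinct scene classes -- oriented gratings, low-pass filtered noise
#' textures, and composite "landscape" patches (sky gradient, textured
#' ground, rectangular structures) -- assigned cyclically, so that both
#' Gabor/HMAX and SIFT/BoW representational dissimilarity matrices have
#' exploitable geometry (within-class distances below between-class
#' distances on average). Deterministic per seed.
#'
#' @param n_frames number of frames (>= 2); the reference stimulus set in
#'   this line of work has 290 frames.
#' @param size integer `(height, width)`, each >= 64 so descriptor
#'   geometry (16 px SIFT patches, 11 px Gabor filters over a 10-level
#'   pyramid) fits.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return A [frame_set].
#' @examples
#' fs <- generate_frames(6, size = c(64, 64), seed = 1)
#' @export
generate_frames <- function(n_frames = 290, size = c(128, 128), seed = 1) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (any(size < 64))
    stop("frame size must be at least 64 x 64 to fit descriptor geometry")
  h <- size[1]; w <- size[2]
  with_rng(seed, {
    classes <- rep_len(c("grating", "texture", "scene"), n_frames)
    frames <- lapply(seq_len(n_frames), function(i) {
      switch(classes[i],
             grating = synth_grating(h, w),
             texture = synth_texture(h, w),
             scene   = synth_scene(h, w))
    })
    fs <- frame_set(frames, common_size = c(h, w))
    fs$classes <- classes
    fs
  })
}

synth_grating <- function(h, w) {
  theta <- pi / 6 + stats::runif(1, -0.2, 0.2)
  lambda <- stats::runif(1, 8, 16)
  phase <- stats::runif(1, 0, 2 * pi)
  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)
  u <- cos(theta) * xg + sin(theta) * yg
  g <- 0.5 + 0.4 * sin(2 * pi * u / lambda + phase)
  g + matrix(stats::rnorm(h * w, 0, 0.02), h, w)
}

synth_texture <- function(h, w) {
  sdp <- stats::runif(1, 2, 4)
  n <- matrix(stats::rnorm(h * w), h, w)
  r <- ceiling(3 * sdp)
  k1 <- exp(-((-r:r)^2) / (2 * sdp^2)); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  sm <- conv2_mirror(n, kern)
  sm <- (sm - min(sm)) / max(max(sm) - min(sm), 1e-12)
  0.2 + 0.6 * sm
}

synth_scene <- function(h, w) {
  horizon <- round(h * stats::runif(1, 0.4, 0.6))
  img <- matrix(0.5, h, w)
  # sky: smooth vertical gradient
  img[seq_len(horizon), ] <- matrix(
    rep(seq(0.85, 0.55, length.out = horizon), times = w), horizon, w)
  # ground: darker rough texture
  gh <- h - horizon
  gnd <- matrix(stats::rnorm(gh * w), gh, w)
  k <- outer(stats::dnorm(-4:4, sd = 1.5), stats::dnorm(-4:4, sd = 1.5))
  k <- k / sum(k)
  gnd <- conv2_mirror(gnd, k)
  gnd <- 0.35 + 0.1 * gnd / max(stats::sd(gnd), 1e-12)
  img[(horizon + 1):h, ] <- gnd
  # structures: a few dark rectangles rising from the horizon
  for (b in seq_len(sample(2:4, 1))) {
    bw <- sample(round(w / 16):round(w / 6), 1)
    bh <- sample(round(h / 8):round(h / 3), 1)
    x0 <- sample(seq_len(max(w - bw, 1)), 1)
    top <- max(horizon - bh, 1)
    img[top:horizon, x0:(x0 + bw - 1)] <- stats::runif(1, 0.05, 0.25)
  }
  pmin(pmax(img, 0), 1)
}

#' Write and read frame sets as PNG directories
#'
#' `write_frames()` exports each frame as an 8-bit grayscale PNG plus a
#' JSON manifest recording order, size and provenance; `read_frames()`
#' ingests a directory of raster images (resizing to a common size).
#'
#' @param fs a [frame_set].
#' @param dir output (input) directory.
#' @param meta optional list stored in the manifest (e.g. seed).
#' @return `write_frames()` the manifest path, invisibly; `read_frames()`
#'   a [frame_set].
#' @export
write_frames <- function(fs, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.png", fs$frame_ids)
  for (i in seq_along(fs$frames))
    png::writePNG(fs$frames[[i]], file.path(dir, files[i]))
  manifest <- c(list(frame_files = files, common_size = fs$common_size),
                meta)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_frames
#' @param common_size target `(height, width)`; defaults to the first
#'   frame's size (or the manifest's, when present).
#' @export
read_frames <- function(dir, common_size = NULL) {
  mp <- file.path(dir, "manifest.json")
  if (file.exists(mp)) {
    manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
    files <- file.path(dir, manifest$frame_files)
    if (is.null(common_size)) common_size <- manifest$common_size
  } else {
    files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  }
  if (length(files) < 2) stop("no frames found in ", dir)
  bad <- files[!file.exists(files)]
  if (length(bad)) stop("unreadable frame file: ", bad[1])
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  frame_set(frames,
            frame_ids = sub("\\.png$", "", basename(files)),
            common_size = common_size)
}
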