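#' Gabor filter bank for the S1 layer
#'
#' Builds `n_orientations` even-symmetric Gabor filters of a fixed pixel
#' size. Each filter is made exactly zero-mean and L2-normalized, so a
#' constant image yields (numerically) zero S1 response. The same bank is
#' applied at every pyramid level; scale selectivity comes from image
#' downsampling, not from rescaling the filters.
#'
#' @param n_orientations number of equally spaced orientations (default 4:
#'   0, 45, 90, 135 degrees).
#' @param size odd filter side in pixels (default 11).
#' @param wavelength carrier wavelength in pixels (default `0.8 * size`).
#' @param sigma Gaussian envelope sd in pixels (default `0.4 * size`).
#' @param aspect envelope aspect ratio gamma (default 0.3).
#' @return An object of class `gabor_bank`: list of filter matrices plus
#'   the generating parameters.
#' @export
gabor_bank <- function(n_orientations = 4, size = 11,
                       wavelength = 0.8 * size, sigma = 0.4 * size,
                       aspect = 0.3) {
  stopifnot(size %% 2 == 1, n_orientations >= 1)
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, each = size), size, size)   # column coord
  ys <- matrix(rep(-half:half, times = size), size, size)  # row coord
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  filters <- lapply(thetas, function(th) {
    xp <- xs * cos(th) + ys * sin(th)
    yp <- -xs * sin(th) + ys * cos(th)
    g <- exp(-(xp^2 + (aspect * yp)^2) / (2 * sigma^2)) *
      cos(2 * pi * xp / wavelength)
    g <- g - mean(g)
    g / sqrt(sum(g^2))
  })
  structure(list(filters = filters, thetas = thetas,
                 n_orientations = n_orientations, size = size,
                 wavelength = wavelength, sigma = sigma, aspect = aspect),
            class = "gabor_bank")
}

#' Multi-scale image pyramid
#'
#' Level 1 is the input frame; each subsequent level is a bilinear
#' downsampling by a fixed factor (default `2^(-1/4)`, so 10 levels span
#' about 4.75 octaves). Level sizes follow the closed form
#' `ceiling(size * factor^(level - 1))`.
#'
#' @param frame numeric intensity matrix.
#' @param n_levels number of pyramid levels (default 10).
#' @param factor per-level downsampling factor in (0, 1).
#' @param min_side smallest admissible level side (default 11, the S1
#'   filter size).
#' @return List of matrices, finest first.
#' @export
build_pyramid <- function(frame, n_levels = 10, factor = 2^(-1 / 4),
                          min_side = 11) {
  d0 <- dim(frame)
  sizes <- lapply(seq_len(n_levels) - 1, function(l) ceiling(d0 * factor^l))
  small <- which(vapply(sizes, function(s) any(s < min_side), logical(1)))
  if (length(small))
    stop(sprintf(
      "frame %dx%d too small: pyramid level %d would be %dx%d (< %d px)",
      d0[1], d0[2], small[1], sizes[[small[1]]][1], sizes[[small[1]]][2],
      min_side))
  out <- vector("list", n_levels)
  out[[1]] <- frame
  for (l in 2:n_levels)
    out[[l]] <- resize_bilinear(frame, sizes[[l]][1], sizes[[l]][2])
  out
}

#' S1 layer: oriented Gabor filtering over the pyramid
#'
#' Convolves every pyramid level with every bank orientation (mirror
#' padding, same-size output) and takes the absolute value of the filter
#' response (phase-invariant magnitude).
#'
#' @param pyramid list of matrices from [build_pyramid()].
#' @param bank a [gabor_bank].
#' @return List over levels; each element a list over orientations of
#'   non-negative response matrices.
#' @export
s1_convolve <- function(pyramid, bank) {
  lapply(pyramid, function(level) {
    lapply(bank$filters, function(f) abs(conv2_mirror(level, f)))
  })
}

#' C1 layer: local max pooling over position and scale
#'
#' Pools S1 responses with a max filter over `window` x `window` spatial
#' regions (sampled at `stride`) and over 2 adjacent scales: the scales
#' are paired disjointly (10 scales give 5 bands), each scale's maps are
#' window-pooled on their own raster, cropped to the common grid and
#' combined by elementwise max. Bands whose coarser level is smaller than
#' the window are skipped with a warning.
#'
#' @param s1 output of [s1_convolve()].
#' @param window pooling window side in S1 units (default 10).
#' @param stride pooling grid step (default 5, i.e. 50% overlap).
#' @return An object of class `c1_maps`: `bands` is a list (one element
#'   per scale band) of lists over orientations of pooled matrices;
#'   `geometry` records window/stride/scale pairing.
#' @export
c1_pool <- function(s1, window = 10, stride = 5) {
  n_scales <- length(s1)
  if (n_scales < 2) stop("c1_pool needs at least 2 scales")
  n_bands <- n_scales %/% 2
  bands <- list()
  pairs <- list()
  for (b in seq_len(n_bands)) {
    sc <- c(2 * b - 1, 2 * b)
    dims <- vapply(sc, function(s) dim(s1[[s]][[1]]), integer(2))
    if (any(dims < window)) {
      warning(sprintf("scale band %d skipped: level %dx%d smaller than %d",
                      b, min(dims[1, ]), min(dims[2, ]), window))
      next
    }
    maps <- lapply(seq_along(s1[[1]]), function(o) {
      p1 <- win_max(s1[[sc[1]]][[o]], window, stride)
      p2 <- win_max(s1[[sc[2]]][[o]], window, stride)
      gr <- min(nrow(p1), nrow(p2)); gc <- min(ncol(p1), ncol(p2))
      pmax(p1[seq_len(gr), seq_len(gc), drop = FALSE],
           p2[seq_len(gr), seq_len(gc), drop = FALSE])
    })
    bands[[length(bands) + 1]] <- maps
    pairs[[length(pairs) + 1]] <- sc
  }
  if (!length(bands)) stop("all scale bands smaller than the pooling window")
  structure(list(bands = bands,
                 geometry = list(window = window, stride = stride,
                                 scale_pairs = pairs)),
            class = "c1_maps")
}

#' Gabor (C1-level) feature vector of a frame
#'
#' Concatenates all C1 maps in a fixed order -- bands outermost, then
#' orientations, then map entries in R column-major order -- giving the
#' low-level representation `f_gabor`. Frames sharing a common size yield
#' vectors of identical length.
#'
#' @param c1 a `c1_maps` object.
#' @return Numeric vector.
#' @export
gabor_vector <- function(c1) {
  unlist(lapply(c1$bands, function(maps)
    lapply(maps, as.numeric)), use.names = FALSE)
}

# C1 maps for one frame with shared defaults.
frame_c1 <- function(frame, bank, n_levels = 10, factor = 2^(-1 / 4),
                     window = 10, stride = 5) {
  pyr <- build_pyramid(frame, n_levels, factor, min_side = bank$size)
  c1_pool(s1_convolve(pyr, bank), window, stride)
}

#' Sample C1 prototype patches for the HMAX visual dictionary
#'
#' Draws `n_prototypes` patches verbatim from the C1 layers of a training
#' frame set: candidate positions are all (frame, band, size, row, col)
#' placements of square patches spanning all orientations; `n_prototypes`
#' are drawn uniformly without replacement from the pooled candidate list
#' (so the same frame can contribute several patches).
#'
#' @param training a [frame_set] (or a list of precomputed `c1_maps` via
#'   `c1_list`).
#' @param n_prototypes dictionary size P (the reference configuration
#'   uses 4096).
#' @param patch_sizes candidate square patch sides in C1 cells.
#' @param seed integer seed; sampling is reproducible per seed.
#' @param bank,c1_list optional: Gabor bank (default [gabor_bank()]) and
#'   precomputed C1 maps.
#' @param ... passed to the C1 computation ([frame_c1()] parameters).
#' @return Object of class `prototype_dictionary`: `patches` is a list of
#'   `(patch, size, band)` records, `patch` an `size x size x
#'   n_orientations` array.
#' @export
sample_prototypes <- function(training, n_prototypes = 4096,
                              patch_sizes = c(4, 8, 12, 16), seed = 1,
                              bank = gabor_bank(), c1_list = NULL, ...) {
  if (is.null(c1_list))
    c1_list <- lapply(training$frames, frame_c1, bank = bank, ...)
  # enumerate candidate placements
  cand <- list()
  for (f in seq_along(c1_list)) {
    for (b in seq_along(c1_list[[f]]$bands)) {
      g <- dim(c1_list[[f]]$bands[[b]][[1]])
      for (s in patch_sizes) {
        if (g[1] >= s && g[2] >= s) {
          np <- (g[1] - s + 1L) * (g[2] - s + 1L)
          cand[[length(cand) + 1]] <-
            list(frame = f, band = b, size = s, n = np, gr = g[1] - s + 1L)
        }
      }
    }
  }
  total <- sum(vapply(cand, `[[`, numeric(1), "n"))
  if (total < n_prototypes)
    stop(sprintf("only %d candidate patch positions for %d prototypes",
                 total, n_prototypes))
  offsets <- cumsum(c(0, vapply(cand, `[[`, numeric(1), "n")))
  idx <- with_rng(seed, sample.int(total, n_prototypes))
  patches <- lapply(idx, function(k) {
    ci <- which(offsets[-length(offsets)] < k & k <= offsets[-1])
    rec <- cand[[ci]]
    within <- k - offsets[ci] - 1L           # 0-based within block
    r0 <- within %% rec$gr + 1L
    c0 <- within %/% rec$gr + 1L
    maps <- c1_list[[rec$frame]]$bands[[rec$band]]
    patch <- array(0, c(rec$size, rec$size, length(maps)))
    for (o in seq_along(maps))
      patch[, , o] <- maps[[o]][r0:(r0 + rec$size - 1L),
                                c0:(c0 + rec$size - 1L)]
    list(patch = patch, size = rec$size, band = rec$band,
         frame = rec$frame, row = r0, col = c0)
  })
  structure(list(patches = patches, n_prototypes = n_prototypes,
                 patch_sizes = patch_sizes, seed = seed),
            class = "prototype_dictionary")
}

#' S2 template matching and C2 global max pooling
#'
#' For each dictionary prototype the similarity to the C1 patch centred at
#' every valid position of every scale band is computed as a Gaussian
#' radial basis on Euclidean patch distance,
#' `exp(-d^2 / (2 * sigma^2 * n))` with `n` the patch element count, and
#' the global max over positions and bands is the C2 unit `h_p` in (0,1].
#' A prototype copied verbatim from the frame's own C1 maps attains
#' exactly 1. Prototypes larger than every C1 grid yield 0 with a warning.
#'
#' @param c1 a `c1_maps` object for one frame.
#' @param dict a `prototype_dictionary`.
#' @param sigma radial-basis bandwidth (default 1).
#' @return Numeric vector of length `dict$n_prototypes` (`f_vdhmax` row).
#' @export
s2_c2 <- function(c1, dict, sigma = 1) {
  n_orient <- length(c1$bands[[1]])
  # cache of sliding sum-of-squares per (band, size)
  ss_cache <- new.env(parent = emptyenv())
  band_ss <- function(b, s) {
    key <- paste(b, s)
    got <- get0(key, envir = ss_cache)
    if (!is.null(got)) return(got)
    maps <- c1$bands[[b]]
    ss <- box_sum(maps[[1]]^2, s)
    for (o in seq_along(maps)[-1]) ss <- ss + box_sum(maps[[o]]^2, s)
    assign(key, ss, envir = ss_cache)
    ss
  }
  vapply(dict$patches, function(rec) {
    s <- rec$size
    np <- s * s * n_orient
    p2 <- sum(rec$patch^2)
    best <- -Inf
    for (b in seq_along(c1$bands)) {
      g <- dim(c1$bands[[b]][[1]])
      if (g[1] < s || g[2] < s) next
      cross <- conv2_valid(c1$bands[[b]][[1]], rec$patch[, , 1])
      for (o in seq_len(n_orient)[-1])
        cross <- cross + conv2_valid(c1$bands[[b]][[o]], rec$patch[, , o])
      d2 <- pmax(band_ss(b, s) - 2 * cross + p2, 0)
      m <- min(d2)
      if (-m > best) best <- -m
    }
    if (!is.finite(best)) {
      warning("prototype larger than every C1 grid; C2 unit set to 0")
      return(0)
    }
    exp(best / (2 * sigma^2 * np))
  }, numeric(1))
}

#' HMAX feature matrices for a frame set
#'
#' Computes the two HMAX representations per frame: the Gabor C1-level
#' vector `f_gabor` and (when a prototype dictionary is supplied) the C2
#' visual-dictionary vector `f_vdhmax`.
#'
#' @param fs a [frame_set].
#' @param dict optional `prototype_dictionary`; when `NULL` only the
#'   Gabor representation is returned.
#' @param bank a [gabor_bank].
#' @param sigma S2 radial-basis bandwidth.
#' @param ... C1 parameters passed to [frame_c1()].
#' @return List with `f_gabor` (and `f_vdhmax`) [feature_matrix] objects.
#' @export
hmax_features <- function(fs, dict = NULL, bank = gabor_bank(),
                          sigma = 1, ...) {
  c1s <- lapply(fs$frames, frame_c1, bank = bank, ...)
  gv <- lapply(c1s, gabor_vector)
  lens <- vapply(gv, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("f_gabor length differs across frames; common-size policy violated")
  out <- list(f_gabor = feature_matrix(do.call(rbind, gv),
                                       model = "hmax", level = "low"))
  if (!is.null(dict)) {
    c2 <- t(vapply(c1s, s2_c2, numeric(dict$n_prototypes),
                   dict = dict, sigma = sigma))
    out$f_vdhmax <- feature_matrix(c2, model = "hmax", level = "dictionary")
  }
  out
}

#' Per-stimulus feature matrices
#'
#' Thin container for an `n_stimuli x d` matrix of finite model features,
#' tagged with the model family and hierarchical level.
#'
#' @param m numeric matrix, rows = stimuli.
#' @param model `"hmax"` or `"bow"`.
#' @param level `"low"` or `"dictionary"`.
#' @return A `feature_matrix` (matrix with attributes).
#' @export
feature_matrix <- function(m, model = c("hmax", "bow"),
                           level = c("low", "dictionary")) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("feature matrix entries must be finite")
  structure(m, model_tag = match.arg(model), level_tag = match.arg(level),
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s/%s]: %d stimuli x %d dims\n",
              attr(x, "model_tag"), attr(x, "level_tag"),
              nrow(x), ncol(x)))
  invisible(x)
}
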