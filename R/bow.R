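#' Dense SIFT descriptors over a frame
#'
#' Computes the standard 128-dimensional SIFT descriptor (4 x 4 spatial
#' cells x 8 orientation bins of gradient magnitude, trilinear soft
#' binning, Gaussian spatial weighting) on a dense grid of square patches.
#' Descriptors are L2-normalized, clamped at 0.2 and renormalized; an
#' all-zero gradient patch yields an all-zero descriptor (no division).
#'
#' @param frame numeric intensity matrix.
#' @param stride grid step in pixels (default 8).
#' @param patch patch side in pixels (default 16; must be a multiple of 4
#'   and >= 8).
#' @return Object of class `descriptor_set`: `descriptors` is an
#'   `n_keypoints x 128` matrix; keypoints are ordered in raster order
#'   (rows of patch origins outermost, then columns).
#' @export
dense_sift <- function(frame, stride = 8, patch = 16) {
  if (patch < 8 || patch %% 4 != 0)
    stop("patch must be >= 8 px and a multiple of 4")
  h <- nrow(frame); w <- ncol(frame)
  if (h < patch || w < patch)
    stop(sprintf("frame %dx%d smaller than the %d px patch", h, w, patch))
  # gradients: central differences, replicated edges
  gx <- (frame[, c(2:w, w), drop = FALSE] -
           frame[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  gy <- (frame[c(2:h, h), , drop = FALSE] -
           frame[c(1, 1:(h - 1)), , drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% (2 * pi)

  geom <- sift_patch_geometry(patch)
  r0s <- seq(1, h - patch + 1, by = stride)
  c0s <- seq(1, w - patch + 1, by = stride)
  kp <- expand.grid(col = c0s, row = r0s)[, c("row", "col")]
  desc <- matrix(0, nrow(kp), 128)
  rel <- patch - 1L
  for (k in seq_len(nrow(kp))) {
    rr <- kp$row[k]:(kp$row[k] + rel)
    cc <- kp$col[k]:(kp$col[k] + rel)
    desc[k, ] <- sift_descriptor(mag[rr, cc], ori[rr, cc], geom)
  }
  structure(list(descriptors = desc, keypoints = kp,
                 stride = stride, patch = patch,
                 frame_size = c(h, w)),
            class = "descriptor_set")
}

# Precomputed per-pixel spatial binning geometry for a patch size:
# bilinear weights of each pixel onto the 4x4 cell grid, plus the
# Gaussian window (sd = patch / 2).
sift_patch_geometry <- function(patch) {
  cell <- patch / 4
  pos <- (seq_len(patch) - 0.5) / cell - 0.5       # cell coordinate, 0-based
  lo <- floor(pos); frac <- pos - lo
  u <- matrix(rep(pos, times = patch), patch, patch)        # row coord
  v <- matrix(rep(pos, each = patch), patch, patch)         # col coord
  ctr <- (patch - 1) / 2
  px <- matrix(rep(seq_len(patch) - 1, times = patch), patch, patch)
  py <- matrix(rep(seq_len(patch) - 1, each = patch), patch, patch)
  gw <- exp(-((px - ctr)^2 + (py - ctr)^2) / (2 * (patch / 2)^2))
  n <- patch * patch
  rlo <- as.vector(matrix(rep(lo, times = patch), patch, patch))
  rfr <- as.vector(matrix(rep(frac, times = patch), patch, patch))
  clo <- as.vector(matrix(rep(lo, each = patch), patch, patch))
  cfr <- as.vector(matrix(rep(frac, each = patch), patch, patch))
  sid <- matrix(NA_integer_, n, 4)
  sw <- matrix(0, n, 4)
  combo <- 0L
  for (dr in 0:1) for (dc in 0:1) {
    combo <- combo + 1L
    r <- rlo + dr; cc <- clo + dc
    wgt <- (if (dr == 0) 1 - rfr else rfr) * (if (dc == 0) 1 - cfr else cfr)
    ok <- r >= 0 & r <= 3 & cc >= 0 & cc <= 3 & wgt > 0
    sid[ok, combo] <- as.integer(r[ok] * 4 + cc[ok])      # cell id 0..15
    sw[ok, combo] <- wgt[ok]
  }
  list(sid = sid, sw = sw, gauss = as.vector(gw))
}

# One descriptor from patch gradient magnitude/orientation rasters.
sift_descriptor <- function(mag, ori, geom) {
  wt <- as.vector(mag) * geom$gauss
  ob <- as.vector(ori) / (2 * pi / 8)
  o0 <- floor(ob); of <- ob - o0
  o0 <- as.integer(o0 %% 8); o1 <- as.integer((o0 + 1L) %% 8)
  d <- numeric(128)
  for (k in 1:4) {
    ok <- !is.na(geom$sid[, k])
    if (!any(ok)) next
    base <- geom$sid[ok, k] * 8L
    wsp <- geom$sw[ok, k] * wt[ok]
    idx <- c(base + o0[ok], base + o1[ok]) + 1L
    wv <- c(wsp * (1 - of[ok]), wsp * of[ok])
    acc <- rowsum(wv, idx)
    ii <- as.integer(rownames(acc))
    d[ii] <- d[ii] + acc[, 1]
  }
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) return(d)
  d <- pmin(d / nrm, 0.2)
  d / sqrt(sum(d^2))
}

#' Concatenated dense-SIFT vector of a frame (`f_sift`)
#'
#' Concatenates all descriptors of a [dense_sift()] grid in fixed raster
#' order; frames sharing a common size yield equal-length vectors.
#'
#' @param ds a `descriptor_set`.
#' @return Numeric vector of length `128 * n_keypoints`.
#' @export
sift_vector <- function(ds) as.vector(t(ds$descriptors))

#' Learn a visual-word codebook by k-means
#'
#' Lloyd iterations with k-means++ initialization over pooled training
#' descriptors: hard nearest-center assignment, mean update, empty
#' clusters re-seeded to the points farthest from their assigned centers,
#' stopping at a relative inertia improvement below `tol` or `max_iter`
#' iterations. The per-iteration inertia trace is retained (it is
#' monotone non-increasing).
#'
#' @param descriptors numeric matrix (rows = descriptors) or a
#'   `descriptor_set` / list of them.
#' @param n_words codebook size M (the reference configuration uses
#'   4000).
#' @param seed integer seed (initialization is reproducible per seed).
#' @param max_iter,tol stopping rule.
#' @return Object of class `codebook`: `centers` (`M x d`), `inertia`,
#'   `inertia_trace`, `seed`.
#' @export
learn_codebook <- function(descriptors, n_words = 4000, seed = 1,
                           max_iter = 300, tol = 1e-4) {
  X <- pool_descriptors(descriptors)
  n <- nrow(X)
  if (n < n_words)
    stop(sprintf("%d training descriptors for %d words; need at least M",
                 n, n_words))
  Xu <- unique(X)
  if (nrow(Xu) < n_words)
    stop(sprintf("only %d distinct descriptors for %d words",
                 nrow(Xu), n_words))
  with_rng(seed, {
    C <- Xu[kmeanspp_init(Xu, n_words), , drop = FALSE]
    trace <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      D2 <- dist2_matrix(X, C)
      assign_ <- max.col(-D2, ties.method = "first")
      inertia <- sum(pmax(D2[cbind(seq_len(n), assign_)], 0))
      trace <- c(trace, inertia)
      counts <- tabulate(assign_, n_words)
      Cnew <- rowsum(X, factor(assign_, levels = seq_len(n_words)))
      nz <- counts > 0
      Cnew[nz, ] <- Cnew[nz, , drop = FALSE] / counts[nz]
      empty <- which(!nz)
      if (length(empty)) {
        far <- order(D2[cbind(seq_len(n), assign_)], decreasing = TRUE)
        Cnew[empty, ] <- X[far[seq_along(empty)], , drop = FALSE]
      } else if (it > 1 && prev - inertia <= tol * max(prev, 1e-300)) {
        break  # keep the centers whose inertia was just measured
      }
      C <- Cnew
      prev <- inertia
    }
    structure(list(centers = C, n_words = n_words, seed = seed,
                   inertia = trace[length(trace)], inertia_trace = trace,
                   iterations = length(trace)),
              class = "codebook")
  })
}

pool_descriptors <- function(x) {
  if (inherits(x, "descriptor_set")) return(x$descriptors)
  if (is.list(x))
    return(do.call(rbind, lapply(x, function(e)
      if (inherits(e, "descriptor_set")) e$descriptors else as.matrix(e))))
  as.matrix(x)
}

# squared Euclidean distances, n x k
dist2_matrix <- function(X, C) {
  rx <- rowSums(X^2); rc <- rowSums(C^2)
  d2 <- outer(rx, rc, "+") - 2 * tcrossprod(X, C)
  pmax(d2, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ], "-")^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 <= 0)) idx[j] <- sample.int(n, 1)
    else idx[j] <- sample.int(n, 1, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ], "-")^2))
  }
  idx
}

#' Encode descriptors as a visual-word histogram (`f_vdbow`)
#'
#' Hard-assigns every descriptor to its nearest codebook center
#' (Euclidean; ties broken by lowest center index) and counts word
#' occurrences. With `normalize = TRUE` counts are divided by the
#' descriptor count (the average-pooling variant).
#'
#' @param ds a `descriptor_set` (or descriptor matrix).
#' @param cb a [learn_codebook()] codebook.
#' @param normalize return frequencies instead of raw counts.
#' @return Numeric histogram of length `cb$n_words`; in raw-count mode the
#'   entries sum exactly to the descriptor count.
#' @export
encode_bow <- function(ds, cb, normalize = FALSE) {
  X <- pool_descriptors(ds)
  if (ncol(X) != ncol(cb$centers))
    stop(sprintf("descriptor dim %d does not match codebook dim %d",
                 ncol(X), ncol(cb$centers)))
  D2 <- dist2_matrix(X, cb$centers)
  assign_ <- max.col(-D2, ties.method = "first")
  h <- tabulate(assign_, cb$n_words)
  if (normalize) h / nrow(X) else h
}

#' BoW feature matrices for a frame set
#'
#' Computes the dense-SIFT concatenation `f_sift` per frame and (when a
#' codebook is supplied) the visual-word histogram `f_vdbow`.
#'
#' @param fs a [frame_set].
#' @param codebook optional [learn_codebook()] codebook.
#' @param stride,patch dense grid parameters.
#' @param normalize histogram normalization flag (see [encode_bow()]).
#' @return List with `f_sift` (and `f_vdbow`) [feature_matrix] objects.
#' @export
bow_features <- function(fs, codebook = NULL, stride = 8, patch = 16,
                         normalize = FALSE) {
  dss <- lapply(fs$frames, dense_sift, stride = stride, patch = patch)
  sv <- lapply(dss, sift_vector)
  lens <- vapply(sv, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("f_sift length differs across frames; grid geometry mismatch")
  out <- list(f_sift = feature_matrix(do.call(rbind, sv),
                                      model = "bow", level = "low"))
  if (!is.null(codebook)) {
    hm <- t(vapply(dss, encode_bow, numeric(codebook$n_words),
                   cb = codebook, normalize = normalize))
    out$f_vdbow <- feature_matrix(hm, model = "bow", level = "dictionary")
  }
  out
}
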