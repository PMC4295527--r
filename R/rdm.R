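#' Representational dissimilarity matrices
#'
#' An `rdm` wraps a symmetric, zero-diagonal, non-negative `n x n`
#' distance matrix between stimulus representations, tagged with the
#' distance metric and a source label (e.g. `F_gabor`, `F_vdbow`, `Y`).
#'
#' @param m numeric square matrix.
#' @param metric `"euclidean"` or `"cityblock"`.
#' @param source free-form source tag.
#' @return Object of class `rdm`.
#' @export
rdm <- function(m, metric = c("euclidean", "cityblock"), source = "") {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  n <- nrow(m)
  if (n != ncol(m) || n < 2) stop("an RDM must be square with n >= 2")
  if (!all(is.finite(m))) stop("RDM entries must be finite")
  if (max(abs(m - t(m))) > 1e-9) stop("RDM asymmetric beyond 1e-9")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (min(m) < -1e-12) stop("RDM entries must be non-negative")
  structure(list(matrix = m, n = n, metric = match.arg(metric),
                 source = source),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("rdm [%s, %s]: %d x %d\n", x$source, x$metric, x$n, x$n))
  invisible(x)
}

#' Compute an RDM from a feature matrix
#'
#' Pairwise distances between the rows of a per-stimulus feature matrix:
#' Euclidean for model features, Cityblock (L1) available for neural
#' patterns.
#'
#' @param features numeric matrix (rows = stimuli) or [feature_matrix].
#' @param metric distance metric.
#' @param source source tag stored in the RDM.
#' @return An [rdm].
#' @export
compute_rdm <- function(features, metric = c("euclidean", "cityblock"),
                        source = NULL) {
  metric <- match.arg(metric)
  m <- as.matrix(features)
  if (!all(is.finite(m))) {
    bad <- which(!apply(is.finite(m), 1, all))
    stop("non-finite features in rows: ", paste(bad, collapse = ", "))
  }
  if (nrow(m) < 2) stop("need at least 2 stimuli")
  if (is.null(source)) {
    source <- if (inherits(features, "feature_matrix"))
      paste0("F_", attr(features, "model_tag"), "_",
             attr(features, "level_tag")) else "F"
  }
  d <- stats::dist(m, method = switch(metric, euclidean = "euclidean",
                                      cityblock = "manhattan"))
  rdm(as.matrix(d), metric = metric, source = source)
}

#' Searchlight specification
#'
#' Geometry of the moving cube used to extract multivariate voxel
#' patterns: radius 1 gives the default 3 x 3 x 3 cube of 27 voxels.
#' Only interior voxels (full cube inside the mask) are analyzed.
#'
#' @param radius cube radius in voxels.
#' @param metric distance between stimulus patterns (default cityblock).
#' @return Object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius = 1, metric = "cityblock") {
  structure(list(radius = as.integer(radius), metric = metric,
                 cube_size = (2L * as.integer(radius) + 1L)^3),
            class = "searchlight_spec")
}

#' Searchlight neural RDM at a voxel
#'
#' Extracts the T stimulus response patterns of the searchlight cube
#' centred at `center` and returns their pairwise Cityblock distance
#' matrix `Y` (T x T).
#'
#' @param brain a [generate_subject()] `synthetic_brain`, or any list with
#'   a 4-D `volumes` array and 3-D `mask`.
#' @param center integer voxel coordinate `(x, y, z)`.
#' @param spec a [searchlight_spec].
#' @return An [rdm] with source `"Y"`.
#' @export
searchlight_rdm <- function(brain, center, spec = searchlight_spec()) {
  pat <- searchlight_patterns(brain, center, spec)
  d <- stats::dist(pat, method = switch(spec$metric,
                                        cityblock = "manhattan",
                                        euclidean = "euclidean"))
  rdm(as.matrix(d), metric = spec$metric, source = "Y")
}

# T x cube_size pattern matrix for one searchlight placement.
searchlight_patterns <- function(brain, center, spec) {
  r <- spec$radius
  dm <- dim(brain$volumes)
  xs <- (center[1] - r):(center[1] + r)
  ys <- (center[2] - r):(center[2] + r)
  zs <- (center[3] - r):(center[3] + r)
  if (min(xs, ys, zs) < 1 || xs[length(xs)] > dm[1] ||
      ys[length(ys)] > dm[2] || zs[length(zs)] > dm[3])
    stop("searchlight cube extends outside the volume")
  if (!all(brain$mask[xs, ys, zs] > 0))
    stop("searchlight cube extends outside the mask")
  cube <- brain$volumes[xs, ys, zs, , drop = FALSE]
  t(matrix(cube, prod(dim(cube)[1:3]), dm[4]))
}

#' Voxels whose full searchlight cube lies inside the mask
#'
#' @param mask binary 3-D array.
#' @param radius searchlight radius.
#' @return Integer matrix of voxel coordinates (columns x, y, z).
#' @export
interior_voxels <- function(mask, radius = 1) {
  dm <- dim(mask)
  ok <- array(TRUE, dm)
  for (dx in -radius:radius) for (dy in -radius:radius)
    for (dz in -radius:radius) {
      sh <- shift_array(mask > 0, c(dx, dy, dz), fill = FALSE)
      ok <- ok & sh
    }
  which(ok & mask > 0, arr.ind = TRUE)
}

# shift a 3-D array by d (positive = towards higher indices), filling
shift_array <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (d[k] >= 0) {
      src[[k]] <- seq_len(dm[k] - d[k])
      dst[[k]] <- src[[k]] + d[k]
    } else {
      src[[k]] <- seq_len(dm[k] + d[k]) - d[k]
      dst[[k]] <- seq_len(dm[k] + d[k])
    }
    if (!length(src[[k]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Vectorize an RDM for regression
#'
#' Returns the strictly-lower-triangle entries in row-major order: row
#' `i` runs over 2..n, and within row `i` columns 1..i-1, so entry
#' `(i, j)` sits at position `(i-1)(i-2)/2 + j`. `rdm_unvectorize()` is
#' the exact inverse.
#'
#' @param x an [rdm] (or symmetric matrix).
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
rdm_vectorize <- function(x) {
  m <- if (inherits(x, "rdm")) x$matrix else as.matrix(x)
  if (max(abs(m - t(m))) > 1e-9) stop("matrix asymmetric beyond 1e-9")
  t(m)[upper.tri(m)]
}

#' @rdname rdm_vectorize
#' @param v distance vector from `rdm_vectorize()`.
#' @param n RDM order.
#' @export
rdm_unvectorize <- function(v, n) {
  if (length(v) != n * (n - 1) / 2)
    stop("vector length does not match n (n - 1) / 2")
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- t(m)
  m + t(m)
}
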