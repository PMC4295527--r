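#' Default ellipsoidal brain mask
#'
#' Binary mask of an axis-aligned ellipsoid inscribed in the grid (semi
#' axes `grid/2 - 0.5`), the desk-scale stand-in for a brain mask.
#'
#' @param grid integer `(x, y, z)` dimensions (default `c(16, 16, 16)`).
#' @return Binary 3-D array.
#' @export
ellipsoid_mask <- function(grid = c(16, 16, 16)) {
  ctr <- (grid + 1) / 2
  ax <- grid / 2 - 0.5
  x <- (seq_len(grid[1]) - ctr[1]) / ax[1]
  y <- (seq_len(grid[2]) - ctr[2]) / ax[2]
  z <- (seq_len(grid[3]) - ctr[3]) / ax[3]
  d <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(as.numeric(d <= 1), grid)
}

#' Default planted signal region
#'
#' Coordinates of a `side^3` block centred in the grid (default 4 x 4 x 4,
#' 64 voxels), lying in the mask interior.
#'
#' @param grid grid dimensions.
#' @param side block side in voxels.
#' @param offset integer shift of the block centre.
#' @return Integer matrix of voxel coordinates (columns x, y, z).
#' @export
central_block <- function(grid = c(16, 16, 16), side = 4, offset = c(0, 0, 0)) {
  start <- floor((grid - side) / 2) + 1 + offset
  as.matrix(expand.grid(x = start[1]:(start[1] + side - 1),
                        y = start[2]:(start[2] + side - 1),
                        z = start[3]:(start[3] + side - 1)))
}

#' Generate a synthetic subject volume with planted RDM structure
#'
#' Voxels in `region` respond to the stimulus set as a linear mixture of
#' two model feature spaces: each region voxel gets one fixed random
#' Gaussian projection of the rows of `feature_a` (weight `w_a`) and of
#' `feature_b` (weight `w_b`); each projected time course is z-scored so
#' the weights are on a common scale, and i.i.d. Gaussian noise of sd
#' `noise_sd` is added per volume. Masked voxels outside the region carry
#' pure noise; voxels outside the mask are zero. Because the signal is
#' injected at the response level, the searchlight RDM arises through the
#' same computation as in the real pipeline. The projections are drawn
#' from `proj_seed` (shared across a cohort), the noise from `seed`.
#'
#' @param frames a [frame_set] (defines T) or an integer T.
#' @param feature_a,feature_b [feature_matrix] objects (rows = stimuli).
#' @param w_a,w_b non-negative mixture weights.
#' @param noise_sd noise standard deviation.
#' @param grid volume dimensions.
#' @param region integer matrix of signal voxel coordinates; must lie in
#'   the mask interior (full 3 x 3 x 3 neighborhoods inside the mask).
#' @param mask binary 3-D array (default [ellipsoid_mask()]).
#' @param seed noise seed.
#' @param proj_seed projection seed (default derived from `seed`).
#' @return Object of class `synthetic_brain`: `volumes` (4-D X,Y,Z,T
#'   array), `mask`, `roi_labels` (1 = mask background, 2 = region),
#'   `truth` (weights, noise sd, region, seeds).
#' @export
generate_subject <- function(frames, feature_a, feature_b, w_a = 1,
                             w_b = 0, noise_sd = 0.3,
                             grid = c(16, 16, 16), region = NULL,
                             mask = NULL, seed = 1, proj_seed = NULL) {
  n_t <- if (inherits(frames, "frame_set")) length(frames$frames)
         else as.integer(frames)
  if (w_a < 0 || w_b < 0) stop("mixture weights must be non-negative")
  if (nrow(feature_a) != n_t || nrow(feature_b) != n_t)
    stop(sprintf("feature rows (%d, %d) do not match T = %d",
                 nrow(feature_a), nrow(feature_b), n_t))
  if (is.null(mask)) mask <- ellipsoid_mask(grid)
  grid <- dim(mask)
  if (is.null(region)) region <- central_block(grid)
  region <- as.matrix(region)
  interior <- interior_voxels(mask, 1)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  if (!all(key(region) %in% key(interior)))
    stop("region must lie in the mask interior (full 3x3x3 neighborhoods)")
  if (is.null(proj_seed)) proj_seed <- derive_seed(seed, 777L)

  n_reg <- nrow(region)
  signal <- with_rng(proj_seed, {
    Pa <- matrix(stats::rnorm(ncol(feature_a) * n_reg), ncol(feature_a))
    Pb <- matrix(stats::rnorm(ncol(feature_b) * n_reg), ncol(feature_b))
    sa <- scale_columns(as.matrix(feature_a) %*% Pa)
    sb <- scale_columns(as.matrix(feature_b) %*% Pb)
    w_a * sa + w_b * sb                     # T x n_reg
  })
  vols <- with_rng(seed, {
    v <- array(0, c(grid, n_t))
    in_mask <- which(mask > 0, arr.ind = TRUE)
    noise <- matrix(stats::rnorm(nrow(in_mask) * n_t, 0, noise_sd),
                    nrow(in_mask), n_t)
    for (t in seq_len(n_t)) {
      slab <- array(0, grid)
      slab[in_mask] <- noise[, t]
      slab[region] <- slab[region] + signal[t, ]
      v[, , , t] <- slab
    }
    v
  })
  roi <- array(0L, grid)
  roi[mask > 0] <- 1L
  roi[region] <- 2L
  structure(list(volumes = vols, mask = mask, roi_labels = roi,
                 truth = list(w_a = w_a, w_b = w_b, noise_sd = noise_sd,
                              region = region, seed = seed,
                              proj_seed = proj_seed)),
            class = "synthetic_brain")
}

scale_columns <- function(m) {
  sds <- apply(m, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  sweep(sweep(m, 2, colMeans(m)), 2, sds, "/")
}

#' @export
print.synthetic_brain <- function(x, ...) {
  dm <- dim(x$volumes)
  cat(sprintf(
    "synthetic_brain: %dx%dx%d grid, T = %d, %d mask voxels, %d signal\n",
    dm[1], dm[2], dm[3], dm[4], sum(x$mask > 0), nrow(x$truth$region)))
  invisible(x)
}

#' Generate a cohort of subjects sharing a signal region
#'
#' All subjects share the planted region, the mixing weights and the
#' feature projections (one projection seed for the cohort); the noise is
#' independent per subject.
#'
#' @param n_subjects number of subjects (>= 2; the reference study
#'   samples 20).
#' @param seed master seed; subject noise seeds are derived from it.
#' @inheritParams generate_subject
#' @return List of `synthetic_brain` objects with identical `truth`
#'   (except the per-subject noise seed).
#' @export
generate_cohort <- function(n_subjects, frames, feature_a, feature_b,
                            w_a = 1, w_b = 0, noise_sd = 0.3,
                            grid = c(16, 16, 16), region = NULL,
                            mask = NULL, seed = 1) {
  if (n_subjects < 2) stop("a cohort needs at least 2 subjects")
  proj_seed <- derive_seed(seed, 0L)
  lapply(seq_len(n_subjects), function(s)
    generate_subject(frames, feature_a, feature_b, w_a = w_a, w_b = w_b,
                     noise_sd = noise_sd, grid = grid, region = region,
                     mask = mask, seed = derive_seed(seed, s),
                     proj_seed = proj_seed))
}

#' Export / import a synthetic brain as NIfTI plus a JSON truth sidecar
#'
#' Writes the 4-D volume series, mask and ROI labels as NIfTI files and
#' the ground-truth record as JSON.
#'
#' @param brain a `synthetic_brain`.
#' @param dir output directory.
#' @return `write_brain()` the directory, invisibly; `read_brain()` a
#'   `synthetic_brain`.
#' @export
write_brain <- function(brain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(brain$volumes),
                     file.path(dir, "volumes.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(brain$mask),
                     file.path(dir, "mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(brain$roi_labels * 1),
                     file.path(dir, "roi_labels.nii.gz"))
  truth <- brain$truth
  truth$region <- unname(apply(truth$region, 1, paste, collapse = ","))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_brain
#' @export
read_brain <- function(dir) {
  vols <- as.array(RNifti::readNifti(file.path(dir, "volumes.nii.gz")))
  mask <- as.array(RNifti::readNifti(file.path(dir, "mask.nii.gz")))
  roi_path <- file.path(dir, "roi_labels.nii.gz")
  roi <- if (file.exists(roi_path))
    array(as.integer(round(as.array(RNifti::readNifti(roi_path)))),
          dim(mask)) else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (!is.null(truth$region))
      truth$region <- do.call(rbind, lapply(strsplit(truth$region, ","),
                                            as.integer))
  }
  structure(list(volumes = vols, mask = mask, roi_labels = roi,
                 truth = truth),
            class = "synthetic_brain")
}
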