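#' Connected-component labeling of a binary 3-D volume
#'
#' Breadth-first labeling under 6- (faces), 18- or 26-neighbor
#' connectivity.
#'
#' @param bin binary 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return List: `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per label).
#' @export
label_components <- function(bin, connectivity = 6) {
  dm <- dim(bin)
  offs <- connectivity_offsets(connectivity)
  lab <- array(0L, dm)
  idx <- which(bin > 0)
  if (!length(idx)) return(list(labels = lab, sizes = integer(0)))
  nxt <- 0L
  sizes <- integer(0)
  stack <- integer(length(idx))
  for (s in idx) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    top <- 1L; stack[1] <- s
    size <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      size <- size + 1L
      z <- (cur - 1L) %/% (dm[1] * dm[2])
      rem <- (cur - 1L) %% (dm[1] * dm[2])
      y <- rem %/% dm[1]; x <- rem %% dm[1]
      for (k in seq_len(nrow(offs))) {
        nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
        if (nx < 0 || ny < 0 || nz < 0 || nx >= dm[1] || ny >= dm[2] ||
            nz >= dm[3]) next
        ni <- 1L + nx + dm[1] * ny + dm[1] * dm[2] * nz
        if (bin[ni] > 0 && lab[ni] == 0L) {
          lab[ni] <- nxt
          top <- top + 1L; stack[top] <- ni
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = lab, sizes = sizes)
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  d <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[d == 1, , drop = FALSE],
         "18" = g[d <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

#' Cluster-extent thresholding of a p-value map
#'
#' Binarizes `p < alpha`, labels connected components and drops those
#' below the minimum cluster size -- the multiple-comparison control of
#' the searchlight analysis (reference settings: p < 0.05, minimum 25
#' voxels).
#'
#' @param p_map a [stat_volume] of p-values in (0, 1].
#' @param alpha voxel-level threshold.
#' @param min_size minimum surviving cluster size in voxels.
#' @param connectivity 6, 18 or 26.
#' @return Object of class `cluster_report`: `labels` (surviving-cluster
#'   label array), `sizes`, `significant` (binary array), plus the
#'   parameters.
#' @export
cluster_threshold <- function(p_map, alpha = 0.05, min_size = 25,
                              connectivity = 6) {
  vals <- p_map$values
  bad <- vals[p_map$mask > 0]
  if (any(bad <= 0 | bad > 1))
    stop("p-values must lie in (0, 1]")
  bin <- array(FALSE, dim(vals))
  bin[p_map$mask > 0] <- vals[p_map$mask > 0] < alpha
  comp <- label_components(bin, connectivity)
  keep <- which(comp$sizes >= min_size)
  lab <- comp$labels
  lab[!(lab %in% keep)] <- 0L
  # relabel surviving clusters 1..k
  if (length(keep)) {
    relab <- integer(max(comp$labels))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  structure(list(labels = lab, sizes = comp$sizes[keep],
                 significant = lab > 0, mask = p_map$mask,
                 alpha = alpha, min_size = min_size,
                 connectivity = connectivity),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d clusters >= %d voxels (alpha %.3g)\n",
              length(x$sizes), x$min_size, x$alpha))
  invisible(x)
}

#' Monte-Carlo minimum cluster size for family-wise control
#'
#' Simulates null p-maps (independent uniform p per masked voxel, or a
#' smoothed Gaussian field when `smooth_sd > 0`), records the largest
#' suprathreshold cluster per simulation at voxel threshold `alpha`, and
#' returns the smallest cluster size whose null exceedance frequency is
#' below `fwe_target`.
#'
#' @param mask binary 3-D array (or grid dimensions).
#' @param alpha voxel-level threshold.
#' @param fwe_target family-wise false-positive target.
#' @param n_sim number of simulations (>= 100).
#' @param seed integer seed.
#' @param connectivity cluster connectivity.
#' @param smooth_sd Gaussian field smoothness in voxels (0 = independent
#'   voxels).
#' @return Integer minimum cluster size; the simulated max-cluster-size
#'   distribution is attached as attribute `"max_sizes"`.
#' @export
mc_cluster_size <- function(mask, alpha = 0.05, fwe_target = 0.05,
                            n_sim = 1000, seed = 1, connectivity = 6,
                            smooth_sd = 0) {
  if (n_sim < 100) stop("n_sim must be >= 100")
  if (is.numeric(mask) && is.null(dim(mask))) mask <- array(1, mask)
  dm <- dim(mask)
  inmask <- mask > 0
  nvox <- sum(inmask)
  maxs <- with_rng(seed, {
    vapply(seq_len(n_sim), function(s) {
      if (smooth_sd > 0) {
        z <- array(stats::rnorm(prod(dm)), dm)
        z <- smooth_gauss3d(z, smooth_sd)
        z <- (z - mean(z)) / stats::sd(z)
        p <- array(1, dm)
        p[inmask] <- stats::pnorm(z[inmask], lower.tail = FALSE)
      } else {
        p <- array(1, dm)
        p[inmask] <- stats::runif(nvox)
      }
      bin <- array(FALSE, dm)
      bin[inmask] <- p[inmask] < alpha
      sz <- label_components(bin, connectivity)$sizes
      if (length(sz)) max(sz) else 0L
    }, integer(1))
  })
  k <- 1L
  while (mean(maxs >= k) >= fwe_target) k <- k + 1L
  structure(k, max_sizes = maxs)
}

#' Across-subject consistency map with a spatial chi-square statistic
#'
#' Counts, per voxel, the subjects whose surviving clusters cover it;
#' compares the (optionally Gaussian-smoothed) count map against the
#' expected count E (the mean over masked voxels) with the per-voxel
#' chi-square `(O - E)^2 / E`. A voxel is significant when its
#' chi-square exceeds the upper-alpha chi-square(1 df) quantile and the
#' deviation is positive (more subjects than expected). A translation
#' permutation null -- each subject's binary map independently
#' circularly shifted in 3-D before recounting -- is run alongside and
#' its volume-wise max-chi-square distribution reported as a
#' conservative diagnostic (`null_max`, `threshold_perm`); preserved
#' cluster extent makes that null extremely conservative when clusters
#' are large relative to the mask, so it is not the significance rule.
#'
#' @param reports list of per-subject [cluster_threshold()] reports
#'   sharing a grid and mask.
#' @param smooth_sd Gaussian smoothing sd of the count map in voxels
#'   (default 1; 0 disables).
#' @param alpha significance level of the chi-square test.
#' @param n_perm number of translation permutations (0 disables the
#'   diagnostic null).
#' @param seed integer seed.
#' @return Object of class `consistency_map`: `counts`, `expected`,
#'   `chi_sq` (stat_volume), `threshold` (chi-square(1) quantile),
#'   `significant` (binary array), `null_max`, `threshold_perm`.
#' @export
consistency_map <- function(reports, smooth_sd = 1, alpha = 0.05,
                            n_perm = 499, seed = 1) {
  if (!length(reports)) stop("no subject reports")
  mask <- reports[[1]]$mask
  dm <- dim(mask)
  for (r in reports)
    if (!identical(dim(r$mask), dm)) stop("subject grids differ")
  bins <- lapply(reports, function(r) r$significant * 1)
  chi_of <- function(maps) {
    counts <- Reduce(`+`, maps)
    sm <- if (smooth_sd > 0) smooth_gauss3d(counts, smooth_sd) else counts
    e <- mean(sm[mask > 0])
    chi <- array(0, dm)
    if (e > 0) chi[mask > 0] <- (sm[mask > 0] - e)^2 / e
    list(counts = counts, smoothed = sm, expected = e, chi = chi)
  }
  obs <- chi_of(bins)
  null_max <- if (n_perm > 0) with_rng(seed, {
    vapply(seq_len(n_perm), function(k) {
      shifted <- lapply(bins, function(b) {
        sh <- floor(stats::runif(3) * dm)
        circular_shift3d(b, sh) * (mask > 0)
      })
      max(chi_of(shifted)$chi[mask > 0])
    }, numeric(1))
  }) else numeric(0)
  thr <- stats::qchisq(1 - alpha, df = 1)
  thr_perm <- if (n_perm > 0)
    stats::quantile(null_max, 1 - alpha, names = FALSE, type = 8)
  else NA_real_
  structure(list(counts = obs$counts, smoothed = obs$smoothed,
                 expected = obs$expected,
                 chi_sq = stat_volume(obs$chi, mask, "chi_sq"),
                 threshold = thr, threshold_perm = thr_perm,
                 significant = obs$chi > thr & obs$smoothed > obs$expected &
                   mask > 0,
                 null_max = null_max, n_subjects = length(reports),
                 smooth_sd = smooth_sd, alpha = alpha),
            class = "consistency_map")
}

circular_shift3d <- function(a, sh) {
  dm <- dim(a)
  ix <- ((seq_len(dm[1]) - 1 - sh[1]) %% dm[1]) + 1
  iy <- ((seq_len(dm[2]) - 1 - sh[2]) %% dm[2]) + 1
  iz <- ((seq_len(dm[3]) - 1 - sh[3]) %% dm[3]) + 1
  a[ix, iy, iz, drop = FALSE]
}

#' @export
print.consistency_map <- function(x, ...) {
  cat(sprintf(
    "consistency_map: %d subjects, E = %.3f, chi-sq threshold %.3f, %d significant voxels\n",
    x$n_subjects, x$expected, x$threshold, sum(x$significant)))
  invisible(x)
}

#' ROI summary of significant voxels and explained variation
#'
#' For every integer ROI label: the number of voxels significant
#' (cluster-surviving) in at least one subject, the maximum explained
#' variation (percent) over subjects and significant voxels, and the mean
#' explained variation (percent) over subjects and their significant
#' voxels. ROI labels absent from the volume (or without significant
#' voxels) give zero rows.
#'
#' @param r2_volumes list (per subject) of [stat_volume]s of explained
#'   variation fractions in \[0, 1\].
#' @param reports list (per subject) of [cluster_threshold()] reports.
#' @param roi_labels integer 3-D label array (0 = unlabeled).
#' @param roi_names optional names for the labels.
#' @return `data.frame` with columns `roi`, `n_significant`, `max_ev`,
#'   `mean_ev` (explained variation in percent).
#' @export
roi_summary <- function(r2_volumes, reports, roi_labels,
                        roi_names = NULL) {
  dm <- dim(roi_labels)
  stopifnot(length(r2_volumes) == length(reports))
  labs <- sort(setdiff(unique(as.integer(roi_labels)), 0L))
  if (!is.null(roi_names)) {
    want <- as.integer(names(roi_names))
    labs <- sort(unique(c(labs, want)))
  }
  rows <- lapply(labs, function(lb) {
    in_roi <- roi_labels == lb
    union_sig <- array(FALSE, dm)
    vals <- numeric(0)
    for (s in seq_along(reports)) {
      sig <- reports[[s]]$significant & in_roi
      union_sig <- union_sig | sig
      if (any(sig)) vals <- c(vals, r2_volumes[[s]]$values[sig])
    }
    vals <- vals[is.finite(vals)]
    data.frame(roi = if (!is.null(roi_names) &&
                         !is.na(roi_names[as.character(lb)]))
                 roi_names[as.character(lb)] else as.character(lb),
               n_significant = sum(union_sig),
               max_ev = if (length(vals)) 100 * max(vals) else 0,
               mean_ev = if (length(vals)) 100 * mean(vals) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
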