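#' Explained variation of an RDM by predictor RDMs
#'
#' Ordinary least squares of the vectorized (strictly lower triangle)
#' target RDM on the vectorized predictor RDMs plus an intercept,
#' returning the coefficient of determination R^2. Near-collinear
#' predictors (condition number above 1e10) fall back to a reduced-rank
#' (pseudo-inverse) fit with a warning. A constant target (zero total sum
#' of squares) has R^2 defined as 0.
#'
#' @param y target [rdm] (typically the neural RDM `Y`).
#' @param predictors list of predictor [rdm]s (or a single one).
#' @return R^2 in \[0, 1\].
#' @export
rdm_regression <- function(y, predictors) {
  if (inherits(predictors, "rdm")) predictors <- list(predictors)
  if (!length(predictors)) stop("need at least one predictor RDM")
  n <- if (inherits(y, "rdm")) y$n else nrow(as.matrix(y))
  for (p in predictors) {
    pn <- if (inherits(p, "rdm")) p$n else nrow(as.matrix(p))
    if (pn != n) stop("predictor RDM order differs from target")
  }
  L <- n * (n - 1) / 2
  if (L <= length(predictors) + 1)
    stop("too few distance pairs for the number of predictors")
  yv <- rdm_vectorize(y)
  X <- vapply(predictors, rdm_vectorize, numeric(L))
  r2_project(yv, ortho_basis(X))
}

# Orthonormal basis of the centered predictor columns; warns on severe
# collinearity and drops dependent columns (pseudo-inverse equivalent).
ortho_basis <- function(X) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  if (any(pos) && max(sv$d) / min(sv$d[sv$d > 0]) > 1e10)
    warning("near-collinear predictors: reduced-rank (pseudo-inverse) fit")
  sv$u[, pos, drop = FALSE]
}

r2_project <- function(yv, Q) {
  yc <- yv - mean(yv)
  tss <- sum(yc^2)
  if (tss < 1e-24) return(0)
  min(sum(crossprod(Q, yc)^2) / tss, 1)
}

#' Variation partitioning of a neural RDM over two predictor RDMs
#'
#' Decomposes the explained variation of `y` into the fraction unique to
#' `f_a`, unique to `f_b`, and shared, by differences of nested
#' regressions: with `R2_full = R2(y ~ a + b)`,
#' `unique_a = R2_full - R2(y ~ b)`, `unique_b = R2_full - R2(y ~ a)` and
#' `shared = R2_full - unique_a - unique_b`. Unique and shared fractions
#' may be slightly negative under suppression and are reported raw. The
#' residual is `1 - R2_full`. The three fractions sum to `R2_full` by
#' construction (to floating-point accuracy).
#'
#' @param y target [rdm].
#' @param f_a,f_b predictor [rdm]s.
#' @param labels length-2 character labels for the two predictors.
#' @return Object of class `partition_fractions` with fields `r2_full`,
#'   `r2_unique_a`, `r2_unique_b`, `r2_shared`, `residual`, `labels`.
#' @export
partition <- function(y, f_a, f_b, labels = c("a", "b")) {
  n <- if (inherits(y, "rdm")) y$n else nrow(as.matrix(y))
  L <- n * (n - 1) / 2
  yv <- rdm_vectorize(y)
  Xa <- rdm_vectorize(f_a); Xb <- rdm_vectorize(f_b)
  if (length(Xa) != L || length(Xb) != L)
    stop("predictor RDM order differs from target")
  fr <- partition_from_vectors(yv, ortho_basis(cbind(Xa, Xb)),
                               ortho_basis(Xa), ortho_basis(Xb))
  structure(c(fr, list(labels = labels)), class = "partition_fractions")
}

partition_from_vectors <- function(yv, Qab, Qa, Qb) {
  r2_full <- r2_project(yv, Qab)
  r2_a <- r2_project(yv, Qa)
  r2_b <- r2_project(yv, Qb)
  ua <- r2_full - r2_b
  ub <- r2_full - r2_a
  list(r2_full = r2_full, r2_unique_a = ua, r2_unique_b = ub,
       r2_shared = r2_full - ua - ub, residual = 1 - r2_full)
}

#' @export
print.partition_fractions <- function(x, ...) {
  cat(sprintf(
    "partition: full %.4f | unique %s %.4f | unique %s %.4f | shared %.4f\n",
    x$r2_full, x$labels[1], x$r2_unique_a, x$labels[2], x$r2_unique_b,
    x$r2_shared))
  invisible(x)
}

#' Permutation test for partition fractions
#'
#' Mantel-style stimulus-label permutation: the rows and columns of the
#' target RDM are permuted simultaneously while the predictors stay
#' fixed, the chosen statistic is recomputed for each permutation, and
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`, so p lies in
#' `[1 / (n_perm + 1), 1]`. One permutation set is shared across the four
#' statistics of a voxel.
#'
#' @param y target [rdm].
#' @param f_a,f_b predictor [rdm]s.
#' @param statistic which fraction to test.
#' @param n_perm number of permutations (>= 99; the reference analysis
#'   uses 1000).
#' @param seed integer seed.
#' @return Object of class `permutation_result` with `observed`,
#'   `p_value`, `n_perm`, `seed`, and `p_all` (p-values of all four
#'   fractions from the shared permutation set).
#' @export
permutation_test <- function(y, f_a, f_b,
                             statistic = c("full", "unique_a", "unique_b",
                                           "shared"),
                             n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  if (n_perm < 99) stop("n_perm must be >= 99")
  n <- if (inherits(y, "rdm")) y$n else nrow(as.matrix(y))
  yv <- rdm_vectorize(y)
  Xa <- rdm_vectorize(f_a); Xb <- rdm_vectorize(f_b)
  eng <- vp_engine_setup(n, Xa, Xb)
  res <- vp_engine_run(eng, yv, n_perm, seed)
  structure(list(observed = res$observed[[statistic]],
                 p_value = res$p[[statistic]], p_all = res$p,
                 fractions = res$observed, statistic = statistic,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

# Precompute everything that is shared across voxels for a fixed
# predictor pair: orthonormal bases and the lower-triangle pair indices.
vp_engine_setup <- function(n, Xa, Xb) {
  lp <- lower_pairs(n)
  list(n = n, L = n * (n - 1) / 2, i = lp$i, j = lp$j,
       Qab = ortho_basis(cbind(Xa, Xb)),
       Qa = ortho_basis(Xa), Qb = ortho_basis(Xb))
}

# Observed fractions plus permutation p-values for one target vector.
# The permuted vector is obtained by index remapping: entry (i, j) of the
# permuted RDM is entry (perm[i], perm[j]) of the original, located in
# the row-major lower-triangle vector via pair_pos().
vp_engine_run <- function(eng, yv, n_perm, seed) {
  obs <- partition_from_vectors(yv, eng$Qab, eng$Qa, eng$Qb)
  idx <- with_rng(seed, {
    vapply(seq_len(n_perm), function(k) {
      pr <- sample.int(eng$n)
      pi_ <- pr[eng$i]; pj <- pr[eng$j]
      as.integer(pair_pos(pmax(pi_, pj), pmin(pi_, pj)))
    }, integer(eng$L))
  })
  Ymat <- matrix(yv[idx], eng$L, n_perm)
  Yc <- sweep(Ymat, 2, colMeans(Ymat))
  tss <- colSums(Yc^2)
  proj <- function(Q) colSums(crossprod(Q, Yc)^2)
  safe <- tss >= 1e-24
  r2 <- function(Q) {
    out <- numeric(n_perm)
    out[safe] <- pmin(proj(Q)[safe] / tss[safe], 1)
    out
  }
  r2ab <- r2(eng$Qab); r2a <- r2(eng$Qa); r2b <- r2(eng$Qb)
  perm <- list(full = r2ab, unique_a = r2ab - r2b, unique_b = r2ab - r2a,
               shared = r2a + r2b - r2ab)
  obs_stats <- list(full = obs$r2_full, unique_a = obs$r2_unique_a,
                    unique_b = obs$r2_unique_b, shared = obs$r2_shared)
  p <- lapply(names(perm), function(s)
    (1 + sum(perm[[s]] >= obs_stats[[s]] - 1e-12)) / (1 + n_perm))
  names(p) <- names(perm)
  list(observed = obs, p = p)
}

#' Voxel-wise variation partitioning over a brain volume
#'
#' Runs the searchlight neural-RDM extraction and two-predictor variation
#' partitioning with permutation inference at every interior voxel of the
#' mask. Per-voxel permutation seeds are derived from the master seed and
#' the voxel's linear index (x fastest), so results are independent of
#' iteration order.
#'
#' @param brain a `synthetic_brain` (or compatible list with `volumes`
#'   and `mask`).
#' @param f_a,f_b predictor [rdm]s.
#' @param spec a [searchlight_spec].
#' @param n_perm permutations per voxel.
#' @param seed master seed.
#' @param labels predictor labels.
#' @return Object of class `vp_maps`: a named list of [stat_volume]s
#'   (`r2_full`, `r2_unique_a`, `r2_unique_b`, `r2_shared`, `p_full`,
#'   `p_unique_a`, `p_unique_b`, `p_shared`), plus `voxels` (analyzed
#'   coordinates) and `skipped` (masked voxels without a full cube).
#' @export
voxelwise_partition <- function(brain, f_a, f_b, spec = searchlight_spec(),
                                n_perm = 1000, seed = 1,
                                labels = c("a", "b")) {
  dm <- dim(brain$volumes)
  n <- dm[4]
  Xa <- rdm_vectorize(f_a); Xb <- rdm_vectorize(f_b)
  if (length(Xa) != n * (n - 1) / 2)
    stop("predictor RDM order differs from the volume series length")
  eng <- vp_engine_setup(n, Xa, Xb)
  vox <- interior_voxels(brain$mask, spec$radius)
  all_mask <- which(brain$mask > 0, arr.ind = TRUE)
  skipped <- all_mask[!paste(all_mask[, 1], all_mask[, 2], all_mask[, 3]) %in%
                        paste(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
  quantities <- c("r2_full", "r2_unique_a", "r2_unique_b", "r2_shared",
                  "p_full", "p_unique_a", "p_unique_b", "p_shared")
  maps <- lapply(quantities, function(q) array(NA_real_, dm[1:3]))
  names(maps) <- quantities
  metric <- switch(spec$metric, cityblock = "manhattan", "euclidean")
  for (v in seq_len(nrow(vox))) {
    cen <- vox[v, ]
    pat <- searchlight_patterns(brain, cen, spec)
    yv_colmajor <- as.numeric(stats::dist(pat, method = metric))
    yv <- dist_to_rowmajor(yv_colmajor, n)
    lin <- cen[1] + dm[1] * (cen[2] - 1) + dm[1] * dm[2] * (cen[3] - 1)
    res <- vp_engine_run(eng, yv, n_perm, derive_seed(seed, lin))
    maps$r2_full[cen[1], cen[2], cen[3]] <- res$observed$r2_full
    maps$r2_unique_a[cen[1], cen[2], cen[3]] <- res$observed$r2_unique_a
    maps$r2_unique_b[cen[1], cen[2], cen[3]] <- res$observed$r2_unique_b
    maps$r2_shared[cen[1], cen[2], cen[3]] <- res$observed$r2_shared
    maps$p_full[cen[1], cen[2], cen[3]] <- res$p$full
    maps$p_unique_a[cen[1], cen[2], cen[3]] <- res$p$unique_a
    maps$p_unique_b[cen[1], cen[2], cen[3]] <- res$p$unique_b
    maps$p_shared[cen[1], cen[2], cen[3]] <- res$p$shared
  }
  analyzed <- array(FALSE, dm[1:3])
  analyzed[vox] <- TRUE
  vols <- lapply(quantities, function(q)
    stat_volume(maps[[q]], analyzed, quantity = q))
  names(vols) <- quantities
  structure(list(maps = vols, voxels = vox, skipped = skipped,
                 labels = labels, n_perm = n_perm, seed = seed),
            class = "vp_maps")
}

# reorder a stats::dist vector (column-major lower triangle) into the
# package's row-major lower-triangle order
dist_to_rowmajor <- function(v, n) {
  lp <- lower_pairs(n)
  # position of (i, j), i > j, in dist order: n(j-1) - j(j-1)/2 + i - j
  q <- n * (lp$j - 1) - lp$j * (lp$j - 1) / 2 + lp$i - lp$j
  v[q]
}
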