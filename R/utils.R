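# Internal numeric / RNG helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream seed from a master seed and a counter, independent of
# iteration order (32-bit safe: result in [1, 2147483586]).
derive_seed <- function(master, counter) {
  x <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(counter) * 16807
  as.integer(x %% 2147483586) + 1L
}

# Mirror-pad a matrix by (kr, kc) on each side (reflection about the edge
# pixel, which is not duplicated). Requires nrow > kr and ncol > kc.
pad_mirror <- function(m, kr, kc) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr > kr, nc > kc)
  ri <- c(rev(seq_len(kr) + 1L), seq_len(nr), nr - seq_len(kr))
  ci <- c(rev(seq_len(kc) + 1L), seq_len(nc), nc - seq_len(kc))
  m[ri, ci, drop = FALSE]
}

# Same-size 2-D cross-correlation (filter response) with mirror padding.
# EBImage::filter2 performs true convolution, so the kernel is flipped
# here to obtain correlation. Kernel dims must be odd.
conv2_mirror <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  hr <- (kr - 1L) / 2L; hc <- (kc - 1L) / 2L
  xp <- pad_mirror(x, hr, hc)
  kf <- k[kr:1, kc:1, drop = FALSE]
  out <- EBImage::filter2(xp, kf, boundary = "circular")
  out[(hr + 1):(hr + nrow(x)), (hc + 1):(hc + ncol(x)), drop = FALSE]
}

# Valid-mode 2-D cross-correlation by shift accumulation (exact, no FFT).
conv2_valid <- function(x, k) {
  nr <- nrow(x) - nrow(k) + 1L
  nc <- ncol(x) - ncol(k) + 1L
  stopifnot(nr >= 1, nc >= 1)
  out <- matrix(0, nr, nc)
  for (u in seq_len(nrow(k))) {
    for (v in seq_len(ncol(k))) {
      kv <- k[u, v]
      if (kv != 0)
        out <- out + kv * x[u:(u + nr - 1L), v:(v + nc - 1L), drop = FALSE]
    }
  }
  out
}

# Integral image (summed-area table) with a leading zero row/column.
integral_image <- function(x) {
  ii <- apply(x, 2, cumsum)
  ii <- t(apply(ii, 1, cumsum))
  rbind(0, cbind(0, ii))
}

# Valid-mode sliding sum of x over s-by-s windows, via integral image.
box_sum <- function(x, s) {
  ii <- integral_image(x)
  nr <- nrow(x) - s + 1L; nc <- ncol(x) - s + 1L
  r <- seq_len(nr); cc <- seq_len(nc)
  ii[r + s, cc + s, drop = FALSE] - ii[r, cc + s, drop = FALSE] -
    ii[r + s, cc, drop = FALSE] + ii[r, cc, drop = FALSE]
}

# Max over w-by-w windows sampled at `stride`: separable running max by
# shift-and-pmax over row then column offsets.
win_max <- function(m, w, stride) {
  stopifnot(nrow(m) >= w, ncol(m) >= w)
  nr <- nrow(m) - w + 1L
  rm_ <- m[seq_len(nr), , drop = FALSE]
  for (d in seq_len(w - 1L))
    rm_ <- pmax(rm_, m[seq_len(nr) + d, , drop = FALSE])
  nc <- ncol(m) - w + 1L
  out <- rm_[, seq_len(nc), drop = FALSE]
  for (d in seq_len(w - 1L))
    out <- pmax(out, rm_[, seq_len(nc) + d, drop = FALSE])
  out[seq(1, nr, by = stride), seq(1, nc, by = stride), drop = FALSE]
}

# Bilinear resize of a matrix to (nh, nw). EBImage::resize maps `w` to the
# first array dimension.
resize_bilinear <- function(m, nh, nw) {
  out <- EBImage::resize(m, w = nh, h = nw, filter = "bilinear")
  matrix(as.numeric(out), nh, nw)
}

# Row-major strictly-lower-triangle pair indices: i runs 2..n, j 1..i-1.
lower_pairs <- function(n) {
  i <- rep.int(2:n, times = seq_len(n - 1L))
  j <- unlist(lapply(2:n, function(k) seq_len(k - 1L)), use.names = FALSE)
  list(i = i, j = j)
}

# Position of entry (i, j), i > j, in the row-major lower-triangle vector.
pair_pos <- function(i, j) (i - 1) * (i - 2) / 2 + j

# Separable Gaussian smoothing of a 3-D array (zero padding at edges).
smooth_gauss3d <- function(a, sd) {
  if (sd <= 0) return(a)
  r <- ceiling(3 * sd)
  kern <- exp(-((-r:r)^2) / (2 * sd^2))
  kern <- kern / sum(kern)
  band <- function(n) {
    b <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) b[cbind(idx + d, idx)] <- kern[d + r + 1]
      else b[cbind(idx, idx - d)] <- kern[-d + r + 1]
    }
    b
  }
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  m <- band(d[1]) %*% m
  a <- array(m, d)
  a <- aperm(a, c(2, 1, 3))
  m <- band(d[2]) %*% matrix(a, d[2], d[1] * d[3])
  a <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  m <- band(d[3]) %*% matrix(a, d[3], d[1] * d[2])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}
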