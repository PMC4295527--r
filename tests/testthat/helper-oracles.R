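# Shared fixtures (computed once per test run) and independent brute-force
# oracles used to cross-check the fast implementations.

fixture_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  got <- get0(name, envir = fixture_cache)
  if (is.null(got)) {
    got <- builder()
    assign(name, got, envir = fixture_cache)
  }
  got
}

# 30 structured frames and cheap low-level features for RDM/partition tests
fx_frames <- function() fx("frames", function()
  generate_frames(30, c(64, 64), seed = 101))
fx_gabor <- function() fx("gabor", function()
  hmax_features(fx_frames())$f_gabor)
fx_sift <- function() fx("sift", function()
  bow_features(fx_frames())$f_sift)
fx_rdm_gabor <- function() fx("rdm_gabor", function()
  compute_rdm(fx_gabor(), source = "F_gabor"))
fx_rdm_sift <- function() fx("rdm_sift", function()
  compute_rdm(fx_sift(), source = "F_sift"))

# 40-frame study-condition fixture for calibration / recovery runs
fx_frames40 <- function() fx("frames40", function()
  generate_frames(40, c(64, 64), seed = 11))
fx_gabor40 <- function() fx("gabor40", function()
  hmax_features(fx_frames40())$f_gabor)
fx_sift40 <- function() fx("sift40", function()
  bow_features(fx_frames40())$f_sift)

# --- oracles ---------------------------------------------------------------

# direct double-loop cross-correlation with mirror padding
naive_conv2 <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  ridx <- function(i) { i <- abs(i - 1) + 1; abs(nr - abs(nr - i)) }
  cidx <- function(j) { j <- abs(j - 1) + 1; abs(nc - abs(nc - j)) }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (u in seq_len(kr)) for (v in seq_len(kc))
      acc <- acc + k[u, v] * x[ridx(r + u - 1 - hr), cidx(cc + v - 1 - hc)]
    out[r, cc] <- acc
  }
  out
}

# exhaustive window/stride max
naive_win_max <- function(m, w, stride) {
  rows <- seq(1, nrow(m) - w + 1, by = stride)
  cols <- seq(1, ncol(m) - w + 1, by = stride)
  out <- matrix(0, length(rows), length(cols))
  for (a in seq_along(rows)) for (b in seq_along(cols))
    out[a, b] <- max(m[rows[a]:(rows[a] + w - 1), cols[b]:(cols[b] + w - 1)])
  out
}

# exhaustive S2 position/band scan for one prototype
naive_c2_one <- function(c1, rec, sigma = 1) {
  s <- rec$size
  n_orient <- dim(rec$patch)[3]
  np <- s * s * n_orient
  best <- -Inf
  for (b in seq_along(c1$bands)) {
    g <- dim(c1$bands[[b]][[1]])
    if (g[1] < s || g[2] < s) next
    for (r in seq_len(g[1] - s + 1)) for (cc in seq_len(g[2] - s + 1)) {
      d2 <- 0
      for (o in seq_len(n_orient))
        d2 <- d2 + sum((c1$bands[[b]][[o]][r:(r + s - 1), cc:(cc + s - 1)] -
                          rec$patch[, , o])^2)
      sim <- exp(-d2 / (2 * sigma^2 * np))
      if (sim > best) best <- sim
    }
  }
  if (is.finite(best)) best else 0
}

# exhaustive nearest-center assignment (lowest index wins ties)
naive_nn <- function(X, C) {
  apply(X, 1, function(x) {
    d <- colSums((t(C) - x)^2)
    which(d == min(d))[1]
  })
}

# direct pairwise distance matrix
naive_rdm <- function(m, metric = "euclidean") {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- if (metric == "euclidean") sqrt(sum((m[i, ] - m[j, ])^2))
                 else sum(abs(m[i, ] - m[j, ]))
  out
}

# normal-equations R^2 with intercept
naive_r2 <- function(yv, X) {
  Xf <- cbind(1, X)
  beta <- solve(crossprod(Xf), crossprod(Xf, yv))
  fit <- Xf %*% beta
  1 - sum((yv - fit)^2) / sum((yv - mean(yv))^2)
}

# exact distribution of the max cluster size on a small grid by
# enumerating every threshold pattern
exact_min_cluster_size <- function(dims, alpha, fwe_target,
                                   connectivity = 6) {
  nv <- prod(dims)
  stopifnot(nv <= 16)
  pmax_size <- numeric(nv + 1)   # P(max cluster size == s), s = 0..nv
  for (pat in 0:(2^nv - 1)) {
    bits <- as.integer(intToBits(pat)[seq_len(nv)])
    prob <- alpha^sum(bits) * (1 - alpha)^(nv - sum(bits))
    bin <- array(bits, dims)
    sz <- label_components(bin, connectivity)$sizes
    s <- if (length(sz)) max(sz) else 0
    pmax_size[s + 1] <- pmax_size[s + 1] + prob
  }
  exceed <- rev(cumsum(rev(pmax_size)))  # P(max >= s), s = 0..nv
  k <- 1
  while (k <= nv && exceed[k + 1] >= fwe_target) k <- k + 1
  k
}
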