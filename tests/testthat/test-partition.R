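random_rdm <- function(n, d = 5) compute_rdm(matrix(rnorm(n * d), n))

test_that("RDM regression matches the normal-equations oracle", {
  set.seed(31)
  for (k in 1:5) {
    n <- 20
    y <- random_rdm(n); fa <- random_rdm(n); fb <- random_rdm(n)
    r2 <- rdm_regression(y, list(fa, fb))
    oracle <- naive_r2(rdm_vectorize(y),
                       cbind(rdm_vectorize(fa), rdm_vectorize(fb)))
    expect_equal(r2, oracle, tolerance = 1e-10)
  }
  # a predictor explains itself exactly
  fa <- random_rdm(15)
  expect_equal(rdm_regression(fa, fa), 1)
  # independent target at n = 100 explains almost nothing
  set.seed(32)
  expect_lt(rdm_regression(random_rdm(100), random_rdm(100)), 0.05)
})

test_that("partition fractions obey the subtraction-scheme identities", {
  set.seed(41)
  y <- random_rdm(25); fa <- random_rdm(25); fb <- random_rdm(25)
  p <- partition(y, fa, fb)
  expect_equal(p$r2_unique_a + p$r2_unique_b + p$r2_shared, p$r2_full,
               tolerance = 1e-12)
  expect_equal(p$residual, 1 - p$r2_full, tolerance = 1e-12)
  # order symmetry: swapping predictors swaps the unique fractions
  q <- partition(y, fb, fa)
  expect_equal(q$r2_unique_a, p$r2_unique_b, tolerance = 1e-12)
  expect_equal(q$r2_unique_b, p$r2_unique_a, tolerance = 1e-12)
  expect_equal(q$r2_shared, p$r2_shared, tolerance = 1e-12)
  # identical predictors: nothing unique, everything shared
  pp <- suppressWarnings(partition(y, fa, fa))
  expect_equal(pp$r2_unique_a, 0, tolerance = 1e-10)
  expect_equal(pp$r2_unique_b, 0, tolerance = 1e-10)
  expect_equal(pp$r2_shared, pp$r2_full, tolerance = 1e-10)
})

test_that("a target built from one predictor loads only its unique fraction", {
  set.seed(43)
  n <- 30
  fa <- random_rdm(n)
  # orthogonalize a second predictor against the first in distance space
  fb0 <- random_rdm(n)
  va <- rdm_vectorize(fa); vb <- rdm_vectorize(fb0)
  vb_orth <- stats::resid(stats::lm(vb ~ va))
  vb_orth <- vb_orth - min(vb_orth)  # keep distances non-negative
  fb <- rdm(rdm_unvectorize(vb_orth, n))
  y <- fa
  p <- partition(y, fa, fb)
  expect_equal(p$r2_unique_b, 0, tolerance = 1e-9)
  expect_equal(p$r2_unique_a, p$r2_full, tolerance = 1e-9)
  expect_equal(p$r2_full, 1, tolerance = 1e-9)
})

test_that("permutation p-values are valid, extreme for strong signal, and deterministic", {
  set.seed(51)
  n <- 25
  fa <- random_rdm(n); fb <- random_rdm(n)
  # permutation-invariant target: all off-diagonal distances equal
  yflat <- rdm(matrix(1, n, n) - diag(1, n))
  pt <- permutation_test(yflat, fa, fb, "full", n_perm = 99, seed = 1)
  expect_equal(pt$p_value, 1)
  # strong planted signal reaches the smallest attainable p
  ys <- rdm(fa$matrix)
  pt2 <- permutation_test(ys, fa, fb, "full", n_perm = 199, seed = 2)
  expect_equal(pt2$p_value, 1 / 200)
  expect_true(all(unlist(pt2$p_all) >= 1 / 200 & unlist(pt2$p_all) <= 1))
  # determinism per seed
  y <- random_rdm(n)
  a <- permutation_test(y, fa, fb, "unique_a", n_perm = 99, seed = 9)
  b <- permutation_test(y, fa, fb, "unique_a", n_perm = 99, seed = 9)
  expect_identical(a$p_value, b$p_value)
  expect_error(permutation_test(y, fa, fb, n_perm = 50), "99")
})

test_that("null permutation p-values reject at close to nominal rate", {
  set.seed(61)
  n <- 20
  fa <- random_rdm(n); fb <- random_rdm(n)
  p <- replicate(120, {
    y <- random_rdm(n)
    permutation_test(y, fa, fb, "full", n_perm = 99,
                     seed = sample.int(1e6, 1))$p_value
  })
  rate <- mean(p < 0.05)
  ci <- 0.05 + c(-2, 2) * sqrt(0.05 * 0.95 / 120)
  expect_gte(rate, max(ci[1], 0))
  expect_lte(rate, ci[2] + 0.02)
})

test_that("voxel-wise partitioning keeps shape contracts and records skips", {
  fa <- fx_rdm_gabor(); fb <- fx_rdm_sift()
  br <- generate_subject(30, fx_gabor(), fx_sift(), w_a = 1, w_b = 0,
                         noise_sd = 0.3, grid = c(9, 9, 9),
                         region = central_block(c(9, 9, 9), 3), seed = 3)
  vp <- voxelwise_partition(br, fa, fb, n_perm = 99, seed = 5)
  for (m in vp$maps) {
    expect_identical(dim(m$values), dim(br$mask))
    expect_true(all(is.finite(m$values[m$mask > 0])))
  }
  # skipped = masked voxels without a full searchlight cube
  expect_equal(nrow(vp$voxels) + nrow(vp$skipped), sum(br$mask > 0))
  # decomposition identity at every analyzed voxel
  idx <- vp$voxels
  expect_equal(vp$maps$r2_unique_a$values[idx] + vp$maps$r2_unique_b$values[idx] +
                 vp$maps$r2_shared$values[idx],
               vp$maps$r2_full$values[idx], tolerance = 1e-10)
  # iteration-order independence: same master seed, restricted mask
  br2 <- br
  keep <- central_block(c(9, 9, 9), 3)   # the 4:6 cube
  m2 <- array(0, dim(br$mask)); m2[3:7, 3:7, 3:7] <- 1
  br2$mask <- m2
  vp2 <- voxelwise_partition(br2, fa, fb, n_perm = 99, seed = 5)
  common <- keep[1, , drop = FALSE]
  expect_equal(vp2$maps$p_full$values[common], vp$maps$p_full$values[common])
})
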