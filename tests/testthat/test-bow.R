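test_that("dense SIFT descriptors have standard geometry and normalization", {
  fs <- fx_frames()
  ds <- dense_sift(fs$frames[[1]])
  expect_equal(ncol(ds$descriptors), 128)
  ng <- length(seq(1, 64 - 16 + 1, by = 8))^2
  expect_equal(nrow(ds$descriptors), ng)
  nrms <- sqrt(rowSums(ds$descriptors^2))
  expect_true(all(nrms <= 1 + 1e-6))
  expect_true(all(ds$descriptors >= 0))
  # constant frame: zero gradients, all-zero descriptors
  dc <- dense_sift(matrix(0.4, 64, 64))
  expect_equal(max(abs(dc$descriptors)), 0)
  expect_error(dense_sift(matrix(0, 8, 8), patch = 16), "smaller")
})

test_that("a linear ramp concentrates mass in the gradient-direction bins", {
  # intensity increasing along columns: gradient points along +x, angle 0
  ramp <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64, 64)
  ds <- dense_sift(ramp)
  d <- ds$descriptors[5, ]
  byori <- rowSums(matrix(d, nrow = 8))  # cells are 8-bin blocks
  expect_identical(which.max(byori), 1L)
  expect_gt(byori[1] / sum(byori), 0.9)
})

test_that("sift vectors concatenate in fixed order and detect rearrangement", {
  fs <- fx_frames()
  ds <- dense_sift(fs$frames[[1]])
  v <- sift_vector(ds)
  expect_length(v, 128 * nrow(ds$descriptors))
  expect_identical(v[1:128], ds$descriptors[1, ])
  v2 <- sift_vector(dense_sift(fs$frames[[1]]))
  expect_identical(v, v2)
  flipped <- fs$frames[[1]][, 64:1]
  expect_gt(sum(abs(v - sift_vector(dense_sift(flipped)))), 0)
})

test_that("k-means codebook recovers well-separated cluster means", {
  set.seed(77)
  n <- 300
  blob1 <- matrix(rnorm(n * 2, mean = 0, sd = 0.5), n, 2)
  blob2 <- matrix(rnorm(n * 2, mean = 8, sd = 0.5), n, 2)
  cb <- learn_codebook(rbind(blob1, blob2), n_words = 2, seed = 5)
  cent <- cb$centers[order(cb$centers[, 1]), ]
  expect_lt(max(abs(cent[1, ] - colMeans(blob1))), 3 * 0.5 / sqrt(n))
  expect_lt(max(abs(cent[2, ] - colMeans(blob2))), 3 * 0.5 / sqrt(n))
  # inertia comparable to stats::kmeans as an independent check
  km <- stats::kmeans(rbind(blob1, blob2), 2, nstart = 5)
  expect_lt(cb$inertia, km$tot.withinss * 1.001 + 1e-9)
})

test_that("k-means is deterministic per seed with monotone inertia", {
  set.seed(3)
  X <- matrix(rnorm(500 * 4), 500, 4)
  cb1 <- learn_codebook(X, 20, seed = 9)
  cb2 <- learn_codebook(X, 20, seed = 9)
  expect_identical(cb1$centers, cb2$centers)
  expect_true(all(diff(cb1$inertia_trace) <= 1e-9))
  # M equal to the number of distinct points: zero inertia
  Xs <- matrix(rnorm(12 * 3), 12, 3)
  cb0 <- learn_codebook(Xs, 12, seed = 1)
  expect_lt(cb0$inertia, 1e-12)
  expect_equal(dim(cb0$centers), c(12L, 3L))
  expect_error(learn_codebook(Xs, 50, seed = 1), "12")
})

test_that("BoW encoding matches the exhaustive nearest-neighbor oracle", {
  set.seed(21)
  C <- matrix(rnorm(10 * 4), 10, 4)
  cb <- structure(list(centers = C, n_words = 10), class = "codebook")
  for (k in 1:5) {
    X <- matrix(rnorm(40 * 4), 40, 4)
    h <- encode_bow(X, cb)
    expect_equal(h, tabulate(naive_nn(X, C), 10))
    expect_equal(sum(h), 40)  # count conservation
  }
  # all descriptors exactly at center 3 -> one-hot histogram
  X3 <- C[rep(3, 7), ]
  expect_equal(encode_bow(X3, cb), c(0, 0, 7, rep(0, 7)))
  # tie between centers 1 and 2 resolves to the lowest index
  Ct <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  cbt <- structure(list(centers = Ct, n_words = 2), class = "codebook")
  expect_equal(encode_bow(matrix(c(1, 5), 1), cbt), c(1, 0))
  # frequency normalization
  expect_equal(sum(encode_bow(X3, cb, normalize = TRUE)), 1)
  expect_error(encode_bow(matrix(0, 2, 3), cb), "dim")
})

test_that("bow feature matrices have codebook-length histograms", {
  fs <- fx_frames()
  sub <- frame_set(fs$frames[1:6])
  cb <- learn_codebook(lapply(sub$frames, dense_sift), 16, seed = 2)
  bw <- bow_features(sub, codebook = cb)
  expect_equal(dim(bw$f_vdbow), c(6L, 16L))
  expect_equal(unname(rowSums(bw$f_vdbow)), rep(49, 6))
})
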