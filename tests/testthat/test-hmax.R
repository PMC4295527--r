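test_that("gabor bank filters are zero-mean and unit-norm", {
  bank <- gabor_bank()
  expect_length(bank$filters, 4)
  for (f in bank$filters) {
    expect_lt(abs(sum(f)), 1e-6 * sqrt(sum(f^2)))
    expect_equal(sum(f^2), 1, tolerance = 1e-12)
  }
})

test_that("pyramid has 10 levels with closed-form sizes", {
  frame <- matrix(runif(128 * 128), 128)
  pyr <- build_pyramid(frame)
  expect_length(pyr, 10)
  expect_identical(pyr[[1]], frame)
  fac <- 2^(-1 / 4)
  for (l in seq_along(pyr))
    expect_identical(dim(pyr[[l]]), as.integer(ceiling(128 * fac^(l - 1))) * c(1L, 1L))
  # constant frame stays constant at every level
  cpyr <- build_pyramid(matrix(0.7, 128, 128))
  for (lv in cpyr) expect_lt(max(abs(lv - 0.7)), 1e-9)
  expect_error(build_pyramid(matrix(0, 20, 20)), "level")
})

test_that("S1 responses vanish on constant input and detect edge orientation", {
  bank <- gabor_bank()
  s1 <- s1_convolve(build_pyramid(matrix(0.5, 64, 64)), bank)
  expect_lt(max(unlist(s1)), 1e-6)
  # vertical step edge: vertical-carrier filter wins at the edge locus
  edge <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  s1e <- s1_convolve(build_pyramid(edge), bank)
  resp <- vapply(s1e[[1]], function(m) m[32, 32], numeric(1))
  # orientation 1 (theta = 0) has carrier along x, i.e. responds to the
  # vertical edge; direct-convolution oracle agrees
  expect_identical(which.max(resp), 1L)
  oracle <- abs(naive_conv2(edge, bank$filters[[1]]))
  expect_equal(s1e[[1]][[1]], oracle, tolerance = 1e-9)
  expect_length(unlist(s1e, recursive = FALSE), 40)  # 10 scales x 4 orients
})

test_that("C1 pooling equals the brute-force window max", {
  set.seed(5)
  for (k in 1:5) {
    m <- matrix(rnorm(40 * 35), 40, 35)
    expect_equal(rsavp:::win_max(m, 10, 5), naive_win_max(m, 10, 5))
    expect_equal(rsavp:::win_max(m, 7, 3), naive_win_max(m, 7, 3))
  }
  # single nonzero S1 value lands in its covering C1 cells
  m <- matrix(0, 30, 30); m[12, 17] <- 3
  wm <- rsavp:::win_max(m, 10, 5)
  expect_equal(max(wm), 3)
  expect_true(all(wm %in% c(0, 3)))
  # 10 scales pool into 5 disjoint bands
  s1 <- s1_convolve(build_pyramid(matrix(runif(128 * 128), 128)), gabor_bank())
  c1 <- c1_pool(s1)
  expect_length(c1$bands, 5)
})

test_that("gabor vectors have conserved layout and discriminate rotation", {
  fs <- fx_frames()
  bank <- gabor_bank()
  c1 <- rsavp:::frame_c1(fs$frames[[1]], bank)
  v <- gabor_vector(c1)
  cells <- sum(vapply(c1$bands, function(b) prod(dim(b[[1]])), numeric(1)))
  expect_length(v, cells * 4)
  # identical frames -> identical vectors
  v2 <- gabor_vector(rsavp:::frame_c1(fs$frames[[1]], bank))
  expect_identical(v, v2)
  # a rotated grating is a different representation
  g <- rsavp:::with_rng(1, rsavp:::synth_grating(64, 64))
  vg <- gabor_vector(rsavp:::frame_c1(g, bank))
  vr <- gabor_vector(rsavp:::frame_c1(t(g), bank))
  expect_gt(sqrt(sum((vg - vr)^2)), 0)
})

test_that("prototype sampling is reproducible and extracts verbatim patches", {
  fs <- fx_frames()
  d1 <- sample_prototypes(fs, 12, c(4, 8), seed = 7)
  d2 <- sample_prototypes(fs, 12, c(4, 8), seed = 7)
  expect_equal(d1$patches, d2$patches)
  expect_length(d1$patches, 12)
  # each patch appears verbatim in its source frame's C1 maps
  rec <- d1$patches[[1]]
  c1 <- rsavp:::frame_c1(fs$frames[[rec$frame]], gabor_bank())
  got <- c1$bands[[rec$band]][[2]][rec$row:(rec$row + rec$size - 1),
                                   rec$col:(rec$col + rec$size - 1)]
  expect_equal(got, rec$patch[, , 2])
  expect_error(sample_prototypes(fs, 1e7, c(4, 8), seed = 1), "candidate")
})

test_that("C2 units match the exhaustive scan and attain their maximum", {
  fs <- fx_frames()
  dict <- sample_prototypes(fs, 6, c(4, 8), seed = 13)
  c1 <- rsavp:::frame_c1(fs$frames[[3]], gabor_bank())
  h <- s2_c2(c1, dict)
  expect_length(h, 6)
  expect_true(all(h > 0 & h <= 1))
  for (p in seq_along(dict$patches))
    expect_equal(h[p], naive_c2_one(c1, dict$patches[[p]]), tolerance = 1e-9)
  # verbatim prototype from this frame scores exactly 1
  dict3 <- sample_prototypes(fs, 4, c(4, 8), seed = 21,
                             c1_list = list(c1))
  h3 <- s2_c2(c1, dict3)
  expect_equal(h3, rep(1, 4), tolerance = 1e-12)
})

test_that("dictionary features are more translation-tolerant than Gabor", {
  bank <- gabor_bank()
  rel_change <- function(v1, v2) sqrt(sum((v1 - v2)^2)) / sqrt(sum(v1^2))
  dg <- dh <- numeric(0)
  for (s in 1:10) {
    g <- rsavp:::with_rng(s, rsavp:::synth_grating(72, 72))
    shift <- 2   # half the C1 stride is 2.5
    f1 <- g[1:64, 1:64]; f2 <- g[1:64 + shift, 1:64]
    fs2 <- frame_set(list(f1, f2))
    dict <- sample_prototypes(fs2, 8, c(4, 8), seed = s)
    hm <- hmax_features(fs2, dict = dict, bank = bank)
    dg[s] <- rel_change(hm$f_gabor[1, ], hm$f_gabor[2, ])
    dh[s] <- rel_change(hm$f_vdhmax[1, ], hm$f_vdhmax[2, ])
  }
  expect_lt(mean(dh), mean(dg))
})
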