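test_that("connected components respect the stated connectivity", {
  a <- array(0, c(4, 4, 1))
  a[1, 1, 1] <- 1; a[2, 2, 1] <- 1   # touch only diagonally
  expect_length(label_components(a, 6)$sizes, 2)
  expect_length(label_components(a, 26)$sizes, 1)
  b <- array(0, c(5, 5, 5))
  b[2:4, 2:4, 2:4] <- 1
  lc <- label_components(b, 6)
  expect_equal(lc$sizes, 27)
  expect_equal(sum(lc$labels > 0), 27)
  expect_length(label_components(array(0, c(3, 3, 3)), 6)$sizes, 0)
})

test_that("cluster thresholding keeps blocks and removes scattered voxels", {
  dims <- c(16, 16, 16)
  mask <- array(1, dims)
  p <- array(0.5, dims)
  blk <- central_block(dims, 4)
  p[blk] <- 0.001
  # 24 isolated significant voxels far from the block and each other
  iso <- as.matrix(expand.grid(x = c(1, 5, 13, 16), y = c(1, 8, 16),
                               z = c(2, 15)))
  p[iso] <- 0.001
  rep_ <- cluster_threshold(stat_volume(p, mask, "p"), alpha = 0.05,
                            min_size = 25)
  expect_length(rep_$sizes, 1)
  expect_equal(rep_$sizes, 64)
  expect_equal(sum(rep_$significant), 64)
  expect_true(all(rep_$significant[blk]))
  # anti-extensivity: correction never adds voxels
  expect_true(all(which(rep_$significant) %in% which(p < 0.05)))
  # nothing below alpha -> empty report
  empty <- cluster_threshold(stat_volume(array(0.9, dims), mask, "p"))
  expect_length(empty$sizes, 0)
  expect_error(cluster_threshold(stat_volume(array(0, dims), mask, "p")),
               "0, 1")
})

test_that("Monte-Carlo minimum cluster size matches exhaustive enumeration", {
  # tiny alpha: no suprathreshold voxels, minimum size 1
  expect_equal(as.integer(mc_cluster_size(c(8, 8, 8), alpha = 1e-6,
                                          n_sim = 200, seed = 1)), 1L)
  # 4 x 4 x 1 grid against the exact enumeration oracle
  for (alpha in c(0.15, 0.3)) {
    mc <- mc_cluster_size(c(4, 4, 1), alpha = alpha, fwe_target = 0.05,
                          n_sim = 3000, seed = 7)
    expect_equal(as.integer(mc),
                 exact_min_cluster_size(c(4, 4, 1), alpha, 0.05))
  }
  # monotone: a stricter voxel threshold never needs a larger cluster
  sizes <- vapply(c(0.01, 0.05, 0.2), function(a)
    as.integer(mc_cluster_size(c(10, 10, 10), alpha = a, n_sim = 300,
                               seed = 3)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("the Monte-Carlo threshold controls family-wise error on fresh nulls", {
  dims <- c(12, 12, 12)
  k <- as.integer(mc_cluster_size(dims, alpha = 0.05, fwe_target = 0.05,
                                  n_sim = 500, seed = 11))
  hits <- rsavp:::with_rng(99, {
    replicate(300, {
      bin <- array(runif(prod(dims)) < 0.05, dims)
      sz <- label_components(bin, 6)$sizes
      length(sz) && max(sz) >= k
    })
  })
  rate <- mean(hits)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})

test_that("consistency maps count subjects and localize shared structure", {
  dims <- c(10, 10, 10)
  mask <- array(1, dims)
  blk <- central_block(dims, 3)
  mk_report <- function(sig) {
    lab <- array(0L, dims); lab[sig] <- 1L
    structure(list(labels = lab, sizes = sum(lab), significant = lab > 0,
                   mask = mask, alpha = 0.05, min_size = 25,
                   connectivity = 6), class = "cluster_report")
  }
  reports <- replicate(20, mk_report(blk), simplify = FALSE)
  cm <- consistency_map(reports, smooth_sd = 0, n_perm = 99, seed = 5)
  expect_true(all(cm$counts %in% c(0, 20)))
  expect_equal(unname(cm$counts[blk]), rep(20, 27))
  expect_true(all(cm$significant[blk]))
  far <- matrix(c(1, 1, 1), 1)
  expect_false(any(cm$significant[far]))
  # subject order is irrelevant
  cm2 <- consistency_map(rev(reports), smooth_sd = 0, n_perm = 0)
  expect_identical(cm2$counts, cm$counts)
  # uniform coverage: chi-square identically zero
  all_cover <- replicate(4, mk_report(which(mask > 0, arr.ind = TRUE)),
                         simplify = FALSE)
  cmu <- consistency_map(all_cover, smooth_sd = 0, n_perm = 0)
  expect_equal(max(cmu$chi_sq$values), 0)
  expect_false(any(cmu$significant))
})

test_that("ROI summaries match hand counts on a toy volume", {
  dims <- c(6, 6, 6)
  roi <- array(0L, dims)
  roi[1:3, , ] <- 1L; roi[4:6, , ] <- 2L
  roi[6, 6, 6] <- 3L
  mask <- array(1, dims)
  r2a <- array(0.02, dims); r2a[1, 1, 1] <- 0.07; r2a[6, 6, 6] <- 0.04
  sig1 <- array(FALSE, dims); sig1[1:2, 1, 1] <- TRUE; sig1[6, 6, 6] <- TRUE
  sig2 <- array(FALSE, dims); sig2[2:3, 1, 1] <- TRUE
  mk <- function(sig) structure(list(significant = sig, mask = mask),
                                class = "cluster_report")
  tab <- roi_summary(list(stat_volume(r2a, mask, "r2"),
                          stat_volume(r2a, mask, "r2")),
                     list(mk(sig1), mk(sig2)), roi,
                     roi_names = c("1" = "V1", "2" = "V2", "3" = "pt",
                                   "4" = "absent"))
  v1 <- tab[tab$roi == "V1", ]
  expect_equal(v1$n_significant, 3)  # union of {1,2} and {2,3}
  expect_equal(v1$max_ev, 7)         # percent
  # mean over per-subject significant voxels: (7+2+2+2)/4
  expect_equal(v1$mean_ev, 100 * mean(c(0.07, 0.02, 0.02, 0.02)))
  # single-voxel ROI: max equals mean equals the value
  pt <- tab[tab$roi == "pt", ]
  expect_equal(pt$n_significant, 1)
  expect_equal(pt$max_ev, 4)
  expect_equal(pt$mean_ev, 4)
  # ROI with no significant voxels (and absent labels) give zero rows
  v2 <- tab[tab$roi == "V2", ]
  expect_equal(v2$n_significant, 0)
  expect_equal(v2$max_ev, 0)
  expect_equal(tab[tab$roi == "absent", ]$n_significant, 0)
})
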