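# Group t-maps, conjunction logic, cluster labelling, Monte-Carlo extent
# threshold.

test_that("one-sample t matches the closed form on (1, 2, 3)", {
  g <- group_ttest(list(1, 2, 3))
  expect_equal(g$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(g$t, 3.464, tolerance = 1e-3)
  expect_equal(g$p_one_sided, stats::pt(g$t, df = 2, lower.tail = FALSE))
})

test_that("zero-variance voxels are masked out and reported", {
  maps <- list(c(1, 2), c(1, 3), c(1, 4))
  g <- group_ttest(maps)
  expect_true(is.na(g$t[1]))
  expect_identical(g$degenerate_voxels, 1L)
  expect_false(is.na(g$t[2]))
})

test_that("grid mismatches and tiny groups are rejected", {
  expect_error(group_ttest(list(1:3, 1:4)), "grid mismatch")
  expect_error(group_ttest(list(1:3)), "at least 2")
})

test_that("the conjunction mask is the intersection of suprathreshold sets", {
  set.seed(5)
  n <- 10
  mk <- function() group_ttest(lapply(1:8, function(i) stats::rnorm(200)))
  a <- mk(); b <- mk()
  m <- conjunction_mask(a, b, voxel_p = 0.1)
  expect_true(all(m <= (a$p_one_sided < 0.1)))
  expect_true(all(m <= (b$p_one_sided < 0.1)))
  expect_identical(m, (a$p_one_sided < 0.1) & (b$p_one_sided < 0.1))
  # one map entirely non-significant -> empty conjunction
  b0 <- b; b0$p_one_sided[] <- 0.9
  expect_false(any(conjunction_mask(a, b0, 0.001)))
})

test_that("cluster labelling matches the flood-fill oracle on random masks", {
  set.seed(6)
  for (conn in c(6, 18, 26)) {
    for (i in 1:4) {
      mask <- array(stats::runif(10^3) < 0.25, c(10, 10, 10))
      lab <- neuroverlap:::label_components(mask, conn)
      orc <- oracle_flood_fill(mask, conn)
      # same partition: sizes of matched components agree
      expect_identical(lab > 0, orc > 0)
      for (id in setdiff(unique(as.vector(orc)), 0)) {
        vox <- which(orc == id)
        expect_identical(length(unique(lab[vox])), 1L)
        expect_identical(sum(lab == lab[vox[1]]), length(vox))
      }
    }
  }
})

test_that("two face-touching blobs merge into one 30-voxel cluster", {
  mask <- array(FALSE, c(12, 12, 12))
  mask[2:6, 2:3, 2] <- TRUE          # 5x2x1 = 10 voxels
  mask[2:6, 4:7, 2] <- TRUE          # 5x4x1 = 20 voxels, shares the y=3/4 face
  tab <- label_clusters(mask, k_min = 18)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$size_voxels, 30L)
  # with a higher floor the merged cluster still survives; alone, the small
  # blob would not
  tab2 <- label_clusters(array(mask & (slice.index(mask, 2) <= 3), dim(mask)),
                         k_min = 18)
  expect_identical(nrow(tab2), 0L)
})

test_that("a planted 264-voxel blob is recovered with its peak", {
  mask <- array(FALSE, c(24, 24, 24))
  mask[3:13, 5:10, 7:10] <- TRUE     # 11 x 6 x 4 = 264 voxels
  stat <- array(0, c(24, 24, 24))
  stat[8, 7, 9] <- 12
  tab <- label_clusters(mask, k_min = 18, stat = stat,
                        spec = acquisition_spec())
  expect_identical(tab$size_voxels, 264L)
  expect_identical(c(tab$peak_i, tab$peak_j, tab$peak_k), c(7L, 6L, 8L))
  expect_equal(tab$peak_stat, 12)
  # mm coordinates follow the centred RAS affine
  expect_equal(tab$peak_x_mm, (7 - 11.5) * 2.5)
})

test_that("empty masks give an empty table", {
  tab <- label_clusters(array(FALSE, c(6, 6, 6)), k_min = 1)
  expect_identical(nrow(tab), 0L)
})

test_that("cluster-extent threshold is monotone in smoothness and alpha", {
  ks <- vapply(c(0, 5, 9), function(fw)
    estimate_cluster_threshold(c(14, 14, 14), 2.5, fw, voxel_p = 0.01,
                               alpha = 0.05, n_iterations = 1000,
                               seed = 99)$k_threshold, integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_gt(ks[3], ks[1])
  # stricter forming threshold -> smaller clusters -> k does not increase
  k_strict <- estimate_cluster_threshold(c(14, 14, 14), 2.5, 9,
                                         voxel_p = 0.0005, alpha = 0.05,
                                         n_iterations = 1000,
                                         seed = 99)$k_threshold
  expect_lte(k_strict, ks[3])
  # more lenient alpha -> smaller or equal k
  r <- estimate_cluster_threshold(c(14, 14, 14), 2.5, 6, voxel_p = 0.01,
                                  alpha = 0.05, n_iterations = 1000, seed = 7)
  k_rel <- max(1, ceiling(stats::quantile(r$null_max_sizes, 1 - 0.2,
                                          names = FALSE, type = 1)))
  expect_lte(k_rel, r$k_threshold)
  expect_error(estimate_cluster_threshold(c(14, 14, 14), 2.5, 6,
                                          n_iterations = 500), "1000")
})

test_that("smoothness estimation recovers the generating FWHM roughly", {
  set.seed(8)
  spec <- acquisition_spec(grid_shape = c(20, 20, 20))
  Y <- matrix(stats::rnorm(30 * 8000), 30)
  S <- neuroverlap:::smooth_timeseries(Y, spec$grid_shape, 6, 2.5)
  est <- estimate_smoothness_fwhm(S, spec)
  expect_gt(est, 4); expect_lt(est, 8)
  # white residuals -> near-zero smoothness
  expect_lt(estimate_smoothness_fwhm(Y, spec), 2)
})
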