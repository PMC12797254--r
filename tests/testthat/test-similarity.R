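# Naive RSA: Fisher transform, Steiger's Z, group tests, Sidak correction,
# pattern extraction.

test_that("fisher_z matches the closed form and is odd", {
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_identical(fisher_z(0), 0)
  for (r in c(0.1, 0.37, 0.83, 0.999))
    expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("steiger_z vanishes when the compared correlations are equal", {
  for (r23 in c(-0.5, 0, 0.4, 0.9))
    expect_identical(steiger_z(0.3, 0.3, r23, 100), 0)
})

test_that("steiger_z is antisymmetric and monotone in the z difference", {
  z1 <- steiger_z(0.5, 0.2, 0.4, 150)
  z2 <- steiger_z(0.2, 0.5, 0.4, 150)
  expect_equal(z1, -z2, tolerance = 1e-12)
  expect_gt(z1, 0)
  ladder <- vapply(c(0.25, 0.35, 0.45, 0.55), function(r12)
    steiger_z(r12, 0.2, 0.4, 150), numeric(1))
  expect_true(all(diff(ladder) > 0))
  expect_error(steiger_z(0.5, 0.2, 0.4, 3), "n >= 4")
  expect_error(steiger_z(1, 0.2, 0.4, 50), "\\|r\\| < 1")
})

test_that("steiger_z null rejection rate is calibrated (small Monte Carlo)", {
  # null: rho12 = rho13 = 0.3, rho23 = 0.5; 2000 replicates at n = 200
  C <- matrix(c(1, .3, .3, .3, 1, .5, .3, .5, 1), 3, 3)
  L <- chol(C)
  set.seed(11)
  n <- 200; n_rep <- 2000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    X <- matrix(stats::rnorm(n * 3), n, 3) %*% L
    r <- stats::cor(X)
    z <- steiger_z(r[1, 2], r[1, 3], r[2, 3], n)
    rej[i] <- abs(z) > 1.96
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("similarity_record is invariant to affine rescaling of patterns", {
  tw <- tiny_world()
  U <- simulate_pattern_set(tw$truth, "roi", seed = 3,
                            conditions = c("Small", "Large", "Rhyme"))
  ps <- structure(list(roi_id = "roi", conditions = rownames(U),
                       patterns = U, n_voxels = ncol(U)),
                  class = "roi_pattern_set")
  rec <- similarity_record(ps)
  ps2 <- ps; ps2$patterns <- 3.2 * U + 7
  rec2 <- similarity_record(ps2)
  expect_equal(rec$r_small_rhyme, rec2$r_small_rhyme, tolerance = 1e-12)
  expect_equal(rec$steiger_z, rec2$steiger_z, tolerance = 1e-12)
  # bookkeeping invariants
  expect_equal(rec$z_small_rhyme, atanh(rec$r_small_rhyme))
  expect_identical(sign(rec$steiger_z),
                   sign(rec$z_small_rhyme - rec$z_large_rhyme))
})

test_that("patterns extracted from noiseless fits equal the generating patterns", {
  tw <- tiny_world(n = 6, noise_sd = 0, spatial_fwhm_mm = 0,
                   ar1_coefficient = 0)
  subj <- generate_subject(1, tw$truth, tw$spec, seed = 13)
  fits <- list(fit_task(subj, "arithmetic", tw$spec),
               fit_task(subj, "rhyming", tw$spec))
  pats <- extract_roi_patterns(fits, tw$masks$roi)
  u <- simulate_pattern_set(subj$truth, "roi",
                            seed = derive_seed(subj$truth$seed, "patterns", "roi"))
  for (cc in c("Small", "Large", "Rhyme")) {
    amp <- tw$truth$amplitudes$roi[[cc]]
    truef <- amp * (tw$truth$pattern_mean + tw$truth$pattern_sd * u[cc, ])
    expect_lt(max(abs(pats$patterns[cc, ] - truef)), 1e-8)
  }
  # canonical voxel ordering: shuffling the index input does not matter
  vox <- which(tw$masks$roi)
  pats2 <- extract_roi_patterns(fits, sample(vox))
  expect_identical(pats$patterns, pats2$patterns)
  expect_error(extract_roi_patterns(fits, array(FALSE, dim(tw$masks$roi))),
               "empty")
})

test_that("group_steiger_test matches the t oracle and rejects degenerate input", {
  g <- group_steiger_test(c(1, 2, 3), alpha_corrected = 0.017)
  expect_equal(g$t, 3.4641016, tolerance = 1e-6)
  expect_equal(g$p, 2 * stats::pt(-g$t, df = 2), tolerance = 1e-12)
  expect_error(group_steiger_test(rep(0, 5)), "zero variance")
  expect_error(group_steiger_test(1.5), "2 participants")
})

test_that("dunn_sidak reproduces the published corrected alphas and identity", {
  expect_equal(round(dunn_sidak(0.05, 3), 3), 0.017)
  expect_equal(round(dunn_sidak(0.05, 4), 3), 0.013)
  expect_equal(dunn_sidak(0.05, 1), 0.05, tolerance = 1e-12)
  for (m in 1:50)
    expect_equal((1 - dunn_sidak(0.05, m))^m, 0.95, tolerance = 1e-12)
})
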