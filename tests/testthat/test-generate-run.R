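# Forward model of the BOLD generator.

test_that("zero noise and zero amplitudes give constant baseline data", {
  tw <- tiny_world(n = 6, noise_sd = 0, spatial_fwhm_mm = 0,
                   ar1_coefficient = 0)
  tw$truth$amplitudes <- lapply(tw$truth$amplitudes, function(a) a * 0)
  d <- make_block_design("arithmetic", tw$spec, seed = 1)
  run <- generate_run(d, tw$truth, tw$spec, seed = 1, motion_walk_sd = 0)
  expect_true(all(run$data == 100))
  expect_true(all(run$global_signal == 100))
})

test_that("with zero noise a voxel time course is the scaled convolved boxcar", {
  tw <- tiny_world(n = 6, noise_sd = 0, spatial_fwhm_mm = 0,
                   ar1_coefficient = 0)
  # single responsive condition
  tw$truth$amplitudes <- list(roi = c(Small = 1))
  d <- make_block_design("arithmetic", tw$spec, seed = 2)
  run <- generate_run(d, tw$truth, tw$spec, seed = 5, motion_walk_sd = 0,
                      baseline = 0)
  ev <- d$events[d$events$condition == "Small", ]
  reg <- hrf_regressor(ev$onset_s, ev$duration_s, tw$spec)
  u <- simulate_pattern_set(tw$truth, "roi",
                            seed = derive_seed(tw$truth$seed, "patterns", "roi"))
  pat <- 1 * (tw$truth$pattern_mean + tw$truth$pattern_sd * u["Small", ])
  for (v in c(1, 100, 216)) {
    expect_equal(run$data[, v], reg * pat[v], tolerance = 1e-12)
  }
})

test_that("noiseless GLM fits recover the generating per-voxel effects to 1e-8", {
  tw <- tiny_world(n = 6, noise_sd = 0, spatial_fwhm_mm = 0,
                   ar1_coefficient = 0)
  d <- make_block_design("arithmetic", tw$spec, seed = 7)
  run <- generate_run(d, tw$truth, tw$spec, seed = 3)
  dm <- build_design_matrix(d, tw$spec, motion = run$motion)
  fit <- fit_glm(run, dm)
  u <- simulate_pattern_set(tw$truth, "roi",
                            seed = derive_seed(tw$truth$seed, "patterns", "roi"))
  for (cc in c("Small", "Large", "PlusOne")) {
    amp <- tw$truth$amplitudes$roi[[cc]]
    truef <- amp * (tw$truth$pattern_mean + tw$truth$pattern_sd * u[cc, ])
    expect_lt(max(abs(fit$betas[cc, ] - truef)), 1e-8)
  }
})

test_that("an injected motion spike is flagged by outlier detection", {
  tw <- tiny_world(n = 6)
  d <- make_block_design("arithmetic", tw$spec, seed = 4)
  run <- generate_run(d, tw$truth, tw$spec, seed = 8,
                      motion_spikes = data.frame(volume = 100, mm = 2))
  rep <- flag_outlier_volumes(run$motion, run$global_signal)
  expect_true(100 %in% rep$flagged_volumes)
  expect_identical(unname(rep$reasons["100"]), "displacement")
  # and an injected global-signal deviation is flagged as signal
  run2 <- generate_run(d, tw$truth, tw$spec, seed = 8,
                       signal_spikes = data.frame(volume = 50, sd = 8))
  rep2 <- flag_outlier_volumes(run2$motion, run2$global_signal)
  expect_true(50 %in% rep2$flagged_volumes)
})

test_that("cohorts are deterministic under the master seed and subjects differ", {
  tw <- tiny_world(n = 6)
  c1 <- generate_cohort(2, tw$truth, tw$spec, seed = 21)
  c2 <- generate_cohort(2, tw$truth, tw$spec, seed = 21)
  expect_identical(c1$subjects[[1]]$runs$arithmetic_1$data,
                   c2$subjects[[1]]$runs$arithmetic_1$data)
  expect_identical(c1$subjects[[2]]$runs$rhyming_2$data,
                   c2$subjects[[2]]$runs$rhyming_2$data)
  expect_false(identical(c1$subjects[[1]]$runs$arithmetic_1$data,
                         c1$subjects[[2]]$runs$arithmetic_1$data))
  # a cohort of one is a valid first-level input
  c3 <- generate_cohort(1, tw$truth, tw$spec, seed = 5)
  expect_length(c3$subjects, 1)
  expect_named(c3$subjects[[1]]$runs,
               c("arithmetic_1", "arithmetic_2", "rhyming_1", "rhyming_2"))
})
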