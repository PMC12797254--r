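# Schedule generator: printed timing structure, determinism, validation.

expected_trials <- list(arithmetic = list(n = 36, per_block = 6, stim = 3.5,
                                          itis = c(1, 1.5, 2), iti_sum = 9),
                        rhyming = list(n = 30, per_block = 5, stim = 4,
                                       itis = c(1.5, 2, 2.5), iti_sum = 10))

test_that("schedules honour the printed block and run timing", {
  for (task in c("arithmetic", "rhyming")) {
    ex <- expected_trials[[task]]
    for (seed in 1:4) {
      d <- make_block_design(task, acquisition_spec(), seed = seed)
      ev <- d$events
      expect_equal(nrow(ev), ex$n)
      # per-condition trial counts are balanced
      expect_true(all(table(ev$condition) == ex$n / length(unique(ev$condition))))
      expect_true(all(ev$duration_s == ex$stim))
      # block structure: trials fall into 6 blocks of per_block trials
      block_id <- rep(1:6, each = ex$per_block)
      expect_identical(length(unique(ev$condition[block_id == 1])), 1L)
      for (b in 1:6) {
        on <- ev$onset_s[block_id == b]
        expect_identical(length(unique(ev$condition[block_id == b])), 1L)
        gaps <- diff(on) - ex$stim
        expect_true(all(vapply(gaps, function(g)
          any(abs(g - ex$itis) < 1e-9), logical(1))))
        # the unobserved trailing ITI closes the block to exactly 30 s
        trailing <- ex$iti_sum - sum(gaps)
        expect_true(any(abs(trailing - ex$itis) < 1e-9))
        span <- (max(on) + ex$stim + trailing) - min(on)
        expect_equal(span, 30)
      }
      # fixation intervals: before each block and a final one, jittered
      # around 9 s and rescaled so the run is exactly 244 s
      starts <- ev$onset_s[block_id %in% 1:6 & !duplicated(block_id)]
      fix <- c(starts[1], diff(starts) - 30, 244 - (starts[6] + 30))
      expect_true(all(fix > 8.2 & fix < 10.1))
      expect_equal(sum(fix), 244 - 180)
      expect_true(all(ev$onset_s + ev$duration_s < 244))
    }
  }
})

test_that("schedules are deterministic under a fixed seed and vary across seeds", {
  a1 <- make_block_design("rhyming", seed = 11)
  a2 <- make_block_design("rhyming", seed = 11)
  expect_identical(a1$events, a2$events)
  a3 <- make_block_design("rhyming", seed = 12)
  expect_false(identical(a1$events, a3$events))
})

test_that("a run too short for the schedule is a configuration error", {
  expect_error(make_block_design("arithmetic",
                                 acquisition_spec(n_volumes = 200)),
               "shorter than")
})

test_that("incorrect trials appear at the configured rate", {
  d <- make_block_design("arithmetic", seed = 3, p_correct = 0.5)
  expect_true(any(!d$events$correct) && any(d$events$correct))
  expect_true(all(make_block_design("arithmetic", seed = 3)$events$correct))
})

test_that("block_design validates vocabulary, overlap and ordering", {
  ev <- data.frame(condition = "Rhyme", onset_s = 10, duration_s = 4,
                   correct = TRUE)
  expect_error(block_design("arithmetic", ev), "invalid condition")
  ev2 <- data.frame(condition = c("Small", "Small"), onset_s = c(10, 12),
                    duration_s = c(3.5, 3.5), correct = TRUE)
  expect_error(block_design("arithmetic", ev2), "overlap")
  ev3 <- data.frame(condition = c("Small", "Large"), onset_s = c(20, 10),
                    duration_s = 3.5, correct = TRUE)
  expect_warning(d <- block_design("arithmetic", ev3), "sort")
  expect_identical(d$events$condition, c("Large", "Small"))
  expect_error(block_design("arithmetic", ev3[2, ], run_duration_s = 12),
               "past the scheduled run duration")
})
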