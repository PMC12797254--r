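# Two-task block design: event schedules for the arithmetic and rhyming runs.

#' Construct a block design from an event table
#'
#' Low-level constructor; most users will call [make_block_design()]. Events
#' must belong to the task's condition vocabulary (arithmetic: Small, Large,
#' PlusOne; rhyming: Rhyme, LetterMatch), be sorted by onset, non-overlapping,
#' and end before the run does.
#'
#' @param task `"arithmetic"` or `"rhyming"`.
#' @param events data.frame with columns `condition`, `onset_s`, `duration_s`,
#'   `correct` (logical).
#' @param run_label identifier for the run.
#' @param run_duration_s scheduled run duration in seconds (used for
#'   validation); may be `NA` to skip the end-of-run check.
#' @return an object of class `block_design`.
#' @export
block_design <- function(task, events, run_label = "run-01",
                         run_duration_s = NA_real_) {
  task <- match.arg(task, c("arithmetic", "rhyming"))
  stopifnot(is.data.frame(events),
            all(c("condition", "onset_s", "duration_s", "correct") %in% names(events)))
  valid <- task_conditions(task)
  bad <- setdiff(unique(as.character(events$condition)), valid)
  if (length(bad))
    stop_input("invalid condition(s) for ", task, " task: ",
               paste(bad, collapse = ", "),
               " (valid: ", paste(valid, collapse = ", "), ")")
  if (any(events$onset_s < 0) || any(events$duration_s <= 0))
    stop_input("events need onset_s >= 0 and duration_s > 0")
  o <- order(events$onset_s)
  if (is.unsorted(events$onset_s)) {
    warning("events were not sorted by onset; sorting", call. = FALSE)
    events <- events[o, , drop = FALSE]
  }
  ends <- events$onset_s + events$duration_s
  if (nrow(events) > 1 && any(events$onset_s[-1] < ends[-nrow(events)] - 1e-9))
    stop_input("events overlap in time")
  if (is.finite(run_duration_s) && any(ends > run_duration_s + 1e-9))
    stop_input("events extend past the scheduled run duration (",
               run_duration_s, " s)")
  rownames(events) <- NULL
  events$condition <- as.character(events$condition)
  events$correct <- as.logical(events$correct)
  structure(list(task = task, events = events, run_label = run_label,
                 run_duration_s = run_duration_s),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> task = %s, %d events, run %s\n",
              x$task, nrow(x$events), x$run_label))
  invisible(x)
}

# Sample a multiset of ITIs from `choices` (a symmetric ladder) whose sum is
# exactly `target`, returned in random order. Valid count vectors are
# enumerated and one is drawn uniformly.
sample_itis <- function(n, choices, target) {
  grid <- expand.grid(lapply(seq_along(choices), function(i) 0:n))
  ok <- rowSums(grid) == n &
    abs(as.matrix(grid) %*% choices - target) < 1e-9
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) stop_input("no ITI multiset of size ", n, " sums to ", target)
  pick <- grid[sample.int(nrow(grid), 1), ]
  sample(rep(choices, times = as.integer(pick)))
}

#' Generate a randomized block schedule for one run
#'
#' Builds the event list for one run of either task, honouring the printed
#' timing structure: arithmetic runs contain 6 blocks (2 per condition in
#' seed-permuted order) of 6 trials x 3.5 s with inter-trial intervals drawn
#' from \{1, 1.5, 2\} s; rhyming runs contain 6 blocks (3 Rhyme, 3
#' LetterMatch) of 5 trials x 4 s with ITIs from \{1.5, 2, 2.5\} s. Within a
#' block the ITI multiset is constrained so every block lasts exactly 30 s.
#' Fixation intervals (one before each block plus a final one) are drawn
#' uniformly from [8.6, 9.4] s and rescaled so the run totals exactly 244 s.
#'
#' @param task `"arithmetic"` or `"rhyming"`.
#' @param spec an [acquisition_spec()]; the run must be at least 244 s long.
#' @param seed integer seed; identical seeds give identical schedules.
#' @param p_correct probability that a trial is answered correctly
#'   (default 1); incorrect trials later feed a dedicated nuisance regressor.
#' @param run_label identifier stored in the design.
#' @return a [block_design()].
#' @examples
#' d <- make_block_design("arithmetic", acquisition_spec(), seed = 1)
#' range(d$events$onset_s + d$events$duration_s)  # all events end before 244 s
#' @export
make_block_design <- function(task, spec = acquisition_spec(), seed = 1,
                              p_correct = 1, run_label = NULL) {
  task <- match.arg(task, c("arithmetic", "rhyming"))
  total_s <- 244
  if (run_duration(spec) < total_s - 1e-9)
    stop_input("run duration ", run_duration(spec),
               " s is shorter than the scheduled ", total_s, " s")
  if (task == "arithmetic") {
    block_conds_pool <- rep(ARITH_CONDITIONS, each = 2)
    n_trials <- 6; stim_s <- 3.5
    iti_choices <- c(1, 1.5, 2); iti_target <- 9
  } else {
    block_conds_pool <- rep(RHYME_CONDITIONS, each = 3)
    n_trials <- 5; stim_s <- 4
    iti_choices <- c(1.5, 2, 2.5); iti_target <- 10
  }
  n_blocks <- length(block_conds_pool)
  block_s <- n_trials * stim_s + iti_target  # 30 s by construction
  fix_total <- total_s - n_blocks * block_s  # 64 s
  n_fix <- n_blocks + 1                      # before each block + final

  with_seed(seed, {
    block_conds <- sample(block_conds_pool)
    fix <- runif(n_fix, 8.6, 9.4)
    fix <- fix * fix_total / sum(fix)
    rows <- vector("list", n_blocks)
    t0 <- fix[1]
    for (b in seq_len(n_blocks)) {
      itis <- sample_itis(n_trials, iti_choices, iti_target)
      onsets <- t0 + c(0, cumsum(stim_s + itis))[seq_len(n_trials)]
      rows[[b]] <- data.frame(condition = block_conds[b],
                              onset_s = onsets,
                              duration_s = stim_s,
                              correct = runif(n_trials) <= p_correct)
      t0 <- t0 + block_s + fix[b + 1]
    }
    events <- do.call(rbind, rows)
    stopifnot(abs(t0 - total_s) < 1e-6)
    block_design(task, events,
                 run_label = run_label %||% paste0("sim-", task),
                 run_duration_s = run_duration(spec))
  })
}
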