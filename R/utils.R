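# Internal utilities: seed handling, small helpers.

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed; component
#' sub-streams (per subject, per run, per ROI, ...) are derived by hashing the
#' master seed together with a string tag. This makes any single component
#' independently reproducible without consuming a global RNG stream.
#'
#' @param seed integer master seed.
#' @param ... character or numeric tags identifying the sub-stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  tag <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                      character(1)), collapse = "::")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  # avoid 0 (set.seed(0) is legal but keep strictly positive for clarity)
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a style 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp output tables with a config fingerprint (no external digest
# dependency).
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), code)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# condition vocabularies
ARITH_CONDITIONS <- c("Small", "Large", "PlusOne")
RHYME_CONDITIONS <- c("Rhyme", "LetterMatch")
ALL_CONDITIONS   <- c(ARITH_CONDITIONS, RHYME_CONDITIONS)

task_conditions <- function(task) {
  switch(task,
         arithmetic = ARITH_CONDITIONS,
         rhyming    = RHYME_CONDITIONS,
         stop("unknown task: ", task))
}

stop_input <- function(...) stop(..., call. = FALSE)
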