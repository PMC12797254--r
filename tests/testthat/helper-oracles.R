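# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force matrix algebra, direct convolution
# sums, and breadth-first flood fill.

# OLS via the normal equations, one response at a time.
oracle_ols <- function(X, y) {
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  r <- y - X %*% b
  dof <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / dof
  list(beta = drop(b), sigma2 = s2, dof = dof,
       cov_unscaled = solve(t(X) %*% X))
}

oracle_contrast_t <- function(X, y, w) {
  o <- oracle_ols(X, y)
  eff <- sum(w * o$beta)
  se <- sqrt(o$sigma2 * drop(t(w) %*% o$cov_unscaled %*% w))
  list(effect = eff, t = eff / se)
}

# Direct (slow) discrete convolution of a boxcar with a kernel sampled at dt,
# evaluated at the volume times.
oracle_convolved_regressor <- function(onsets, durations, n_vol, tr, kern_fun,
                                       dt = 0.1) {
  total <- n_vol * tr
  tt <- seq(0, total, by = dt)
  box <- numeric(length(tt))
  for (k in seq_along(onsets))
    box[tt >= onsets[k] - 1e-9 & tt < onsets[k] + durations[k] - 1e-9] <- 1
  kt <- seq(0, 32, by = dt)
  kern <- kern_fun(kt) * dt
  kern <- kern / sum(kern)
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    jmax <- min(i, length(kern))
    out[i] <- sum(kern[1:jmax] * box[i - (1:jmax) + 1])
  }
  out[round((0:(n_vol - 1)) * tr / dt) + 1]
}

# Breadth-first flood fill component labelling on a logical 3D mask.
oracle_flood_fill <- function(mask, connectivity = 18) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, ], "18" = offs[nz >= 1 & nz <= 2, ],
                 "26" = offs[nz >= 1, ])
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- ijk + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# Brute-force separable-equivalent 3D Gaussian smoothing by explicit sums,
# with the same boundary convention as the package: truncated weights are
# renormalized so each output is a weighted average of available voxels.
oracle_smooth <- function(vol, fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(4 * sigma))
  w1 <- exp(-((-r:r)^2) / (2 * sigma^2)); w1 <- w1 / sum(w1)
  d <- dim(vol)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0; wsum <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      w <- w1[di + r + 1] * w1[dj + r + 1] * w1[dk + r + 1]
      acc <- acc + vol[ii, jj, kk] * w
      wsum <- wsum + w
    }
    out[i, j, k] <- acc / wsum
  }
  out
}

dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Small all-responsive world used by several tests: every voxel of an n^3
# grid belongs to one ROI driven by all five conditions.
tiny_world <- function(n = 8, seed = 1, ...) {
  spec <- acquisition_spec(grid_shape = rep(n, 3))
  masks <- list(roi = array(TRUE, rep(n, 3)))
  amps <- c(Small = 1.5, Large = 1.5, PlusOne = 0.75,
            Rhyme = 1.5, LetterMatch = 0.75)
  list(spec = spec, masks = masks,
       truth = ground_truth(masks, amps, seed = seed, ...))
}

# Unsmoothed first-level fit of one task from a generated subject.
fit_task <- function(subject, task, spec, per_run = FALSE) {
  keys <- grep(paste0("^", task), names(subject$runs), value = TRUE)
  runs <- subject$runs[keys]
  dms <- lapply(runs, function(r)
    build_design_matrix(r$design, spec, motion = r$motion))
  if (per_run) mapply(fit_glm, runs, dms, SIMPLIFY = FALSE)
  else fit_glm(runs, dms)
}
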