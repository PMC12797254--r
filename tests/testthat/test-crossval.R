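# Noise covariance shrinkage, whitening, split-half similarity and its zero
# null baseline.

test_that("iid residuals give near-identity covariance", {
  set.seed(21)
  R <- matrix(stats::rnorm(2000 * 15), 2000, 15)
  nc <- estimate_noise_covariance(R, dof = 1990)
  expect_lt(max(abs(nc$sigma - diag(15))), 0.12)
  # with a diagonal truth the shrinkage target equals the truth, so the
  # analytic intensity is free to be large; it must stay in [0, 1] and the
  # result must stay near the identity
  expect_gte(nc$shrinkage_lambda, 0)
  expect_lte(nc$shrinkage_lambda, 1)
  # whitener inverts sigma: W sigma W' ~ I
  err <- nc$whitener %*% nc$sigma %*% t(nc$whitener) - diag(15)
  expect_lt(max(abs(err)), 1e-6)
})

test_that("strong real correlations keep the shrinkage intensity small", {
  set.seed(27)
  V <- 10; Tn <- 2000
  Sigma_true <- 0.7 + 0.3 * diag(V)
  R <- matrix(stats::rnorm(Tn * V), Tn) %*% chol(Sigma_true)
  nc <- estimate_noise_covariance(R, dof = Tn - 5)
  expect_lt(nc$shrinkage_lambda, 0.2)
  expect_gt(mean(nc$sigma[upper.tri(nc$sigma)]), 0.5)
})

test_that("whitened residuals approach identity covariance as T grows", {
  set.seed(22)
  V <- 12
  A <- matrix(stats::rnorm(V * V), V) / sqrt(V)
  Sigma_true <- tcrossprod(A) + diag(V) * 0.5
  frob <- vapply(c(150, 1500), function(Tn) {
    R <- matrix(stats::rnorm(Tn * V), Tn) %*% chol(Sigma_true)
    nc <- estimate_noise_covariance(R, dof = Tn - 10)
    W <- nc$whitener
    emp <- stats::cov(R %*% W)
    norm(emp - diag(V), "F")
  }, numeric(1))
  expect_lt(frob[2], frob[1])
  expect_lt(frob[2], 0.6)
})

test_that("too few time points trigger the maximal-shrinkage warning", {
  set.seed(23)
  R <- matrix(stats::rnorm(3 * 8), 3, 8)
  expect_warning(nc <- estimate_noise_covariance(R, dof = 1), "maximal shrinkage")
  expect_identical(nc$shrinkage_lambda, 1)
  expect_equal(nc$sigma, diag(diag(nc$sigma)), tolerance = 1e-12)
})

test_that("whitening is identity under identity covariance and scales correctly", {
  P <- matrix(stats::rnorm(3 * 10), 3, 10,
              dimnames = list(c("Small", "Large", "Rhyme"), NULL))
  mk_cov <- function(sigma) {
    e <- eigen(sigma, symmetric = TRUE)
    structure(list(sigma = sigma,
                   whitener = e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors),
                   shrinkage_lambda = 0, dof = 100),
              class = "noise_covariance")
  }
  expect_equal(whiten_patterns(P, mk_cov(diag(10))), P, tolerance = 1e-12)
  expect_equal(whiten_patterns(P, mk_cov(2 * diag(10))), P / sqrt(2),
               tolerance = 1e-12)
  expect_error(whiten_patterns(P, mk_cov(diag(4))), "does not match")
})

test_that("whitening already-whitened patterns changes little at large T", {
  set.seed(24)
  V <- 10; Tn <- 4000
  A <- matrix(stats::rnorm(V * V), V) / sqrt(V)
  Sigma_true <- tcrossprod(A) + diag(V)
  R <- matrix(stats::rnorm(Tn * V), Tn) %*% chol(Sigma_true)
  nc1 <- estimate_noise_covariance(R, dof = Tn - 5)
  P <- matrix(stats::rnorm(3 * V), 3, V,
              dimnames = list(c("Small", "Large", "Rhyme"), NULL))
  P1 <- whiten_patterns(P, nc1)
  R1 <- R %*% nc1$whitener
  nc2 <- estimate_noise_covariance(R1, dof = Tn - 5)
  P2 <- whiten_patterns(P1, nc2)
  rel <- norm(P2 - P1, "F") / norm(P1, "F")
  expect_lt(rel, 0.05)
})

test_that("split-half similarity is 1 for identical patterns and errors on misuse", {
  P <- matrix(stats::rnorm(2 * 50), 2, 50,
              dimnames = list(c("Small", "Rhyme"), NULL))
  expect_equal(split_half_similarity(P, P, c("Small", "Rhyme")),
               stats::cor(P["Small", ], P["Rhyme", ]), tolerance = 1e-12)
  Q <- rbind(Small = P["Small", ], Rhyme = P["Small", ])
  expect_equal(split_half_similarity(Q, Q, c("Small", "Rhyme")), 1,
               tolerance = 1e-12)
  expect_error(split_half_similarity(P[1, , drop = FALSE], P,
                                     c("Small", "Rhyme")), "both runs")
})

test_that("split-half has a zero null while within-run similarity is inflated
           by shared run noise", {
  set.seed(25)
  V <- 300; n_rep <- 1500
  r_cv <- r_within <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    shared1 <- stats::rnorm(V); shared2 <- stats::rnorm(V)
    mk <- function(shared) rbind(Small = stats::rnorm(V) + shared,
                                 Rhyme = stats::rnorm(V) + shared)
    P1 <- mk(shared1); P2 <- mk(shared2)
    r_cv[i] <- split_half_similarity(P1, P2, c("Small", "Rhyme"))
    r_within[i] <- within_run_similarity(P1, P2, c("Small", "Rhyme"))
  }
  se_cv <- stats::sd(r_cv) / sqrt(n_rep)
  expect_lt(abs(mean(r_cv)), 3 * se_cv)
  # the naive estimate is far above zero (true shared-noise correlation 0.5)
  expect_gt(mean(r_within), 0.4)
  # paired comparison: inflation is positive in essentially every replicate
  expect_gt(mean(r_within - r_cv > 0), 0.99)
})

test_that("group_crossval_test mirrors the naive group test and flags cells", {
  set.seed(26)
  rec <- do.call(rbind, lapply(1:10, function(s)
    data.frame(participant_id = s, roi_id = "roi",
               pair = c("Small-Rhyme", "Large-Rhyme"),
               r_cv = c(0.2, 0.4) + stats::rnorm(2, sd = 0.05))))
  g <- group_crossval_test(rec, alpha_corrected = 0.01)
  expect_identical(nrow(g), 2L)
  expect_true(all(g$significant))
  z <- atanh(rec$r_cv[rec$pair == "Small-Rhyme"])
  tt <- stats::t.test(z)
  expect_equal(g$t[g$pair == "Small-Rhyme"], unname(tt$statistic),
               tolerance = 1e-12)
  rec0 <- rec; rec0$r_cv <- 0
  expect_error(group_crossval_test(rec0), "zero variance")
})
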