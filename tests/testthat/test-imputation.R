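test_that("fill_zero zeroes masked columns and nothing else", {
  s <- make_series(matrix(rnorm(80), 20, 4))
  f <- fill_zero(s, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(f$bold[, 2], rep(0, 20))
  expect_identical(f$bold[, c(1, 3, 4)], s$bold[, c(1, 3, 4)])
  # empty mask is the identity; refilling is idempotent
  expect_identical(fill_zero(s, rep(FALSE, 4))$bold, s$bold)
  expect_identical(fill_zero(f, c(FALSE, TRUE, FALSE, FALSE))$bold, f$bold)
})

test_that("fill_mean averages donors element-wise and excludes the subject", {
  coh <- make_fake_cohort(3)
  coh$missing_mask[[1]] <- c(FALSE, TRUE, FALSE, FALSE)
  f1 <- fill_mean(coh$subjects[[1]], coh$missing_mask[[1]], coh, subject = 1)
  # two donors: element-wise average, computed by hand
  hand <- (coh$subjects[[2]]$bold[, 2] + coh$subjects[[3]]$bold[, 2]) / 2
  expect_equal(f1$bold[, 2], hand)
  expect_false(isTRUE(all.equal(f1$bold[, 2], coh$subjects[[1]]$bold[, 2])))

  # single donor: the filled column equals the donor's column
  coh2 <- make_fake_cohort(2)
  f2 <- fill_mean(coh2$subjects[[1]], c(TRUE, FALSE, FALSE, FALSE), coh2, 1)
  expect_equal(f2$bold[, 1], coh2$subjects[[2]]$bold[, 1])

  # a donor whose node is itself masked does not contribute
  coh$missing_mask[[3]] <- c(FALSE, TRUE, FALSE, FALSE)
  f3 <- fill_mean(coh$subjects[[1]], coh$missing_mask[[1]], coh, 1)
  expect_equal(f3$bold[, 2], coh$subjects[[2]]$bold[, 2])

  # no donors at all -> explicit error
  coh$missing_mask[[2]] <- c(FALSE, TRUE, FALSE, FALSE)
  expect_error(fill_mean(coh$subjects[[1]], coh$missing_mask[[1]], coh, 1),
               "donor")
})

test_that("fill_noise draws seeded white noise at 0.05% of mean signal level", {
  coh <- make_fake_cohort(1, n_samples = 200, node_means = c(0, 2, 2, 2))
  s <- coh$subjects[[1]]
  mask <- c(TRUE, FALSE, FALSE, FALSE)
  level <- mean(s$bold[, 2:4]) + 100
  pooled <- unlist(lapply(1:100, function(i)
    fill_noise(s, mask, seed = i)$bold[, 1]))
  expect_equal(stats::sd(pooled), 5e-4 * level, tolerance = 0.05)

  f <- fill_noise(s, mask, seed = 7)
  expect_identical(f$bold, fill_noise(s, mask, seed = 7)$bold)
  expect_identical(f$bold[, 2:4], s$bold[, 2:4])
  # white fill: lag-1 autocorrelation within the 2/sqrt(n) band
  r1 <- stats::cor(f$bold[-200, 1], f$bold[-1, 1])
  expect_lt(abs(r1), 0.15)
})

test_that("EM fit reduces to sample moments without missingness and never decreases the log-likelihood", {
  s <- make_series(matrix(rnorm(200), 50, 4))
  fit <- em_fit_gaussian(s, rep(FALSE, 4))
  expect_true(fit$converged)
  expect_equal(fit$n_iter, 1L)
  expect_equal(unname(fit$mean), unname(colMeans(s$bold)))
  expect_equal(unname(fit$cov), unname(stats::cov(s$bold) * 49 / 50),
               tolerance = 1e-12)

  # property: nondecreasing observed-data log-likelihood on random instances
  withr::with_seed(42, {
    for (i in 1:100) {
      n_nodes <- sample(3:5, 1)
      Sig <- crossprod(matrix(rnorm(n_nodes^2), n_nodes)) + diag(n_nodes)
      X <- matrix(rnorm(30 * n_nodes), 30) %*% chol(Sig)
      mask <- rep(FALSE, n_nodes); mask[sample(n_nodes, 1)] <- TRUE
      fit_i <- em_fit_gaussian(make_series(X), mask, max_iter = 40)
      expect_true(all(diff(fit_i$loglik_trace) >= -1e-8))
    }
  })
})

test_that("EM recovers the marginal of a fully missing column of a known Gaussian", {
  # all nodes share the same marginal, so the pooled-moment estimate of the
  # missing column is a consistent estimate of its true marginal
  mu_true <- 1.5; sd_true <- 2
  R <- matrix(0.5, 4, 4); diag(R) <- 1
  L <- chol(R * sd_true^2)
  T_ <- 400
  hits_mean <- 0; hits_sd <- 0; n_rep <- 20
  withr::with_seed(99, {
    for (r in 1:n_rep) {
      X <- mu_true + matrix(rnorm(T_ * 4), T_) %*% L
      fit <- em_fit_gaussian(make_series(X), c(FALSE, TRUE, FALSE, FALSE))
      se_mean <- sd_true / sqrt(3 * T_)  # pooled over the 3 observed nodes
      se_sd <- sd_true / sqrt(2 * 3 * T_)
      hits_mean <- hits_mean + (abs(fit$mean[2] - mu_true) < 3 * se_mean * sqrt(3))
      hits_sd <- hits_sd + (abs(sqrt(fit$cov[2, 2]) - sd_true) < 3 * se_sd * sqrt(3))
    }
  })
  # pooling correlated columns inflates the se; allow the correlation factor
  # (sqrt(3) above) and require near-universal coverage
  expect_gte(hits_mean, n_rep - 1)
  expect_gte(hits_sd, n_rep - 1)
})

test_that("fill_em draws i.i.d. noise at the EM-estimated moments", {
  coh <- make_fake_cohort(1, n_samples = 200, node_means = c(1, 1, 1, 1))
  s <- coh$subjects[[1]]
  mask <- c(FALSE, FALSE, TRUE, FALSE)
  f <- fill_em(s, mask, seed = 3)
  fit <- attr(f, "em_fit")
  expect_identical(f$bold[, c(1, 2, 4)], s$bold[, c(1, 2, 4)])
  expect_equal(mean(f$bold[, 3]), fit$mean[3],
               tolerance = 3 / sqrt(200) * sqrt(fit$cov[3, 3]) /
                 max(abs(fit$mean[3]), 1e-8), ignore_attr = TRUE)
  expect_equal(stats::sd(f$bold[, 3]), sqrt(fit$cov[3, 3]), tolerance = 0.2)
  expect_identical(f$bold, fill_em(s, mask, seed = 3)$bold)

  # conditional mode regresses on the observed columns instead
  fc <- fill_em(s, mask, method = "conditional")
  expect_lt(stats::sd(fc$bold[, 3]), stats::sd(f$bold[, 3]))
})

test_that("fill_cohort dispatches by name and preserves unmasked data bit-exactly", {
  coh <- remove_nodes(make_fake_cohort(4, n_samples = 30), 1, seed = 2)
  for (m in c("zero", "mean", "noise", "em")) {
    filled <- fill_cohort(coh, m, seed = 5)
    expect_equal(filled$fill_method, m)
    for (i in 1:4) {
      keep <- !coh$missing_mask[[i]]
      expect_identical(filled$subjects[[i]]$bold[, keep],
                       coh$subjects[[i]]$bold[, keep])
    }
  }
})
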