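test_that("telegraph stimulus realizes the designed dwell-time process", {
  # long run: empirical dwell means within 5% for the auditory design
  des <- stimulus_design(2.5, 10, dt = 0.005, duration = 10000)
  s <- generate_stimulus(des, seed = 4)
  up <- attr(s, "dwell_up"); down <- attr(s, "dwell_down")
  expect_equal(mean(up), 2.5, tolerance = 0.05)
  expect_equal(mean(down), 10, tolerance = 0.05)

  # dwell distribution is exponential (KS test at alpha = 0.01)
  expect_gt(stats::ks.test(up, "pexp", rate = 1 / 2.5)$p.value, 0.01)
  expect_gt(stats::ks.test(down, "pexp", rate = 1 / 10)$p.value, 0.01)

  # no jitter -> exactly two signal values
  des0 <- stimulus_design(5, 5, height = 2, noise_frac = 0, duration = 500)
  s0 <- generate_stimulus(des0, seed = 1)
  expect_setequal(unique(as.numeric(s0)), c(0, 2))

  # jitter sd is 1/20 of the state-height difference
  des1 <- stimulus_design(5, 5, height = 2, noise_frac = 1 / 20,
                          dt = 0.005, duration = 5000)
  s1 <- generate_stimulus(des1, seed = 1)
  resid <- as.numeric(s1) - as.numeric(s0[seq_along(s1)]) * 0
  # compare against the same dwell pattern: regenerate with same seed
  s1b <- generate_stimulus(stimulus_design(5, 5, height = 2, noise_frac = 0,
                                           dt = 0.005, duration = 5000),
                           seed = 1)
  expect_equal(stats::sd(as.numeric(s1) - as.numeric(s1b)), 2 / 20,
               tolerance = 0.02)

  # seeded determinism
  expect_identical(as.numeric(generate_stimulus(des, seed = 9)),
                   as.numeric(generate_stimulus(des, seed = 9)))
})

test_that("the default family has 16 distinct models with fixed input wiring", {
  fam <- model_family()
  expect_length(fam, 16)
  keys <- vapply(fam, function(m) paste(m$topology, collapse = ""), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (m in fam) {
    conn <- sample_connectivity(m, seed = 1)
    # u1 enters only V, u2 enters only A
    expect_equal(conn$C[, 1], c(V = 1, A = 0, M = 0, P = 0),
                 ignore_attr = TRUE)
    expect_equal(conn$C[, 2], c(V = 0, A = 1, M = 0, P = 0),
                 ignore_attr = TRUE)
  }
  # subsets of size 8 and 4 retain the designated true model
  for (sz in c(8, 4)) {
    sub <- family_subset(fam, sz, true_model_id = 16)
    expect_length(sub, sz)
    expect_true(16 %in% vapply(sub, `[[`, integer(1), "model_id"))
  }
  expect_error(family_subset(fam, 4, true_model_id = 99), "true model")
})

test_that("sampled connection strengths follow the truncated normal contract", {
  fam <- model_family()
  m16 <- fam[[16]]
  draws <- unlist(lapply(1:2500, function(i) {
    A <- sample_connectivity(m16, seed = i)$A
    A[A != -1 & A != 0]
  }))
  expect_length(draws, 10000)
  expect_true(all(draws >= 0.2 & draws <= 0.6))
  # numeric-integration oracle for the truncated-normal mean (symmetric
  # bounds about the mode leave the mean at 0.4)
  Z <- stats::pnorm(0.6, 0.4, 0.1) - stats::pnorm(0.2, 0.4, 0.1)
  oracle_mean <- stats::integrate(function(x)
    x * stats::dnorm(x, 0.4, 0.1) / Z, 0.2, 0.6)$value
  expect_equal(mean(draws), oracle_mean, tolerance = 0.01 / oracle_mean)
  expect_equal(oracle_mean, 0.4, tolerance = 1e-8)

  A <- sample_connectivity(m16, seed = 1)$A
  expect_equal(unname(diag(A)), rep(-1, 4))
  # absent edges are exactly zero (model 1 has no pool edges)
  A1 <- sample_connectivity(fam[[1]], seed = 1)$A
  expect_equal(sum(A1 != 0 & A1 != -1), 0)
  # inhibitory modulation sits on the P->M edge only
  B2 <- sample_connectivity(m16, seed = 2)$B[[2]]
  expect_lt(B2["M", "P"], -0.2)
  expect_equal(sum(B2 != 0), 1)
})

test_that("cohort simulation is reproducible with subject-level independence", {
  fam <- model_family()
  coh <- simulate_cohort(fam[[16]], 3, seed = 5)
  coh2 <- simulate_cohort(fam[[16]], 3, seed = 5)
  expect_identical(coh$subjects[[2]]$bold, coh2$subjects[[2]]$bold)
  expect_false(identical(coh$subjects[[1]]$bold, coh$subjects[[2]]$bold))
  expect_equal(coh$true_model_id, rep(16L, 3))
  expect_equal(dim(coh$subjects[[1]]$bold), c(200, 4))
  # per-subject derived seeds make generation order-independent: a larger
  # cohort reproduces the smaller one's subjects exactly
  coh4 <- simulate_cohort(fam[[16]], 4, seed = 5)
  expect_identical(coh4$subjects[[3]]$bold, coh$subjects[[3]]$bold)
})

test_that("node removal marks the requested number of nodes uniformly", {
  coh <- make_fake_cohort(20)
  expect_true(all(!unlist(remove_nodes(coh, 0, seed = 1)$missing_mask)))
  r1 <- remove_nodes(coh, 1, seed = 1)
  expect_true(all(vapply(r1$missing_mask, sum, numeric(1)) == 1))
  r2 <- remove_nodes(coh, 2, seed = 1)
  expect_true(all(vapply(r2$missing_mask, sum, numeric(1)) == 2))
  expect_error(remove_nodes(coh, 4, seed = 1), "smaller")

  # uniform choice: frequency 0.25 +/- 0.02 over 10,000 removals
  big <- make_fake_cohort(10000, n_samples = 2)
  rb <- remove_nodes(big, 1, seed = 3)
  freq <- colMeans(do.call(rbind, rb$missing_mask))
  expect_true(all(abs(freq - 0.25) < 0.02))
})
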