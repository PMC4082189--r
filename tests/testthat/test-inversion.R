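test_that("parameter flattening is a bijection with a stable name index", {
  fam <- model_family()
  m <- fam[[16]]
  conn <- sample_connectivity(m, seed = 2)
  hs <- jitter_hemodynamics(hemodynamic_params(), 4, seed = 3)
  th <- flatten_params(conn, hs, m)
  back <- unflatten_params(th, m)
  expect_equal(back$conn$A, conn$A)
  expect_equal(back$conn$B, conn$B, ignore_attr = TRUE)
  expect_equal(back$conn$C, conn$C, ignore_attr = TRUE)
  for (i in 1:4)
    expect_equal(unlist(back$h[[i]]), unlist(hs[[i]]), tolerance = 1e-12)
  # round trip again through flatten
  th2 <- flatten_params(back$conn, back$h, m)
  expect_identical(names(th), names(th2))
  expect_equal(as.numeric(th), as.numeric(th2), tolerance = 1e-12)
})

test_that("default priors fix structural zeros and centre h at the prior means", {
  fam <- model_family()
  pr <- default_priors(fam[[12]])   # lacks the P->M edge
  idx <- pr$index
  # absent edge: not free, mean 0 (infinite precision at zero)
  k <- which(idx$name == "A[M,P]")
  expect_false(pr$free[k])
  expect_equal(unname(pr$mean[k]), 0)
  # diagonal fixed at -1
  expect_equal(unname(pr$mean[idx$name == "A[V,V]"]), -1)
  # modulation of an absent edge is not free either
  expect_false(pr$free[idx$name == "B2[M,P]"])
  # hemodynamic prior means match the documented constants
  h <- hemodynamic_params()
  expect_equal(unname(pr$mean[idx$name == "log_tau[V]"]), log(h$tau))
  expect_equal(unname(pr$mean[idx$name == "log_E0[M]"]), log(h$E0))
  expect_false(pr$free[idx$name == "log_E0[M]"])
  # free-parameter covariance is positive definite
  expect_silent(chol(pr$cov))
})

test_that("predict_response reproduces training data at the true parameters and is flat for zero C", {
  fam <- model_family()
  m <- fam[[16]]
  coh <- simulate_cohort(m, 1, seed = 12, noise_sd_frac = 0)
  truth <- flatten_params(coh$truth[[1]]$conn, coh$truth[[1]]$h, m)
  U <- coh$subjects[[1]]$inputs
  # same integrator step as the simulator: exact self-consistency
  pred <- predict_response(truth, m, U, dt = 0.005, tr = 3)
  expect_equal(pred, coh$subjects[[1]]$bold, tolerance = 1e-12,
               ignore_attr = TRUE)
  # the coarse inversion step stays within integration tolerance
  pred_c <- predict_response(truth, m,
                             dcmimpute:::resample_inputs(U, 0.005, 0.1),
                             dt = 0.1, tr = 3)
  expect_lt(max(abs(pred_c - coh$subjects[[1]]$bold)), 0.05)

  th0 <- truth
  th0[grep("^C\\[", names(th0))] <- 0
  flat <- predict_response(th0, m, U, dt = 0.005, tr = 3)
  expect_equal(max(abs(flat)), 0, tolerance = 1e-12)
})

test_that("the forward-difference response Jacobian matches a central-difference oracle", {
  fam <- model_family()
  m <- fam[[16]]
  pr <- default_priors(m)
  coh <- simulate_cohort(m, 1, seed = 9)
  U <- dcmimpute:::resample_inputs(coh$subjects[[1]]$inputs, 0.005, 0.1)
  free0 <- pr$mean[pr$free] + 0.1   # move off exact structural zeros
  g <- function(v) {
    th <- pr$mean; th[pr$free] <- v
    attr(th, "index") <- pr$index
    predict_response(th, m, U, dt = 0.1, tr = 3)
  }
  k <- which(names(free0) == "A[M,V]")
  h <- 1e-4
  g0 <- g(free0)
  gp <- g(free0 + h * (seq_along(free0) == k))
  gm <- g(free0 - h * (seq_along(free0) == k))
  J_forward <- (gp - g0) / h
  J_central <- (gp - gm) / (2 * h)
  expect_lt(max(abs(J_forward - J_central)) / max(abs(J_central)), 1e-4)
})

test_that("the linear-Gaussian limit matches the closed-form evidence to 1e-3", {
  withr::with_seed(1, {
    T_ <- 40; N <- 3
    X <- matrix(rnorm(T_ * N), T_, N)
    lam <- 25
    y <- X %*% c(0.5, -0.3, 0.2) + rnorm(T_, 0, sqrt(1 / lam))
    m0 <- rep(0, N); S0 <- diag(0.5, N)
    fit <- dcmimpute:::vb_laplace(matrix(y), function(t) matrix(X %*% t),
                                  m0, S0,
                                  settings = inversion_settings(
                                    lambda_fixed = lam, center = FALSE,
                                    tol = 1e-10, max_iter = 200))
    Sig <- X %*% S0 %*% t(X) + diag(1 / lam, T_)
    ch <- chol(Sig)
    z <- backsolve(ch, y - X %*% m0, transpose = TRUE)
    log_ev <- -0.5 * T_ * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
    expect_equal(fit$free_energy, log_ev, tolerance = 1e-3)
    # and the posterior matches the conjugate solution
    P <- solve(S0) + lam * crossprod(X)
    expect_equal(as.numeric(fit$mean),
                 as.numeric(solve(P, lam * crossprod(X, y))),
                 tolerance = 1e-6)
  })
})

test_that("inversion is well-behaved: monotone F, SPD posterior, stable at the prior", {
  fam <- model_family()
  m <- fam[[14]]
  # data generated at the prior means with negligible noise: nothing should
  # move far, and the free energy only increases over accepted iterations
  pr <- default_priors(m)
  U <- cbind(generate_stimulus(stimulus_design(5, 5, duration = 600), seed = 2),
             generate_stimulus(stimulus_design(2.5, 10, duration = 600), seed = 3))
  th <- pr$mean; attr(th, "index") <- pr$index
  clean <- predict_response(th, m, U, dt = 0.005, tr = 3)
  dat <- node_time_series(clean + withr::with_seed(4,
                            matrix(rnorm(length(clean), 0, 1e-4), nrow(clean))),
                          tr = 3, inputs = U, dt = 0.005)
  post <- invert_dcm(dat, m, priors = pr)
  expect_true(all(diff(post$F_trace) >= -1e-9))
  expect_silent(chol(post$cov))
  moved <- abs(post$mean[pr$free] - pr$mean[pr$free])
  expect_true(all(moved < 0.05))
  expect_equal(log_evidence(post), post$free_energy)
  # BIC penalizes harder than AIC once log(n)/2 > 1
  expect_lt(log_evidence(post, "bic"), log_evidence(post, "aic"))
})

test_that("free energy is invariant to the ordering of free parameters", {
  withr::with_seed(7, {
    T_ <- 30; N <- 4
    X <- matrix(rnorm(T_ * N), T_, N)
    y <- matrix(X %*% rnorm(N) + rnorm(T_, 0, 0.3))
    S0 <- diag(c(0.3, 0.5, 0.7, 0.9))
    m0 <- rep(0, N)
    st <- inversion_settings(lambda_fixed = 10, center = FALSE, tol = 1e-10,
                             max_iter = 100)
    f1 <- dcmimpute:::vb_laplace(y, function(t) matrix(X %*% t), m0, S0, st)
    perm <- c(3, 1, 4, 2)
    f2 <- dcmimpute:::vb_laplace(y, function(t) matrix(X[, perm] %*% t),
                                 m0[perm], diag(diag(S0)[perm]), st)
    expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-8)
  })
})
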