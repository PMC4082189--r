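test_that("neural_derivative implements the bilinear state equation", {
  # pure self-decay
  conn <- effective_connectivity(diag(-1, 4), C = matrix(0, 4, 1),
                                 alpha_decay = 20)
  expect_equal(neural_derivative(c(1, 0, 0, 0), 0, conn), c(-20, 0, 0, 0))

  # input drive only
  conn2 <- effective_connectivity(diag(-1, 4), C = diag(1, 4))
  expect_equal(neural_derivative(rep(0, 4), c(1, 0, 0, 0), conn2),
               c(1, 0, 0, 0))

  # random instance vs element-wise summation oracle (no matrix routines)
  withr::with_seed(11, {
    for (rep in 1:5) {
      A <- matrix(rnorm(16), 4, 4); diag(A) <- -1
      B <- list(matrix(rnorm(16), 4, 4), matrix(rnorm(16), 4, 4))
      C <- matrix(rnorm(8), 4, 2)
      z <- rnorm(4); u <- rnorm(2)
      conn3 <- effective_connectivity(A, B, C, alpha_decay = 3.5)
      oracle <- numeric(4)
      for (i in 1:4) {
        for (k in 1:4) {
          coef <- 3.5 * A[i, k]
          for (j in 1:2) coef <- coef + u[j] * B[[j]][i, k]
          oracle[i] <- oracle[i] + coef * z[k]
        }
        for (j in 1:2) oracle[i] <- oracle[i] + C[i, j] * u[j]
      }
      expect_equal(neural_derivative(z, u, conn3), oracle, tolerance = 1e-12)
    }
  })

  expect_error(neural_derivative(c(1, 2), 0, conn), "length 2")
  expect_error(neural_derivative(rep(0, 4), c(1, 1), conn), "1 inputs")
})

test_that("hemodynamic_derivative has the balloon resting fixed point and response shape", {
  h <- hemodynamic_params()
  expect_equal(unname(hemodynamic_derivative(c(0, 1, 1, 1), 0, h)),
               rep(0, 4), tolerance = 1e-14)
  expect_error(hemodynamic_derivative(c(0, -1, 1, 1), 0, h), "positive")

  # brief neural pulse: inflow f exceeds 1 within 2 s of onset (fine Euler)
  dt <- 1e-3
  x <- c(0, 1, 1, 1)
  f_hit <- NA
  for (k in seq_len(2 / dt)) {
    z <- if (k * dt <= 0.5) 1 else 0
    x <- x + dt * hemodynamic_derivative(x, z, h)
    if (is.na(f_hit) && x[2] > 1.01) f_hit <- k * dt
  }
  expect_lt(f_hit, 2)

  # canonical HRF shape: peak 3-7 s post stimulus at prior means
  peak <- hrf_peak_delay(h)
  expect_gt(peak, 3)
  expect_lt(peak, 7)
})

test_that("bold_signal is zero at rest and monotone in deoxyhemoglobin", {
  h <- hemodynamic_params()
  expect_equal(bold_signal(1, 1, h), 0)
  expect_gt(bold_signal(1, 0.9, h), bold_signal(1, 1, h))
  expect_gt(bold_signal(1, 0.8, h), bold_signal(1, 0.9, h))
  expect_error(bold_signal(-1, 1, h), "positive")
})

test_that("simulate_bold returns the default acquisition geometry and conserves rest", {
  fam <- model_family()
  conn <- sample_connectivity(fam[[16]], seed = 1)
  designs <- default_stimulus_designs()
  stim <- cbind(generate_stimulus(designs$visual, seed = 1),
                generate_stimulus(designs$auditory, seed = 2))
  ts <- simulate_bold(conn, hemodynamic_params(), stim, noise_sd_frac = 0.003,
                      seed = 3)
  expect_s3_class(ts, "node_time_series")
  expect_equal(dim(ts$bold), c(200, 4))
  expect_equal(ts$tr, 3)

  # identical seed -> bit-identical
  ts2 <- simulate_bold(conn, hemodynamic_params(), stim, noise_sd_frac = 0.003,
                       seed = 3)
  expect_identical(ts$bold, ts2$bold)

  # zero input, zero noise -> constant at resting BOLD (0)
  flat <- simulate_bold(conn, hemodynamic_params(),
                        matrix(0, 4000, 2), noise_sd_frac = 0)
  expect_equal(max(abs(flat$bold)), 0, tolerance = 1e-12)
})

test_that("RK4 at 5 ms matches a fine-step Euler oracle built from the R derivatives", {
  conn <- two_node_conn()
  h <- hemodynamic_params()
  dur <- 9
  U5 <- boxcar_input(dur, 0.005, 1, 3, height = 4)
  ts <- simulate_bold(conn, h, U5, dt = 0.005, tr = 3, noise_sd_frac = 0)

  # independent Euler integration at 0.1 ms using the R-level derivatives
  dte <- 1e-4
  Ue <- boxcar_input(dur, dte, 1, 3, height = 4)
  z <- c(0, 0)
  x <- list(c(0, 1, 1, 1), c(0, 1, 1, 1))
  out <- matrix(0, 3, 2)
  sample_every <- round(3 / dte)
  s_idx <- 1
  for (k in seq_len(nrow(Ue))) {
    if ((k - 1) %% sample_every == 0) {
      out[s_idx, ] <- c(bold_signal(x[[1]][3], x[[1]][4], h),
                        bold_signal(x[[2]][3], x[[2]][4], h))
      s_idx <- s_idx + 1
    }
    dz <- neural_derivative(z, Ue[k, ], conn)
    for (i in 1:2) x[[i]] <- x[[i]] + dte * hemodynamic_derivative(x[[i]], z[i], h)
    z <- z + dte * dz
  }
  rng <- diff(range(ts$bold))
  expect_lt(max(abs(ts$bold[1:3, ] - out)), 0.01 * rng)
})

test_that("halving the integration step behaves like a 4th-order scheme", {
  conn <- two_node_conn()
  h <- hemodynamic_params()
  sim <- function(dt) simulate_bold(conn, h, boxcar_input(30, dt, 2, 7, 4),
                                    dt = dt, tr = 3, noise_sd_frac = 0)$bold
  ref <- sim(0.00125)
  err_halved <- max(abs(sim(0.0025) - ref))
  err_doubled <- max(abs(sim(0.01) - ref))
  expect_lt(err_halved, err_doubled)
})

test_that("peak neural response is linear in the input scale for small inputs", {
  conn0 <- two_node_conn()
  peak_at <- function(lam) {
    C <- matrix(c(lam, 0), 2, 1)
    conn <- effective_connectivity(conn0$A, C = C, alpha_decay = 20,
                                   node_labels = conn0$node_labels)
    ts <- simulate_bold(conn, hemodynamic_params(), boxcar_input(12, 0.005, 1, 4, 1),
                        dt = 0.005, tr = 3, noise_sd_frac = 0, keep_neural = TRUE)
    max(ts$neural[, 1])
  }
  p1 <- peak_at(1e-3)
  p2 <- peak_at(2e-3)
  expect_equal(p2 / p1, 2, tolerance = 0.02)
})

test_that("HRF jitter realizes the requested peak-delay spread", {
  hs <- jitter_hemodynamics(hemodynamic_params(), 120, delay_sd = 0.5, seed = 8)
  delays <- vapply(hs, hrf_peak_delay, numeric(1), dt = 0.05)
  expect_gt(stats::sd(delays), 0.35)
  expect_lt(stats::sd(delays), 0.65)
  # jitter leaves the non-randomized constants untouched
  expect_true(all(vapply(hs, function(h) h$E0 == 0.34 && h$V0 == 0.04,
                         logical(1))))
})

test_that("integration blow-up is reported with the offending time index", {
  conn <- effective_connectivity(matrix(c(-1, 30, 30, -1), 2, 2),
                                 C = matrix(c(1, 0), 2, 1))
  expect_error(simulate_bold(conn, hemodynamic_params(),
                             boxcar_input(30, 0.005, 1, 25, 50),
                             dt = 0.005, tr = 3),
               "step")
})
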