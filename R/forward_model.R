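#' Bilinear effective-connectivity parameter set
#'
#' Bundles the parameters of the bilinear neural state equation
#' \deqn{\dot z = (\alpha A + \sum_j u_j B_j) z + C u}
#' for one candidate network. `A[i, j]` is the influence of node `j` on node
#' `i` (receiver in the row, so the equation is a plain matrix product `A
#' \%*\% z`); the self-connections on the diagonal are fixed at -1 so that
#' `alpha_decay` sets the within-node exponential decay rate. The default
#' `alpha_decay = 20` /s gives a mean neural lag of about 50 ms, the
#' realistic value used for simulation rather than the long lag conventional
#' in Bayesian priors.
#'
#' @param A n x n intrinsic coupling matrix, diagonal -1.
#' @param B list of n x n modulatory matrices, one per input, or `NULL` for
#'   no modulation.
#' @param C n x m direct-input weight matrix.
#' @param alpha_decay within-node decay rate (1/s); `1/alpha_decay` is the
#'   mean neural lag.
#' @param node_labels character names of the nodes.
#' @return an object of class `effective_connectivity`.
#' @export
effective_connectivity <- function(A, B = NULL, C,
                                   alpha_decay = 20,
                                   node_labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  assert_that(ncol(A) == n, "A must be square")
  assert_that(all(abs(diag(A) + 1) < 1e-12),
              "every diagonal entry of A must equal -1")
  assert_that(is.numeric(alpha_decay) && alpha_decay > 0,
              "alpha_decay must be positive")
  C <- as.matrix(C)
  assert_that(nrow(C) == n, "C must have one row per node")
  m <- ncol(C)
  if (is.null(B)) B <- replicate(m, matrix(0, n, n), simplify = FALSE)
  assert_that(length(B) == m, "need one B matrix per input")
  B <- lapply(B, function(b) {
    b <- as.matrix(b)
    assert_that(all(dim(b) == c(n, n)), "each B matrix must be n x n")
    b
  })
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  assert_that(length(node_labels) == n, "need one label per node")
  structure(list(A = A, B = B, C = C, alpha_decay = alpha_decay,
                 node_labels = node_labels, n_nodes = n, n_inputs = m),
            class = "effective_connectivity")
}

#' Balloon-model hemodynamic parameters
#'
#' Constants of the balloon-Windkessel hemodynamic model for one node.
#' Defaults are the conventional prior means of the fMRI DCM forward model:
#' transit time `tau` = 0.98 s, Grubb vessel-stiffness exponent
#' `alpha_grubb` = 0.32, resting oxygen extraction `E0` = 0.34, resting
#' venous volume fraction `V0` = 0.04, signal decay time constant `tau_s` =
#' 1/0.65 s, autoregulatory feedback time constant `tau_f` = 1/0.41 s, and
#' unit neuronal efficacy `epsilon` (response amplitude is carried by the
#' stimulus scaling instead).
#'
#' Note the model has two distinct alphas: the neural decay rate
#' (`alpha_decay` in [effective_connectivity()]) and the Grubb exponent
#' (`alpha_grubb` here).
#'
#' @param tau mean transit time (s).
#' @param alpha_grubb Grubb stiffness exponent, in (0, 1).
#' @param E0 resting oxygen extraction fraction, in (0, 1).
#' @param V0 resting blood volume fraction, in (0, 1).
#' @param tau_s vasodilatory signal decay time constant (s).
#' @param tau_f flow autoregulation time constant (s).
#' @param epsilon neuronal efficacy (unitless).
#' @return an object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(tau = 0.98, alpha_grubb = 0.32, E0 = 0.34,
                               V0 = 0.04, tau_s = 1 / 0.65, tau_f = 1 / 0.41,
                               epsilon = 1) {
  p <- c(tau = tau, alpha_grubb = alpha_grubb, E0 = E0, V0 = V0,
         tau_s = tau_s, tau_f = tau_f, epsilon = epsilon)
  assert_that(all(p > 0), "all hemodynamic parameters must be positive")
  assert_that(E0 < 1 && V0 < 1 && alpha_grubb < 1,
              "E0, V0 and alpha_grubb must lie in (0, 1)")
  structure(as.list(p), class = "hemodynamic_params")
}

# 7 x n parameter matrix for the compiled integrator; rows in the fixed
# order tau, alpha_grubb, E0, V0, tau_s, tau_f, epsilon.
hparams_matrix <- function(h, n_nodes) {
  if (inherits(h, "hemodynamic_params")) h <- replicate(n_nodes, h, simplify = FALSE)
  assert_that(length(h) == n_nodes, "need hemodynamic parameters for every node")
  vapply(h, function(p) unlist(p[c("tau", "alpha_grubb", "E0", "V0",
                                   "tau_s", "tau_f", "epsilon")]),
         numeric(7))
}

#' Neural rate of change under the bilinear state equation
#'
#' Evaluates \eqn{\dot z = (\alpha A + \sum_j u_j B_j) z + C u}.
#'
#' @param z neural state vector (one entry per node).
#' @param u input vector (one entry per input).
#' @param conn an [effective_connectivity()] object.
#' @return rate-of-change vector (1/s).
#' @export
neural_derivative <- function(z, u, conn) {
  stopifnot(inherits(conn, "effective_connectivity"))
  if (length(z) != conn$n_nodes)
    stop(sprintf("z has length %d but the network has %d nodes",
                 length(z), conn$n_nodes))
  if (length(u) != conn$n_inputs)
    stop(sprintf("u has length %d but the network has %d inputs",
                 length(u), conn$n_inputs))
  J <- conn$alpha_decay * conn$A
  for (j in seq_along(conn$B)) J <- J + u[j] * conn$B[[j]]
  as.numeric(J %*% z + conn$C %*% u)
}

#' Balloon-model state derivative for one node
#'
#' The hemodynamic state is `x = c(s, f, v, q)`: vasodilatory signal, inflow,
#' venous volume and deoxyhemoglobin content. Dynamics:
#' \deqn{\dot s = \epsilon z - s/\tau_s - (f-1)/\tau_f, \quad \dot f = s,}
#' \deqn{\tau \dot v = f - v^{1/\alpha}, \quad
#'       \tau \dot q = f E(f, E_0)/E_0 - v^{1/\alpha} q / v,}
#' with \eqn{E(f, E_0) = 1 - (1-E_0)^{1/f}}. The resting fixed point is
#' `(0, 1, 1, 1)`.
#'
#' @param x state vector `c(s, f, v, q)` with `f, v, q > 0`.
#' @param z neural activity scalar driving the node.
#' @param h a [hemodynamic_params()] object.
#' @return derivative vector `c(ds, df, dv, dq)`.
#' @export
hemodynamic_derivative <- function(x, z, h) {
  stopifnot(inherits(h, "hemodynamic_params"), length(x) == 4)
  s <- x[1]; f <- x[2]; v <- x[3]; q <- x[4]
  if (f <= 0 || v <= 0 || q <= 0)
    stop("hemodynamic states f, v, q must be strictly positive")
  fv <- v^(1 / h$alpha_grubb)
  Ef <- 1 - (1 - h$E0)^(1 / f)
  c(s = h$epsilon * z - s / h$tau_s - (f - 1) / h$tau_f,
    f = s,
    v = (f - fv) / h$tau,
    q = (f * Ef / h$E0 - fv * q / v) / h$tau)
}

#' BOLD observation equation
#'
#' Static nonlinear map from venous volume and deoxyhemoglobin to BOLD
#' percent signal change:
#' \deqn{y = 100 V_0 [k_1(1-q) + k_2(1-q/v) + k_3(1-v)]}
#' with \eqn{k_1 = 7E_0}, \eqn{k_2 = 2}, \eqn{k_3 = 2E_0 - 0.2}. At rest
#' (`v = q = 1`) the signal is 0.
#'
#' @param v venous volume (normalized, > 0).
#' @param q deoxyhemoglobin content (normalized, > 0).
#' @param h a [hemodynamic_params()] object.
#' @return BOLD percent signal change.
#' @export
bold_signal <- function(v, q, h) {
  stopifnot(inherits(h, "hemodynamic_params"))
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be strictly positive")
  k1 <- 7 * h$E0; k2 <- 2; k3 <- 2 * h$E0 - 0.2
  100 * h$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Per-node BOLD and input container
#'
#' @param bold samples x nodes matrix of BOLD percent signal change.
#' @param tr repetition time (s).
#' @param inputs optional fine-resolution input matrix (steps x m).
#' @param dt input resolution (s).
#' @param neural optional sampled neural traces.
#' @param node_labels node names.
#' @return an object of class `node_time_series`.
#' @export
node_time_series <- function(bold, tr, inputs = NULL, dt = NULL,
                             neural = NULL, node_labels = NULL) {
  bold <- as.matrix(bold)
  if (!is.null(node_labels)) colnames(bold) <- node_labels
  structure(list(bold = bold, tr = tr, n_samples = nrow(bold),
                 n_nodes = ncol(bold), inputs = inputs, dt = dt,
                 neural = neural,
                 node_labels = colnames(bold) %||% paste0("n", seq_len(ncol(bold)))),
            class = "node_time_series")
}

#' @export
print.node_time_series <- function(x, ...) {
  cat(sprintf("<node_time_series> %d samples x %d nodes, TR = %g s\n",
              x$n_samples, x$n_nodes, x$tr))
  invisible(x)
}

#' Simulate BOLD time series from a bilinear DCM
#'
#' Integrates the coupled neural and balloon equations with a fourth-order
#' Runge-Kutta scheme at step `dt`, computes the BOLD observation per node,
#' point-samples it at multiples of `tr` (no anti-alias filtering, matching
#' common simulator practice), and adds i.i.d. Gaussian observation noise
#' per node with standard deviation `noise_sd_frac` times the mean signal
#' level.
#'
#' The mean signal level follows the percent-signal-change convention with
#' an implicit baseline of 100 (`baseline = "psc100"`), i.e. thermal noise
#' of 0.1--1 percent of mean intensity corresponds to `noise_sd_frac`
#' between 0.001 and 0.01. Set `baseline = "raw"` to use the mean of the
#' noise-free trace itself.
#'
#' @param conn an [effective_connectivity()] object.
#' @param h a [hemodynamic_params()] object (shared) or a list with one per
#'   node.
#' @param stimulus steps x m input matrix at resolution `dt`.
#' @param dt integrator step (s); must divide `tr`.
#' @param tr sampling interval (s).
#' @param noise_sd_frac observation noise as a fraction of mean signal level;
#'   0 disables noise.
#' @param seed integer seed for the noise draw.
#' @param keep_neural keep the neural trace sampled at `tr`.
#' @param baseline `"psc100"` (default) or `"raw"`; see Details.
#' @return a [node_time_series()] with `floor(duration / tr)` samples.
#' @export
simulate_bold <- function(conn, h, stimulus, dt = 0.005, tr = 3,
                          noise_sd_frac = 0, seed = NULL,
                          keep_neural = FALSE, baseline = c("psc100", "raw")) {
  stopifnot(inherits(conn, "effective_connectivity"))
  baseline <- match.arg(baseline)
  stimulus <- as.matrix(stimulus)
  assert_that(ncol(stimulus) == conn$n_inputs,
              "stimulus must have one column per input")
  stride <- round(tr / dt)
  assert_that(abs(stride * dt - tr) < 1e-9 * tr, "dt must divide tr")
  duration <- nrow(stimulus) * dt
  assert_that(duration >= tr, "duration must be at least one TR")
  n_samples <- floor(duration / tr)

  n <- conn$n_nodes
  H <- hparams_matrix(h, n)
  Barr <- array(unlist(conn$B), dim = c(n, n, conn$n_inputs))
  out <- integrate_dcm_cpp(conn$A, conn$alpha_decay, as.numeric(Barr),
                           conn$C, stimulus, dt, stride, n_samples,
                           H, keep_neural, FALSE)
  bold <- out$bold
  if (noise_sd_frac > 0) {
    level <- if (baseline == "psc100") mean(bold) + 100 else mean(bold)
    sd <- noise_sd_frac * abs(level)
    noise <- with_seed(seed, matrix(stats::rnorm(length(bold), 0, sd),
                                    nrow(bold), ncol(bold)))
    bold <- bold + noise
  }
  node_time_series(bold, tr = tr, inputs = stimulus, dt = dt,
                   neural = if (keep_neural) out$neural else NULL,
                   node_labels = conn$node_labels)
}

#' Peak-to-baseline BOLD amplitude relative to mean intensity
#'
#' Summary used to calibrate the simulator against the ~4% percent-signal-
#' change amplitudes typical of 3T task fMRI: per node, the peak excursion
#' above the resting baseline divided by the mean intensity of the time
#' course, in percent. Under the percent-signal-change convention the
#' baseline is 100 and the intensity of sample t is `100 + bold[t]`.
#'
#' @param series a [node_time_series()].
#' @return named per-node amplitude vector (percent).
#' @export
bold_amplitude <- function(series) {
  stopifnot(inherits(series, "node_time_series"))
  intensity <- 100 + series$bold
  100 * apply(series$bold, 2, max) / colMeans(intensity)
}

# Hemodynamic response of a single node to a prescribed neural trace,
# integrated in plain R (used for HRF calibration and as a test oracle).
hemodynamic_response <- function(z_series, h, dt) {
  x <- c(0, 1, 1, 1)
  y <- numeric(length(z_series))
  for (k in seq_along(z_series)) {
    z <- z_series[k]
    k1 <- hemodynamic_derivative(x, z, h)
    k2 <- hemodynamic_derivative(x + dt / 2 * k1, z, h)
    k3 <- hemodynamic_derivative(x + dt / 2 * k2, z, h)
    k4 <- hemodynamic_derivative(x + dt * k3, z, h)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[k] <- bold_signal(x[3], x[4], h)
  }
  y
}

#' Time to peak of the hemodynamic response function
#'
#' Drives a single node's balloon model with a brief (0.5 s) unit neural
#' pulse and returns the time of the BOLD peak, the standard summary of HRF
#' delay used to calibrate per-node HRF variability.
#'
#' @param h a [hemodynamic_params()] object.
#' @param dt integration step (s).
#' @param t_max horizon (s).
#' @return peak time (s).
#' @export
hrf_peak_delay <- function(h, dt = 0.02, t_max = 20) {
  tt <- seq(0, t_max, by = dt)
  z <- as.numeric(tt < 0.5)
  y <- hemodynamic_response(z, h, dt)
  tt[which.max(y)]
}

# Calibration constant: realized sd of the HRF peak delay per unit sd of the
# shared log-normal jitter applied to (tau, tau_s, tau_f). Frozen from
# scripts/calibrate_hrf.R.
.hrf_delay_per_log_sd <- 1.35

#' Randomize hemodynamic parameters to emulate HRF variability
#'
#' Applies independent multiplicative log-normal perturbations to the three
#' time constants (`tau`, `tau_s`, `tau_f`) of each node, with a shared log
#' standard deviation calibrated so that the realized HRF peak delay has the
#' requested standard deviation across nodes (default 0.5 s; see
#' `scripts/calibrate_hrf.R` for the calibration).
#'
#' @param h baseline [hemodynamic_params()].
#' @param n_nodes number of per-node parameter sets to draw.
#' @param delay_sd target sd of the HRF peak delay (s).
#' @param seed integer seed.
#' @return list of `n_nodes` [hemodynamic_params()] objects.
#' @export
jitter_hemodynamics <- function(h, n_nodes, delay_sd = 0.5, seed = NULL) {
  stopifnot(inherits(h, "hemodynamic_params"))
  sigma <- delay_sd / .hrf_delay_per_log_sd
  with_seed(seed, lapply(seq_len(n_nodes), function(i) {
    fac <- exp(stats::rnorm(3, 0, sigma))
    hemodynamic_params(tau = h$tau * fac[1], alpha_grubb = h$alpha_grubb,
                       E0 = h$E0, V0 = h$V0, tau_s = h$tau_s * fac[2],
                       tau_f = h$tau_f * fac[3], epsilon = h$epsilon)
  }))
}
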