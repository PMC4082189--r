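# Shared fixtures, built in code at test time.

# quick node_time_series with given bold matrix
make_series <- function(bold, tr = 3, inputs = NULL, dt = 0.005) {
  node_time_series(as.matrix(bold), tr = tr, inputs = inputs, dt = dt)
}

# minimal synthetic cohort without running the ODE simulator: each subject
# gets Gaussian signals with per-node means so donor averaging is checkable
make_fake_cohort <- function(n_subjects, n_samples = 20, n_nodes = 4,
                             seed = 1, node_means = seq_len(n_nodes)) {
  subjects <- withr::with_seed(seed, lapply(seq_len(n_subjects), function(i)
    make_series(sweep(matrix(rnorm(n_samples * n_nodes), n_samples, n_nodes),
                      2, node_means, `+`))))
  structure(list(subjects = subjects,
                 true_model_id = rep(1L, n_subjects),
                 missing_mask = replicate(n_subjects, rep(FALSE, n_nodes),
                                          simplify = FALSE),
                 truth = NULL, seed = seed, tr = 3, noise_sd_frac = 0,
                 node_labels = paste0("n", seq_len(n_nodes)),
                 n_subjects = n_subjects),
            class = "dcm_cohort")
}

# a small two-node connectivity for integrator tests
two_node_conn <- function(w = 0.4, alpha_decay = 20) {
  effective_connectivity(matrix(c(-1, w, 0, -1), 2, 2),
                         C = matrix(c(1, 0), 2, 1),
                         alpha_decay = alpha_decay,
                         node_labels = c("a", "b"))
}

# boxcar input matrix at resolution dt
boxcar_input <- function(duration, dt, on_from, on_to, height = 1, m = 1,
                         col = 1) {
  tt <- seq(0, duration - dt, by = dt)
  U <- matrix(0, length(tt), m)
  U[tt >= on_from & tt < on_to, col] <- height
  U
}
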