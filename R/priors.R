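# Parameter vector plumbing: flattening theta = {A, B, C, h} with a name
# index, and shrinkage priors for inversion.
#
# Layout of the flattened vector (4-node model, m inputs):
#   A[i,j]      all n^2 entries, receiver-row convention; diagonal fixed -1,
#               absent edges fixed 0, present edges free.
#   B<j>[i,k]   modulatory entries per input; free only where modulated.
#   C[i,j]      direct input weights; free where the input enters.
#   log_<p>[node]  hemodynamic parameters on the log scale; the constants
#               that vary across nodes in the generative world (tau, tau_s,
#               tau_f) plus the efficacy epsilon are free, the rest fixed
#               at prior means.

H_FIELDS <- c("tau", "alpha_grubb", "E0", "V0", "tau_s", "tau_f", "epsilon")
H_FREE <- c("tau", "tau_s", "tau_f", "epsilon")

# index of every flattened entry for a candidate model
param_index <- function(model) {
  n <- model$n_nodes; m <- model$n_inputs; lab <- model$node_labels
  rows <- list()
  for (j in seq_len(n)) for (i in seq_len(n))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("A[%s,%s]", lab[i], lab[j]), block = "A",
      row = i, col = j, stringsAsFactors = FALSE)
  for (u in seq_len(m)) for (j in seq_len(n)) for (i in seq_len(n))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("B%d[%s,%s]", u, lab[i], lab[j]), block = "B",
      row = i, col = j, input = u, stringsAsFactors = FALSE)
  for (u in seq_len(m)) for (i in seq_len(n))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("C[%s,%d]", lab[i], u), block = "C",
      row = i, col = u, input = u, stringsAsFactors = FALSE)
  for (i in seq_len(n)) for (p in H_FIELDS)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("log_%s[%s]", p, lab[i]), block = "h",
      row = i, col = match(p, H_FIELDS), stringsAsFactors = FALSE)
  idx <- do.call(rbind, lapply(rows, function(r) {
    r$input <- r$input %||% NA_integer_; r
  }))
  rownames(idx) <- NULL
  idx
}

free_mask <- function(model, idx) {
  n <- model$n_nodes
  free <- logical(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, ]
    free[k] <- switch(r$block,
      A = r$row != r$col && model$topology[r$col, r$row] == 1,
      B = any(vapply(model$modulation, function(mo)
            mo$input == r$input &&
            match(mo$to, model$node_labels) == r$row &&
            match(mo$from, model$node_labels) == r$col, logical(1))),
      C = model$input_map[r$input] == r$row,
      h = H_FIELDS[r$col] %in% H_FREE)
  }
  free
}

#' Flatten connectivity and hemodynamics into a named parameter vector
#'
#' The flattened vector theta = {A, B, C, h} carries every entry with a
#' name index; hemodynamic parameters are stored on the log scale.
#' [unflatten_params()] is its exact inverse.
#'
#' @param conn an [effective_connectivity()].
#' @param h list of per-node [hemodynamic_params()].
#' @param model the [candidate_model()] defining the layout.
#' @return named numeric vector with attributes `index` and `free`.
#' @export
flatten_params <- function(conn, h, model) {
  idx <- param_index(model)
  H <- hparams_matrix(h, model$n_nodes)
  v <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, ]
    v[k] <- switch(r$block,
      A = conn$A[r$row, r$col],
      B = conn$B[[r$input]][r$row, r$col],
      C = conn$C[r$row, r$col],
      h = log(H[r$col, r$row]))
  }
  names(v) <- idx$name
  attr(v, "index") <- idx
  attr(v, "free") <- free_mask(model, idx)
  v
}

#' Rebuild connectivity and hemodynamics from a flattened parameter vector
#'
#' @param theta named vector from [flatten_params()] (or with the same
#'   layout).
#' @param model the [candidate_model()] defining the layout.
#' @param alpha_decay within-node decay rate (1/s), not part of theta.
#' @return list with elements `conn` and `h`.
#' @export
unflatten_params <- function(theta, model, alpha_decay = 20) {
  idx <- attr(theta, "index") %||% param_index(model)
  n <- model$n_nodes; m <- model$n_inputs
  theta <- as.numeric(theta)
  blk <- idx$block
  A <- matrix(0, n, n)
  kA <- which(blk == "A")
  A[cbind(idx$row[kA], idx$col[kA])] <- theta[kA]
  B <- lapply(seq_len(m), function(u) {
    Bu <- matrix(0, n, n)
    kB <- which(blk == "B" & idx$input == u)
    Bu[cbind(idx$row[kB], idx$col[kB])] <- theta[kB]
    Bu
  })
  C <- matrix(0, n, m)
  kC <- which(blk == "C")
  C[cbind(idx$row[kC], idx$col[kC])] <- theta[kC]
  H <- matrix(0, 7, n)
  kH <- which(blk == "h")
  H[cbind(idx$col[kH], idx$row[kH])] <- exp(theta[kH])
  dimnames(A) <- list(model$node_labels, model$node_labels)
  hs <- lapply(seq_len(n), function(i)
    structure(as.list(stats::setNames(H[, i], H_FIELDS)),
              class = "hemodynamic_params"))
  list(conn = structure(list(A = A, B = B, C = C, alpha_decay = alpha_decay,
                             node_labels = model$node_labels, n_nodes = n,
                             n_inputs = m),
                        class = "effective_connectivity"),
       h = hs)
}

#' Default shrinkage priors for a candidate model
#'
#' Gaussian priors over the flattened parameter vector: free A, B and C
#' entries have mean 0; A and B entries get variance `conn_var` (default
#' 0.25, i.e. sd 0.5, loose enough to cover the 0.2--0.6 simulated strength
#' range and typical modulation sizes) and C entries the looser `c_var`
#' (default 1); absent edges are fixed at 0 with prior variance 0
#' (infinite precision); the diagonal of A is fixed at -1. Hemodynamic
#' parameters have log-normal priors centred at the conventional prior
#' means with log sd `h_log_sd` (default 0.15) on the free components
#' (the jittered time constants tau, tau_s, tau_f plus epsilon) and
#' variance 0 on the rest.
#'
#' @param model a [candidate_model()].
#' @param conn_var prior variance of free A and B entries.
#' @param c_var prior variance of free C entries.
#' @param h_log_sd prior sd of free log hemodynamic parameters.
#' @param h prior-mean [hemodynamic_params()].
#' @param alpha_decay fixed within-node decay rate (1/s).
#' @return an object of class `dcm_prior` with fields `mean` (full vector),
#'   `cov` (free x free), `free`, `index`, `model`, `alpha_decay`.
#' @export
default_priors <- function(model, conn_var = 0.25, c_var = 1, h_log_sd = 0.15,
                           h = hemodynamic_params(), alpha_decay = 20) {
  stopifnot(inherits(model, "candidate_model"))
  idx <- param_index(model)
  free <- free_mask(model, idx)
  mu <- numeric(nrow(idx))
  var_full <- numeric(nrow(idx))
  hvals <- log(unlist(h[H_FIELDS]))
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, ]
    if (r$block == "A" && r$row == r$col) mu[k] <- -1
    if (r$block == "h") mu[k] <- hvals[r$col]
    var_full[k] <- if (!free[k]) 0
      else switch(r$block, h = h_log_sd^2, C = c_var, conn_var)
  }
  names(mu) <- idx$name
  structure(list(mean = mu, cov = diag(var_full[free], sum(free)),
                 free = free, index = idx, model = model,
                 alpha_decay = alpha_decay),
            class = "dcm_prior")
}

# insert free values into the full prior-mean vector
full_theta <- function(prior, free_values) {
  th <- prior$mean
  th[prior$free] <- free_values
  attr(th, "index") <- prior$index
  attr(th, "free") <- prior$free
  th
}
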