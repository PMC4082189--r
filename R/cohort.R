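# Synthetic Go/No-Go cohort generation: telegraph stimuli, candidate model
# family, randomized connectivity, per-subject simulation, node removal.

# Input up-state height shared by both stimuli. Calibrated once (see
# scripts/calibrate_amplitude.R) so that simulated BOLD percent-signal-change
# amplitudes are approximately 4% of mean intensity, matching typical 3T
# task data.
.default_stim_height <- 4.2

#' Telegraph stimulus design
#'
#' A two-state (box-car) input whose switching is governed by a Poisson
#' process: dwell times in the up and down states are exponentially
#' distributed with the given means. Gaussian neural variability with
#' standard deviation `noise_frac` times the height difference between the
#' two states is added at resolution `dt`.
#'
#' The package defaults mirror a Go/No-Go design: a visual input with 5 s
#' (up) / 5 s (down) mean dwell and an auditory stop signal with 2.5 s (up)
#' / 10 s (down); see [default_stimulus_designs()].
#'
#' @param mean_up,mean_down mean dwell times (s) of the up and down states.
#' @param height up-state height (down state is 0); the default is
#'   calibrated for ~4% BOLD amplitude.
#' @param noise_frac jitter sd as a fraction of the state-height difference.
#' @param dt sample resolution (s).
#' @param duration total length (s).
#' @return an object of class `stimulus_design`.
#' @export
stimulus_design <- function(mean_up, mean_down, height = .default_stim_height,
                            noise_frac = 1 / 20, dt = 0.005, duration = 600) {
  assert_that(mean_up > 0 && mean_down > 0, "mean dwell times must be positive")
  assert_that(noise_frac >= 0, "noise_frac must be nonnegative")
  structure(list(mean_up = mean_up, mean_down = mean_down, height = height,
                 noise_frac = noise_frac, dt = dt, duration = duration),
            class = "stimulus_design")
}

#' Default visual and auditory stimulus designs
#'
#' @param duration total length (s).
#' @param dt sample resolution (s).
#' @param height up-state height.
#' @return named list with elements `visual` (5 s up / 5 s down) and
#'   `auditory` (2.5 s up / 10 s down).
#' @export
default_stimulus_designs <- function(duration = 600, dt = 0.005,
                                     height = .default_stim_height) {
  list(visual   = stimulus_design(5, 5, height, dt = dt, duration = duration),
       auditory = stimulus_design(2.5, 10, height, dt = dt, duration = duration))
}

#' Generate one telegraph stimulus realization
#'
#' @param design a [stimulus_design()].
#' @param seed integer seed.
#' @return numeric vector of length `duration / dt` with attributes
#'   `dwell_up` and `dwell_down` holding the drawn dwell times (s).
#' @export
generate_stimulus <- function(design, seed = NULL) {
  stopifnot(inherits(design, "stimulus_design"))
  n <- round(design$duration / design$dt)
  with_seed(seed, {
    # alternate exponentially distributed dwells, starting in the down state
    t_acc <- 0
    up <- FALSE
    starts <- numeric(0); states <- logical(0); dwells <- numeric(0)
    while (t_acc < design$duration) {
      d <- stats::rexp(1, rate = 1 / if (up) design$mean_up else design$mean_down)
      starts <- c(starts, t_acc); states <- c(states, up); dwells <- c(dwells, d)
      t_acc <- t_acc + d
      up <- !up
    }
    tt <- (seq_len(n) - 1) * design$dt
    state_at <- states[findInterval(tt, starts)]
    sig <- ifelse(state_at, design$height, 0)
    if (design$noise_frac > 0)
      sig <- sig + stats::rnorm(n, 0, design$noise_frac * design$height)
    attr(sig, "dwell_up") <- dwells[states]
    attr(sig, "dwell_down") <- dwells[!states]
    sig
  })
}

#' Candidate network topology
#'
#' One member of the model family: a binary adjacency over the four nodes
#' V (visual), A (auditory), M (motor), P (prefrontal), with element
#' `(i, j)` marking a directed connection from node i to node j. Input u1
#' always enters V and u2 always enters A; u2 (the stop signal) modulates
#' the P -> M edge when that edge is present, implementing inhibition of the
#' motor response by the auditory stimulus.
#'
#' @param model_id integer identifier.
#' @param topology binary n x n matrix, rows = source node.
#' @param node_labels node names.
#' @param input_map integer vector: node index receiving each input.
#' @param modulation list of lists `list(input =, from =, to =)` naming
#'   modulated edges, or empty.
#' @return an object of class `candidate_model`.
#' @export
candidate_model <- function(model_id, topology,
                            node_labels = c("V", "A", "M", "P"),
                            input_map = c(1L, 2L),
                            modulation = list(list(input = 2L, from = "P", to = "M"))) {
  topology <- as.matrix(topology)
  n <- nrow(topology)
  assert_that(n == 4 && ncol(topology) == 4, "candidate models have exactly 4 nodes")
  assert_that(all(topology %in% c(0, 1)), "topology must be binary")
  assert_that(all(diag(topology) == 0), "topology excludes self-loops")
  dimnames(topology) <- list(node_labels, node_labels)
  # keep only modulations whose edge exists in this topology
  modulation <- Filter(function(m) topology[m$from, m$to] == 1, modulation)
  structure(list(model_id = as.integer(model_id), topology = topology,
                 node_labels = node_labels, input_map = as.integer(input_map),
                 modulation = modulation, n_nodes = n,
                 n_inputs = length(input_map)),
            class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  edges <- which(x$topology == 1, arr.ind = TRUE)
  lab <- if (nrow(edges)) paste(x$node_labels[edges[, 1]], "->",
                                x$node_labels[edges[, 2]], collapse = ", ")
         else "(no inter-node edges)"
  cat(sprintf("<candidate_model %d> %s\n", x$model_id, lab))
  invisible(x)
}

#' The default 16-model family
#'
#' Builds 16 distinct four-node topologies by toggling the presence of each
#' edge in a pool of four directed edges (by default V->P, A->P, P->M,
#' V->M) over a fixed base in which u1 drives V and u2 drives A. Model ids
#' are 1 + the binary code of the included edges (edge k present sets bit
#' k - 1), so model 16 contains the full pool and model 1 none of it. The
#' family always contains the designated true model and all adjacencies are
#' pairwise distinct by construction.
#'
#' @param edge_pool list of `c(from, to)` label pairs toggled across the
#'   family.
#' @param node_labels the four node names.
#' @param modulation modulation specification applied to every member (only
#'   realized where the modulated edge exists).
#' @return list of 2^length(edge_pool) [candidate_model()] objects.
#' @export
model_family <- function(edge_pool = list(c("V", "P"), c("A", "P"),
                                          c("P", "M"), c("V", "M")),
                         node_labels = c("V", "A", "M", "P"),
                         modulation = list(list(input = 2L, from = "P", to = "M"))) {
  n_edge <- length(edge_pool)
  fam <- lapply(seq_len(2^n_edge), function(id) {
    topo <- matrix(0, 4, 4, dimnames = list(node_labels, node_labels))
    bits <- as.integer(intToBits(id - 1))[seq_len(n_edge)]
    for (k in which(bits == 1L))
      topo[edge_pool[[k]][1], edge_pool[[k]][2]] <- 1
    candidate_model(id, topo, node_labels = node_labels,
                    modulation = modulation)
  })
  keys <- vapply(fam, function(m) paste(m$topology, collapse = ""), character(1))
  if (anyDuplicated(keys)) stop("model family contains duplicate topologies")
  fam
}

#' Deterministic family subset that retains the true model
#'
#' Members are ranked by decreasing edge count (ties broken by id) and the
#' first `size` are kept; if the true model is not among them it replaces
#' the last. This keeps the densest, most confusable competitors while
#' preserving the paper-style experimental structure of comparing subsets
#' of 16, 8 or 4 models that include the truth.
#'
#' @param family list of [candidate_model()].
#' @param size subset size.
#' @param true_model_id id that must be retained.
#' @return list of `size` models, ordered by id.
#' @export
family_subset <- function(family, size, true_model_id) {
  ids <- vapply(family, `[[`, integer(1), "model_id")
  assert_that(true_model_id %in% ids, "true model must be in the family")
  assert_that(size >= 1 && size <= length(family), "invalid subset size")
  n_edges <- vapply(family, function(m) sum(m$topology), numeric(1))
  ord <- order(-n_edges, ids)
  keep <- ids[ord][seq_len(size)]
  if (!(true_model_id %in% keep)) keep[size] <- true_model_id
  out <- family[ids %in% keep]
  out[order(vapply(out, `[[`, integer(1), "model_id"))]
}

#' Draw randomized connection strengths for a candidate topology
#'
#' Present edges receive independent Gaussian(0.4, 0.1) weights truncated
#' (by rejection) to the range 0.2 to 0.6; absent edges are exactly 0 and
#' the diagonal of A is -1. Direct input weights are 1 (response amplitude
#' is carried by the calibrated stimulus height). Modulated edges get a
#' negative (inhibitory) weight of the same truncated-normal magnitude.
#'
#' @param model a [candidate_model()].
#' @param seed integer seed.
#' @param strength_mean,strength_sd,strength_range moments and range of the
#'   truncated normal edge-weight distribution.
#' @param alpha_decay within-node decay rate (1/s).
#' @return an [effective_connectivity()] object.
#' @export
sample_connectivity <- function(model, seed = NULL, strength_mean = 0.4,
                                strength_sd = 0.1, strength_range = c(0.2, 0.6),
                                alpha_decay = 20) {
  stopifnot(inherits(model, "candidate_model"))
  rtrunc <- function(k) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      repeat {
        x <- stats::rnorm(1, strength_mean, strength_sd)
        if (x >= strength_range[1] && x <= strength_range[2]) break
      }
      out[i] <- x
    }
    out
  }
  with_seed(seed, {
    n <- model$n_nodes
    edges <- which(model$topology == 1, arr.ind = TRUE)
    A <- diag(-1, n)
    dimnames(A) <- dimnames(model$topology)
    if (nrow(edges)) {
      w <- rtrunc(nrow(edges))
      for (e in seq_len(nrow(edges)))
        A[edges[e, 2], edges[e, 1]] <- w[e]  # receiver-row convention
    }
    B <- replicate(model$n_inputs,
                   matrix(0, n, n, dimnames = dimnames(A)),
                   simplify = FALSE)
    for (mod in model$modulation)
      B[[mod$input]][match(mod$to, model$node_labels),
                     match(mod$from, model$node_labels)] <- -rtrunc(1)
    C <- matrix(0, n, model$n_inputs,
                dimnames = list(model$node_labels, NULL))
    for (j in seq_along(model$input_map)) C[model$input_map[j], j] <- 1
    effective_connectivity(A, B, C, alpha_decay = alpha_decay,
                           node_labels = model$node_labels)
  })
}

#' Simulate a cohort of subjects under one true model
#'
#' Each subject gets an independent stimulus realization for both inputs,
#' an independent connectivity draw, per-node HRF jitter and independent
#' observation noise; all per-subject seeds derive from `seed` via
#' [derive_seed()], so generation is order-independent. The per-subject
#' ground truth (connectivity and hemodynamic parameters) is retained for
#' parameter-recovery diagnostics.
#'
#' @param true_model a [candidate_model()].
#' @param n_subjects number of subjects.
#' @param seed master seed.
#' @param noise_sd_frac thermal observation noise as a fraction of mean
#'   signal level (default 0.003, the mid-range of 0.1--1%).
#' @param hrf_delay_sd sd of the HRF peak delay across nodes (s); 0 keeps
#'   every node at the prior-mean hemodynamics.
#' @param designs list of [stimulus_design()], one per input.
#' @param h baseline [hemodynamic_params()].
#' @param dt integrator step (s).
#' @param tr repetition time (s).
#' @param duration session length (s).
#' @return an object of class `dcm_cohort`.
#' @export
simulate_cohort <- function(true_model, n_subjects, seed = 1,
                            noise_sd_frac = 0.003, hrf_delay_sd = 0.5,
                            designs = default_stimulus_designs(duration = duration, dt = dt),
                            h = hemodynamic_params(),
                            dt = 0.005, tr = 3, duration = 600) {
  stopifnot(inherits(true_model, "candidate_model"), n_subjects >= 1)
  subjects <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    stim <- vapply(seq_along(designs), function(j)
      as.numeric(generate_stimulus(designs[[j]],
                                   seed = derive_seed(seed, paste0("stimulus", j), i))),
      numeric(round(duration / dt)))
    conn <- sample_connectivity(true_model,
                                seed = derive_seed(seed, "connectivity", i))
    hs <- if (hrf_delay_sd > 0)
      jitter_hemodynamics(h, true_model$n_nodes, delay_sd = hrf_delay_sd,
                          seed = derive_seed(seed, "hrf", i))
    else replicate(true_model$n_nodes, h, simplify = FALSE)
    ts <- tryCatch(
      simulate_bold(conn, hs, stim, dt = dt, tr = tr,
                    noise_sd_frac = noise_sd_frac,
                    seed = derive_seed(seed, "noise", i)),
      error = function(e) stop(sprintf("subject %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    subjects[[i]] <- ts
    truth[[i]] <- list(conn = conn, h = hs)
  }
  structure(list(subjects = subjects,
                 true_model_id = rep(true_model$model_id, n_subjects),
                 missing_mask = replicate(n_subjects,
                                          rep(FALSE, true_model$n_nodes),
                                          simplify = FALSE),
                 truth = truth, seed = seed, tr = tr,
                 noise_sd_frac = noise_sd_frac,
                 node_labels = true_model$node_labels,
                 n_subjects = n_subjects),
            class = "dcm_cohort")
}

#' @export
print.dcm_cohort <- function(x, ...) {
  cat(sprintf("<dcm_cohort> %d subjects, true model %s, %d x %d series, TR = %g s\n",
              x$n_subjects, paste(unique(x$true_model_id), collapse = "/"),
              x$subjects[[1]]$n_samples, x$subjects[[1]]$n_nodes, x$tr))
  invisible(x)
}

#' Mark nodes as missing across a cohort
#'
#' For each subject, `n_missing` distinct nodes are chosen uniformly at
#' random and flagged in the missing mask. The underlying series is
#' retained privately (the mask is the contract: downstream fills replace
#' flagged columns, and ground-truth diagnostics may still read the
#' original data).
#'
#' @param cohort a `dcm_cohort`.
#' @param n_missing 0, 1 or 2 nodes to remove per subject.
#' @param seed integer seed.
#' @return the cohort with `missing_mask` set.
#' @export
remove_nodes <- function(cohort, n_missing, seed = NULL) {
  stopifnot(inherits(cohort, "dcm_cohort"))
  n_nodes <- cohort$subjects[[1]]$n_nodes
  assert_that(n_missing >= 0 && n_missing < n_nodes,
              "n_missing must be smaller than the number of nodes")
  cohort$missing_mask <- with_seed(seed,
    lapply(seq_len(cohort$n_subjects), function(i) {
      m <- rep(FALSE, n_nodes)
      if (n_missing > 0) m[sample.int(n_nodes, n_missing)] <- TRUE
      m
    }))
  cohort
}
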