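# The four missing-node estimation methods: zero-, mean-, noise-filling and
# EM-Gaussian estimation. All fills leave unmasked columns bit-exact.

#' Replace missing-node columns with zeros
#'
#' @param series a [node_time_series()].
#' @param mask logical vector, one entry per node; `TRUE` marks a missing
#'   node.
#' @return the series with masked columns set to 0 (idempotent).
#' @export
fill_zero <- function(series, mask) {
  stopifnot(inherits(series, "node_time_series"))
  mask <- check_mask(series, mask)
  series$bold[, mask] <- 0
  series
}

#' Replace missing-node columns with the cross-subject mean
#'
#' The masked column is replaced by the time-point-wise average of the same
#' node across the other subjects of the cohort in which that node is
#' available (not itself masked). The subject itself never contributes.
#'
#' @param series a [node_time_series()] (one subject of `cohort`).
#' @param mask logical missing-node mask for that subject.
#' @param cohort the `dcm_cohort` providing donor subjects.
#' @param subject index of `series` within `cohort` (excluded from donors).
#' @return the filled series.
#' @export
fill_mean <- function(series, mask, cohort, subject) {
  stopifnot(inherits(series, "node_time_series"), inherits(cohort, "dcm_cohort"))
  mask <- check_mask(series, mask)
  for (node in which(mask)) {
    donors <- setdiff(which(!vapply(cohort$missing_mask, `[`, logical(1), node)),
                      subject)
    if (length(donors) == 0)
      stop(sprintf("no donor subject has node %d available", node))
    donor_mat <- vapply(donors, function(s) cohort$subjects[[s]]$bold[, node],
                        numeric(series$n_samples))
    series$bold[, node] <- rowMeans(donor_mat)
  }
  series
}

#' Replace missing-node columns with minimal white noise
#'
#' Masked columns are filled with i.i.d. Gaussian noise of standard
#' deviation `sd_frac` times the subject's mean signal level (default
#' 0.0005, i.e. 0.05% of mean intensity under the percent-signal-change
#' convention with baseline 100). Mean signal level is computed over the
#' unmasked entries of the series.
#'
#' @param series a [node_time_series()].
#' @param mask logical missing-node mask.
#' @param sd_frac noise sd as a fraction of mean signal level.
#' @param seed integer seed.
#' @return the filled series.
#' @export
fill_noise <- function(series, mask, sd_frac = 5e-4, seed = NULL) {
  stopifnot(inherits(series, "node_time_series"))
  mask <- check_mask(series, mask)
  assert_that(sd_frac > 0, "sd_frac must be positive")
  level <- mean(series$bold[, !mask, drop = FALSE]) + 100
  sd <- sd_frac * abs(level)
  with_seed(seed, {
    for (node in which(mask))
      series$bold[, node] <- stats::rnorm(series$n_samples, 0, sd)
  })
  series
}

#' Multivariate-Gaussian EM over node signals with missing columns
#'
#' Treats each time point as one draw from an n-node multivariate Gaussian
#' and the masked nodes' entries as missing at random. The E-step computes
#' the conditional mean and covariance of the missing coordinates given the
#' observed ones under the current (mean, covariance); the M-step updates
#' the moments from the completed sufficient statistics. Iteration stops
#' when the relative gain in observed-data log-likelihood drops below `tol`
#' or after `max_iter` iterations. The observed-data log-likelihood is
#' nondecreasing by the EM guarantee.
#'
#' Initialization: observed nodes at their sample moments; missing nodes at
#' the pooled observed mean and pooled observed variance, with zero initial
#' cross-covariance. With an entirely missing column the likelihood carries
#' no information about it, so the estimate stays at this pooled marginal
#' (the intended degenerate behaviour).
#'
#' @param series a [node_time_series()].
#' @param mask logical missing-node mask (entire columns missing).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `gaussian_estimate` with fields `mean`,
#'   `cov`, `loglik_trace`, `n_iter`, `converged`.
#' @export
em_fit_gaussian <- function(series, mask, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(series, "node_time_series"))
  mask <- check_mask(series, mask)
  Y <- series$bold
  n <- ncol(Y); T_ <- nrow(Y)
  assert_that(any(!mask), "at least one node must be observed")
  assert_that(T_ > n, "need more time points than nodes")
  obs <- which(!mask); mis <- which(mask)

  mu <- numeric(n)
  S <- diag(1, n)
  mu[obs] <- colMeans(Y[, obs, drop = FALSE])
  S[obs, obs] <- stats::cov(Y[, obs, drop = FALSE]) * (T_ - 1) / T_
  if (length(mis)) {
    pooled_mu <- mean(Y[, obs, drop = FALSE])
    pooled_var <- mean(apply(Y[, obs, drop = FALSE], 2, stats::var)) * (T_ - 1) / T_
    mu[mis] <- pooled_mu
    S[mis, mis] <- diag(pooled_var, length(mis))
    S[obs, mis] <- 0; S[mis, obs] <- 0
  }

  obs_loglik <- function(mu, S) {
    So <- S[obs, obs, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    R <- sweep(Y[, obs, drop = FALSE], 2, mu[obs])
    z <- backsolve(ch, t(R), transpose = TRUE)
    -0.5 * T_ * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch)))) -
      0.5 * sum(z^2)
  }

  ll <- obs_loglik(mu, S)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  if (length(mis) == 0) {
    # nothing missing: the sample moments already maximize the likelihood
    converged <- TRUE; iter <- 1L; trace <- c(trace, obs_loglik(mu, S))
  } else {
    for (iter in seq_len(max_iter)) {
      So <- S[obs, obs, drop = FALSE]
      ch <- tryCatch(chol(So), error = function(e) NULL)
      if (is.null(ch)) {
        warning("singular observed covariance; applying ridge regularization")
        So <- So + diag(1e-8 * mean(diag(So)) + 1e-12, nrow(So))
        ch <- chol(So)
      }
      # regression of missing on observed coordinates
      W <- S[mis, obs, drop = FALSE] %*% chol2inv(ch)
      Ro <- sweep(Y[, obs, drop = FALSE], 2, mu[obs])
      Em <- matrix(mu[mis], T_, length(mis), byrow = TRUE) + Ro %*% t(W)
      Cm <- S[mis, mis, drop = FALSE] - W %*% S[obs, mis, drop = FALSE]

      Yc <- Y
      Yc[, mis] <- Em
      mu_new <- colMeans(Yc)
      Rc <- sweep(Yc, 2, mu_new)
      S_new <- crossprod(Rc) / T_
      S_new[mis, mis] <- S_new[mis, mis] + Cm
      S_new <- (S_new + t(S_new)) / 2

      mu <- mu_new; S <- S_new
      ll_new <- obs_loglik(mu, S)
      trace <- c(trace, ll_new)
      if (is.finite(ll) && abs(ll_new - ll) <= tol * max(1, abs(ll))) {
        converged <- TRUE
        ll <- ll_new
        break
      }
      ll <- ll_new
    }
  }
  names(mu) <- series$node_labels
  dimnames(S) <- list(series$node_labels, series$node_labels)
  structure(list(mean = mu, cov = S, loglik_trace = trace,
                 n_iter = iter, converged = converged, mask = mask),
            class = "gaussian_estimate")
}

#' Replace missing-node columns with an EM-estimated Gaussian process
#'
#' Fits the node-signal Gaussian by [em_fit_gaussian()] and fills each
#' masked column with independent identically distributed draws from the
#' estimated marginal (mean and variance) of that node. The fill is i.i.d.
#' by design; a conditional-mean fill (the E-step regression on the
#' observed nodes) is available with `method = "conditional"` but is not
#' the default.
#'
#' @param series a [node_time_series()].
#' @param mask logical missing-node mask.
#' @param seed integer seed for the fill draw.
#' @param method `"marginal"` (default, i.i.d. draws) or `"conditional"`.
#' @param fit optional precomputed [em_fit_gaussian()] result.
#' @return the filled series with the fit attached as attribute `em_fit`.
#' @export
fill_em <- function(series, mask, seed = NULL,
                    method = c("marginal", "conditional"), fit = NULL) {
  stopifnot(inherits(series, "node_time_series"))
  method <- match.arg(method)
  mask <- check_mask(series, mask)
  if (is.null(fit)) fit <- em_fit_gaussian(series, mask)
  mis <- which(mask); obs <- which(!mask)
  if (length(mis)) {
    if (method == "marginal") {
      with_seed(seed, {
        for (node in mis)
          series$bold[, node] <- stats::rnorm(series$n_samples,
                                              fit$mean[node],
                                              sqrt(max(fit$cov[node, node], 0)))
      })
    } else {
      W <- fit$cov[mis, obs, drop = FALSE] %*% solve(fit$cov[obs, obs, drop = FALSE])
      Ro <- sweep(series$bold[, obs, drop = FALSE], 2, fit$mean[obs])
      series$bold[, mis] <- matrix(fit$mean[mis], series$n_samples,
                                   length(mis), byrow = TRUE) + Ro %*% t(W)
    }
  }
  attr(series, "em_fit") <- fit
  series
}

#' Apply a fill method by name
#'
#' Dispatcher used by the experiment runner and command line: one of
#' `"zero"`, `"mean"`, `"noise"`, `"em"`, applied subject-wise across a
#' cohort using each subject's missing mask.
#'
#' @param cohort a `dcm_cohort` with masks set (see [remove_nodes()]).
#' @param method fill method name.
#' @param seed master seed for the stochastic fills.
#' @return a cohort whose subjects' masked columns are filled.
#' @export
fill_cohort <- function(cohort, method = c("zero", "mean", "noise", "em"),
                        seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "dcm_cohort"))
  for (i in seq_len(cohort$n_subjects)) {
    m <- cohort$missing_mask[[i]]
    if (!any(m)) next
    s <- cohort$subjects[[i]]
    cohort$subjects[[i]] <- switch(method,
      zero  = fill_zero(s, m),
      mean  = fill_mean(s, m, cohort, i),
      noise = fill_noise(s, m, seed = derive_seed(seed %||% 0, "fill_noise", i)),
      em    = fill_em(s, m, seed = derive_seed(seed %||% 0, "fill_em", i)))
  }
  cohort$fill_method <- method
  cohort
}

check_mask <- function(series, mask) {
  mask <- as.logical(mask)
  assert_that(length(mask) == series$n_nodes,
              "mask length must equal the number of nodes")
  mask
}
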