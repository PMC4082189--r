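# Diagnostics: RMSE between parameter vectors, histogram mutual
# information, and k-means cluster summaries over estimated parameters.

#' Root mean square error between two parameter vectors
#'
#' `sqrt(mean((theta_hat - theta)^2))` over identically named entries.
#'
#' @param theta,theta_hat named numeric vectors with the same name index.
#' @return nonnegative scalar.
#' @export
parameter_rmse <- function(theta, theta_hat) {
  assert_that(length(theta) == length(theta_hat),
              "parameter vectors must have equal length")
  if (!is.null(names(theta)) && !is.null(names(theta_hat))) {
    bad <- which(names(theta) != names(theta_hat))
    if (length(bad))
      stop(sprintf("parameter name mismatch at '%s' vs '%s'",
                   names(theta)[bad[1]], names(theta_hat)[bad[1]]))
  }
  sqrt(mean((as.numeric(theta_hat) - as.numeric(theta))^2))
}

#' Plug-in mutual information between two signals (nats)
#'
#' Estimates `MI(x, y) = sum p(x,y) log(p(x,y) / (p(x) p(y)))` on an
#' equal-width joint histogram with `n_bins` bins per axis; cells with zero
#' probability contribute zero. The plug-in estimate is nonnegative. A
#' constant signal carries no information: MI is 0 with a warning.
#'
#' @param x,y numeric signals of equal length (at least `n_bins`).
#' @param n_bins bins per axis (default 16).
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y, n_bins = 16) {
  assert_that(length(x) == length(y), "signals must have equal length")
  assert_that(length(x) >= n_bins, "need at least n_bins samples")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant signal: mutual information is 0")
    return(0)
  }
  bx <- cut(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
            include.lowest = TRUE, labels = FALSE)
  by <- cut(y, breaks = seq(min(y), max(y), length.out = n_bins + 1),
            include.lowest = TRUE, labels = FALSE)
  pxy <- table(factor(bx, levels = seq_len(n_bins)),
               factor(by, levels = seq_len(n_bins))) / length(x)
  px <- rowSums(pxy); py <- colSums(pxy)
  keep <- pxy > 0
  sum(pxy[keep] * log(pxy[keep] / outer(px, py)[keep]))
}

#' k-means diagnostics over estimated parameter vectors
#'
#' Lloyd's algorithm, best of `n_restarts` random starts by total
#' within-cluster sum of squared errors. Reports the within-cluster SSE,
#' the mean pairwise Euclidean distance between cluster centers (averaged
#' over unordered center pairs), the percentage of the population in each
#' cluster, and per-cluster per-parameter mean, mode (midpoint of the
#' modal histogram bin, 16 bins) and standard deviation.
#'
#' @param params subjects x parameters matrix.
#' @param k number of clusters (at most the number of subjects).
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @return an object of class `cluster_result`.
#' @export
kmeans_cluster <- function(params, k, seed = NULL, n_restarts = 10) {
  params <- as.matrix(params)
  assert_that(k >= 1 && k <= nrow(params),
              "k must be between 1 and the number of subjects")
  fit <- with_seed(seed, {
    best <- NULL
    tries <- 0
    while (is.null(best) && tries < 10 * n_restarts) {
      tries <- tries + 1
      cand <- tryCatch(
        stats::kmeans(params, centers = k, nstart = n_restarts,
                      algorithm = "Lloyd", iter.max = 100),
        error = function(e) NULL,
        warning = function(w) suppressWarnings(
          stats::kmeans(params, centers = k, nstart = n_restarts,
                        algorithm = "Lloyd", iter.max = 100)))
      if (!is.null(cand) && length(unique(cand$cluster)) == k) best <- cand
    }
    if (is.null(best)) stop("k-means failed to produce k non-empty clusters")
    best
  })
  centers <- fit$centers
  cd <- if (k > 1) mean(stats::dist(centers)) else NA_real_
  comp <- 100 * as.numeric(table(factor(fit$cluster, levels = seq_len(k)))) /
    nrow(params)
  bin_mode <- function(v, n_bins = 16) {
    if (diff(range(v)) == 0) return(v[1])
    br <- seq(min(v), max(v), length.out = n_bins + 1)
    h <- tabulate(cut(v, br, include.lowest = TRUE, labels = FALSE), n_bins)
    b <- which.max(h)
    (br[b] + br[b + 1]) / 2
  }
  summaries <- lapply(seq_len(k), function(c) {
    sub <- params[fit$cluster == c, , drop = FALSE]
    list(mean = colMeans(sub),
         mode = apply(sub, 2, bin_mode),
         sd = apply(sub, 2, stats::sd))
  })
  structure(list(k = k, assignments = fit$cluster,
                 within_sse = fit$tot.withinss,
                 center_distances = cd, composition = comp,
                 centers = centers, summaries = summaries),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, within-SSE = %.4g, mean center distance = %.4g\n",
              x$k, x$within_sse, x$center_distances))
  invisible(x)
}
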