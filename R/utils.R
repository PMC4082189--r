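# Internal helpers: seeded evaluation and seed derivation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of a pipeline (stimulus draw, connectivity draw,
#' HRF jitter, observation noise, node removal, fill, bootstrap) derives its
#' own seed from the master seed plus a stage label and an index, so cohort
#' generation is order-independent and embarrassingly parallel.
#'
#' The derivation is a small multiplicative-congruential hash over the label
#' bytes and the index, reduced modulo 2^31 - 2 (R seeds are 32-bit signed).
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"stimulus"`.
#' @param index nonnegative integer index within the stage.
#' @return a positive integer seed, deterministic in its arguments.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  mod <- 2147483647 # 2^31 - 1, prime
  h <- (as.double(master) %% mod)
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% mod
  h <- (h * 131 + as.double(index) + 1) %% mod
  as.integer(h %% (mod - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
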