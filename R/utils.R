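#' Clip probabilities away from 0 and 1
#'
#' Predicted probabilities are clipped to `[eps, 1 - eps]` before any log-odds
#' transform so that attributions and partial-dependence values stay finite.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping bound, default `1e-6`.
#' @return clipped numeric vector.
#' @export
clip_prob <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Derive a stage seed from a master seed
#'
#' Counter-based fan-out: stage `k` gets `(master + 7919 * k) mod (2^31 - 1)`.
#' Every source of randomness in a pipeline run draws its seed through this
#' scheme, so individual stages can be re-run in isolation.
#'
#' @param master integer master seed.
#' @param k stage counter (non-negative integer).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 7919 * as.numeric(k)) %% 2147483647)
}

# internal: classed errors so callers can distinguish failure modes
pa_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pdpaudit_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified index sample preserving class proportions; assumes RNG is set
strat_sample_idx <- function(y, size) {
  n <- length(y)
  stopifnot(size <= n)
  frac <- size / n
  idx <- integer(0)
  for (cl in sort(unique(y))) {
    pool <- which(y == cl)
    take <- floor(length(pool) * frac + 0.5)
    take <- max(1L, min(take, length(pool)))
    idx <- c(idx, sort(sample(pool, take)))
  }
  sort(idx)
}
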