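# Internal helpers shared across the package.

#' Derive a per-stage seed from a single run seed
#'
#' A single user-facing seed fans out to independent per-stage seeds by a
#' stable polynomial hash of the stage name, so adding a stage never perturbs
#' the random stream of another. Results stay below 2^31 - 1.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name (e.g. `"covariates"`).
#' @return A single integer usable with [set.seed()].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2099 + h) %% 2147483629L
}

# Rank-based (Mann-Whitney) AUC; ties get mean ranks. NA if single class.
auc_mw <- function(y, p) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Bernoulli deviance of probabilities p against binary y (total, not mean).
bernoulli_deviance <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
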