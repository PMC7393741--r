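# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL runs as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: the sum is -Inf, avoid NaN from (-Inf) - (-Inf)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# (1 - 1/X)^k, computed in log space so very large X stays accurate;
# the X = 1, k = 0 corner is 0^0 = 1
pow_miss <- function(X, k) {
  out <- exp(k * log1p(-1 / X))
  out[k == 0] <- 1
  out
}

# label for a subset of samples, canonical sample order
subset_label <- function(idx, sample_names) {
  paste(sample_names[sort(idx)], collapse = "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
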