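# Independent oracles used across tests. These re-derive expected values
# by brute force or direct formula evaluation and must stay independent
# of the package implementation paths they check.

# Exact droplet-type probabilities by enumerating all X^Y equally likely
# assignments of cells to droplets; droplet 1 is representative by
# symmetry. y is the per-sample cell count vector.
enum_formation <- function(X, y) {
  M <- length(y)
  Y <- sum(y)
  lab <- rep(seq_len(M), y)
  assign <- as.matrix(expand.grid(rep(list(seq_len(X)), Y)))
  in1 <- assign == 1L
  cnt <- rowSums(in1)
  distinct <- apply(in1, 1L, function(r) length(unique(lab[r])))
  p_ne <- mean(cnt > 0)
  p_ssd_l <- vapply(seq_len(M), function(l) {
    mean(cnt > 0 & distinct == 1L &
           apply(in1, 1L, function(r) all(lab[r] == l)))
  }, numeric(1L))
  list(
    p_nonempty = p_ne,
    p_singlet = mean(cnt == 1L) / p_ne,
    p_msm = mean(distinct >= 2L) / p_ne,
    p_ssm = mean(cnt >= 2L & distinct == 1L) / p_ne,
    p_ssd_l = p_ssd_l / p_ne
  )
}

# All 2^M subset probabilities prod(p[U]) * prod(1 - p[-U]) by direct
# enumeration; element j + 1 corresponds to bitmask j.
subset_probs <- function(p) {
  M <- length(p)
  vapply(0:(2^M - 1), function(code) {
    idx <- which(bitwAnd(code, 2^(seq_len(M) - 1L)) > 0L)
    prod(p[idx]) * prod(1 - p[setdiff(seq_len(M), idx)])
  }, numeric(1L))
}

# Direct column-wise CLR evaluation (geometric-mean form)
clr_oracle <- function(counts, pc = 1) {
  apply(counts, 2L, function(col) {
    g <- exp(mean(log(col + pc)))
    log((col + pc) / g)
  })
}

# Exact one-sided binomial tail sums
binom_upper_tail <- function(x, n, p) sum(stats::dbinom(x:n, n, p))
binom_lower_tail <- function(x, n, p) sum(stats::dbinom(0:x, n, p))

# random formation parameters for property-style loops
random_params <- function() {
  M <- sample(2:6, 1L)
  y <- stats::runif(M, 50, 5000)
  formation_params(X = stats::runif(1, sum(y) * 0.5, sum(y) * 20),
                   r_cap = stats::runif(1, 0.2, 1), y = y)
}

# merge a classification with simulation ground truth
truth_vs_class <- function(fit, sim) {
  cls <- fit$classification
  member <- attr(cls, "membership")
  pred_msm <- rowSums(member) >= 2L
  m <- match(sim$truth$barcode, cls$barcode)
  data.frame(class = cls$class[m], pred_msm = pred_msm[m],
             is_msm = sim$truth$is_msm,
             unclear = cls$class[m] == "UNCLEAR")
}
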