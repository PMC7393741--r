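#' Centered-log-ratio transform of an HTO matrix
#'
#' Applies the CLR transform column-wise (per sample, across GEMs):
#' `x[i, l] = log((counts[i, l] + pc) / g_l)` where `g_l` is the geometric
#' mean of `counts[, l] + pc` over all GEMs. Each transformed column has
#' mean zero. UMI counts of zero are common, so a pseudocount (default 1)
#' keeps the logarithm defined.
#'
#' @param counts HTO count matrix (GEMs x samples).
#' @param pseudocount non-negative value added to every count before the
#'   log; must be positive if any count is zero.
#' @return numeric matrix of CLR values with the input dimnames, and the
#'   per-column log geometric means in attribute `"log_geomean"`.
#' @export
clr_normalize <- function(counts, pseudocount = 1) {
  counts <- as_hto_matrix(counts)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && any(counts == 0L)) {
    stop("zero counts present: use a positive pseudocount")
  }
  lx <- log(counts + pseudocount)
  lg <- colMeans(lx)
  out <- sweep(lx, 2L, lg, `-`)
  attr(out, "log_geomean") <- lg
  out
}
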