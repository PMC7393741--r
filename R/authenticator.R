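#' Expected MSM fraction of a phony-type GEM cluster
#'
#' A phony-type cluster consists entirely of multiplets spanning several
#' cell types. A member GEM containing `k` cells is a same-sample
#' multiplet only if all `k` cells carry the same sample tag, which under
#' independent tagging with sample proportions `q` has probability
#' `sum(q^k)`; the MSM fraction of GEMs of order `k` is therefore
#' `1 - sum(q^k)`. With `order` distinct member cell types the smallest
#' possible GEM has `k = order` cells, giving the conservative
#' lower-bound expectation `1 - sum(q^order)` (the default): for
#' doublet-only clusters with `M` equal samples this is `1 - 1/M`.
#' Supplying formation parameters instead averages over the model-implied
#' distribution of the droplet cell count (Binomial(`Y`, `1/X`) truncated
#' to `k >= order`), which is slightly larger because some member GEMs
#' carry more than `order` cells.
#'
#' @param q sample proportions (positive, summing to 1).
#' @param order number of distinct member cell types (>= 2).
#' @param params optional [formation_params()] object enabling the
#'   order-averaged expectation.
#' @return expected MSM fraction in `[0, 1]`.
#' @export
phony_msm_expectation <- function(q, order = 2L, params = NULL) {
  if (order < 2L) stop("a phony-type GEM has at least 2 member types")
  q <- as.numeric(q)
  if (any(q <= 0) || abs(sum(q) - 1) > 1e-8) {
    stop("q must be positive proportions summing to 1")
  }
  if (is.null(params)) {
    return(1 - sum(q^order))
  }
  stopifnot(inherits(params, "formation_params"))
  X <- params$X
  Y <- params$Y
  k_max <- max(order + 30L, 50L)
  k <- order:k_max
  logw <- lgamma(Y + 1) - lgamma(k + 1) - lgamma(Y - k + 1) -
    k * log(X) + (Y - k) * log1p(-1 / X)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  sum(w * (1 - vapply(k, function(ki) sum(q^ki), numeric(1L))))
}

#' Expected MSM fraction of a pure-type GEM cluster
#'
#' Hypothetical MSM fraction of a cluster under the assumption that it
#' represents a real cell type: the type's underlying cell population
#' `y_t` is inferred from the cluster GEM count by inverting the
#' captured non-empty-droplet expectation
#' (`n_G = r_cap * X * (1 - (1-1/X)^y_t)`), and the formation model is
#' then applied to that population alone, split across samples with
#' proportions `q`. Small clusters of a rare type almost never
#' self-collide, so the expectation grows with `n_G`.
#'
#' @param n_G number of (confidently classified) GEMs in the cluster.
#' @param q sample proportions (positive, summing to 1).
#' @param params a [formation_params()] object for the whole dataset.
#' @return expected MSM fraction in `[0, 1]`.
#' @export
pure_msm_expectation <- function(n_G, q, params) {
  stopifnot(inherits(params, "formation_params"))
  q <- as.numeric(q)
  if (any(q <= 0) || abs(sum(q) - 1) > 1e-8) {
    stop("q must be positive proportions summing to 1")
  }
  if (n_G < 1) stop("cluster must contain at least one GEM")
  cap <- params$r_cap * params$X
  if (n_G >= cap) {
    stop("cluster GEM count exceeds the captured-droplet capacity")
  }
  y_t <- log1p(-n_G / cap) / log1p(-1 / params$X)
  type_params <- formation_params(X = params$X, r_cap = params$r_cap,
                                  y = stats::setNames(q * y_t,
                                                      names(params$y)[seq_along(q)]))
  formation_rates(type_params)$p_msm
}

#' Binomial authentication of a GEM cluster
#'
#' Tests the observed MSM count of a cluster against both hypotheses: the
#' pure-type test is the upper-tail exact binomial test at the pure-type
#' expectation (a pure cluster should not exceed it), and the phony-type
#' test is the lower-tail test at the phony-type expectation (a phony
#' cluster should not fall below it). The verdict is `"pure"` when only
#' the phony hypothesis is rejected, `"phony"` when only the pure
#' hypothesis is rejected, `"mixture"` when both are rejected, and
#' `"indeterminate"` when neither is (e.g. tiny clusters).
#'
#' @param n_G cluster GEM count (confidently classified GEMs).
#' @param n_msm_G observed MSM count within the cluster.
#' @param p_pure expected pure-type MSM fraction in `(0, 1)`.
#' @param p_phony expected phony-type MSM fraction in `(0, 1)`.
#' @param alpha significance level for both one-sided tests.
#' @return an object of class `"cluster_report"`: list with the inputs,
#'   the observed ratio `r_msm`, `p_value_pure`, `p_value_phony`, and
#'   `verdict`.
#' @export
authenticate_counts <- function(n_G, n_msm_G, p_pure, p_phony,
                                alpha = 0.05) {
  if (n_G < 1) stop("cluster must contain at least one GEM")
  if (n_msm_G < 0 || n_msm_G > n_G) stop("0 <= n_msm_G <= n_G required")
  if (p_pure <= 0 || p_pure >= 1 || p_phony <= 0 || p_phony >= 1) {
    stop("expectations must lie strictly inside (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p_value_pure <- stats::binom.test(n_msm_G, n_G, p = p_pure,
                                    alternative = "greater")$p.value
  p_value_phony <- stats::binom.test(n_msm_G, n_G, p = p_phony,
                                     alternative = "less")$p.value
  reject_pure <- p_value_pure < alpha
  reject_phony <- p_value_phony < alpha
  verdict <- if (reject_pure && reject_phony) {
    "mixture"
  } else if (reject_pure) {
    "phony"
  } else if (reject_phony) {
    "pure"
  } else {
    "indeterminate"
  }
  structure(list(n_G = n_G, n_msm_G = n_msm_G, r_msm = n_msm_G / n_G,
                 p_pure_expected = p_pure, p_phony_expected = p_phony,
                 p_value_pure = p_value_pure,
                 p_value_phony = p_value_phony,
                 alpha = alpha, verdict = verdict),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("GEM cluster authentication\n")
  cat(sprintf("  GEMs: %d   MSMs: %d   observed MSM%%: %.2f\n",
              x$n_G, x$n_msm_G, 100 * x$r_msm))
  cat(sprintf("  expected MSM%% (pure): %.2f   (phony): %.2f\n",
              100 * x$p_pure_expected, 100 * x$p_phony_expected))
  cat(sprintf("  p value (pure): %.3g   p value (phony): %.3g\n",
              x$p_value_pure, x$p_value_phony))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Authenticate a barcoded GEM cluster from a fitted demultiplexing run
#'
#' High-level wrapper: extracts the cluster's confidently classified GEMs
#' (NEGATIVE and UNCLEAR members are excluded), counts its MSMs, derives
#' the pure- and phony-type expectations from the fitted formation
#' parameters (sample proportions default to the fitted `y / Y`), and
#' runs [authenticate_counts()].
#'
#' @param fit a fitted [demux()] object.
#' @param barcodes character vector of GEM barcodes defining the cluster.
#' @param alpha significance level.
#' @param q optional sample proportions; defaults to the fitted split.
#' @param order assumed number of member cell types for the phony
#'   hypothesis (default 2, the conservative doublet bound).
#' @return a `"cluster_report"` (see [authenticate_counts()]).
#' @export
authenticate_cluster <- function(fit, barcodes, alpha = 0.05, q = NULL,
                                 order = 2L) {
  stopifnot(inherits(fit, "demux_fit"))
  cls <- fit$classification
  rows <- cls[cls$barcode %in% barcodes, , drop = FALSE]
  if (!nrow(rows)) stop("no cluster barcodes found in the classification")
  rows <- rows[!(rows$class %in% c("NEGATIVE", "UNCLEAR")), , drop = FALSE]
  if (!nrow(rows)) stop("cluster contains no confidently classified GEMs")
  member <- attr(cls, "membership")[cls$barcode %in% barcodes, ,
                                    drop = FALSE]
  n_msm <- sum(rowSums(member) >= 2L)
  q <- q %||% (fit$params$y / fit$params$Y)
  rep <- authenticate_counts(
    n_G = nrow(rows), n_msm_G = n_msm,
    p_pure = pure_msm_expectation(nrow(rows), q, fit$params),
    p_phony = phony_msm_expectation(q, order = order),
    alpha = alpha
  )
  rep
}
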