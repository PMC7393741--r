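#' Demultiplex a sample-barcoded dataset and estimate multiplet rates
#'
#' The full pipeline on an HTO count matrix of post-filtering, non-empty
#' droplets: CLR-normalize per sample ([clr_normalize()]), fit each
#' sample's two-component Gaussian mixture by EM
#' ([fit_sample_mixture()]), compute per-GEM posterior probabilities of
#' enclosing cells from each sample ([posterior_high()]), classify every
#' GEM into one of up to `2^M + 1` classes ([classify_gems()]), tally the
#' observables ([count_observed()]), and — given the user-estimated total
#' loaded cell count — fit the droplet-formation model by maximum
#' likelihood ([estimate_formation()]) to obtain the singlet, MSM, SSM
#' and RSSM rates ([formation_rates()]).
#'
#' The EM initialization is deterministic, so repeated runs on the same
#' input produce identical classifications; `seed` only affects the
#' estimator's multi-start jitter.
#'
#' @param counts HTO count matrix (GEMs x samples), e.g. from
#'   [read_hto_mtx()] or [read_hto_csv()].
#' @param total_cells user-estimated total number of loaded cells `Y`
#'   (e.g. from a hemocytometer). `NULL` skips rate estimation.
#' @param confidence confidence cutoff `c` for the UNCLEAR class.
#' @param pseudocount CLR pseudocount.
#' @param fix_X optional profiled droplet count passed to the estimator.
#' @param seed RNG seed for the estimator multi-starts.
#' @return an object of class `"demux_fit"`: list with `counts`, `clr`,
#'   `mixtures` (per-sample fits), `posteriors`, `classification`,
#'   `observed`, and — when rates are estimated — `params`
#'   (formation-parameter MLE), `rates` (rate report) and `obs_msm_rate`
#'   (classifier-observed MSM fraction among confidently classified
#'   GEMs).
#' @examples
#' sim <- sim_hashing(sim_config(n_droplets = 2000, seed = 7))
#' fit <- demux(sim$counts, total_cells = 2200)
#' summary(fit)
#' @export
demux <- function(counts, total_cells = NULL, confidence = 0.8,
                  pseudocount = 1, fix_X = NULL, seed = 1L) {
  counts <- as_hto_matrix(counts)
  clr <- clr_normalize(counts, pseudocount = pseudocount)
  mixtures <- lapply(seq_len(ncol(clr)), function(l) {
    fit_sample_mixture(clr[, l])
  })
  names(mixtures) <- colnames(counts)
  posteriors <- vapply(seq_len(ncol(clr)), function(l) {
    posterior_high(mixtures[[l]], clr[, l])
  }, numeric(nrow(clr)))
  dimnames(posteriors) <- dimnames(counts)

  classification <- classify_gems(posteriors, confidence = confidence)
  observed <- count_observed(classification)

  fit <- list(counts = counts, clr = clr, mixtures = mixtures,
              posteriors = posteriors, classification = classification,
              observed = observed, confidence = confidence,
              pseudocount = pseudocount, total_cells = total_cells)
  class(fit) <- "demux_fit"

  if (!is.null(total_cells)) {
    fit$params <- estimate_formation(observed, total_cells = total_cells,
                                     fix_X = fix_X, seed = seed)
    fit$rates <- formation_rates(fit$params)
    n_classified <- observed$n_total - observed$n_negative -
      observed$n_unclear
    fit$obs_msm_rate <- if (n_classified > 0) {
      observed$n_msm / n_classified
    } else {
      NA_real_
    }
  }
  fit
}

#' @export
print.demux_fit <- function(x, ...) {
  obs <- x$observed
  cat("Sample-barcoding demultiplexing fit\n")
  cat("  GEMs:", obs$n_total, "  samples:", length(obs$sample_names),
      "  confidence cutoff:", x$confidence, "\n")
  cat("  MSMs:", obs$n_msm, "  negative:", obs$n_negative,
      "  unclear:", obs$n_unclear, "\n")
  if (!is.null(x$params)) {
    cat("  estimated X:", format(round(x$params$X), big.mark = ","),
        "  r_cap:", round(x$params$r_cap, 3), "\n")
  }
  invisible(x)
}

#' @export
summary.demux_fit <- function(object, ...) {
  obs <- object$observed
  out <- list(
    n_total = obs$n_total,
    class_counts = sort(table(object$classification$class),
                        decreasing = TRUE),
    observed = obs,
    params = object$params,
    rates = object$rates,
    obs_msm_rate = object$obs_msm_rate
  )
  class(out) <- "summary.demux_fit"
  out
}

#' @export
print.summary.demux_fit <- function(x, ...) {
  cat("Classification (", x$n_total, " GEMs):\n", sep = "")
  print(x$class_counts)
  if (!is.null(x$rates)) {
    pct <- function(p) sprintf("%.2f%%", 100 * p)
    r <- x$rates
    cat("\nEstimated rates: singlet ", pct(r$p_singlet),
        "  MSM ", pct(r$p_msm), " (observed ", pct(x$obs_msm_rate), ")",
        "  SSM ", pct(r$p_ssm), "  RSSM ", pct(r$rssm), "\n", sep = "")
    cat("Formation parameters: X = ",
        format(round(x$params$X), big.mark = ","),
        ", r_cap = ", round(x$params$r_cap, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object a `"demux_fit"`.
#' @param what `"formation"` (droplet-formation MLE: X, r_cap, per-sample
#'   y) or `"mixture"` (per-sample Gaussian mixture parameters).
#' @param ... unused.
#' @return named numeric vector (`"formation"`) or a matrix with one row
#'   per sample (`"mixture"`).
#' @export
coef.demux_fit <- function(object, what = c("formation", "mixture"),
                           ...) {
  what <- match.arg(what)
  if (what == "formation") {
    if (is.null(object$params)) {
      stop("no formation parameters: refit with total_cells")
    }
    p <- object$params
    return(c(X = p$X, r_cap = p$r_cap,
             stats::setNames(p$y, paste0("y_", names(p$y)))))
  }
  t(vapply(object$mixtures, function(m) {
    c(mu_low = m$mu[1L], mu_high = m$mu[2L],
      sigma_low = m$sigma[1L], sigma_high = m$sigma[2L],
      pi_low = m$pi[1L], pi_high = m$pi[2L])
  }, numeric(6L)))
}

#' Classify new GEMs with a fitted model
#'
#' Applies the fitted per-sample mixtures to new raw HTO counts. The CLR
#' transform of the new counts reuses the training data's per-sample log
#' geometric means, so new GEMs are scored on the same scale the
#' mixtures were fitted on.
#'
#' @param object a `"demux_fit"`.
#' @param newdata HTO count matrix with the same samples.
#' @param type `"class"` for a classification table, `"posterior"` for
#'   the per-sample posterior matrix.
#' @param ... unused.
#' @export
predict.demux_fit <- function(object, newdata,
                              type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  newdata <- as_hto_matrix(newdata)
  if (ncol(newdata) != ncol(object$counts)) {
    stop("newdata must have the same samples as the fitted data")
  }
  lg <- attr(object$clr, "log_geomean")
  clr <- sweep(log(newdata + object$pseudocount), 2L, lg, `-`)
  post <- vapply(seq_len(ncol(clr)), function(l) {
    posterior_high(object$mixtures[[l]], clr[, l])
  }, numeric(nrow(clr)))
  dimnames(post) <- dimnames(newdata)
  if (type == "posterior") return(post)
  classify_gems(post, confidence = object$confidence)
}

#' Plot fitted per-sample mixtures over the CLR histograms
#'
#' One panel per sample: the histogram of CLR-transformed counts with the
#' two fitted Gaussian components and their weighted sum overlaid.
#'
#' @param x a `"demux_fit"`.
#' @param samples samples to plot (names or indices); default all.
#' @param breaks passed to [graphics::hist()].
#' @param ... further arguments passed to [graphics::hist()].
#' @export
plot.demux_fit <- function(x, samples = NULL, breaks = 60, ...) {
  sel <- samples %||% seq_along(x$mixtures)
  if (is.character(sel)) sel <- match(sel, names(x$mixtures))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(sel)))
  on.exit(graphics::par(old))
  for (l in sel) {
    v <- x$clr[, l]
    m <- x$mixtures[[l]]
    h <- graphics::hist(v, breaks = breaks, freq = FALSE,
                        main = names(x$mixtures)[l], xlab = "CLR value",
                        border = "grey70", ...)
    xs <- seq(min(v), max(v), length.out = 400)
    graphics::lines(xs, m$pi[1L] * stats::dnorm(xs, m$mu[1L], m$sigma[1L]),
                    col = "firebrick", lwd = 2)
    graphics::lines(xs, m$pi[2L] * stats::dnorm(xs, m$mu[2L], m$sigma[2L]),
                    col = "forestgreen", lwd = 2)
    graphics::lines(xs,
                    m$pi[1L] * stats::dnorm(xs, m$mu[1L], m$sigma[1L]) +
                      m$pi[2L] * stats::dnorm(xs, m$mu[2L], m$sigma[2L]),
                    col = "grey30", lty = 2)
  }
  invisible(x)
}

#' Simulate droplet formation at the fitted parameters
#'
#' Runs the generative formation model ([simulate_formation()]) at the
#' fitted parameter estimates, e.g. to compare simulated against
#' observed multiplet tallies.
#'
#' @param object a fitted `"demux_fit"` with formation parameters.
#' @param nsim number of formation experiments.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.demux_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (is.null(object$params)) {
    stop("no formation parameters: refit with total_cells")
  }
  simulate_formation(object$params, reps = nsim, seed = seed)
}
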