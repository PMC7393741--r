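#' Fit a two-component Gaussian mixture to one sample's CLR values
#'
#' Each sample's CLR-transformed HTO counts are bimodal: a low component
#' of GEMs carrying only ambient/background antibody for that sample, and
#' a high component of GEMs enclosing cells from the sample. The mixture
#' is fitted by expectation-maximization. Initialization splits the data
#' at its median and moment-matches each half; priors start at 0.5/0.5.
#' Components are returned ordered so that `mu_low < mu_high`.
#'
#' @param x numeric vector of CLR values for one sample (length >= 4,
#'   nonzero variance).
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the relative log-likelihood change.
#' @param var_floor lower bound applied to component variances, guarding
#'   against collapse onto point masses.
#' @return an object of class `"sample_mixture"`: list with `mu`, `sigma`,
#'   `pi` (each length 2, low then high), `loglik`, `iter`, `converged`.
#' @examples
#' x <- c(rnorm(200, 0, 0.3), rnorm(100, 4, 0.5))
#' fit <- fit_sample_mixture(x)
#' @export
fit_sample_mixture <- function(x, max_iter = 1000L, tol = 1e-6,
                               var_floor = 1e-6) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("need at least 4 observations per sample")
  if (stats::var(x) == 0) stop("degenerate column: all values equal")

  med <- stats::median(x)
  lo <- x[x <= med]
  hi <- x[x > med]
  if (!length(hi)) { # > half the data sits exactly at the median
    lo <- x[x < med]
    hi <- x[x >= med]
  }
  mu <- c(mean(lo), mean(hi))
  sigma <- sqrt(pmax(c(stats::var(lo), stats::var(hi)), var_floor,
                     na.rm = TRUE))
  sigma[is.na(sigma)] <- sqrt(var_floor)
  pi_k <- c(0.5, 0.5)

  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    l1 <- stats::dnorm(x, mu[1L], sigma[1L], log = TRUE) + log(pi_k[1L])
    l2 <- stats::dnorm(x, mu[2L], sigma[2L], log = TRUE) + log(pi_k[2L])
    norm <- log_sum_exp(l1, l2)
    ll <- sum(norm)
    g2 <- exp(l2 - norm) # responsibility of component 2
    g1 <- 1 - g2

    n1 <- sum(g1)
    n2 <- sum(g2)
    pi_k <- c(n1, n2) / length(x)
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    sigma <- sqrt(pmax(c(sum(g1 * (x - mu[1L])^2) / n1,
                         sum(g2 * (x - mu[2L])^2) / n2), var_floor))

    if (is.finite(loglik) &&
        abs(ll - loglik) < tol * (abs(loglik) + tol)) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }

  ord <- order(mu)
  structure(list(mu = mu[ord], sigma = sigma[ord], pi = pi_k[ord],
                 loglik = loglik, iter = iter, converged = converged),
            class = "sample_mixture")
}

#' @export
print.sample_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture\n")
  tab <- rbind(mu = x$mu, sigma = x$sigma, pi = x$pi)
  colnames(tab) <- c("low", "high")
  print(round(tab, 4))
  cat("log-likelihood:", format(x$loglik), " (", x$iter, "iterations)\n")
  invisible(x)
}

#' Posterior probability of the high (cell-enclosing) component
#'
#' Bayes' rule on the fitted mixture: the probability that a CLR value
#' originates from the high component, i.e. that the GEM contains cells
#' from the sample. Computed in log space to avoid underflow far in the
#' tails.
#'
#' @param model a `"sample_mixture"` fit.
#' @param x numeric vector of CLR values.
#' @return vector of probabilities in `[0, 1]`.
#' @export
posterior_high <- function(model, x) {
  stopifnot(inherits(model, "sample_mixture"))
  l_low <- stats::dnorm(x, model$mu[1L], model$sigma[1L], log = TRUE) +
    log(model$pi[1L])
  l_high <- stats::dnorm(x, model$mu[2L], model$sigma[2L], log = TRUE) +
    log(model$pi[2L])
  stats::plogis(l_high - l_low)
}
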