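#' Log-likelihood of observed cell-enclosing GEM counts
#'
#' Under the formation model, the number of droplets enclosing cells of
#' sample `l` is Binomial(`X`, `p_l`) with
#' `p_l = 1 - (1 - 1/X)^y_l`; the classifier observes the captured
#' fraction `z_l`, so `z_l / r_cap` such droplets are implied in total.
#' The log-likelihood sums `log Binom(z_l / r_cap; X, p_l)` over samples,
#' using the continuous (log-Gamma) extension of the binomial coefficient
#' since neither `X` nor `z_l / r_cap` need be integral.
#'
#' @param params a [formation_params()] object.
#' @param z named or plain non-negative vector of per-sample
#'   cell-enclosing GEM counts (one per sample), or an
#'   `"observed_counts"` object from [count_observed()].
#' @return the log-likelihood (`-Inf` outside the support, e.g. when
#'   `z_l / r_cap > X`).
#' @export
formation_loglik <- function(params, z) {
  stopifnot(inherits(params, "formation_params"))
  if (inherits(z, "observed_counts")) z <- z$z
  z <- as.numeric(z)
  if (length(z) != length(params$y)) {
    stop("z must have one count per sample")
  }
  if (params$r_cap <= 0) stop("r_cap must be positive to scale z")
  X <- params$X
  k <- z / params$r_cap
  if (any(k > X) || any(k < 0)) return(-Inf)
  p <- 1 - pow_miss(X, params$y)
  if (any(p <= 0) || any(p >= 1)) return(-Inf)
  sum(lgamma(X + 1) - lgamma(k + 1) - lgamma(X - k + 1) +
        k * log(p) + (X - k) * log1p(-p))
}

#' Maximum-likelihood estimation of droplet-formation parameters
#'
#' Infers `(X, r_cap, y_1..y_M)` from the classifier-observed per-sample
#' cell-enclosing GEM counts `z_l` and the user-supplied total cell count
#' `Y`, by maximizing [formation_loglik()] subject to `sum(y) = Y`,
#' `y > 0`, `X > 0`, `r_cap` in `(0, 1]`.
#'
#' With `M` counts and `M + 1` free parameters the likelihood has a flat
#' exact-fit ridge, so by default the estimate is anchored on one more
#' observable: the total number of cell-enclosing GEMs `n_gem`
#' (`r_cap * X * (1 - (1-1/X)^Y) = n_gem`), which determines `r_cap`
#' given `X` and makes the system exactly determined. Alternatively `X`
#' can be pinned to a profiled equipment value via `fix_X`, or the raw
#' unanchored maximization requested with `anchor = "none"` (its ridge
#' degeneracy pushes `X` toward the boundary; see the package vignette).
#' The per-sample split is parameterized on the simplex through softmax
#' weights, and optimization uses Nelder-Mead multi-starts followed by a
#' polish from the best start.
#'
#' @param observed an `"observed_counts"` object or a vector of `z`
#'   counts.
#' @param total_cells the user-estimated number of loaded cells `Y`.
#' @param n_gem observed number of cell-enclosing GEMs; defaults to
#'   `n_total - n_negative` when `observed` is an `"observed_counts"`
#'   object. Required for the default anchor.
#' @param fix_X optional fixed droplet count.
#' @param anchor `"gem_count"` (default) or `"none"`.
#' @param n_starts number of multi-starts.
#' @param seed seed for start-point jitter (the optimization itself is
#'   deterministic given the starts).
#' @param profile if `TRUE`, also compute the profile log-likelihood over
#'   a grid of `X` values (weights re-optimized at each), returned in
#'   attribute `"profile"`.
#' @return a [formation_params()] object with attributes `"loglik"`,
#'   `"anchor"`, `"n_gem"`, and optionally `"profile"` (data.frame with
#'   columns `X`, `r_cap`, `loglik`).
#' @export
estimate_formation <- function(observed, total_cells, n_gem = NULL,
                               fix_X = NULL,
                               anchor = c("gem_count", "none"),
                               n_starts = 10L, seed = 1L,
                               profile = FALSE) {
  anchor <- match.arg(anchor)
  if (inherits(observed, "observed_counts")) {
    z <- observed$z
    if (is.null(n_gem)) n_gem <- observed$n_total - observed$n_negative
  } else {
    z <- observed
  }
  z <- stats::setNames(as.numeric(z),
                       names(z) %||% paste0("HTO", seq_along(z)))
  M <- length(z)
  Y <- total_cells
  if (is.null(Y) || Y <= 0) stop("total_cells (Y) must be positive")
  if (all(z < 1)) stop("at least one sample must have z_l >= 1")
  if (anchor == "gem_count" && is.null(n_gem)) {
    stop("anchor = 'gem_count' needs n_gem (total cell-enclosing GEMs)")
  }

  # r_cap implied by the GEM-count anchor at a given X (NA if infeasible)
  anchored_r <- function(X) {
    r <- n_gem / (X * (1 - pow_miss(X, Y)))
    if (is.finite(r) && r > 0 && r <= 1) r else NA_real_
  }

  make_params <- function(X, r, w) {
    y <- Y * w
    if (any(y <= 0)) return(NULL)
    formation_params(X = X, r_cap = r, y = stats::setNames(y, names(z)))
  }

  softmax <- function(a) {
    e <- exp(c(a, 0) - max(a, 0))
    e / sum(e)
  }

  # negative log-likelihood over the active parameterization
  free_X <- is.null(fix_X)
  obj <- function(theta) {
    i <- 1L
    X <- if (free_X) exp(theta[i]) else fix_X
    if (free_X) i <- i + 1L
    r <- if (anchor == "gem_count") {
      anchored_r(X)
    } else {
      stats::plogis(theta[i])
    }
    if (anchor == "none") i <- i + 1L
    if (is.na(r)) return(1e10)
    w <- softmax(theta[i:(i + M - 2L)])
    if (M == 1L) w <- 1
    par <- make_params(X, r, w)
    if (is.null(par)) return(1e10)
    ll <- formation_loglik(par, z)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  n_free <- (if (free_X) 1L else 0L) +
    (if (anchor == "none") 1L else 0L) + (M - 1L)

  theta_of <- function(X0, r0, w0) {
    th <- numeric(0)
    if (free_X) th <- c(th, log(X0))
    if (anchor == "none") th <- c(th, stats::qlogis(min(max(r0, 1e-3), 0.999)))
    if (M > 1L) th <- c(th, log(w0[-M] / w0[M]))
    th
  }

  # start grid: X log-spaced between the infeasibility floor and 10 Y
  X_lo <- max(max(z), if (anchor == "gem_count") n_gem else max(z)) * 1.05
  X_hi <- max(10 * Y, X_lo * 2)
  starts <- list()
  w_prop <- if (sum(z) > 0) z / sum(z) else rep(1 / M, M)
  w_prop <- pmax(w_prop, 1e-6)
  w_prop <- w_prop / sum(w_prop)
  with_seed(seed, {
    X_grid <- exp(seq(log(X_lo), log(X_hi), length.out = max(2L, n_starts)))
    for (s in seq_len(max(2L, n_starts))) {
      w0 <- if (s %% 2L == 0L) rep(1 / M, M) else w_prop
      w0 <- w0 * exp(stats::rnorm(M, 0, 0.05))
      w0 <- w0 / sum(w0)
      starts[[s]] <- theta_of(X_grid[s], 0.5 * exp(stats::rnorm(1, 0, 0.1)),
                              w0)
    }
  })

  run_optim <- function(th0) {
    if (n_free == 1L) {
      opt <- stats::optim(th0, obj, method = "Brent",
                          lower = th0 - 20, upper = th0 + 20)
    } else {
      opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
    }
    opt
  }

  fits <- lapply(starts, run_optim)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  best <- run_optim(best$par) # polish
  if (n_free > 1L) {
    bfgs <- tryCatch(
      stats::optim(best$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(bfgs) && bfgs$value < best$value) best <- bfgs
  }

  # unpack the winner
  i <- 1L
  X_hat <- if (free_X) exp(best$par[i]) else fix_X
  if (free_X) i <- i + 1L
  r_hat <- if (anchor == "gem_count") anchored_r(X_hat) else
    stats::plogis(best$par[i])
  if (anchor == "none") i <- i + 1L
  w_hat <- if (M > 1L) softmax(best$par[i:(i + M - 2L)]) else 1
  est <- make_params(X_hat, r_hat, w_hat)
  if (is.null(est) || !is.finite(formation_loglik(est, z))) {
    stop("optimizer failed to find a feasible parameter set")
  }
  attr(est, "loglik") <- -best$value
  attr(est, "anchor") <- if (!free_X) "fixed_X" else anchor
  attr(est, "n_gem") <- n_gem

  if (profile) {
    X_grid <- exp(seq(log(max(X_lo, X_hat / 4)), log(X_hat * 4),
                      length.out = 15L))
    prof <- t(vapply(X_grid, function(Xg) {
      rg <- if (anchor == "gem_count") anchored_r(Xg) else r_hat
      if (is.na(rg)) return(c(NA_real_, NA_real_))
      if (M > 1L) {
        w_obj <- function(a) {
          par <- make_params(Xg, rg, softmax(a))
          if (is.null(par)) return(1e10)
          ll <- formation_loglik(par, z)
          if (!is.finite(ll)) 1e10 else -ll
        }
        a0 <- log(w_prop[-M] / w_prop[M])
        o <- if (M == 2L) {
          stats::optim(a0, w_obj, method = "Brent",
                       lower = a0 - 10, upper = a0 + 10)
        } else {
          stats::optim(a0, w_obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
        }
        c(rg, -o$value)
      } else {
        par <- make_params(Xg, rg, 1)
        c(rg, if (is.null(par)) NA_real_ else formation_loglik(par, z))
      }
    }, numeric(2L)))
    attr(est, "profile") <- data.frame(X = X_grid, r_cap = prof[, 1L],
                                       loglik = prof[, 2L])
  }
  est
}
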