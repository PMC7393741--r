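#' Plan a sample-multiplexing experiment
#'
#' Closed-form outcome prediction for a planned experiment: given the
#' droplet count `X` of the library-preparation equipment, the planned
#' cell load `Y`, the number of barcoded samples `M` (cells assumed
#' evenly split, `y_l = Y / M`), and the droplet capture rate, returns
#' the expected singlet/MSM/SSM/RSSM rates and the expected numbers of
#' cell-enclosing GEMs and of SSDs remaining after MSM removal. Inputs
#' outside the ranges typical of droplet platforms (`X` 60K-100K, `Y`
#' 1K-80K, `M` 1-20) trigger a warning, not an error.
#'
#' @param X number of cell-assay droplets.
#' @param Y planned number of cells.
#' @param M planned number of samples.
#' @param r_cap droplet capture rate in `[0, 1]`.
#' @return an `"experiment_plan"` object: the [formation_rates()] report
#'   augmented with the planner configuration.
#' @examples
#' plan_experiment(X = 68480, Y = 35685, M = 4, r_cap = 0.56)
#' @export
plan_experiment <- function(X, Y, M, r_cap = 1) {
  if (Y <= 0) stop("Y must be positive")
  if (M < 1 || M != round(M)) stop("M must be a positive integer")
  if (X < 6e4 || X > 1e5) {
    warning("X = ", X, " is outside the usual 60K-100K equipment range")
  }
  if (Y < 1e3 || Y > 8e4) {
    warning("Y = ", Y, " is outside the usual 1K-80K planning range")
  }
  if (M > 20) warning("M = ", M, " is outside the usual 1-20 range")
  params <- formation_params(X = X, r_cap = r_cap,
                             y = rep(Y / M, M), Y = Y)
  rates <- formation_rates(params)
  rates$config <- list(X = X, Y = Y, M = M, r_cap = r_cap)
  class(rates) <- c("experiment_plan", class(rates))
  rates
}

#' @export
print.experiment_plan <- function(x, digits = 2, ...) {
  cfg <- x$config
  cat("Planned experiment: X =", format(cfg$X, big.mark = ","),
      " Y =", format(cfg$Y, big.mark = ","),
      " M =", cfg$M, " r_cap =", cfg$r_cap, "\n")
  NextMethod()
}

#' Sweep the experiment planner over parameter grids
#'
#' Evaluates [plan_experiment()] on the Cartesian grid of the supplied
#' parameter vectors, mirroring the slider exploration of an interactive
#' planner.
#'
#' @param X,Y,M,r_cap numeric vectors of values to combine.
#' @return data.frame with one row per grid point: the four inputs plus
#'   `p_singlet`, `p_msm`, `p_ssm`, `rssm`, `n_gem`, `n_ssd`.
#' @export
sweep_plan <- function(X, Y, M, r_cap = 1) {
  grid <- expand.grid(X = X, Y = Y, M = M, r_cap = r_cap,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty planner grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- suppressWarnings(plan_experiment(grid$X[i], grid$Y[i],
                                          grid$M[i], grid$r_cap[i]))
    data.frame(p_singlet = p$p_singlet, p_msm = p$p_msm,
               p_ssm = p$p_ssm, rssm = p$rssm,
               n_gem = p$n_gem, n_ssd = p$n_ssd)
  })
  cbind(grid, do.call(rbind, res))
}
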