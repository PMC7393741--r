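#' Droplet-formation model parameters
#'
#' The generative model of GEM formation: the pooled cell assay is split
#' into `X` cell-assay droplets; each of the `Y = sum(y)` loaded cells
#' falls independently and uniformly into one droplet (probability `1/X`
#' per droplet); each droplet is captured as a sequenced GEM with
#' probability `r_cap`. `y[l]` is the number of cells loaded from sample
#' `l`. `X` and `y` may be real-valued — the closed-form rates extend
#' continuously, and maximum-likelihood estimates are rarely integral.
#'
#' @param X positive number of cell-assay droplets.
#' @param r_cap droplet capture rate in `[0, 1]`.
#' @param y positive vector of per-sample cell counts.
#' @param Y total cell count; defaults to `sum(y)` and must match it.
#' @return an object of class `"formation_params"`.
#' @export
formation_params <- function(X, r_cap = 1, y, Y = sum(y)) {
  if (!is.numeric(X) || length(X) != 1L || X <= 0) stop("X must be > 0")
  if (r_cap < 0 || r_cap > 1) stop("r_cap must lie in [0, 1]")
  if (any(y <= 0)) stop("per-sample cell counts y must be > 0")
  if (abs(sum(y) - Y) > 1e-6 * max(1, Y)) stop("sum(y) must equal Y")
  nm <- names(y) %||% paste0("HTO", seq_along(y))
  y <- as.numeric(y)
  names(y) <- nm
  structure(list(X = as.numeric(X), r_cap = as.numeric(r_cap),
                 y = y, Y = sum(y)),
            class = "formation_params")
}

#' @export
print.formation_params <- function(x, ...) {
  cat("Droplet-formation parameters\n")
  cat("  X (cell-assay droplets):", format(x$X, big.mark = ","), "\n")
  cat("  r_cap (capture rate):   ", round(x$r_cap, 4), "\n")
  cat("  Y (total cells):        ", format(x$Y, big.mark = ","), "\n")
  cat("  per-sample cells y:\n")
  print(round(x$y, 1))
  invisible(x)
}

#' Singlet rate of the droplet-formation model
#'
#' Probability that a non-empty cell-assay droplet contains exactly one
#' cell: `Y (1 - 1/X)^(Y-1) / (X (1 - (1 - 1/X)^Y))`. Depends only on `X`
#' and `Y` — not on how cells are split across samples.
#'
#' @param X positive number of cell-assay droplets.
#' @param Y total number of loaded cells (>= 1).
#' @return probability in `[0, 1]`.
#' @export
singlet_rate <- function(X, Y) {
  if (any(X <= 0)) stop("X must be > 0")
  if (any(Y < 1)) stop("Y must be >= 1")
  Y * pow_miss(X, Y - 1) / (X * (1 - pow_miss(X, Y)))
}

#' Analytic multiplet rates of the droplet-formation model
#'
#' Closed-form rates, all conditional on a droplet being non-empty (empty
#' droplets are never sequenced): the singlet rate; the probability of
#' being an SSD of each sample,
#' `P(SSD_l) = (1 - (1-1/X)^y_l) (1-1/X)^(Y - y_l)` (unconditional, then
#' normalized by `P(non-empty)`); the MSM rate
#' `1 - sum_l P(SSD_l) / P(non-empty)`; the SSM rate as the complement of
#' singlet and MSM, with the equivalent per-sample decomposition
#' (`P(SSM_l) = P(SSD_l) (1 - E[#singlets_l] / E[#SSD_l])`) also
#' reported; and the relative SSM rate `RSSM = SSM / (singlet + SSM)`,
#' the irreducible multiplet noise left after MSM removal. Expected GEM
#' counts use the capture rate: `n_gem = r_cap X P(non-empty)` and
#' `n_ssd = n_gem (1 - P(MSM))`.
#'
#' @param params a [formation_params()] object.
#' @return an object of class `"rate_report"`: list with elements
#'   `p_singlet`, `p_msm`, `p_ssm`, `p_ssd`, `rssm`, per-sample vectors
#'   `p_ssd_sample`, `p_ssm_sample`, `p_singlet_sample`, `rssm_sample`
#'   (all conditional on non-empty except `rssm_sample`, a ratio),
#'   expected counts `n_gem`, `n_ssd`, and the input `params`.
#' @export
formation_rates <- function(params) {
  stopifnot(inherits(params, "formation_params"))
  X <- params$X
  y <- params$y
  Y <- params$Y
  p_ne <- 1 - pow_miss(X, Y)

  p_singlet <- singlet_rate(X, Y)
  p_ssd_u <- (1 - pow_miss(X, y)) * pow_miss(X, Y - y) # unconditional
  p_ssd_sample <- p_ssd_u / p_ne
  p_msm <- 1 - sum(p_ssd_u) / p_ne
  p_ssm <- 1 - p_singlet - p_msm

  # per-sample route: singlets of l among SSDs of l
  e_singlet_l <- y * pow_miss(X, Y - 1) / X    # E[#singlets_l] / X
  p_singlet_sample <- e_singlet_l / p_ne
  p_ssm_sample <- p_ssd_sample - p_singlet_sample
  rssm_sample <- ifelse(p_ssd_sample > 0, p_ssm_sample / p_ssd_sample, 0)

  p_ssd <- p_singlet + p_ssm
  rssm <- if (p_ssd > 0) p_ssm / p_ssd else 0
  n_gem <- params$r_cap * X * p_ne

  structure(list(
    p_singlet = p_singlet,
    p_msm = p_msm,
    p_ssm = p_ssm,
    p_ssd = p_ssd,
    rssm = rssm,
    p_ssd_sample = p_ssd_sample,
    p_ssm_sample = p_ssm_sample,
    p_singlet_sample = p_singlet_sample,
    rssm_sample = rssm_sample,
    n_gem = n_gem,
    n_ssd = n_gem * (1 - p_msm),
    params = params
  ), class = "rate_report")
}

#' @export
print.rate_report <- function(x, digits = 2, ...) {
  pct <- function(p) paste0(format(round(100 * p, digits)), "%")
  cat("Droplet-formation rates (conditional on non-empty)\n")
  cat("  singlet:", pct(x$p_singlet), "  MSM:", pct(x$p_msm),
      "  SSM:", pct(x$p_ssm), "  RSSM:", pct(x$rssm), "\n")
  cat("  expected cell-enclosing GEMs:", format(round(x$n_gem)),
      "  expected SSDs after MSM removal:", format(round(x$n_ssd)), "\n")
  invisible(x)
}

#' Expected GEM counts per sample combination (model Venn diagram)
#'
#' For every subset `U` of samples, the expected number of captured GEMs
#' containing cells from exactly the samples in `U`:
#' `r_cap * X * prod(1 - (1-1/X)^y[U]) * (1-1/X)^sum(y[-U])`.
#' Singleton subsets are the expected SSD counts; subsets of two or more
#' samples form the model-derived MSM Venn diagram that can be compared
#' against classifier-observed combination counts.
#'
#' @param params a [formation_params()] object.
#' @param min_size smallest subset size to report (2 = MSM combinations
#'   only; 1 adds the SSD expectations).
#' @return named numeric vector of expected counts, names as in
#'   [classify_gems()] labels.
#' @export
expected_msm_venn <- function(params, min_size = 2L) {
  stopifnot(inherits(params, "formation_params"))
  M <- length(params$y)
  if (M > 16L) stop("subset enumeration limited to 16 samples")
  X <- params$X
  y <- params$y
  p_in <- 1 - pow_miss(X, y)   # P(droplet contains >= 1 cell of l)
  p_out <- pow_miss(X, y)
  labels <- character(0)
  vals <- numeric(0)
  for (code in seq_len(2^M - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(M) - 1L)) > 0L)
    if (length(idx) < min_size) next
    vals <- c(vals, params$r_cap * X * prod(p_in[idx]) * prod(p_out[-idx]))
    labels <- c(labels, subset_label(idx, names(params$y)))
  }
  stats::setNames(vals, labels)
}

#' Simulate the droplet-formation process
#'
#' Monte-Carlo counterpart (and correctness oracle) of the closed-form
#' rates: in each of `reps` independent formations, every cell is placed
#' uniformly at random into one of `X` droplets, each non-empty droplet
#' is captured with probability `r_cap`, and captured droplets are
#' tallied as singlets, same-sample multiplets, or multi-sample
#' multiplets. `X` and `y` are rounded to integers for simulation.
#'
#' @param params a [formation_params()] object.
#' @param reps number of independent formation experiments.
#' @param seed optional RNG seed (the caller's RNG state is preserved).
#' @param keep_droplets if `TRUE` and `reps == 1`, also return the
#'   per-droplet composition table (size, sample membership, type).
#' @return list with empirical `rates` (`p_singlet`, `p_msm`, `p_ssm`),
#'   captured-GEM tallies (`n_gem`, `n_singlet`, `n_msm`, `n_ssm`), the
#'   per-sample cell-enclosing GEM counts `z`, the MSM combination counts
#'   `venn` (for `M <= 16`), and optionally `droplets`.
#' @export
simulate_formation <- function(params, reps = 1L, seed = NULL,
                               keep_droplets = FALSE) {
  stopifnot(inherits(params, "formation_params"))
  X <- as.integer(round(params$X))
  y <- as.integer(round(params$y))
  if (X < 1L || any(y < 1L)) stop("simulation needs integral X >= 1, y >= 1")
  M <- length(y)
  Y <- sum(y)
  sample_names <- names(params$y)
  do_venn <- M <= 16L

  tall <- list(n_gem = 0, n_singlet = 0, n_msm = 0, n_ssm = 0,
               z = numeric(M),
               venn = if (do_venn) numeric(2^M - 1) else NULL)
  if (keep_droplets && reps != 1L) {
    stop("keep_droplets requires reps = 1")
  }
  droplets <- NULL

  with_seed(seed, {
    chunk <- max(1L, min(reps, as.integer(2e6 / Y)))
    done <- 0L
    base_lab <- rep.int(seq_len(M), y)
    while (done < reps) {
      nc <- min(chunk, reps - done)
      done <- done + nc
      drop_id <- sample.int(X, nc * Y, replace = TRUE)
      rep_id <- rep(seq_len(nc), each = Y)
      lab <- rep.int(base_lab, nc)
      key <- (rep_id - 1) * as.double(X) + drop_id
      o <- order(key, lab)
      k <- key[o]
      s <- lab[o]
      runs <- rle(k)
      size <- runs$lengths
      ndrop <- length(size)
      last <- cumsum(size)
      first <- last - size + 1L
      captured <- stats::runif(ndrop) < params$r_cap

      one_sample <- s[first] == s[last]
      is_singlet <- size == 1L
      is_msm <- !one_sample
      is_ssm <- one_sample & !is_singlet

      tall$n_gem <- tall$n_gem + sum(captured)
      tall$n_singlet <- tall$n_singlet + sum(captured & is_singlet)
      tall$n_msm <- tall$n_msm + sum(captured & is_msm)
      tall$n_ssm <- tall$n_ssm + sum(captured & is_ssm)

      di <- rep.int(seq_len(ndrop), size)
      n_cell <- length(s)
      first_pair <- c(TRUE, k[-1L] != k[-n_cell] | s[-1L] != s[-n_cell])
      cap_cell <- captured[di]
      tall$z <- tall$z +
        tabulate(s[first_pair & cap_cell], nbins = M)

      if (do_venn) {
        sel <- first_pair & cap_cell
        if (any(sel)) {
          mask <- rowsum(2^(s[sel] - 1), di[sel])
          msm_mask <- mask[captured[as.integer(rownames(mask))] &
                             is_msm[as.integer(rownames(mask))]]
          if (length(msm_mask)) {
            tall$venn <- tall$venn +
              tabulate(as.integer(msm_mask), nbins = 2^M - 1)
          }
        }
      }
      if (keep_droplets) {
        droplets <- data.frame(
          size = size, captured = captured,
          type = ifelse(is_singlet, "singlet",
                        ifelse(is_msm, "MSM", "SSM"))
        )
      }
    }
  })

  venn <- NULL
  if (do_venn) {
    codes <- which(tall$venn > 0)
    venn <- stats::setNames(tall$venn[codes], vapply(codes, function(code) {
      subset_label(which(bitwAnd(code, 2^(seq_len(M) - 1L)) > 0L),
                   sample_names)
    }, character(1L)))
  }
  n <- tall$n_gem
  rates <- if (n > 0) {
    list(p_singlet = tall$n_singlet / n, p_msm = tall$n_msm / n,
         p_ssm = tall$n_ssm / n)
  } else {
    list(p_singlet = NA_real_, p_msm = NA_real_, p_ssm = NA_real_)
  }
  out <- list(rates = rates, n_gem = n, n_singlet = tall$n_singlet,
              n_msm = tall$n_msm, n_ssm = tall$n_ssm,
              z = stats::setNames(tall$z, sample_names), venn = venn,
              reps = reps)
  if (keep_droplets) out$droplets <- droplets
  out
}
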