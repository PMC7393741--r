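#' Default per-sample HTO intensity profile
#'
#' On-target and off-target (background) raw-count means and standard
#' deviations for single-sample droplets, modelled on a four-sample
#' cell-hashing experiment: each sample has a large on-target mean on its
#' own tag and small background means on the others, with one
#' deliberately brighter sample reflecting the staining inconsistencies
#' seen in real runs. For `M <= 4` the leading `M` samples/tags are
#' used; for `M > 4` additional samples get a mid-range profile
#' (on-target mean 800, sd 650; background mean 40, sd 20).
#'
#' @param M number of samples.
#' @return list with `mean` and `sd`, each an `M x M` matrix
#'   (rows = source sample, columns = HTO tag).
#' @export
default_hto_profile <- function(M = 4L) {
  base_mean <- matrix(c(
    2789.10,  20.94,   38.99,  17.34,
      76.91, 831.75,   36.06,  15.86,
      77.66,  19.92, 1117.05,  16.12,
      75.56,  19.33,   36.25, 717.48
  ), nrow = 4L, byrow = TRUE)
  base_sd <- matrix(c(
    1637.15, 11.85,  18.33,   9.94,
      43.92, 680.13, 17.56,  10.09,
      43.16,  12.04, 783.55, 10.23,
      43.34,  11.66,  18.22, 457.40
  ), nrow = 4L, byrow = TRUE)
  mean_m <- matrix(40, M, M)
  sd_m <- matrix(20, M, M)
  diag(mean_m) <- 800
  diag(sd_m) <- 650
  k <- min(M, 4L)
  mean_m[seq_len(k), seq_len(k)] <- base_mean[seq_len(k), seq_len(k)]
  sd_m[seq_len(k), seq_len(k)] <- base_sd[seq_len(k), seq_len(k)]
  dimnames(mean_m) <- dimnames(sd_m) <-
    list(paste0("sample", seq_len(M)), paste0("HTO", seq_len(M)))
  list(mean = mean_m, sd = sd_m)
}

#' Configuration for the synthetic sample-barcoding generator
#'
#' @param M number of barcoded samples.
#' @param n_droplets total number of simulated droplets (GEMs).
#' @param msm_fraction target fraction of droplets that are cross-sample
#'   multiplets (ground-truth MSMs), in `[0, 1)`.
#' @param ssm_fraction fraction of droplets that are same-sample doublets
#'   (ground-truth SSMs); default 0.
#' @param ratios relative sample population sizes (e.g. `c(9, 3, 1)`).
#' @param profile on/off-target intensity profile as returned by
#'   [default_hto_profile()].
#' @param weight_mean,weight_sd merge-weight distribution for multi-SSD
#'   droplets: each member's counts are scaled by an independent
#'   `N(weight_mean, weight_sd^2)` draw before summation (defaults 1 and
#'   0.2, i.e. variance 0.04).
#' @param seed RNG seed for [sim_hashing()].
#' @return a `"sim_config"` list.
#' @export
sim_config <- function(M = 4L, n_droplets = 20000L, msm_fraction = 0.10,
                       ssm_fraction = 0, ratios = rep(1, M),
                       profile = default_hto_profile(M),
                       weight_mean = 1, weight_sd = 0.2, seed = NULL) {
  if (M < 1L) stop("M must be >= 1")
  if (msm_fraction < 0 || msm_fraction >= 1) {
    stop("msm_fraction must lie in [0, 1)")
  }
  if (msm_fraction > 0 && M < 2L) {
    stop("cross-sample multiplets need M >= 2")
  }
  if (ssm_fraction < 0 || msm_fraction + ssm_fraction >= 1) {
    stop("msm_fraction + ssm_fraction must be < 1")
  }
  if (length(ratios) != M || any(ratios <= 0)) {
    stop("ratios must be ", M, " positive values")
  }
  if (!identical(dim(profile$mean), c(as.integer(M), as.integer(M))) ||
      !identical(dim(profile$sd), dim(profile$mean))) {
    stop("profile mean/sd must be M x M matrices")
  }
  if (any(profile$mean <= 0) || any(profile$sd < 0)) {
    stop("profile means must be positive and sds non-negative")
  }
  structure(list(M = as.integer(M), n_droplets = as.integer(n_droplets),
                 msm_fraction = msm_fraction, ssm_fraction = ssm_fraction,
                 ratios = ratios / sum(ratios), profile = profile,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 seed = seed),
            class = "sim_config")
}

# lognormal draws moment-matched to (mean, sd), rounded to UMI counts;
# sd = 0 degenerates to the rounded mean
rlnorm_counts <- function(n, mean, sd) {
  if (sd == 0) return(rep(round(mean), n))
  s2 <- log1p((sd / mean)^2)
  mu <- log(mean) - s2 / 2
  pmax(0, round(stats::rlnorm(n, mu, sqrt(s2))))
}

#' Simulate single-sample-droplet HTO profiles
#'
#' Draws raw HTO count vectors for SSDs of each sample: the own-tag count
#' from the sample's on-target distribution and every other tag from the
#' corresponding background distribution, each a moment-matched
#' lognormal rounded to integer UMIs (positive, right-skewed, as raw UMI
#' counts are).
#'
#' @param n_per_sample integer vector of SSD counts per sample.
#' @param profile intensity profile (see [default_hto_profile()]).
#' @param seed optional RNG seed.
#' @return list with `counts` (matrix, rows = SSDs) and `sample` (integer
#'   source-sample label per row).
#' @export
sim_hto_profiles <- function(n_per_sample,
                             profile = default_hto_profile(length(n_per_sample)),
                             seed = NULL) {
  M <- length(n_per_sample)
  with_seed(seed, {
    counts <- matrix(0L, sum(n_per_sample), M,
                     dimnames = list(NULL, colnames(profile$mean)))
    labels <- rep.int(seq_len(M), n_per_sample)
    for (s in seq_len(M)) {
      rows <- which(labels == s)
      if (!length(rows)) next
      for (tag in seq_len(M)) {
        counts[rows, tag] <- rlnorm_counts(length(rows),
                                           profile$mean[s, tag],
                                           profile$sd[s, tag])
      }
    }
    list(counts = counts, sample = labels)
  })
}

#' Generate a synthetic sample-barcoding dataset with ground truth
#'
#' Builds a droplet-level HTO matrix following the simulation protocol
#' used to benchmark hashing classifiers: SSD profiles are drawn per
#' sample ([sim_hto_profiles()]), a fixed fraction of droplets are
#' cross-sample doublets (two SSDs from distinct samples chosen with
#' probability proportional to the sample ratios), optionally a fraction
#' are same-sample doublets, and the remaining droplets carry a single
#' SSD. Multi-SSD droplet counts are the weight-perturbed sums of their
#' members' counts (`sum_i w_i x_i`, `w_i ~ N(weight_mean,
#' weight_sd^2)`, rounded and floored at 0); single-SSD droplets inherit
#' their SSD's counts unchanged.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (HTO matrix with `GEM<n>` barcodes),
#'   `truth` (data.frame: `barcode`, `members` — `"+"`-joined source
#'   samples, `n_cells`, `is_msm`, `is_ssm`, `is_singlet`), and `config`.
#' @export
sim_hashing <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$M
  n <- config$n_droplets
  n_msm <- round(config$msm_fraction * n)
  n_ssm <- round(config$ssm_fraction * n)
  n_single <- n - n_msm - n_ssm
  if (n_single < 0) stop("msm/ssm fractions exceed the droplet budget")

  with_seed(config$seed, {
    # sample of origin for every SSD needed: singles, SSM pairs, MSM pairs
    single_lab <- sample.int(M, n_single, replace = TRUE,
                             prob = config$ratios)
    ssm_lab <- sample.int(M, n_ssm, replace = TRUE, prob = config$ratios)
    msm_pairs <- if (n_msm > 0) {
      t(replicate(n_msm, sample.int(M, 2L, prob = config$ratios)))
    } else {
      matrix(integer(0), 0L, 2L)
    }

    need <- tabulate(c(single_lab, ssm_lab, ssm_lab,
                       msm_pairs[, 1L], msm_pairs[, 2L]), nbins = M)
    pool <- sim_hto_profiles(need, config$profile)
    # per-sample queues of SSD rows
    queues <- split(seq_len(nrow(pool$counts)), pool$sample)
    ptr <- integer(M)
    take <- function(s) {
      ptr[s] <<- ptr[s] + 1L
      queues[[s]][ptr[s]]
    }

    counts <- matrix(0L, n, M, dimnames = list(paste0("GEM", seq_len(n)),
                                               colnames(pool$counts)))
    members <- character(n)
    n_cells <- integer(n)
    w <- function(k) stats::rnorm(k, config$weight_mean, config$weight_sd)

    i <- 0L
    for (j in seq_len(n_single)) {
      i <- i + 1L
      s <- single_lab[j]
      counts[i, ] <- pool$counts[take(s), ]
      members[i] <- as.character(s)
      n_cells[i] <- 1L
    }
    for (j in seq_len(n_ssm)) {
      i <- i + 1L
      s <- ssm_lab[j]
      ww <- w(2L)
      counts[i, ] <- pmax(0L, as.integer(round(
        ww[1L] * pool$counts[take(s), ] + ww[2L] * pool$counts[take(s), ])))
      members[i] <- paste(s, s, sep = "+")
      n_cells[i] <- 2L
    }
    for (j in seq_len(n_msm)) {
      i <- i + 1L
      pair <- msm_pairs[j, ]
      ww <- w(2L)
      counts[i, ] <- pmax(0L, as.integer(round(
        ww[1L] * pool$counts[take(pair[1L]), ] +
          ww[2L] * pool$counts[take(pair[2L]), ])))
      members[i] <- paste(sort(pair), collapse = "+")
      n_cells[i] <- 2L
    }

    # shuffle droplet order so truth labels are not positional
    perm <- sample.int(n)
    counts <- counts[perm, , drop = FALSE]
    members <- members[perm]
    n_cells <- n_cells[perm]
    rownames(counts) <- paste0("GEM", seq_len(n))

    span <- vapply(strsplit(members, "+", fixed = TRUE),
                   function(m) length(unique(m)), integer(1L))
    truth <- data.frame(
      barcode = rownames(counts),
      members = members,
      n_cells = n_cells,
      is_msm = span >= 2L,
      is_ssm = span == 1L & n_cells >= 2L,
      is_singlet = n_cells == 1L,
      stringsAsFactors = FALSE
    )
    list(counts = as_hto_matrix(counts), truth = truth, config = config)
  })
}
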