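#' Classify GEMs from per-sample posterior probabilities
#'
#' Given the matrix of posterior probabilities `P(high | x)` for every GEM
#' and sample, each GEM is assigned the sample subset `U` maximizing
#' `P(U) = prod(p[l in U]) * prod(1 - p[l not in U])` over all `2^M`
#' subsets. The empty subset is the NEGATIVE class, singletons are
#' single-sample droplets (SSDs), and subsets of two or more samples are
#' multi-sample multiplets (MSMs) — at most `2^M + 1` labels including
#' UNCLEAR. Because the subset probabilities factorize over samples, the
#' maximizing subset is exactly `{l : p_l > 0.5}` and its probability is
#' `prod(pmax(p, 1 - p))`; ties at 0.5 resolve to the smaller subset. The
#' maximum probability is the classification confidence; GEMs whose
#' confidence falls below the cutoff are relabelled UNCLEAR.
#'
#' @param posteriors numeric matrix (GEMs x samples) of probabilities,
#'   with barcode rownames and sample colnames.
#' @param confidence confidence cutoff `c` in `[0, 1]`; default 0.8.
#' @param sample_names optional sample names overriding the colnames.
#' @return data.frame with columns `barcode`, `class`, `confidence`, one
#'   row per GEM. MSM classes are labelled `"s1+s2"` in canonical sample
#'   order; the logical membership matrix is kept in attribute
#'   `"membership"` and the sample names in `"sample_names"`.
#' @export
classify_gems <- function(posteriors, confidence = 0.8,
                          sample_names = colnames(posteriors)) {
  posteriors <- as.matrix(posteriors)
  if (any(posteriors < 0 | posteriors > 1, na.rm = TRUE) ||
      anyNA(posteriors)) {
    stop("posteriors must lie in [0, 1]")
  }
  if (length(confidence) != 1L || confidence < 0 || confidence > 1) {
    stop("confidence cutoff must be a single value in [0, 1]")
  }
  M <- ncol(posteriors)
  if (is.null(sample_names)) sample_names <- paste0("HTO", seq_len(M))
  barcodes <- rownames(posteriors) %||% paste0("GEM", seq_len(nrow(posteriors)))

  member <- posteriors > 0.5 # argmax subset; tie at 0.5 -> exclude
  conf <- apply(pmax(posteriors, 1 - posteriors), 1L, prod)
  k <- rowSums(member)
  label <- character(nrow(posteriors))
  label[k == 0L] <- "NEGATIVE"
  multi <- which(k > 0L)
  if (length(multi)) {
    label[multi] <- vapply(multi, function(i) {
      subset_label(which(member[i, ]), sample_names)
    }, character(1L))
  }
  unclear <- conf < confidence
  label[unclear] <- "UNCLEAR"
  member[unclear, ] <- FALSE

  out <- data.frame(barcode = barcodes, class = label, confidence = conf,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "membership") <- member
  attr(out, "sample_names") <- sample_names
  out
}

#' Tally a classification table into observed counts
#'
#' Computes the observables of the droplet-formation model from a
#' classification: `z[l]`, the number of confidently classified GEMs whose
#' class subset contains sample `l` (SSDs of `l` plus every MSM involving
#' `l`); the per-combination MSM counts (the observed Venn diagram); and
#' the NEGATIVE/UNCLEAR tallies.
#'
#' @param classification data.frame from [classify_gems()].
#' @return an object of class `"observed_counts"`: list with `z` (named
#'   integer vector), `ssd` (per-sample SSD counts), `venn` (named integer
#'   vector over subsets of size >= 2), `n_msm`, `n_negative`,
#'   `n_unclear`, `n_total`, and `sample_names`.
#' @export
count_observed <- function(classification) {
  member <- attr(classification, "membership")
  sample_names <- attr(classification, "sample_names")
  if (is.null(member) || is.null(sample_names)) {
    stop("classification must come from classify_gems()")
  }
  k <- rowSums(member)
  z <- colSums(member)
  names(z) <- sample_names
  ssd <- colSums(member[k == 1L, , drop = FALSE])
  names(ssd) <- sample_names

  msm_rows <- which(k >= 2L)
  venn <- integer(0)
  if (length(msm_rows)) {
    labels <- classification$class[msm_rows]
    venn_tab <- table(labels)
    venn <- as.integer(venn_tab)
    names(venn) <- names(venn_tab)
  }
  structure(list(
    z = z,
    ssd = ssd,
    venn = venn,
    n_msm = length(msm_rows),
    n_negative = sum(classification$class == "NEGATIVE"),
    n_unclear = sum(classification$class == "UNCLEAR"),
    n_total = nrow(classification),
    sample_names = sample_names
  ), class = "observed_counts")
}

#' @export
print.observed_counts <- function(x, ...) {
  cat("Observed GEM counts (", x$n_total, " GEMs, ",
      length(x$sample_names), " samples)\n", sep = "")
  cat("cell-enclosing GEMs per sample (z):\n")
  print(x$z)
  cat("SSDs per sample:\n")
  print(x$ssd)
  cat("MSMs:", x$n_msm, " negative:", x$n_negative,
      " unclear:", x$n_unclear, "\n")
  if (length(x$venn)) {
    cat("MSM combinations:\n")
    print(x$venn)
  }
  invisible(x)
}
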