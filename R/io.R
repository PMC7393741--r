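#' Read an HTO matrix from a CellRanger-style MatrixMarket triplet
#'
#' Reads a `.mtx` count matrix with its barcode and feature sidecar files
#' (plain or gzip). CellRanger stores features in rows and GEM barcodes in
#' columns; the orientation is detected from the sidecar lengths and the
#' returned matrix always has GEMs in rows. When the matrix mixes
#' modalities (gene expression plus antibody capture), pass `features` to
#' select the HTO rows by name.
#'
#' @param matrix_path path to the MatrixMarket `.mtx` file.
#' @param barcodes_path path to the barcode sidecar (one barcode per line).
#' @param features_path path to the feature sidecar; for multi-column
#'   (CellRanger v3) files the second column is used as the feature name.
#' @param features optional character vector of HTO feature names to keep.
#' @return validated HTO count matrix (see [as_hto_matrix()]).
#' @export
read_hto_mtx <- function(matrix_path, barcodes_path, features_path,
                         features = NULL) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- read_sidecar(barcodes_path, column = 1L)
  feat_tab <- read_sidecar(features_path, column = NA)
  feat <- if (is.matrix(feat_tab) && ncol(feat_tab) >= 2L) {
    feat_tab[, 2L]
  } else {
    as.character(feat_tab)
  }
  if (nrow(m) == length(feat) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m) # CellRanger orientation: features x barcodes
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(feat))) {
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecars (", length(barcodes), " barcodes, ",
         length(feat), " features)")
  }
  counts <- as.matrix(m)
  dimnames(counts) <- list(barcodes, feat)
  if (!is.null(features)) {
    missing <- setdiff(features, feat)
    if (length(missing)) {
      stop("features not present in matrix: ", paste(missing, collapse = ", "))
    }
    counts <- counts[, features, drop = FALSE]
  }
  as_hto_matrix(counts)
}

# one- or multi-column sidecar, transparently gunzipped by file()
read_sidecar <- function(path, column = 1L) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty sidecar file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- max(lengths(parts))
  if (width == 1L) {
    out <- vapply(parts, `[`, character(1L), 1L)
    return(if (is.na(column)) out else out)
  }
  tab <- t(vapply(parts, function(p) {
    length(p) <- width
    p
  }, character(width)))
  if (is.na(column)) tab else tab[, column]
}

#' Read an HTO matrix from CSV
#'
#' Expects the layout of a plain HTO table: a header row of sample names,
#' the first column holding GEM barcodes, and integer UMI counts in the
#' body.
#'
#' @param path path to the CSV file.
#' @return validated HTO count matrix.
#' @export
read_hto_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("CSV must have a barcode column and >= 1 sample")
  barcodes <- as.character(tab[[1L]])
  if (anyDuplicated(barcodes)) stop("duplicate GEM barcodes in ", path)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric HTO counts in ", path)
  rownames(counts) <- barcodes
  as_hto_matrix(counts)
}

#' Write an HTO matrix to CSV (inverse of [read_hto_csv()])
#' @param counts HTO count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hto_csv <- function(counts, path) {
  counts <- as_hto_matrix(counts)
  tab <- data.frame(barcode = rownames(counts), counts,
                    check.names = FALSE, row.names = NULL)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an HTO matrix as a MatrixMarket triplet in CellRanger orientation
#'
#' Emits `matrix.mtx`, `barcodes.tsv` and `features.tsv` (features in
#' rows, as CellRanger does), so the files round-trip through
#' [read_hto_mtx()].
#'
#' @param counts HTO count matrix.
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
write_hto_mtx <- function(counts, dir) {
  counts <- as_hto_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             barcodes = file.path(dir, "barcodes.tsv"),
             features = file.path(dir, "features.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(t(counts), sparse = TRUE),
                              "generalMatrix"),
                  paths[["matrix"]])
  writeLines(rownames(counts), paths[["barcodes"]])
  writeLines(colnames(counts), paths[["features"]])
  invisible(paths)
}

#' Write classification and rate-summary output files
#'
#' Produces the three plain-text outputs of a demultiplexing run:
#' `classification.csv` (barcode, class, confidence), `sample_rates.csv`
#' (per-sample cell-enclosing GEM counts and estimated SSM/RSSM rates, in
#' percent), and `summary.csv` (key/value pairs: dataset-level rates, the
#' estimated droplet count X and capture rate).
#'
#' @param fit a fitted [demux()] object.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_demux_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "demux_fit"))
  if (!nrow(fit$classification)) stop("empty classification table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(classification = file.path(dir, "classification.csv"),
             sample_rates = file.path(dir, "sample_rates.csv"),
             summary = file.path(dir, "summary.csv"))
  utils::write.csv(fit$classification, paths[["classification"]],
                   row.names = FALSE, quote = FALSE)

  rates <- fit$rates
  sample_tab <- data.frame(
    sample = names(fit$observed$z),
    gems = as.integer(fit$observed$z),
    ssm_pct = 100 * rates$p_ssm_sample,
    rssm_pct = 100 * rates$rssm_sample,
    row.names = NULL
  )
  utils::write.csv(sample_tab, paths[["sample_rates"]],
                   row.names = FALSE, quote = FALSE)

  obs <- fit$observed
  summary_tab <- data.frame(
    key = c("n_gems_input", "n_negative", "n_unclear", "X", "r_cap",
            "Y", "singlet_pct", "est_msm_pct", "obs_msm_pct", "ssm_pct",
            "rssm_pct"),
    value = c(obs$n_total, obs$n_negative, obs$n_unclear,
              fit$params$X, fit$params$r_cap, fit$params$Y,
              100 * rates$p_singlet, 100 * rates$p_msm,
              100 * fit$obs_msm_rate, 100 * rates$p_ssm,
              100 * rates$rssm)
  )
  utils::write.csv(summary_tab, paths[["summary"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
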