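#' Validate an HTO count matrix
#'
#' An HTO matrix stores the hashtag-oligonucleotide UMI counts of
#' post-filtering, non-empty droplets: one row per GEM (indexed by its GEM
#' barcode) and one column per barcoded sample. Counts must be
#' non-negative integers, barcodes unique, and sample names free of the
#' `"+"` separator used in multiplet class labels.
#'
#' @param counts numeric matrix (or object coercible to one) of UMI
#'   counts, GEMs in rows.
#' @param barcodes character vector of GEM barcodes; defaults to
#'   `rownames(counts)`.
#' @param samples character vector of sample (HTO tag) names; defaults to
#'   `colnames(counts)`.
#' @return an integer matrix with barcode rownames and sample colnames.
#' @examples
#' m <- as_hto_matrix(matrix(c(50, 2, 3, 61), 2, 2,
#'   dimnames = list(c("AAAC", "TTTG"), c("HTO1", "HTO2"))))
#' @export
as_hto_matrix <- function(counts, barcodes = rownames(counts),
                          samples = colnames(counts)) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  M <- ncol(counts)
  if (n < 1L || M < 1L) {
    stop("HTO matrix must have at least one GEM and one sample")
  }
  if (is.null(barcodes)) barcodes <- paste0("GEM", seq_len(n))
  if (is.null(samples)) samples <- paste0("HTO", seq_len(M))
  if (length(barcodes) != n || length(samples) != M) {
    stop("barcode/sample name lengths do not match matrix dimensions")
  }
  if (anyDuplicated(barcodes)) stop("duplicate GEM barcodes")
  if (any(grepl("+", samples, fixed = TRUE))) {
    stop("sample names must not contain '+'")
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("HTO counts must be numeric and non-missing")
  }
  if (any(counts < 0)) stop("HTO counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("HTO counts must be integral UMI counts")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(as.character(barcodes), as.character(samples))
  counts
}
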