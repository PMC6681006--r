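# Count ingestion, upper-quartile CPM normalization and the expression filter.

#' Construct a count matrix with sample metadata
#'
#' The basic container for gene-level RNA-Seq counts from a two-line selection
#' design: an integer gene x sample matrix plus per-sample metadata giving the
#' selection line (HIGH or LOW) and brain-region (or other batch) label.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All entries must be non-negative
#'   integers.
#' @param meta data frame with columns `sample_id`, `line` and `region`.
#'   `line` is matched case-insensitively against HIGH/LOW.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `meta` (data frame, one row per sample, in column
#'   order of `counts`).
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    abort("duplicated gene id: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    abort("duplicated sample id: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  if (!is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts)))
    abort("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "region")
  if (!all(need %in% names(meta)))
    abort("metadata must have columns: %s", paste(need, collapse = ", "))
  missing_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_meta))
    abort("sample(s) missing from metadata: %s",
          paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), need, drop = FALSE]
  meta$line <- normalize_line(meta$line)
  rownames(meta) <- NULL

  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d HIGH, %d LOW)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$meta$line == "HIGH"), sum(x$meta$line == "LOW")))
  invisible(x)
}

#' Read a gene-level count table and sample metadata from TSV
#'
#' The count TSV has a header row of sample ids with the first column holding
#' gene ids; the metadata TSV has columns `sample_id`, `line`, `region`.
#' Lines starting with `#` are ignored in both files. Entries are validated to
#' be non-negative integers, and every sample column must appear in the
#' metadata (extra metadata rows are allowed and dropped).
#'
#' @param path path to the count TSV.
#' @param meta_path path to the metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path) {
  raw <- read_tsv(path)
  if (ncol(raw) < 2L) abort("count table needs a gene id column plus samples")
  gene_ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(raw[-1L], is.numeric, logical(1)))[1]
    abort("non-numeric counts in column '%s'", colnames(raw)[-1L][bad])
  }
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    abort("invalid count at gene '%s', sample '%s' (must be integer >= 0)",
          gene_ids[bad[1, 1]], colnames(mat)[bad[1, 2]])
  rownames(mat) <- gene_ids
  meta <- read_tsv(meta_path)
  count_matrix(mat, meta)
}

#' Write a count matrix (and its metadata) as TSV
#'
#' @param cm a [count_matrix()].
#' @param path output path for the count TSV.
#' @param meta_path output path for the metadata TSV (omit to skip).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, meta_path = NULL) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(meta_path)) write_tsv(cm$meta, meta_path)
  invisible(path)
}

#' Upper-quartile normalization to counts per million
#'
#' Each sample's scale factor is the 75th percentile (linear interpolation
#' between order statistics, R quantile type 7) of its counts over the genes
#' that are nonzero in at least one sample, divided by its library size.
#' Scale factors are centered so their geometric mean is 1; the effective
#' library size is library size x centered factor, and
#' CPM = count / effective library size x 1e6. Scaling a sample's counts by a
#' constant therefore leaves its CPM column unchanged.
#'
#' @param cm a [count_matrix()].
#' @param pseudocount added to CPM before taking log2 (default 1).
#' @return An object of class `normalized_expression`: list with `cpm`,
#'   `log2cpm` (matrices), `scale_factors` (named numeric, geometric mean 1),
#'   `lib_sizes`, and the sample `meta`.
#' @export
upper_quartile_normalize <- function(cm, pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  check_scalar(pseudocount, "pseudocount", lo = 0)
  counts <- cm$counts
  lib <- colSums(counts)
  if (any(lib == 0))
    abort("sample(s) with all-zero counts cannot be normalized: %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  expressed <- rowSums(counts) > 0
  uq <- apply(counts[expressed, , drop = FALSE], 2, stats::quantile,
              probs = 0.75, names = FALSE, type = 7)
  if (any(uq == 0))
    abort("sample(s) with zero upper quartile over expressed genes: %s",
          paste(colnames(counts)[uq == 0], collapse = ", "))
  f <- uq / lib
  f <- f / exp(mean(log(f)))      # geometric-mean centering
  eff_lib <- lib * f
  cpm <- sweep(counts, 2, eff_lib, "/") * 1e6
  structure(list(cpm = cpm,
                 log2cpm = log2(cpm + pseudocount),
                 scale_factors = f,
                 lib_sizes = lib,
                 meta = cm$meta),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("normalized_expression: %d genes x %d samples (upper-quartile CPM)\n",
              nrow(x$cpm), ncol(x$cpm)))
  invisible(x)
}

#' Filter genes by mean CPM
#'
#' Keeps genes whose mean CPM across all samples (both lines pooled) is
#' strictly greater than `threshold`; gene order is preserved. Applying the
#' filter twice at the same threshold equals applying it once.
#'
#' @param ne a `normalized_expression` object.
#' @param threshold minimum mean CPM, exclusive (default 1).
#' @return The filtered `normalized_expression`.
#' @export
filter_by_cpm <- function(ne, threshold = 1) {
  stopifnot(inherits(ne, "normalized_expression"))
  check_scalar(threshold, "threshold", lo = 0)
  keep <- rowMeans(ne$cpm) > threshold
  ne$cpm <- ne$cpm[keep, , drop = FALSE]
  ne$log2cpm <- ne$log2cpm[keep, , drop = FALSE]
  ne
}
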