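# Cosplicing networks: exon-usage profiles, per-gene sample distance matrices
# and Mantel correlations between genes, feeding the shared network engine.

#' Exon-usage proportions per gene
#'
#' Converts an exon-level count table into per-gene exon-usage profiles: for
#' each sample, the proportion of the gene's reads falling on each exon
#' (treating each exon equally, with no length weighting). Samples whose total
#' count for a gene is below `min_gene_count` are masked: they receive the
#' uniform placeholder vector and are excluded pairwise from all downstream
#' distance computations. Single-exon genes carry no usage signal and are
#' excluded with a message.
#'
#' @param ect data frame with columns `gene_id`, `exon_id`, then one integer
#'   count column per sample.
#' @param min_gene_count minimum per-sample gene total for a usable profile
#'   (default 10).
#' @return Object of class `exon_profiles`: named list (by gene) of lists with
#'   `proportions` (sample x exon matrix, rows summing to 1), `mask` (logical,
#'   TRUE = sample usable), `exon_ids`; plus attributes `samples` and
#'   `excluded` (single-exon genes).
#' @export
exon_proportions <- function(ect, min_gene_count = 10) {
  stopifnot(is.data.frame(ect))
  need <- c("gene_id", "exon_id")
  if (!all(need %in% names(ect)))
    abort("exon table must have columns gene_id, exon_id, then samples")
  samples <- setdiff(names(ect), need)
  if (!length(samples)) abort("exon table has no sample columns")
  check_scalar(min_gene_count, "min_gene_count", lo = 1)
  cnt <- as.matrix(ect[, samples, drop = FALSE])
  if (any(!is.finite(cnt)) || any(cnt < 0))
    abort("exon counts must be finite and >= 0")
  genes <- split(seq_len(nrow(ect)), ect$gene_id)
  excluded <- character(0)
  out <- list()
  for (g in names(genes)) {
    rows <- genes[[g]]
    ex <- as.character(ect$exon_id[rows])
    if (anyDuplicated(ex))
      abort("duplicated exon_id within gene %s", g)
    if (length(rows) < 2L) {
      excluded <- c(excluded, g)
      next
    }
    m <- t(cnt[rows, , drop = FALSE])           # sample x exon
    tot <- rowSums(m)
    mask <- tot >= min_gene_count
    p <- m / ifelse(tot > 0, tot, 1)
    p[!mask, ] <- 1 / length(rows)              # uniform placeholder, masked
    colnames(p) <- ex
    rownames(p) <- samples
    out[[g]] <- list(proportions = p, mask = mask, exon_ids = ex)
  }
  if (length(excluded))
    message(sprintf("excluded %d single-exon gene(s) from cosplicing: %s",
                    length(excluded),
                    paste(utils::head(excluded, 5), collapse = ", ")))
  structure(out, samples = samples, excluded = excluded,
            class = "exon_profiles")
}

#' Sample-by-sample distance matrix of one gene's exon usage
#'
#' Distances between samples' exon-proportion vectors; masked (low-count)
#' samples get NA rows/columns so they are excluded pairwise downstream.
#'
#' @param profile one element of an [exon_proportions()] result.
#' @param metric `"euclidean"` (default), `"manhattan"` or `"canberra"`.
#' @return Symmetric distance matrix with zero diagonal; NA for pairs
#'   involving masked samples. Returns `NULL` (with a message) when fewer than
#'   3 samples are usable.
#' @export
gene_sample_distance <- function(profile, metric = c("euclidean", "manhattan",
                                                     "canberra")) {
  metric <- match.arg(metric)
  p <- profile$proportions
  mask <- profile$mask
  if (sum(mask) < 3L) {
    message("gene dropped: fewer than 3 usable samples")
    return(NULL)
  }
  d <- as.matrix(stats::dist(p, method = metric))
  d[!mask, ] <- NA_real_
  d[, !mask] <- NA_real_
  diag(d) <- ifelse(mask, 0, NA_real_)
  d
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the vectorized strict upper triangles of two
#' distance matrices over the same samples in the same order. NA entries
#' (masked sample pairs) are excluded pairwise. When either matrix is constant
#' off-diagonal the statistic is undefined and NA is returned.
#'
#' @param da,db square distance matrices, same dimension and sample order.
#' @return Mantel correlation in \[-1, 1\], or NA when undefined.
#' @export
mantel_correlation <- function(da, db) {
  stopifnot(is.matrix(da), is.matrix(db), all(dim(da) == dim(db)))
  va <- upper_vec(da)
  vb <- upper_vec(db)
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) return(NA_real_)
  stats::cor(va[ok], vb[ok])
}

#' Pairwise Mantel correlation matrix over genes
#'
#' Vectorizes each gene's distance matrix (restricted to `sample_idx`) and
#' correlates the upper triangles across genes, excluding masked pairs
#' pairwise. Genes whose distance vector is constant (no usage variation)
#' yield NA against every partner.
#'
#' @param dist_list named list of full sample x sample distance matrices
#'   (see [gene_sample_distance()]).
#' @param sample_idx integer indices of the samples to use (e.g. one line).
#' @return Gene x gene Mantel correlation matrix with unit diagonal.
#' @export
mantel_matrix <- function(dist_list, sample_idx = NULL) {
  stopifnot(length(dist_list) >= 2L)
  n <- nrow(dist_list[[1]])
  sample_idx <- sample_idx %||% seq_len(n)
  v <- vapply(dist_list,
              function(d) upper_vec(d[sample_idx, sample_idx, drop = FALSE]),
              numeric(length(sample_idx) * (length(sample_idx) - 1L) / 2L))
  sds <- apply(v, 2, stats::sd, na.rm = TRUE)
  m <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  m[sds == 0 | !is.finite(sds), ] <- NA_real_
  m[, sds == 0 | !is.finite(sds)] <- NA_real_
  diag(m) <- 1
  rownames(m) <- colnames(m) <- names(dist_list)
  m
}

#' Consensus cosplicing network from exon-usage profiles
#'
#' Per line, each gene's sample-by-sample exon-usage distance matrix is
#' computed from that line's samples only, gene pairs are scored by Mantel
#' correlation, and the resulting per-line similarity matrices feed the same
#' consensus/module machinery as coexpression ([build_network()]). Genes with
#' undefined Mantel correlations (constant usage, too few usable samples) are
#' excluded with a message. When the scale-free fit fails for the network,
#' downstream hub/connectivity analyses should be skipped (`power_law_ok` is
#' FALSE); module detection still proceeds.
#'
#' @param profiles an [exon_proportions()] result.
#' @param meta sample metadata data frame (`sample_id`, `line`), rows in the
#'   order of the profile sample columns.
#' @param metric distance metric, see [gene_sample_distance()].
#' @param ... passed to [build_network()].
#' @return A `gene_network` with an extra element `dist_by_gene` (full-sample
#'   distance matrices, used by permutation tests).
#' @export
cosplicing_network <- function(profiles, meta,
                               metric = c("euclidean", "manhattan", "canberra"),
                               ...) {
  metric <- match.arg(metric)
  stopifnot(inherits(profiles, "exon_profiles"))
  samples <- attr(profiles, "samples")
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  lines <- sort(unique(normalize_line(meta$line)))
  dist_list <- lapply(profiles, gene_sample_distance, metric = metric)
  dist_list <- dist_list[!vapply(dist_list, is.null, logical(1))]
  if (length(dist_list) < 2L) abort("need at least 2 eligible genes")
  corr <- lapply(lines, function(l)
    mantel_matrix(dist_list, which(normalize_line(meta$line) == l)))
  names(corr) <- lines
  # drop genes undefined in any line
  ok <- Reduce(`&`, lapply(corr, function(m) colSums(is.na(m)) < nrow(m) - 1L))
  if (any(!ok))
    message(sprintf("excluded %d gene(s) with undefined Mantel correlations",
                    sum(!ok)))
  corr <- lapply(corr, function(m) {
    m <- m[ok, ok, drop = FALSE]
    m[is.na(m)] <- 0        # isolated undefined pairs carry no edge weight
    m
  })
  net <- build_network(corr, ...)
  net$dist_by_gene <- dist_list[ok]
  net$type <- "cosplicing"
  net
}
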