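# Differential expression (Welch on log2 CPM), differential wiring of
# coexpression and cosplicing networks (edge change >= threshold, permutation
# null) and the exon-equal differential-splicing statistic.

# One shared, seeded permutation schedule: line labels are permuted over
# samples and the same schedule is applied to every gene so that gene-level
# statistics are comparable and runs reproduce.
permutation_schedule <- function(n, n_perm, seed) {
  set.seed(as.integer(seed))
  lapply(seq_len(n_perm), function(i) sample.int(n))
}

perm_pvalues <- function(observed, n_as_extreme, n_perm) {
  p <- (n_as_extreme + 1) / (n_perm + 1)
  data.frame(observed_stat = observed, n_perm = n_perm,
             n_as_extreme = n_as_extreme, p = p,
             fdr = stats::p.adjust(p, method = "BH"))
}

#' Differential expression between lines
#'
#' Per-gene two-sample Welch t-test on log2 CPM between the HIGH and LOW
#' lines, with Benjamini-Hochberg FDR across genes. The fold change is
#' reported as HIGH minus LOW on the log2 scale, and genes are split by
#' direction. Genes with zero variance in both lines and equal means are
#' untestable and get p = 1 with a flag.
#'
#' @param ne a `normalized_expression` object, or a numeric matrix of log2
#'   expression (genes x samples) if `line` is given.
#' @param line optional character vector of HIGH/LOW labels (required when
#'   `ne` is a bare matrix).
#' @return data frame: `gene`, `log2fc`, `statistic`, `p`, `fdr`, `direction`,
#'   `untestable`.
#' @export
differential_expression <- function(ne, line = NULL) {
  if (inherits(ne, "normalized_expression")) {
    x <- ne$log2cpm
    line <- ne$meta$line
  } else {
    x <- as.matrix(ne)
    if (is.null(line)) abort("supply line labels with a bare matrix")
    line <- normalize_line(line)
  }
  ih <- which(line == "HIGH")
  il <- which(line == "LOW")
  if (length(ih) < 3L || length(il) < 3L)
    abort("need at least 3 samples per line")
  xh <- x[, ih, drop = FALSE]
  xl <- x[, il, drop = FALSE]
  n1 <- length(ih); n2 <- length(il)
  m1 <- rowMeans(xh); m2 <- rowMeans(xl)
  v1 <- rowSums((xh - m1)^2) / (n1 - 1)
  v2 <- rowSums((xl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  untestable <- se2 == 0
  p[untestable & (m1 == m2)] <- 1
  tstat[untestable & (m1 == m2)] <- 0
  # zero variance but different means: effectively infinite evidence
  p[untestable & (m1 != m2)] <- .Machine$double.xmin
  data.frame(gene = rownames(x),
             log2fc = m1 - m2,
             statistic = tstat,
             p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             direction = ifelse(m1 >= m2, "HIGH>LOW", "LOW>HIGH"),
             untestable = untestable,
             row.names = NULL, stringsAsFactors = FALSE)
}

# count, per gene, partners whose edge changed by >= delta
dw_counts <- function(ch, cl, delta) {
  m <- abs(ch - cl) >= delta
  diag(m) <- FALSE
  rowSums(m, na.rm = TRUE)
}

#' Differential wiring of the coexpression network
#'
#' A gene's observed statistic is the number of partners whose Pearson
#' correlation with it changes between the lines by at least
#' `delta_threshold`. Significance comes from a permutation null: line labels
#' are permuted over samples (one shared schedule across genes), both
#' correlation matrices are recomputed, and the per-gene changed-edge count is
#' re-tallied. p = (number of permutations with a count >= observed + 1) /
#' (n_perm + 1); BH FDR across genes.
#'
#' @param expr numeric matrix of log2 expression (genes x samples) for the
#'   genes entering the analysis (typically the culled network genes).
#' @param line character vector of HIGH/LOW labels, one per sample column.
#' @param delta_threshold minimum |correlation change| per edge, in (0, 1\]
#'   (default 0.5).
#' @param n_perm number of label permutations (default 10000; values below
#'   100 warn).
#' @param seed integer seed for the permutation schedule.
#' @return data frame: `gene`, `changed_edge_count`, `observed_stat`,
#'   `n_perm`, `n_as_extreme`, `p`, `fdr`, plus attributes
#'   `mean_changed_edges` (per-gene average) and `partners` (named list of
#'   partner genes for genes with at least one changed edge).
#' @export
differential_wiring <- function(expr, line, delta_threshold = 0.5,
                                n_perm = 10000, seed = 1) {
  expr <- as.matrix(expr)
  line <- normalize_line(line)
  check_scalar(delta_threshold, "delta_threshold", lo = 0, hi = 1,
               open_lo = TRUE)
  if (n_perm < 100) warn("n_perm < 100 gives unstable permutation p-values")
  ih <- which(line == "HIGH"); il <- which(line == "LOW")
  corr_pair <- function(hi, lo)
    list(h = stats::cor(t(expr[, hi, drop = FALSE])),
         l = stats::cor(t(expr[, lo, drop = FALSE])))
  obs_mats <- corr_pair(ih, il)
  observed <- dw_counts(obs_mats$h, obs_mats$l, delta_threshold)

  dmat <- abs(obs_mats$h - obs_mats$l) >= delta_threshold
  diag(dmat) <- FALSE
  partners <- apply(dmat, 1, function(r) rownames(expr)[which(r)],
                    simplify = FALSE)
  partners <- partners[vapply(partners, length, integer(1)) > 0]

  sched <- permutation_schedule(ncol(expr), n_perm, seed)
  n_extreme <- integer(nrow(expr))
  nh <- length(ih)
  for (perm in sched) {
    mats <- corr_pair(perm[seq_len(nh)], perm[-seq_len(nh)])
    cnt <- dw_counts(mats$h, mats$l, delta_threshold)
    n_extreme <- n_extreme + (cnt >= observed)
  }
  out <- cbind(data.frame(gene = rownames(expr),
                          changed_edge_count = observed),
               perm_pvalues(observed, n_extreme, n_perm))
  rownames(out) <- NULL
  attr(out, "mean_changed_edges") <- mean(observed)
  attr(out, "partners") <- partners
  out
}

#' Differential wiring of the cosplicing network
#'
#' Same contract as [differential_wiring()], with edges given by Mantel
#' correlations between per-gene sample-distance matrices: per line, each
#' gene's distance matrix is restricted to that line's samples and gene pairs
#' are scored by [mantel_matrix()]. Under permutation the line labels are
#' permuted over samples and both Mantel matrices recomputed from the
#' (precomputed) full-sample distance matrices.
#'
#' @param dist_by_gene named list of full sample x sample distance matrices
#'   (e.g. `net$dist_by_gene` from [cosplicing_network()]).
#' @param line HIGH/LOW labels, one per sample (order of the distance matrix
#'   rows).
#' @inheritParams differential_wiring
#' @return As [differential_wiring()].
#' @export
differential_wiring_cosplicing <- function(dist_by_gene, line,
                                           delta_threshold = 0.5,
                                           n_perm = 10000, seed = 1) {
  line <- normalize_line(line)
  check_scalar(delta_threshold, "delta_threshold", lo = 0, hi = 1,
               open_lo = TRUE)
  if (n_perm < 100) warn("n_perm < 100 gives unstable permutation p-values")
  n <- nrow(dist_by_gene[[1]])
  ih <- which(line == "HIGH"); il <- which(line == "LOW")
  mantel_pair <- function(hi, lo)
    list(h = mantel_matrix(dist_by_gene, hi),
         l = mantel_matrix(dist_by_gene, lo))
  obs <- mantel_pair(ih, il)
  observed <- dw_counts(obs$h, obs$l, delta_threshold)

  dmat <- abs(obs$h - obs$l) >= delta_threshold
  diag(dmat) <- FALSE
  dmat[is.na(dmat)] <- FALSE
  partners <- apply(dmat, 1, function(r) names(dist_by_gene)[which(r)],
                    simplify = FALSE)
  partners <- partners[vapply(partners, length, integer(1)) > 0]

  sched <- permutation_schedule(n, n_perm, seed)
  n_extreme <- integer(length(dist_by_gene))
  nh <- length(ih)
  for (perm in sched) {
    mats <- mantel_pair(perm[seq_len(nh)], perm[-seq_len(nh)])
    cnt <- dw_counts(mats$h, mats$l, delta_threshold)
    n_extreme <- n_extreme + (cnt >= observed)
  }
  out <- cbind(data.frame(gene = names(dist_by_gene),
                          changed_edge_count = observed),
               perm_pvalues(observed, n_extreme, n_perm))
  rownames(out) <- NULL
  attr(out, "mean_changed_edges") <- mean(observed)
  attr(out, "partners") <- partners
  out
}

# exon-equal splicing distance between line-mean usage profiles:
# mean over exons of |mean_HIGH(prop) - mean_LOW(prop)|, masked samples
# excluded from the means
ds_statistic <- function(p, mask, ih, il) {
  uh <- ih[mask[ih]]; ul <- il[mask[il]]
  if (length(uh) < 3L || length(ul) < 3L) return(NA_real_)
  mean(abs(colMeans(p[uh, , drop = FALSE]) - colMeans(p[ul, , drop = FALSE])))
}

#' Differential splicing between lines
#'
#' Per-gene statistic D = (1/E) * sum over exons of |mean exon proportion in
#' HIGH - mean exon proportion in LOW| -- a distance between the line-mean
#' exon-usage profiles in which each exon carries equal weight. Significance
#' by label permutation with a shared schedule (p = (b + 1)/(B + 1), BH FDR
#' across genes). Masked (low-count) samples are excluded from the line means;
#' genes with fewer than 3 usable samples in either line under the observed
#' labels are reported NA and excluded from the FDR.
#'
#' @param profiles an [exon_proportions()] result.
#' @param line HIGH/LOW labels, one per profile sample.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation schedule.
#' @return data frame: `gene`, `n_exons`, `observed_stat`, `n_perm`,
#'   `n_as_extreme`, `p`, `fdr`.
#' @export
differential_splicing <- function(profiles, line, n_perm = 10000, seed = 1) {
  stopifnot(inherits(profiles, "exon_profiles"))
  line <- normalize_line(line)
  n <- length(line)
  ih <- which(line == "HIGH"); il <- which(line == "LOW")
  if (n_perm < 100) warn("n_perm < 100 gives unstable permutation p-values")

  observed <- vapply(profiles, function(pr)
    ds_statistic(pr$proportions, pr$mask, ih, il), numeric(1))
  usable <- !is.na(observed)

  sched <- permutation_schedule(n, n_perm, seed)
  n_extreme <- integer(length(profiles))
  nh <- length(ih)
  for (perm in sched) {
    ph <- perm[seq_len(nh)]; pl <- perm[-seq_len(nh)]
    stat <- vapply(profiles, function(pr)
      ds_statistic(pr$proportions, pr$mask, ph, pl), numeric(1))
    n_extreme <- n_extreme + (!is.na(stat) & stat >= observed)
  }
  p <- rep(NA_real_, length(profiles))
  fdr <- rep(NA_real_, length(profiles))
  p[usable] <- (n_extreme[usable] + 1) / (n_perm + 1)
  fdr[usable] <- stats::p.adjust(p[usable], method = "BH")
  data.frame(gene = names(profiles),
             n_exons = vapply(profiles, function(pr) length(pr$exon_ids),
                              integer(1)),
             observed_stat = observed, n_perm = n_perm,
             n_as_extreme = n_extreme, p = p, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}
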