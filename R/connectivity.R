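# Connectivity culling, per-line connectivity profiles, hub calls and
# between-line connectivity comparisons.

#' Cull leaf nodes by total connectivity
#'
#' Genes are sorted by decreasing total connectivity (ties broken by input
#' order, deterministically) and the shortest prefix whose summed connectivity
#' reaches `keep_fraction` of the total is retained: the genes contributing
#' the bottom `1 - keep_fraction` of network connectivity are dropped.
#'
#' @param k_total named numeric vector of total connectivities (>= 0).
#' @param keep_fraction fraction of summed connectivity to retain, in (0, 1\]
#'   (default 0.90).
#' @return Character vector of retained gene ids (in decreasing-k order).
#' @export
cull_network <- function(k_total, keep_fraction = 0.90) {
  check_scalar(keep_fraction, "keep_fraction", lo = 0, hi = 1, open_lo = TRUE)
  if (any(k_total < 0)) abort("k_total must be >= 0")
  if (is.null(names(k_total))) abort("k_total must be named by gene id")
  ord <- order(-k_total, seq_along(k_total))
  cum <- cumsum(k_total[ord])
  target <- keep_fraction * sum(k_total)
  m <- which(cum >= target - 1e-12)[1]
  names(k_total)[ord[seq_len(m)]]
}

#' Per-line connectivity profile
#'
#' For every gene: total connectivity `k_total` (row sum of the adjacency
#' excluding self), intramodular connectivity `k_within` (row sum restricted
#' to the gene's module), and relative connectivity `k_rel` = `k_within`
#' divided by the maximum `k_within` in that gene's module (so the most
#' connected gene of every module scores exactly 1). Genes in single-gene
#' modules have no within-module partners; their `k_rel` is 0 with a warning.
#'
#' @param adjacency adjacency matrix for one line.
#' @param modules named character vector gene -> module label covering all
#'   genes of the adjacency ("grey" allowed).
#' @param line line label recorded in the output.
#' @return data frame of class `connectivity_table`: columns `gene`, `line`,
#'   `module`, `k_total`, `k_within`, `k_rel`.
#' @export
connectivity_profile <- function(adjacency, modules, line = NA_character_) {
  ids <- rownames(adjacency)
  if (!all(ids %in% names(modules)))
    abort("modules must cover all genes in the adjacency")
  mod <- modules[ids]
  a <- adjacency
  diag(a) <- 0
  k_total <- rowSums(a)
  k_within <- numeric(length(ids))
  for (m in unique(mod)) {
    idx <- which(mod == m)
    if (length(idx) == 1L) {
      warn("module '%s' has a single gene; its k_rel is 0", m)
      k_within[idx] <- 0
    } else {
      k_within[idx] <- rowSums(a[idx, idx, drop = FALSE])
    }
  }
  k_rel <- numeric(length(ids))
  for (m in unique(mod)) {
    idx <- which(mod == m)
    mx <- max(k_within[idx])
    k_rel[idx] <- if (mx > 0) k_within[idx] / mx else 0
  }
  out <- data.frame(gene = ids, line = line, module = unname(mod),
                    k_total = unname(k_total), k_within = unname(k_within),
                    k_rel = unname(k_rel), stringsAsFactors = FALSE)
  class(out) <- c("connectivity_table", class(out))
  out
}

#' Flag hub genes by intramodular connectivity
#'
#' Hubs are the genes at or above the `hub_quantile` of `k_within` within
#' their own module (ties expand the set). Lowering the quantile never removes
#' a hub.
#'
#' @param ct a [connectivity_profile()] table.
#' @param hub_quantile quantile of within-module connectivity (default 0.90).
#' @return `ct` with an added logical column `hub`.
#' @export
identify_hubs <- function(ct, hub_quantile = 0.90) {
  check_scalar(hub_quantile, "hub_quantile", lo = 0, hi = 1)
  hub <- logical(nrow(ct))
  for (m in unique(ct$module)) {
    idx <- which(ct$module == m)
    thr <- stats::quantile(ct$k_within[idx], probs = hub_quantile,
                           names = FALSE, type = 7)
    hub[idx] <- ct$k_within[idx] >= thr
  }
  ct$hub <- hub
  ct
}

#' Genes whose relative connectivity changes between lines
#'
#' Flags genes with |k_rel(LOW) - k_rel(HIGH)| >= `delta_threshold`, reporting
#' both values, the higher line, the difference and (when `hub` columns are
#' present) whether the gene is a hub in the higher-connectivity line.
#' Exchanging the two tables flips the direction labels and nothing else.
#'
#' @param ct_high,ct_low connectivity tables for the two lines (same genes and
#'   modules; genes present in only one table are excluded with a message).
#' @param delta_threshold minimum |difference| in relative connectivity
#'   (default 0.5, on the 0-1 scale).
#' @return data frame: `gene`, `module`, `k_rel_high`, `k_rel_low`, `delta`,
#'   `direction` ("HIGH>LOW"/"LOW>HIGH"), `hub_in_higher_line` (NA when hub
#'   flags are absent).
#' @export
differential_connectivity <- function(ct_high, ct_low, delta_threshold = 0.5) {
  check_scalar(delta_threshold, "delta_threshold", lo = 0, hi = 1,
               open_lo = TRUE)
  common <- intersect(ct_high$gene, ct_low$gene)
  dropped <- length(union(ct_high$gene, ct_low$gene)) - length(common)
  if (dropped > 0)
    message(sprintf("excluded %d gene(s) missing from one line", dropped))
  hi <- ct_high[match(common, ct_high$gene), ]
  lo <- ct_low[match(common, ct_low$gene), ]
  delta <- abs(lo$k_rel - hi$k_rel)
  keep <- delta >= delta_threshold
  dir <- ifelse(hi$k_rel >= lo$k_rel, "HIGH>LOW", "LOW>HIGH")
  hub_col <- if (!is.null(hi$hub) && !is.null(lo$hub))
    ifelse(dir == "HIGH>LOW", hi$hub, lo$hub) else NA
  data.frame(gene = common, module = hi$module,
             k_rel_high = hi$k_rel, k_rel_low = lo$k_rel,
             delta = delta, direction = dir,
             hub_in_higher_line = hub_col,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Compare mean connectivity between lines
#'
#' Means of total (`scope = "total"`) or intramodular (`scope = "modular"`)
#' connectivity in each line over a gene subset, with a paired two-sided
#' Wilcoxon signed-rank test across genes.
#'
#' @param ct_high,ct_low connectivity tables paired by gene.
#' @param scope `"total"` or `"modular"`.
#' @param gene_subset optional character vector restricting the comparison.
#' @return list: `mean_high`, `mean_low`, `p_value` (NA with a warning when
#'   fewer than 10 genes are compared), `n`.
#' @export
compare_mean_connectivity <- function(ct_high, ct_low,
                                      scope = c("total", "modular"),
                                      gene_subset = NULL) {
  scope <- match.arg(scope)
  col <- if (scope == "total") "k_total" else "k_within"
  common <- intersect(ct_high$gene, ct_low$gene)
  if (!is.null(gene_subset)) common <- intersect(common, gene_subset)
  x <- ct_high[[col]][match(common, ct_high$gene)]
  y <- ct_low[[col]][match(common, ct_low$gene)]
  if (length(common) < 10L) {
    warn("fewer than 10 genes in the comparison; p-value not reported")
    return(list(mean_high = mean(x), mean_low = mean(y), p_value = NA_real_,
                n = length(common)))
  }
  p <- if (all(x == y)) 1 else
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
  list(mean_high = mean(x), mean_low = mean(y), p_value = p, n = length(common))
}
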