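# Weighted coexpression networks: per-line Pearson correlation, soft-threshold
# adjacency, topological overlap, cross-line consensus and module detection.

# Module label palette; labels are arbitrary colors with no meaning within or
# across networks. Overflow modules get numbered labels.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta")

#' Per-line Pearson correlation matrix
#'
#' Computes the gene x gene Pearson correlation of expression across the
#' samples of one selection line. Zero-variance genes cannot be correlated and
#' are dropped with a warning.
#'
#' @param ne a `normalized_expression` object (log2 CPM is correlated).
#' @param line which line's samples to use, `"HIGH"` or `"LOW"`.
#' @return Symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\], dimnames = retained gene ids.
#' @export
correlation_matrix <- function(ne, line) {
  stopifnot(inherits(ne, "normalized_expression"))
  line <- normalize_line(line)
  idx <- which(ne$meta$line == line)
  if (length(idx) < 3L)
    abort("need at least 3 samples in line %s, found %d", line, length(idx))
  x <- ne$log2cpm[, idx, drop = FALSE]
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warn("dropping %d zero-variance gene(s) before correlation: %s",
         sum(v == 0), paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  # guard against numerical drift outside [-1, 1]
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Unsigned soft-threshold adjacency
#'
#' @param corr correlation (or Mantel correlation) matrix.
#' @param beta soft-threshold power (>= 1).
#' @return Adjacency `|corr|^beta`, entries in \[0, 1\], unit diagonal.
#' @export
adjacency_matrix <- function(corr, beta) {
  check_scalar(beta, "beta", lo = 1)
  a <- abs(corr)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity values `k` into `n_bins` equal-occupancy bins,
#' estimates the density P(k) per bin (bin count / (n * bin width)), and
#' regresses log10 P(k) on log10 of the mean k per bin. Empty or zero-width
#' bins are dropped. The fit passes when r-squared >= `fit_threshold` and the
#' slope is negative.
#'
#' @param adjacency square adjacency matrix; connectivity is the row sum
#'   excluding the diagonal. Alternatively supply `k` directly.
#' @param k optional numeric vector of connectivities (overrides `adjacency`).
#' @param n_bins number of bins (>= 5).
#' @param fit_threshold minimum r-squared to pass (default 0.8).
#' @return list of class `scale_free_fit`: `r_squared`, `slope`, `passes`,
#'   `degenerate` (TRUE when the degree distribution cannot be fit, e.g. all
#'   connectivities identical).
#' @export
scale_free_fit <- function(adjacency = NULL, k = NULL, n_bins = 10,
                           fit_threshold = 0.8) {
  check_scalar(n_bins, "n_bins", lo = 5)
  check_scalar(fit_threshold, "fit_threshold", lo = 0, hi = 1)
  if (is.null(k)) {
    stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
    k <- rowSums(adjacency) - diag(adjacency)
  }
  k <- k[is.finite(k)]
  out <- structure(list(r_squared = 0, slope = NA_real_, passes = FALSE,
                        degenerate = TRUE),
                   class = "scale_free_fit")
  if (length(k) < n_bins || diff(range(k)) == 0) return(out)

  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 4L) return(out)   # too few distinct bins to regress
  bin <- cut(k, breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = length(breaks) - 1L)
  width <- diff(breaks)
  mean_k <- tapply(k, bin, mean)
  dens <- cnt / (length(k) * width)
  keep <- cnt > 0 & width > 0 & mean_k > 0 & dens > 0
  if (sum(keep) < 3L) return(out)
  fit <- stats::lm(log10(dens[keep]) ~ log10(mean_k[keep]))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(r_squared = r2, slope = slope,
                 passes = r2 >= fit_threshold && slope < 0,
                 degenerate = FALSE),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("scale_free_fit: r2 = %.3f, slope = %.3f, %s%s\n",
              x$r_squared, x$slope,
              if (x$passes) "PASS" else "FAIL",
              if (x$degenerate) " (degenerate degree distribution)" else ""))
  invisible(x)
}

#' Choose the soft-threshold power by scale-free fit
#'
#' Evaluates the scale-free topology fit of `|corr|^beta` for each candidate
#' power and returns the smallest one that passes. When no candidate passes,
#' the power with the largest r-squared is returned and `warned` is set.
#'
#' @param corr correlation matrix.
#' @param candidate_betas candidate powers, all >= 1 (default seq(2, 20, 2)).
#' @param fit_threshold minimum r-squared for a pass (default 0.8).
#' @param n_bins bins for [scale_free_fit()].
#' @return list: `beta` (chosen power), `fits` (data frame of beta, r_squared,
#'   slope, passes), `warned` (TRUE when no candidate passed).
#' @export
pick_soft_power <- function(corr, candidate_betas = seq(2, 20, by = 2),
                            fit_threshold = 0.8, n_bins = 10) {
  if (!length(candidate_betas) || any(candidate_betas < 1))
    abort("candidate_betas must be non-empty and all >= 1")
  fits <- lapply(candidate_betas, function(b)
    scale_free_fit(adjacency_matrix(corr, b), n_bins = n_bins,
                   fit_threshold = fit_threshold))
  tab <- data.frame(beta = candidate_betas,
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                    slope = vapply(fits, `[[`, numeric(1), "slope"),
                    passes = vapply(fits, `[[`, logical(1), "passes"))
  if (any(tab$passes)) {
    list(beta = min(tab$beta[tab$passes]), fits = tab, warned = FALSE)
  } else {
    warn("no candidate soft power reached r2 >= %g; using the best fit (beta = %g)",
         fit_threshold, tab$beta[which.max(tab$r_squared)])
    list(beta = tab$beta[which.max(tab$r_squared)], fits = tab, warned = TRUE)
  }
}

#' Topological overlap matrix (unsigned)
#'
#' TOM(i,j) = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj over u != i, j, and k the connectivity (row sum of
#' the adjacency excluding the diagonal); TOM(i,i) = 1.
#'
#' @param adjacency adjacency matrix with entries in \[0, 1\].
#' @return TOM similarity matrix in \[0, 1\].
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  tom <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  tom
}

#' Consensus of per-line topological overlap matrices
#'
#' Per-line TOMs are made comparable by quantile scaling: each non-reference
#' TOM `T` is raised to the power log(q_ref)/log(q_T), where q is the
#' `scale_quantile` of the strict upper triangle, so that its reference
#' quantile matches the first line's. The consensus is the component-wise
#' minimum of the scaled matrices.
#'
#' @param tom_by_line named list of TOM matrices (same genes, same order).
#' @param scale_quantile upper-triangle quantile to align (default 0.95).
#' @return list: `consensus` matrix, `scaled` (list of scaled TOMs),
#'   `exponents` (named scaling powers, reference = 1).
#' @export
consensus_network <- function(tom_by_line, scale_quantile = 0.95) {
  stopifnot(is.list(tom_by_line), length(tom_by_line) >= 1L)
  ids <- lapply(tom_by_line, rownames)
  if (length(tom_by_line) > 1L &&
      !all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    abort("per-line matrices must cover the same genes in the same order")
  q <- vapply(tom_by_line, function(m) stats::quantile(upper_vec(m),
              probs = scale_quantile, names = FALSE), numeric(1))
  expo <- rep(1, length(tom_by_line))
  names(expo) <- names(tom_by_line)
  scaled <- tom_by_line
  if (length(tom_by_line) > 1L && all(q > 0 & q < 1)) {
    for (i in seq_along(tom_by_line)[-1]) {
      expo[i] <- log(q[1]) / log(q[i])
      scaled[[i]] <- tom_by_line[[i]]^expo[i]
    }
  }
  cons <- Reduce(pmin, scaled)
  list(consensus = cons, scaled = scaled, exponents = expo)
}

#' Detect modules on a consensus TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - consensus) followed by an adaptive static cut (a simplified stand-in
#' for dynamic tree cut): candidate partitions with 2..n_max clusters are
#' scanned and the one whose number of sufficiently large clusters is closest
#' to `target_module_count` is kept (ties resolved toward fewer unassigned
#' genes). Clusters smaller than `min_module_size` become the reserved label
#' `"grey"`. Two refinement stages then use a similarity matrix (by default
#' the consensus itself): (1) validity -- a candidate module whose mean
#' within-module similarity does not exceed twice the between-module
#' background is dissolved into grey, so structureless data yields mostly
#' grey; (2) rescue (analogous to the PAM stage of dynamic tree cut) -- an
#' unassigned gene joins its best-matching module when its mean similarity to
#' that module clears background plus a quarter of the module's
#' cohesion-background gap. Module labels are arbitrary colors ordered by
#' decreasing module size and carry no meaning across networks.
#'
#' @param consensus consensus TOM (symmetric, entries in \[0, 1\]).
#' @param min_module_size smallest cluster kept as a module (default 100).
#' @param target_module_count module count the cut search aims for
#'   (default 25; best effort).
#' @param similarity optional gene x gene similarity used for the validity
#'   and rescue stages (e.g. a consensus correlation); defaults to
#'   `consensus`.
#' @param n_max largest cluster count scanned (default
#'   `max(60, 3 * target_module_count)`).
#' @return Named character vector: gene id -> module color ("grey" =
#'   unassigned), with attribute `n_modules`.
#' @export
detect_modules <- function(consensus, min_module_size = 100,
                           target_module_count = 25, similarity = NULL,
                           n_max = NULL) {
  stopifnot(is.matrix(consensus), nrow(consensus) == ncol(consensus))
  check_scalar(min_module_size, "min_module_size", lo = 2)
  check_scalar(target_module_count, "target_module_count", lo = 1)
  ids <- rownames(consensus)
  n <- nrow(consensus)
  sim <- similarity %||% consensus
  if (n < min_module_size) {
    warn("fewer genes (%d) than min_module_size (%d); returning one module", n,
         min_module_size)
    out <- rep(MODULE_COLORS[1], n)
    names(out) <- ids
    attr(out, "n_modules") <- 1L
    return(out)
  }
  h <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  n_max <- n_max %||% max(60, 3 * target_module_count)
  best <- NULL
  for (k in 2:min(n - 1L, n_max)) {
    cl <- stats::cutree(h, k = k)
    sizes <- tabulate(cl)
    n_mod <- sum(sizes >= min_module_size)
    assigned <- sum(sizes[sizes >= min_module_size])
    score <- abs(n_mod - target_module_count)
    if (n_mod >= 1 &&
        (is.null(best) || score < best$score ||
         (score == best$score && assigned > best$assigned))) {
      best <- list(cl = cl, score = score, assigned = assigned, n_mod = n_mod)
    }
  }
  grey_out <- function() {
    out <- rep("grey", n)
    names(out) <- ids
    attr(out, "n_modules") <- 0L
    out
  }
  if (is.null(best)) return(grey_out())

  sizes <- table(best$cl)
  big <- names(sizes)[sizes >= min_module_size]
  cl <- as.character(best$cl)
  cl[!cl %in% big] <- "grey"

  # validity: dissolve candidate modules without real internal cohesion
  off <- upper_vec(sim)
  members <- split(seq_len(n), cl)
  members$grey <- NULL
  cohesion <- vapply(members, function(idx)
    mean(sim[idx, idx][upper.tri(sim[idx, idx])]), numeric(1))
  # between-module background: everything outside the candidate modules'
  # internal pairs
  within_mask <- matrix(FALSE, n, n)
  for (idx in members) within_mask[idx, idx] <- TRUE
  bg_vals <- sim[upper.tri(sim) & !within_mask]
  bg <- if (length(bg_vals)) mean(bg_vals) else mean(off)
  valid <- names(cohesion)[cohesion > 2 * bg]
  cl[!cl %in% valid] <- "grey"
  if (!length(valid)) return(grey_out())

  # one membership criterion, applied both ways: a gene belongs in a module
  # when its mean similarity to the module clears background plus a quarter
  # of the module's cohesion-background gap
  thr <- bg + 0.25 * (cohesion[valid] - bg)
  # purge: cut artifacts without real membership go to grey
  for (v in valid) {
    idx <- which(cl == v)
    memb <- vapply(idx, function(g) mean(sim[g, setdiff(idx, g)]), numeric(1))
    cl[idx[memb <= thr[v]]] <- "grey"
  }
  # rescue: reattach unassigned genes with clear membership
  grey_idx <- which(cl == "grey")
  if (length(grey_idx)) {
    for (g in grey_idx) {
      ms <- vapply(valid, function(v)
        mean(sim[g, cl == v]), numeric(1))
      ok <- is.finite(ms) & ms > thr
      if (any(ok)) cl[g] <- valid[which.max(ms - thr)]
    }
  }
  # a purged module may fall below the size floor; dissolve it
  for (v in valid) if (sum(cl == v) < min_module_size) cl[cl == v] <- "grey"

  sizes <- table(cl[cl != "grey"])
  mods <- names(sizes)[order(-sizes, names(sizes))]
  labels <- c(MODULE_COLORS, paste0("module", seq_len(max(0,
              length(mods) - length(MODULE_COLORS)))))[seq_along(mods)]
  out <- rep("grey", n)
  for (i in seq_along(mods)) out[cl == mods[i]] <- labels[i]
  names(out) <- ids
  attr(out, "n_modules") <- length(mods)
  out
}

#' Build a per-line network with consensus modules
#'
#' Shared engine for coexpression and cosplicing networks: per-line similarity
#' matrices are soft-thresholded into adjacencies, turned into topological
#' overlap, quantile-scaled into a consensus, and clustered into modules. The
#' soft power is chosen per line by [pick_soft_power()] and the maximum over
#' lines is used for all lines, unless `beta` is supplied.
#'
#' @param corr_by_line named list (by line) of similarity matrices in
#'   \[-1, 1\], same genes in the same order.
#' @param beta soft power; `NULL` (default) chooses it by scale-free fit.
#' @param candidate_betas,fit_threshold passed to [pick_soft_power()].
#' @param min_module_size,target_module_count passed to [detect_modules()].
#' @return Object of class `gene_network`: list with `gene_ids`,
#'   `corr_by_line`, `adjacency_by_line`, `tom_by_line`, `consensus`, `beta`,
#'   `modules`, `scale_free_by_line` (per-line [scale_free_fit()] of the
#'   adjacency), and `power_law_ok` (all lines pass).
#' @export
build_network <- function(corr_by_line, beta = NULL,
                          candidate_betas = seq(2, 20, by = 2),
                          fit_threshold = 0.8, min_module_size = 100,
                          target_module_count = 25) {
  stopifnot(is.list(corr_by_line), length(corr_by_line) >= 1L)
  ids <- rownames(corr_by_line[[1]])
  if (length(corr_by_line) > 1L &&
      !all(vapply(corr_by_line[-1], function(m) identical(rownames(m), ids),
                  logical(1))))
    abort("per-line similarity matrices must cover the same genes")
  if (is.null(beta)) {
    picks <- lapply(corr_by_line, pick_soft_power,
                    candidate_betas = candidate_betas,
                    fit_threshold = fit_threshold)
    beta <- max(vapply(picks, `[[`, numeric(1), "beta"))
  }
  adj <- lapply(corr_by_line, adjacency_matrix, beta = beta)
  fits <- lapply(adj, scale_free_fit, fit_threshold = fit_threshold)
  toms <- lapply(adj, tom_similarity)
  cons <- consensus_network(toms)
  # validity/rescue in module detection works on the consensus correlation
  # (min over lines of |r|), whose contrast for weak module members survives
  # high soft powers better than the TOM
  cons_corr <- Reduce(pmin, lapply(corr_by_line, abs))
  modules <- detect_modules(cons$consensus, min_module_size = min_module_size,
                            target_module_count = target_module_count,
                            similarity = cons_corr)
  structure(list(gene_ids = ids,
                 corr_by_line = corr_by_line,
                 adjacency_by_line = adj,
                 tom_by_line = toms,
                 consensus = cons$consensus,
                 consensus_exponents = cons$exponents,
                 beta = beta,
                 modules = modules,
                 scale_free_by_line = fits,
                 power_law_ok = all(vapply(fits, `[[`, logical(1), "passes"))),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(paste0("gene_network: %d genes, %d lines, beta = %g, ",
                     "%d modules (+%d grey), power law %s\n"),
              length(x$gene_ids), length(x$corr_by_line), x$beta,
              attr(x$modules, "n_modules"), sum(x$modules == "grey"),
              if (x$power_law_ok) "ok" else "FAILED"))
  invisible(x)
}

#' Consensus coexpression network from normalized expression
#'
#' Convenience wrapper: per-line Pearson correlation of log2 CPM (via
#' [correlation_matrix()]) followed by [build_network()]. Genes dropped for
#' zero variance in either line are excluded from both.
#'
#' @param ne a `normalized_expression` object covering both lines.
#' @param ... passed to [build_network()].
#' @return A `gene_network`.
#' @export
coexpression_network <- function(ne, ...) {
  lines <- sort(unique(ne$meta$line))
  corr <- lapply(lines, function(l) correlation_matrix(ne, l))
  names(corr) <- lines
  common <- Reduce(intersect, lapply(corr, rownames))
  corr <- lapply(corr, function(m) m[common, common, drop = FALSE])
  build_network(corr, ...)
}
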