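# Module-level Fisher's-exact enrichment with Bonferroni correction over
# modules, including the protection (under-enrichment) direction.

#' Fisher's exact enrichment of a gene set in a module
#'
#' Builds the 2x2 table (module yes/no x flagged yes/no) over the universe and
#' reports exact one-tailed hypergeometric p-values in both directions:
#' enrichment (at least the observed overlap) and depletion (at most the
#' observed overlap). The odds ratio comes from the table; when a zero cell
#' makes it undefined, 0.5 is added to every cell and the result flagged.
#'
#' @param module_genes character vector of the module's genes.
#' @param flagged_genes character vector of flagged genes (e.g. DE/DW/DS, or
#'   a cell-type marker set); intersected with the universe.
#' @param universe all genes eligible in the analysis (e.g. the culled
#'   network); `module_genes` must be a subset.
#' @return list: `a`,`b`,`c`,`d` (table counts), `odds_ratio`,
#'   `or_corrected` (TRUE when the continuity correction was used),
#'   `p_enriched`, `p_depleted`.
#' @export
fisher_enrichment <- function(module_genes, flagged_genes, universe) {
  if (!length(module_genes) || !length(universe))
    abort("module and universe must be non-empty")
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    abort("module_genes must be a subset of the universe")
  flagged_genes <- intersect(unique(flagged_genes), universe)
  N <- length(universe)
  K <- length(flagged_genes)
  m <- length(module_genes)
  a <- length(intersect(module_genes, flagged_genes))
  b <- m - a
  cc <- K - a
  d <- N - m - cc
  p_enr <- stats::phyper(a - 1, K, N - K, m, lower.tail = FALSE)
  p_dep <- stats::phyper(a, K, N - K, m, lower.tail = TRUE)
  zero <- a == 0 || b == 0 || cc == 0 || d == 0
  or <- if (zero) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  list(a = a, b = b, c = cc, d = d, odds_ratio = or, or_corrected = zero,
       p_enriched = p_enr, p_depleted = p_dep)
}

#' Bonferroni correction over the number of modules
#'
#' @param p raw p-value in (0, 1\].
#' @param n_modules number of modules tested (>= 1).
#' @return min(1, p * n_modules).
#' @export
bonferroni_correct <- function(p, n_modules) {
  if (any(p <= 0) || any(p > 1)) abort("p must be in (0, 1]")
  check_scalar(n_modules, "n_modules", lo = 1)
  pmin(1, p * n_modules)
}

#' Per-module enrichment and protection calls for a flagged gene set
#'
#' Runs both-direction Fisher tests for every module against the flagged set,
#' Bonferroni-corrects over the number of modules tested, and calls each
#' module `enriched` (corrected enrichment p <= alpha), `protected` (corrected
#' depletion p <= alpha; significantly fewer flagged genes than expected,
#' i.e. shielded from the effects of selection) or `neutral`. The two calls
#' are mutually exclusive. Grey (unassigned) genes stay in the universe but
#' "grey" is not tested as a module.
#'
#' @param modules named character vector gene -> module label.
#' @param flagged_genes flagged gene set (e.g. DE/DW/DS genes).
#' @param universe gene universe (default: names of `modules`).
#' @param alpha significance level on the corrected p (default 0.01).
#' @param set_name label recorded in the output.
#' @return data frame: `module`, `set_name`, `module_size`, `a`..`d`,
#'   `odds_ratio`, `p_enriched`, `p_depleted`, `p_corrected` (corrected p of
#'   the smaller tail), `call`.
#' @export
module_selection_impact <- function(modules, flagged_genes,
                                    universe = names(modules), alpha = 0.01,
                                    set_name = "flagged") {
  check_scalar(alpha, "alpha", lo = 0, hi = 1, open_lo = TRUE)
  mods <- setdiff(unique(modules), "grey")
  if (!length(mods)) abort("no non-grey modules to test")
  n_mod <- length(mods)
  rows <- lapply(mods, function(m) {
    fe <- fisher_enrichment(names(modules)[modules == m], flagged_genes,
                            universe)
    p_enr_c <- bonferroni_correct(fe$p_enriched, n_mod)
    p_dep_c <- bonferroni_correct(fe$p_depleted, n_mod)
    call <- if (p_enr_c <= alpha) "enriched"
            else if (p_dep_c <= alpha) "protected" else "neutral"
    data.frame(module = m, set_name = set_name,
               module_size = sum(modules == m),
               a = fe$a, b = fe$b, c = fe$c, d = fe$d,
               odds_ratio = fe$odds_ratio,
               p_enriched = fe$p_enriched, p_depleted = fe$p_depleted,
               p_corrected = min(p_enr_c, p_dep_c), call = call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read gene sets in GMT format
#'
#' Standard tab format: set name, description, then member genes; one set per
#' line. Parsing is delegated to `fgsea::gmtPathways`.
#'
#' @param path path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
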