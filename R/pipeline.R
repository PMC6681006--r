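# End-to-end pipeline: normalize -> consensus networks -> cull ->
# connectivity/hubs -> DE/DW/DS -> enrichment/protection -> report, from one
# seeded configuration, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Bundles inputs and analysis parameters. The defaults are the analysis
#' constants used throughout the package: CPM filter > 1, keep the top 90% of
#' summed connectivity, minimum module size 100 with ~25 modules targeted,
#' edge-change threshold 0.5, 10,000 permutations, FDR 0.05 and corrected
#' protection alpha 0.01.
#'
#' @param counts path to a gene-count TSV, or a [count_matrix()].
#' @param meta path to the sample metadata TSV (ignored when `counts` is a
#'   `count_matrix`).
#' @param exon_counts optional path to an exon-count TSV, or a data frame
#'   (`gene_id`, `exon_id`, samples). `NULL` skips cosplicing and splicing.
#' @param gene_sets optional path to a GMT file of marker sets tested for
#'   module enrichment.
#' @param cpm_threshold mean-CPM expression filter (default 1).
#' @param keep_fraction connectivity fraction retained by culling
#'   (default 0.90).
#' @param min_module_size minimum module size (default 100).
#' @param target_modules module-count target for the tree cut (default 25).
#' @param delta_threshold edge-change threshold for differential wiring and
#'   relative-connectivity differences (default 0.5).
#' @param n_perm permutations for DW/DS (default 10000).
#' @param fdr_alpha FDR threshold used in the report (default 0.05).
#' @param protection_alpha corrected alpha for enrichment/protection calls
#'   (default 0.01).
#' @param hub_quantile intramodular-connectivity quantile defining hubs
#'   (default 0.90).
#' @param beta optional fixed soft power (default: chosen by scale-free fit).
#' @param min_gene_count per-sample gene total below which an exon-usage
#'   profile is masked (default 10).
#' @param seed master seed; every stage derives its randomness from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, meta = NULL, exon_counts = NULL,
                            gene_sets = NULL, cpm_threshold = 1,
                            keep_fraction = 0.90, min_module_size = 100,
                            target_modules = 25, delta_threshold = 0.5,
                            n_perm = 10000, fdr_alpha = 0.05,
                            protection_alpha = 0.01, hub_quantile = 0.90,
                            beta = NULL, min_gene_count = 10, seed = 1) {
  check_scalar(cpm_threshold, "cpm_threshold", lo = 0)
  check_scalar(keep_fraction, "keep_fraction", lo = 0, hi = 1, open_lo = TRUE)
  check_scalar(delta_threshold, "delta_threshold", lo = 0, hi = 1,
               open_lo = TRUE)
  check_scalar(fdr_alpha, "fdr_alpha", lo = 0, hi = 1, open_lo = TRUE)
  check_scalar(protection_alpha, "protection_alpha", lo = 0, hi = 1,
               open_lo = TRUE)
  structure(list(counts = counts, meta = meta, exon_counts = exon_counts,
                 gene_sets = gene_sets, cpm_threshold = cpm_threshold,
                 keep_fraction = keep_fraction,
                 min_module_size = min_module_size,
                 target_modules = target_modules,
                 delta_threshold = delta_threshold, n_perm = n_perm,
                 fdr_alpha = fdr_alpha, protection_alpha = protection_alpha,
                 hub_quantile = hub_quantile, beta = beta,
                 min_gene_count = min_gene_count, seed = as.integer(seed)),
            class = "pipeline_config")
}

# cull by summed per-line total connectivity and rebuild on the retained set
cull_and_rebuild <- function(corr_by_line, beta, keep_fraction,
                             min_module_size, target_modules) {
  adj <- lapply(corr_by_line, adjacency_matrix, beta = beta)
  k_sum <- Reduce(`+`, lapply(adj, function(a) rowSums(a) - diag(a)))
  names(k_sum) <- rownames(corr_by_line[[1]])
  kept <- cull_network(k_sum, keep_fraction)
  kept <- rownames(corr_by_line[[1]])[rownames(corr_by_line[[1]]) %in% kept]
  corr_culled <- lapply(corr_by_line, function(m) m[kept, kept, drop = FALSE])
  net <- build_network(corr_culled, beta = beta,
                       min_module_size = min_module_size,
                       target_module_count = target_modules)
  list(net = net, kept = kept, k_sum = k_sum)
}

# connectivity/hub/differential-connectivity block shared by both networks
hub_block <- function(net, cfg) {
  ct <- lapply(names(net$adjacency_by_line), function(l)
    identify_hubs(connectivity_profile(net$adjacency_by_line[[l]],
                                       net$modules, line = l),
                  cfg$hub_quantile))
  names(ct) <- names(net$adjacency_by_line)
  dc <- differential_connectivity(ct$HIGH, ct$LOW, cfg$delta_threshold)
  cmp <- do.call(rbind, lapply(c("total", "modular"), function(sc) {
    r <- compare_mean_connectivity(ct$HIGH, ct$LOW, scope = sc)
    data.frame(scope = sc, mean_high = r$mean_high, mean_low = r$mean_low,
               p_value = r$p_value, n = r$n)
  }))
  list(table = do.call(rbind, ct), diff = dc, comparison = cmp)
}

#' Run the full selection-network pipeline
#'
#' Executes: ingest and upper-quartile CPM normalization with the expression
#' filter; per-line Pearson coexpression networks, leaf culling on summed
#' connectivity and consensus module detection; a scale-free topology gate
#' (when a network's fit fails, its hub/connectivity analyses are skipped
#' with a warning and the run continues -- modules are still reported);
#' connectivity profiles, hubs and between-line comparisons; differential
#' expression, differential wiring; and, when exon counts are supplied,
#' cosplicing networks with the same gate plus differential splicing and
#' cosplicing differential wiring; module enrichment/protection calls for
#' every flagged set. All stage outputs are written as TSV under `out_dir`
#' together with a `manifest.json` (parameters, seed, input hashes, stage
#' log) and a summary report. Two runs with the same config and seed produce
#' byte-identical directories.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; existing stage files are
#'   overwritten).
#' @return Invisibly, a list with the in-memory stage results (`network`,
#'   `de`, `dw`, `connectivity`, `cosplicing`, `ds`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed, c("dw", "ds", "dw_cosplice"))
  log <- character(0)
  note <- function(msg) {
    log <<- c(log, msg)
    message(msg)
  }

  # --- ingest + normalize -------------------------------------------------
  cm <- if (inherits(config$counts, "count_matrix")) config$counts
        else read_counts(config$counts, config$meta)
  input_hashes <- list()
  if (is.character(config$counts))
    input_hashes$counts <- unname(tools::md5sum(config$counts))
  if (is.character(config$meta %||% ""))
    input_hashes$meta <- if (!is.null(config$meta))
      unname(tools::md5sum(config$meta)) else NULL
  ne <- filter_by_cpm(upper_quartile_normalize(cm), config$cpm_threshold)
  note(sprintf("normalize: %d/%d genes pass mean CPM > %g",
               nrow(ne$cpm), nrow(cm$counts), config$cpm_threshold))
  write_tsv(data.frame(sample_id = colnames(ne$cpm),
                       scale_factor = unname(ne$scale_factors),
                       lib_size = unname(ne$lib_sizes)),
            file.path(out_dir, "scale_factors.tsv"))
  write_tsv(data.frame(gene_id = rownames(ne$log2cpm), ne$log2cpm,
                       check.names = FALSE),
            file.path(out_dir, "log2cpm.tsv"))

  # --- coexpression network ----------------------------------------------
  lines <- c("HIGH", "LOW")
  corr <- lapply(lines, function(l) correlation_matrix(ne, l))
  names(corr) <- lines
  common <- Reduce(intersect, lapply(corr, rownames))
  corr <- lapply(corr, function(m) m[common, common, drop = FALSE])
  beta <- config$beta
  if (is.null(beta)) {
    picks <- suppressWarnings(lapply(corr, pick_soft_power))
    beta <- max(vapply(picks, `[[`, numeric(1), "beta"))
    note(sprintf("coexpression: soft power beta = %g", beta))
  }
  # the scale-free gate is judged on the full (pre-cull) network, where the
  # soft power was chosen; culling truncates the low-connectivity tail and
  # would fail any degree-distribution fit by construction
  gate_fits <- lapply(corr, function(m)
    scale_free_fit(adjacency_matrix(m, beta)))
  gate_ok <- all(vapply(gate_fits, `[[`, logical(1), "passes"))
  cx <- cull_and_rebuild(corr, beta, config$keep_fraction,
                         config$min_module_size, config$target_modules)
  net <- cx$net
  net$scale_free_by_line <- gate_fits
  net$power_law_ok <- gate_ok
  note(sprintf("coexpression: culled %d -> %d genes; %d modules",
               length(common), length(cx$kept), attr(net$modules, "n_modules")))
  write_tsv(data.frame(gene_id = names(net$modules),
                       module = unname(net$modules)),
            file.path(out_dir, "coexpr_modules.tsv"))
  fit_tab <- do.call(rbind, lapply(names(gate_fits), function(l) {
    f <- gate_fits[[l]]
    data.frame(network = "coexpression", line = l, r_squared = f$r_squared,
               slope = f$slope, passes = f$passes, degenerate = f$degenerate)
  }))

  de <- differential_expression(ne$log2cpm[cx$kept, , drop = FALSE],
                                ne$meta$line)
  write_tsv(de, file.path(out_dir, "de.tsv"))

  enr <- list()
  if (net$power_law_ok) {
    hb <- hub_block(net, config)
    write_tsv(hb$table, file.path(out_dir, "connectivity.tsv"))
    write_tsv(hb$diff, file.path(out_dir, "diff_connectivity.tsv"))
    write_tsv(hb$comparison, file.path(out_dir, "connectivity_comparison.tsv"))
  } else {
    hb <- NULL
    note(paste("coexpression: scale-free fit FAILED;",
               "hub/connectivity analyses skipped"))
  }
  dw <- differential_wiring(ne$log2cpm[cx$kept, , drop = FALSE], ne$meta$line,
                            delta_threshold = config$delta_threshold,
                            n_perm = config$n_perm, seed = seeds[["dw"]])
  write_tsv(dw, file.path(out_dir, "dw.tsv"))
  note(sprintf("differential wiring: mean changed edges = %.2f",
               attr(dw, "mean_changed_edges")))

  safe_enrich <- function(modules, flagged, set_name) {
    if (all(modules == "grey")) {
      note(sprintf("enrichment (%s) skipped: no modules detected", set_name))
      return(NULL)
    }
    module_selection_impact(modules, flagged, alpha = config$protection_alpha,
                            set_name = set_name)
  }
  enr$de <- safe_enrich(net$modules, de$gene[de$fdr < config$fdr_alpha], "DE")
  enr$dw <- safe_enrich(net$modules, dw$gene[dw$fdr < config$fdr_alpha], "DW")
  if (!is.null(config$gene_sets)) {
    sets <- read_gmt(config$gene_sets)
    input_hashes$gene_sets <- unname(tools::md5sum(config$gene_sets))
    enr <- c(enr, lapply(names(sets), function(s)
      safe_enrich(net$modules, sets[[s]], s)))
  }

  # --- cosplicing ---------------------------------------------------------
  cosp <- NULL; ds <- NULL; dwc <- NULL
  if (!is.null(config$exon_counts)) {
    ect <- if (is.data.frame(config$exon_counts)) config$exon_counts
           else read_tsv(config$exon_counts)
    if (is.character(config$exon_counts))
      input_hashes$exon_counts <- unname(tools::md5sum(config$exon_counts))
    profiles <- suppressMessages(
      exon_proportions(ect, min_gene_count = config$min_gene_count))
    cosp_full <- suppressMessages(suppressWarnings(
      cosplicing_network(profiles, ne$meta, beta = beta,
                         min_module_size = config$min_module_size,
                         target_module_count = config$target_modules)))
    kcos <- Reduce(`+`, lapply(cosp_full$adjacency_by_line,
                               function(a) rowSums(a) - diag(a)))
    names(kcos) <- cosp_full$gene_ids
    kept_cos <- cull_network(kcos, config$keep_fraction)
    corr_cos <- lapply(cosp_full$corr_by_line,
                       function(m) m[kept_cos, kept_cos, drop = FALSE])
    cosp <- suppressWarnings(
      build_network(corr_cos, beta = beta,
                    min_module_size = config$min_module_size,
                    target_module_count = config$target_modules))
    # gate judged on the full cosplicing network, as for coexpression
    cosp$scale_free_by_line <- cosp_full$scale_free_by_line
    cosp$power_law_ok <- cosp_full$power_law_ok
    cosp$dist_by_gene <- cosp_full$dist_by_gene[kept_cos]
    note(sprintf("cosplicing: culled %d -> %d genes; %d modules",
                 length(cosp_full$gene_ids), length(kept_cos),
                 attr(cosp$modules, "n_modules")))
    write_tsv(data.frame(gene_id = names(cosp$modules),
                         module = unname(cosp$modules)),
              file.path(out_dir, "cosplice_modules.tsv"))
    fit_tab <- rbind(fit_tab, do.call(rbind,
      lapply(names(cosp$scale_free_by_line), function(l) {
        f <- cosp$scale_free_by_line[[l]]
        data.frame(network = "cosplicing", line = l, r_squared = f$r_squared,
                   slope = f$slope, passes = f$passes,
                   degenerate = f$degenerate)
      })))
    if (cosp$power_law_ok) {
      hbc <- hub_block(cosp, config)
      write_tsv(hbc$table, file.path(out_dir, "cosplice_connectivity.tsv"))
      write_tsv(hbc$comparison,
                file.path(out_dir, "cosplice_connectivity_comparison.tsv"))
    } else {
      hbc <- NULL
      note(paste("cosplicing: scale-free fit FAILED;",
                 "hub/connectivity analyses skipped"))
    }
    keep_names <- names(profiles)[names(profiles) %in% kept_cos]
    prof_kept <- structure(profiles[keep_names],
                           samples = attr(profiles, "samples"),
                           excluded = attr(profiles, "excluded"),
                           class = "exon_profiles")
    ds <- differential_splicing(prof_kept, ne$meta$line,
                                n_perm = config$n_perm, seed = seeds[["ds"]])
    write_tsv(ds, file.path(out_dir, "ds.tsv"))
    dwc <- differential_wiring_cosplicing(cosp$dist_by_gene, ne$meta$line,
                                          delta_threshold =
                                            config$delta_threshold,
                                          n_perm = config$n_perm,
                                          seed = seeds[["dw_cosplice"]])
    write_tsv(dwc, file.path(out_dir, "dw_cosplice.tsv"))
    enr$ds <- safe_enrich(cosp$modules,
                          ds$gene[!is.na(ds$fdr) & ds$fdr < config$fdr_alpha],
                          "DS")
  } else {
    note("cosplicing/splicing skipped: no exon counts supplied")
    hbc <- NULL
  }

  write_tsv(fit_tab, file.path(out_dir, "scale_free_fit.tsv"))
  enr_tab <- do.call(rbind, enr[!vapply(enr, is.null, logical(1))])
  if (!is.null(enr_tab))
    write_tsv(enr_tab, file.path(out_dir, "enrichment.tsv"))

  manifest <- list(package = "selnet",
                   parameters = config[!(names(config) %in%
                                           c("counts", "meta", "exon_counts",
                                             "gene_sets"))],
                   seed = config$seed,
                   stage_seeds = as.list(seeds),
                   input_hashes = input_hashes,
                   log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_report(out_dir, fdr_alpha = config$fdr_alpha)
  invisible(list(normalized = ne, network = net, de = de, dw = dw,
                 connectivity = hb, cosplicing = cosp, ds = ds,
                 dw_cosplicing = dwc,
                 cosplice_connectivity = if (exists("hbc")) hbc else NULL,
                 enrichment = enr_tab, manifest = manifest))
}

#' Summarize a pipeline run directory
#'
#' Reads the stage TSVs written by [run_pipeline()] and produces one tidy
#' summary table (`summary.tsv`) and a short human-readable `summary.txt`:
#' counts of significant DE/DW/DS genes, per-line mean connectivities, and
#' module enrichment/protection calls. Regeneration is idempotent; stages
#' missing from the run directory are reported as gaps.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @param fdr_alpha FDR threshold for the significant-gene counts.
#' @return Invisibly, the summary data frame.
#' @export
write_report <- function(run_dir, fdr_alpha = 0.05) {
  rows <- list()
  add <- function(stage, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, metric = metric,
                                             value = value)
  grab <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) read_tsv(p) else NULL
  }
  de <- grab("de.tsv")
  if (!is.null(de)) {
    add("de", "n_genes_tested", nrow(de))
    add("de", sprintf("n_signif_fdr_%g", fdr_alpha), sum(de$fdr < fdr_alpha))
    add("de", "n_signif_high_gt_low",
        sum(de$fdr < fdr_alpha & de$direction == "HIGH>LOW"))
    add("de", "n_signif_low_gt_high",
        sum(de$fdr < fdr_alpha & de$direction == "LOW>HIGH"))
  } else add("de", "missing", NA)
  for (nm in c(dw = "dw.tsv", ds = "ds.tsv", dw_cosplice = "dw_cosplice.tsv")) {
    tab <- grab(nm)
    stage <- sub("\\.tsv$", "", nm)
    if (!is.null(tab)) {
      add(stage, "n_genes_tested", sum(!is.na(tab$p)))
      add(stage, sprintf("n_signif_fdr_%g", fdr_alpha),
          sum(tab$fdr < fdr_alpha, na.rm = TRUE))
      if ("changed_edge_count" %in% names(tab))
        add(stage, "mean_changed_edges", mean(tab$changed_edge_count))
    } else add(stage, "missing", NA)
  }
  for (nm in c(connectivity = "connectivity_comparison.tsv",
               cosplice_connectivity =
                 "cosplice_connectivity_comparison.tsv")) {
    tab <- grab(nm)
    stage <- names(which(c(connectivity = "connectivity_comparison.tsv",
                           cosplice_connectivity =
                             "cosplice_connectivity_comparison.tsv") == nm))
    if (!is.null(tab)) {
      for (i in seq_len(nrow(tab))) {
        add(stage, sprintf("mean_%s_high", tab$scope[i]), tab$mean_high[i])
        add(stage, sprintf("mean_%s_low", tab$scope[i]), tab$mean_low[i])
      }
    } else add(stage, "missing_or_skipped", NA)
  }
  enr <- grab("enrichment.tsv")
  if (!is.null(enr)) {
    for (s in unique(enr$set_name)) {
      add("enrichment", sprintf("%s_enriched_modules", s),
          sum(enr$set_name == s & enr$call == "enriched"))
      add("enrichment", sprintf("%s_protected_modules", s),
          sum(enr$set_name == s & enr$call == "protected"))
    }
  }
  out <- do.call(rbind, rows)
  write_tsv(out, file.path(run_dir, "summary.tsv"))
  txt <- c("selnet pipeline summary",
           "=======================",
           sprintf("%-22s %-28s %s", out$stage, out$metric,
                   ifelse(is.na(out$value), "-",
                          format(out$value, digits = 6, trim = TRUE))))
  writeLines(txt, file.path(run_dir, "summary.txt"))
  invisible(out)
}
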