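# Synthetic two-line datasets with planted structure: modular negative-
# binomial gene counts, exon-usage tables with line-specific splicing shifts,
# and simulated bidirectional selective-breeding records. Every effect is
# recorded in a ground-truth object so downstream stages can be validated.

#' Simulation configuration
#'
#' Describes a two-line RNA-Seq study with planted network structure. The
#' defaults define the package's reference dataset: five modules of 200 genes,
#' 24 samples per line, moderate negative-binomial dispersion and a scaled-
#' down library size.
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of planted module sizes; genes beyond
#'   `sum(module_sizes)` are background (module 0).
#' @param n_samples_per_line samples per selection line (default 24).
#' @param within_module_corr target count-level Pearson correlation between
#'   same-module genes, in \[0, 1).
#' @param de_fraction fraction of genes with a planted expression difference.
#' @param de_log2fc planted log2 fold change (HIGH - LOW), split evenly in
#'   sign across the DE genes.
#' @param dw_gene_fraction fraction of modular genes with rewired factor
#'   loading in the HIGH line.
#' @param dw_delta_r target drop in same-module pairwise correlation for
#'   rewired genes (HIGH vs LOW), in \[0, 1\].
#' @param ds_gene_fraction fraction of genes with a planted splicing shift
#'   (exon simulator only).
#' @param ds_delta_prop total L1 distance between the line-mean exon
#'   proportion vectors of a planted splicing gene, in \[0, 2).
#' @param exons_per_gene length-2 integer range of exons per gene.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param library_size_mean nominal library size (log-normal across samples).
#' @param seed integer seed fixing all outputs bit-for-bit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       module_sizes = rep(200L, 5),
                       n_samples_per_line = 24,
                       within_module_corr = 0.6,
                       de_fraction = 0.05,
                       de_log2fc = 2,
                       dw_gene_fraction = 0.05,
                       dw_delta_r = 0.7,
                       ds_gene_fraction = 0.05,
                       ds_delta_prop = 0.3,
                       exons_per_gene = c(3L, 8L),
                       nb_dispersion = 0.05,
                       library_size_mean = 150000,
                       seed = 1) {
  check_scalar(n_genes, "n_genes", lo = 10)
  if (sum(module_sizes) > n_genes)
    abort("sum(module_sizes) = %d exceeds n_genes = %d",
          sum(module_sizes), n_genes)
  check_scalar(within_module_corr, "within_module_corr", lo = 0, hi = 1,
               open_hi = TRUE)
  check_scalar(de_fraction, "de_fraction", lo = 0, hi = 1)
  check_scalar(dw_gene_fraction, "dw_gene_fraction", lo = 0, hi = 1)
  check_scalar(ds_gene_fraction, "ds_gene_fraction", lo = 0, hi = 1)
  check_scalar(dw_delta_r, "dw_delta_r", lo = 0, hi = 1)
  check_scalar(ds_delta_prop, "ds_delta_prop", lo = 0, hi = 2, open_hi = TRUE)
  check_scalar(n_samples_per_line, "n_samples_per_line", lo = 3)
  check_scalar(nb_dispersion, "nb_dispersion", lo = 1e-8)
  if (length(exons_per_gene) != 2L || exons_per_gene[1] < 2L ||
      exons_per_gene[2] < exons_per_gene[1])
    abort("exons_per_gene must be an increasing range with minimum >= 2")
  structure(list(n_genes = as.integer(n_genes),
                 n_modules = length(module_sizes),
                 module_sizes = as.integer(module_sizes),
                 n_samples_per_line = as.integer(n_samples_per_line),
                 within_module_corr = within_module_corr,
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 dw_gene_fraction = dw_gene_fraction, dw_delta_r = dw_delta_r,
                 ds_gene_fraction = ds_gene_fraction,
                 ds_delta_prop = ds_delta_prop,
                 exons_per_gene = as.integer(exons_per_gene),
                 nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# biological log2 noise sd shared by all genes
SIM_LOG2_NOISE_SD <- 0.3
# log sd of library sizes
SIM_LIBSIZE_SDLOG <- 0.3
# compensation for count-layer attenuation of the latent factor: the
# log2(count + 1) transform and negative-binomial tails shrink realized
# correlations below the delta-method prediction; this one-time numerical
# calibration restores a realized within-module correlation of about
# within_module_corr for unit-loading gene pairs
SIM_ATTEN_COMP <- 1.5

# deterministic per-run gene architecture shared by the count and exon
# simulators: module labels, planted gene sets, baseline expression
sim_architecture <- function(config) {
  seeds <- stage_seeds(config$seed,
                       c("genes", "truth", "factors", "libs", "noise",
                         "counts", "exon_base", "exon_noise", "exon_counts"))
  G <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(G))
  module <- integer(G)
  pos <- 1L
  for (m in seq_along(config$module_sizes)) {
    module[pos:(pos + config$module_sizes[m] - 1L)] <- m
    pos <- pos + config$module_sizes[m]
  }

  set.seed(seeds[["genes"]])
  b <- stats::runif(G, 5, 10)                # log2 baseline count
  loading_scale <- stats::runif(G, 0.75, 1)
  # one planted high-loading hub per module: at study-scale sample sizes a
  # gene's connectivity rank is noisy, so the hub loading is set well above
  # the module range to make the planted hub decisively the most connected
  for (m in seq_along(config$module_sizes))
    loading_scale[match(m, module)] <- 2

  set.seed(seeds[["truth"]])
  n_de <- round(config$de_fraction * G)
  de_genes <- sort(sample.int(G, n_de))
  de_sign <- rep_len(c(1, -1), n_de)
  modular <- which(module > 0)
  n_dw <- round(config$dw_gene_fraction * length(modular))
  dw_genes <- sort(sample(modular, n_dw))
  # rewired genes carry the full module loading so the planted edge change
  # realizes the requested dw_delta_r
  loading_scale[dw_genes] <- 1
  n_ds <- round(config$ds_gene_fraction * G)
  ds_genes <- sort(sample.int(G, n_ds))

  list(seeds = seeds, gene_ids = gene_ids, module = module, b = b,
       loading_scale = loading_scale, de_genes = de_genes, de_sign = de_sign,
       dw_genes = dw_genes, ds_genes = ds_genes)
}

# module factors: iid Gaussian scores orthogonalized across the pooled
# samples, so planted modules are mutually uncorrelated by construction and
# chance factor alignment cannot merge two modules in an unsigned network
sim_module_factors <- function(n_modules, n_samples) {
  if (n_modules == 0L) return(matrix(numeric(0), 0, n_samples))
  m <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules)
  m <- scale(m, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(m))
  t(q) * sqrt(n_samples - 1)
}

sim_sample_frame <- function(config) {
  S <- 2L * config$n_samples_per_line
  data.frame(sample_id = sprintf("s%02d", seq_len(S)),
             line = rep(c("HIGH", "LOW"), each = config$n_samples_per_line),
             region = "SIM", stringsAsFactors = FALSE)
}

#' Simulate a two-line gene-level count dataset
#'
#' Counts are negative binomial around a log-normal signal with a per-module
#' latent Gaussian factor: gene g in module m has log2 mean
#' `b_g + lambda_g * z_{m,s} + e_{gs}` plus line effects, scaled by a
#' log-normally drawn library size. The factor loading `lambda_g` is
#' calibrated against the total non-factor variance (biological log2 noise
#' plus the delta-method negative-binomial contribution) so that the
#' count-level correlation between two average same-module genes is
#' approximately `within_module_corr`. Planted effects:
#' * DE genes get +/- `de_log2fc`/2 per line (log2fc HIGH - LOW =
#'   +/- `de_log2fc`);
#' * DW genes have their loading multiplied, in the HIGH line only, by
#'   `(w - dw_delta_r)/w` (attenuation, or sign flip when `dw_delta_r > w`),
#'   so same-module edge correlations drop by about `dw_delta_r`;
#' * one gene per module carries the maximal loading (a planted hub).
#'
#' @param config a [sim_config()].
#' @return list: `data` (a [count_matrix()]) and `truth` (list with
#'   `module_labels` (named integer, 0 = background), `de_genes`, `dw_genes`,
#'   `ds_genes`, `hub_genes`, `config`).
#' @export
simulate_count_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- sim_architecture(config)
  G <- config$n_genes
  meta <- sim_sample_frame(config)
  S <- nrow(meta)
  w <- config$within_module_corr
  disp <- config$nb_dispersion

  # calibrated loading: log2-scale noise includes biology + NB sampling
  mu_bar <- 2^arch$b
  v_noise <- (SIM_LOG2_NOISE_SD^2 + (1 / mu_bar + disp) / log(2)^2) *
    SIM_ATTEN_COMP
  lambda <- if (w > 0) sqrt(w / (1 - w) * v_noise) * arch$loading_scale
            else numeric(G)

  set.seed(arch$seeds[["factors"]])
  z <- sim_module_factors(config$n_modules, S)
  set.seed(arch$seeds[["libs"]])
  lib <- stats::rlnorm(S, log(config$library_size_mean), SIM_LIBSIZE_SDLOG)
  set.seed(arch$seeds[["noise"]])
  e <- matrix(stats::rnorm(G * S, 0, SIM_LOG2_NOISE_SD), G, S)

  is_high <- meta$line == "HIGH"
  eta <- arch$b + e
  # line-specific loading: rewired genes attenuated/flipped in HIGH only
  c_high <- rep(1, G)
  if (w > 0 && length(arch$dw_genes))
    c_high[arch$dw_genes] <- (w - config$dw_delta_r) / w
  for (m in seq_len(config$n_modules)) {
    idx <- which(arch$module == m)
    load_line <- outer(lambda[idx], rep(1, S))
    load_line[, is_high] <- load_line[, is_high] * c_high[idx]
    eta[idx, ] <- eta[idx, ] + load_line * matrix(z[m, ], length(idx), S,
                                                 byrow = TRUE)
  }
  if (length(arch$de_genes)) {
    half <- config$de_log2fc / 2 * arch$de_sign
    eta[arch$de_genes, is_high] <- eta[arch$de_genes, is_high] + half
    eta[arch$de_genes, !is_high] <- eta[arch$de_genes, !is_high] - half
  }
  mu <- 2^eta * rep(lib / config$library_size_mean, each = G)

  set.seed(arch$seeds[["counts"]])
  counts <- matrix(stats::rnbinom(G * S, mu = mu, size = 1 / disp), G, S,
                   dimnames = list(arch$gene_ids, meta$sample_id))
  truth <- list(module_labels = stats::setNames(arch$module, arch$gene_ids),
                de_genes = arch$gene_ids[arch$de_genes],
                dw_genes = arch$gene_ids[arch$dw_genes],
                ds_genes = arch$gene_ids[arch$ds_genes],
                hub_genes = arch$gene_ids[match(seq_len(config$n_modules),
                                                arch$module)],
                config = config)
  list(data = count_matrix(counts, meta), truth = truth)
}

# logit-scale splicing factor strength relative to the jitter, mirroring the
# coexpression calibration so within_module_corr also governs cosplicing
SIM_SPLICE_JITTER_SD <- 0.15
# compensation for the attenuation between logit-scale usage shifts and the
# Mantel correlation of proportion-space distance matrices (softmax squashing,
# multinomial counting noise); numerically calibrated once so unit-loading
# same-module gene pairs reach a Mantel correlation of about
# within_module_corr
SIM_SPLICE_COMP <- 2.5

#' Simulate a two-line exon-level count dataset
#'
#' Each gene gets E exons (uniform in `exons_per_gene`) and per-sample exon
#' counts are multinomial draws from sample-specific usage vectors: softmax of
#' log base proportions plus a per-module latent splicing factor (genes in the
#' same planted module share sample-level usage shifts, giving Mantel-
#' correlated distance structure) plus logit-normal jitter. Planted splicing
#' (DS) genes have uniform base proportions and line-shifted means: a mass of
#' `ds_delta_prop`/2 is moved from exon 2 to exon 1 in the HIGH line and the
#' reverse in the LOW line, so the line-mean proportion vectors differ by
#' `ds_delta_prop` in total L1 (and the exon-equal splicing statistic by
#' about `ds_delta_prop`/E). Infeasible shifts (exons cannot absorb the mass)
#' are rejected. Gene totals are negative binomial.
#'
#' @param config a [sim_config()].
#' @return list: `data` (data frame: `gene_id`, `exon_id`, sample columns),
#'   `meta` (sample metadata) and `truth` (as in
#'   [simulate_count_dataset()], with `n_exons` added).
#' @export
simulate_exon_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- sim_architecture(config)
  G <- config$n_genes
  meta <- sim_sample_frame(config)
  S <- nrow(meta)
  is_high <- meta$line == "HIGH"
  w <- config$within_module_corr
  delta <- config$ds_delta_prop

  set.seed(arch$seeds[["exon_base"]])
  e_range <- seq.int(config$exons_per_gene[1], config$exons_per_gene[2])
  E <- e_range[sample.int(length(e_range), G, replace = TRUE)]
  base <- lapply(seq_len(G), function(g) {
    p <- stats::rgamma(E[g], shape = 5)
    p / sum(p)
  })
  # planted DS genes: uniform base, mass delta/2 moved between exons 1 and 2
  ds_idx <- arch$ds_genes
  if (length(ds_idx) && delta > 0) {
    shift <- delta / 4                       # per-line half-shift
    for (g in ds_idx) {
      if (1 / E[g] - shift < 0 || 1 / E[g] + shift > 1)
        abort("ds_delta_prop = %g infeasible for a %d-exon gene", delta, E[g])
      base[[g]] <- rep(1 / E[g], E[g])
    }
  }
  # per-gene splicing contrast direction (which exons the module factor moves)
  contrast <- lapply(seq_len(G), function(g) {
    d <- stats::rnorm(E[g])
    d - mean(d)
  })
  gene_mean <- 2^stats::runif(G, 6, 9)       # expected gene total per sample

  set.seed(arch$seeds[["factors"]])          # same module factors as counts
  z <- sim_module_factors(config$n_modules, S)
  h <- if (w > 0)
    SIM_SPLICE_JITTER_SD * sqrt(w / (1 - w)) * SIM_SPLICE_COMP else 0

  set.seed(arch$seeds[["exon_noise"]])
  jitter <- lapply(seq_len(G), function(g)
    matrix(stats::rnorm(S * E[g], 0, SIM_SPLICE_JITTER_SD), S, E[g]))

  set.seed(arch$seeds[["exon_counts"]])
  tot <- matrix(stats::rnbinom(G * S, mu = rep(gene_mean, S),
                               size = 1 / config$nb_dispersion), G, S)
  rows <- vector("list", G)
  for (g in seq_len(G)) {
    pb <- matrix(base[[g]], S, E[g], byrow = TRUE)
    if (g %in% ds_idx && delta > 0) {
      shift <- delta / 4
      pb[is_high, 1] <- pb[is_high, 1] + shift
      pb[is_high, 2] <- pb[is_high, 2] - shift
      pb[!is_high, 1] <- pb[!is_high, 1] - shift
      pb[!is_high, 2] <- pb[!is_high, 2] + shift
    }
    logits <- log(pb) + jitter[[g]]
    m <- arch$module[g]
    if (m > 0 && h > 0) {
      # splicing-rewired genes: factor loading attenuated/flipped in HIGH
      load <- rep(h * arch$loading_scale[g], S)
      if (g %in% arch$dw_genes)
        load[is_high] <- load[is_high] * (w - config$dw_delta_r) / w
      logits <- logits + outer(z[m, ] * load, contrast[[g]])
    }
    p <- exp(logits)
    p <- p / rowSums(p)
    cnt <- vapply(seq_len(S), function(s)
      as.numeric(stats::rmultinom(1, tot[g, s], p[s, ])), numeric(E[g]))
    rows[[g]] <- data.frame(gene_id = arch$gene_ids[g],
                            exon_id = sprintf("e%02d", seq_len(E[g])),
                            cnt, stringsAsFactors = FALSE)
  }
  ect <- do.call(rbind, rows)
  names(ect)[-(1:2)] <- meta$sample_id
  truth <- list(module_labels = stats::setNames(arch$module, arch$gene_ids),
                de_genes = arch$gene_ids[arch$de_genes],
                dw_genes = arch$gene_ids[arch$dw_genes],
                ds_genes = arch$gene_ids[arch$ds_genes],
                n_exons = stats::setNames(E, arch$gene_ids),
                config = config)
  list(data = ect, meta = meta, truth = truth)
}

#' Simulate a selective-breeding experiment
#'
#' One line bred by truncation selection for `n_generations` offspring
#' generations under the breeder's equation: the next generation's expected
#' mean is the current mean plus `true_h2` times the realized selection
#' differential. With `sampling = TRUE` (default) individuals are drawn
#' (phenotype = generation mean + Normal(0, phenotype_sd)) and all recorded
#' means are realized sample means; with `sampling = FALSE` the records are
#' exact expectations, using the normal truncation selection intensity
#' `i = dnorm(qnorm(1 - f))/f` for the selected-parent mean.
#'
#' @param true_h2 narrow-sense heritability in \[0, 1\].
#' @param n_generations number of offspring generations (default 4).
#' @param founder_n founder population size (default 120).
#' @param selected_fraction fraction of each generation bred, in (0, 1).
#' @param phenotype_sd phenotypic standard deviation (trait units).
#' @param n_offspring phenotyped offspring per generation (default 60).
#' @param direction +1 selects upward (high line), -1 downward.
#' @param founder_mean founder trait mean (default 3, trait units).
#' @param sampling draw individuals (TRUE) or record exact expectations.
#' @param seed integer seed.
#' @return data frame of class `selection_records`: `generation`,
#'   `population_mean`, `selected_parent_mean`, `offspring_mean` (row t
#'   describes generation t and the mean of its offspring, generation t+1).
#' @export
simulate_breeding <- function(true_h2, n_generations = 4, founder_n = 120,
                              selected_fraction = 26 / 120, phenotype_sd = 2,
                              n_offspring = 60, direction = 1,
                              founder_mean = 3, sampling = TRUE, seed = 1) {
  check_scalar(true_h2, "true_h2", lo = 0, hi = 1)
  check_scalar(selected_fraction, "selected_fraction", lo = 0, hi = 1,
               open_lo = TRUE, open_hi = TRUE)
  check_scalar(n_generations, "n_generations", lo = 1)
  check_scalar(phenotype_sd, "phenotype_sd", lo = 0)
  if (floor(selected_fraction * founder_n) < 1)
    abort("founder_n = %d too small to select a fraction of %g", founder_n,
          selected_fraction)
  direction <- sign(direction)
  set.seed(as.integer(seed))
  rows <- vector("list", n_generations)
  if (sampling) {
    pheno <- stats::rnorm(founder_n, founder_mean, phenotype_sd)
    for (t in seq_len(n_generations)) {
      n_sel <- max(1L, floor(selected_fraction * length(pheno)))
      sel <- sort(pheno, decreasing = direction > 0)[seq_len(n_sel)]
      pm <- mean(pheno)
      sm <- mean(sel)
      mu_next <- pm + true_h2 * (sm - pm)
      offspring <- stats::rnorm(n_offspring, mu_next, phenotype_sd)
      rows[[t]] <- data.frame(generation = t, population_mean = pm,
                              selected_parent_mean = sm,
                              offspring_mean = mean(offspring))
      pheno <- offspring
    }
  } else {
    intensity <- stats::dnorm(stats::qnorm(1 - selected_fraction)) /
      selected_fraction
    pm <- founder_mean
    for (t in seq_len(n_generations)) {
      sm <- pm + direction * intensity * phenotype_sd
      mu_next <- pm + true_h2 * (sm - pm)
      rows[[t]] <- data.frame(generation = t, population_mean = pm,
                              selected_parent_mean = sm,
                              offspring_mean = mu_next)
      pm <- mu_next
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("selection_records", class(out))
  out
}
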