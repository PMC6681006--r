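# Differential expression, wiring and splicing, with permutation conventions.

test_that("differential expression handles forced cases and direction", {
  set.seed(5)
  x <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  line <- rep(c("HIGH", "LOW"), each = 6)
  x["g1", ] <- 3                       # identical in both lines
  x["g2", line == "HIGH"] <- x["g2", line == "HIGH"] + 5
  de <- differential_expression(x, line)
  expect_equal(de$log2fc[de$gene == "g1"], 0)
  expect_equal(de$p[de$gene == "g1"], 1)
  expect_true(de$untestable[de$gene == "g1"])
  expect_lt(de$p[de$gene == "g2"], 1e-4)
  expect_equal(de$direction[de$gene == "g2"], "HIGH>LOW")
  # Welch test agrees with stats::t.test gene by gene
  for (g in c("g3", "g7")) {
    tt <- t.test(x[g, line == "HIGH"], x[g, line == "LOW"])
    expect_equal(de$p[de$gene == g], tt$p.value, tolerance = 1e-12)
    expect_equal(de$statistic[de$gene == g], unname(tt$statistic),
                 tolerance = 1e-12)
  }
  # FDR never below raw p; direction consistent with the sign of log2fc
  expect_true(all(de$fdr >= de$p - 1e-15))
  expect_true(all((de$log2fc >= 0) == (de$direction == "HIGH>LOW")))
})

test_that("differential expression is calibrated under a permuted null", {
  sim <- ref_sim()
  ne <- ref_norm()
  set.seed(77)
  shuffled <- sample(ne$meta$line)
  de <- differential_expression(ne$log2cpm, shuffled)
  # p-values approximately uniform: modest bounds on two quantiles
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(de$p < 0.5) - 0.5), 0.08)
  expect_lte(mean(de$fdr < 0.05), 0.05)
})

test_that("changed-edge counting is exact and symmetric", {
  ch <- matrix(c(1, .9, .2,
                 .9, 1, .2,
                 .2, .2, 1), 3, byrow = TRUE)
  cl <- matrix(c(1, .1, .2,
                 .1, 1, .2,
                 .2, .2, 1), 3, byrow = TRUE)
  cnt <- selnet:::dw_counts(ch, cl, 0.5)
  expect_equal(cnt, c(1, 1, 0))
  # every changed edge is counted once from each endpoint
  set.seed(11)
  a <- cor(matrix(rnorm(200), 20, 10)); b <- cor(matrix(rnorm(200), 20, 10))
  cnt2 <- selnet:::dw_counts(a, b, 0.5)
  m <- abs(a - b) >= 0.5; diag(m) <- FALSE
  expect_equal(sum(cnt2), 2 * sum(m[upper.tri(m)]))
})

test_that("differential wiring separates planted rewired genes from the null", {
  cfg <- sim_config(seed = 4, n_genes = 200, module_sizes = 80L,
                    de_fraction = 0, ds_gene_fraction = 0,
                    dw_gene_fraction = 0.25)
  sim <- simulate_count_dataset(cfg)
  ne <- filter_by_cpm(upper_quartile_normalize(sim$data))
  dw <- differential_wiring(ne$log2cpm, ne$meta$line, n_perm = 300, seed = 9)
  is_dw <- dw$gene %in% sim$truth$dw_genes
  # planted genes carry far more changed edges and much smaller p
  expect_gt(median(dw$changed_edge_count[is_dw]),
            4 * median(dw$changed_edge_count[!is_dw]))
  expect_lt(median(dw$p[is_dw]), 0.01)
  # permutation p-values never reach 0 and respect the add-one floor
  expect_true(all(dw$p >= 1 / 301 - 1e-15))
  expect_true(all(dw$p <= 1))
  # genes whose observed count beats every permutation sit exactly at the floor
  at_floor <- dw$n_as_extreme == 0
  expect_true(any(at_floor))
  expect_equal(unique(dw$p[at_floor]), 1 / 301, tolerance = 1e-15)
  # partners are symmetric: every changed edge names both endpoints
  partners <- attr(dw, "partners")
  for (g in names(partners)) {
    for (p in partners[[g]]) expect_true(g %in% partners[[p]])
  }
  expect_error(differential_wiring(ne$log2cpm, ne$meta$line,
                                   delta_threshold = 1.5), "delta_threshold")
})

test_that("cosplicing wiring sees zero changed edges for mirrored lines", {
  # construct per-gene distance matrices identical in both line blocks
  set.seed(13)
  n <- 6                                  # samples per line
  dists <- lapply(1:5, function(g) {
    x <- matrix(runif(n * 3), n)
    d1 <- as.matrix(dist(x))
    full <- matrix(0, 2 * n, 2 * n)
    full[1:n, 1:n] <- d1
    full[(n + 1):(2 * n), (n + 1):(2 * n)] <- d1   # LOW mirrors HIGH
    cross <- as.matrix(dist(rbind(x, x)))[1:n, (n + 1):(2 * n)]
    full[1:n, (n + 1):(2 * n)] <- cross
    full[(n + 1):(2 * n), 1:n] <- t(cross)
    dimnames(full) <- list(paste0("s", 1:(2 * n)), paste0("s", 1:(2 * n)))
    full
  })
  names(dists) <- paste0("g", 1:5)
  line <- rep(c("HIGH", "LOW"), each = n)
  dwc <- suppressWarnings(differential_wiring_cosplicing(dists, line,
                                                         n_perm = 100,
                                                         seed = 3))
  expect_equal(dwc$changed_edge_count, rep(0L, 5), ignore_attr = TRUE)
  expect_true(all(dwc$p >= 1 / 101 - 1e-15))
})

test_that("cosplicing wiring recovers planted splicing-rewired genes", {
  cfg <- sim_config(seed = 4, n_genes = 120, module_sizes = 60L,
                    exons_per_gene = c(3L, 6L), de_fraction = 0,
                    ds_gene_fraction = 0, dw_gene_fraction = 0.25)
  es <- simulate_exon_dataset(cfg)
  prof <- suppressMessages(exon_proportions(es$data))
  dists <- lapply(prof, gene_sample_distance)
  dists <- dists[!vapply(dists, is.null, logical(1))]
  dwc <- differential_wiring_cosplicing(dists, es$meta$line, n_perm = 300,
                                        seed = 9)
  is_dw <- dwc$gene %in% es$truth$dw_genes
  expect_gte(mean(dwc$fdr[is_dw] < 0.05), 0.8)
})

test_that("the splicing statistic weighs exons equally and is invariant", {
  # two-exon gene with line means (0.8, 0.2) vs (0.2, 0.8): D = 0.6
  mk_profile <- function(p_by_sample, mask = NULL) {
    rownames(p_by_sample) <- paste0("s", seq_len(nrow(p_by_sample)))
    list(proportions = p_by_sample,
         mask = mask %||% setNames(rep(TRUE, nrow(p_by_sample)),
                                   rownames(p_by_sample)),
         exon_ids = paste0("e", seq_len(ncol(p_by_sample))))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  n <- 12
  ph <- matrix(rep(c(0.8, 0.2), each = n), n)
  pl <- matrix(rep(c(0.2, 0.8), each = n), n)
  prof <- structure(list(gX = mk_profile(rbind(ph, pl))),
                    samples = paste0("s", 1:(2 * n)), excluded = character(0),
                    class = "exon_profiles")
  line <- rep(c("HIGH", "LOW"), each = n)
  ds <- differential_splicing(prof, line, n_perm = 200, seed = 1)
  expect_equal(ds$observed_stat, 0.6, tolerance = 1e-12)
  expect_equal(ds$p, 1 / 201, tolerance = 1e-12)   # beats every permutation

  # identical line means: statistic 0, p near 1
  prof0 <- structure(list(gX = mk_profile(rbind(ph, ph))),
                     samples = paste0("s", 1:(2 * n)),
                     excluded = character(0), class = "exon_profiles")
  ds0 <- differential_splicing(prof0, line, n_perm = 200, seed = 1)
  expect_equal(ds0$observed_stat, 0, tolerance = 1e-12)
  expect_gt(ds0$p, 0.99)

  # invariance to exon relabeling and to sample order
  noisy <- rbind(ph, pl) + matrix(runif(2 * n * 2, 0, 0.05), 2 * n)
  noisy <- noisy / rowSums(noisy)
  prof1 <- structure(list(gX = mk_profile(noisy)),
                     samples = paste0("s", 1:(2 * n)),
                     excluded = character(0), class = "exon_profiles")
  prof2 <- structure(list(gX = mk_profile(noisy[, 2:1])),
                     samples = paste0("s", 1:(2 * n)),
                     excluded = character(0), class = "exon_profiles")
  ds1 <- differential_splicing(prof1, line, n_perm = 100, seed = 2)
  ds2 <- differential_splicing(prof2, line, n_perm = 100, seed = 2)
  expect_equal(ds1$observed_stat, ds2$observed_stat, tolerance = 1e-12)
  expect_equal(ds1$p, ds2$p, tolerance = 1e-12)
  perm <- sample(2 * n)
  prof3 <- structure(list(gX = mk_profile(noisy[perm, ])),
                     samples = paste0("s", 1:(2 * n))[perm],
                     excluded = character(0), class = "exon_profiles")
  ds3 <- differential_splicing(prof3, line[perm], n_perm = 100, seed = 2)
  expect_equal(ds3$observed_stat, ds1$observed_stat, tolerance = 1e-12)
})

test_that("planted splicing shifts are detected with calibrated nulls", {
  es <- ref_exon()
  prof <- ref_profiles()
  ds <- differential_splicing(prof, es$meta$line, n_perm = 1000, seed = 3)
  is_ds <- ds$gene %in% es$truth$ds_genes
  expect_gte(mean(ds$fdr[is_ds] < 0.05), 0.8)
  expect_lte(mean(ds$fdr[!is_ds] < 0.05, na.rm = TRUE), 0.05)
})
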