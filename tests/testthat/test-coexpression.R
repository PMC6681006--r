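# Correlation, adjacency, scale-free fit, TOM, consensus, module detection.

make_norm <- function(mat, lines) {
  structure(list(log2cpm = mat, cpm = 2^mat,
                 meta = data.frame(sample_id = colnames(mat), line = lines,
                                   region = "x")),
            class = "normalized_expression")
}

test_that("correlation matrix matches the direct formula and handles edge cases", {
  set.seed(7)
  mat <- matrix(rnorm(4 * 6), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  ne <- make_norm(mat, rep("HIGH", 6))
  r <- correlation_matrix(ne, "HIGH")
  expect_equal(r, oracle_corr_matrix(mat), tolerance = 1e-12)
  expect_true(all(abs(r) <= 1))
  expect_equal(diag(r), setNames(rep(1, 4), rownames(mat)))

  # duplicated gene and a negated gene
  mat2 <- rbind(mat, dup = mat[1, ], neg = -mat[1, ])
  r2 <- correlation_matrix(make_norm(mat2, rep("HIGH", 6)), "HIGH")
  expect_equal(r2["g1", "dup"], 1, tolerance = 1e-12)
  expect_equal(r2["g1", "neg"], -1, tolerance = 1e-12)

  # permuting sample order leaves the matrix unchanged
  perm <- c(4, 1, 6, 3, 2, 5)
  r3 <- correlation_matrix(make_norm(mat[, perm], rep("HIGH", 6)), "HIGH")
  expect_equal(r3, r, tolerance = 1e-12)

  # fewer than 3 samples in the line errors; zero-variance genes are dropped
  expect_error(correlation_matrix(make_norm(mat[, 1:2], rep("HIGH", 2)),
                                  "HIGH"), "3 samples")
  mat4 <- rbind(mat, flat = rep(1, 6))
  expect_warning(r4 <- correlation_matrix(make_norm(mat4, rep("HIGH", 6)),
                                          "HIGH"), "zero-variance")
  expect_false("flat" %in% rownames(r4))
})

test_that("adjacency is bounded and monotone decreasing in beta", {
  set.seed(1)
  r <- cor(matrix(rnorm(80), 10, 8))
  a4 <- adjacency_matrix(r, 4)
  a8 <- adjacency_matrix(r, 8)
  expect_true(all(a4 >= 0 & a4 <= 1))
  expect_true(all(a8 <= a4 + 1e-15))      # raising beta never increases entries
  expect_equal(diag(a8), rep(1, 8))
  expect_error(adjacency_matrix(r, 0.5), "beta")
})

test_that("TOM matches a triple-loop oracle and is bounded", {
  set.seed(3)
  r <- cor(matrix(rnorm(30 * 12), 12, 30))
  adj <- adjacency_matrix(r, 6)
  dimnames(adj) <- list(paste0("g", 1:30), paste0("g", 1:30))
  tom <- tom_similarity(adj)
  expect_equal(tom, oracle_tom(adj), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 30))
})

test_that("consensus is the minimum of quantile-scaled TOMs", {
  set.seed(4)
  mk <- function() {
    r <- cor(matrix(rnorm(5 * 20), 20, 5))
    a <- adjacency_matrix(r, 4)
    dimnames(a) <- list(paste0("g", 1:5), paste0("g", 1:5))
    tom_similarity(a)
  }
  t1 <- mk(); t2 <- mk()
  cons <- consensus_network(list(HIGH = t1, LOW = t2))
  # consensus never exceeds either scaled matrix
  expect_true(all(cons$consensus <= cons$scaled$HIGH + 1e-15))
  expect_true(all(cons$consensus <= cons$scaled$LOW + 1e-15))
  # the scaling exponent aligns the 0.95 upper-triangle quantiles
  q <- function(m) quantile(m[upper.tri(m)], 0.95, names = FALSE)
  expect_equal(q(t2)^cons$exponents[["LOW"]], q(t1), tolerance = 1e-12)
  # hand-checked scaling: exponent log(q_ref)/log(q_other), then pmin
  expo <- log(q(t1)) / log(q(t2))
  expect_equal(cons$consensus, pmin(t1, t2^expo), tolerance = 1e-12)

  # identical inputs: consensus equals the common TOM
  cons2 <- consensus_network(list(HIGH = t1, LOW = t1))
  expect_equal(cons2$consensus, t1, tolerance = 1e-12)

  expect_error(consensus_network(list(t1, t2[c(2, 1, 3:5), c(2, 1, 3:5)])),
               "same genes")
})

test_that("scale-free fit passes power-law connectivity and fails degenerate input", {
  set.seed(8)
  k_pl <- (1 - runif(3000))^(-1 / 1.5)        # Pareto tail, exponent 2.5
  fit <- scale_free_fit(k = k_pl)
  expect_true(fit$passes)
  expect_gt(fit$r_squared, 0.8)
  expect_lt(fit$slope, 0)

  # equal-degree input: point-mass P(k), explicit degenerate failure
  fit2 <- scale_free_fit(k = rep(5, 500))
  expect_false(fit2$passes)
  expect_true(fit2$degenerate)
  expect_equal(fit2$r_squared, 0)
})

test_that("soft power selection returns the smallest passing beta or warns", {
  # identity correlation: no structure, nothing passes
  r_id <- diag(1, 50)
  dimnames(r_id) <- list(paste0("g", 1:50), paste0("g", 1:50))
  expect_warning(p <- pick_soft_power(r_id), "no candidate")
  expect_true(p$warned)
  expect_false(any(p$fits$passes))

  # block-structured data from the generator: some beta in the grid passes,
  # and the chosen beta is the smallest passing one
  cfgb <- sim_config(seed = 3, n_genes = 400, module_sizes = rep(80L, 2))
  neb <- filter_by_cpm(upper_quartile_normalize(simulate_count_dataset(cfgb)$data))
  r_blk <- correlation_matrix(neb, "HIGH")
  p2 <- pick_soft_power(r_blk)
  expect_false(p2$warned)
  expect_true(any(p2$fits$passes))
  expect_equal(p2$beta, min(p2$fits$beta[p2$fits$passes]))
})

test_that("module detection recovers planted modules and leaves noise grey", {
  net <- ref_network()
  truth <- ref_sim()$truth$module_labels[names(net$modules)]
  expect_gte(adjusted_rand(net$modules, truth), 0.9)
  expect_equal(attr(net$modules, "n_modules"), 5L)
  # labels are colors; grey is reserved for unassigned
  expect_true(all(net$modules %in% c("turquoise", "blue", "brown", "yellow",
                                     "green", "grey")))

  # structureless data: no module survives the validity stage
  cfg0 <- sim_config(seed = 5, within_module_corr = 0, de_fraction = 0,
                     dw_gene_fraction = 0, n_genes = 300,
                     module_sizes = integer(0))
  ne0 <- filter_by_cpm(upper_quartile_normalize(simulate_count_dataset(cfg0)$data))
  net0 <- suppressWarnings(coexpression_network(ne0, min_module_size = 50,
                                                target_module_count = 5))
  expect_gt(mean(net0$modules == "grey"), 0.9)

  # fewer genes than the size floor: one module plus a warning
  cons_small <- diag(1, 10)
  dimnames(cons_small) <- list(paste0("g", 1:10), paste0("g", 1:10))
  expect_warning(m <- detect_modules(cons_small, min_module_size = 100),
                 "fewer genes")
  expect_equal(attr(m, "n_modules"), 1L)
})
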