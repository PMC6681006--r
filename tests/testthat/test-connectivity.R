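# Leaf culling, connectivity profiles, hub calls, between-line comparisons.

star_adjacency <- function(n = 6) {
  a <- matrix(0, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  a[1, -1] <- a[-1, 1] <- 1
  diag(a) <- 1
  a
}

test_that("culling retains the top of the cumulative connectivity", {
  k <- c(a = 10, b = 5, c = 3, d = 1, e = 1)
  expect_identical(cull_network(k, 0.9), c("a", "b", "c"))
  # equal connectivity: exactly 90 of 100 genes retained
  keq <- setNames(rep(2, 100), sprintf("g%03d", 1:100))
  expect_length(cull_network(keq, 0.9), 90)
  # keep_fraction 1 is the identity (as a set)
  expect_setequal(cull_network(k, 1), names(k))
  expect_error(cull_network(k, 0), "keep_fraction")
  expect_error(cull_network(k, 1.2), "keep_fraction")
  # property: retained genes always carry at least the requested share
  set.seed(10)
  for (i in 1:20) {
    kr <- setNames(rexp(50), paste0("g", 1:50))
    kept <- cull_network(kr, 0.9)
    expect_gte(sum(kr[kept]), 0.9 * sum(kr) - 1e-9)
  }
})

test_that("connectivity profiles match hand arithmetic", {
  a <- star_adjacency(6)
  mods <- setNames(rep("m1", 6), rownames(a))
  ct <- connectivity_profile(a, mods, line = "HIGH")
  expect_equal(ct$k_total, c(5, rep(1, 5)))
  expect_equal(ct$k_within, ct$k_total)        # single module
  expect_equal(ct$k_rel, c(1, rep(0.2, 5)))

  # weighted 4-gene toy, two modules
  w <- matrix(c(1, .8, .1, .2,
                .8, 1, .3, .0,
                .1, .3, 1, .6,
                .2, .0, .6, 1), 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  mods2 <- setNames(c("m1", "m1", "m2", "m2"), rownames(w))
  ct2 <- connectivity_profile(w, mods2, "LOW")
  expect_equal(ct2$k_total, c(1.1, 1.1, 1.0, 0.8), tolerance = 1e-12)
  expect_equal(ct2$k_within, c(0.8, 0.8, 0.6, 0.6), tolerance = 1e-12)
  # the top gene of every module has relative connectivity exactly 1
  expect_true(all(tapply(ct2$k_rel, ct2$module, max) == 1))
  # k_within never exceeds k_total
  expect_true(all(ct2$k_within <= ct2$k_total + 1e-12))

  # single-gene module: k_rel 0 with a warning
  mods3 <- setNames(c("m1", "m1", "m1", "lonely"), rownames(w))
  expect_warning(ct3 <- connectivity_profile(w, mods3, "LOW"), "single gene")
  expect_equal(ct3$k_rel[4], 0)
})

test_that("hub flags are the top intramodular quantile and monotone", {
  set.seed(2)
  k <- sort(runif(10), decreasing = TRUE)
  ct <- data.frame(gene = paste0("g", 1:10), line = "H", module = "m1",
                   k_total = k, k_within = k, k_rel = k / max(k))
  hubs <- identify_hubs(ct, 0.9)
  expect_identical(hubs$gene[hubs$hub], "g1")    # exactly the top gene
  # lowering the quantile never removes a hub
  hubs2 <- identify_hubs(ct, 0.5)
  expect_true(all(hubs2$hub[hubs$hub]))

  # planted high-loading hubs are recovered from the reference simulation
  net <- ref_network()
  truth <- ref_sim()$truth
  flags <- vapply(c("HIGH", "LOW"), function(l) {
    ct <- suppressWarnings(connectivity_profile(net$adjacency_by_line[[l]],
                                                net$modules, l))
    ct <- identify_hubs(ct, 0.9)
    sum(ct$hub[ct$gene %in% truth$hub_genes])
  }, numeric(1))
  expect_gte(sum(flags), 9)   # at least 9 of the 10 (gene, line) hub slots
})

test_that("differential connectivity flags relative changes with direction", {
  ct <- data.frame(gene = paste0("g", 1:4), line = "HIGH", module = "m1",
                   k_total = 4:1, k_within = 4:1, k_rel = c(1, .9, .3, .1),
                   hub = c(TRUE, TRUE, FALSE, FALSE))
  # identical tables: nothing flagged
  expect_equal(nrow(differential_connectivity(ct, ct)), 0L)
  # forced change 0.9 -> 0.3
  ct_low <- transform(ct, k_rel = c(1, .3, .9, .1), hub = c(TRUE, FALSE, TRUE, FALSE))
  dc <- differential_connectivity(ct, ct_low, 0.5)
  expect_setequal(dc$gene, c("g2", "g3"))
  expect_equal(dc$delta[dc$gene == "g2"], 0.6, tolerance = 1e-12)
  expect_equal(dc$direction[dc$gene == "g2"], "HIGH>LOW")
  expect_equal(dc$direction[dc$gene == "g3"], "LOW>HIGH")
  # hub in the higher line is read from the corresponding table
  expect_true(dc$hub_in_higher_line[dc$gene == "g2"])
  # exchanging the arguments flips direction only
  dc_swap <- differential_connectivity(ct_low, ct, 0.5)
  expect_setequal(dc_swap$gene, dc$gene)
  expect_equal(sort(dc_swap$delta), sort(dc$delta), tolerance = 1e-12)
  expect_equal(dc_swap$direction[dc_swap$gene == "g2"], "LOW>HIGH")

  # planted rewired genes are enriched among flagged genes (simulation)
  net <- ref_network()
  truth <- ref_sim()$truth
  cts <- lapply(c(HIGH = "HIGH", LOW = "LOW"), function(l)
    identify_hubs(suppressWarnings(connectivity_profile(
      net$adjacency_by_line[[l]], net$modules, l)), 0.9))
  dcs <- differential_connectivity(cts$HIGH, cts$LOW, 0.5)
  fe <- fisher_enrichment(dcs$gene, truth$dw_genes, net$gene_ids)
  expect_gt(fe$odds_ratio, 1)
  expect_lt(fe$p_enriched, 0.05)
})

test_that("mean connectivity comparison is symmetric and detects damping", {
  set.seed(6)
  k <- rexp(1000)
  ct_h <- data.frame(gene = paste0("g", 1:1000), line = "HIGH", module = "m1",
                     k_total = k, k_within = k, k_rel = k / max(k))
  # identical tables: zero difference, p about 1
  cmp0 <- compare_mean_connectivity(ct_h, ct_h, "total")
  expect_equal(cmp0$mean_high, cmp0$mean_low)
  expect_gt(cmp0$p_value, 0.99)
  # damping one line by 0.5 is detected
  ct_l <- transform(ct_h, k_total = k_total * 0.5 + rnorm(1000, 0, 1e-3))
  cmp <- compare_mean_connectivity(ct_h, ct_l, "total")
  expect_gt(cmp$mean_high, cmp$mean_low)
  expect_lt(cmp$p_value, 1e-10)
  # swapping the lines swaps the means, p unchanged
  cmp_swap <- compare_mean_connectivity(ct_l, ct_h, "total")
  expect_equal(cmp_swap$mean_high, cmp$mean_low)
  expect_equal(cmp_swap$p_value, cmp$p_value, tolerance = 1e-12)
  # small subsets give no p-value
  expect_warning(cmp_small <- compare_mean_connectivity(
    ct_h[1:5, ], ct_l[1:5, ], "total"), "fewer than 10")
  expect_true(is.na(cmp_small$p_value))
})
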