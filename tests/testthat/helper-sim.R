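# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the reference dataset: generator defaults (5 modules x 200 genes, 24+24)
ref_sim <- function() cached("ref_sim", {
  simulate_count_dataset(sim_config(seed = 11))
})

ref_norm <- function() cached("ref_norm", {
  filter_by_cpm(upper_quartile_normalize(ref_sim()$data))
})

ref_network <- function() cached("ref_network", {
  suppressWarnings(coexpression_network(ref_norm(), min_module_size = 100,
                                        target_module_count = 25))
})

# small exon dataset with two planted splicing-module groups
ref_exon <- function() cached("ref_exon", {
  simulate_exon_dataset(sim_config(seed = 2, n_genes = 150,
                                   module_sizes = rep(50L, 2),
                                   exons_per_gene = c(3L, 6L)))
})

ref_profiles <- function() cached("ref_profiles", {
  suppressMessages(exon_proportions(ref_exon()$data))
})

# tiny deterministic count matrix for I/O and normalization tests
toy_counts <- function() {
  counts <- matrix(c(10L, 0L, 25L, 3L,
                     20L, 0L, 50L, 6L,
                     5L,  1L, 12L, 80L,
                     0L,  0L, 0L,  0L,
                     7L,  2L, 30L, 11L),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     line = c("HIGH", "HIGH", "LOW", "LOW"),
                     region = "toy")
  count_matrix(counts, meta)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
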