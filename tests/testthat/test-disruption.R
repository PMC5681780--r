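cfg <- pipeline_config()

annot1 <- tibble::tibble(
  site_id = c("s1", "s2", "s3"),
  snv_class = c("G", "S", "N"),
  sift_class = c(NA, "S", "D"),
  pph_hdiv_class = c(NA, "S", "D"),
  pph_hvar_class = c(NA, "S", "D")
)

test_that("expressing-cell counts apply the two-read rule per allele", {
  counts <- make_counts(rep("s1", 3), c("c1", "c2", "c3"),
                        ref = c(3, 2, 0), alt = c(0, 2, 5))
  out <- expressing_cell_counts(counts, annot1, c("s1", "s2"), "SNV", cfg)
  expect_equal(out$n_cells_ref[out$site_id == "s1"], 2L)
  expect_equal(out$n_cells_alt[out$site_id == "s1"], 2L)
  # a hetSNP with no coverage at all still appears with zero counts
  expect_equal(out$n_cells_ref[out$site_id == "s2"], 0L)
  expect_equal(out$annotation_class, c("G", "S"))
  # under SIFT, site s1 (stop-gain) has no class and is dropped
  out_sift <- expressing_cell_counts(counts, annot1, c("s1", "s2"), "SIFT", cfg)
  expect_equal(out_sift$site_id, "s2")
  expect_error(expressing_cell_counts(counts, annot1, "s1", "bogus"))
})

test_that("reference-fraction observations apply both depth filters", {
  counts <- make_counts(rep("s1", 3), c("c1", "c2", "c3"),
                        ref = c(9, 8, 5), alt = c(1, 2, 4))
  out <- ref_fraction_by_class(counts, annot1, "s1", "SNV", cfg)
  # (9,1): alt below 2; (5,4): sum below 10; only (8,2) survives
  expect_equal(out$cell_id, "c2")
  expect_equal(out$ref_fraction, 0.8)
  # filters commute: relaxing one and applying the other in sequence gives
  # the same final set
  cfg_each <- pipeline_config(disruption_min_sum = 1L)
  step1 <- ref_fraction_by_class(counts, annot1, "s1", "SNV", cfg_each)
  survivors <- step1[counts$ref_depth[match(step1$cell_id, counts$cell_id)] +
                       counts$alt_depth[match(step1$cell_id, counts$cell_id)] >=
                       10, ]
  expect_equal(survivors$cell_id, out$cell_id)
})

test_that("rank-sum comparisons match exact enumeration and handle ties", {
  obs <- tibble::tibble(
    annotation_class = rep(c("A", "B"), each = 3),
    ref_fraction = c(1, 2, 3, 10, 20, 30)
  )
  out <- class_comparison_tests(obs, "A", "B", alternative = "less")
  expect_equal(out$p_value, 1 / choose(6, 3))
  expect_equal(out$method, "exact")
  expect_equal(out$median_a, 2)
  expect_equal(out$median_b, 20)

  # exchangeable samples: one-sided p is exactly 0.5 under the normal
  # approximation without continuity correction
  same <- tibble::tibble(annotation_class = rep(c("A", "B"), each = 4),
                         ref_fraction = rep(c(1, 2, 3, 4), 2))
  out2 <- class_comparison_tests(same, "A", "B", alternative = "greater")
  expect_equal(out2$p_value, 0.5)
  expect_error(class_comparison_tests(obs, "A", "Z", "less"),
               "no observations in class Z")
})

test_that("deleterious alternative alleles show the built-in expression deficit", {
  sim <- simulate_allelic_dataset(tiny_params(
    n_genes = 250L, deleterious_frac = 0.5, deleterious_penalty = 6,
    hetsnps_per_gene_probs = c(`1` = 1),
    gene_mode_probs = c(random_MA = 0, biallelic = 1, imprinted = 0),
    burst_prob_active_allele = 1, dropout_prob = 0.1,
    n_cells_per_type = c(neuron = 20L), rng_seed = 31L
  ))
  het <- sim$truth$sites$site_id[sim$truth$sites$genotype == "het"]
  counts1 <- sim$counts[sim$counts$cell_id %in%
                          sim$cells$cell_id[sim$cells$individual == "ind01"], ]
  cc <- expressing_cell_counts(counts1, sim$annotation, het, "SIFT", cfg)
  res <- allele_expressing_test(cc[cc$annotation_class == "D", ], "D",
                                alternative = "greater")
  expect_lt(res$p_value, 0.05)
  expect_gte(res$median_ref, res$median_alt)

  fr <- ref_fraction_by_class(counts1, sim$annotation, het, "SIFT", cfg)
  comp <- class_comparison_tests(fr, "D", "S", alternative = "greater")
  expect_lt(comp$p_value, 0.05)
})

test_that("synonymous sites are the balanced negative control without bias", {
  sim <- simulate_allelic_dataset(tiny_params(
    n_genes = 200L, deleterious_frac = 0,
    gene_mode_probs = c(random_MA = 0, biallelic = 1, imprinted = 0),
    burst_prob_active_allele = 1, dropout_prob = 0, seq_error = 0,
    n_cells_per_type = c(neuron = 15L), rng_seed = 17L
  ))
  het <- sim$truth$sites$site_id[sim$truth$sites$genotype == "het"]
  fr <- ref_fraction_by_class(sim$counts, sim$annotation, het, "SNV", cfg)
  s_med <- stats::median(fr$ref_fraction[fr$annotation_class == "S"])
  expect_gt(s_med, 0.47)
  expect_lt(s_med, 0.53)

  # configured reference bias shifts the synonymous control upward
  sim_b <- simulate_allelic_dataset(tiny_params(
    n_genes = 200L, deleterious_frac = 0,
    gene_mode_probs = c(random_MA = 0, biallelic = 1, imprinted = 0),
    burst_prob_active_allele = 1, dropout_prob = 0, seq_error = 0,
    ref_bias = 0.6, n_cells_per_type = c(neuron = 15L), rng_seed = 17L
  ))
  fr_b <- ref_fraction_by_class(sim_b$counts, sim_b$annotation,
                                sim_b$truth$sites$site_id[
                                  sim_b$truth$sites$genotype == "het"],
                                "SNV", cfg)
  expect_gt(stats::median(fr_b$ref_fraction[fr_b$annotation_class == "S"]),
            s_med + 0.03)
})
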