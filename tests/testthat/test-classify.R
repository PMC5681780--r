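cfg <- pipeline_config()

test_that("the worked single-observation examples classify per the rules", {
  # one test in the family: fdr equals the raw p-value
  calls <- classify_allelic(make_counts("s1", "c1", 20, 0), "s1", cfg)
  expect_equal(calls$status, "MA")
  expect_equal(calls$expressed_allele, "ref")
  expect_equal(calls$fdr, 2 * 0.5^20, tolerance = 1e-12)

  calls <- classify_allelic(make_counts("s1", "c1", 10, 10), "s1", cfg)
  expect_equal(calls$status, "BA")
  expect_equal(calls$p_value, 1)

  calls <- classify_allelic(make_counts("s1", "c1", 1, 0), "s1", cfg)
  expect_equal(calls$status, "Unknown")

  # MA takes precedence over the 2-read BA rule
  calls <- classify_allelic(make_counts("s1", "c1", 100, 4), "s1", cfg)
  expect_equal(calls$status, "MA")
  expect_gt(calls$ref_ratio, 0.95)

  # a ratio of exactly 0.95 is not MA (strict inequality), but 19/20 vs 1/20
  # both alleles: ref 19, alt 1 -> ratio 0.95 exactly
  calls <- classify_allelic(make_counts("s1", "c1", 19, 1), "s1", cfg)
  expect_false(calls$status == "MA")
})

test_that("every covered observation gets exactly one status", {
  sim <- simulate_allelic_dataset(tiny_params())
  chain <- run_chain(sim)
  covered <- sim$counts[sim$counts$site_id %in% chain$hetsnps$site_id &
                          sim$counts$ref_depth + sim$counts$alt_depth >= 1 &
                          sim$counts$cell_id %in%
                            sim$cells$cell_id[sim$cells$individual == "ind01"], ]
  expect_equal(nrow(chain$calls), nrow(covered))
  expect_true(all(chain$calls$status %in% c("MA", "BA", "Unknown")))
  # other_depth never enters the informative total
  expect_equal(chain$calls$ref_ratio,
               chain$calls$ref_depth /
                 (chain$calls$ref_depth + chain$calls$alt_depth))
})

test_that("FDR families follow the configuration", {
  counts <- make_counts(rep("s1", 4), c("c1", "c2", "c3", "c4"),
                        ref = c(20, 18, 6, 10), alt = c(0, 0, 0, 10))
  joint <- classify_allelic(counts, "s1", cfg)
  per_cell <- classify_allelic(counts, "s1",
                               pipeline_config(fdr_family = "cell"))
  # joint family adjusts 4 p-values together; per-cell families of size 1
  # leave raw p-values untouched
  expect_equal(per_cell$fdr, per_cell$p_value)
  expect_true(all(joint$fdr >= joint$p_value - 1e-15))

  cells <- tibble::tibble(cell_id = c("c1", "c2", "c3", "c4"),
                          individual = c("i1", "i1", "i2", "i2"),
                          cell_type = "neuron")
  by_ind <- classify_allelic(counts, "s1", cfg, cells)
  # within individual i2, the family is {p(6,6), p(10,20)}
  p1 <- binom_test_two_sided(6, 6)
  expect_equal(by_ind$fdr[by_ind$cell_id == "c3"],
               stats::p.adjust(c(p1, 1), "BH")[1])
})

test_that("pseudo-bulk pooling averages opposite monoallelic cells to 0.5", {
  cells <- tibble::tibble(cell_id = c("c1", "c2"), individual = "i1",
                          cell_type = "neuron")
  counts <- make_counts(c("s1", "s1"), c("c1", "c2"),
                        ref = c(30, 0), alt = c(0, 30))
  pb <- pseudo_bulk_ratios(counts, cells, "individual")
  expect_equal(pb$ref_ratio, 0.5)
  expect_equal(pb$pooled_depth, 60L)

  pb2 <- pseudo_bulk_ratios(counts, cells, "individual_cell_type")
  expect_true("cell_type" %in% names(pb2))
})

test_that("ratio banding reports the balanced fraction", {
  pb <- tibble::tibble(
    site_id = sprintf("s%d", 1:5), individual = "i1",
    pooled_ref = c(50L, 45L, 10L, 0L, 60L),
    pooled_alt = c(50L, 55L, 90L, 100L, 40L)
  )
  pb$pooled_depth <- pb$pooled_ref + pb$pooled_alt
  pb$ref_ratio <- pb$pooled_ref / pb$pooled_depth
  out <- ratio_band_summary(pb)
  expect_equal(out$band$n_sites, 5L)
  expect_equal(out$band$n_in_band, 3L)  # 0.5, 0.45, 0.6
  expect_equal(out$band$frac_in_band, 0.6)
  expect_equal(sum(out$histogram$n), 5L)
})

test_that("imprinted sites deviate from 0.5 while balanced sites do not", {
  pb <- tibble::tibble(
    site_id = c("imp", "bal"), individual = "i1",
    pooled_ref = c(30L, 15L), pooled_alt = c(0L, 15L)
  )
  pb$pooled_depth <- pb$pooled_ref + pb$pooled_alt
  pb$ref_ratio <- pb$pooled_ref / pb$pooled_depth
  sites <- make_sites(c("imp", "bal"), gene_ids = c("GI", "GB"))
  chk <- imprinted_ratio_check(pb, "GI", sites)
  obs <- chk$observations
  expect_equal(obs$deviation[obs$site_id == "imp"], 0.5)
  expect_equal(obs$deviation[obs$site_id == "bal"], 0)
  expect_error(imprinted_ratio_check(pb, character(), sites), "empty")
})

test_that("simulated imprinting dominates the deviation distribution", {
  sim <- simulate_allelic_dataset(tiny_params(
    gene_mode_probs = c(random_MA = 0.4, biallelic = 0.4, imprinted = 0.2),
    n_genes = 80L, rng_seed = 21L
  ))
  het <- sim$truth$sites$site_id[sim$truth$sites$genotype == "het"]
  pb <- pseudo_bulk_ratios(sim$counts[sim$counts$site_id %in% het, ],
                           sim$cells, "individual")
  imp <- sim$truth$genes$gene_id[startsWith(sim$truth$genes$mode, "imprinted")]
  chk <- imprinted_ratio_check(pb, imp, sim$sites)
  expect_true(all(chk$tests$p_value < 0.01))
  expect_true(all(chk$tests$median_dev_imprinted >
                    chk$tests$median_dev_other))
})
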