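cfg <- pipeline_config()

make_expr <- function(cell_id, gene_ids, fpkm) {
  tibble::tibble(gene_id = gene_ids, cell_id = cell_id, fpkm = fpkm)
}

gene_call_rows <- function(gene_id, cell_id, status) {
  tibble::tibble(gene_id = gene_id, cell_id = cell_id,
                 n_snps_ma = 0L, n_snps_ba = 0L, n_snps_unknown = 0L,
                 status = status)
}

full_mask <- function(gene_calls) {
  tibble::tibble(cell_id = gene_calls$cell_id, gene_id = gene_calls$gene_id)
}

cells_of <- function(n, type = "neuron", individual = "i1", prefix = "c") {
  tibble::tibble(cell_id = sprintf("%s%02d", prefix, seq_len(n)),
                 individual = individual, cell_type = type)
}

test_that("the top-percentile mask keeps the ceiling of expressed genes", {
  expr <- make_expr("c1", sprintf("g%02d", 1:10), fpkm = 10:1)
  mask <- top_percentile_mask(expr, 0.30)
  expect_equal(nrow(mask), 3L)  # ceiling(0.3 * 10)
  expect_setequal(mask$gene_id, c("g01", "g02", "g03"))
  cuts <- attr(mask, "cutoffs")
  expect_equal(cuts$n_expressed, 10L)
  expect_equal(cuts$cutoff_fpkm, 8)
})

test_that("mask tie-break is lexicographic and zero FPKM genes never enter", {
  expr <- make_expr("c1", c("gB", "gA", "gC", "gZ"), fpkm = c(5, 5, 5, 0))
  mask <- top_percentile_mask(expr, 0.34)  # ceiling(0.34 * 3) = 2 of 3 expressed
  expect_equal(sort(mask$gene_id), c("gA", "gB"))
  expect_warning(top_percentile_mask(make_expr("c9", "g1", 0), 0.3),
                 "no expressed genes")
})

test_that("cell-type MA calls need four masked supporting cells and no BA veto", {
  cells <- cells_of(6)
  # 4 MA cells, rest Unknown -> MA
  gc4 <- gene_call_rows("G1", cells$cell_id,
                        c("MA", "MA", "MA", "MA", "Unknown", "Unknown"))
  out <- call_celltype_ma(gc4, full_mask(gc4), cells, cfg)
  expect_equal(out$status, "MA")
  expect_equal(out$n_supporting_cells, 4L)

  # 5 MA cells but one BA cell -> BA, regardless of support
  gc5 <- gene_call_rows("G1", cells$cell_id,
                        c("MA", "MA", "MA", "MA", "MA", "BA"))
  expect_equal(call_celltype_ma(gc5, full_mask(gc5), cells, cfg)$status, "BA")

  # 3 masked MA cells -> undetermined
  gc3 <- gene_call_rows("G1", cells$cell_id,
                        c("MA", "MA", "MA", "Unknown", "Unknown", "Unknown"))
  expect_equal(call_celltype_ma(gc3, full_mask(gc3), cells, cfg)$status,
               "undetermined")

  # 5 MA cells but only 3 in the mask -> undetermined (mask gates support)
  gc <- gene_call_rows("G1", cells$cell_id,
                       c("MA", "MA", "MA", "MA", "MA", "Unknown"))
  mask3 <- full_mask(gc)[1:3, ]
  expect_equal(call_celltype_ma(gc, mask3, cells, cfg)$status, "undetermined")

  # the BA veto ignores the mask entirely
  gc_veto <- gene_call_rows("G1", cells$cell_id,
                            c("MA", "MA", "MA", "MA", "MA", "BA"))
  mask5 <- full_mask(gc_veto)[1:5, ]
  expect_equal(call_celltype_ma(gc_veto, mask5, cells, cfg)$status, "BA")
})

test_that("a gene is never both cell-type MA and cell-type BA", {
  sim <- simulate_allelic_dataset(tiny_params())
  chain <- run_chain(sim)
  mask <- top_percentile_mask(sim$expression, cfg$expr_percentile)
  out <- call_celltype_ma(chain$gene_calls, mask, sim$cells, cfg)
  expect_equal(anyDuplicated(out[, c("gene_id", "individual", "cell_type")]), 0L)
  ma <- out[out$status == "MA", ]
  expect_true(all(ma$n_cells_ba == 0L))
  expect_true(all(ma$n_supporting_cells >= cfg$min_supporting_cells))
})

test_that("removing a supporting cell never promotes a gene to MA", {
  cells <- cells_of(6)
  gc <- gene_call_rows("G1", cells$cell_id,
                       c("MA", "MA", "MA", "MA", "Unknown", "Unknown"))
  mask <- full_mask(gc)
  base <- call_celltype_ma(gc, mask, cells, cfg)
  expect_equal(base$status, "MA")
  dropped <- gc[gc$cell_id != "c01", ]
  out <- call_celltype_ma(dropped, mask, cells[cells$cell_id != "c01", ], cfg)
  expect_equal(out$status, "undetermined")
})

test_that("permutation tests demand enough cells and honour the seed", {
  cells <- dplyr::bind_rows(cells_of(10, "neuron"),
                            cells_of(6, "oligodendrocyte", prefix = "o"))
  gc <- gene_call_rows(rep("G1", 16), cells$cell_id, rep("MA", 16))
  expect_error(
    between_vs_within_permutation(gc, full_mask(gc), cells, "neuron",
                                  "oligodendrocyte", 5, 1, cfg),
    "at least 12 cells"
  )
  cells2 <- dplyr::bind_rows(cells_of(12, "neuron"),
                             cells_of(4, "oligodendrocyte", prefix = "o"))
  gc2 <- gene_call_rows(rep("G1", 16), cells2$cell_id, rep("MA", 16))
  a <- between_vs_within_permutation(gc2, full_mask(gc2), cells2, "neuron",
                                     "oligodendrocyte", 10, 7, cfg)
  b <- between_vs_within_permutation(gc2, full_mask(gc2), cells2, "neuron",
                                     "oligodendrocyte", 10, 7, cfg)
  expect_identical(a$within, b$within)
  expect_identical(a$between, b$between)
  gl <- glance(a)
  expect_equal(gl$k, 4L)
  td <- tidy(a)
  expect_equal(nrow(td), 20L)
})

test_that("split-half overlap is 100% for deterministic MA genes", {
  cells <- cells_of(10)
  gc <- dplyr::bind_rows(
    gene_call_rows(rep("G1", 10), cells$cell_id, rep("MA", 10)),
    gene_call_rows(rep("G2", 10), cells$cell_id, rep("MA", 10))
  )
  out <- split_half_overlap(gc, full_mask(gc), cells, "neuron", 20, 1, cfg)
  expect_true(all(out$overlap_pct == 100))
  expect_error(split_half_overlap(gc, full_mask(gc), cells_of(7), "neuron",
                                  5, 1, cfg),
               "at least 8 cells")
})

test_that("saturation is zero below the supporting-cell rule and exact at k = n", {
  cells <- cells_of(6)
  gc <- gene_call_rows("G1", cells$cell_id, rep("MA", 6))
  sat <- saturation_curve(gc, full_mask(gc), cells, "neuron", n_iter = 50,
                          seed = 1, config = cfg)
  expect_equal(sat$mean_n_ma[sat$k < 4], rep(0, 3))
  expect_true(all(sat$mean_n_ma[sat$k >= 4] == 1))
  expect_true(all(sat$exact))  # choose(6, k) <= 50 for all k

  sat_n <- saturation_curve(gc, full_mask(gc), cells, "neuron", n_iter = 50,
                            seed = 1, config = cfg, k_values = 6L)
  expect_equal(sat_n$n_draws, 1L)
})

test_that("shared MA alleles require the same expressed allele", {
  cells <- cells_of(2)
  same <- tibble::tibble(
    site_id = rep(c("s1", "s2"), 2),
    cell_id = rep(c("c01", "c02"), each = 2),
    status = "MA",
    expressed_allele = "ref"
  )
  out <- shared_ma_allele_pairs(same, cells, "neuron", n_pairs = 5, seed = 1,
                                config = cfg)
  expect_true(all(out$shared_pct == 100))

  opposite <- same
  opposite$expressed_allele[opposite$cell_id == "c02"] <- "alt"
  out2 <- shared_ma_allele_pairs(opposite, cells, "neuron", n_pairs = 5,
                                 seed = 1, config = cfg)
  expect_true(all(out2$shared_pct == 0))
})

test_that("background gene definitions differ as configured", {
  sites <- make_sites(c("s1", "s2"), gene_ids = c("G1", "G2"))
  cells <- cells_of(2)
  calls <- tibble::tibble(site_id = c("s1", "s2"), cell_id = "c01",
                          status = c("MA", "Unknown"),
                          expressed_allele = NA_character_)
  bg <- background_genes(calls, sites, cells, "neuron")
  expect_setequal(bg, c("G1", "G2"))
  expr <- make_expr(rep("c01", 2), c("G1", "G2"), fpkm = c(5, 0.5))
  bg2 <- background_genes(calls, sites, cells, "neuron",
                          method = "expressed_fpkm", expr = expr)
  expect_equal(bg2, "G1")  # mean FPKM over 2 cells: 2.5 vs 0.25
})
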