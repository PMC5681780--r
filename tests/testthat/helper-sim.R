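# Small, fast simulation setups shared across test files.

tiny_params <- function(...) {
  defaults <- list(
    n_individuals = 1L,
    n_cells_per_type = c(neuron = 20L, oligodendrocyte = 10L),
    n_genes = 40L,
    n_background_genes = 40L,
    frac_het_sites = 0.7,
    rng_seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# deterministic, noise-free generator settings: no dropout, no sequencing
# error, no mapping bias, no expression penalty
noise_free <- function(...) {
  tiny_params(dropout_prob = 0, seq_error = 0, ref_bias = 1,
              deleterious_frac = 0, frac_het_sites = 1, ...)
}

# run the standard chain from counts to per-cell gene status for one
# individual
run_chain <- function(sim, config = pipeline_config(), individual = "ind01",
                      cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- config$pooled_depth_cutoff
  pooled <- pool_allelic_depths(sim$counts, sim$cells, individual)
  hets <- call_hetsnps(pooled, sim$sites, cutoff)
  keep_cells <- sim$cells$cell_id[sim$cells$individual == individual]
  counts <- sim$counts[sim$counts$cell_id %in% keep_cells, ]
  calls <- classify_allelic(counts, hets, config)
  gene_calls <- gene_status_per_cell(calls, sim$sites)
  list(pooled = pooled, hetsnps = hets, calls = calls,
       gene_calls = gene_calls)
}

# minimal handmade site table: one single-gene site per row
make_sites <- function(site_ids, gene_ids = NULL) {
  n <- length(site_ids)
  tibble::tibble(
    site_id = site_ids,
    chrom = "chr1",
    pos = seq_len(n),
    ref_allele = "A",
    alt_allele = "G",
    gene_ids = if (is.null(gene_ids)) replicate(n, character(), simplify = FALSE)
    else lapply(gene_ids, function(g) if (is.na(g[1])) character() else g)
  )
}

make_counts <- function(site_id, cell_id, ref, alt, other = 0L) {
  tibble::tibble(
    site_id = site_id, cell_id = cell_id,
    ref_depth = as.integer(ref), alt_depth = as.integer(alt),
    other_depth = as.integer(rep_len(other, length(site_id)))
  )
}
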