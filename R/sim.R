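#' Simulation parameters for synthetic allelic-count data
#'
#' Defines the generative model used to test the pipeline end-to-end without
#' external sequencing data. Genes are assigned an allelic mode (random
#' monoallelic, biallelic, or imprinted); per cell, each allele of a gene is
#' switched on according to the mode (independent Bernoulli bursting for
#' biallelic genes, a fair coin for the expressed allele of random-MA genes,
#' a fixed allele for imprinted genes). Read depth per active allele follows
#' a negative binomial scaled by a per-gene expression factor, thinned by
#' allelic dropout; homozygous candidate sites emit opposite-allele reads at
#' the sequencing-error rate and are the source of false heterozygous calls
#' used for cutoff calibration. Reference mapping bias thins
#' alternative-allele read capture.
#'
#' @param n_individuals Number of simulated individuals (default 2).
#' @param n_cells_per_type Named integer vector: cells per cell type per
#'   individual. Default mirrors a small brain scRNA-seq cohort with five
#'   cell types and more neurons than the rarer glial types.
#' @param n_genes Number of genes carrying candidate SNP sites (default 200).
#' @param n_background_genes Genes without candidate sites, present only in
#'   the expression matrix (default 200).
#' @param hetsnps_per_gene_probs Named probabilities for the number of truly
#'   heterozygous sites per gene; the default 80/14/6 split over 1/2/3 sites
#'   matches the observed predominance of single-hetSNP genes.
#' @param frac_het_sites Fraction of candidate sites that are truly
#'   heterozygous; the remainder are homozygous and can only produce false
#'   het calls through sequencing error (default 0.7).
#' @param gene_mode_probs Probabilities of the three gene modes
#'   `random_MA`, `biallelic`, `imprinted`; must sum to 1.
#' @param celltype_specific_ma_frac Fraction of random-MA genes whose MA
#'   behaviour is restricted to one randomly chosen cell type; elsewhere they
#'   behave biallelically (default 0.3).
#' @param burst_prob_active_allele Probability that an allele of a
#'   biallelically behaving gene is transcriptionally active in a cell
#'   (default 0.85).
#' @param depth_mean,depth_dispersion Negative-binomial mean and size for the
#'   read depth of one active allele of a gene with average expression
#'   (defaults 30 and 2).
#' @param dropout_prob Per-allele, per-cell probability that an active
#'   allele's transcripts are not captured at all (default 0.2).
#' @param seq_error Per-read probability that a read at a homozygous site is
#'   miscalled as the opposite candidate allele (default 0.005).
#' @param ref_bias Multiplicative capture probability for alternative-allele
#'   reads, in (0, 1]; 1 means no mapping bias (default 1).
#' @param deleterious_frac Fraction of non-synonymous heterozygous sites
#'   annotated as deleterious (default 0.15). Stop-gain sites are always
#'   deleterious.
#' @param deleterious_penalty Fold reduction applied to the alternative
#'   allele's read depth for genes carrying a deleterious heterozygous site,
#'   emulating degradation of the damaged transcript (default 4).
#' @param rng_seed Integer seed; with a fixed seed the generated dataset is
#'   bit-reproducible.
#'
#' @return A list of class `scase_sim_params`.
#' @export
sim_params <- function(n_individuals = 2L,
                       n_cells_per_type = c(astrocyte = 12L, microglia = 8L,
                                            neuron = 20L, oligodendrocyte = 12L,
                                            OPC = 8L),
                       n_genes = 200L,
                       n_background_genes = 200L,
                       hetsnps_per_gene_probs = c(`1` = 0.80, `2` = 0.14, `3` = 0.06),
                       frac_het_sites = 0.7,
                       gene_mode_probs = c(random_MA = 0.50, biallelic = 0.45,
                                           imprinted = 0.05),
                       celltype_specific_ma_frac = 0.30,
                       burst_prob_active_allele = 0.85,
                       depth_mean = 30,
                       depth_dispersion = 2,
                       dropout_prob = 0.20,
                       seq_error = 0.005,
                       ref_bias = 1.0,
                       deleterious_frac = 0.15,
                       deleterious_penalty = 4,
                       rng_seed = 1L) {
  p <- list(
    n_individuals = as.integer(n_individuals),
    n_cells_per_type = n_cells_per_type,
    n_genes = as.integer(n_genes),
    n_background_genes = as.integer(n_background_genes),
    hetsnps_per_gene_probs = hetsnps_per_gene_probs,
    frac_het_sites = frac_het_sites,
    gene_mode_probs = gene_mode_probs,
    celltype_specific_ma_frac = celltype_specific_ma_frac,
    burst_prob_active_allele = burst_prob_active_allele,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    dropout_prob = dropout_prob,
    seq_error = seq_error,
    ref_bias = ref_bias,
    deleterious_frac = deleterious_frac,
    deleterious_penalty = deleterious_penalty,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_params(p)
  structure(p, class = "scase_sim_params")
}

validate_sim_params <- function(p) {
  if (is.null(names(p$n_cells_per_type)) || any(names(p$n_cells_per_type) == "")) {
    stop("n_cells_per_type must be a named integer vector (cell type -> count)")
  }
  probs <- c(p$gene_mode_probs, p$hetsnps_per_gene_probs,
             p$frac_het_sites, p$celltype_specific_ma_frac,
             p$burst_prob_active_allele, p$dropout_prob, p$seq_error)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(p$gene_mode_probs) - 1) > 1e-8) {
    stop("gene_mode_probs must sum to 1")
  }
  if (!setequal(names(p$gene_mode_probs), c("random_MA", "biallelic", "imprinted"))) {
    stop("gene_mode_probs must name exactly random_MA, biallelic, imprinted")
  }
  if (abs(sum(p$hetsnps_per_gene_probs) - 1) > 1e-8) {
    stop("hetsnps_per_gene_probs must sum to 1")
  }
  stopifnot(
    p$n_individuals >= 1L, all(p$n_cells_per_type >= 1L),
    p$n_genes >= 1L, p$n_background_genes >= 0L,
    p$depth_mean > 0, p$depth_dispersion > 0,
    p$ref_bias > 0, p$ref_bias <= 1,
    p$frac_het_sites > 0,
    p$deleterious_penalty >= 1
  )
  invisible(p)
}

# Gene intervals are laid out end to end on one chromosome so that interval
# overlap in the gene model is unambiguous by construction.
sim_gene_intervals <- function(n_genes) {
  tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = "chr1",
    start = (seq_len(n_genes) - 1L) * 10000L + 1L,
    end = (seq_len(n_genes) - 1L) * 10000L + 5000L
  )
}

#' Simulate a complete allelic-expression dataset
#'
#' Generates every input the pipeline consumes — candidate SNP sites, the
#' sparse per-site-per-cell allelic count table, a per-cell FPKM expression
#' matrix, cell metadata, a functional annotation table — together with the
#' ground truth (per-site genotypes, per-gene allelic modes, and per
#' (gene, cell) active alleles) needed for calibration and parameter
#' recovery. See [sim_params()] for the generative model.
#'
#' Genotypes are shared across individuals: the truth set records one
#' genotype per site, and every individual's cells draw from the same gene
#' modes, so pooled hetSNP calling can be exercised per individual against a
#' single truth table.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `scase_sim` with elements `sites`, `counts`,
#'   `expression`, `cells`, `annotation`, `truth` (itself a list with
#'   `sites`, `genes`, `gene_cell`), and `params`.
#' @examples
#' sim <- simulate_allelic_dataset(sim_params(n_genes = 20, rng_seed = 7))
#' head(sim$counts)
#' @export
simulate_allelic_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "scase_sim_params"))
  p <- params
  set.seed(p$rng_seed)

  cell_types <- names(p$n_cells_per_type)
  individuals <- sprintf("ind%02d", seq_len(p$n_individuals))

  cells <- purrr::map_dfr(individuals, function(ind) {
    purrr::map_dfr(cell_types, function(ct) {
      tibble::tibble(
        cell_id = sprintf("%s_%s_c%02d", ind, ct, seq_len(p$n_cells_per_type[[ct]])),
        individual = ind,
        cell_type = ct
      )
    })
  })
  n_cells <- nrow(cells)

  # ---- genes -----------------------------------------------------------
  genes <- sim_gene_intervals(p$n_genes)
  mode3 <- sample(names(p$gene_mode_probs), p$n_genes, replace = TRUE,
                  prob = p$gene_mode_probs)
  imprint_side <- sample(c("imprinted_ref", "imprinted_alt"), p$n_genes,
                         replace = TRUE)
  genes$mode <- ifelse(mode3 == "imprinted", imprint_side, mode3)
  genes$specific <- genes$mode == "random_MA" &
    stats::runif(p$n_genes) < p$celltype_specific_ma_frac
  ct_draw <- sample(cell_types, p$n_genes, replace = TRUE)
  genes$ma_cell_type <- ifelse(genes$specific, ct_draw, NA_character_)
  gf <- stats::rlnorm(p$n_genes, meanlog = 0, sdlog = 1)
  genes$gene_factor <- gf / mean(gf)

  # ---- candidate sites -------------------------------------------------
  n_het_per_gene <- as.integer(sample(names(p$hetsnps_per_gene_probs),
                                      p$n_genes, replace = TRUE,
                                      prob = p$hetsnps_per_gene_probs))
  het_gene_idx <- rep(seq_len(p$n_genes), n_het_per_gene)
  n_het <- length(het_gene_idx)
  n_hom <- max(0L, as.integer(round(n_het * (1 - p$frac_het_sites) / p$frac_het_sites)))
  hom_gene_idx <- if (n_hom > 0) sample(seq_len(p$n_genes), n_hom, replace = TRUE) else integer()

  gene_idx <- c(het_gene_idx, hom_gene_idx)
  genotype <- c(rep("het", n_het),
                sample(c("hom_ref", "hom_alt"), n_hom, replace = TRUE))
  n_sites <- length(gene_idx)

  # one unique position per site within its gene interval
  offset <- integer(n_sites)
  for (g in unique(gene_idx)) {
    idx <- which(gene_idx == g)
    offset[idx] <- sample.int(5000L, length(idx), replace = FALSE)
  }
  pos <- genes$start[gene_idx] + offset - 1L

  bases <- c("A", "C", "G", "T")
  ref_allele <- sample(bases, n_sites, replace = TRUE)
  alt_allele <- vapply(ref_allele, function(r) sample(setdiff(bases, r), 1L), "")

  ord <- order(gene_idx, pos)
  sites <- tibble::tibble(
    site_id = sprintf("s%05d", seq_len(n_sites)),
    chrom = "chr1",
    pos = pos[ord],
    ref_allele = ref_allele[ord],
    alt_allele = unname(alt_allele[ord]),
    gene_ids = as.list(genes$gene_id[gene_idx[ord]])
  )
  site_gene <- genes$gene_id[gene_idx[ord]]
  site_genotype <- genotype[ord]

  # ---- annotation ------------------------------------------------------
  snv_class <- sample(c("S", "N", "L", "G"), n_sites, replace = TRUE,
                      prob = c(0.55, 0.42, 0.01, 0.02))
  penalized <- snv_class == "G" |
    (snv_class == "N" & stats::runif(n_sites) < p$deleterious_frac)
  sift_class <- dplyr::case_when(
    snv_class == "S" ~ "S",
    snv_class == "N" & penalized ~ "D",
    snv_class == "N" ~ "T",
    TRUE ~ NA_character_
  )
  pph_benign <- sample(c("B", "P"), n_sites, replace = TRUE, prob = c(0.8, 0.2))
  pph_class <- dplyr::case_when(
    snv_class == "S" ~ "S",
    snv_class == "N" & penalized ~ "D",
    snv_class == "N" ~ pph_benign,
    TRUE ~ NA_character_
  )
  annotation <- tibble::tibble(
    site_id = sites$site_id,
    snv_class = snv_class,
    sift_class = sift_class,
    pph_hdiv_class = pph_class,
    pph_hvar_class = pph_class
  )
  # the damaged transcript belongs to the whole alternative allele of the
  # gene, so the expression penalty is applied at gene level
  pen_genes <- unique(site_gene[penalized & site_genotype == "het"])
  genes$alt_penalized <- genes$gene_id %in% pen_genes

  # ---- per (gene, cell) allele activity and depth ----------------------
  gc <- tidyr::expand_grid(gene_id = genes$gene_id, cell_id = cells$cell_id)
  gc <- dplyr::left_join(gc, cells, by = "cell_id")
  gidx <- match(gc$gene_id, genes$gene_id)
  mode <- genes$mode[gidx]
  applies_ma <- mode == "random_MA" &
    (!genes$specific[gidx] | gc$cell_type == genes$ma_cell_type[gidx])
  burst_like <- mode == "biallelic" | (mode == "random_MA" & !applies_ma)

  n_gc <- nrow(gc)
  pick_ref <- stats::runif(n_gc) < 0.5
  b_ref <- stats::runif(n_gc) < p$burst_prob_active_allele
  b_alt <- stats::runif(n_gc) < p$burst_prob_active_allele
  ref_active <- (mode == "imprinted_ref") |
    (applies_ma & pick_ref) | (burst_like & b_ref)
  alt_active <- (mode == "imprinted_alt") |
    (applies_ma & !pick_ref) | (burst_like & b_alt)

  mu <- p$depth_mean * genes$gene_factor[gidx]
  d_ref <- ifelse(ref_active,
                  stats::rnbinom(n_gc, size = p$depth_dispersion, mu = mu), 0L)
  d_alt <- ifelse(alt_active,
                  stats::rnbinom(n_gc, size = p$depth_dispersion, mu = mu), 0L)
  d_ref <- d_ref * (stats::runif(n_gc) >= p$dropout_prob)
  d_alt <- d_alt * (stats::runif(n_gc) >= p$dropout_prob)
  pen <- genes$alt_penalized[gidx]
  d_alt[pen] <- stats::rbinom(sum(pen), d_alt[pen], 1 / p$deleterious_penalty)

  gc$ref_active <- ref_active
  gc$alt_active <- alt_active
  gc$active <- dplyr::case_when(
    ref_active & alt_active ~ "both",
    ref_active ~ "ref",
    alt_active ~ "alt",
    TRUE ~ "none"
  )
  gc$ref_depth <- as.integer(d_ref)
  gc$alt_depth <- as.integer(d_alt)

  # ---- site-by-cell counts ---------------------------------------------
  site_tbl <- tibble::tibble(site_id = sites$site_id, gene_id = site_gene,
                             genotype = site_genotype)
  sc <- dplyr::inner_join(site_tbl,
                          gc[, c("gene_id", "cell_id", "ref_depth", "alt_depth")],
                          by = "gene_id", relationship = "many-to-many")
  n_sc <- nrow(sc)
  is_het <- sc$genotype == "het"
  is_hr <- sc$genotype == "hom_ref"
  is_ha <- sc$genotype == "hom_alt"

  ref_obs <- integer(n_sc)
  alt_obs <- integer(n_sc)

  # het sites observe the gene-level allele depths; mapping bias thins the
  # capture of alternative-allele reads per site
  ref_obs[is_het] <- sc$ref_depth[is_het]
  alt_obs[is_het] <- stats::rbinom(sum(is_het), sc$alt_depth[is_het], p$ref_bias)

  # homozygous sites: every transcript carries the homozygous base; reads are
  # miscalled to the opposite candidate allele at the sequencing-error rate
  tot_hr <- sc$ref_depth[is_hr] + sc$alt_depth[is_hr]
  mis_hr <- stats::rbinom(sum(is_hr), tot_hr, p$seq_error)
  ref_obs[is_hr] <- tot_hr - mis_hr
  alt_obs[is_hr] <- stats::rbinom(sum(is_hr), mis_hr, p$ref_bias)

  tot_ha <- sc$ref_depth[is_ha] + sc$alt_depth[is_ha]
  cap_ha <- stats::rbinom(sum(is_ha), tot_ha, p$ref_bias)
  mis_ha <- stats::rbinom(sum(is_ha), cap_ha, p$seq_error)
  alt_obs[is_ha] <- cap_ha - mis_ha
  ref_obs[is_ha] <- mis_ha

  counts <- tibble::tibble(
    site_id = sc$site_id,
    cell_id = sc$cell_id,
    ref_depth = ref_obs,
    alt_depth = alt_obs,
    other_depth = 0L
  )
  counts <- counts[counts$ref_depth + counts$alt_depth > 0L, ]

  # ---- expression matrix -----------------------------------------------
  cell_factor <- stats::rlnorm(n_cells, meanlog = log(0.5), sdlog = 0.3)
  names(cell_factor) <- cells$cell_id
  expr_snp <- tibble::tibble(
    gene_id = gc$gene_id,
    cell_id = gc$cell_id,
    fpkm = (gc$ref_depth + gc$alt_depth) * unname(cell_factor[gc$cell_id])
  )
  if (p$n_background_genes > 0) {
    bg_id <- sprintf("B%04d", seq_len(p$n_background_genes))
    bg_mean <- stats::rlnorm(p$n_background_genes, meanlog = 0, sdlog = 1) *
      p$depth_mean
    bg <- tidyr::expand_grid(gene_id = bg_id, cell_id = cells$cell_id)
    bidx <- match(bg$gene_id, bg_id)
    bg$fpkm <- bg_mean[bidx] * unname(cell_factor[bg$cell_id]) *
      stats::rlnorm(nrow(bg), 0, 0.3)
    expr <- dplyr::bind_rows(expr_snp, bg)
  } else {
    expr <- expr_snp
  }
  expr <- expr[expr$fpkm > 0, ]

  truth <- list(
    sites = tibble::tibble(site_id = sites$site_id, gene_id = site_gene,
                           genotype = site_genotype),
    genes = genes,
    gene_cell = gc[, c("gene_id", "cell_id", "cell_type", "ref_active",
                       "alt_active", "active", "ref_depth", "alt_depth")]
  )

  structure(
    list(sites = sites, counts = counts, expression = expr, cells = cells,
         annotation = annotation, truth = truth, params = p),
    class = "scase_sim"
  )
}

#' Ground-truth monoallelic labels from a simulation
#'
#' Converts the truth component of [simulate_allelic_dataset()] into label
#' tables for parameter-recovery tests.
#'
#' At `site_cell` level an observation is labelled `MA` when exactly one
#' allele of the gene is transcriptionally active in the cell, `BA` when both
#' are, and `none` when neither is. At `gene_celltype` level a gene is `MA`
#' for a cell type when its mode forces a single allele there: imprinted
#' genes everywhere, random-MA genes in every cell type (or only their
#' specific cell type, when restricted); otherwise `BA`.
#'
#' @param truth The `truth` element of a `scase_sim`.
#' @param level `"site_cell"` or `"gene_celltype"`.
#' @return A tibble of labels; at `site_cell` level with the expressed
#'   allele, at `gene_celltype` level with the MA flavour (`imprinted` or
#'   `random`).
#' @export
truth_ma_labels <- function(truth, level = c("site_cell", "gene_celltype")) {
  level <- match.arg(level)
  if (level == "site_cell") {
    het <- truth$sites[truth$sites$genotype == "het", c("site_id", "gene_id")]
    out <- dplyr::inner_join(het, truth$gene_cell, by = "gene_id",
                             relationship = "many-to-many")
    out$label <- dplyr::case_when(
      out$active == "both" ~ "BA",
      out$active %in% c("ref", "alt") ~ "MA",
      TRUE ~ "none"
    )
    out$expressed_allele <- ifelse(out$label == "MA", out$active, NA_character_)
    return(tibble::as_tibble(out[, c("site_id", "cell_id", "label",
                                     "expressed_allele")]))
  }
  genes <- truth$genes
  cell_types <- sort(unique(truth$gene_cell$cell_type))
  grid <- tidyr::expand_grid(gene_id = genes$gene_id, cell_type = cell_types)
  gidx <- match(grid$gene_id, genes$gene_id)
  mode <- genes$mode[gidx]
  ma <- mode %in% c("imprinted_ref", "imprinted_alt") |
    (mode == "random_MA" &
       (!genes$specific[gidx] | grid$cell_type == genes$ma_cell_type[gidx]))
  grid$label <- ifelse(ma, "MA", "BA")
  grid$ma_kind <- dplyr::case_when(
    !ma ~ NA_character_,
    mode == "random_MA" ~ "random",
    TRUE ~ "imprinted"
  )
  grid
}

#' @export
print.scase_sim <- function(x, ...) {
  cat("<scase simulated dataset>\n")
  cat(sprintf("  %d sites (%d het), %d cells, %d genes with sites\n",
              nrow(x$sites), sum(x$truth$sites$genotype == "het"),
              nrow(x$cells), x$params$n_genes))
  cat(sprintf("  %d non-zero count rows, %d expression rows\n",
              nrow(x$counts), nrow(x$expression)))
  invisible(x)
}
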