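#' Per-cell top-percentile expression mask
#'
#' For every cell, ranks its expressed genes (FPKM > 0) in decreasing
#' expression and keeps the top `ceiling(percentile * n_expressed)`. Ties
#' are broken deterministically by lexicographic gene id. Low-expressed
#' genes are prone to spurious monoallelic calls (one allele's few
#' transcripts are easily missed), so only genes in this mask may *support*
#' a cell-type monoallelic call.
#'
#' @param expr Long expression tibble `gene_id, cell_id, fpkm`.
#' @param percentile Fraction of expressed genes to keep, in (0, 1]
#'   (default 0.30).
#' @return A tibble `cell_id, gene_id` of retained genes, with attribute
#'   `"cutoffs"`: per-cell `n_expressed` and `cutoff_fpkm` (the smallest
#'   retained FPKM). Cells with no expressed gene contribute no rows and
#'   raise a warning.
#' @export
top_percentile_mask <- function(expr, percentile = 0.30) {
  stopifnot(percentile > 0, percentile <= 1)
  x <- expr[!is.na(expr$fpkm) & expr$fpkm > 0, ]
  empty <- setdiff(unique(expr$cell_id), unique(x$cell_id))
  if (length(empty) > 0) {
    warning("cell(s) with no expressed genes: ",
            paste(utils::head(empty, 3), collapse = ", "))
  }
  if (nrow(x) == 0) {
    out <- tibble::tibble(cell_id = character(), gene_id = character())
    attr(out, "cutoffs") <- tibble::tibble(
      cell_id = character(), n_expressed = integer(), n_kept = integer(),
      cutoff_fpkm = double())
    return(out)
  }
  x <- x[order(x$cell_id, -x$fpkm, x$gene_id), ]
  kept <- dplyr::group_modify(
    dplyr::group_by(x, .data$cell_id),
    function(d, key) utils::head(d, ceiling(percentile * nrow(d)))
  )
  kept <- dplyr::ungroup(kept)
  cutoffs <- dplyr::summarise(
    dplyr::group_by(kept, .data$cell_id),
    n_kept = dplyr::n(),
    cutoff_fpkm = min(.data$fpkm),
    .groups = "drop"
  )
  n_expr <- dplyr::count(dplyr::group_by(x, .data$cell_id), name = "n_expressed")
  cutoffs <- dplyr::left_join(dplyr::ungroup(n_expr), cutoffs, by = "cell_id")
  out <- kept[, c("cell_id", "gene_id")]
  attr(out, "cutoffs") <- cutoffs
  out
}

# gene-by-cell status and mask matrices shared by the cell-type caller and
# the permutation statistics
celltype_matrices <- function(gene_calls, mask, cells) {
  genes <- sort(unique(gene_calls$gene_id))
  cell_ids <- cells$cell_id
  status <- matrix(NA_character_, nrow = length(genes), ncol = length(cell_ids),
                   dimnames = list(genes, cell_ids))
  keep <- gene_calls$cell_id %in% cell_ids
  status[cbind(match(gene_calls$gene_id[keep], genes),
               match(gene_calls$cell_id[keep], cell_ids))] <-
    gene_calls$status[keep]
  m <- matrix(FALSE, nrow = length(genes), ncol = length(cell_ids),
              dimnames = list(genes, cell_ids))
  mk <- mask[mask$gene_id %in% genes & mask$cell_id %in% cell_ids, ]
  m[cbind(match(mk$gene_id, genes), match(mk$cell_id, cell_ids))] <- TRUE
  list(status = status, mask = m)
}

# cell-type MA gene set for a subset of cells, matrix fast path
ma_genes_for_cells <- function(mats, cell_ids, min_support) {
  s <- mats$status[, cell_ids, drop = FALSE]
  m <- mats$mask[, cell_ids, drop = FALSE]
  supporting <- rowSums(s == "MA" & m, na.rm = TRUE)
  vetoed <- rowSums(s == "BA", na.rm = TRUE) > 0
  rownames(s)[supporting >= min_support & !vetoed]
}

#' Cell-type-level monoallelic gene calls
#'
#' A gene is monoallelic in a cell type (within one individual) when at
#' least `min_supporting_cells` cells of the type call it MA while the gene
#' sits in each such cell's top-expression mask, and *no* cell of the type
#' calls it BA. A single BA cell vetoes the call regardless of its
#' expression rank, and regardless of how many cells support MA. A gene
#' with any BA cell is cell-type BA; anything else is undetermined. Cells
#' with Unknown status neither support nor veto.
#'
#' @param gene_calls Per-cell gene status from [gene_status_per_cell()].
#' @param mask Top-percentile mask from [top_percentile_mask()].
#' @param cells Cell metadata.
#' @param config A [pipeline_config()].
#' @return A tibble `gene_id, individual, cell_type, n_supporting_cells,
#'   n_cells_ba, status, supporting_cells` (comma-separated supporting cell
#'   ids).
#' @export
call_celltype_ma <- function(gene_calls, mask, cells,
                             config = pipeline_config()) {
  x <- dplyr::inner_join(gene_calls, cells, by = "cell_id")
  mask_key <- paste(mask$gene_id, mask$cell_id)
  x$in_mask <- paste(x$gene_id, x$cell_id) %in% mask_key
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id, .data$individual, .data$cell_type),
    n_supporting_cells = sum(.data$status == "MA" & .data$in_mask),
    n_cells_ba = sum(.data$status == "BA"),
    supporting_cells = paste(
      sort(.data$cell_id[.data$status == "MA" & .data$in_mask]),
      collapse = ","),
    .groups = "drop"
  )
  out$status <- ifelse(
    out$n_cells_ba >= 1L, "BA",
    ifelse(out$n_supporting_cells >= config$min_supporting_cells, "MA",
           "undetermined")
  )
  out[, c("gene_id", "individual", "cell_type", "n_supporting_cells",
          "n_cells_ba", "status", "supporting_cells")]
}

#' Within- versus between-cell-type MA overlap permutation test
#'
#' Tests whether monoallelic genes are cell-type specific. Each iteration
#' draws, from cell type `type_a`, two disjoint groups of `k` cells (where
#' `k` is the number of `type_b` cells) and counts the overlap of their
#' cell-type MA gene sets (the *within* distribution); and draws `k` cells
#' of `type_a` against all `type_b` cells (the *between* distribution).
#' Cell-type-specific MA expression shows as within-overlap exceeding
#' between-overlap; the two overlap means are compared with a two-sample
#' t-test.
#'
#' @param gene_calls Per-cell gene status.
#' @param mask Top-percentile mask.
#' @param cells Cell metadata, already restricted to the individual of
#'   interest.
#' @param type_a Cell type sampled from; needs at least `2 * k` cells.
#' @param type_b Cell type compared against.
#' @param n_iter Number of permutation draws (default from `config`).
#' @param seed Integer seed for the draws.
#' @param config A [pipeline_config()].
#' @return An object of class `scase_ma_permutation`: a list with `within`
#'   and `between` overlap-count vectors, `t_statistic`, `p_value`, `k`,
#'   and the cell types compared. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
between_vs_within_permutation <- function(gene_calls, mask, cells, type_a,
                                          type_b, n_iter = NULL, seed = 1L,
                                          config = pipeline_config()) {
  if (is.null(n_iter)) n_iter <- config$n_permutations
  cells_a <- cells$cell_id[cells$cell_type == type_a]
  cells_b <- cells$cell_id[cells$cell_type == type_b]
  k <- length(cells_b)
  if (k < 1L) stop("no cells of type ", type_b)
  if (length(cells_a) < 2L * k) {
    stop("need at least ", 2L * k, " cells of type ", type_a,
         " (two disjoint groups of k = ", k, ")")
  }
  mats <- celltype_matrices(gene_calls, mask, cells)
  ma_b <- ma_genes_for_cells(mats, cells_b, config$min_supporting_cells)
  set.seed(seed)
  within <- integer(n_iter)
  between <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    grp <- sample(cells_a, 2L * k)
    ma1 <- ma_genes_for_cells(mats, grp[seq_len(k)], config$min_supporting_cells)
    ma2 <- ma_genes_for_cells(mats, grp[k + seq_len(k)], config$min_supporting_cells)
    within[i] <- length(intersect(ma1, ma2))
    grp_b <- sample(cells_a, k)
    ma3 <- ma_genes_for_cells(mats, grp_b, config$min_supporting_cells)
    between[i] <- length(intersect(ma3, ma_b))
  }
  tt <- tryCatch(stats::t.test(within, between),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  structure(
    list(within = within, between = between,
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         k = k, type_a = type_a, type_b = type_b, n_iter = n_iter),
    class = "scase_ma_permutation"
  )
}

#' Split-half reproducibility of cell-type MA genes
#'
#' Randomly splits the cells of one type into two halves, calls cell-type
#' MA genes in each, and reports the overlap percentage per iteration. The
#' denominator follows `config$overlap_denominator` (union by default:
#' Jaccard index times 100).
#'
#' @param gene_calls Per-cell gene status.
#' @param mask Top-percentile mask.
#' @param cells Cell metadata (one individual).
#' @param cell_type Cell type to split; needs at least 8 cells so each half
#'   can reach the 4-supporting-cell rule.
#' @param n_iter Number of splits.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return A tibble `iteration, n_ma_first, n_ma_second, n_shared,
#'   overlap_pct` (`overlap_pct` is `NA` when the denominator is empty).
#' @export
split_half_overlap <- function(gene_calls, mask, cells, cell_type,
                               n_iter = NULL, seed = 1L,
                               config = pipeline_config()) {
  if (is.null(n_iter)) n_iter <- config$n_permutations
  ids <- cells$cell_id[cells$cell_type == cell_type]
  n <- length(ids)
  if (n < 2L * config$min_supporting_cells) {
    stop("need at least ", 2L * config$min_supporting_cells, " cells of type ",
         cell_type, " to support the per-half MA rule")
  }
  mats <- celltype_matrices(gene_calls, mask, cells)
  h1 <- floor(n / 2)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_iter), function(i) {
    perm <- sample(ids)
    ma1 <- ma_genes_for_cells(mats, perm[seq_len(h1)],
                              config$min_supporting_cells)
    ma2 <- ma_genes_for_cells(mats, perm[(h1 + 1L):n],
                              config$min_supporting_cells)
    shared <- length(intersect(ma1, ma2))
    denom <- switch(config$overlap_denominator,
                    union = length(union(ma1, ma2)),
                    min = min(length(ma1), length(ma2)),
                    intersection_only = 1L)
    pct <- if (config$overlap_denominator == "intersection_only") {
      as.numeric(shared)
    } else if (denom > 0) 100 * shared / denom else NA_real_
    tibble::tibble(iteration = i, n_ma_first = length(ma1),
                   n_ma_second = length(ma2), n_shared = shared,
                   overlap_pct = pct)
  })
}

#' Saturation of cell-type MA discovery with cell number
#'
#' Subsamples `k` cells of a type, calls cell-type MA genes on the subset,
#' and averages the MA-gene count over draws, for each `k`. All subsets are
#' enumerated exactly when there are no more than `n_iter` of them. Because
#' a cell-type MA call needs at least `min_supporting_cells` supporting
#' cells, the curve is identically zero below that subset size.
#'
#' @param gene_calls Per-cell gene status.
#' @param mask Top-percentile mask.
#' @param cells Cell metadata (one individual).
#' @param cell_type Cell type to subsample; needs at least 5 cells.
#' @param n_iter Draws per subset size.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @param k_values Subset sizes (default `1:(n_cells - 1)`).
#' @return A tibble `k, n_draws, mean_n_ma, exact`.
#' @export
saturation_curve <- function(gene_calls, mask, cells, cell_type,
                             n_iter = NULL, seed = 1L,
                             config = pipeline_config(), k_values = NULL) {
  if (is.null(n_iter)) n_iter <- config$n_permutations
  ids <- cells$cell_id[cells$cell_type == cell_type]
  n <- length(ids)
  if (n < 5L) stop("need at least 5 cells of type ", cell_type)
  if (is.null(k_values)) k_values <- seq_len(n - 1L)
  mats <- celltype_matrices(gene_calls, mask, cells)
  set.seed(seed)
  purrr::map_dfr(k_values, function(k) {
    n_comb <- choose(n, k)
    exact <- n_comb <= n_iter
    if (exact) {
      subsets <- utils::combn(ids, k, simplify = FALSE)
    } else {
      subsets <- replicate(n_iter, sample(ids, k), simplify = FALSE)
    }
    counts <- vapply(subsets, function(s) {
      length(ma_genes_for_cells(mats, s, config$min_supporting_cells))
    }, integer(1))
    tibble::tibble(k = k, n_draws = length(subsets),
                   mean_n_ma = mean(counts), exact = exact)
  })
}

#' Shared monoallelic alleles between random cell pairs
#'
#' Draws random pairs of cells of one type and reports the percentage of
#' hetSNP sites called MA in both cells *with the same expressed allele*,
#' relative to the sites called MA in either cell (union denominator by
#' default, configurable). Low sharing indicates random allele choice
#' and/or technical dropout; imprinted expression shares close to 100%.
#'
#' @param calls Site-level calls from [classify_allelic()].
#' @param cells Cell metadata (one individual).
#' @param cell_type Cell type to pair; needs at least 2 cells.
#' @param n_pairs Number of random pairs.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return A tibble `pair, cell_1, cell_2, n_shared, n_denominator,
#'   shared_pct`.
#' @export
shared_ma_allele_pairs <- function(calls, cells, cell_type, n_pairs = NULL,
                                   seed = 1L, config = pipeline_config()) {
  if (is.null(n_pairs)) n_pairs <- config$n_permutations
  ids <- cells$cell_id[cells$cell_type == cell_type]
  if (length(ids) < 2L) stop("need at least 2 cells of type ", cell_type)
  ma <- calls[calls$status == "MA" & calls$cell_id %in% ids, ]
  ma_by_cell <- split(paste(ma$site_id, ma$expressed_allele), ma$cell_id)
  sites_by_cell <- split(ma$site_id, ma$cell_id)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    pr <- sample(ids, 2L)
    a <- ma_by_cell[[pr[1]]] %||% character()
    b <- ma_by_cell[[pr[2]]] %||% character()
    sa <- sites_by_cell[[pr[1]]] %||% character()
    sb <- sites_by_cell[[pr[2]]] %||% character()
    shared <- length(intersect(a, b))
    denom <- switch(config$overlap_denominator,
                    union = length(union(sa, sb)),
                    min = min(length(sa), length(sb)),
                    intersection_only = 1L)
    pct <- if (config$overlap_denominator == "intersection_only") {
      as.numeric(shared)
    } else if (denom > 0) 100 * shared / denom else NA_real_
    tibble::tibble(pair = i, cell_1 = pr[1], cell_2 = pr[2],
                   n_shared = shared, n_denominator = denom,
                   shared_pct = pct)
  })
}

#' Background gene sets for cell-type comparisons
#'
#' Two background definitions are supported: `"covered_hetsnp"` — genes
#' with at least one covered hetSNP in at least one cell of the type (the
#' Venn-style background); `"expressed_fpkm"` — genes with hetSNPs whose
#' mean FPKM across the type's cells is at least
#' `config$background_mean_fpkm` (the enrichment-test background).
#'
#' @param calls Site-level calls.
#' @param sites Site tibble.
#' @param cells Cell metadata.
#' @param cell_type Cell type.
#' @param method Background definition.
#' @param expr Long expression tibble; required for `"expressed_fpkm"`.
#' @param config A [pipeline_config()].
#' @return Character vector of gene ids.
#' @export
background_genes <- function(calls, sites, cells, cell_type,
                             method = c("covered_hetsnp", "expressed_fpkm"),
                             expr = NULL, config = pipeline_config()) {
  method <- match.arg(method)
  ids <- cells$cell_id[cells$cell_type == cell_type]
  gene_map <- sites_single_gene(sites)
  covered <- dplyr::inner_join(calls[calls$cell_id %in% ids, ], gene_map,
                               by = "site_id")
  genes_with_snps <- sort(unique(covered$gene_id))
  if (method == "covered_hetsnp") {
    return(genes_with_snps)
  }
  if (is.null(expr)) stop("expr is required for the expressed_fpkm background")
  e <- expr[expr$cell_id %in% ids & expr$gene_id %in% genes_with_snps, ]
  means <- tapply(e$fpkm, e$gene_id, sum) / length(ids)  # absent cells count 0
  sort(names(means)[means >= config$background_mean_fpkm])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
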