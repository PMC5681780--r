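#' Pool allelic depths across the cells of one individual
#'
#' Heterozygous sites are discovered from pooled read depths: summing each
#' allele's reads over all cells of an individual mimics a bulk RNA-seq
#' library in which both alleles of a gene are visible even when each single
#' cell expresses only one of them.
#'
#' @param counts Allelic count tibble.
#' @param cells Cell metadata tibble.
#' @param individual Individual identifier; must exist in `cells`.
#' @return A tibble `site_id, pooled_ref, pooled_alt, pooled_other`, sites
#'   with zero pooled coverage omitted.
#' @examples
#' counts <- tibble::tibble(site_id = "s1", cell_id = c("c1", "c2"),
#'                          ref_depth = c(3L, 2L), alt_depth = c(0L, 5L),
#'                          other_depth = 0L)
#' cells <- tibble::tibble(cell_id = c("c1", "c2"), individual = "ind01",
#'                         cell_type = "neuron")
#' pool_allelic_depths(counts, cells, "ind01")
#' @export
pool_allelic_depths <- function(counts, cells, individual) {
  if (!individual %in% cells$individual) {
    stop("unknown individual: ", individual)
  }
  keep_cells <- cells$cell_id[cells$individual == individual]
  x <- counts[counts$cell_id %in% keep_cells, ]
  pooled <- dplyr::summarise(
    dplyr::group_by(x, .data$site_id),
    pooled_ref = sum(.data$ref_depth),
    pooled_alt = sum(.data$alt_depth),
    pooled_other = sum(.data$other_depth),
    .groups = "drop"
  )
  pooled[pooled$pooled_ref + pooled$pooled_alt + pooled$pooled_other > 0L, ]
}

#' Call heterozygous SNPs from pooled depths
#'
#' A site is scored heterozygous when both candidate alleles are supported by
#' at least `cutoff` pooled reads. Before applying the cutoff, sites where
#' the reference allele is not among the two most-supported bases of the
#' pooled pileup (reference reads strictly fewer than both the alternative
#' and the unmatched-base reads) are excluded: such sites are dominated by
#' two non-reference alleles and cannot be interpreted against the candidate
#' ref/alt pair.
#'
#' @param pooled Output of [pool_allelic_depths()].
#' @param sites Site tibble (kept for interface symmetry and id checking).
#' @param cutoff Minimum pooled read support per allele (default 20).
#' @return A tibble of called sites: `site_id, pooled_ref, pooled_alt`.
#' @export
call_hetsnps <- function(pooled, sites, cutoff = 20L) {
  stopifnot(cutoff >= 1L)
  unknown <- setdiff(pooled$site_id, sites$site_id)
  if (length(unknown) > 0) {
    stop("pooled depths reference unknown site(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  excluded <- pooled$pooled_ref < pooled$pooled_alt &
    pooled$pooled_ref < pooled$pooled_other
  called <- !excluded &
    pooled$pooled_ref >= cutoff & pooled$pooled_alt >= cutoff
  pooled[called, c("site_id", "pooled_ref", "pooled_alt")]
}

#' Calibrate the pooled-depth cutoff against truth genotypes
#'
#' Sweeps the per-allele read-depth cutoff and, for each value, computes the
#' number of called sites, the positive predictive value (fraction of calls
#' that are truly heterozygous), and the true positive rate (fraction of
#' truth heterozygous sites recovered). This reproduces, on simulated data,
#' the calibration performed against known genotypes to choose a
#' conservative cutoff.
#'
#' @param pooled Output of [pool_allelic_depths()].
#' @param sites Site tibble.
#' @param truth_sites Tibble `site_id, genotype` with genotypes in
#'   `hom_ref, het, hom_alt`, covering all candidate sites.
#' @param cutoffs Integer vector of cutoffs to sweep (default 1:30).
#' @return A tibble of class `scase_calibration`: one row per cutoff with
#'   `cutoff, n_called, n_true_het, ppv, tpr`. `ppv` is `NA` when no site is
#'   called at a cutoff.
#' @export
calibrate_cutoff <- function(pooled, sites, truth_sites, cutoffs = 1:30) {
  missing_truth <- setdiff(pooled$site_id, truth_sites$site_id)
  if (length(missing_truth) > 0) {
    stop("truth genotypes missing for ", length(missing_truth), " site(s)")
  }
  het_sites <- truth_sites$site_id[truth_sites$genotype == "het"]
  rows <- purrr::map_dfr(sort(unique(as.integer(cutoffs))), function(ct) {
    called <- call_hetsnps(pooled, sites, cutoff = ct)$site_id
    n_called <- length(called)
    n_tp <- length(intersect(called, het_sites))
    tibble::tibble(
      cutoff = ct,
      n_called = n_called,
      n_true_het = n_tp,
      ppv = if (n_called > 0) n_tp / n_called else NA_real_,
      tpr = if (length(het_sites) > 0) n_tp / length(het_sites) else NA_real_
    )
  })
  class(rows) <- c("scase_calibration", class(rows))
  rows
}
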