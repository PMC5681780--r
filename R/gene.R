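#' Gene-level allelic status per cell
#'
#' Lifts site-level calls to genes with a fixed hierarchy: a gene is `BA` in
#' a cell if any of its hetSNPs is BA there; otherwise `MA` if any hetSNP is
#' MA; otherwise `Unknown`. Sites mapping to zero or multiple genes are
#' excluded before aggregation, since their signal cannot be attributed to a
#' single gene.
#'
#' @param calls Site-level calls from [classify_allelic()].
#' @param sites Site tibble with the `gene_ids` list-column.
#' @return A tibble `gene_id, cell_id, n_snps_ma, n_snps_ba,
#'   n_snps_unknown, status`.
#' @examples
#' sites <- tibble::tibble(site_id = c("s1", "s2"), chrom = "chr1",
#'                         pos = c(1L, 2L), ref_allele = "A",
#'                         alt_allele = "G", gene_ids = list("G1", "G1"))
#' calls <- tibble::tibble(site_id = c("s1", "s2"), cell_id = "c1",
#'                         status = c("MA", "BA"))
#' gene_status_per_cell(calls, sites)  # BA wins
#' @export
gene_status_per_cell <- function(calls, sites) {
  gene_map <- sites_single_gene(sites)
  x <- dplyr::inner_join(calls, gene_map, by = "site_id")
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id, .data$cell_id),
    n_snps_ma = sum(.data$status == "MA"),
    n_snps_ba = sum(.data$status == "BA"),
    n_snps_unknown = sum(.data$status == "Unknown"),
    .groups = "drop"
  )
  out$status <- ifelse(out$n_snps_ba >= 1L, "BA",
                       ifelse(out$n_snps_ma >= 1L, "MA", "Unknown"))
  out
}

#' Consistency of allelic calls between two hetSNPs of the same gene
#'
#' Restricts to (gene, cell) observations carrying exactly two determinate
#' (MA or BA) site calls and tallies concordant (MA-MA or BA-BA) versus
#' discordant (MA-BA) pairs. High concordance is an internal accuracy check:
#' two exonic hetSNPs of one gene sample the same transcripts and should
#' agree.
#'
#' @param calls Site-level calls.
#' @param sites Site tibble.
#' @return A one-row tibble `n_ma_ma, n_ba_ba, n_ma_ba, n_pairs,
#'   pct_consistent`.
#' @export
two_snp_consistency <- function(calls, sites) {
  gene_map <- sites_single_gene(sites)
  x <- dplyr::inner_join(calls, gene_map, by = "site_id")
  x <- x[x$status %in% c("MA", "BA"), ]
  tab <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id, .data$cell_id),
    n_det = dplyr::n(),
    n_ma = sum(.data$status == "MA"),
    .groups = "drop"
  )
  tab <- tab[tab$n_det == 2L, ]
  n_ma_ma <- sum(tab$n_ma == 2L)
  n_ba_ba <- sum(tab$n_ma == 0L)
  n_ma_ba <- sum(tab$n_ma == 1L)
  n_pairs <- nrow(tab)
  tibble::tibble(
    n_ma_ma = n_ma_ma, n_ba_ba = n_ba_ba, n_ma_ba = n_ma_ba,
    n_pairs = n_pairs,
    pct_consistent = if (n_pairs > 0) 100 * (n_ma_ma + n_ba_ba) / n_pairs else NA_real_
  )
}

#' Distribution of covered hetSNPs per (gene, cell)
#'
#' Counts, over all (gene, cell) observations with at least one covered
#' hetSNP, how many carry one, two, or more than two covered sites.
#'
#' @param calls Site-level calls.
#' @param sites Site tibble.
#' @return A tibble `bin` (`"1"`, `"2"`, `">2"`), `n`, `frac`.
#' @export
snp_per_gene_histogram <- function(calls, sites) {
  gene_map <- sites_single_gene(sites)
  x <- dplyr::inner_join(calls, gene_map, by = "site_id")
  tab <- dplyr::count(dplyr::group_by(x, .data$gene_id, .data$cell_id),
                      name = "n_snps")
  bins <- factor(ifelse(tab$n_snps == 1L, "1",
                        ifelse(tab$n_snps == 2L, "2", ">2")),
                 levels = c("1", "2", ">2"))
  counts <- as.integer(table(bins))
  out <- tibble::tibble(bin = levels(bins), n = counts)
  out$frac <- if (sum(out$n) > 0) out$n / sum(out$n) else NA_real_
  out
}
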