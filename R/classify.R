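#' Classify per-cell allelic expression at heterozygous sites
#'
#' For every (hetSNP, cell) observation with at least one informative read,
#' tests the reference read count against a balanced binomial null and
#' assigns one of three statuses:
#'
#' * `MA` (monoallelic): BH-adjusted p-value below `ma_fdr` **and** strictly
#'   more than `ma_ratio` of the informative reads from one allele;
#' * `BA` (biallelic): not MA, and both alleles supported by at least
#'   `ba_min_allele_reads` reads;
#' * `Unknown`: covered but satisfying neither rule.
#'
#' MA takes precedence: an observation meeting the MA criteria is MA even if
#' the minor allele has enough reads for BA. Reads matching neither
#' candidate allele (`other_depth`) are ignored throughout. The BH family
#' is, by default, all tested observations passed in one call (intended to
#' be one individual); set `fdr_family = "cell"` in the configuration to
#' adjust within each cell instead, or pass `cells` to adjust within each
#' individual when `counts` spans several.
#'
#' @param counts Allelic count tibble.
#' @param hetsnps Character vector of called heterozygous site ids (or a
#'   tibble with a `site_id` column, as returned by [call_hetsnps()]).
#' @param config A [pipeline_config()].
#' @param cells Optional cell metadata; when supplied, BH adjustment pools
#'   observations within each individual.
#' @return A tibble with one row per covered (site, cell): `site_id,
#'   cell_id, ref_depth, alt_depth, ref_ratio, p_value, fdr, status,
#'   expressed_allele` (`ref`/`alt` for MA calls, `NA` otherwise).
#' @examples
#' cfg <- pipeline_config()
#' counts <- tibble::tibble(site_id = "s1", cell_id = c("c1", "c2", "c3"),
#'                          ref_depth = c(20L, 10L, 1L),
#'                          alt_depth = c(0L, 10L, 0L), other_depth = 0L)
#' classify_allelic(counts, "s1", cfg)
#' @export
classify_allelic <- function(counts, hetsnps, config = pipeline_config(),
                             cells = NULL) {
  if (is.data.frame(hetsnps)) hetsnps <- hetsnps$site_id
  x <- counts[counts$site_id %in% hetsnps, ]
  x <- x[x$ref_depth + x$alt_depth >= 1L, ]
  if (nrow(x) == 0) {
    return(tibble::tibble(
      site_id = character(), cell_id = character(), ref_depth = integer(),
      alt_depth = integer(), ref_ratio = double(), p_value = double(),
      fdr = double(), status = character(), expressed_allele = character()
    ))
  }
  n <- x$ref_depth + x$alt_depth
  ratio <- x$ref_depth / n
  p <- binom_test_two_sided(x$ref_depth, n,
                            alternative = config$binom_alternative)
  if (config$fdr_family == "cell") {
    fam <- x$cell_id
  } else if (!is.null(cells)) {
    fam <- cells$individual[match(x$cell_id, cells$cell_id)]
  } else {
    fam <- rep("all", nrow(x))
  }
  fdr <- stats::ave(p, fam, FUN = bh_adjust)

  major_ratio <- pmax(ratio, 1 - ratio)
  is_ma <- major_ratio > config$ma_ratio & fdr < config$ma_fdr
  is_ba <- !is_ma & x$ref_depth >= config$ba_min_allele_reads &
    x$alt_depth >= config$ba_min_allele_reads
  status <- ifelse(is_ma, "MA", ifelse(is_ba, "BA", "Unknown"))

  tibble::tibble(
    site_id = x$site_id,
    cell_id = x$cell_id,
    ref_depth = x$ref_depth,
    alt_depth = x$alt_depth,
    ref_ratio = ratio,
    p_value = p,
    fdr = fdr,
    status = status,
    expressed_allele = ifelse(is_ma, ifelse(ratio > 0.5, "ref", "alt"),
                              NA_character_)
  )
}

#' Pseudo-bulk allelic ratios
#'
#' Pools allelic reads over groups of cells (per individual, or per
#' individual and cell type) and reports the pooled reference-allele ratio
#' per site. Pooling many cells mimics a bulk RNA-seq measurement: random
#' monoallelic expression that is extreme in single cells averages toward
#' balanced ratios in the pool, while imprinted genes stay extreme.
#'
#' @param counts Allelic count tibble.
#' @param cells Cell metadata.
#' @param group_by `"individual"` or `"individual_cell_type"`.
#' @return A tibble `site_id, individual[, cell_type], pooled_ref,
#'   pooled_alt, pooled_depth, ref_ratio` (sites with zero informative pooled
#'   reads omitted).
#' @export
pseudo_bulk_ratios <- function(counts, cells,
                               group_by = c("individual", "individual_cell_type")) {
  group_by <- match.arg(group_by)
  x <- dplyr::inner_join(counts, cells, by = "cell_id")
  keys <- if (group_by == "individual") "individual" else c("individual", "cell_type")
  out <- dplyr::summarise(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(c("site_id", keys)))),
    pooled_ref = sum(.data$ref_depth),
    pooled_alt = sum(.data$alt_depth),
    .groups = "drop"
  )
  out$pooled_depth <- out$pooled_ref + out$pooled_alt
  out <- out[out$pooled_depth > 0L, ]
  out$ref_ratio <- out$pooled_ref / out$pooled_depth
  out
}

#' Band the pseudo-bulk ratio distribution
#'
#' Bins pooled reference-allele ratios into fixed-width bands and reports,
#' per group, the fraction of sites whose pooled ratio falls in a central
#' band (default 0.4-0.6), the bulk signature of balanced biallelic
#' expression.
#'
#' @param pseudo_bulk Output of [pseudo_bulk_ratios()].
#' @param binwidth Histogram bin width (default 0.1).
#' @param band Closed interval treated as "balanced" (default `c(0.4, 0.6)`).
#' @param min_depth Minimum pooled depth for a site to enter the summary
#'   (default 1).
#' @return A list with `histogram` (per-group bin counts) and `band`
#'   (per-group `n_sites, n_in_band, frac_in_band`).
#' @export
ratio_band_summary <- function(pseudo_bulk, binwidth = 0.1,
                               band = c(0.4, 0.6), min_depth = 1L) {
  x <- pseudo_bulk[pseudo_bulk$pooled_depth >= min_depth, ]
  keys <- intersect(c("individual", "cell_type"), names(x))
  breaks <- seq(0, 1, by = binwidth)
  x$bin <- cut(x$ref_ratio, breaks = breaks, include.lowest = TRUE)
  hist <- dplyr::count(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))), .data$bin,
    .drop = FALSE, name = "n"
  )
  x$in_band <- x$ref_ratio >= band[1] & x$ref_ratio <= band[2]
  band_tbl <- dplyr::summarise(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))),
    n_sites = dplyr::n(),
    n_in_band = sum(.data$in_band),
    frac_in_band = mean(.data$in_band),
    .groups = "drop"
  )
  list(histogram = dplyr::ungroup(hist), band = band_tbl)
}

#' Compare pooled allelic ratios of imprinted versus other genes
#'
#' Imprinted genes express one parental allele in every cell, so their
#' pooled reference-allele ratios deviate from 0.5 even in large pools. The
#' check compares `|ratio - 0.5|` between sites in a supplied imprinted gene
#' list and all other sites, per group, with a one-sided rank-sum test
#' (alternative: imprinted deviations are larger).
#'
#' @param pseudo_bulk Output of [pseudo_bulk_ratios()].
#' @param imprinted_genes Character vector of imprinted gene ids; must be
#'   non-empty.
#' @param sites Site tibble with `gene_ids`; only single-gene sites are
#'   used.
#' @return An object of class `scase_imprinted_check`: a list with
#'   `observations` (per-site deviations and imprinted flag) and `tests`
#'   (per-group medians, rank-sum statistic and one-sided p-value).
#' @export
imprinted_ratio_check <- function(pseudo_bulk, imprinted_genes, sites) {
  if (length(imprinted_genes) == 0) stop("imprinted gene set is empty")
  gene_map <- sites_single_gene(sites)
  x <- dplyr::inner_join(pseudo_bulk, gene_map, by = "site_id")
  x$imprinted <- x$gene_id %in% imprinted_genes
  x$deviation <- abs(x$ref_ratio - 0.5)
  keys <- intersect(c("individual", "cell_type"), names(x))
  tests <- dplyr::group_modify(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))),
    function(d, key) {
      a <- d$deviation[d$imprinted]
      b <- d$deviation[!d$imprinted]
      if (length(a) == 0 || length(b) == 0) {
        return(tibble::tibble(
          n_imprinted = length(a), n_other = length(b),
          median_dev_imprinted = stats::median(a),
          median_dev_other = stats::median(b),
          statistic = NA_real_, p_value = NA_real_
        ))
      }
      ts <- rank_sum_test(a, b, alternative = "greater")
      tibble::tibble(
        n_imprinted = length(a), n_other = length(b),
        median_dev_imprinted = stats::median(a),
        median_dev_other = stats::median(b),
        statistic = ts$statistic, p_value = ts$p_value
      )
    }
  )
  structure(list(observations = x, tests = dplyr::ungroup(tests)),
            class = "scase_imprinted_check")
}

#' @export
print.scase_imprinted_check <- function(x, ...) {
  cat("<imprinted-gene pooled ratio check>\n")
  print(x$tests)
  invisible(x)
}
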