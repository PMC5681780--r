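#' Cells expressing each allele, per hetSNP, by functional class
#'
#' For every heterozygous site, counts the cells in which the reference and
#' the alternative allele are each expressed (at least
#' `config$disruption_min_each` reads), grouped by the functional class of
#' the alternative allele under the chosen annotation scheme. A functionally
#' disrupted alternative allele (e.g. a stop-gain) is expected to be
#' expressed in fewer cells than its reference counterpart, for instance
#' through nonsense-mediated decay of the damaged transcript.
#'
#' @param counts Allelic count tibble.
#' @param annot Annotation tibble from [read_annotation_table()] (or a
#'   simulation).
#' @param hetsnps Character vector of hetSNP site ids (or a tibble with a
#'   `site_id` column).
#' @param scheme `"SNV"` (S/N/L/G), `"SIFT"` (S/T/D), `"PPH_HDIV"` or
#'   `"PPH_HVAR"` (S/B/P/D).
#' @param config A [pipeline_config()].
#' @return A tibble `site_id, annotation_class, n_cells_ref, n_cells_alt`
#'   (sites without a class under the scheme are dropped).
#' @export
expressing_cell_counts <- function(counts, annot, hetsnps,
                                   scheme = c("SNV", "SIFT", "PPH_HDIV", "PPH_HVAR"),
                                   config = pipeline_config()) {
  scheme <- match.arg(scheme)
  cls <- annotation_class_column(annot, scheme)
  if (is.data.frame(hetsnps)) hetsnps <- hetsnps$site_id
  x <- counts[counts$site_id %in% hetsnps, ]
  per_site <- dplyr::summarise(
    dplyr::group_by(x, .data$site_id),
    n_cells_ref = sum(.data$ref_depth >= config$disruption_min_each),
    n_cells_alt = sum(.data$alt_depth >= config$disruption_min_each),
    .groups = "drop"
  )
  # hetSNPs with no coverage at all still count as (0, 0)
  missing <- setdiff(hetsnps, per_site$site_id)
  if (length(missing) > 0) {
    per_site <- dplyr::bind_rows(
      per_site,
      tibble::tibble(site_id = missing, n_cells_ref = 0L, n_cells_alt = 0L)
    )
  }
  per_site$annotation_class <- unname(cls[per_site$site_id])
  out <- per_site[!is.na(per_site$annotation_class),
                  c("site_id", "annotation_class", "n_cells_ref", "n_cells_alt")]
  out[order(out$site_id), ]
}

#' Reference-read fractions at biallelically covered sites, by class
#'
#' One observation per (site, cell) where both alleles have at least
#' `config$disruption_min_each` reads and the informative total reaches
#' `config$disruption_min_sum`; a site expressed in several cells appears as
#' several observations. The reference fraction measures how strongly
#' expression leans toward the reference allele where both alleles are
#' detectably expressed.
#'
#' @inheritParams expressing_cell_counts
#' @return A tibble `site_id, cell_id, annotation_class, ref_fraction`.
#' @export
ref_fraction_by_class <- function(counts, annot, hetsnps,
                                  scheme = c("SNV", "SIFT", "PPH_HDIV", "PPH_HVAR"),
                                  config = pipeline_config()) {
  scheme <- match.arg(scheme)
  cls <- annotation_class_column(annot, scheme)
  if (is.data.frame(hetsnps)) hetsnps <- hetsnps$site_id
  x <- counts[counts$site_id %in% hetsnps, ]
  keep <- pmin(x$ref_depth, x$alt_depth) >= config$disruption_min_each &
    (x$ref_depth + x$alt_depth) >= config$disruption_min_sum
  x <- x[keep, ]
  out <- tibble::tibble(
    site_id = x$site_id,
    cell_id = x$cell_id,
    annotation_class = unname(cls[x$site_id]),
    ref_fraction = x$ref_depth / (x$ref_depth + x$alt_depth)
  )
  out[!is.na(out$annotation_class), ]
}

#' Compare a statistic between two annotation classes
#'
#' One-sided (or two-sided) Wilcoxon rank-sum comparison of a per-observation
#' value (by default the reference-read fraction) between two annotation
#' classes, e.g. stop-gain versus synonymous. The exact null distribution is
#' used when both classes have at most 25 observations and no ties; the
#' normal approximation otherwise (see [rank_sum_test()]).
#'
#' @param observations Tibble with `annotation_class` and the value column.
#' @param class_a,class_b Class labels to compare; both must be non-empty in
#'   `observations`.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"` — sidedness of
#'   `class_a` relative to `class_b`.
#' @param value Name of the value column (default `"ref_fraction"`).
#' @return A one-row tibble `class_a, class_b, n_a, n_b, median_a, median_b,
#'   statistic, p_value, method`.
#' @export
class_comparison_tests <- function(observations, class_a, class_b,
                                   alternative = c("greater", "less", "two.sided"),
                                   value = "ref_fraction") {
  alternative <- match.arg(alternative)
  a <- observations[[value]][observations$annotation_class == class_a]
  b <- observations[[value]][observations$annotation_class == class_b]
  if (length(a) == 0) stop("no observations in class ", class_a)
  if (length(b) == 0) stop("no observations in class ", class_b)
  ts <- rank_sum_test(a, b, alternative = alternative)
  tibble::tibble(
    class_a = class_a, class_b = class_b,
    n_a = length(a), n_b = length(b),
    median_a = stats::median(a), median_b = stats::median(b),
    statistic = ts$statistic, p_value = ts$p_value, method = ts$method
  )
}

#' Compare expressing-cell counts of reference versus alternative alleles
#'
#' Within one annotation class, rank-sum comparison of the number of cells
#' expressing the reference allele against the number expressing the
#' alternative allele across sites (alternative `"greater"`: reference
#' expressed in more cells).
#'
#' @param allele_counts Output of [expressing_cell_counts()].
#' @param class Annotation class to test.
#' @param alternative Test sidedness for reference versus alternative.
#' @return A one-row tibble `annotation_class, n_sites, median_ref,
#'   median_alt, statistic, p_value, method`.
#' @export
allele_expressing_test <- function(allele_counts, class,
                                   alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- allele_counts[allele_counts$annotation_class == class, ]
  if (nrow(x) == 0) stop("no sites in class ", class)
  ts <- rank_sum_test(x$n_cells_ref, x$n_cells_alt, alternative = alternative)
  tibble::tibble(
    annotation_class = class, n_sites = nrow(x),
    median_ref = stats::median(x$n_cells_ref),
    median_alt = stats::median(x$n_cells_alt),
    statistic = ts$statistic, p_value = ts$p_value, method = ts$method
  )
}

annotation_class_column <- function(annot, scheme) {
  col <- switch(scheme,
                SNV = "snv_class", SIFT = "sift_class",
                PPH_HDIV = "pph_hdiv_class", PPH_HVAR = "pph_hvar_class")
  if (!col %in% names(annot)) stop("annotation lacks column for scheme ", scheme)
  stats::setNames(annot[[col]], annot$site_id)
}
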