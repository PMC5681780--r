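#' Pipeline configuration
#'
#' Bundles every tunable threshold of the allelic-expression pipeline into a
#' single validated list, so that all stages of an analysis are driven by one
#' object that can be written to and read from YAML.
#'
#' @param pooled_depth_cutoff Minimum pooled read support required for *each*
#'   allele before a site is called heterozygous (default 20 reads).
#' @param ma_fdr Benjamini-Hochberg FDR threshold below which a site-cell
#'   observation may be called monoallelic (default 0.05).
#' @param ma_ratio Allelic-ratio threshold: a monoallelic call additionally
#'   requires strictly more than this fraction of reads from one allele
#'   (default 0.95; a ratio of exactly 0.95 is not monoallelic).
#' @param ba_min_allele_reads Minimum reads per allele to confirm biallelic
#'   expression (default 2).
#' @param min_supporting_cells Minimum number of supporting cells for a
#'   cell-type-level monoallelic gene call (default 4).
#' @param expr_percentile Expressed-gene percentile a cell-type MA supporting
#'   cell must reach: the gene must rank in the top `expr_percentile` of that
#'   cell's non-zero-FPKM genes (default 0.30).
#' @param disruption_min_each Per-allele read minimum for the disrupted-allele
#'   analyses (default 2).
#' @param disruption_min_sum Total-read minimum for the reference-fraction
#'   observations of the disrupted-allele analyses (default 10).
#' @param background_mean_fpkm Mean-FPKM floor defining "expressed" background
#'   genes for enrichment-style comparisons (default 1).
#' @param n_permutations Number of random draws for permutation analyses
#'   (default 1000).
#' @param fdr_family Family over which p-values are jointly BH-adjusted:
#'   `"individual"` pools all (site, cell) tests of one individual (default),
#'   `"cell"` adjusts within each cell separately.
#' @param binom_alternative Sidedness of the binomial test (default
#'   `"two.sided"`; `"one.sided"` tests departure toward the majority allele).
#' @param overlap_denominator Denominator of permutation overlap percentages:
#'   `"union"` (Jaccard, default), `"min"`, or `"intersection_only"` (raw
#'   intersection counts, no percentage scaling).
#' @param rng_seed Integer seed used by stages that draw random numbers.
#'
#' @return A list of class `scase_config`.
#' @examples
#' cfg <- pipeline_config(ma_fdr = 0.01)
#' cfg$ma_fdr
#' @export
pipeline_config <- function(pooled_depth_cutoff = 20L,
                            ma_fdr = 0.05,
                            ma_ratio = 0.95,
                            ba_min_allele_reads = 2L,
                            min_supporting_cells = 4L,
                            expr_percentile = 0.30,
                            disruption_min_each = 2L,
                            disruption_min_sum = 10L,
                            background_mean_fpkm = 1.0,
                            n_permutations = 1000L,
                            fdr_family = c("individual", "cell"),
                            binom_alternative = c("two.sided", "one.sided"),
                            overlap_denominator = c("union", "min", "intersection_only"),
                            rng_seed = 1L) {
  fdr_family <- match.arg(fdr_family)
  binom_alternative <- match.arg(binom_alternative)
  overlap_denominator <- match.arg(overlap_denominator)
  cfg <- list(
    pooled_depth_cutoff = as.integer(pooled_depth_cutoff),
    ma_fdr = ma_fdr,
    ma_ratio = ma_ratio,
    ba_min_allele_reads = as.integer(ba_min_allele_reads),
    min_supporting_cells = as.integer(min_supporting_cells),
    expr_percentile = expr_percentile,
    disruption_min_each = as.integer(disruption_min_each),
    disruption_min_sum = as.integer(disruption_min_sum),
    background_mean_fpkm = background_mean_fpkm,
    n_permutations = as.integer(n_permutations),
    fdr_family = fdr_family,
    binom_alternative = binom_alternative,
    overlap_denominator = overlap_denominator,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "scase_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$ma_ratio > 0, cfg$ma_ratio < 1,
    cfg$ma_fdr > 0, cfg$ma_fdr < 1,
    cfg$expr_percentile > 0, cfg$expr_percentile <= 1,
    cfg$pooled_depth_cutoff >= 1L,
    cfg$ba_min_allele_reads >= 1L,
    cfg$min_supporting_cells >= 1L,
    cfg$disruption_min_each >= 1L,
    cfg$disruption_min_sum >= 1L,
    cfg$n_permutations >= 1L
  )
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected so that typos do not silently fall
#' back to defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a `scase_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config A `scase_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "scase_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.scase_config <- function(x, ...) {
  cat("<scase pipeline configuration>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
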