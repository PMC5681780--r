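#' Read candidate SNP sites and assign them to genes
#'
#' Reads a VCF-like site list (tab-separated `CHROM POS ID REF ALT ...`
#' columns, `##` meta lines ignored) and a gene model, and annotates every
#' site with all gene intervals it falls in. Multi-gene sites are kept here;
#' downstream gene-level analysis excludes them.
#'
#' Coordinates are 1-based and fully closed for sites. BED gene models are
#' converted from 0-based half-open intervals on read; GTF/GFF models are
#' read with [rtracklayer::import()] and are already 1-based.
#'
#' @param path Path to the VCF-like site list.
#' @param gene_model Path to a BED (4+ columns, name column = gene id) or
#'   GTF/GFF file with `gene_id` attributes.
#' @return A tibble with columns `site_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, and a list-column `gene_ids`.
#' @export
read_snp_sites <- function(path, gene_model) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) == 0) stop("empty site list: ", path)
  header <- startsWith(lines[1], "#CHROM")
  raw <- utils::read.table(
    text = lines, sep = "\t", header = FALSE, skip = as.integer(header),
    colClasses = "character", comment.char = ""
  )
  if (ncol(raw) < 5) stop("site list needs CHROM POS ID REF ALT columns: ", path)
  names(raw)[1:5] <- c("chrom", "pos", "id", "ref", "alt")
  pos <- suppressWarnings(as.integer(raw$pos))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad) > 0) {
    stop("malformed POS at line ", bad[1] + as.integer(header), " of ", path)
  }
  if (any(raw$ref == raw$alt)) {
    stop("REF equals ALT at line ",
         which(raw$ref == raw$alt)[1] + as.integer(header), " of ", path)
  }
  site_id <- raw$id
  site_id[is.na(site_id) | site_id == "." | site_id == ""] <-
    paste0(raw$chrom, ":", raw$pos)[is.na(site_id) | site_id == "." | site_id == ""]
  if (anyDuplicated(site_id)) stop("duplicate site_id in ", path)

  sites <- tibble::tibble(
    site_id = site_id, chrom = raw$chrom, pos = pos,
    ref_allele = raw$ref, alt_allele = raw$alt
  )
  genes <- read_gene_model(gene_model)
  hits <- dplyr::inner_join(
    sites[, c("site_id", "chrom", "pos")], genes,
    by = dplyr::join_by(chrom, dplyr::between(pos, start, end)),
    relationship = "many-to-many"
  )
  gene_map <- split(hits$gene_id, hits$site_id)
  sites$gene_ids <- lapply(sites$site_id, function(s) {
    g <- gene_map[[s]]
    if (is.null(g)) character() else sort(unique(g))
  })
  sites
}

#' Read a gene model as 1-based closed intervals
#'
#' @param path BED or GTF/GFF file.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end` (1-based,
#'   closed).
#' @export
read_gene_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    md <- as.data.frame(gr)
    if (!"gene_id" %in% names(md)) stop("gene model lacks gene_id attributes: ", path)
    out <- tibble::tibble(
      gene_id = as.character(md$gene_id),
      chrom = as.character(md$seqnames),
      start = as.integer(md$start),
      end = as.integer(md$end)
    )
  } else {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character")
    if (ncol(bed) < 4) stop("BED gene model needs at least 4 columns: ", path)
    out <- tibble::tibble(
      gene_id = bed[[4]],
      chrom = bed[[1]],
      start = as.integer(bed[[2]]) + 1L,  # 0-based half-open -> 1-based closed
      end = as.integer(bed[[3]])
    )
  }
  if (any(is.na(out$start)) || any(out$start > out$end)) {
    stop("invalid gene intervals in ", path)
  }
  out
}

#' Read a sparse allelic read-depth table
#'
#' Expects a TSV with header `site_id cell_id ref_depth alt_depth
#' other_depth`. The table is sparse: absent (site, cell) pairs mean zero
#' coverage. Rows naming a site absent from `sites`, negative depths, and
#' duplicate (site, cell) rows are rejected.
#'
#' @param path Path to the TSV.
#' @param sites Site tibble from [read_snp_sites()] (or a simulation); used
#'   for referential integrity.
#' @return A tibble `site_id, cell_id, ref_depth, alt_depth, other_depth`.
#' @export
read_allelic_counts <- function(path, sites) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    site_id = readr::col_character(), cell_id = readr::col_character(),
    ref_depth = readr::col_integer(), alt_depth = readr::col_integer(),
    other_depth = readr::col_integer()
  ))
  if (any(is.na(x$ref_depth) | is.na(x$alt_depth) | is.na(x$other_depth))) {
    stop("non-integer depth in ", path)
  }
  if (any(x$ref_depth < 0 | x$alt_depth < 0 | x$other_depth < 0)) {
    stop("negative depth in ", path)
  }
  if (anyDuplicated(x[, c("site_id", "cell_id")])) {
    stop("duplicate (site_id, cell_id) row in ", path)
  }
  unknown <- setdiff(x$site_id, sites$site_id)
  if (length(unknown) > 0) {
    stop("count rows reference unknown site(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  x
}

#' Look up allelic depths with a sparse zero default
#'
#' @param counts Count tibble.
#' @param site_id,cell_id Scalars identifying one observation.
#' @return Named integer vector `ref_depth, alt_depth, other_depth`; zeros
#'   when the pair is absent.
#' @export
count_lookup <- function(counts, site_id, cell_id) {
  row <- counts[counts$site_id == site_id & counts$cell_id == cell_id, ]
  if (nrow(row) == 0) {
    return(c(ref_depth = 0L, alt_depth = 0L, other_depth = 0L))
  }
  c(ref_depth = row$ref_depth[[1]], alt_depth = row$alt_depth[[1]],
    other_depth = row$other_depth[[1]])
}

#' Read cell metadata
#'
#' TSV with header `cell_id individual cell_type`; cell ids must be unique.
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_cell_metadata <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("cell_id", "individual", "cell_type")
  if (!all(req %in% names(x))) stop("cell metadata needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(x$cell_id)) stop("duplicate cell_id in ", path)
  x[, req]
}

#' Read a gene-by-cell FPKM matrix
#'
#' Wide TSV: first column `gene_id`, one column per cell. Returned in long
#' sparse form (zero entries dropped); absent (gene, cell) pairs mean zero.
#'
#' @param path Path to the TSV.
#' @return A tibble `gene_id, cell_id, fpkm`.
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  long <- tidyr::pivot_longer(x, -"gene_id", names_to = "cell_id",
                              values_to = "fpkm")
  if (any(long$fpkm < 0, na.rm = TRUE)) stop("negative FPKM in ", path)
  long[!is.na(long$fpkm) & long$fpkm > 0, ]
}

#' Read an SNV functional-annotation table
#'
#' TSV with header `site_id snv_class sift_class pph_hdiv_class
#' pph_hvar_class`; the last three may be `NA` for sites without a
#' prediction. SNV classes follow the exome-summary convention:
#' S synonymous, N non-synonymous, L stop-loss, G stop-gain.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_annotation_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("site_id", "snv_class")
  if (!all(req %in% names(x))) stop("annotation needs columns: ", paste(req, collapse = ", "))
  if (any(is.na(x$snv_class))) stop("snv_class must be present for every annotated site")
  for (col in c("sift_class", "pph_hdiv_class", "pph_hvar_class")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  x[, c("site_id", "snv_class", "sift_class", "pph_hdiv_class", "pph_hvar_class")]
}

# ---- writers -----------------------------------------------------------

#' Write pipeline tables
#'
#' Writers matching the readers above, used by the simulation subcommand and
#' by tests; a write followed by the corresponding read reproduces the
#' in-memory object.
#'
#' @param sites,counts,cells,expression,annotation Objects as produced by the
#'   readers or [simulate_allelic_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_snp_sites <- function(sites, path) {
  vcf <- data.frame(
    "#CHROM" = sites$chrom, POS = sites$pos, ID = sites$site_id,
    REF = sites$ref_allele, ALT = sites$alt_allele, QUAL = ".", FILTER = ".",
    INFO = ".", check.names = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  utils::write.table(vcf, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @param gene_model Gene-interval tibble (`gene_id, chrom, start, end`,
#'   1-based closed), e.g. `truth$genes` of a simulation.
#' @export
write_gene_model_bed <- function(gene_model, path) {
  bed <- data.frame(gene_model$chrom, gene_model$start - 1L, gene_model$end,
                    gene_model$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_allelic_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname writers
#' @export
write_cell_metadata <- function(cells, path) {
  readr::write_tsv(cells[, c("cell_id", "individual", "cell_type")], path)
  invisible(path)
}

#' @rdname writers
#' @export
write_expression_matrix <- function(expression, path) {
  wide <- tidyr::pivot_wider(expression, names_from = "cell_id",
                             values_from = "fpkm", values_fill = 0)
  wide <- wide[order(wide$gene_id), ]
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname writers
#' @export
write_annotation_table <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' Write a full simulated dataset to a directory
#'
#' Emits every pipeline input format plus the truth tables
#' (`truth_sites.tsv`, `truth_genes.tsv`, `truth_gene_cell.tsv`).
#'
#' @param sim A `scase_sim` from [simulate_allelic_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "scase_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sites = file.path(dir, "sites.vcf"),
    gene_model = file.path(dir, "genes.bed"),
    counts = file.path(dir, "allelic_counts.tsv"),
    expression = file.path(dir, "expression_fpkm.tsv"),
    cells = file.path(dir, "cell_metadata.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_gene_cell = file.path(dir, "truth_gene_cell.tsv")
  )
  write_snp_sites(sim$sites, paths[["sites"]])
  write_gene_model_bed(sim$truth$genes, paths[["gene_model"]])
  write_allelic_counts(sim$counts, paths[["counts"]])
  write_expression_matrix(sim$expression, paths[["expression"]])
  write_cell_metadata(sim$cells, paths[["cells"]])
  write_annotation_table(sim$annotation, paths[["annotation"]])
  readr::write_tsv(sim$truth$sites, paths[["truth_sites"]])
  readr::write_tsv(sim$truth$genes, paths[["truth_genes"]])
  readr::write_tsv(sim$truth$gene_cell, paths[["truth_gene_cell"]])
  invisible(paths)
}

# sites with exactly one gene assignment, as a plain site -> gene lookup
sites_single_gene <- function(sites) {
  keep <- lengths(sites$gene_ids) == 1L
  tibble::tibble(
    site_id = sites$site_id[keep],
    gene_id = vapply(sites$gene_ids[keep], `[[`, "", 1L)
  )
}
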