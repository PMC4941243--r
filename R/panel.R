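#' Cholesterol-metabolism pathway SNP panel
#'
#' Loads the packaged 33-SNP / 12-gene tagging panel used throughout the
#' pipeline. Each row gives the rs identifier, gene symbol and the two
#' alleles of the SNP (first character = minor allele by package convention).
#' The `sim_maf` column holds plausible synthetic minor-allele frequencies
#' used by the data generator; they are package defaults, not measured
#' population frequencies.
#'
#' @param path Optional path to an alternative panel TSV with columns
#'   `snp_id`, `gene`, `allele` and optionally `sim_maf`.
#' @return A tibble with columns `snp_id`, `gene`, `allele`, `sim_maf`.
#' @export
#' @examples
#' panel <- snp_panel()
#' nrow(panel)            # 33
#' dplyr::n_distinct(panel$gene)  # 12
snp_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cholesterol_snp_panel.tsv",
                                package = "alffnet", mustWork = TRUE)
  panel <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             snp_id = readr::col_character(),
                             gene = readr::col_character(),
                             allele = readr::col_character(),
                             sim_maf = readr::col_double()
                           ))
  if (anyDuplicated(panel$snp_id)) {
    abort("panel contains duplicated snp_id entries")
  }
  if (any(!nzchar(panel$gene)) || any(is.na(panel$gene))) {
    abort("panel gene symbols must be non-empty")
  }
  if (any(nchar(panel$allele) != 2)) {
    abort("panel alleles must be two-character strings")
  }
  panel
}

#' Interaction-cluster ROI table
#'
#' Loads the packaged table of regions whose SNP-by-diagnosis interaction
#' clusters survived imaging-space correction: one row per region with the
#' defining SNP and gene, anatomical label, hemisphere tag, peak MNI
#' coordinate (mm), cluster size (cubic mm), peak F value and the two
#' correction flags (`pass_S`: imaging-space corrected; `pass_SG`:
#' additionally corrected across SNPs per gene).
#'
#' @param path Optional path to an alternative ROI TSV with the same columns.
#' @return A tibble of ROIs with a unique `roi_id` column prepended.
#' @export
#' @examples
#' rois <- roi_table()
#' nrow(rois)  # 31
roi_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "interaction_roi_table.tsv",
                                package = "alffnet", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           snp_id = readr::col_character(),
                           gene = readr::col_character(),
                           allele = readr::col_character(),
                           label = readr::col_character(),
                           abbrev = readr::col_character(),
                           hemisphere = readr::col_character(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           z = readr::col_double(),
                           cluster_size_mm3 = readr::col_double(),
                           peak_F = readr::col_double(),
                           pass_S = readr::col_logical(),
                           pass_SG = readr::col_logical()
                         ))
  if (nrow(raw) == 0) abort("ROI table is empty")
  required <- c("snp_id", "gene", "abbrev", "hemisphere", "x", "y", "z",
                "cluster_size_mm3", "peak_F", "pass_S", "pass_SG")
  bad <- which(!complete.cases(raw[required]))
  if (length(bad) > 0) {
    abort(sprintf("malformed ROI row(s) at line(s): %s",
                  paste(bad + 1, collapse = ", ")))
  }
  if (!all(raw$hemisphere %in% c("L", "R", "bilateral", "vermis"))) {
    abort("hemisphere must be one of L, R, bilateral, vermis")
  }
  if (any(raw$pass_SG & !raw$pass_S)) {
    abort("pass_SG requires pass_S")
  }
  dplyr::mutate(raw,
                roi_id = paste(.data$abbrev, .data$snp_id, sep = "_"),
                .before = 1)
}
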