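# Small shared fixtures, built once per test run.

# desk-scale study grid
study_mask <- ellipsoid_mask(c(24, 28, 24))
study_affine <- default_affine(c(24, 28, 24), 3)

# compact grid for fast pipeline-level tests
tiny_config <- function(seed = 1, effect_blobs = list(), ...) {
  simulation_config(grid_shape = c(14, 16, 14), n_volumes = 40, n_discard = 4,
                    n_amci = 8, n_controls = 8, effect_blobs = effect_blobs,
                    seed = seed, ...)
}

# genotype tibble built directly from dosage vectors (first allele = minor)
genotypes_from_dosage <- function(dosage_list, panel) {
  n <- length(dosage_list[[1]])
  out <- tibble::tibble(subject_id = sprintf("s%02d", seq_len(n)))
  for (s in names(dosage_list)) {
    alleles <- strsplit(panel$allele[panel$snp_id == s], "")[[1]]
    out[[s]] <- c(paste0(alleles[2], alleles[2]),
                  paste0(alleles[1], alleles[2]),
                  paste0(alleles[1], alleles[1]))[dosage_list[[s]] + 1]
  }
  out
}
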