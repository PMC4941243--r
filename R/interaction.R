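#' Build the genotype-by-diagnosis design for one SNP
#'
#' Full model: intercept, diagnosis indicator (control = 0, aMCI = 1),
#' genotype code column(s) chosen by the genetic model, their
#' diagnosis-by-genotype product(s), and the age, gender (0/1) and
#' education covariates. The reduced model omits the interaction column(s);
#' the partial F for the interaction compares the two. A voxelwise
#' grey-matter covariate can be appended to both models downstream.
#'
#' @param phenotypes Phenotype tibble with `group`, `age`, `gender`,
#'   `education`.
#' @param minor_counts Minor-allele dosage vector for the SNP.
#' @param model `"genotypic"` or `"recessive"`.
#' @return A list with `full` and `reduced` design matrices and
#'   `interaction_cols` (column names of the interaction terms).
#' @export
build_interaction_design <- function(phenotypes, minor_counts,
                                     model = c("genotypic", "recessive")) {
  model <- match.arg(model)
  n <- nrow(phenotypes)
  stopifnot(length(minor_counts) == n)
  group <- as.numeric(phenotypes$group == "aMCI")
  geno <- code_genotypes(minor_counts, model)
  inter <- geno * group
  colnames(inter) <- paste0("group_x_", colnames(geno))
  gender <- as.numeric(factor(phenotypes$gender)) - 1
  covars <- cbind(age = phenotypes$age, gender = gender,
                  education = phenotypes$education)
  full <- cbind(intercept = 1, group = group, geno, inter, covars)
  reduced <- full[, setdiff(colnames(full), colnames(inter)), drop = FALSE]
  list(full = full, reduced = reduced, interaction_cols = colnames(inter))
}

#' Partial F-test for the interaction term at one voxel
#'
#' Least-squares fits of the full and reduced models;
#' `F = ((RSS_r - RSS_f) / df1) / (RSS_f / df2)` with `df1` the rank gained
#' by the interaction column(s) and `df2 = n - rank(full)`. Aliased columns
#' (e.g. a genotype class absent in one group) are absorbed by pivoted QR;
#' the effective `df1` shrinks accordingly. A voxel whose reduced model is
#' rank deficient to the point that no interaction information remains is
#' flagged invalid (`F = 0`, `p = 1`).
#'
#' @param y Response vector (ALFF at one voxel across subjects).
#' @param design List with `full` and `reduced` matrices (see
#'   [build_interaction_design()]); an extra covariate column may have been
#'   appended to both.
#' @return Named numeric vector `c(F, p, df1, df2)`.
#' @export
fit_voxel_interaction <- function(y, design) {
  ff <- .lm.fit(design$full, y)
  fr <- .lm.fit(design$reduced, y)
  df1 <- ff$rank - fr$rank
  df2 <- length(y) - ff$rank
  rss_f <- sum(ff$residuals^2)
  rss_r <- sum(fr$residuals^2)
  # a voxel with (numerically) no residual variance under the reduced model
  # carries no information about the interaction
  if (df1 <= 0 || df2 <= 0 ||
      rss_r <= .Machine$double.eps^0.75 * max(1, sum(y^2))) {
    return(c(F = 0, p = 1, df1 = max(df1, 0), df2 = max(df2, 0)))
  }
  fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  fstat <- max(fstat, 0)
  c(F = fstat, p = pf(fstat, df1, df2, lower.tail = FALSE),
    df1 = df1, df2 = df2)
}

#' Voxelwise SNP-by-diagnosis interaction scan
#'
#' Fits the covariate-adjusted interaction model at every in-mask voxel for
#' one SNP, with the subject's grey-matter probability at that voxel as an
#' additional nuisance covariate when grey-matter maps are supplied. A
#' subject with a missing grey-matter map has its voxelwise covariate
#' mean-imputed from the other subjects, with a warning.
#'
#' @param alff_maps List of `alff_map` objects (or 3D arrays), one per
#'   subject, in phenotype row order.
#' @param genotypes Genotype tibble.
#' @param phenotypes Phenotype tibble.
#' @param snp_id SNP to scan.
#' @param panel SNP panel tibble.
#' @param mask Logical 3D mask.
#' @param affine 4x4 affine.
#' @param gm_maps Optional list of 3D grey-matter maps (entries may be
#'   `NULL`).
#' @param model Genetic model; default chosen from the observed MAF via
#'   [select_genetic_model()].
#' @return A list of class `snp_stat_map`: `F` and `p` 3D arrays, `df1`,
#'   `df2`, `snp_id`, `model`, `maf`, `n`, `affine`, `mask`,
#'   `n_aliased_voxels`.
#' @export
run_snp_scan <- function(alff_maps, genotypes, phenotypes, snp_id, panel,
                         mask, affine, gm_maps = NULL, model = NULL) {
  n <- nrow(phenotypes)
  if (length(alff_maps) != n) abort("one ALFF map per phenotype row required")
  if (!identical(genotypes$subject_id, phenotypes$subject_id)) {
    abort("genotype and phenotype subject ids disagree")
  }
  if (!snp_id %in% panel$snp_id) abort(sprintf("SNP %s not in panel", snp_id))
  dosage <- minor_allele_counts(genotypes, panel)[, snp_id]
  maf <- compute_maf(sum(dosage == 2), sum(dosage == 1), sum(dosage == 0))$maf
  model <- model %||% select_genetic_model(maf)$model
  design <- build_interaction_design(phenotypes, dosage, model)

  vin <- which(mask)
  get_data <- function(m) if (inherits(m, "alff_map")) m$data else m
  y_mat <- vapply(alff_maps, function(m) get_data(m)[vin], numeric(length(vin)))

  gm_mat <- NULL
  if (!is.null(gm_maps)) {
    if (length(gm_maps) != n) abort("one grey-matter map per subject required")
    missing <- vapply(gm_maps, is.null, logical(1))
    gm_mat <- matrix(0, length(vin), n)
    for (i in which(!missing)) gm_mat[, i] <- gm_maps[[i]][vin]
    if (any(missing)) {
      warn(sprintf("%d subject(s) missing a grey-matter map; voxelwise covariate mean-imputed",
                   sum(missing)))
      fill <- rowMeans(gm_mat[, !missing, drop = FALSE])
      for (i in which(missing)) gm_mat[, i] <- fill
    }
  }

  nvox <- length(vin)
  f_out <- numeric(nvox); p_out <- numeric(nvox); df1_out <- numeric(nvox)
  df2_out <- numeric(nvox)
  full_df1 <- qr(design$full)$rank - qr(design$reduced)$rank
  for (v in seq_len(nvox)) {
    dv <- design
    if (!is.null(gm_mat)) {
      dv$full <- cbind(design$full, gm = gm_mat[v, ])
      dv$reduced <- cbind(design$reduced, gm = gm_mat[v, ])
    }
    res <- fit_voxel_interaction(y_mat[v, ], dv)
    f_out[v] <- res["F"]; p_out[v] <- res["p"]
    df1_out[v] <- res["df1"]; df2_out[v] <- res["df2"]
  }

  f_map <- array(0, dim(mask)); p_map <- array(1, dim(mask))
  f_map[vin] <- f_out; p_map[vin] <- p_out
  structure(list(F = f_map, p = p_map,
                 df1 = as.integer(median(df1_out)),
                 df2 = as.integer(median(df2_out)),
                 snp_id = snp_id, model = model, maf = maf, n = n,
                 affine = affine, mask = mask,
                 n_aliased_voxels = sum(df1_out < full_df1)),
            class = "snp_stat_map")
}

#' @export
print.snp_stat_map <- function(x, ...) {
  cat(sprintf("<snp_stat_map> %s (%s model, df %d/%d, n = %d)\n",
              x$snp_id, x$model, x$df1, x$df2, x$n))
  cat(sprintf("  peak F = %.2f at voxel p = %.2g; %d aliased voxel(s)\n",
              max(x$F), min(x$p), x$n_aliased_voxels))
  invisible(x)
}
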