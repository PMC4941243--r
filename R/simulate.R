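#' Group distribution parameters for the phenotype generator
#'
#' Means and standard deviations (and the male:female split) used to draw
#' synthetic demographic and neuropsychological variables for the amnestic
#' MCI and control groups. Neuropsychological scores are on the z scale.
#'
#' @return A tibble with one row per variable: `variable`, `amci_mean`,
#'   `amci_sd`, `control_mean`, `control_sd`.
#' @export
phenotype_parameters <- function() {
  tibble::tribble(
    ~variable,          ~amci_mean, ~amci_sd, ~control_mean, ~control_sd,
    "age",                   72.00,     4.88,         72.93,        3.93,
    "education",             13.58,     3.10,         14.98,        2.67,
    "mmse",                  27.05,     1.53,         28.20,        1.37,
    "avlt_delayed_z",        -0.64,     0.57,          0.99,        0.62,
    "reyo_delayed_z",        -0.26,     0.96,          0.44,        0.91,
    "tmt_a_z",                0.25,     1.03,         -0.37,        0.85,
    "tmt_b_z",                0.22,     1.11,         -0.41,        0.60,
    "symbol_digit_z",        -0.24,     0.94,          0.39,        0.96,
    "clock_drawing_z",       -0.23,     1.14,          0.29,        0.70,
    "digit_span_z",          -0.13,     0.93,          0.23,        0.99
  )
}

# male fraction per group used by the phenotype generator
.male_fraction <- c(aMCI = 27 / 43, control = 17 / 30)

#' Specify a ground-truth interaction effect blob
#'
#' Inside the blob, the band-limited BOLD amplitude of subject `i` is scaled
#' by `1 + effect_size * group_i * code_i`, where `group_i` is the disease
#' indicator (control = 0, aMCI = 1) and `code_i` is the genotype design
#' code the mapping stage will use for the SNP (recessive carrier indicator
#' or the linear orthogonal-polynomial contrast), so the injected signal is
#' a pure genotype-by-diagnosis interaction.
#'
#' @param center_voxel Three 1-based voxel indices of the blob centre.
#' @param radius_vox Blob radius in voxels.
#' @param snp_id Panel SNP the effect is attached to.
#' @param effect_size Multiplicative amplitude modulation per unit of the
#'   genotype code in the diseased group. Note the band-limited amplitude
#'   responds to the magnitude of the multiplier, so for genotypic-model
#'   SNPs (linear code spanning about +/-0.71) effect sizes should keep
#'   `1 + effect_size * code` positive.
#' @return A list of class `effect_blob`.
#' @export
effect_blob <- function(center_voxel, radius_vox, snp_id, effect_size) {
  stopifnot(length(center_voxel) == 3, radius_vox >= 0, is.finite(effect_size))
  structure(list(center_voxel = as.integer(center_voxel),
                 radius_vox = radius_vox, snp_id = snp_id,
                 effect_size = effect_size),
            class = "effect_blob")
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic study: a
#' desk-scale 3 mm grid, a 3 s repetition time with 142 volumes of which the
#' first 8 are discarded downstream, 43 aMCI and 30 control subjects, the
#' packaged SNP panel, and the spatial smoothness / noise level of the
#' generated data.
#'
#' @param grid_shape Three voxel counts (default `c(24, 28, 24)`).
#' @param voxel_size_mm Isotropic voxel size (default 3).
#' @param tr_s Repetition time in seconds (default 3).
#' @param n_volumes Number of volumes acquired (default 142).
#' @param n_discard Initial volumes discarded during preprocessing
#'   (default 8).
#' @param n_amci,n_controls Subject counts (defaults 43 and 30).
#' @param snp_panel Panel tibble with `snp_id`, `gene`, `allele`, `sim_maf`.
#' @param effect_blobs List of [effect_blob()] objects (may be empty).
#' @param noise_sd White measurement-noise SD relative to the unit-variance
#'   baseline fluctuation (default 1).
#' @param smooth_fwhm_mm Spatial smoothness of the baseline fluctuation
#'   field in mm FWHM (default 8).
#' @param trend_sd SD of the per-subject linear scanner drift over the full
#'   scan, in baseline-SD units (default 0.5).
#' @param n_components Number of band-limited sinusoid components per
#'   subject (default 10).
#' @param missing_gm If `TRUE`, withhold the grey-matter map of the first
#'   aMCI subject (default `FALSE`).
#' @param seed Master seed; every stage derives named sub-streams from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(grid_shape = c(24, 28, 24), voxel_size_mm = 3,
                              tr_s = 3.0, n_volumes = 142, n_discard = 8,
                              n_amci = 43, n_controls = 30,
                              snp_panel = alffnet::snp_panel(),
                              effect_blobs = list(), noise_sd = 1,
                              smooth_fwhm_mm = 8, trend_sd = 0.5,
                              n_components = 10,
                              missing_gm = FALSE, seed = 1L) {
  if (any(grid_shape <= 0)) abort("grid_shape must be positive")
  if (n_volumes <= n_discard) abort("n_volumes must exceed n_discard")
  if (tr_s <= 0) abort("tr_s must be positive")
  if (smooth_fwhm_mm < 0) abort("smooth_fwhm_mm must be non-negative")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (n_amci < 2 || n_controls < 2) abort("need at least 2 subjects per group")
  if (any(snp_panel$sim_maf <= 0 | snp_panel$sim_maf > 0.5)) {
    abort("panel sim_maf values must lie in (0, 0.5]")
  }
  for (b in effect_blobs) {
    if (!inherits(b, "effect_blob")) abort("effect_blobs must be effect_blob objects")
    if (!b$snp_id %in% snp_panel$snp_id) {
      abort(sprintf("blob snp_id %s not in panel", b$snp_id))
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 n_volumes = as.integer(n_volumes),
                 n_discard = as.integer(n_discard),
                 n_amci = as.integer(n_amci),
                 n_controls = as.integer(n_controls),
                 snp_panel = snp_panel, effect_blobs = effect_blobs,
                 noise_sd = noise_sd, smooth_fwhm_mm = smooth_fwhm_mm,
                 trend_sd = trend_sd, n_components = as.integer(n_components),
                 missing_gm = isTRUE(missing_gm), seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw genotypes in Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently: the minor-allele dosage is Binomial(2,
#' MAF), which yields the equilibrium genotype proportions q^2 / 2pq / p^2.
#' Genotype strings use the panel's allele pair, first character = minor
#' allele.
#'
#' @param n_subjects Number of subjects.
#' @param panel Panel tibble with a `sim_maf` column in (0, 0.5].
#' @param seed Integer seed.
#' @return A tibble with `subject_id` and one two-letter genotype column per
#'   panel SNP.
#' @export
generate_genotypes <- function(n_subjects, panel, seed = 1L) {
  if (any(panel$sim_maf <= 0 | panel$sim_maf > 0.5)) {
    abort("sim_maf must lie in (0, 0.5]")
  }
  set.seed(stream_seed(seed, "genotypes"))
  cols <- lapply(seq_len(nrow(panel)), function(j) {
    alleles <- strsplit(panel$allele[j], "")[[1]]
    dose <- rbinom(n_subjects, 2, panel$sim_maf[j])
    c(paste0(alleles[2], alleles[2]),       # dose 0: major homozygote
      paste0(alleles[1], alleles[2]),       # dose 1: heterozygote
      paste0(alleles[1], alleles[1]))[dose + 1]
  })
  names(cols) <- panel$snp_id
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("sub-%03d", seq_len(n_subjects))),
    tibble::as_tibble(cols))
}

#' Draw demographic and neuropsychological phenotypes
#'
#' Continuous variables are Normal with the group means and SDs of
#' [phenotype_parameters()]; gender is Bernoulli at each group's male
#' fraction. Rows are ordered aMCI first, then controls.
#'
#' @param n_amci,n_controls Subject counts (each at least 2).
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `group` (factor, control/aMCI),
#'   `gender` and the continuous variables.
#' @export
generate_phenotypes <- function(n_amci, n_controls, seed = 1L) {
  if (n_amci < 2 || n_controls < 2) abort("need at least 2 subjects per group")
  set.seed(stream_seed(seed, "phenotypes"))
  pars <- phenotype_parameters()
  n <- n_amci + n_controls
  group <- factor(rep(c("aMCI", "control"), c(n_amci, n_controls)),
                  levels = c("control", "aMCI"))
  out <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group,
    gender = ifelse(runif(n) < .male_fraction[as.character(group)], "M", "F"))
  for (j in seq_len(nrow(pars))) {
    mu <- ifelse(group == "aMCI", pars$amci_mean[j], pars$control_mean[j])
    sdv <- ifelse(group == "aMCI", pars$amci_sd[j], pars$control_sd[j])
    out[[pars$variable[j]]] <- rnorm(n, mu, sdv)
  }
  out
}

# genotype design code used for effect injection: identical to the first
# design column the mapping stage will fit for this SNP
injection_code <- function(minor_counts, maf, cutoff = maf_model_cutoff()) {
  if (maf >= cutoff) {
    contr.poly(3)[minor_counts + 1, 1]
  } else {
    as.numeric(minor_counts >= 1)
  }
}

# per-subject amplitude multiplier field over in-mask voxels
amplitude_field <- function(config, mask, blob_masks, multipliers, subject) {
  a <- rep(1, sum(mask))
  for (b in seq_along(blob_masks)) {
    a[blob_masks[[b]][mask]] <- a[blob_masks[[b]][mask]] * multipliers[[b]][subject]
  }
  a
}

#' Generate a synthetic resting-state dataset with known ground truth
#'
#' For each subject, every in-mask voxel's time series is a unit-variance
#' band-limited baseline (a mixture of sinusoids with frequencies uniform in
#' 0.01-0.08 Hz and random phases, with spatially smooth mixing weights at
#' the configured FWHM), scaled inside each effect blob by
#' `1 + effect_size * group * genotype_code`, plus a per-subject linear
#' scanner drift and spatially white measurement noise. Grey-matter
#' probability maps are smooth fields in \[0, 1\] on the same grid.
#'
#' @param config A [simulation_config()].
#' @param genotypes Genotype tibble from [generate_genotypes()].
#' @param phenotypes Phenotype tibble from [generate_phenotypes()].
#' @param keep_series If `FALSE`, per-subject 4D arrays are not retained
#'   (they can be regenerated deterministically with
#'   [simulate_subject_series()]); mask, grey matter and ground truth are
#'   still returned. Default `TRUE`.
#' @return A list of class `bold_dataset` with elements `subjects` (list of
#'   4D arrays or `NULL`s), `mask`, `affine`, `gm` (list of 3D arrays, an
#'   entry may be `NULL` when a map is withheld), `ground_truth`,
#'   `genotypes`, `phenotypes`, `config`.
#' @export
generate_bold_dataset <- function(config, genotypes, phenotypes,
                                  keep_series = TRUE) {
  n <- config$n_amci + config$n_controls
  if (nrow(genotypes) != n || nrow(phenotypes) != n) {
    abort("subject counts of config, genotypes and phenotypes disagree")
  }
  if (!identical(genotypes$subject_id, phenotypes$subject_id)) {
    abort("genotype and phenotype subject ids disagree")
  }
  mask <- ellipsoid_mask(config$grid_shape)
  affine <- default_affine(config$grid_shape, config$voxel_size_mm)
  dosage <- minor_allele_counts(genotypes, config$snp_panel)

  blob_masks <- list(); multipliers <- list()
  for (b in config$effect_blobs) {
    bm <- sphere_mask(config$grid_shape, b$center_voxel, b$radius_vox)
    if (any(bm & !mask)) abort("effect blob extends outside the brain mask")
    maf <- config$snp_panel$sim_maf[config$snp_panel$snp_id == b$snp_id]
    code <- injection_code(dosage[, b$snp_id], maf)
    grp <- as.numeric(phenotypes$group == "aMCI")
    blob_masks <- c(blob_masks, list(bm))
    multipliers <- c(multipliers, list(1 + b$effect_size * grp * code))
  }

  gm <- lapply(seq_len(n), function(i) simulate_gm_map(config, mask, i))
  if (config$missing_gm) {
    gm[which(phenotypes$group == "aMCI")[1]] <- list(NULL)
  }

  ground_truth <- list(
    blobs = lapply(seq_along(config$effect_blobs), function(b) {
      list(snp_id = config$effect_blobs[[b]]$snp_id,
           effect_size = config$effect_blobs[[b]]$effect_size,
           center_voxel = config$effect_blobs[[b]]$center_voxel,
           radius_vox = config$effect_blobs[[b]]$radius_vox,
           voxels = which(blob_masks[[b]]),
           subject_multiplier = multipliers[[b]])
    }),
    seed = config$seed)

  subjects <- if (keep_series) {
    lapply(seq_len(n), function(i) {
      simulate_subject_series(config, mask, blob_masks, multipliers, i)
    })
  } else {
    vector("list", n)
  }

  structure(list(subjects = subjects, mask = mask, affine = affine, gm = gm,
                 ground_truth = ground_truth, genotypes = genotypes,
                 phenotypes = phenotypes, config = config,
                 blob_masks = blob_masks, multipliers = multipliers),
            class = "bold_dataset")
}

#' Regenerate one subject's 4D series deterministically
#'
#' All randomness flows from named sub-streams of the master seed, so a
#' subject's series can be rebuilt at any time without storing it.
#'
#' @param config A [simulation_config()].
#' @param mask Logical 3D brain mask.
#' @param blob_masks List of logical blob masks.
#' @param multipliers List of per-subject amplitude multipliers, one numeric
#'   vector per blob.
#' @param subject Subject index.
#' @return 4D numeric array (grid x time).
#' @export
simulate_subject_series <- function(config, mask, blob_masks, multipliers,
                                    subject) {
  set.seed(stream_seed(config$seed, "bold", subject))
  dims <- config$grid_shape
  nt <- config$n_volumes
  vin <- which(mask)
  nv <- length(vin)
  k <- config$n_components

  freqs <- runif(k, 0.01, 0.08)
  phases <- runif(k, 0, 2 * pi)
  t_s <- (seq_len(nt) - 1) * config$tr_s
  basis <- sapply(seq_len(k), function(j) sin(2 * pi * freqs[j] * t_s + phases[j]))

  w <- matrix(rnorm(nv * k), nv, k)
  if (config$smooth_fwhm_mm > 0) {
    for (j in seq_len(k)) {
      field <- array(0, dims); field[vin] <- w[, j]
      field <- gaussian_smooth_3d(field, config$smooth_fwhm_mm, config$voxel_size_mm)
      w[, j] <- field[vin]
    }
  }
  signal <- w %*% t(basis)                        # nv x nt
  rs <- sqrt(rowSums((signal - rowMeans(signal))^2) / (nt - 1))
  rs[rs == 0] <- 1
  signal <- signal / rs                           # unit temporal variance

  amp <- amplitude_field(config, mask, blob_masks, multipliers, subject)
  drift <- rnorm(1, 0, config$trend_sd)
  trend <- drift * (t_s / max(t_s) - 0.5)
  noise <- matrix(rnorm(nv * nt, 0, config$noise_sd), nv, nt)

  out <- array(0, c(dims, nt))
  flat <- amp * signal + noise + rep(trend, each = nv)
  idx <- rep(vin, nt) + rep((seq_len(nt) - 1) * prod(dims), each = nv)
  out[idx] <- flat
  out
}

# smooth probability field in [0, 1]; out-of-mask voxels 0
simulate_gm_map <- function(config, mask, subject) {
  set.seed(stream_seed(config$seed, "gm", subject))
  field <- array(rnorm(prod(config$grid_shape)), config$grid_shape)
  if (config$smooth_fwhm_mm > 0) {
    field <- gaussian_smooth_3d(field, config$smooth_fwhm_mm, config$voxel_size_mm)
  }
  vin <- which(mask)
  z <- (field[vin] - mean(field[vin])) / sd(field[vin])
  gm <- array(0, config$grid_shape)
  gm[vin] <- pnorm(z)
  gm
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Per-subject 4D NIfTI volumes, the mask and grey-matter maps as 3D NIfTI,
#' genotype and phenotype tables as TSV, and the ground truth as JSON.
#'
#' @param dataset A `bold_dataset` (with series retained).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_bold_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- dataset$affine
  write_volume(dataset$mask * 1, aff, file.path(dir, "mask.nii.gz"))
  for (i in seq_along(dataset$subjects)) {
    id <- dataset$phenotypes$subject_id[i]
    if (!is.null(dataset$subjects[[i]])) {
      write_volume(dataset$subjects[[i]], aff,
                   file.path(dir, paste0(id, "_bold.nii.gz")),
                   tr_s = dataset$config$tr_s)
    }
    if (!is.null(dataset$gm[[i]])) {
      write_volume(dataset$gm[[i]], aff, file.path(dir, paste0(id, "_gm.nii.gz")))
    }
  }
  readr::write_tsv(dataset$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(dataset$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
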