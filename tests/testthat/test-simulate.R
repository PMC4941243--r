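test_that("genotypes follow Hardy-Weinberg proportions at the panel MAFs", {
  panel <- snp_panel()
  gt <- generate_genotypes(1e4, panel[panel$snp_id == "rs405509", ], seed = 21)
  dose <- minor_allele_counts(gt, panel)
  # MAF 0.45: heterozygote fraction 2 * 0.45 * 0.55 = 0.495
  het <- mean(dose[, "rs405509"] == 1)
  se <- sqrt(0.495 * 0.505 / 1e4)
  expect_lt(abs(het - 0.495), 3 * se)

  # own HWE test passes at alpha 0.001 across the panel (allowing one
  # chance failure among the 33 draws)
  gt_all <- generate_genotypes(1e4, panel, seed = 22)
  dose_all <- minor_allele_counts(gt_all, panel)
  pvals <- vapply(colnames(dose_all), function(s) {
    x <- dose_all[, s]
    hwe_test(sum(x == 2), sum(x == 1), sum(x == 0))$p_value
  }, numeric(1))
  expect_gte(sum(pvals > 0.001), 32)
})

test_that("genotype generation validates MAFs and is deterministic", {
  panel <- snp_panel()[1:3, ]
  bad <- panel; bad$sim_maf[1] <- 0
  expect_error(generate_genotypes(10, bad, seed = 1), "0, 0.5")
  a <- generate_genotypes(50, panel, seed = 5)
  b <- generate_genotypes(50, panel, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_genotypes(50, panel, seed = 6)))
})

test_that("phenotypes reproduce the configured group distributions", {
  big <- generate_phenotypes(4000, 4000, seed = 31)
  pars <- phenotype_parameters()
  amci <- big[big$group == "aMCI", ]
  ctrl <- big[big$group == "control", ]
  # aMCI age 72.00 +/- 4.88; SE of the mean at n = 4000
  expect_lt(abs(mean(amci$age) - 72.00), 3 * 4.88 / sqrt(4000))
  expect_lt(abs(sd(amci$education) - 3.10), 0.2)
  expect_lt(abs(mean(ctrl$mmse) - 28.20), 3 * 1.37 / sqrt(4000))
  # control male fraction 17/30
  p <- 17 / 30
  expect_lt(abs(mean(ctrl$gender == "M") - p), 3 * sqrt(p * (1 - p) / 4000))
  # every configured variable is present
  expect_true(all(pars$variable %in% names(big)))

  small <- generate_phenotypes(2, 2, seed = 1)
  expect_equal(nrow(small), 4)
  expect_error(generate_phenotypes(1, 30, seed = 1), "at least 2")
})

test_that("synthetic BOLD volumes are finite, masked and deterministic", {
  cfg <- tiny_config(seed = 8)
  gt <- generate_genotypes(16, cfg$snp_panel, seed = 8)
  ph <- generate_phenotypes(8, 8, seed = 8)
  ds1 <- generate_bold_dataset(cfg, gt, ph)
  ds2 <- generate_bold_dataset(cfg, gt, ph)
  expect_identical(ds1$subjects, ds2$subjects)
  expect_identical(ds1$gm, ds2$gm)

  v <- ds1$subjects[[1]]
  expect_true(all(is.finite(v)))
  out_of_mask <- !ds1$mask
  expect_true(all(v[which(out_of_mask)] == 0))
  gm_vals <- unlist(lapply(ds1$gm, function(g) g[ds1$mask]))
  expect_true(all(gm_vals >= 0 & gm_vals <= 1))
})

test_that("effect blobs must stay inside the brain mask", {
  blob <- effect_blob(c(1, 1, 1), 3, "rs2230806", 0.5)
  cfg <- tiny_config(seed = 2, effect_blobs = list(blob))
  gt <- generate_genotypes(16, cfg$snp_panel, seed = 2)
  ph <- generate_phenotypes(8, 8, seed = 2)
  expect_error(generate_bold_dataset(cfg, gt, ph), "outside")
})

test_that("missing grey-matter flag withholds exactly one aMCI map", {
  cfg <- tiny_config(seed = 3, missing_gm = TRUE)
  gt <- generate_genotypes(16, cfg$snp_panel, seed = 3)
  ph <- generate_phenotypes(8, 8, seed = 3)
  ds <- generate_bold_dataset(cfg, gt, ph, keep_series = FALSE)
  expect_equal(sum(vapply(ds$gm, is.null, logical(1))), 1)
  expect_null(ds$gm[[which(ph$group == "aMCI")[1]]])
})

test_that("injected amplitude modulation is recovered in noise-free ALFF", {
  blob <- effect_blob(c(7, 8, 7), 2.5, "rs3753526", 1.0)  # MAF 0.25: recessive
  cfg <- tiny_config(seed = 12, effect_blobs = list(blob),
                     noise_sd = 0, trend_sd = 0)
  gt <- generate_genotypes(16, cfg$snp_panel, seed = 12)
  ph <- generate_phenotypes(8, 8, seed = 12)
  ds <- generate_bold_dataset(cfg, gt, ph)
  mult <- ds$multipliers[[1]]
  expect_true(any(mult == 2) && any(mult == 1))  # both cells populated
  blobvox <- which(ds$blob_masks[[1]])
  bgvox <- setdiff(which(ds$mask), blobvox)
  ratio <- vapply(seq_len(16), function(i) {
    prep <- preprocess_series(vol_series(ds$subjects[[i]], ds$affine, cfg$tr_s),
                              cfg$n_discard)
    am <- compute_alff_map(prep, ds$mask)
    mean(am$data[blobvox]) / mean(am$data[bgvox])
  }, numeric(1))
  ref <- mean(ratio[mult == 1])
  expect_equal(unname(ratio / ref), unname(mult), tolerance = 0.1)
})

test_that("datasets round-trip through NIfTI, TSV and JSON on disk", {
  dir <- withr::local_tempdir()
  blob <- effect_blob(c(7, 8, 7), 2, "rs2230806", 0.8)
  cfg <- tiny_config(seed = 6, effect_blobs = list(blob))
  gt <- generate_genotypes(16, cfg$snp_panel, seed = 6)
  ph <- generate_phenotypes(8, 8, seed = 6)
  ds <- generate_bold_dataset(cfg, gt, ph)
  write_bold_dataset(ds, dir)
  m <- read_volume(file.path(dir, "mask.nii.gz"))
  expect_equal(m$data > 0, unclass(ds$mask))
  expect_equal(m$affine, ds$affine, tolerance = 1e-6)
  b <- read_volume(file.path(dir, "sub-001_bold.nii.gz"))
  expect_equal(b$data, ds$subjects[[1]], tolerance = 1e-6)
  gt_rt <- readr::read_tsv(file.path(dir, "genotypes.tsv"),
                           show_col_types = FALSE)
  expect_equal(gt_rt$rs2230806, gt$rs2230806)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$blobs$snp_id, "rs2230806")
})
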