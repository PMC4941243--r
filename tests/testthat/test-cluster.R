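test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(31)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:4) {
      vol <- array(runif(10 * 11 * 9) < 0.25, c(10, 11, 9))
      got <- label_clusters(vol, conn)
      want <- oracle_flood_fill(vol, conn)
      expect_true(same_partition(got$voxels, got$labels, want[got$voxels]))
      expect_equal(sort(got$sizes),
                   sort(as.integer(tabulate(want[want > 0]))))
    }
  }
})

test_that("corner-touching blobs split by connectivity", {
  vol <- array(FALSE, c(6, 6, 6))
  vol[2, 2, 2] <- TRUE
  vol[3, 3, 3] <- TRUE        # touches only at a corner
  expect_length(label_clusters(vol, 26)$sizes, 1)
  expect_length(label_clusters(vol, 18)$sizes, 2)

  vol2 <- array(FALSE, c(6, 6, 6))
  vol2[2, 2, 2] <- TRUE
  vol2[3, 3, 2] <- TRUE       # edge contact: joined under 18, split under 6
  expect_length(label_clusters(vol2, 18)$sizes, 1)
  expect_length(label_clusters(vol2, 6)$sizes, 2)
})

test_that("cluster extraction respects the extent rule and reports MNI peaks", {
  dims <- c(20, 20, 12)
  aff <- default_affine(dims, 3)
  mask <- array(TRUE, dims)
  p <- array(1, dims); f <- array(0, dims)
  big <- which(sphere_mask(dims, c(6, 6, 6), 2.5))    # 81 voxels
  small <- which(sphere_mask(dims, c(15, 15, 6), 1.3)) # < 20 voxels
  stopifnot(length(big) >= 48, length(small) < 48)
  p[big] <- 1e-4; p[small] <- 1e-4
  f[big] <- 10; f[small] <- 10
  f[big[3]] <- 25                                      # unique peak
  sm <- structure(list(F = f, p = p, snp_id = "rs1", affine = aff,
                       mask = mask), class = "snp_stat_map")
  cl <- extract_clusters(sm, voxel_p = 0.005, min_extent = 48)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size_vox, length(big))
  expect_equal(cl$size_mm3, length(big) * 27)
  expect_equal(cl$peak_stat, 25)
  want_mni <- voxel_to_mni(arrayInd(big[3], dims), aff)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z), as.vector(want_mni))

  # both kept at a permissive extent; empty result allowed at a strict one
  expect_equal(nrow(extract_clusters(sm, 0.005, 5)), 2)
  expect_equal(nrow(extract_clusters(sm, 0.005, 1e5)), 0)
})

test_that("voxel-to-MNI mapping follows the 3 mm affine convention", {
  aff <- default_affine(c(24, 28, 24), 3)  # origin (-36, -42, -36)
  aff[1:3, 4] <- c(-36, -48, -36)
  # 0-based voxel (5, 10, 10) is R index (6, 11, 11)
  expect_equal(voxel_to_mni(c(6, 11, 11), aff), c(-21, -18, -6))
})

test_that("Monte-Carlo extent threshold matches the independent-voxel oracle at FWHM 0", {
  dims <- c(12, 12, 10)
  mask <- ellipsoid_mask(dims)
  thr <- simulate_cluster_threshold(mask, fwhm_mm = 0, voxel_size_mm = 3,
                                    voxel_p = 0.005, alpha = 0.05,
                                    n_iter = 300, connectivity = 18, seed = 77)
  oracle <- oracle_alphasim_fwhm0(mask, 0.005, 0.05, 300, 18, seed = 77)
  expect_identical(thr$extent_vox, oracle$extent)
  expect_identical(thr$null_max_sizes, oracle$max_sizes)
})

test_that("extent thresholds are monotone in smoothness and voxel threshold", {
  dims <- c(16, 16, 12)
  mask <- ellipsoid_mask(dims)
  t0 <- simulate_cluster_threshold(mask, 0, 3, n_iter = 250, seed = 5)
  t8 <- simulate_cluster_threshold(mask, 8, 3, n_iter = 250, seed = 5)
  expect_gte(t8$extent_vox, t0$extent_vox)

  strict <- simulate_cluster_threshold(mask, 8, 3, voxel_p = 0.001,
                                       n_iter = 250, seed = 5)
  expect_lte(strict$extent_vox, t8$extent_vox)

  again <- simulate_cluster_threshold(mask, 8, 3, n_iter = 250, seed = 5)
  expect_identical(t8$extent_vox, again$extent_vox)

  expect_error(simulate_cluster_threshold(mask, 8, 3, n_iter = 100), "200")
  expect_error(simulate_cluster_threshold(array(FALSE, dims), 8, 3,
                                          n_iter = 250), "empty")
})

test_that("within-gene correction divides alpha by the gene's SNP count", {
  panel <- snp_panel()
  mk_cluster <- function(snp, size) {
    tibble::tibble(snp_id = snp, cluster_id = 1L, size_vox = size,
                   size_mm3 = size * 27, peak_stat = 20, peak_p = 1e-5,
                   peak_x = 0, peak_y = 0, peak_z = 0,
                   voxels = list(seq_len(size)))
  }
  clusters <- dplyr::bind_rows(mk_cluster("rs429358", 60),  # APOE: 5 SNPs
                               mk_cluster("rs1801133", 60), # MTHFR: 1 SNP
                               mk_cluster("rs7412", 10))
  res <- correct_within_gene(clusters, panel, min_extent = 48)
  expect_equal(res$alpha_snp[res$snp_id == "rs429358"], 0.05 / 5)
  expect_equal(res$alpha_snp[res$snp_id == "rs1801133"], 0.05)
  expect_true(res$pass_S[res$snp_id == "rs429358"])
  expect_false(res$pass_S[res$snp_id == "rs7412"])  # below extent

  # Monte-Carlo mode: corrected p from the null distribution, within-gene alpha
  null_max <- c(rep(10, 950), rep(70, 50))  # P(max >= 60) = 0.05
  res_mc <- correct_within_gene(clusters, panel, null_max_sizes = null_max)
  expect_equal(res_mc$p_corrected[res_mc$snp_id == "rs429358"], 0.05)
  expect_false(res_mc$pass_S[res_mc$snp_id == "rs429358"])  # 0.05 > 0.01
  expect_true(res_mc$pass_S[res_mc$snp_id == "rs1801133"])  # 0.05 <= 0.05

  unknown <- mk_cluster("rs0000", 60)
  expect_error(correct_within_gene(unknown, panel), "gene")
  empty <- correct_within_gene(clusters[0, ], panel)
  expect_equal(nrow(empty), 0)
})

test_that("between-gene stage tightens the voxel threshold by the SNP count", {
  panel <- snp_panel()
  dims <- c(8, 8, 6)
  aff <- default_affine(dims, 3)
  flat_map <- function(snp) {
    structure(list(F = array(0, dims), p = array(1, dims), snp_id = snp,
                   affine = aff, mask = array(TRUE, dims)),
              class = "snp_stat_map")
  }
  snps15 <- panel$snp_id[1:15]
  clusters <- purrr::map_dfr(snps15, function(s) {
    tibble::tibble(snp_id = s, cluster_id = 1L, size_vox = 60,
                   size_mm3 = 60 * 27, peak_stat = 15, peak_p = 1e-4,
                   peak_x = 0, peak_y = 0, peak_z = 0,
                   voxels = list(1:60), gene = "g", alpha_snp = 0.05,
                   p_corrected = NA_real_, pass_S = TRUE)
  })
  maps <- lapply(snps15, flat_map); names(maps) <- snps15
  res <- correct_between_genes(maps, clusters, voxel_p = 0.005)
  expect_equal(res$ledger$stage2_voxel_p, 0.005 / 15)
  expect_equal(round(res$ledger$stage2_voxel_p, 4), 3e-4)
  expect_false(any(res$clusters$pass_SG))  # nothing survives the flat maps

  one <- clusters[1, ]
  res1 <- correct_between_genes(maps[1], one, voxel_p = 0.005)
  expect_equal(res1$ledger$stage2_voxel_p, 0.005)

  none <- dplyr::mutate(clusters, pass_S = FALSE)
  res0 <- correct_between_genes(maps, none, voxel_p = 0.005)
  expect_equal(res0$ledger$note, "no stage-2 test performed")
  expect_true(is.na(res0$ledger$stage2_voxel_p))
})

test_that("a strong injected effect survives both correction stages", {
  blob <- effect_blob(c(7, 8, 7), 2.5, "rs3753526", 2.0)
  cfg <- tiny_config(seed = 29, effect_blobs = list(blob))
  gt <- generate_genotypes(16, cfg$snp_panel, seed = 29)
  ph <- generate_phenotypes(8, 8, seed = 29)
  ds <- generate_bold_dataset(cfg, gt, ph)
  alff <- lapply(ds$subjects, function(s) {
    prep <- preprocess_series(vol_series(s, ds$affine, cfg$tr_s), cfg$n_discard)
    compute_alff_map(prep, ds$mask)
  })
  sm <- run_snp_scan(alff, gt, ph, "rs3753526", cfg$snp_panel, ds$mask,
                     ds$affine, gm_maps = ds$gm)
  clusters <- extract_clusters(sm, 0.005, min_extent = 20)
  expect_gte(nrow(clusters), 1)
  staged <- correct_within_gene(clusters, cfg$snp_panel, min_extent = 20)
  res <- correct_between_genes(list(rs3753526 = sm), staged,
                               voxel_p = 0.005, min_extent = 20)
  expect_true(any(res$clusters$pass_SG))
  expect_true(all(res$clusters$pass_S[res$clusters$pass_SG]))
})
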