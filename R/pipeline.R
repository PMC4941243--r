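#' Full pipeline configuration
#'
#' Bundles the simulation settings with every analysis parameter at its
#' standard default: 0.01-0.08 Hz band, single-voxel p 0.005, family-wise
#' alpha 0.05, 8 mm FWHM, 48-voxel (1296 cubic mm) cluster extent,
#' correlation thresholds 0.3/0.5/0.7, edge-test thresholds
#' 0.05/0.01/0.005/0.001, MAF exclusion below 0.05 and genetic-model cutoff
#' 0.31.
#'
#' @param sim A [simulation_config()].
#' @param band Analysis frequency band in Hz.
#' @param voxel_p Single-voxel interaction threshold.
#' @param alpha Family-wise cluster alpha.
#' @param extent `"fixed"` (use `min_extent_vox`) or `"simulate"`
#'   (Monte-Carlo threshold at the configured smoothness).
#' @param min_extent_vox Fixed cluster extent in voxels.
#' @param cluster_n_iter Monte-Carlo iterations when `extent = "simulate"`.
#' @param connectivity Cluster connectivity (6/18/26).
#' @param r_thresholds Network correlation thresholds.
#' @param edge_p_thresholds Edge-test significance thresholds.
#' @param maf_min MAF exclusion threshold.
#' @param maf_cutoff Genetic-model selection cutoff.
#' @param snps Optional character vector restricting the scan to a SNP
#'   subset (default: all SNPs that pass filtering).
#' @param behaviour_scores Phenotype columns correlated with node strength.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            band = c(0.01, 0.08), voxel_p = 0.005,
                            alpha = 0.05, extent = c("fixed", "simulate"),
                            min_extent_vox = 48, cluster_n_iter = 1000,
                            connectivity = 18,
                            r_thresholds = c(0.3, 0.5, 0.7),
                            edge_p_thresholds = c(0.05, 0.01, 0.005, 0.001),
                            maf_min = 0.05, maf_cutoff = maf_model_cutoff(),
                            snps = NULL,
                            behaviour_scores = c("mmse", "avlt_delayed_z",
                                                 "tmt_b_z")) {
  structure(list(sim = sim, band = band, voxel_p = voxel_p, alpha = alpha,
                 extent = match.arg(extent), min_extent_vox = min_extent_vox,
                 cluster_n_iter = cluster_n_iter, connectivity = connectivity,
                 r_thresholds = r_thresholds,
                 edge_p_thresholds = edge_p_thresholds,
                 maf_min = maf_min, maf_cutoff = maf_cutoff, snps = snps,
                 behaviour_scores = behaviour_scores),
            class = "pipeline_config")
}

#' Validate and normalise a pipeline configuration
#'
#' Checks internal consistency (band inside the Nyquist limit implied by
#' the repetition time, discard count below the volume count, thresholds in
#' range) and records derived acquisition facts such as the total scan
#' duration.
#'
#' @param config A [pipeline_config()].
#' @return A list with `config` (normalised), `warnings` (character vector)
#'   and `provenance` (named list: `n_volumes`, `tr_s`,
#'   `scan_duration_s`, `retained_volumes`, `extent_mm3`).
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  warnings <- character(0)
  nyquist <- 1 / (2 * sim$tr_s)
  if (config$band[2] > nyquist + 1e-12) {
    abort(sprintf("band upper edge %.3f Hz exceeds the Nyquist frequency %.4f Hz for TR %.1f s",
                  config$band[2], nyquist, sim$tr_s))
  }
  if (sim$n_discard >= sim$n_volumes) {
    abort("n_discard must be smaller than n_volumes")
  }
  if (config$voxel_p <= 0 || config$voxel_p >= 1) abort("voxel_p must be in (0, 1)")
  if (config$alpha <= 0 || config$alpha >= 1) abort("alpha must be in (0, 1)")
  if (config$min_extent_vox < 1) abort("min_extent_vox must be at least 1")
  if (any(diff(config$r_thresholds) <= 0)) {
    warnings <- c(warnings, "r_thresholds are not strictly increasing")
  }
  provenance <- list(
    n_volumes = sim$n_volumes, tr_s = sim$tr_s,
    scan_duration_s = sim$n_volumes * sim$tr_s,
    retained_volumes = sim$n_volumes - sim$n_discard,
    extent_mm3 = extent_to_mm3(config$min_extent_vox, sim$voxel_size_mm),
    seed = sim$seed)
  list(config = config, warnings = warnings, provenance = provenance)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulation, per-subject ALFF, SNP-by-diagnosis interaction mapping,
#' cluster-extent inference with the two-stage correction ledger, ROI
#' network reconstruction with node strength, edge-wise group tests,
#' brain-behaviour correlations and the demographic comparison table.
#' Deterministic for a fixed configuration: every stage derives its
#' randomness from the master seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `alffnet_report` with elements `provenance`,
#'   `snp_filter`, `cluster_table`, `ledger`, `network` (node strengths,
#'   edge tests, behaviour correlations, hemispheric summary; `NULL` when
#'   fewer than 2 ROIs survive) and `demographics`.
#' @export
run_pipeline <- function(config) {
  checked <- validate_config(config)
  config <- checked$config
  sim <- config$sim
  n <- sim$n_amci + sim$n_controls

  genotypes <- generate_genotypes(n, sim$snp_panel, seed = sim$seed)
  phenotypes <- generate_phenotypes(sim$n_amci, sim$n_controls, seed = sim$seed)
  dataset <- generate_bold_dataset(sim, genotypes, phenotypes,
                                   keep_series = FALSE)

  alff_maps <- lapply(seq_len(n), function(i) {
    raw <- simulate_subject_series(sim, dataset$mask, dataset$blob_masks,
                                   dataset$multipliers, i)
    prep <- preprocess_series(vol_series(raw, dataset$affine, sim$tr_s),
                              n_discard = sim$n_discard)
    compute_alff_map(prep, dataset$mask, band = config$band)
  })

  snp_filter <- filter_snps(genotypes, sim$snp_panel, maf_min = config$maf_min)
  scan_snps <- config$snps %||% snp_filter$snp_id[snp_filter$kept]
  scan_snps <- intersect(scan_snps, snp_filter$snp_id[snp_filter$kept])

  statmaps <- lapply(scan_snps, function(s) {
    run_snp_scan(alff_maps, genotypes, phenotypes, s, sim$snp_panel,
                 dataset$mask, dataset$affine, gm_maps = dataset$gm)
  })
  names(statmaps) <- scan_snps

  null_max <- NULL
  min_extent <- config$min_extent_vox
  if (config$extent == "simulate") {
    thr <- simulate_cluster_threshold(dataset$mask, sim$smooth_fwhm_mm,
                                      sim$voxel_size_mm, config$voxel_p,
                                      config$alpha, config$cluster_n_iter,
                                      config$connectivity,
                                      seed = stream_seed(sim$seed, "alphasim"))
    null_max <- thr$null_max_sizes
    min_extent <- thr$extent_vox
  }

  clusters <- purrr::map_dfr(statmaps, extract_clusters,
                             voxel_p = config$voxel_p,
                             min_extent = min_extent,
                             connectivity = config$connectivity)
  clusters <- correct_within_gene(clusters, sim$snp_panel,
                                  null_max_sizes = null_max,
                                  min_extent = min_extent,
                                  alpha = config$alpha)
  stage2 <- correct_between_genes(statmaps, clusters,
                                  voxel_p = config$voxel_p,
                                  min_extent = min_extent,
                                  connectivity = config$connectivity,
                                  alpha = config$alpha)
  clusters <- stage2$clusters

  network <- NULL
  rois_s <- clusters[clusters$pass_S, ]
  if (nrow(rois_s) >= 2) {
    roi_ids <- sprintf("%s_c%d", rois_s$snp_id, rois_s$cluster_id)
    roi_masks <- lapply(rois_s$voxels, function(v) {
      m <- array(FALSE, dim(dataset$mask)); m[v] <- TRUE; m
    })
    names(roi_masks) <- roi_ids
    conn <- lapply(seq_len(n), function(i) {
      raw <- simulate_subject_series(sim, dataset$mask, dataset$blob_masks,
                                     dataset$multipliers, i)
      prep <- preprocess_series(vol_series(raw, dataset$affine, sim$tr_s),
                                n_discard = sim$n_discard)
      ts_mat <- sapply(roi_masks, function(m) extract_roi_series(prep, m))
      build_connectivity(ts_mat)
    })
    amci <- which(phenotypes$group == "aMCI")
    strengths <- purrr::map_dfr(seq_len(n), function(i) {
      dplyr::mutate(node_strength(conn[[i]]),
                    subject_id = phenotypes$subject_id[i], .before = 1)
    })
    edge_tests <- compare_edges(conn[amci], conn[-amci],
                                p_thresholds = config$edge_p_thresholds)
    strengths_amci <- strengths[strengths$subject_id %in%
                                  phenotypes$subject_id[amci], ]
    scores <- phenotypes[amci, intersect(config$behaviour_scores,
                                         names(phenotypes)), drop = FALSE]
    behaviour <- if (ncol(scores) > 0 && length(amci) >= 4) {
      behavior_correlation(strengths_amci, scores)
    }
    roi_meta <- tibble::tibble(
      roi_id = roi_ids,
      hemisphere = dplyr::case_when(rois_s$peak_x < 0 ~ "L",
                                    rois_s$peak_x > 0 ~ "R",
                                    TRUE ~ "bilateral"))
    mean_conn <- Reduce(`+`, conn) / length(conn)
    network <- list(
      roi_ids = roi_ids,
      n_nodes = length(roi_ids),
      n_edges = count_edges(length(roi_ids)),
      retained_edges = lapply(setNames(config$r_thresholds,
                                       paste0("r_", config$r_thresholds)),
                              function(thr) threshold_network(mean_conn, thr)),
      node_strengths = strengths,
      edge_tests = edge_tests,
      behaviour = behaviour,
      hemispheric = hemispheric_strength_summary(mean_conn, roi_meta))
  }

  structure(list(provenance = c(checked$provenance,
                                list(min_extent_vox = min_extent,
                                     voxel_p = config$voxel_p,
                                     band = config$band,
                                     n_snps_scanned = length(scan_snps))),
                 snp_filter = snp_filter,
                 cluster_table = dplyr::select(clusters, -"voxels"),
                 ledger = stage2$ledger,
                 network = network,
                 demographics = demographic_tests(phenotypes)),
            class = "alffnet_report")
}

#' @export
print.alffnet_report <- function(x, ...) {
  cat("<alffnet_report>\n")
  cat(sprintf("  scan: %d volumes x %.1f s TR = %.0f s\n",
              x$provenance$n_volumes, x$provenance$tr_s,
              x$provenance$scan_duration_s))
  cat(sprintf("  SNPs scanned: %d; clusters pass_S: %d; pass_SG: %d\n",
              x$provenance$n_snps_scanned, sum(x$cluster_table$pass_S),
              sum(x$cluster_table$pass_SG)))
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d nodes, %d edges\n", x$network$n_nodes,
                x$network$n_edges))
  }
  invisible(x)
}
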