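# neighbour offsets for 6- (faces), 18- (faces+edges) or 26-connectivity
connectivity_offsets <- function(connectivity = 18) {
  if (!connectivity %in% c(6, 18, 26)) abort("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  d <- rowSums(abs(off))
  if (connectivity == 6) off <- off[d == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[d <= 2, , drop = FALSE]
  off
}

#' Label connected components of a binary 3D volume
#'
#' Union-find over the supra-threshold voxels under 6-, 18- or
#' 26-connectivity.
#'
#' @param binary Logical 3D array.
#' @param connectivity 6, 18 (default, faces + edges) or 26.
#' @return A list with `voxels` (linear indices of `TRUE` voxels), `labels`
#'   (component id per voxel, components numbered from 1 in first-voxel
#'   order) and `sizes` (voxel count per component).
#' @export
label_clusters <- function(binary, connectivity = 18) {
  dims <- dim(binary)
  vox <- which(binary)
  nv <- length(vox)
  if (nv == 0) {
    return(list(voxels = integer(0), labels = integer(0), sizes = integer(0)))
  }
  coords <- arrayInd(vox, dims)
  pos <- array(0L, dims)
  pos[vox] <- seq_len(nv)
  off <- connectivity_offsets(connectivity)

  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(off))) {
    nb <- coords + matrix(off[o, ], nv, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
      (nb[ok, 3] - 1) * dims[1] * dims[2]
    nid <- pos[nlin]
    pair_a <- which(ok)[nid > 0]
    pair_b <- nid[nid > 0]
    for (p in seq_along(pair_a)) {
      ra <- find(pair_a[p]); rb <- find(pair_b[p])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  labels <- match(roots, unique(roots))
  list(voxels = vox, labels = labels,
       sizes = as.integer(tabulate(labels)))
}

#' Monte-Carlo cluster-extent threshold (AlphaSim style)
#'
#' Repeatedly generates Gaussian white noise on the grid, smooths it to the
#' stated FWHM, thresholds the in-mask values at the upper-tail `voxel_p`
#' quantile and records the largest supra-threshold cluster. The returned
#' extent is the smallest cluster size whose family-wise probability under
#' this null does not exceed `alpha`.
#'
#' @param mask Logical 3D brain mask.
#' @param fwhm_mm Assumed smoothness of the statistic map (mm FWHM).
#' @param voxel_size_mm Voxel edge length in millimetres.
#' @param voxel_p Single-voxel threshold (default 0.005).
#' @param alpha Family-wise cluster alpha (default 0.05).
#' @param n_iter Number of noise realisations (at least 200; default 1000).
#' @param connectivity Cluster connectivity (default 18).
#' @param seed Integer seed.
#' @return A list of class `cluster_threshold`: `extent_vox`,
#'   `extent_mm3`, `null_max_sizes` (per-iteration largest cluster) and the
#'   simulation parameters.
#' @export
simulate_cluster_threshold <- function(mask, fwhm_mm = 8, voxel_size_mm = 3,
                                       voxel_p = 0.005, alpha = 0.05,
                                       n_iter = 1000, connectivity = 18,
                                       seed = 1L) {
  if (!any(mask)) abort("mask is empty")
  if (fwhm_mm < 0) abort("fwhm must be non-negative")
  if (n_iter < 200) abort("need at least 200 iterations")
  if (voxel_p <= 0 || voxel_p >= 1 || alpha <= 0 || alpha >= 1) {
    abort("voxel_p and alpha must lie in (0, 1)")
  }
  dims <- dim(mask)
  vin <- which(mask)
  set.seed(seed)
  max_sizes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    noise <- array(rnorm(prod(dims)), dims)
    if (fwhm_mm > 0) noise <- gaussian_smooth_3d(noise, fwhm_mm, voxel_size_mm)
    vals <- noise[vin]
    thr <- quantile(vals, 1 - voxel_p)
    supra <- array(FALSE, dims)
    supra[vin[vals > thr]] <- TRUE
    comp <- label_clusters(supra, connectivity)
    max_sizes[i] <- if (length(comp$sizes) == 0) 0L else max(comp$sizes)
  }
  extent <- min_extent_from_null(max_sizes, alpha)
  structure(list(extent_vox = extent,
                 extent_mm3 = extent_to_mm3(extent, voxel_size_mm),
                 null_max_sizes = max_sizes,
                 fwhm_mm = fwhm_mm, voxel_size_mm = voxel_size_mm,
                 voxel_p = voxel_p, alpha = alpha, n_iter = n_iter,
                 connectivity = connectivity, seed = seed),
            class = "cluster_threshold")
}

# smallest extent k with P(max null cluster >= k) <= alpha
min_extent_from_null <- function(null_max_sizes, alpha) {
  k <- 1L
  while (mean(null_max_sizes >= k) > alpha) k <- k + 1L
  k
}

# family-wise corrected p-value of an observed cluster size
cluster_corrected_p <- function(size, null_max_sizes) {
  vapply(size, function(s) mean(null_max_sizes >= s), numeric(1))
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Voxels with `p < voxel_p` are labelled into connected components;
#' components of at least `min_extent` voxels are returned with their peak
#' statistic and peak MNI coordinate (ties broken at the lowest linear
#' voxel index).
#'
#' @param statmap A `snp_stat_map` (see [run_snp_scan()]).
#' @param voxel_p Single-voxel p threshold (default 0.005).
#' @param min_extent Minimum cluster extent in voxels (default 48, i.e.
#'   1296 cubic mm at 3 mm voxels).
#' @param connectivity Cluster connectivity (default 18).
#' @return A tibble with one row per cluster: `snp_id`, `cluster_id`,
#'   `size_vox`, `size_mm3`, `peak_stat`, `peak_p`, `peak_x/y/z` (MNI mm)
#'   and a `voxels` list-column of linear indices.
#' @export
extract_clusters <- function(statmap, voxel_p = 0.005, min_extent = 48,
                             connectivity = 18) {
  supra <- statmap$p < voxel_p & statmap$mask
  comp <- label_clusters(supra, connectivity)
  vox_mm3 <- voxel_volume_mm3(statmap$affine)
  keep <- which(comp$sizes >= min_extent)
  if (length(keep) == 0) {
    return(tibble::tibble(snp_id = character(0), cluster_id = integer(0),
                          size_vox = integer(0), size_mm3 = numeric(0),
                          peak_stat = numeric(0), peak_p = numeric(0),
                          peak_x = numeric(0), peak_y = numeric(0),
                          peak_z = numeric(0), voxels = list()))
  }
  rows <- purrr::map_dfr(seq_along(keep), function(j) {
    members <- comp$voxels[comp$labels == keep[j]]
    stats <- statmap$F[members]
    peak <- members[which.max(stats)]   # which.max takes the first (lowest index) tie
    mni <- voxel_to_mni(arrayInd(peak, dim(statmap$mask)), statmap$affine)
    tibble::tibble(snp_id = statmap$snp_id %||% NA_character_,
                   cluster_id = j,
                   size_vox = length(members),
                   size_mm3 = length(members) * vox_mm3,
                   peak_stat = max(stats), peak_p = statmap$p[peak],
                   peak_x = mni[1], peak_y = mni[2], peak_z = mni[3],
                   voxels = list(members))
  })
  dplyr::arrange(rows, dplyr::desc(.data$size_vox))
}

#' Imaging-space correction with within-gene Bonferroni alpha
#'
#' Flags `pass_S` for clusters that survive the cluster-extent correction.
#' When a Monte-Carlo null distribution is supplied, each cluster's
#' family-wise corrected p is compared against `alpha` divided by the
#' number of panel SNPs in the cluster's gene; otherwise the packaged
#' fixed-extent rule (`size_vox >= min_extent`) is applied.
#'
#' @param clusters Cluster tibble from [extract_clusters()] (any number of
#'   SNPs row-bound together).
#' @param panel SNP panel tibble (supplies the gene assignment and
#'   per-gene SNP counts).
#' @param null_max_sizes Optional null distribution of maximal cluster
#'   sizes from [simulate_cluster_threshold()].
#' @param min_extent Fixed extent rule used when no null distribution is
#'   given (default 48 voxels).
#' @param alpha Family-wise alpha before the within-gene division
#'   (default 0.05).
#' @return The cluster tibble with `gene`, `alpha_snp`, `p_corrected`
#'   (`NA` in fixed-extent mode) and `pass_S` columns.
#' @export
correct_within_gene <- function(clusters, panel, null_max_sizes = NULL,
                                min_extent = 48, alpha = 0.05) {
  if (nrow(clusters) == 0) {
    return(dplyr::mutate(clusters, gene = character(0),
                         alpha_snp = numeric(0), p_corrected = numeric(0),
                         pass_S = logical(0)))
  }
  if (!all(clusters$snp_id %in% panel$snp_id)) {
    abort("cluster table contains SNPs without a gene assignment")
  }
  gene_counts <- dplyr::count(panel, .data$gene, name = "n_snps")
  out <- clusters |>
    dplyr::left_join(panel[, c("snp_id", "gene")], by = "snp_id") |>
    dplyr::left_join(gene_counts, by = "gene") |>
    dplyr::mutate(alpha_snp = alpha / .data$n_snps)
  if (is.null(null_max_sizes)) {
    out$p_corrected <- NA_real_
    out$pass_S <- out$size_vox >= min_extent
  } else {
    out$p_corrected <- cluster_corrected_p(out$size_vox, null_max_sizes)
    out$pass_S <- out$p_corrected <= out$alpha_snp
  }
  dplyr::select(out, -"n_snps")
}

#' Between-gene correction across surviving SNPs
#'
#' Counts the SNPs with at least one `pass_S` cluster (`k`), tightens the
#' single-voxel threshold to `voxel_p / k`, re-extracts clusters from each
#' surviving SNP's statistic map under the same extent rule, and flags
#' `pass_SG` on the stage-1 clusters that still contain a surviving
#' stage-2 cluster peak.
#'
#' @param statmaps Named list of `snp_stat_map` objects (names = snp ids)
#'   for at least the SNPs with `pass_S` clusters.
#' @param clusters Cluster tibble with `pass_S` flags (see
#'   [correct_within_gene()]).
#' @param voxel_p Stage-1 single-voxel threshold (default 0.005).
#' @param min_extent Cluster extent rule in voxels (default 48).
#' @param connectivity Cluster connectivity (default 18).
#' @param alpha Family-wise alpha recorded in the ledger (default 0.05).
#' @return A list with `clusters` (tibble gaining `pass_SG`) and `ledger`
#'   (a `correction_ledger`).
#' @export
correct_between_genes <- function(statmaps, clusters, voxel_p = 0.005,
                                  min_extent = 48, connectivity = 18,
                                  alpha = 0.05) {
  surviving <- unique(clusters$snp_id[clusters$pass_S])
  k <- length(surviving)
  clusters$pass_SG <- FALSE
  ledger <- structure(list(stage1_voxel_p = voxel_p, alpha = alpha,
                           n_stage1_snps = k,
                           stage2_voxel_p = if (k > 0) voxel_p / k else NA_real_,
                           min_extent_vox = min_extent,
                           note = if (k == 0) "no stage-2 test performed" else NA_character_),
                      class = "correction_ledger")
  if (k == 0) {
    return(list(clusters = clusters, ledger = ledger))
  }
  p2 <- voxel_p / k
  for (s in surviving) {
    if (!s %in% names(statmaps)) {
      abort(sprintf("statistic map for surviving SNP %s not supplied", s))
    }
    stage2 <- extract_clusters(statmaps[[s]], voxel_p = p2,
                               min_extent = min_extent,
                               connectivity = connectivity)
    if (nrow(stage2) == 0) next
    rows <- which(clusters$snp_id == s & clusters$pass_S)
    for (j in seq_len(nrow(stage2))) {
      peak2 <- stage2$voxels[[j]][which.max(statmaps[[s]]$F[stage2$voxels[[j]]])]
      hit <- rows[vapply(rows, function(r) peak2 %in% clusters$voxels[[r]],
                         logical(1))]
      clusters$pass_SG[hit] <- TRUE
    }
  }
  list(clusters = clusters, ledger = ledger)
}

#' @export
print.correction_ledger <- function(x, ...) {
  cat("<correction_ledger>\n")
  cat(sprintf("  stage 1: voxel p < %g, extent >= %d voxels, alpha %g\n",
              x$stage1_voxel_p, x$min_extent_vox, x$alpha))
  if (!is.na(x$note)) {
    cat("  stage 2:", x$note, "\n")
  } else {
    cat(sprintf("  stage 2: %d surviving SNP(s), voxel p < %g/%d = %g\n",
                x$n_stage1_snps, x$stage1_voxel_p, x$n_stage1_snps,
                x$stage2_voxel_p))
  }
  invisible(x)
}
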