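#' Build ROI voxel masks from peak coordinates
#'
#' Realises each ROI as a sphere of `radius_mm` around its peak MNI
#' coordinate, intersected with the brain mask. Used when only the peak
#' table is available; cluster-voxel masks can be supplied directly where
#' clusters were extracted in-session.
#'
#' @param rois ROI tibble (see [roi_table()]) with `roi_id`, `x`, `y`, `z`.
#' @param mask Logical 3D brain mask.
#' @param affine 4x4 affine of the grid.
#' @param radius_mm Sphere radius in millimetres (default 6).
#' @return Named list of logical 3D masks, one per ROI. ROIs whose sphere
#'   contains no in-mask voxel are dropped with a warning.
#' @export
roi_sphere_masks <- function(rois, mask, affine, radius_mm = 6) {
  dims <- dim(mask)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  mm <- voxel_to_mni(idx, affine)
  out <- lapply(seq_len(nrow(rois)), function(i) {
    d2 <- (mm[, 1] - rois$x[i])^2 + (mm[, 2] - rois$y[i])^2 +
      (mm[, 3] - rois$z[i])^2
    array(d2 <= radius_mm^2, dims) & mask
  })
  names(out) <- rois$roi_id
  empty <- !vapply(out, any, logical(1))
  if (any(empty)) {
    warn(sprintf("%d ROI(s) have no in-mask voxels and were dropped: %s",
                 sum(empty), paste(names(out)[empty], collapse = ", ")))
    out <- out[!empty]
  }
  out
}

#' Mean time series over an ROI
#'
#' @param series A [vol_series()] or 4D array.
#' @param roi_mask Logical 3D ROI mask.
#' @return Numeric vector: the unweighted voxel mean at each time point.
#' @export
extract_roi_series <- function(series, roi_mask) {
  data <- if (inherits(series, "vol_series")) series$data else series
  vin <- which(roi_mask)
  if (length(vin) == 0) abort("ROI mask is empty")
  dims <- dim(data)
  flat <- matrix(data, prod(dims[1:3]), dims[4])
  colMeans(flat[vin, , drop = FALSE])
}

#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlations of the ROI time series, clipped to
#' `+/-(1 - 1e-7)` and Fisher z-transformed (`atanh`). The diagonal is set
#' to 0 and is excluded from all downstream statistics.
#'
#' @param roi_series Numeric matrix, time points x ROIs (column names become
#'   node names).
#' @return Symmetric ROI x ROI matrix of z values, class `conn_matrix`.
#' @export
build_connectivity <- function(roi_series) {
  roi_series <- as.matrix(roi_series)
  if (nrow(roi_series) < 3) abort("need at least 3 time points")
  if (ncol(roi_series) < 2) abort("need at least 2 ROIs")
  sds <- apply(roi_series, 2, sd)
  degenerate <- sds == 0
  if (any(degenerate)) {
    warn(sprintf("%d ROI series have zero variance; their edges are set to 0",
                 sum(degenerate)))
  }
  r <- suppressWarnings(cor(roi_series))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  class(z) <- c("conn_matrix", class(z))
  z
}

#' Number of edges of a complete undirected network
#' @param n_nodes Number of nodes.
#' @return `n (n - 1) / 2`.
#' @export
#' @examples
#' count_edges(31)  # 465
count_edges <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  n_nodes * (n_nodes - 1) / 2
}

#' Threshold a connectivity matrix on the correlation scale
#'
#' Retains the edges whose correlation magnitude reaches `r_threshold`;
#' weights are reported on the Fisher-z scale, signs preserved.
#'
#' @param z `conn_matrix` of Fisher-z weights.
#' @param r_threshold Correlation threshold in `[0, 1)`.
#' @return Tibble of retained edges: `node_i`, `node_j` (i < j order), `r`,
#'   `z`.
#' @export
threshold_network <- function(z, r_threshold = 0.3) {
  if (r_threshold < 0 || r_threshold >= 1) abort("r_threshold must be in [0, 1)")
  nodes <- colnames(z) %||% as.character(seq_len(ncol(z)))
  ut <- which(upper.tri(z), arr.ind = TRUE)
  r <- tanh(z[ut])
  keep <- abs(r) >= r_threshold
  tibble::tibble(node_i = nodes[ut[keep, 1]], node_j = nodes[ut[keep, 2]],
                 r = r[keep], z = z[ut][keep])
}

#' Node strength of a weighted network
#'
#' `S_i = sum_{j != i} w_ij`, the signed sum of the Fisher-z edge weights
#' incident to each node.
#'
#' @param z Symmetric weight matrix (diagonal ignored).
#' @return Tibble with `node` and `strength`.
#' @export
#' @examples
#' w <- matrix(1, 31, 31); diag(w) <- 0
#' node_strength(w)$strength[1]  # 30
node_strength <- function(z) {
  z <- as.matrix(z)
  stopifnot(nrow(z) == ncol(z))
  zz <- z
  diag(zz) <- 0
  tibble::tibble(node = colnames(z) %||% as.character(seq_len(ncol(z))),
                 strength = rowSums(zz))
}

#' Edge-wise two-sample comparison of connectivity
#'
#' Pooled-variance two-sample t-test on the Fisher-z weight of every edge,
#' with significance flags at each requested (uncorrected) p threshold and
#' a Bonferroni-adjusted p column.
#'
#' @param matrices_a,matrices_b Lists of `conn_matrix` objects for the two
#'   groups (at least 2 subjects each).
#' @param p_thresholds Uncorrected significance thresholds
#'   (default `c(0.05, 0.01, 0.005, 0.001)`).
#' @return Tibble with one row per edge: `node_i`, `node_j`, group means,
#'   `statistic`, `df`, `p_value`, `p_bonferroni` and one `sig_<p>` logical
#'   column per threshold. Edges with zero variance in both groups are
#'   returned with `NA` statistics.
#' @export
compare_edges <- function(matrices_a, matrices_b,
                          p_thresholds = c(0.05, 0.01, 0.005, 0.001)) {
  if (length(matrices_a) < 2 || length(matrices_b) < 2) {
    abort("need at least 2 subjects per group")
  }
  n_edge <- sum(upper.tri(matrices_a[[1]]))
  za <- matrix(vapply(matrices_a, function(m) m[upper.tri(m)],
                      numeric(n_edge)), nrow = n_edge)
  zb <- matrix(vapply(matrices_b, function(m) m[upper.tri(m)],
                      numeric(n_edge)), nrow = n_edge)
  nodes <- colnames(matrices_a[[1]]) %||%
    as.character(seq_len(ncol(matrices_a[[1]])))
  ut <- which(upper.tri(matrices_a[[1]]), arr.ind = TRUE)
  n1 <- ncol(za); n2 <- ncol(zb)
  m1 <- rowMeans(za); m2 <- rowMeans(zb)
  v1 <- apply(za, 1, var); v2 <- apply(zb, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- ifelse(se > 0, (m1 - m2) / se, NA_real_)
  if (any(se == 0)) {
    inform(sprintf("%d edge(s) with zero variance in both groups skipped",
                   sum(se == 0)))
  }
  p <- 2 * pt(-abs(stat), n1 + n2 - 2)
  out <- tibble::tibble(node_i = nodes[ut[, 1]], node_j = nodes[ut[, 2]],
                        mean_a = m1, mean_b = m2,
                        statistic = stat, df = n1 + n2 - 2, p_value = p,
                        p_bonferroni = pmin(p * length(p), 1))
  for (thr in p_thresholds) {
    out[[paste0("sig_", thr)]] <- !is.na(p) & p < thr
  }
  class(out) <- c("alffnet_edge_tests", class(out))
  out
}

#' Correlate node strength with behavioural scores
#'
#' Pearson correlation of each node's strength with each score; with
#' covariates supplied, both variables are residualised on the covariates
#' first (partial correlation), with the degrees of freedom reduced
#' accordingly. Both uncorrected and Bonferroni-adjusted p-values are
#' reported.
#'
#' @param strengths Tibble or data frame, subjects x nodes (numeric
#'   columns), or the output of [node_strength()] stacked per subject with
#'   columns `subject_id`, `node`, `strength`.
#' @param scores Tibble of behavioural scores (numeric columns), rows
#'   aligned with `strengths` subjects.
#' @param covariates Optional tibble/matrix of covariates, rows aligned.
#' @return Tibble: `node`, `score`, `r`, `df`, `p_value`, `p_bonferroni`,
#'   `method`.
#' @export
behavior_correlation <- function(strengths, scores, covariates = NULL) {
  if (all(c("node", "strength") %in% names(strengths))) {
    strengths <- tidyr::pivot_wider(strengths, id_cols = "subject_id",
                                    names_from = "node",
                                    values_from = "strength")
    strengths <- strengths[, -1]
  }
  s_mat <- as.matrix(strengths)
  sc_mat <- as.matrix(scores)
  n <- nrow(s_mat)
  if (n < 4) abort("need at least 4 subjects")
  if (any(apply(sc_mat, 2, sd) == 0)) abort("constant score column supplied")
  n_cov <- 0
  if (!is.null(covariates)) {
    cv <- cbind(1, data.matrix(covariates))
    n_cov <- ncol(cv) - 1
    if (n_cov >= n - 2) abort("too many covariates for the sample size")
    resid_on <- function(m) m - cv %*% solve(crossprod(cv), crossprod(cv, m))
    s_mat <- resid_on(s_mat)
    sc_mat <- resid_on(sc_mat)
  }
  grid <- expand.grid(node = colnames(s_mat), score = colnames(sc_mat),
                      stringsAsFactors = FALSE)
  df <- n - 2 - n_cov
  out <- purrr::pmap_dfr(grid, function(node, score) {
    r <- cor(s_mat[, node], sc_mat[, score])
    stat <- r * sqrt(df / (1 - r^2))
    tibble::tibble(node = node, score = score, r = r, df = df,
                   p_value = 2 * pt(-abs(stat), df))
  })
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  out$method <- if (n_cov > 0) "partial" else "pearson"
  out
}

#' Hemispheric aggregate strength and laterality index
#'
#' Sums node strength over left- and right-tagged nodes and reports the
#' laterality index `(L - R) / (L + R)`.
#'
#' @param z Connectivity matrix with node names matching `rois$roi_id`.
#' @param rois ROI tibble with `roi_id` and `hemisphere` columns.
#' @return Tibble with `left_strength`, `right_strength`,
#'   `laterality_index` (NA when no tagged nodes are present).
#' @export
hemispheric_strength_summary <- function(z, rois) {
  s <- node_strength(z)
  s <- dplyr::left_join(s, rois[, c("roi_id", "hemisphere")],
                        by = c(node = "roi_id"))
  l <- sum(s$strength[s$hemisphere %in% "L"])
  r <- sum(s$strength[s$hemisphere %in% "R"])
  n_tagged <- sum(s$hemisphere %in% c("L", "R"))
  tibble::tibble(
    left_strength = if (n_tagged > 0) l else NA_real_,
    right_strength = if (n_tagged > 0) r else NA_real_,
    laterality_index = if (n_tagged > 0 && (l + r) != 0) (l - r) / (l + r)
                       else NA_real_)
}
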