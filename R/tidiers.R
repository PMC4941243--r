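#' @export
glance.snp_stat_map <- function(x, ...) {
  tibble::tibble(snp_id = x$snp_id, model = x$model, maf = x$maf,
                 df1 = x$df1, df2 = x$df2, n = x$n,
                 peak_F = max(x$F), min_p = min(x$p[x$mask]),
                 n_aliased_voxels = x$n_aliased_voxels)
}

#' @export
tidy.cluster_threshold <- function(x, ...) {
  tibble::tibble(extent_vox = x$extent_vox, extent_mm3 = x$extent_mm3,
                 fwhm_mm = x$fwhm_mm, voxel_p = x$voxel_p, alpha = x$alpha,
                 n_iter = x$n_iter, connectivity = x$connectivity)
}

#' @export
tidy.correction_ledger <- function(x, ...) {
  tibble::tibble(stage1_voxel_p = x$stage1_voxel_p, alpha = x$alpha,
                 n_stage1_snps = x$n_stage1_snps,
                 stage2_voxel_p = x$stage2_voxel_p,
                 min_extent_vox = x$min_extent_vox, note = x$note)
}

#' @export
tidy.alffnet_report <- function(x, ...) {
  x$cluster_table
}

#' @export
glance.alffnet_report <- function(x, ...) {
  tibble::tibble(n_snps_scanned = x$provenance$n_snps_scanned,
                 n_clusters = nrow(x$cluster_table),
                 n_pass_S = sum(x$cluster_table$pass_S),
                 n_pass_SG = sum(x$cluster_table$pass_SG),
                 n_nodes = if (is.null(x$network)) 0L else x$network$n_nodes,
                 n_edges = if (is.null(x$network)) 0L else x$network$n_edges,
                 scan_duration_s = x$provenance$scan_duration_s)
}

#' @export
tidy.alffnet_demographics <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "alffnet_demographics")
  out
}

#' @export
glance.alffnet_demographics <- function(x, ...) {
  tibble::tibble(n_variables = dplyr::n_distinct(x$variable),
                 group_1 = attr(x, "groups")[1],
                 group_2 = attr(x, "groups")[2])
}

# middle-slice tibble for raster plots
slice_tibble <- function(vol, slice = NULL) {
  slice <- slice %||% ceiling(dim(vol)[3] / 2)
  tibble::tibble(x = rep(seq_len(dim(vol)[1]), dim(vol)[2]),
                 y = rep(seq_len(dim(vol)[2]), each = dim(vol)[1]),
                 value = as.vector(vol[, , slice]))
}

#' Plot an axial slice of an ALFF map
#' @param object An `alff_map`.
#' @param slice Axial slice index (defaults to the middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alff_map <- function(object, slice = NULL, ...) {
  ggplot2::ggplot(slice_tibble(object$data, slice),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "ALFF") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "ALFF (axial slice)", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of an interaction F map
#' @param object A `snp_stat_map`.
#' @param slice Axial slice index (defaults to the middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snp_stat_map <- function(object, slice = NULL, ...) {
  ggplot2::ggplot(slice_tibble(object$F, slice),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "F", option = "magma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s x diagnosis interaction", object$snp_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of edge-wise group differences
#' @param object An edge-test table from [compare_edges()].
#' @param p_highlight Threshold drawn as a horizontal reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alffnet_edge_tests <- function(object, p_highlight = 0.005, ...) {
  dat <- dplyr::mutate(object, diff = .data$mean_a - .data$mean_b,
                       neglogp = -log10(.data$p_value))
  ggplot2::ggplot(dat, ggplot2::aes(.data$diff, .data$neglogp)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(p_highlight), linetype = 2) +
    ggplot2::labs(x = "group difference in Fisher z",
                  y = expression(-log[10](p)),
                  title = "Edge-wise connectivity differences") +
    ggplot2::theme_minimal()
}

#' Node-strength distribution per node
#' @param strengths Stacked node-strength tibble (`subject_id`, `node`,
#'   `strength`).
#' @return A ggplot object.
#' @export
plot_node_strength <- function(strengths) {
  ggplot2::ggplot(strengths,
                  ggplot2::aes(.data$node, .data$strength)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "node strength (sum of Fisher-z weights)") +
    ggplot2::theme_minimal()
}
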