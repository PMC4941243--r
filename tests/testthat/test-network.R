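test_that("the packaged ROI table matches the published cluster summary", {
  rois <- roi_table()
  expect_equal(nrow(rois), 31)
  expect_true(all(rois$pass_S))
  apoe4 <- rois[rois$snp_id == "rs429358", ]
  expect_equal(nrow(apoe4), 4)
  crbl <- apoe4[apoe4$abbrev == "L.CRBL_Po", ]
  expect_equal(c(crbl$x, crbl$y, crbl$z), c(-36, -57, -33))
  expect_equal(crbl$peak_F, 81.78)
  expect_true(crbl$pass_SG)
  expect_equal(sum(rois$pass_SG), 3)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(readr::read_tsv(system.file(
    "extdata", "interaction_roi_table.tsv", package = "alffnet"),
    show_col_types = FALSE, n_max = 0)), collapse = "\t"), empty)
  expect_error(roi_table(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(system.file("extdata", "interaction_roi_table.tsv",
                                 package = "alffnet"))
  fields <- strsplit(lines[3], "\t")[[1]]
  fields[7] <- ""                      # blank out the x coordinate
  lines[3] <- paste(fields, collapse = "\t")
  writeLines(lines, bad)
  expect_error(suppressWarnings(roi_table(bad)), "line\\(s\\): 3")
})

test_that("ROI series are plain voxel means", {
  dims <- c(6, 6, 4)
  arr <- array(rnorm(prod(dims) * 12), c(dims, 12))
  one <- array(FALSE, dims); one[2, 3, 2] <- TRUE
  expect_equal(extract_roi_series(arr, one), arr[2, 3, 2, ])

  # two voxels carrying x and -x cancel
  sym <- array(0, c(dims, 12))
  x <- rnorm(12)
  sym[1, 1, 1, ] <- x; sym[2, 1, 1, ] <- -x
  two <- array(FALSE, dims); two[1:2, 1, 1] <- TRUE
  expect_equal(extract_roi_series(sym, two), rep(0, 12))

  # brute-force per-timepoint mean oracle
  roi <- array(runif(prod(dims)) < 0.3, dims)
  got <- extract_roi_series(arr, roi)
  want <- vapply(1:12, function(t) mean(arr[, , , t][roi]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(extract_roi_series(arr, array(FALSE, dims)), "empty")
})

test_that("connectivity matrices are symmetric Fisher-z with clipping", {
  set.seed(8)
  base <- rnorm(40)
  ts <- cbind(a = base, b = base, c = -base + 1, d = rnorm(40))
  z <- build_connectivity(ts)
  expect_equal(z["a", "b"], atanh(1 - 1e-7))
  expect_equal(z["a", "c"], -atanh(1 - 1e-7))
  expect_true(all(is.finite(z)))
  expect_equal(unclass(z), t(unclass(z)), ignore_attr = TRUE)

  pair <- make_correlated_pair(0.3, n = 50)
  z2 <- build_connectivity(pair)
  expect_equal(z2["x", "y"], atanh(0.3), tolerance = 1e-10)
  expect_equal(build_connectivity(make_correlated_pair(0.5))["x", "y"],
               0.5493, tolerance = 1e-4)

  flat <- cbind(a = rep(1, 10), b = rnorm(10))
  expect_warning(zf <- build_connectivity(flat), "zero variance")
  expect_equal(zf["a", "b"], 0)
  expect_error(build_connectivity(ts[1:2, ]), "3 time points")
})

test_that("complete-network edge counts follow n(n-1)/2", {
  expect_equal(count_edges(31), 465)
  expect_equal(count_edges(1), 0)
  expect_equal(count_edges(2), 1)
})

test_that("r-thresholded edge sets are nested and exact on constructed values", {
  r_vals <- c(0.2, 0.4, 0.8)
  z <- diag(0, 3)
  z[upper.tri(z)] <- atanh(r_vals)
  z <- z + t(z)
  colnames(z) <- rownames(z) <- c("n1", "n2", "n3")
  class(z) <- c("conn_matrix", class(z))
  expect_equal(nrow(threshold_network(z, 0)), 3)
  expect_equal(nrow(threshold_network(z, 0.5)), 1)
  expect_equal(threshold_network(z, 0.5)$r, 0.8, tolerance = 1e-12)

  set.seed(99)
  zr <- build_connectivity(matrix(rnorm(31 * 40), 40, 31))
  e3 <- threshold_network(zr, 0.3); e5 <- threshold_network(zr, 0.5)
  e7 <- threshold_network(zr, 0.7)
  key <- function(e) paste(e$node_i, e$node_j)
  expect_true(all(key(e7) %in% key(e5)))
  expect_true(all(key(e5) %in% key(e3)))
  expect_error(threshold_network(zr, 1), "r_threshold")
})

test_that("node strength is the signed row sum of incident weights", {
  w <- matrix(1, 31, 31); diag(w) <- 0
  expect_true(all(node_strength(w)$strength == 30))
  expect_true(all(node_strength(matrix(0, 5, 5))$strength == 0))

  w3 <- matrix(0, 4, 4)
  w3[1, 2:4] <- c(0.2, 0.3, -0.1); w3[2:4, 1] <- c(0.2, 0.3, -0.1)
  expect_equal(node_strength(w3)$strength[1], 0.4)

  set.seed(12)
  z <- build_connectivity(matrix(rnorm(10 * 30), 30, 10))
  zz <- unclass(z); diag(zz) <- 0
  expect_identical(node_strength(z)$strength, rowSums(zz))
})

test_that("edge-wise group tests are calibrated, powered and nested", {
  random_conn <- function(seed, shift_edge = FALSE, n = 31) {
    set.seed(seed)
    z <- matrix(0, n, n)
    z[upper.tri(z)] <- rnorm(n * (n - 1) / 2, 0.3, 0.2)
    if (shift_edge) z[1, 2] <- z[1, 2] - 0.4   # 2 pooled SDs
    z + t(z)
  }
  # null calibration: 5 replicate studies, expected 465 * 0.05 hits each
  hits <- vapply(1:5, function(r) {
    a <- lapply(1:43, function(i) random_conn(r * 1000 + i))
    b <- lapply(1:30, function(i) random_conn(r * 1000 + 500 + i))
    res <- compare_edges(a, b)
    sum(res$sig_0.05)
  }, numeric(1))
  expected <- 465 * 0.05
  se <- sqrt(465 * 0.05 * 0.95 / 5)
  expect_lt(abs(mean(hits) - expected), 3 * se)

  # a 2-pooled-SD shift on one edge is found at p < 0.005 in >= 90% of runs
  found <- vapply(1:20, function(r) {
    a <- lapply(1:43, function(i) random_conn(r * 2000 + i, shift_edge = TRUE))
    b <- lapply(1:30, function(i) random_conn(r * 2000 + 500 + i))
    res <- compare_edges(a, b)
    res$sig_0.005[res$node_i == "1" & res$node_j == "2"]
  }, logical(1))
  expect_gte(sum(found), 18)

  a <- lapply(1:10, function(i) random_conn(i))
  b <- lapply(1:10, function(i) random_conn(100 + i))
  res <- compare_edges(a, b)
  expect_true(all(res$p_value[res$sig_0.001]  < 0.005))
  expect_true(all(res$sig_0.005 | !res$sig_0.001))
  expect_true(all(res$sig_0.01 | !res$sig_0.005))
  expect_true(all(res$sig_0.05 | !res$sig_0.01))
  expect_error(compare_edges(a[1], b), "at least 2")
})

test_that("behaviour correlations support exact, partial and oracle checks", {
  set.seed(3)
  n <- 60
  strengths <- tibble::tibble(node_a = rnorm(n), node_b = rnorm(n))
  scores <- tibble::tibble(mmse = 2 * strengths$node_a + 1)
  res <- behavior_correlation(strengths, scores)
  expect_equal(res$r[res$node == "node_a"], 1, tolerance = 1e-12)

  # association fully carried by a covariate vanishes in partial correlation
  n2 <- 500
  confound <- rnorm(n2)
  s2 <- tibble::tibble(node_a = confound + rnorm(n2, 0, 0.05))
  sc2 <- tibble::tibble(score = confound + rnorm(n2, 0, 0.05))
  part <- behavior_correlation(s2, sc2, covariates = tibble::tibble(cv = confound))
  expect_lt(abs(part$r), 0.05)
  expect_equal(part$method, "partial")

  covs <- tibble::tibble(age = rnorm(n), edu = rnorm(n))
  sc <- tibble::tibble(s = rnorm(n))
  got <- behavior_correlation(strengths["node_b"], sc, covariates = covs)
  expect_equal(got$r, oracle_partial_cor(strengths$node_b, sc$s, covs),
               tolerance = 1e-10)

  expect_error(behavior_correlation(strengths,
                                    tibble::tibble(k = rep(1, n))), "constant")
})

test_that("hemispheric summary quantifies lateralisation", {
  rois <- tibble::tibble(roi_id = c("l1", "l2", "r1", "r2"),
                         hemisphere = c("L", "L", "R", "R"))
  sym <- matrix(0.5, 4, 4); diag(sym) <- 0
  colnames(sym) <- rownames(sym) <- rois$roi_id
  res <- hemispheric_strength_summary(sym, rois)
  expect_equal(res$laterality_index, 0)

  left <- matrix(0, 4, 4)
  left[1, 2] <- left[2, 1] <- 1
  colnames(left) <- rownames(left) <- rois$roi_id
  expect_equal(hemispheric_strength_summary(left, rois)$laterality_index, 1)

  set.seed(10)
  for (i in 1:5) {
    z <- abs(matrix(rnorm(16), 4, 4)); z <- z + t(z); diag(z) <- 0
    colnames(z) <- rownames(z) <- rois$roi_id
    li <- hemispheric_strength_summary(z, rois)$laterality_index
    expect_true(li >= -1 - 1e-9 && li <= 1 + 1e-9)
  }

  untagged <- tibble::tibble(roi_id = rois$roi_id,
                             hemisphere = rep("vermis", 4))
  expect_true(is.na(hemispheric_strength_summary(sym, untagged)$laterality_index))
})
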