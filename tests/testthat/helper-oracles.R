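# Independent reference implementations used to cross-check the package.
# These deliberately use naive algorithms (explicit DFT sums, stack-based
# flood fill, normal-equations least squares) so they share no code with
# the implementation paths they verify.

# O(N^2) discrete Fourier transform, band-limited mean single-sided amplitude
oracle_band_amplitude <- function(x, tr_s, band = c(0.01, 0.08)) {
  n <- length(x)
  freqs <- (0:(n %/% 2)) / (n * tr_s)
  bins <- which(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12)
  amps <- vapply(bins, function(b) {
    k <- b - 1
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    2 * sqrt(re^2 + im^2) / n
  }, numeric(1))
  mean(amps)
}

# partial F via explicit normal equations
oracle_partial_f <- function(y, x_full, x_reduced) {
  rss <- function(x) {
    beta <- solve(crossprod(x), crossprod(x, y))
    sum((y - x %*% beta)^2)
  }
  df1 <- ncol(x_full) - ncol(x_reduced)
  df2 <- length(y) - ncol(x_full)
  f <- ((rss(x_reduced) - rss(x_full)) / df1) / (rss(x_full) / df2)
  c(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# stack-based flood fill component labelling
oracle_flood_fill <- function(binary, connectivity = 18) {
  dims <- dim(binary)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  d <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[d == 1, , drop = FALSE],
                "18" = off[d <= 2, , drop = FALSE],
                "26" = off)
  labels <- array(0L, dims)
  current <- 0L
  for (v in which(binary)) {
    if (labels[v] != 0L) next
    current <- current + 1L
    stack <- list(arrayInd(v, dims)[1, ])
    labels[v] <- current
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(off))) {
        q <- p + off[o, ]
        if (any(q < 1) || any(q > dims)) next
        lin <- q[1] + (q[2] - 1) * dims[1] + (q[3] - 1) * dims[1] * dims[2]
        if (binary[lin] && labels[lin] == 0L) {
          labels[lin] <- current
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  labels
}

# do two labelings define the same partition of the TRUE voxels?
same_partition <- function(vox, labels_a, labels_b) {
  key_a <- split(vox, labels_a)
  key_b <- split(vox, labels_b)
  setequal(lapply(key_a, sort), lapply(key_b, sort))
}

# AlphaSim oracle at FWHM = 0: identical noise stream and thresholding, but
# brute-force flood-fill labelling and a direct scan for the extent
oracle_alphasim_fwhm0 <- function(mask, voxel_p, alpha, n_iter, connectivity,
                                  seed) {
  dims <- dim(mask)
  vin <- which(mask)
  set.seed(seed)
  max_sizes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    noise <- array(rnorm(prod(dims)), dims)
    vals <- noise[vin]
    thr <- quantile(vals, 1 - voxel_p)
    supra <- array(FALSE, dims)
    supra[vin[vals > thr]] <- TRUE
    lab <- oracle_flood_fill(supra, connectivity)
    max_sizes[i] <- if (max(lab) == 0) 0L else max(tabulate(lab[lab > 0]))
  }
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  list(extent = k, max_sizes = max_sizes)
}

# residualise y and x on covariates, then plain Pearson correlation
oracle_partial_cor <- function(x, y, covariates) {
  cv <- cbind(1, as.matrix(covariates))
  rx <- x - cv %*% solve(crossprod(cv), crossprod(cv, x))
  ry <- y - cv %*% solve(crossprod(cv), crossprod(cv, y))
  cor(rx, ry)[1, 1]
}

# two series with an exact given sample correlation
make_correlated_pair <- function(r, n = 50, seed = 1) {
  set.seed(seed)
  u <- rnorm(n); u <- (u - mean(u)) / sqrt(sum((u - mean(u))^2))
  v <- rnorm(n); v <- v - mean(v) - u * sum(u * (v - mean(v)))
  v <- v / sqrt(sum(v^2))
  cbind(x = u, y = r * u + sqrt(1 - r^2) * v)
}
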