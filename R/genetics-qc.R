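#' Minor allele frequency from genotype counts
#'
#' @param n_AA,n_Aa,n_aa Counts of the three genotype classes, where `A` is
#'   the first allele of the SNP's allele pair and `a` the second.
#' @return A list with `maf` (frequency of the rarer allele, in \[0, 0.5\])
#'   and `minor` (`"first"` or `"second"`, indicating which allele of the
#'   pair is the minor one; ties report `"second"`).
#' @export
#' @examples
#' compute_maf(30, 33, 10)  # maf = 53/146
compute_maf <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total == 0) abort("all genotype counts are zero")
  f_second <- (2 * n_aa + n_Aa) / (2 * total)
  if (f_second <= 0.5) {
    list(maf = f_second, minor = "second")
  } else {
    list(maf = 1 - f_second, minor = "first")
  }
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) of observed genotype
#' counts against the proportions q^2, 2pq, p^2 expected at the estimated
#' allele frequency. A monomorphic SNP carries no information about
#' equilibrium and returns p = 1 by convention.
#'
#' @inheritParams compute_maf
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: statistic 0, p 1
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) abort("genotype counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("all genotype counts are zero")
  f <- (2 * n_AA + n_Aa) / (2 * total)  # frequency of first allele
  if (f == 0 || f == 1) {
    return(tibble::tibble(statistic = 0, df = 1L, p_value = 1))
  }
  expected <- total * c(f^2, 2 * f * (1 - f), (1 - f)^2)
  stat <- sum((counts - expected)^2 / expected)
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Minor-allele dosage matrix from a genotype table
#'
#' Converts two-letter genotype strings (e.g. `"CT"`) into counts of the
#' minor allele, taken as the first character of the panel's allele pair.
#'
#' @param genotypes Tibble with `subject_id` and one column per rs id.
#' @param panel SNP panel tibble (see [snp_panel()]).
#' @return Integer matrix, subjects x SNPs, entries in `{0, 1, 2}`, with
#'   subject ids as row names.
#' @export
minor_allele_counts <- function(genotypes, panel) {
  snps <- intersect(panel$snp_id, setdiff(names(genotypes), "subject_id"))
  if (length(snps) == 0) abort("no panel SNPs found in genotype table")
  if (anyDuplicated(genotypes$subject_id)) abort("duplicated subject ids")
  counts <- vapply(snps, function(s) {
    alleles <- strsplit(panel$allele[panel$snp_id == s], "")[[1]]
    g <- genotypes[[s]]
    chars <- strsplit(g, "")
    bad <- !vapply(chars, function(x) all(x %in% alleles), logical(1))
    if (any(bad)) {
      abort(sprintf("genotype for %s contains alleles outside the panel pair", s))
    }
    vapply(chars, function(x) sum(x == alleles[1]), integer(1))
  }, integer(nrow(genotypes)))
  rownames(counts) <- genotypes$subject_id
  counts
}

#' Apply the SNP exclusion rules
#'
#' Drops SNPs with minor allele frequency below `maf_min`, then among the
#' survivors drops SNPs in complete linkage disequilibrium with an earlier
#' panel SNP (squared correlation of minor-allele dosage vectors equal to 1;
#' the first SNP in panel order is kept).
#'
#' @param genotypes Genotype tibble (`subject_id` + one column per rs id).
#' @param panel SNP panel tibble.
#' @param maf_min MAF exclusion threshold (default 0.05).
#' @return A tibble with one row per panel SNP: `snp_id`, `gene`, `maf`,
#'   `kept` and `reason` (`NA` for kept SNPs).
#' @export
filter_snps <- function(genotypes, panel, maf_min = 0.05) {
  if (nrow(genotypes) < 2) abort("need at least 2 subjects")
  dosage <- minor_allele_counts(genotypes, panel)
  panel <- panel[panel$snp_id %in% colnames(dosage), ]
  maf <- vapply(panel$snp_id, function(s) {
    x <- dosage[, s]
    compute_maf(sum(x == 2), sum(x == 1), sum(x == 0))$maf
  }, numeric(1))
  reason <- rep(NA_character_, nrow(panel))
  reason[maf < maf_min] <- sprintf("MAF<%s", format(maf_min))
  ok <- which(is.na(reason))
  for (i in seq_along(ok)) {
    if (!is.na(reason[ok[i]])) next
    for (j in seq_len(i - 1)) {
      if (!is.na(reason[ok[j]])) next
      r <- suppressWarnings(cor(dosage[, ok[i]], dosage[, ok[j]]))
      if (!is.na(r) && abs(abs(r) - 1) < 1e-12) {
        reason[ok[i]] <- sprintf("complete LD with %s", panel$snp_id[ok[j]])
        break
      }
    }
  }
  tibble::tibble(snp_id = panel$snp_id, gene = panel$gene,
                 maf = unname(maf), kept = is.na(reason), reason = reason)
}

#' Minor-allele-frequency cutoff for genetic-model selection
#'
#' The genotypic (2 df) model is only identifiable when the rare-homozygote
#' class is populated; the cutoff is the largest two-decimal frequency `q`
#' whose homozygote frequency `q^2` does not exceed `rare_homozygote_max`.
#'
#' @param rare_homozygote_max Maximum tolerated rare-homozygote frequency
#'   (default 0.10).
#' @return The cutoff frequency (0.31 at the default).
#' @export
maf_model_cutoff <- function(rare_homozygote_max = 0.10) {
  q <- seq(0, 0.5, by = 0.01)
  max(q[q^2 <= rare_homozygote_max])
}

#' Choose the genetic model for a SNP
#'
#' SNPs with MAF at or above the cutoff use a genotypic model (orthogonal
#' polynomial contrasts over the three genotype classes, 2 df); rarer SNPs
#' use a recessive-style model merging heterozygotes with rare homozygotes
#' into a single carrier class (1 df).
#'
#' @param maf Minor allele frequency in \[0, 0.5\] (vectorised).
#' @param cutoff Model-selection cutoff, default [maf_model_cutoff()].
#' @return A tibble with `maf`, `model` (`"genotypic"`/`"recessive"`) and
#'   `design_df` (2 or 1).
#' @export
#' @examples
#' select_genetic_model(c(0.45, 0.10, 0.31))
select_genetic_model <- function(maf, cutoff = maf_model_cutoff()) {
  if (any(maf < 0 | maf > 0.5)) abort("maf must lie in [0, 0.5]")
  genotypic <- maf >= cutoff
  tibble::tibble(maf = maf,
                 model = ifelse(genotypic, "genotypic", "recessive"),
                 design_df = ifelse(genotypic, 2L, 1L))
}

#' Design columns for a genotype dosage vector
#'
#' Genotypic model: two orthogonal polynomial contrast columns (linear,
#' quadratic) over the dosage levels 0/1/2, as given by `contr.poly(3)`.
#' Recessive model: a single 0/1 carrier indicator (heterozygote or rare
#' homozygote = 1). If the genotypic model is requested but fewer than three
#' genotype classes are observed, a single linear column is returned with a
#' warning.
#'
#' @param minor_counts Integer vector of minor-allele dosages in `{0, 1, 2}`.
#' @param model `"genotypic"` or `"recessive"`.
#' @return Numeric matrix with 1 or 2 named columns.
#' @export
code_genotypes <- function(minor_counts, model = c("genotypic", "recessive")) {
  model <- match.arg(model)
  if (!all(minor_counts %in% 0:2)) abort("minor_counts must be in {0, 1, 2}")
  n_classes <- length(unique(minor_counts))
  if (n_classes < 2) abort("all genotypes identical; no design column possible")
  if (model == "recessive") {
    out <- cbind(carrier = as.numeric(minor_counts >= 1))
  } else if (n_classes < 3) {
    warn("fewer than 3 genotype classes observed; falling back to a 1-df linear code")
    out <- cbind(linear = minor_counts - 1)
  } else {
    contrasts <- contr.poly(3)
    out <- cbind(linear = contrasts[minor_counts + 1, 1],
                 quadratic = contrasts[minor_counts + 1, 2])
  }
  out
}

#' Two-by-two chi-square test, plain and small-sample adjusted
#'
#' Computes the Pearson chi-square without continuity correction and the
#' `(N-1)/N`-scaled (Mantel-Haenszel style) variant often reported by
#' clinical statistics packages.
#'
#' @param tab 2x2 matrix of counts (groups x categories).
#' @return A tibble with rows for the `"pearson"` and `"adjusted"` variants:
#'   `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_2x2(matrix(c(27, 17, 16, 13), nrow = 2))
chisq_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  num <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  pearson <- n * num / den
  adjusted <- pearson * (n - 1) / n
  tibble::tibble(test = c("pearson", "adjusted"),
                 statistic = c(pearson, adjusted), df = 1L,
                 p_value = pchisq(c(pearson, adjusted), 1, lower.tail = FALSE))
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return A tibble with `statistic`, `df`, `p_value` (two-sided).
#' @export
#' @examples
#' t_test_from_summary(13.58, 3.10, 43, 14.98, 2.67, 30)
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- if (se == 0) 0 else (mean1 - mean2) / se
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * pt(-abs(stat), df))
}

#' Group comparison table for demographic and neuropsychological variables
#'
#' For each continuous variable both a pooled-variance two-sample t-test and
#' a Mann-Whitney U test are reported; the gender split is compared with a
#' 2x2 chi-square in both the plain Pearson and the `(N-1)/N`-adjusted
#' variants.
#'
#' @param phenotypes Phenotype tibble containing a two-level `group` column,
#'   a `gender` column and numeric variables.
#' @param variables Character vector of numeric column names to compare;
#'   defaults to all numeric columns except identifiers.
#' @return A tidy tibble: `variable`, `test`, `statistic`, `df`, `p_value`,
#'   plus per-group means for continuous variables.
#' @export
demographic_tests <- function(phenotypes, variables = NULL) {
  groups <- unique(phenotypes$group)
  if (length(groups) != 2) abort("phenotypes must contain exactly 2 groups")
  g1 <- phenotypes$group == groups[1]
  if (sum(g1) < 2 || sum(!g1) < 2) abort("each group needs at least 2 subjects")
  variables <- variables %||%
    setdiff(names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))],
            c("subject_id"))
  rows <- purrr::map_dfr(variables, function(v) {
    x <- phenotypes[[v]][g1]
    y <- phenotypes[[v]][!g1]
    tt <- t_test_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    tibble::tibble(variable = v,
                   test = c("t_pooled", "mann_whitney"),
                   statistic = c(tt$statistic, unname(mw$statistic)),
                   df = c(tt$df, NA_real_),
                   p_value = c(tt$p_value, mw$p.value),
                   mean_1 = mean(x), mean_2 = mean(y))
  })
  if ("gender" %in% names(phenotypes)) {
    tab <- table(phenotypes$group, phenotypes$gender)
    if (all(dim(tab) == c(2, 2))) {
      cs <- chisq_2x2(tab)
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        variable = "gender",
        test = paste0("chisq_", cs$test),
        statistic = cs$statistic, df = as.numeric(cs$df),
        p_value = cs$p_value, mean_1 = NA_real_, mean_2 = NA_real_))
    }
  }
  out <- dplyr::as_tibble(rows)
  attr(out, "groups") <- as.character(groups)
  class(out) <- c("alffnet_demographics", class(out))
  out
}
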