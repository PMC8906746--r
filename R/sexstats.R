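#' Bonferroni-corrected genome-wide significance threshold
#'
#' -log10(alpha / n_tests), with n_tests the number of independent tests
#' (e.g. LD haploblocks).
#'
#' @param n_tests number of independent tests (>= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return list with \code{threshold} (full precision) and \code{rounded}
#'   (2 decimals).
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  thr <- -log10(alpha / n_tests)
  list(threshold = thr, rounded = round(thr, 2))
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the point-probability two-sided rule (the
#' sum of all tables with fixed margins whose probability does not exceed
#' the observed table's). Degenerate margins give P = 1 by convention,
#' flagged.
#'
#' @param table 2x2 integer matrix of counts.
#' @return list with \code{p}, \code{odds_ratio} (conditional MLE) and
#'   \code{degenerate} flag.
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, odds_ratio = NA_real_, degenerate = TRUE))
  ft <- stats::fisher.test(table)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), degenerate = FALSE)
}

#' Exact binomial test
#'
#' Two-sided P by the point-probability method (sum of P(X = j) over all j
#' with P(X = j) <= P(X = k)), or one-sided tail probabilities.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials.
#' @param p0 null success probability (default 0.5).
#' @param sided "two", "greater" or "less".
#' @return the exact P value.
#' @export
binomial_test <- function(k, n, p0 = 0.5, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  stopifnot(k >= 0, k <= n)
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  stats::binom.test(k, n, p0, alternative = alt)$p.value
}

#' Sex-genotype cohort
#'
#' Counts of gonadal sex by XX/XY call at the sex locus for one cohort.
#'
#' @param xx_female,xx_male,xy_female,xy_male integer counts.
#' @return object of class \code{sex_cohort}.
#' @export
sex_cohort <- function(xx_female, xx_male, xy_female, xy_male) {
  counts <- c(xx_female = xx_female, xx_male = xx_male,
              xy_female = xy_female, xy_male = xy_male)
  stopifnot(all(counts >= 0))
  structure(as.list(counts), class = "sex_cohort")
}

#' Tabulate a cohort from per-sample calls
#' @param genotype character vector of "XX"/"XY" calls.
#' @param sex character vector of "F"/"M".
#' @return a \code{\link{sex_cohort}}.
#' @export
sex_cohort_from_calls <- function(genotype, sex) {
  sex_cohort(sum(genotype == "XX" & sex == "F"),
             sum(genotype == "XX" & sex == "M"),
             sum(genotype == "XY" & sex == "F"),
             sum(genotype == "XY" & sex == "M"))
}

#' Penetrance report across sex-genotype cohorts
#'
#' Per cohort: the XX -> female and XY -> male rates with their exact
#' binomial P values against 0.5; across the first two named cohorts, a
#' Fisher comparison of female/male counts among XX individuals (testing a
#' cohort difference in XX penetrance).
#'
#' @param cohorts named list of \code{\link{sex_cohort}} objects.
#' @return list with \code{rates} (data.frame) and \code{xx_comparison}
#'   (Fisher result between the first two cohorts, or NULL).
#' @export
penetrance_report <- function(cohorts) {
  stopifnot(length(cohorts) >= 1, !is.null(names(cohorts)))
  rates <- do.call(rbind, lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    nxx <- co$xx_female + co$xx_male
    nxy <- co$xy_female + co$xy_male
    data.frame(
      cohort = nm,
      n_xx = nxx, xx_female = co$xx_female,
      xx_female_rate = if (nxx > 0) co$xx_female / nxx else NA_real_,
      xx_p = if (nxx > 0) binomial_test(co$xx_female, nxx) else NA_real_,
      n_xy = nxy, xy_male = co$xy_male,
      xy_male_rate = if (nxy > 0) co$xy_male / nxy else NA_real_,
      xy_p = if (nxy > 0) binomial_test(co$xy_male, nxy) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  cmp <- NULL
  if (length(cohorts) >= 2) {
    a <- cohorts[[1]]; b <- cohorts[[2]]
    tab <- rbind(c(a$xx_female, a$xx_male), c(b$xx_female, b$xx_male))
    cmp <- c(fisher_2x2(tab),
             list(cohorts = names(cohorts)[1:2], table = tab))
  }
  list(rates = rates, xx_comparison = cmp)
}

#' Allele-specific expression test against a balanced null
#'
#' Per observation (sample/timepoint), the fraction of reads from the Y
#' allele and a two-sided exact binomial P against 0.5; a pooled row sums
#' counts across observations (flagged \code{pooled}).
#'
#' @param y Y-allele read counts.
#' @param total total read counts (> 0).
#' @param label optional observation labels.
#' @return data.frame with label, y, total, fraction, p, pooled.
#' @export
ase_test <- function(y, total, label = NULL) {
  stopifnot(length(y) == length(total), all(total > 0), all(y >= 0),
            all(y <= total))
  if (is.null(label)) label <- paste0("obs", seq_along(y))
  per <- data.frame(label = label, y = y, total = total,
                    fraction = y / total,
                    p = mapply(binomial_test, y, total),
                    pooled = FALSE, stringsAsFactors = FALSE)
  if (length(y) > 1) {
    ys <- sum(y); ts <- sum(total)
    per <- rbind(per, data.frame(label = "pooled", y = ys, total = ts,
                                 fraction = ys / ts,
                                 p = binomial_test(ys, ts), pooled = TRUE,
                                 stringsAsFactors = FALSE))
  }
  per
}

#' Within-class nucleotide diversity of a locus and Y:X ratio
#'
#' Mean pairwise per-bp difference among the haplotypes of each class (X
#' and Y) over a locus of known length, and their ratio.
#'
#' @param haplotypes 0/1 matrix, haplotypes in rows, locus sites in columns.
#' @param classes character vector "X"/"Y" per haplotype row.
#' @param locus_length locus length in bp (variant plus invariant sites).
#' @return list with per-class \code{pi} (named vector, NA and flagged when
#'   a class has < 2 haplotypes) and \code{ratio} (Y / X).
#' @export
class_diversity <- function(haplotypes, classes, locus_length) {
  stopifnot(nrow(haplotypes) == length(classes), locus_length > 0)
  pi_of <- function(rows) {
    if (length(rows) < 2) return(NA_real_)
    d <- manhattan(haplotypes[rows, , drop = FALSE])
    mean(d[upper.tri(d)]) / locus_length
  }
  pis <- c(X = pi_of(which(classes == "X")), Y = pi_of(which(classes == "Y")))
  list(pi = pis, ratio = unname(pis["Y"] / pis["X"]),
       flagged = names(pis)[is.na(pis)])
}

#' Per-site allelic association track
#'
#' A plain per-site allelic exact test of a binary phenotype: allele counts
#' by phenotype in a 2x2 Fisher test, after the association preset filters
#' (MAF, missingness, greedy LD pruning at r^2 > 0.8 within 999 kb). This
#' is a deliberately simple stand-in for a kinship-corrected mixed-model
#' association, intended for synthetic panels where relatedness is
#' controlled.
#'
#' @param genotypes integer matrix samples x sites (0/1/2, NA = missing).
#' @param positions site positions (same order as columns).
#' @param chrom chromosome label per site (scalar or vector).
#' @param phenotype binary vector (two levels) per sample.
#' @param config a \code{\link{filter_config}} providing the association
#'   preset (assoc_min_maf, assoc_r2).
#' @param prune_window bp window for LD pruning (default 999 kb).
#' @return data.frame: chrom, pos, p, log10p (empty when the phenotype is
#'   constant).
#' @export
site_association <- function(genotypes, positions, chrom = "chr1", phenotype,
                             config = filter_config(), prune_window = 999000) {
  stopifnot(nrow(genotypes) == length(phenotype))
  lev <- unique(stats::na.omit(phenotype))
  empty <- data.frame(chrom = character(), pos = numeric(), p = numeric(),
                      log10p = numeric(), stringsAsFactors = FALSE)
  if (length(lev) < 2) return(empty)
  if (length(lev) > 2) stop("phenotype must be binary")
  chrom <- rep_len(chrom, ncol(genotypes))
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  miss <- colMeans(is.na(genotypes))
  keep <- which(pmin(p, 1 - p) >= config$assoc_min_maf &
                  miss < config$max_missing)
  # greedy left-to-right LD pruning: drop the later SNP of any close pair
  # with r^2 above the preset
  pruned <- integer(0)
  for (ch in unique(chrom)) {
    idx <- keep[chrom[keep] == ch]
    idx <- idx[order(positions[idx])]
    kept <- integer(0)
    for (j in idx) {
      near <- kept[positions[j] - positions[kept] <= prune_window]
      drop <- FALSE
      for (i in rev(near)) {
        r <- suppressWarnings(stats::cor(genotypes[, i], genotypes[, j],
                                         use = "complete.obs"))
        if (!is.na(r) && r^2 > config$assoc_r2) { drop <- TRUE; break }
      }
      if (!drop) kept <- c(kept, j)
    }
    pruned <- c(pruned, kept)
  }
  if (!length(pruned)) return(empty)
  is_a <- phenotype == lev[1]
  pvals <- vapply(pruned, function(j) {
    g <- genotypes[, j]
    ok <- !is.na(g) & !is.na(phenotype)
    a_alt <- sum(g[ok & is_a]); a_ref <- 2 * sum(ok & is_a) - a_alt
    b_alt <- sum(g[ok & !is_a]); b_ref <- 2 * sum(ok & !is_a) - b_alt
    fisher_2x2(rbind(c(a_alt, a_ref), c(b_alt, b_ref)))$p
  }, 0)
  out <- data.frame(chrom = chrom[pruned], pos = positions[pruned],
                    p = pvals, log10p = -log10(pvals),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
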