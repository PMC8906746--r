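#' Quality-annotated genotype table
#'
#' Per-site and per-genotype quality annotations for biallelic variants:
#' site-level chromosome, position, ref/alt and mapping quality (MQ), and
#' per sample-site called genotype GT (0 = hom-ref, 1 = het, 2 = hom-alt,
#' NA = missing), genotype quality GQ, depth DP and alt-supporting read
#' count AD.
#'
#' @param sites data.frame with columns chrom, pos, ref, alt, MQ (positions
#'   sorted within chromosome).
#' @param GT,GQ,DP,AD matrices samples x sites.
#' @param samples character vector of sample ids.
#' @param params optional list of generative parameters (logged by
#'   \code{\link{observe_trio}}).
#' @return an object of class \code{annotated_genotypes}.
#' @export
annotated_genotypes <- function(sites, GT, GQ, DP, AD, samples, params = NULL) {
  ns <- nrow(sites)
  for (m in list(GT, GQ, DP, AD))
    stopifnot(is.matrix(m), ncol(m) == ns, nrow(m) == length(samples))
  if (any(AD > DP, na.rm = TRUE)) stop("malformed table: AD > DP")
  o <- order(sites$chrom, sites$pos)
  if (is.unsorted(o)) {
    sites <- sites[o, , drop = FALSE]
    GT <- GT[, o, drop = FALSE]; GQ <- GQ[, o, drop = FALSE]
    DP <- DP[, o, drop = FALSE]; AD <- AD[, o, drop = FALSE]
  }
  rownames(GT) <- rownames(GQ) <- rownames(DP) <- rownames(AD) <- samples
  structure(list(sites = sites, GT = GT, GQ = GQ, DP = DP, AD = AD,
                 samples = samples, params = params),
            class = "annotated_genotypes")
}

#' @export
print.annotated_genotypes <- function(x, ...) {
  cat("<annotated_genotypes>", length(x$samples), "samples x",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Genotype and site filter configuration
#'
#' Defaults are the study thresholds: site MQ >= 50; genotype GQ >= 30,
#' DP >= 4, at least 2 reads supporting each called allele; heterozygote
#' variant-allele-fraction within [0.25, 0.75]; exclusion of variants within
#' 3 bp of each other; site missingness <= 0.2. The association preset adds
#' MAF >= 0.05 and greedy LD pruning at r^2 > 0.8.
#'
#' @param min_mq,min_gq,min_dp,min_ad,adjacency_bp,vaf_bounds,max_missing
#'   thresholds as described.
#' @param assoc_min_maf,assoc_r2 association-pruning preset values.
#' @return an object of class \code{filter_config}.
#' @export
filter_config <- function(min_mq = 50, min_gq = 30, min_dp = 4, min_ad = 2,
                          adjacency_bp = 3, vaf_bounds = c(0.25, 0.75),
                          max_missing = 0.2, assoc_min_maf = 0.05,
                          assoc_r2 = 0.8) {
  stopifnot(all(is.finite(c(min_mq, min_gq, min_dp, min_ad, adjacency_bp,
                            vaf_bounds, max_missing))),
            vaf_bounds[1] >= 0, vaf_bounds[2] <= 1)
  structure(list(min_mq = min_mq, min_gq = min_gq, min_dp = min_dp,
                 min_ad = min_ad, adjacency_bp = adjacency_bp,
                 vaf_bounds = vaf_bounds, max_missing = max_missing,
                 assoc_min_maf = assoc_min_maf, assoc_r2 = assoc_r2),
            class = "filter_config")
}

#' Apply genotype- and site-level quality filters
#'
#' Genotype rules run first: a genotype is set missing when GQ < min_gq,
#' DP < min_dp, the called allele(s) have fewer than min_ad supporting reads
#' (for heterozygotes both alleles must reach min_ad), or it is a
#' heterozygote with VAF outside the bounds. Site rules run on the nulled
#' table: a site is removed when MQ < min_mq, when its missing fraction
#' exceeds max_missing, or when another surviving variant lies within
#' adjacency_bp of it (both members of such a pair are removed).
#'
#' @param table an \code{\link{annotated_genotypes}}.
#' @param config a \code{\link{filter_config}}.
#' @return list with \code{table} (filtered) and \code{removed}, a named
#'   vector of per-rule removal counts (genotype rules count genotypes,
#'   site rules count sites).
#' @export
apply_filters <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "annotated_genotypes"))
  gt <- table$GT
  present <- !is.na(gt)
  vaf <- ifelse(table$DP > 0, table$AD / table$DP, NA_real_)
  ref_reads <- table$DP - table$AD

  null_gq <- present & table$GQ < config$min_gq
  null_dp <- present & table$DP < config$min_dp
  supp <- ifelse(gt == 1L, pmin(table$AD, ref_reads),
                 ifelse(gt == 2L, table$AD, ref_reads))
  null_ad <- present & !is.na(supp) & supp < config$min_ad
  null_vaf <- present & gt == 1L &
    (vaf < config$vaf_bounds[1] | vaf > config$vaf_bounds[2])
  null_vaf[is.na(null_vaf)] <- FALSE
  gt[null_gq | null_dp | null_ad | null_vaf] <- NA_integer_

  miss_frac <- colMeans(is.na(gt))
  drop_mq <- table$sites$MQ < config$min_mq
  drop_miss <- miss_frac > config$max_missing
  surviving <- !(drop_mq | drop_miss)
  drop_adj <- rep(FALSE, nrow(table$sites))
  for (ch in unique(table$sites$chrom)) {
    idx <- which(surviving & table$sites$chrom == ch)
    if (length(idx) > 1) {
      pos <- table$sites$pos[idx]
      close <- diff(pos) <= config$adjacency_bp
      hit <- unique(c(idx[which(close)], idx[which(close) + 1L]))
      drop_adj[hit] <- TRUE
    }
  }
  keep <- surviving & !drop_adj
  removed <- c(genotypes_gq = sum(null_gq), genotypes_dp = sum(null_dp),
               genotypes_ad = sum(null_ad), genotypes_vaf = sum(null_vaf),
               sites_mq = sum(drop_mq), sites_missing = sum(drop_miss),
               sites_adjacent = sum(drop_adj), sites_retained = sum(keep))
  out <- annotated_genotypes(table$sites[keep, , drop = FALSE],
                             gt[, keep, drop = FALSE],
                             table$GQ[, keep, drop = FALSE],
                             table$DP[, keep, drop = FALSE],
                             table$AD[, keep, drop = FALSE],
                             table$samples, table$params)
  list(table = out, removed = removed)
}

#' Count Mendelian errors in a trio
#'
#' A site is flagged when the offspring genotype is impossible under
#' Mendelian transmission from the two parental genotypes. Sites at which
#' any trio member is missing are skipped.
#'
#' @param table an \code{\link{annotated_genotypes}} containing the trio.
#' @param trio named character vector with elements father, mother,
#'   offspring giving the sample ids.
#' @return list with \code{n_errors}, \code{n_tested} and logical
#'   \code{flags} per site (NA where skipped).
#' @export
mendelian_errors <- function(table,
                             trio = c(father = "father", mother = "mother",
                                      offspring = "offspring")) {
  stopifnot(all(c("father", "mother", "offspring") %in% names(trio)),
            all(trio %in% table$samples))
  fa <- table$GT[trio[["father"]], ]
  mo <- table$GT[trio[["mother"]], ]
  of <- table$GT[trio[["offspring"]], ]
  ok <- !(is.na(fa) | is.na(mo) | is.na(of))
  # offspring needs one transmissible allele from each parent
  can0 <- function(g) g <= 1L
  can1 <- function(g) g >= 1L
  possible <- (of == 0L & can0(fa) & can0(mo)) |
    (of == 2L & can1(fa) & can1(mo)) |
    (of == 1L & ((can0(fa) & can1(mo)) | (can1(fa) & can0(mo))))
  flags <- ifelse(ok, !possible, NA)
  list(n_errors = sum(flags, na.rm = TRUE), n_tested = sum(ok), flags = flags)
}

#' Filter ROC over a threshold grid
#'
#' For each grid row, applies the corresponding filter configuration and
#' counts retained variants and trio Mendelian errors, tracing the
#' retained-variants vs error-count trade-off used to choose thresholds.
#'
#' @param table an \code{\link{annotated_genotypes}} with the trio samples.
#' @param trio named character vector (father/mother/offspring sample ids).
#' @param grid data.frame with columns among min_gq, min_dp, min_mq, min_ad;
#'   unlisted rules stay at the base config.
#' @param base a \code{\link{filter_config}} providing the fixed rules.
#' @return data.frame: one row per grid config with retained site count and
#'   Mendelian error count, sorted by retained count.
#' @export
filter_roc <- function(table, trio, grid, base = filter_config()) {
  if (is.null(grid) || !nrow(grid)) stop("grid non-empty required")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (f in intersect(names(grid), c("min_gq", "min_dp", "min_mq", "min_ad")))
      cfg[[f]] <- grid[[f]][i]
    res <- apply_filters(table, cfg)
    me <- mendelian_errors(res$table, trio)
    cbind(grid[i, , drop = FALSE],
          retained = unname(res$removed["sites_retained"]),
          mendelian_errors = me$n_errors)
  })
  out <- do.call(rbind, rows)
  out[order(out$retained), , drop = FALSE]
}

#' Coverage window grid
#'
#' 1000-bp windows advancing by 500 bp; the last window ends at the
#' chromosome end (a 3000-bp chromosome yields starts 0, 500, ..., 2000).
#'
#' @param chrom_length chromosome length in bp.
#' @return data.frame with 0-based half-open \code{start}, \code{end}.
#' @export
coverage_windows <- function(chrom_length) {
  starts <- seq(0, max(0, chrom_length - 1000), by = 500)
  data.frame(start = starts, end = pmin(starts + 1000, chrom_length))
}

#' Coverage-based region mask
#'
#' Flags windows with aberrant sequencing depth. Read counts per window are
#' log2-normalized within each sample by that sample's genome-wide median
#' count; a window is masked when any sample's normalized value deviates by
#' more than \code{k} standard deviations from that sample's median
#' normalized value (reason \code{within_sample}), or when the cross-sample
#' variance of normalized values exceeds the median window variance by more
#' than \code{k} standard deviations of the variance distribution (reason
#' \code{cross_sample_variance}). Zero-count windows are masked by the
#' within-sample rule and excluded from the spread estimates.
#'
#' @param counts matrix windows x samples of read counts (>= 0) on the
#'   1000/500 grid.
#' @param windows data.frame with chrom, start, end per row of counts
#'   (defaults to a single-chromosome grid).
#' @param k deviation threshold in SD units (default 2.5).
#' @return a region mask: data.frame(chrom, start, end, reason) of masked
#'   windows, 0-based half-open, with class \code{region_mask}.
#' @export
coverage_region_mask <- function(counts, windows = NULL, k = 2.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("read counts must be >= 0")
  if (is.null(windows))
    windows <- cbind(chrom = "chr1",
                     coverage_windows(500 * (nrow(counts) - 1) + 1000))
  med <- apply(counts, 2, stats::median)
  if (any(med == 0)) stop("all-zero (or majority-zero) sample: median undefined")
  lognorm <- log2(sweep(counts, 2, med, "/"))
  within <- matrix(FALSE, nrow(counts), ncol(counts))
  for (j in seq_len(ncol(counts))) {
    v <- lognorm[, j]
    finite <- is.finite(v)
    center <- stats::median(v[finite])
    spread <- stats::sd(v[finite])
    within[, j] <- !finite | (spread > 0 & abs(v - center) > k * spread)
  }
  within_any <- rowSums(within) > 0
  vr <- apply(lognorm, 1, function(x) stats::var(x[is.finite(x)]))
  vr[is.na(vr)] <- Inf
  fin <- is.finite(vr)
  var_rule <- fin & stats::sd(vr[fin]) > 0 &
    (vr > stats::median(vr[fin]) + k * stats::sd(vr[fin]))
  var_rule <- var_rule | !fin
  masked <- within_any | var_rule
  reason <- ifelse(within_any & var_rule, "within_sample;cross_sample_variance",
                   ifelse(within_any, "within_sample", "cross_sample_variance"))
  out <- data.frame(chrom = windows$chrom[masked],
                    start = windows$start[masked],
                    end = windows$end[masked],
                    reason = reason[masked], stringsAsFactors = FALSE)
  class(out) <- c("region_mask", "data.frame")
  out
}
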