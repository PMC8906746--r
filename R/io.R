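#' Write a haplotype panel as a phased VCF
#'
#' Emits biallelic sites with phased GT ("0|1"), FORMAT GT:GQ:DP:AD and an
#' INFO MQ field. Panels carry true genotypes without read-level noise, so
#' the writer fills the quality fields with nominal generator values
#' (GQ = 99, DP = 30, AD = 15 per carried alt allele, MQ = 60); tables from
#' \code{\link{observe_trio}} carry their own simulated values and should
#' be written with \code{\link{write_genotypes_vcf}}.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_panel_vcf <- function(panel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(panel$chrom_lengths),
                       as.integer(panel$chrom_lengths)),
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")), con)
  for (chrom in names(panel$chromosomes)) {
    ch <- panel$chromosomes[[chrom]]
    if (!length(ch$positions)) next
    odd <- seq(1L, nrow(ch$haplotypes), 2L)
    h1 <- ch$haplotypes[odd, , drop = FALSE]
    h2 <- ch$haplotypes[odd + 1L, , drop = FALSE]
    alt <- h1 + h2
    gt <- matrix(sprintf("%d|%d:99:30:%d,%d", h1, h2, 30L - 15L * alt,
                         15L * alt), nrow = nrow(h1))
    lines <- vapply(seq_along(ch$positions), function(j)
      paste(c(chrom, ch$positions[j], ".", "A", "T", ".", "PASS", "MQ=60",
              "GT:GQ:DP:AD", gt[, j]), collapse = "\t"), "")
    writeLines(lines, con)
  }
  invisible(file)
}

#' Write an annotated genotype table as a VCF
#'
#' Unphased GT with the simulated GQ/DP/AD values and per-site INFO MQ.
#'
#' @param table an \code{\link{annotated_genotypes}}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_genotypes_vcf <- function(table, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$samples), collapse = "\t")), con)
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(table$sites))) {
    g <- table$GT[, j]
    cell <- sprintf("%s:%d:%d:%d,%d",
                    ifelse(is.na(g), "./.", gt_str[as.character(g)]),
                    table$GQ[, j], table$DP[, j],
                    table$DP[, j] - table$AD[, j], table$AD[, j])
    writeLines(paste(c(table$sites$chrom[j], table$sites$pos[j], ".",
                       table$sites$ref[j], table$sites$alt[j], ".", "PASS",
                       sprintf("MQ=%g", table$sites$MQ[j]),
                       "GT:GQ:DP:AD", cell), collapse = "\t"), con)
  }
  invisible(file)
}

#' Write sample metadata TSV
#' @param panel a \code{\link{haplotype_panel}}.
#' @param file output path.
#' @param extra optional data.frame of extra per-sample columns.
#' @return the file path, invisibly.
#' @export
write_sample_metadata <- function(panel, file, extra = NULL) {
  df <- data.frame(sample = panel$samples,
                   population = unname(panel$populations),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write intervals as BED (0-based half-open)
#'
#' Works for tract sets (columns chrom/start/end, 1-based inclusive input
#' coordinates) and region masks (already 0-based half-open).
#'
#' @param x data.frame with chrom, start, end and optional extra columns.
#' @param file output path.
#' @param one_based TRUE when the input start is 1-based inclusive.
#' @return the file path, invisibly.
#' @export
write_bed <- function(x, file, one_based = inherits(x, "tract_set")) {
  start <- if (one_based) x$start - 1 else x$start
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  df <- cbind(data.frame(chrom = x$chrom, start = as.integer(start),
                         end = as.integer(x$end)),
              x[, extra, drop = FALSE])
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write an SFS as TSV (class, count)
#' @param x an \code{\link{sfs}}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_sfs_tsv <- function(x, file) {
  utils::write.table(data.frame(class = seq_len(x$n - 1), count = x$counts),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a bottleneck fit as JSON (with seeds and all replicate optima)
#' @param fit a \code{bottleneck_fit}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  jsonlite::write_json(list(
    best = as.list(fit$best), loglik = fit$loglik,
    null = fit$null, lr = fit$lr, likelihood = fit$likelihood,
    seed = fit$seed, reps = fit$reps, replicates = fit$replicates),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires the vcfR package; genotypes must be phased ("|") and biallelic.
#' Chromosome lengths are taken from the contig header lines.
#'
#' @param file VCF path.
#' @param populations optional named vector sample -> population (default
#'   "unknown").
#' @return a \code{\link{haplotype_panel}} (ancestral state not known).
#' @export
read_panel_vcf <- function(file, populations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_panel_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("|", gt, fixed = TRUE), na.rm = TRUE))
    stop("genotypes must be phased")
  samples <- colnames(gt)
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  meta <- v@meta
  ctg <- regmatches(meta, regexec("##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  ctg <- Filter(length, ctg)
  lens <- stats::setNames(as.numeric(vapply(ctg, `[`, "", 3)),
                          vapply(ctg, `[`, "", 2))
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  chroms <- lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    hap <- matrix(0L, 2L * length(samples), length(idx))
    hap[seq(1, nrow(hap), 2), ] <- t(h1[idx, , drop = FALSE])
    hap[seq(2, nrow(hap), 2), ] <- t(h2[idx, , drop = FALSE])
    list(positions = as.integer(pos[idx]), haplotypes = hap)
  })
  names(chroms) <- unique(chrom)
  if (!length(lens))
    lens <- vapply(chroms, function(c) max(c$positions) + 1, 0)
  pops <- if (is.null(populations)) rep("unknown", length(samples)) else
    unname(populations[samples])
  haplotype_panel(samples, pops, chroms, lens, ancestral_known = FALSE)
}
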