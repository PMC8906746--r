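#' Phased haplotype panel
#'
#' The common currency of all population-genetic stages: a set of diploid
#' samples with population labels and, per chromosome, a sorted vector of
#' 1-based site positions plus a 0/1 haplotype matrix with two rows per
#' sample (rows \code{<sample>_1} and \code{<sample>_2}). Allele 0 is the
#' ancestral state for every site (panels built by \code{\link{simulate_panel}}
#' record the true ancestral allele).
#'
#' @param samples character vector of sample identifiers.
#' @param populations character vector, population label per sample.
#' @param chromosomes named list; each element is a list with fields
#'   \code{positions} (strictly increasing integer vector) and
#'   \code{haplotypes} (integer matrix, \code{2 * length(samples)} rows by
#'   \code{length(positions)} columns, values in \{0, 1\}).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param ancestral_known logical; TRUE when allele 0 is the true ancestral
#'   state at every site.
#' @param seed the seed the panel was generated with, or NA.
#'
#' @return An object of class \code{haplotype_panel}.
#' @export
haplotype_panel <- function(samples, populations, chromosomes, chrom_lengths,
                            ancestral_known = TRUE, seed = NA_integer_) {
  stopifnot(length(samples) == length(populations), length(samples) >= 1)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  nhap <- 2L * length(samples)
  hap_ids <- as.vector(t(outer(samples, 1:2, paste, sep = "_")))
  for (chrom in names(chromosomes)) {
    ch <- chromosomes[[chrom]]
    pos <- ch$positions
    hap <- ch$haplotypes
    if (length(pos) != ncol(hap))
      stop("positions/haplotype dimension mismatch on ", chrom)
    if (nrow(hap) != nhap)
      stop("haplotype matrix must have 2 rows per sample on ", chrom)
    if (length(pos) > 1 && any(diff(pos) <= 0))
      stop("positions not strictly increasing on ", chrom)
    if (length(hap) && !all(hap %in% c(0L, 1L)))
      stop("alleles must be 0/1 on ", chrom)
    rownames(chromosomes[[chrom]]$haplotypes) <- hap_ids
  }
  if (!all(names(chromosomes) %in% names(chrom_lengths)))
    stop("every chromosome needs a length")
  structure(list(
    samples = samples,
    populations = stats::setNames(populations, samples),
    chromosomes = chromosomes,
    chrom_lengths = chrom_lengths[names(chromosomes)],
    ancestral_known = isTRUE(ancestral_known),
    seed = seed
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel>", length(x$samples), "diploid samples,",
      length(x$chromosomes), "chromosomes,",
      sum(vapply(x$chromosomes, function(c) length(c$positions), 0L)),
      "segregating sites\n")
  cat("  populations:", paste(sprintf("%s (%d)", names(table(x$populations)),
                                      table(x$populations)), collapse = ", "), "\n")
  invisible(x)
}

#' Haplotype identifiers of a panel
#' @param panel a \code{haplotype_panel}.
#' @return character vector, two entries per sample.
#' @export
hap_ids <- function(panel) {
  as.vector(t(outer(panel$samples, 1:2, paste, sep = "_")))
}

#' Haplotype row indices for a set of samples or populations
#'
#' @param panel a \code{haplotype_panel}.
#' @param samples sample ids, or NULL.
#' @param populations population labels, or NULL (one of the two must be given).
#' @return integer vector of row indices into the haplotype matrices.
#' @export
hap_rows <- function(panel, samples = NULL, populations = NULL) {
  if (is.null(samples)) {
    if (is.null(populations)) stop("give samples or populations")
    samples <- panel$samples[panel$populations %in% populations]
  }
  bad <- setdiff(samples, panel$samples)
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  idx <- match(samples, panel$samples)
  sort(as.vector(rbind(2L * idx - 1L, 2L * idx)))
}

#' Diploid genotype matrix of a panel
#'
#' @param panel a \code{haplotype_panel}.
#' @param chrom chromosome name, or NULL for all chromosomes column-bound in
#'   panel order.
#' @return integer matrix (samples x sites) with values 0/1/2 counting derived
#'   alleles.
#' @export
genotype_matrix <- function(panel, chrom = NULL) {
  chroms <- if (is.null(chrom)) names(panel$chromosomes) else chrom
  mats <- lapply(chroms, function(ch) {
    hap <- panel$chromosomes[[ch]]$haplotypes
    odd <- seq(1L, nrow(hap), 2L)
    hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE]
  })
  out <- do.call(cbind, mats)
  rownames(out) <- panel$samples
  out
}

#' Derived allele frequencies for a haplotype subset
#'
#' @param panel a \code{haplotype_panel}.
#' @param rows haplotype row indices (see \code{\link{hap_rows}}).
#' @param chrom chromosome name.
#' @return numeric vector of derived-allele frequencies per site.
#' @export
derived_freq <- function(panel, rows, chrom) {
  hap <- panel$chromosomes[[chrom]]$haplotypes
  colMeans(hap[rows, , drop = FALSE])
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
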