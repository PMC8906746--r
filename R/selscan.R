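#' H scan of pairwise haplotype identity-tract lengths
#'
#' For each focal SNP and every unordered pair of group haplotypes, finds
#' the maximal run of SNP identity containing the focal SNP (bounded by the
#' nearest discordant SNP on each side and truncated at the first/last SNP
#' of the chromosome) and records its bp length; H at the focal SNP is the
#' mean tract length over pairs. A pair discordant at the focal SNP itself
#' contributes 0.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param group sample ids (or haplotype row indices) forming the group.
#' @param chroms chromosomes to scan (default all).
#' @return data.frame (class \code{scan_track}): chrom, pos, H.
#' @export
h_scan <- function(panel, group, chroms = names(panel$chromosomes)) {
  rows <- if (is.character(group)) hap_rows(panel, samples = group) else
    as.integer(group)
  if (length(rows) < 2) stop("need >= 2 haplotypes")
  out <- list()
  for (chrom in chroms) {
    ch <- panel$chromosomes[[chrom]]
    pos <- ch$positions
    S <- length(pos)
    if (S < 2) next
    H <- ch$haplotypes[rows, , drop = FALSE]
    pr <- utils::combn(seq_len(nrow(H)), 2)
    acc <- numeric(S)
    seqS <- seq_len(S)
    monomorphic <- TRUE
    for (p in seq_len(ncol(pr))) {
      d <- which(H[pr[1, p], ] != H[pr[2, p], ])
      if (length(d) == 0) {
        acc <- acc + (pos[S] - pos[1])
        next
      }
      monomorphic <- FALSE
      k <- findInterval(seqS, d)          # discordant sites <= focal
      left <- c(0L, d)[k + 1L]            # nearest discordant at/left
      right <- c(d, S + 1L)[k + 1L]       # nearest discordant right of left
      at_disc <- seqS %in% d
      lo <- pmax(left + 1L, 1L)
      hi <- pmin(right - 1L, S)
      tract <- pos[hi] - pos[lo]
      tract[at_disc] <- 0
      acc <- acc + tract
    }
    if (monomorphic)
      warning("group is monomorphic on ", chrom,
              "; all tracts span the full SNP range")
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos,
                               H = acc / ncol(pr), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("scan_track", "data.frame")
  res
}

#' Haplotype-frequency-spectrum G statistics
#'
#' In windows of exactly \code{window} SNPs (tail windows dropped), computes
#' the window haplotype spectrum p1 >= p2 >= ... and the expected-
#' homozygosity statistics G1 = sum pi^2, G12 = (p1 + p2)^2 + sum_{i>=3}
#' pi^2 (soft-sweep sensitive), and G2/G1 = (G1 - p1^2)/G1.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param group sample ids or haplotype row indices.
#' @param window SNPs per window (default 200).
#' @param step SNPs between window starts (default \code{window}, i.e.
#'   non-overlapping).
#' @return data.frame: chrom, first/last SNP index, start/end bp, G1, G12,
#'   G2G1.
#' @export
g_stats <- function(panel, group, window = 200, step = window) {
  rows <- if (is.character(group)) hap_rows(panel, samples = group) else
    as.integer(group)
  if (length(rows) < 2) stop("need >= 2 haplotypes")
  out <- list()
  for (chrom in names(panel$chromosomes)) {
    ch <- panel$chromosomes[[chrom]]
    S <- length(ch$positions)
    if (S < window) next
    H <- ch$haplotypes[rows, , drop = FALSE]
    starts <- seq(1L, S - window + 1L, by = step)
    rows_out <- lapply(starts, function(a) {
      b <- a + window - 1L
      key <- apply(H[, a:b, drop = FALSE], 1, paste, collapse = "")
      p <- sort(as.vector(table(key)) / length(key), decreasing = TRUE)
      G1 <- sum(p^2)
      G12 <- (p[1] + ifelse(length(p) > 1, p[2], 0))^2 +
        if (length(p) > 2) sum(p[-(1:2)]^2) else 0
      data.frame(chrom = chrom, first_snp = a, last_snp = b,
                 start_bp = ch$positions[a], end_bp = ch$positions[b],
                 G1 = G1, G12 = G12, G2G1 = (G1 - p[1]^2) / G1,
                 stringsAsFactors = FALSE)
    })
    out[[chrom]] <- do.call(rbind, rows_out)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Accessible bp of [from, to) (0-based half-open) under sorted disjoint
# accessible intervals (matrix with columns start, end); NULL = everything.
interval_overlap <- function(from, to, acc) {
  if (is.null(acc)) return(to - from)
  starts <- acc[, 1]; ends <- acc[, 2]
  cum <- c(0, cumsum(ends - starts))
  clip <- function(x) {
    i <- findInterval(x, starts)
    ifelse(i == 0, 0, cum[i] + pmin(pmax(x - starts[i], 0), ends[i] - starts[i]))
  }
  clip(to) - clip(from)
}

#' Sliding-window Tajima's D
#'
#' Standard Tajima's D per window from the within-group segregating-site
#' count S and mean pairwise diversity, using the usual a1, a2, b1, b2, c1,
#' c2, e1, e2 constants. Windows with S = 0 or with 3 kb or less of
#' accessible sequence are emitted as NA.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param group sample ids or haplotype row indices (>= 4 haplotypes).
#' @param window,slide window size and slide in bp (defaults 10 kb / 100 bp).
#' @param accessible optional per-chromosome list of accessible-interval
#'   matrices (columns start, end; 0-based half-open); NULL = all
#'   accessible.
#' @param min_accessible minimum accessible bp per window (default 3000,
#'   exclusive bound).
#' @return data.frame (class \code{scan_track}): chrom, start, end
#'   (0-based half-open), S, pi, accessible_bp, D.
#' @export
tajima_d <- function(panel, group, window = 1e4, slide = 100,
                     accessible = NULL, min_accessible = 3000) {
  rows <- if (is.character(group)) hap_rows(panel, samples = group) else
    as.integer(group)
  n <- length(rows)
  if (n < 4) stop("need >= 4 haplotypes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  out <- list()
  for (chrom in names(panel$chromosomes)) {
    ch <- panel$chromosomes[[chrom]]
    len <- panel$chrom_lengths[[chrom]]
    p <- colMeans(ch$haplotypes[rows, , drop = FALSE])
    seg <- p > 0 & p < 1
    pos0 <- ch$positions[seg] - 1          # 0-based
    pi_site <- (n / (n - 1)) * 2 * p[seg] * (1 - p[seg])
    starts <- seq(0, max(0, len - window), by = slide)
    ends <- pmin(starts + window, len)
    cs_pi <- c(0, cumsum(pi_site))
    idx_lo <- findInterval(starts - 0.5, pos0) + 1L
    idx_hi <- findInterval(ends - 0.5, pos0)
    Sw <- pmax(idx_hi - idx_lo + 1L, 0L)
    piw <- ifelse(Sw > 0, cs_pi[idx_hi + 1L] - cs_pi[idx_lo], 0)
    accm <- if (is.null(accessible)) NULL else accessible[[chrom]]
    acc_bp <- interval_overlap(starts, ends, accm)
    thetaw <- Sw / a1
    denom <- sqrt(e1 * Sw + e2 * Sw * (Sw - 1))
    D <- ifelse(Sw == 0 | acc_bp <= min_accessible | denom == 0,
                NA_real_, (piw - thetaw) / denom)
    out[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               S = Sw, pi = piw, accessible_bp = acc_bp,
                               D = D, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("scan_track", "data.frame")
  res
}

#' Pairwise linkage disequilibrium, decay curve and baseline
#'
#' r^2 is the squared correlation of 0/1 allele indicators across phased
#' haplotypes. Sites are filtered to minor allele frequency >=
#' \code{min_maf}; intrachromosomal pairs up to \code{max_dist} apart feed
#' a decay curve of mean r^2 in distance bins of \code{bin_bp}; the
#' interchromosomal baseline is the mean r^2 across chromosomes after
#' greedily thinning sites to at least \code{thin_bp} apart.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param group sample ids or haplotype row indices (default: all samples).
#' @param min_maf minor-allele-frequency cutoff (default 0.2).
#' @param max_dist maximum pair distance in bp (default 999 kb).
#' @param bin_bp decay-bin width in bp (default 3).
#' @param thin_bp interchromosomal thinning distance (default 100 kb).
#' @param max_baseline_pairs cap on baseline pairs (sampled deterministically
#'   by stride if exceeded).
#' @return list with \code{decay} (data.frame bin_start, mean_r2, n_pairs),
#'   \code{baseline} (mean interchromosomal r^2), \code{n_sites} used per
#'   chromosome.
#' @export
ld_r2 <- function(panel, group = panel$samples, min_maf = 0.2,
                  max_dist = 999000, bin_bp = 3, thin_bp = 1e5,
                  max_baseline_pairs = 2e6) {
  rows <- if (is.character(group)) hap_rows(panel, samples = group) else
    as.integer(group)
  Zs <- list(); poss <- list()
  for (chrom in names(panel$chromosomes)) {
    H <- panel$chromosomes[[chrom]]$haplotypes[rows, , drop = FALSE]
    p <- colMeans(H)
    keep <- pmin(p, 1 - p) >= min_maf
    Zs[[chrom]] <- scale(H[, keep, drop = FALSE])
    poss[[chrom]] <- panel$chromosomes[[chrom]]$positions[keep]
  }
  nh <- length(rows)
  bin_sum <- bin_n <- numeric(0)
  nbins <- ceiling(max_dist / bin_bp)
  bin_sum <- numeric(nbins); bin_n <- numeric(nbins)
  chunk <- 512L
  for (chrom in names(Zs)) {
    Z <- Zs[[chrom]]; pos <- poss[[chrom]]
    S <- ncol(Z)
    if (S < 2) next
    for (a in seq(1L, S - 1L, by = chunk)) {
      b <- min(a + chunk - 1L, S - 1L)
      jmax <- findInterval(pos[a:b] + max_dist, pos)
      jtop <- max(jmax)
      if (jtop < a + 1L) next
      R <- crossprod(Z[, a:b, drop = FALSE],
                     Z[, (a + 1L):jtop, drop = FALSE]) / (nh - 1)
      for (ii in seq_len(b - a + 1L)) {
        i <- a + ii - 1L
        if (jmax[ii] <= i) next
        js <- (i + 1L):jmax[ii]
        d <- pos[js] - pos[i]
        r2 <- R[ii, js - a]^2
        bi <- pmin(floor(d / bin_bp) + 1L, nbins)
        add <- rowsum(r2, bi)
        cnt <- rowsum(rep(1, length(bi)), bi)
        at <- as.integer(rownames(add))
        bin_sum[at] <- bin_sum[at] + add[, 1]
        bin_n[at] <- bin_n[at] + cnt[, 1]
      }
    }
  }
  used <- which(bin_n > 0)
  decay <- data.frame(bin_start = (used - 1L) * bin_bp,
                      mean_r2 = bin_sum[used] / bin_n[used],
                      n_pairs = bin_n[used])
  # interchromosomal baseline on thinned sites
  thin <- function(pos) {
    keep <- integer(0); last <- -Inf
    for (i in seq_along(pos))
      if (pos[i] - last >= thin_bp) { keep <- c(keep, i); last <- pos[i] }
    keep
  }
  Zt <- lapply(names(Zs), function(chrom)
    Zs[[chrom]][, thin(poss[[chrom]]), drop = FALSE])
  base <- NA_real_
  if (length(Zt) > 1) {
    tot <- 0; cnt <- 0
    for (i in seq_along(Zt)) for (j in seq_along(Zt)) if (j > i) {
      if (!ncol(Zt[[i]]) || !ncol(Zt[[j]])) next
      R <- crossprod(Zt[[i]], Zt[[j]]) / (nh - 1)
      tot <- tot + sum(R^2); cnt <- cnt + length(R)
    }
    if (cnt > 0) base <- tot / cnt
  }
  list(decay = decay, baseline = base,
       n_sites = vapply(Zs, ncol, 0L))
}

#' LD clumps of scan loci
#'
#' Groups consecutive sites along each chromosome into LD blocks: a site
#' joins the current clump when its r^2 with the previous site exceeds
#' \code{r2_threshold}, otherwise it starts a new clump.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param group sample ids or haplotype rows used to compute r^2 (typically
#'   the union of both compared groups).
#' @param r2_threshold clumping threshold (default 0.8).
#' @return data.frame: chrom, pos, clump (id unique across chromosomes).
#' @export
ld_clumps <- function(panel, group = panel$samples, r2_threshold = 0.8) {
  rows <- if (is.character(group)) hap_rows(panel, samples = group) else
    as.integer(group)
  out <- list(); base <- 0L
  for (chrom in names(panel$chromosomes)) {
    H <- panel$chromosomes[[chrom]]$haplotypes[rows, , drop = FALSE]
    S <- ncol(H)
    if (!S) next
    cl <- integer(S); cl[1] <- 1L
    if (S > 1) {
      r2adj <- vapply(seq_len(S - 1), function(j) {
        r <- suppressWarnings(stats::cor(H[, j], H[, j + 1]))
        if (is.na(r)) 0 else r^2
      }, 0)
      for (j in 2:S)
        cl[j] <- if (r2adj[j - 1] > r2_threshold) cl[j - 1] else cl[j - 1] + 1L
    }
    out[[chrom]] <- data.frame(chrom = chrom,
                               pos = panel$chromosomes[[chrom]]$positions,
                               clump = cl + base, stringsAsFactors = FALSE)
    base <- base + cl[S]
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Permutation test for group differences in a selection scan
#'
#' Reduces each group's scan track to one representative value per LD clump
#' (the clump maximum), then, per chromosome, pools the clump values of
#' both groups and randomly reassigns them to the two groups (preserving
#' sizes) \code{n_perm} times; the absolute per-clump difference |Delta| is
#' recorded for every permutation, and the genome-wide threshold is the
#' requested percentile of the pooled permutation |Delta| distribution.
#' Observed clumps exceeding the threshold are reported.
#'
#' @param track_a,track_b scan tracks (chrom, pos, value column) for the two
#'   groups on identical coordinates; the value column is taken as the
#'   third column or \code{H} if present.
#' @param clumps clump assignment from \code{\link{ld_clumps}} on the same
#'   coordinates.
#' @param n_perm permutations per chromosome (default 1000).
#' @param percentile threshold percentile (default 99, i.e. alpha = 0.01).
#' @param seed integer seed.
#' @return list with \code{threshold}, \code{clumps} (data.frame with per-
#'   clump representatives, observed |Delta| and significance flag) and
#'   \code{n_perm}.
#' @export
delta_scan_permutation <- function(track_a, track_b, clumps, n_perm = 1000,
                                   percentile = 99, seed = 1L) {
  val <- function(tr) if ("H" %in% names(tr)) tr$H else tr[[3]]
  if (nrow(track_a) != nrow(track_b) ||
      any(track_a$chrom != track_b$chrom) || any(track_a$pos != track_b$pos))
    stop("group tracks on mismatched coordinates")
  if (nrow(clumps) != nrow(track_a) || any(clumps$pos != track_a$pos))
    stop("clump table on mismatched coordinates")
  va <- val(track_a); vb <- val(track_b)
  repa <- tapply(va, clumps$clump, max)
  repb <- tapply(vb, clumps$clump, max)
  cl_chrom <- tapply(clumps$chrom, clumps$clump, `[`, 1)
  cl_start <- tapply(clumps$pos, clumps$clump, min)
  cl_end <- tapply(clumps$pos, clumps$clump, max)
  perm_abs <- with_seed(seed, {
    unlist(lapply(unique(cl_chrom), function(ch) {
      ia <- which(cl_chrom == ch)
      pool <- sort(c(repa[ia], repb[ia]))  # canonical order: label-invariant
      C <- length(ia)
      unlist(lapply(seq_len(n_perm), function(b) {
        s <- sample(pool)
        abs(s[seq_len(C)] - s[C + seq_len(C)])
      }))
    }))
  })
  threshold <- stats::quantile(perm_abs, percentile / 100, names = FALSE,
                               type = 7)
  obs <- abs(repa - repb)
  res <- data.frame(clump = as.integer(names(repa)),
                    chrom = as.vector(cl_chrom),
                    start = as.vector(cl_start), end = as.vector(cl_end),
                    rep_a = as.vector(repa), rep_b = as.vector(repb),
                    delta = as.vector(obs),
                    significant = as.vector(obs > threshold),
                    stringsAsFactors = FALSE)
  list(threshold = threshold, clumps = res, n_perm = n_perm,
       percentile = percentile)
}
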