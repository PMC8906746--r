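#' Quartet specification for site-pattern statistics
#'
#' Defines the four groups (p1, p2, p3, outgroup) of an ABBA-BABA style
#' quartet as disjoint, non-empty sets of panel haplotypes.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param p1,p2,p3,outgroup each either a character vector of sample ids or
#'   an integer vector of haplotype row indices.
#' @return an object of class \code{quartet_spec} (named list of haplotype
#'   row indices).
#' @export
quartet_spec <- function(panel, p1, p2, p3, outgroup) {
  as_rows <- function(x) {
    if (is.character(x)) hap_rows(panel, samples = x) else as.integer(x)
  }
  q <- list(p1 = as_rows(p1), p2 = as_rows(p2), p3 = as_rows(p3),
            outgroup = as_rows(outgroup))
  if (any(lengths(q) == 0)) stop("quartet groups must be non-empty")
  all_rows <- unlist(q)
  if (anyDuplicated(all_rows)) stop("quartet groups must be disjoint")
  structure(q, class = "quartet_spec")
}

quartet_freqs <- function(panel, quartet, chrom) {
  list(p1 = derived_freq(panel, quartet$p1, chrom),
       p2 = derived_freq(panel, quartet$p2, chrom),
       p3 = derived_freq(panel, quartet$p3, chrom),
       pO = derived_freq(panel, quartet$outgroup, chrom))
}

abba <- function(p1, p2, p3, pO)
  (1 - p1) * p2 * p3 * (1 - pO) + p1 * (1 - p2) * (1 - p3) * pO
baba <- function(p1, p2, p3, pO) abba(p2, p1, p3, pO)

#' Patterson's D, f4 and block-jackknife Z for a quartet
#'
#' Per site, ABBA = (1-p1) p2 p3 (1-pO) + p1 (1-p2)(1-p3) pO and BABA is the
#' same expression with p1 and p2 swapped. D = sum(ABBA - BABA) /
#' sum(ABBA + BABA); f4 is the mean over sites of (p1-p2)(p3-pO). The Z
#' score comes from an equal-SNP-count block jackknife. By the reporting
#' sign convention, a negative f4 is reported as -f4 with p1 and p2 swapped
#' (field \code{f4_reported}).
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param quartet a \code{\link{quartet_spec}}.
#' @param n_blocks number of jackknife blocks (default 20).
#' @return list with D, Z, f4, f4_reported, counts of ABBA/BABA sums, and
#'   \code{defined} (FALSE when ABBA + BABA sums to zero).
#' @export
pattern_stats <- function(panel, quartet, n_blocks = 20) {
  ab <- ba <- f4s <- numeric(0)
  for (chrom in names(panel$chromosomes)) {
    fr <- quartet_freqs(panel, quartet, chrom)
    ab <- c(ab, abba(fr$p1, fr$p2, fr$p3, fr$pO))
    ba <- c(ba, baba(fr$p1, fr$p2, fr$p3, fr$pO))
    f4s <- c(f4s, (fr$p1 - fr$p2) * (fr$p3 - fr$pO))
  }
  tot <- sum(ab) + sum(ba)
  if (tot == 0)
    return(list(D = NA_real_, Z = NA_real_, f4 = mean(f4s),
                f4_reported = NA_real_, abba = sum(ab), baba = sum(ba),
                defined = FALSE))
  D <- (sum(ab) - sum(ba)) / tot
  n <- length(ab)
  m <- min(n_blocks, n)
  block <- ceiling(seq_along(ab) / (n / m))
  dj <- vapply(seq_len(m), function(j) {
    keep <- block != j
    (sum(ab[keep]) - sum(ba[keep])) / (sum(ab[keep]) + sum(ba[keep]))
  }, 0)
  dj <- dj[is.finite(dj)]
  m_eff <- length(dj)
  se <- if (m_eff > 1)
    sqrt((m_eff - 1) / m_eff * sum((dj - mean(dj))^2)) else NA_real_
  f4 <- mean(f4s)
  list(D = D, Z = if (is.finite(se) && se > 0) D / se else NA_real_, f4 = f4,
       f4_reported = abs(f4), abba = sum(ab), baba = sum(ba), defined = TRUE)
}

#' Windowed f_dM scan
#'
#' Computes the dynamic-donor f_dM statistic in sliding windows of
#' \code{window} SNPs advancing by \code{step} SNPs along each chromosome.
#' The numerator is the windowed sum of per-site (ABBA - BABA); the per-site
#' denominator substitutes the dynamic donor frequency pD: when p2 >= p1 it
#' is (ABBA - BABA) with p2 and p3 both replaced by pD = max(p2, p3), and
#' when p1 > p2 it is the negative of (ABBA - BABA) with p1 and p3 both
#' replaced by pD = max(p1, p3). Windows whose denominator sums to zero are
#' flagged undefined (NA). f_dM is positive for p3 -> p2 gene flow and
#' negative for p3 -> p1 gene flow.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param quartet a \code{\link{quartet_spec}}.
#' @param window,step window size and step in SNPs (defaults 100 / 25).
#' @return data.frame (class \code{fdm_track}): chrom, first/last SNP index,
#'   start/end/mid bp, n_snps, fdm.
#' @export
fdm_scan <- function(panel, quartet, window = 100, step = 25) {
  out <- list()
  for (chrom in names(panel$chromosomes)) {
    pos <- panel$chromosomes[[chrom]]$positions
    S <- length(pos)
    if (S < window) {
      warning("chromosome ", chrom, " has fewer than ", window,
              " SNPs; empty track")
      next
    }
    fr <- quartet_freqs(panel, quartet, chrom)
    num <- abba(fr$p1, fr$p2, fr$p3, fr$pO) - baba(fr$p1, fr$p2, fr$p3, fr$pO)
    pD23 <- pmax(fr$p2, fr$p3)
    pD13 <- pmax(fr$p1, fr$p3)
    den <- ifelse(fr$p2 >= fr$p1,
                  abba(fr$p1, pD23, pD23, fr$pO) -
                    baba(fr$p1, pD23, pD23, fr$pO),
                  -(abba(pD13, fr$p2, pD13, fr$pO) -
                      baba(pD13, fr$p2, pD13, fr$pO)))
    cn <- c(0, cumsum(num)); cd <- c(0, cumsum(den))
    starts <- seq.int(1L, as.integer(S - window + 1), by = as.integer(step))
    ends <- starts + as.integer(window) - 1L
    wn <- cn[ends + 1L] - cn[starts]
    wd <- cd[ends + 1L] - cd[starts]
    fdm <- ifelse(wd == 0, NA_real_, wn / wd)
    out[[chrom]] <- data.frame(
      chrom = chrom, first_snp = starts, last_snp = ends,
      start_bp = pos[starts], end_bp = pos[ends],
      mid_bp = (pos[starts] + pos[ends]) / 2,
      n_snps = window, fdm = fdm, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), first_snp = integer(),
               last_snp = integer(), start_bp = numeric(),
               end_bp = numeric(), mid_bp = numeric(), n_snps = integer(),
               fdm = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("fdm_track", "data.frame")
  res
}

# Winsorize x to a running median +/- k * 1.4826 * running MAD.
mad_winsorize <- function(x, k = 3, run = 15) {
  n <- length(x)
  half <- run %/% 2
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    med <- stats::median(v)
    madv <- stats::median(abs(v - med))
    lim <- k * 1.4826 * madv
    out[i] <- min(max(x[i], med - lim), med + lim)
  }
  out
}

# Optimal partitioning: minimize sum of segment RSS + penalty per segment.
changepoint_partition <- function(x, penalty) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  F <- c(0, rep(Inf, n))
  back <- integer(n)
  for (t in seq_len(n)) {
    s <- seq_len(t)
    segsum <- cs[t + 1] - cs[s]
    segrss <- (cs2[t + 1] - cs2[s]) - segsum^2 / (t - s + 1)
    v <- F[s] + segrss + penalty
    arg <- which.min(v)
    F[t + 1] <- v[arg]
    back[t] <- arg
  }
  ends <- integer(0)
  t <- n
  while (t > 0) { ends <- c(back[t], ends); t <- back[t] - 1L }
  starts <- ends
  cbind(start = starts, end = c(starts[-1] - 1L, n))
}

#' Robust segmentation of an f_dM track
#'
#' Winsorizes the windowed f_dM values to a running median plus/minus
#' \code{k} scaled MADs (so a single-window outlier cannot create its own
#' segment) and then applies least-squares changepoint segmentation with a
#' BIC-style penalty, reporting the mean winsorized f_dM of each segment.
#' Undefined windows are dropped before segmentation.
#'
#' @param track an \code{fdm_track} from \code{\link{fdm_scan}}.
#' @param k winsorization multiplier (default 3).
#' @param run running-window length in f_dM windows (default 15).
#' @param penalty per-changepoint penalty; default 2 * sigma^2 * log(T) with
#'   sigma estimated robustly from first differences.
#' @return data.frame (class \code{fdm_segments}): chrom, window index
#'   range, start/end bp (window midpoints), n_windows, mean_fdm.
#' @export
robust_segment <- function(track, k = 3, run = 15, penalty = NULL) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    tr <- track[track$chrom == chrom & !is.na(track$fdm), , drop = FALSE]
    if (!nrow(tr)) next
    w <- mad_winsorize(tr$fdm, k = k, run = run)
    n <- length(w)
    if (is.null(penalty)) {
      sig <- stats::median(abs(diff(w))) / (sqrt(2) * 0.6745)
      if (!is.finite(sig) || sig == 0) sig <- 1e-4
      pen <- 2 * sig^2 * log(max(n, 2))
    } else pen <- penalty
    seg <- changepoint_partition(w, pen)
    out[[chrom]] <- data.frame(
      chrom = chrom,
      first_window = seg[, "start"], last_window = seg[, "end"],
      start_bp = tr$mid_bp[seg[, "start"]], end_bp = tr$mid_bp[seg[, "end"]],
      n_windows = seg[, "end"] - seg[, "start"] + 1L,
      mean_fdm = vapply(seq_len(nrow(seg)), function(i)
        mean(w[seg[i, "start"]:seg[i, "end"]]), 0),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), first_window = integer(),
               last_window = integer(), start_bp = numeric(),
               end_bp = numeric(), n_windows = integer(),
               mean_fdm = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("fdm_segments", "data.frame")
  res
}

#' Call introgression tracts from f_dM segments
#'
#' Keeps segments with mean f_dM above \code{threshold} and merges adjacent
#' kept segments on the same chromosome whose bp gap is at most
#' \code{merge_gap}; the merged mean is the window-count-weighted mean, and
#' tract endpoints span the midpoints of the first and last constituent
#' windows.
#'
#' @param segments an \code{fdm_segments} table.
#' @param threshold minimum segment mean f_dM (default 0.2, the valley of
#'   the bimodal segment-mean distribution).
#' @param merge_gap maximum gap in bp to merge across (default 5000).
#' @return data.frame (class \code{tract_set}): chrom, start, end, mean_fdm,
#'   n_windows.
#' @export
call_tracts <- function(segments, threshold = 0.2, merge_gap = 5000) {
  keep <- segments[!is.na(segments$mean_fdm) &
                     segments$mean_fdm > threshold, , drop = FALSE]
  out <- list()
  for (chrom in unique(keep$chrom)) {
    sub <- keep[keep$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start_bp), , drop = FALSE]
    i <- 1L
    while (i <= nrow(sub)) {
      j <- i
      while (j < nrow(sub) && sub$start_bp[j + 1] - sub$end_bp[j] <= merge_gap)
        j <- j + 1L
      w <- sub$n_windows[i:j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = sub$start_bp[i], end = sub$end_bp[j],
        mean_fdm = sum(sub$mean_fdm[i:j] * w) / sum(w),
        n_windows = sum(w), stringsAsFactors = FALSE)
      i <- j + 1L
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mean_fdm = numeric(), n_windows = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("tract_set", "data.frame")
  res
}

#' Full introgression-tract scan for one focal sample
#'
#' Runs the fdM scan -> robust segmentation -> tract calling chain once per
#' candidate donor species (p3), takes the union of the called intervals,
#' and assigns each resulting tract a donor label by the local-tree
#' branch-length rule applied to both focal haplotypes
#' (\code{\link{assign_ancestry}}).
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param focal focal sample id (p2).
#' @param p1 sample ids of the non-focal conspecific comparison group.
#' @param donors named list: donor species label -> reference sample ids.
#' @param outgroup outgroup sample ids.
#' @param splendens_ref conspecific reference sample ids for ancestry
#'   assignment (defaults to \code{p1}).
#' @param window,step,threshold,merge_gap passed to the scan chain.
#' @return a \code{tract_set} with columns sample, chrom, start, end,
#'   mean_fdm, donor (label from the local-tree rule; "splendens" when
#'   neither haplotype qualifies), hap1_label, hap2_label.
#' @export
scan_sample_tracts <- function(panel, focal, p1, donors, outgroup,
                               splendens_ref = p1, window = 100, step = 25,
                               threshold = 0.2, merge_gap = 5000) {
  per_donor <- lapply(donors, function(d) {
    q <- quartet_spec(panel, p1 = p1, p2 = focal, p3 = d, outgroup = outgroup)
    call_tracts(robust_segment(fdm_scan(panel, q, window, step)),
                threshold = threshold, merge_gap = merge_gap)
  })
  allt <- do.call(rbind, per_donor)
  if (is.null(allt) || !nrow(allt)) {
    out <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      mean_fdm = numeric(), donor = character(),
                      hap1_label = character(), hap2_label = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("tract_set", "data.frame")
    return(out)
  }
  # union of intervals per chromosome (keep the max mean_fdm of overlaps)
  merged <- list()
  for (ch in unique(allt$chrom)) {
    tt <- allt[allt$chrom == ch, , drop = FALSE]
    tt <- tt[order(tt$start), , drop = FALSE]
    i <- 1L
    while (i <= nrow(tt)) {
      s <- tt$start[i]; e <- tt$end[i]; f <- tt$mean_fdm[i]; j <- i
      while (j < nrow(tt) && tt$start[j + 1] <= e) {
        j <- j + 1L
        e <- max(e, tt$end[j]); f <- max(f, tt$mean_fdm[j])
      }
      merged[[length(merged) + 1L]] <-
        data.frame(chrom = ch, start = s, end = e, mean_fdm = f,
                   stringsAsFactors = FALSE)
      i <- j + 1L
    }
  }
  out <- do.call(rbind, merged)
  species <- c(list(splendens = splendens_ref), donors)
  names(species)[1] <- "splendens"
  lab <- t(vapply(seq_len(nrow(out)), function(i) {
    a1 <- assign_ancestry(panel, out[i, ], paste0(focal, "_1"), species)
    a2 <- assign_ancestry(panel, out[i, ], paste0(focal, "_2"), species)
    c(a1$label, a2$label)
  }, c("", "")))
  donor_lab <- apply(lab, 1, function(x) {
    nons <- setdiff(x, c("splendens", "unassigned"))
    if (length(nons)) paste(unique(nons), collapse = ";") else
      if ("unassigned" %in% x) "unassigned" else "splendens"
  })
  out <- cbind(data.frame(sample = focal, stringsAsFactors = FALSE), out,
               donor = donor_lab, hap1_label = lab[, 1], hap2_label = lab[, 2],
               stringsAsFactors = FALSE)
  class(out) <- c("tract_set", "data.frame")
  out
}

#' Introgressed genome fraction
#'
#' Summed tract length divided by the accessible genome length. When the
#' tract table has a \code{sample} column the fraction is reported per
#' sample.
#'
#' @param tracts a \code{tract_set}.
#' @param accessible_length accessible genome length in bp (> 0).
#' @return a single fraction, or a named vector per sample.
#' @export
introgressed_fraction <- function(tracts, accessible_length) {
  if (accessible_length <= 0) stop("accessible length must be positive")
  if (!nrow(tracts)) return(0)
  len <- tracts$end - tracts$start
  if ("sample" %in% names(tracts))
    return(tapply(len, tracts$sample, sum) / accessible_length)
  sum(len) / accessible_length
}
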